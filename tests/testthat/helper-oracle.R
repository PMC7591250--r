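# Exhaustive Smith-Waterman oracle, independent of the package's aligner:
# Biostrings::pairwiseAlignment over all six frames x all catalog proteins,
# same matrix (BLOSUM62) and gap costs (open 11, extension 1), ties broken
# by catalog order then frame order.

sw_oracle_one <- function(read, catalog) {
  frames <- translate_six_frames(read)
  data(BLOSUM62, package = "Biostrings", envir = environment())
  best <- NULL
  for (p in seq_len(nrow(catalog$proteins))) {
    subject <- Biostrings::AAString(catalog$proteins$sequence[p])
    for (f in seq_along(frames)) {
      if (nchar(frames[[f]]) < 1L) next
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(frames[[f]]), subject, type = "local",
        substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1)
      sc <- Biostrings::score(pa)
      if (is.null(best) || sc > best$score) {
        best <- list(score = sc, target = p, frame = f,
                     matches = Biostrings::nmatch(pa),
                     aln_len = Biostrings::nchar(pa))
      }
    }
  }
  best
}

sw_oracle <- function(reads, catalog) {
  res <- lapply(reads, sw_oracle_one, catalog = catalog)
  data.frame(
    read_id = names(reads),
    target_id = catalog$proteins$protein_id[vapply(res, `[[`, 1, "target")],
    score = vapply(res, `[[`, 1, "score"),
    pident = 100 * vapply(res, `[[`, 1, "matches") /
      vapply(res, `[[`, 1, "aln_len"),
    aln_len = vapply(res, `[[`, 1L, "aln_len"),
    stringsAsFactors = FALSE)
}

# reads derived from catalog proteins at a given divergence (deterministic
# reverse translation; mutations never create indels)
mutated_reads <- function(catalog, n, divergence = 0.1, seg_aa = 50L,
                          seed = 5) {
  set.seed(seed)
  reads <- character(n)
  for (i in seq_len(n)) {
    p <- sample(nrow(catalog$proteins), 1L)
    aa <- strsplit(catalog$proteins$sequence[p], "")[[1]]
    if (length(aa) <= seg_aa) {
      seg <- aa
    } else {
      st <- sample(length(aa) - seg_aa + 1L, 1L)
      seg <- aa[st:(st + seg_aa - 1L)]
    }
    mut <- which(runif(length(seg)) < divergence)
    for (j in mut) seg[j] <- sample(setdiff(AA20, seg[j]), 1L)
    nt <- reverse_translate1(paste(seg, collapse = ""))
    if (runif(1) < 0.5) nt <- reverse_complement(nt)
    reads[i] <- nt
  }
  names(reads) <- sprintf("mr%04d", seq_len(n))
  reads
}
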