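# In-code fixtures shared across test files. Everything is generated
# programmatically under fixed seeds; nothing is read from disk.

# write a catalog FASTA + metadata TSV and load it
make_catalog <- function(proteins, n_markers = 25L) {
  # proteins: data.frame with protein_id, family, category, species, order,
  # genus, sequence
  fa <- tempfile(fileext = ".faa")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(paste0(">", proteins$protein_id, "\n", proteins$sequence), fa)
  write.table(proteins[, c("protein_id", "family", "category", "species",
                           "order", "genus")],
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  load_catalog(fa, tsv, n_markers = n_markers)
}

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

random_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

# deterministic reverse translation (first codon of each amino acid)
CODON1 <- local({
  gc <- Biostrings::GENETIC_CODE
  vapply(setNames(nm = AA20), function(a) names(gc)[gc == a][1L], "")
})
reverse_translate1 <- function(protein) {
  paste(CODON1[strsplit(protein, "")[[1]]], collapse = "")
}

# a small but fully-shaped catalog: n markers + 5 phz families (1 producer
# species each for two producers) + phdA/podA
tiny_catalog <- function(seed = 11, n_markers = 25L, len = 120L) {
  set.seed(seed)
  phz <- c("phzA_B", "phzD", "phzE", "phzF", "phzG")
  rows <- list()
  add <- function(id, fam, cat, sp, ord, gen) {
    rows[[length(rows) + 1L]] <<- data.frame(
      protein_id = id, family = fam, category = cat, species = sp,
      order = ord, genus = gen, sequence = random_protein(len),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_markers)) {
    add(sprintf("marker_%02d|ref", i), sprintf("marker_%02d", i), "marker",
        "reference_consensus", "unassigned", "unassigned")
  }
  for (f in phz) {
    add(paste0(f, "|spA"), f, "trait_biosynthesis", "species_A",
        "Pseudomonadales", "Pseudomonas")
    add(paste0(f, "|spB"), f, "trait_biosynthesis", "species_B",
        "Streptomycetales", "Streptomyces")
  }
  add("phdA|spC", "phdA", "trait_degradation", "species_C",
      "Corynebacteriales", "Mycobacterium")
  add("podA|spC", "podA", "trait_degradation", "species_C",
      "Corynebacteriales", "Mycobacterium")
  make_catalog(do.call(rbind, rows), n_markers = n_markers)
}

# shared synthetic reference set, built once per test run (reduced size so
# catalog + genome construction stays fast)
small_refs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_synthetic_references(seed = 101L, n_background = 6L,
                                          length_range = c(120L, 240L))
    }
    cache
  }
})

# outfmt-6 line writer for parser-driven fixtures
outfmt6_line <- function(qseqid, sseqid, pident, length,
                         mismatch = 0, gapopen = 0, qstart = 1, qend = 50,
                         sstart = 1, send = 50, evalue = 1e-20,
                         bitscore = 100) {
  paste(qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
        sstart, send, evalue, bitscore, sep = "\t")
}

write_outfmt6 <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# hit table addressed at a catalog: one line per (target, pident) pair
hits_for <- function(catalog, target_ids, pident = 100, aln_len = 50) {
  n <- length(target_ids)
  pident <- rep_len(pident, n)
  aln_len <- rep_len(aln_len, n)
  lines <- vapply(seq_len(n), function(i) {
    outfmt6_line(sprintf("q%05d", i), target_ids[i], pident[i], aln_len[i])
  }, "")
  filter_hits(parse_hit_table(write_outfmt6(lines)), 0)
}

# family_counts with prescribed marker/trait RPK values, via a catalog of
# unit-length families (mean length 1000/3 aa -> 1 kb -> rpk == read_count)
counts_from_rpk <- function(rpk_by_family, catalog) {
  counts <- count_by_family(hits_for(catalog,
                                     catalog$proteins$protein_id[0]), catalog)
  idx <- match(names(rpk_by_family), counts$family)
  stopifnot(!anyNA(idx))
  kb <- counts$mean_length_aa[idx] * 3 / 1000
  counts$read_count[idx] <- as.integer(round(rpk_by_family * kb))
  counts$rpk[idx] <- rpk_by_family
  counts
}
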