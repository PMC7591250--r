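#' Six-frame translation of a nucleotide sequence
#'
#' Translates the three forward frames and the three frames of the reverse
#' complement under the standard genetic code. Stop codons are rendered as
#' `*`; codons containing `N` translate to `X`; trailing partial codons are
#' dropped. Sequences shorter than 3 nt yield six empty peptides.
#'
#' @param sequence A single nucleotide string over `{A,C,G,T,N}`
#'   (case-insensitive). Other characters are an error.
#' @return A character vector of six peptides, named `F1`-`F3` (forward) and
#'   `R1`-`R3` (reverse complement).
#' @examples
#' translate_six_frames("ATGAAATGA")[["F1"]]  # "MK*"
#' @export
translate_six_frames <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < 3L) {
    # degenerate input, not an error: no complete codon in any frame
    if (!grepl("^[ACGTNacgtn]*$", sequence)) {
      stop("sequence contains characters outside {A,C,G,T,N}")
    }
    return(setNames(rep("", 6L), c("F1", "F2", "F3", "R1", "R2", "R3")))
  }
  setNames(cpp_translate6(sequence), c("F1", "F2", "F3", "R1", "R2", "R3"))
}

#' Reverse complement nucleotide strings
#'
#' @param sequences Character vector over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(sequences) {
  cpp_revcomp(as.character(sequences))
}

#' Read single-end reads from FASTA or FASTQ
#'
#' Thin wrapper over Biostrings readers (gzip-transparent). Paired-end data
#' should be handled upstream by supplying the read1 file only.
#'
#' @param path Reads file.
#' @param format `"fasta"` or `"fastq"`; guessed from the file name by
#'   default.
#' @return Named character vector of reads.
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  reads <- as.character(x)
  names(reads) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(reads))) {
    stop("duplicated read id: ", names(reads)[duplicated(names(reads))][1L])
  }
  reads
}

# internal constructor for hit tables
.hit_table <- function(df, provenance, identity_threshold = NA_real_) {
  structure(df,
            provenance = provenance,
            identity_threshold = identity_threshold,
            class = c("hit_table", "data.frame"))
}

#' Best-hit translated search against a reference catalog
#'
#' Maps each read, translated in all six frames, against every catalog
#' protein and reports the single best local alignment per read (the `-k 1`
#' best-hit convention). Seeding requires at least one exact amino-acid
#' k-mer shared with a reference protein; seeds are extended by banded
#' affine Smith-Waterman (BLOSUM62, gap open 11, gap extension 1) around the
#' seed diagonal. Reads with no seed, no positive-scoring alignment, or an
#' alignment shorter than `min_aln_len` columns are absent from the result.
#' Ties on alignment score are broken by catalog database order (first
#' occurrence wins).
#'
#' No identity filter is applied here; see [filter_hits()].
#'
#' @param reads Named character vector of reads (or unnamed; ids are then
#'   `read000001`...), or a file path accepted by [read_reads()].
#' @param catalog A `ref_catalog`.
#' @param kmer Exact seed length in amino acids (default 6).
#' @param band Half-width of the alignment band around the seed diagonal in
#'   diagonals (default 3); gaps shifting the diagonal by more than `band`
#'   are not considered.
#' @param min_aln_len Minimum alignment length in aligned columns
#'   (default 15); guards against spurious micro-alignments on short reads.
#'
#' @return A `hit_table`: data frame with columns `read_id`, `target_id`,
#'   `pident` (percent identity, matches / aligned columns x 100),
#'   `aln_len` and `score` (raw Smith-Waterman score), at most one row per
#'   read, with attributes `provenance = "internal"` and
#'   `identity_threshold = NA`.
#' @export
best_hit_search <- function(reads, catalog, kmer = 6L, band = 3L,
                            min_aln_len = 15L) {
  stopifnot(inherits(catalog, "ref_catalog"))
  if (nrow(catalog$proteins) == 0L) stop("catalog is empty")
  if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
      !grepl("^[ACGTNacgtn]+$", reads)) {
    reads <- read_reads(reads)
  }
  ids <- names(reads)
  reads <- as.character(reads)
  if (length(reads) == 0L) {
    return(.hit_table(data.frame(read_id = character(), target_id = character(),
                                 pident = numeric(), aln_len = integer(),
                                 score = numeric(), stringsAsFactors = FALSE),
                      "internal"))
  }
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  res <- cpp_search_reads(unname(reads), catalog$proteins$sequence,
                          as.integer(kmer), as.integer(band),
                          as.integer(min_aln_len))
  .hit_table(data.frame(
    read_id = ids[res$read],
    target_id = catalog$proteins$protein_id[res$target],
    pident = res$pident,
    aln_len = res$aln_len,
    score = as.numeric(res$score),
    stringsAsFactors = FALSE
  ), "internal")
}

#' Parse tabular protein-search output (BLAST outfmt 6)
#'
#' Reads the 12-column tabular format written by `blastx -outfmt 6` or
#' `diamond blastx` (qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore). When a read has several lines, only
#' the first is kept, mirroring the ordering of `-k 1` best-hit output.
#'
#' @param path Tabular hits file.
#' @param format Only `"blast-outfmt6"` is supported.
#' @return A `hit_table` with `provenance = "external"`; `score` carries the
#'   bit score.
#' @export
parse_hit_table <- function(path, format = "blast-outfmt6") {
  if (!identical(format, "blast-outfmt6")) {
    stop("unknown hit-table format: ", format)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(.hit_table(data.frame(read_id = character(), target_id = character(),
                                 pident = numeric(), aln_len = integer(),
                                 score = numeric(), stringsAsFactors = FALSE),
                      "external"))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    stop("malformed outfmt-6 line ", which(nf != 12L)[1L], ": expected 12 ",
         "tab-separated fields, found ", nf[nf != 12L][1L])
  }
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  pident <- suppressWarnings(as.numeric(m[, 3L]))
  alen <- suppressWarnings(as.integer(m[, 4L]))
  bitscore <- suppressWarnings(as.numeric(m[, 12L]))
  bad <- which(is.na(pident) | is.na(alen) | is.na(bitscore))
  if (length(bad)) {
    stop("malformed outfmt-6 line ", bad[1L], ": non-numeric pident/length/bitscore")
  }
  keep <- !duplicated(m[, 1L])
  .hit_table(data.frame(
    read_id = m[keep, 1L],
    target_id = m[keep, 2L],
    pident = pident[keep],
    aln_len = alen[keep],
    score = bitscore[keep],
    stringsAsFactors = FALSE
  ), "external")
}

#' Discard hits below an amino-acid identity threshold
#'
#' Translated reads mapping with less than `min_identity` percent amino-acid
#' identity are discarded; the boundary is kept (only strictly lower
#' identities are removed). Filtering is idempotent and monotone.
#'
#' @param hits A `hit_table` (best-hit reduced).
#' @param min_identity Threshold in percent, in `[0, 100]` (default 80).
#' @return The filtered `hit_table` with `identity_threshold` recorded.
#' @export
filter_hits <- function(hits, min_identity = 80) {
  stopifnot(inherits(hits, "hit_table"))
  if (!is.numeric(min_identity) || length(min_identity) != 1L ||
      is.na(min_identity) || min_identity < 0 || min_identity > 100) {
    stop("min_identity must be a single value in [0, 100]")
  }
  out <- hits[hits$pident >= min_identity, , drop = FALSE]
  rownames(out) <- NULL
  .hit_table(as.data.frame(out), attr(hits, "provenance"),
             as.numeric(min_identity))
}

#' @export
print.hit_table <- function(x, ...) {
  thr <- attr(x, "identity_threshold")
  cat(sprintf("Hit table: %d best hits (%s search%s)\n", nrow(x),
              attr(x, "provenance"),
              if (is.na(thr)) ", unfiltered"
              else sprintf(", identity >= %g%%", thr)))
  if (nrow(x)) print(head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}
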