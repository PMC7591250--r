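#' Load a protein reference catalog
#'
#' Reads a protein FASTA and its sidecar metadata TSV into a validated
#' reference catalog. The catalog defines the gene families quantified by the
#' pipeline in three categories: `trait_biosynthesis` (the merged core
#' phenazine biosynthesis families phzA_B, phzD, phzE, phzF, phzG),
#' `trait_degradation` (phdA, podA, each a single-gene trait) and `marker`
#' (ubiquitous single-copy genes that provide the total-bacteria baseline;
#' 25 by default). Record order in the FASTA is the database order used to
#' break ties between equal-scoring hits.
#'
#' phzC is deliberately not an admissible family: near-identical copies of
#' that gene occur in non-producer genomes, so its presence in the metadata
#' is a hard error.
#'
#' @param protein_fasta Path to a protein FASTA file. Every record id (first
#'   whitespace-delimited token of the header) must have a metadata row.
#' @param metadata_tsv Path to a tab-delimited file with a header row and
#'   columns `protein_id`, `family`, `category`, `species`, `order`, `genus`.
#' @param n_markers Expected number of marker families (default 25).
#'
#' @return An object of class `ref_catalog`: a list with elements
#'   `proteins` (data frame in database order, with sequences and lengths),
#'   `families` (per-family category, mean amino-acid length and member
#'   count) and `config`.
#' @export
load_catalog <- function(protein_fasta, metadata_tsv, n_markers = 25L) {
  seqs <- Biostrings::readAAStringSet(protein_fasta)
  if (length(seqs) == 0L) stop("no protein records in ", protein_fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicated protein id in FASTA: ", ids[duplicated(ids)][1L])
  }
  meta <- read.delim(metadata_tsv, stringsAsFactors = FALSE,
                     colClasses = "character")
  needed <- c("protein_id", "family", "category", "species", "order", "genus")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols)) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  orphan <- setdiff(ids, meta$protein_id)
  if (length(orphan)) {
    stop("no metadata row for FASTA record(s): ", paste(orphan, collapse = ", "))
  }
  meta <- meta[match(ids, meta$protein_id), , drop = FALSE]
  bad_cat <- setdiff(unique(meta$category), .CATEGORIES)
  if (length(bad_cat)) {
    stop("unknown category string(s): ", paste(bad_cat, collapse = ", "),
         " (expected ", paste(.CATEGORIES, collapse = ", "), ")")
  }
  if (any(meta$family == "phzC")) {
    stop("family 'phzC' is not allowed in the catalog: highly similar copies ",
         "occur in non-producer genomes, so phzC is excluded by the catalog ",
         "rules (quantify core genes phzA_B, phzD, phzE, phzF, phzG instead)")
  }
  # a family must belong to exactly one category
  fc <- unique(meta[, c("family", "category")])
  dup_fam <- fc$family[duplicated(fc$family)]
  if (length(dup_fam)) {
    stop("family assigned to more than one category: ",
         paste(unique(dup_fam), collapse = ", "))
  }
  proteins <- data.frame(
    protein_id = ids,
    family = meta$family,
    category = meta$category,
    species = meta$species,
    order = meta$order,
    genus = meta$genus,
    length_aa = Biostrings::width(seqs),
    sequence = as.character(seqs),
    stringsAsFactors = FALSE
  )
  if (any(proteins$length_aa < 1L)) {
    stop("zero-length protein sequence: ",
         proteins$protein_id[proteins$length_aa < 1L][1L])
  }
  rownames(proteins) <- NULL
  cat <- structure(
    list(proteins = proteins,
         families = .family_table(proteins),
         config = list(n_markers = as.integer(n_markers),
                       phz_families = .PHZ_FAMILIES,
                       degradation_families = .DEG_FAMILIES)),
    class = "ref_catalog")
  if (sum(cat$families$category == "marker") == 0L) {
    stop("catalog has no marker families; the total-bacteria baseline ",
         "requires the marker category")
  }
  cat
}

# family summary statistics in order of first appearance
.family_table <- function(proteins) {
  fam <- factor(proteins$family, levels = unique(proteins$family))
  data.frame(
    name = levels(fam),
    category = proteins$category[!duplicated(proteins$family)],
    mean_length_aa = as.numeric(tapply(proteins$length_aa, fam, mean)),
    n_members = as.integer(tapply(proteins$length_aa, fam, length)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Validate a reference catalog against the catalog rules
#'
#' Produces a report checking: the marker family count against the configured
#' number (default 25), presence of all configured trait biosynthesis
#' families, the limit of at most `max_strain_variants` members per species
#' within a family, and duplicated sequences. The report never throws; use
#' `strict = TRUE` to escalate any failed check to an error.
#'
#' @param catalog A `ref_catalog`.
#' @param n_markers Expected marker family count. Defaults to the catalog
#'   configuration.
#' @param phz_families Trait biosynthesis families expected to be present.
#' @param max_strain_variants Maximum members per (species, family)
#'   combination; the catalog construction rules cap strain-level variants
#'   at 10.
#' @param strict Error out if any check fails.
#'
#' @return A `catalog_validation` object: data frame of checks with `check`,
#'   `status` and `detail` columns, plus a `pass` attribute.
#' @export
validate_catalog <- function(catalog, n_markers = NULL, phz_families = NULL,
                             max_strain_variants = 10L, strict = FALSE) {
  stopifnot(inherits(catalog, "ref_catalog"))
  if (is.null(n_markers)) n_markers <- catalog$config$n_markers
  if (is.null(phz_families)) phz_families <- catalog$config$phz_families
  checks <- list()
  add <- function(check, ok, detail) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, status = if (ok) "pass" else "fail", detail = detail,
      stringsAsFactors = FALSE)
  }
  nm <- sum(catalog$families$category == "marker")
  add("marker_family_count", nm == n_markers,
      sprintf("%d marker families (expected %d)", nm, n_markers))
  present <- phz_families %in%
    catalog$families$name[catalog$families$category == "trait_biosynthesis"]
  add("trait_families_present", all(present),
      if (all(present)) sprintf("all %d biosynthesis families present",
                                length(phz_families))
      else paste("missing:", paste(phz_families[!present], collapse = ", ")))
  p <- catalog$proteins
  variants <- table(paste(p$species, p$family, sep = "\r"))
  over <- variants[variants > max_strain_variants]
  add("strain_variant_limit", length(over) == 0L,
      if (length(over) == 0L)
        sprintf("all species within %d variants per family", max_strain_variants)
      else paste0(length(over), " (species, family) pair(s) exceed ",
                  max_strain_variants, " variants; worst: ",
                  sub("\r", " / ", names(which.max(over))),
                  " with ", max(over)))
  dups <- sum(duplicated(p$sequence))
  add("duplicate_sequences", dups == 0L,
      sprintf("%d duplicated sequence(s)", dups))
  report <- do.call(rbind, checks)
  pass <- all(report$status == "pass")
  if (strict && !pass) {
    stop("catalog validation failed: ",
         paste(report$check[report$status == "fail"], collapse = ", "))
  }
  structure(report, pass = pass, class = c("catalog_validation", "data.frame"))
}

#' Export the catalog proteins for an external aligner
#'
#' Writes a single protein FASTA whose record order equals the catalog
#' database order, suitable for building a DIAMOND or BLAST protein database.
#' Ids round-trip through [load_catalog()].
#'
#' @param catalog A `ref_catalog`.
#' @param out Output FASTA path.
#' @return `out`, invisibly.
#' @export
write_search_fasta <- function(catalog, out) {
  stopifnot(inherits(catalog, "ref_catalog"))
  if (nrow(catalog$proteins) == 0L) stop("catalog is empty; nothing to write")
  seqs <- Biostrings::AAStringSet(catalog$proteins$sequence)
  names(seqs) <- catalog$proteins$protein_id
  Biostrings::writeXStringSet(seqs, out)
  invisible(out)
}

#' Write the catalog metadata sidecar TSV
#'
#' Companion to [write_search_fasta()]; the two outputs round-trip through
#' [load_catalog()].
#'
#' @param catalog A `ref_catalog`.
#' @param out Output TSV path.
#' @return `out`, invisibly.
#' @export
write_catalog_metadata <- function(catalog, out) {
  stopifnot(inherits(catalog, "ref_catalog"))
  cols <- c("protein_id", "family", "category", "species", "order", "genus")
  write.table(catalog$proteins[, cols], out, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(out)
}

#' @export
print.ref_catalog <- function(x, ...) {
  byc <- table(factor(x$families$category, levels = .CATEGORIES))
  cat("Reference catalog:", nrow(x$proteins), "proteins in",
      nrow(x$families), "gene families\n")
  cat(sprintf("  trait biosynthesis: %d families; trait degradation: %d; markers: %d (expected %d)\n",
              byc[["trait_biosynthesis"]], byc[["trait_degradation"]],
              byc[["marker"]], x$config$n_markers))
  cat("  species:", length(unique(x$proteins$species)),
      " orders:", length(unique(x$proteins$order)), "\n")
  invisible(x)
}

#' @export
summary.ref_catalog <- function(object, ...) {
  print(object)
  cat("\nFamilies:\n")
  print(object$families, row.names = FALSE)
  invisible(object$families)
}

#' @export
print.catalog_validation <- function(x, ...) {
  cat("Catalog validation:", if (attr(x, "pass")) "PASS" else "FAIL", "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
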