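#' Pool filtered hits into per-family counts and RPK
#'
#' Each hit increments exactly one gene family: the family of its target
#' protein. Counts are normalized to reads per kilobase (RPK) using the
#' family mean protein length expressed as nucleotide-equivalent kilobases
#' (`mean_length_aa * 3 / 1000`), so that long and short genes contribute
#' comparably. All catalog families are reported, including those with zero
#' hits.
#'
#' @param hits A `hit_table`, filtered at the working identity threshold.
#' @param catalog A `ref_catalog`.
#' @return A `family_counts` data frame with columns `family`, `category`,
#'   `mean_length_aa`, `read_count` and `rpk`.
#' @export
count_by_family <- function(hits, catalog) {
  stopifnot(inherits(hits, "hit_table"), inherits(catalog, "ref_catalog"))
  idx <- match(hits$target_id, catalog$proteins$protein_id)
  if (anyNA(idx)) {
    stop("hit targets protein absent from catalog: ",
         hits$target_id[is.na(idx)][1L])
  }
  fam <- factor(catalog$proteins$family[idx],
                levels = catalog$families$name)
  counts <- as.integer(table(fam))
  kb <- catalog$families$mean_length_aa * 3 / 1000
  structure(data.frame(
    family = catalog$families$name,
    category = catalog$families$category,
    mean_length_aa = catalog$families$mean_length_aa,
    read_count = counts,
    rpk = counts / kb,
    stringsAsFactors = FALSE
  ), class = c("family_counts", "data.frame"))
}

#' Total-bacteria marker score
#'
#' The median size-normalized (RPK) signal across the marker gene families
#' (25 by default). The median makes the baseline robust to non-specific
#' signal: inflating one or two marker families arbitrarily leaves the score
#' unchanged.
#'
#' @param counts A `family_counts` table.
#' @param n_markers Number of marker families the catalog is configured
#'   for; fewer present is an error.
#' @return Median marker RPK (non-negative scalar).
#' @export
marker_score <- function(counts, n_markers = 25L) {
  stopifnot(inherits(counts, "family_counts"))
  rpk <- counts$rpk[counts$category == "marker"]
  if (length(rpk) < n_markers) {
    stop("only ", length(rpk), " marker families in counts; expected ",
         n_markers)
  }
  median(rpk)
}

#' Trait score (median RPK of a trait category or single gene)
#'
#' For `"trait_biosynthesis"` (alias `"phz"`), the median RPK over the five
#' merged core families (phzA_B, phzD, phzE, phzF, phzG); the median is zero
#' whenever three or more families lack signal, which suppresses spurious
#' single-gene hits. For a degradation gene (`"phdA"` or `"podA"`) the score
#' is that family's RPK (a median of one value), so the two genes are
#' reported separately.
#'
#' @param counts A `family_counts` table.
#' @param trait `"trait_biosynthesis"`, `"phz"`, `"phdA"` or `"podA"` (or
#'   any single catalog family name).
#' @return Non-negative scalar score.
#' @export
trait_score <- function(counts, trait = "trait_biosynthesis") {
  stopifnot(inherits(counts, "family_counts"))
  if (trait %in% c("trait_biosynthesis", "phz")) {
    fams <- .PHZ_FAMILIES
    rpk <- counts$rpk[match(fams, counts$family)]
    if (anyNA(rpk)) {
      stop("biosynthesis families missing from counts: ",
           paste(fams[is.na(rpk)], collapse = ", "))
    }
    return(median(rpk))
  }
  i <- match(trait, counts$family)
  if (is.na(i)) stop("unknown trait name: ", trait)
  counts$rpk[i]
}

#' Trait fraction of total bacteria
#'
#' Divides a trait score by the marker (total-bacteria) score. Under the
#' single-copy assumption the ratio is interpreted as the fraction of
#' bacteria carrying the trait. The value is a proportion and is not
#' clamped: fractions above 1 indicate catalog or sample pathology and
#' trigger a warning.
#'
#' @param trait_score Non-negative trait score.
#' @param marker_score Positive marker score; zero is an error (no bacterial
#'   signal to normalize by).
#' @return The proportion `trait_score / marker_score`.
#' @export
trait_fraction <- function(trait_score, marker_score) {
  if (!is.numeric(marker_score) || marker_score <= 0) {
    stop("no bacterial signal: marker score must be > 0")
  }
  frac <- trait_score / marker_score
  if (is.finite(frac) && frac > 1) {
    warning("trait fraction exceeds 1 (", signif(frac, 3),
            "); check catalog and sample integrity")
  }
  frac
}

#' Taxonomic breakdown of trait-positive signal
#'
#' Distributes the trait signal across taxa: per taxon, the size-normalized
#' hit counts (count / family mean length in kb) of that taxon's
#' trait-family proteins are summed and the result is normalized to sum
#' to 1. Taxa with zero signal are omitted; with no trait hits at all the
#' result is an empty vector.
#'
#' @param hits A filtered `hit_table`.
#' @param catalog A `ref_catalog`.
#' @param level `"species"`, `"genus"` or `"order"`.
#' @param trait Trait category (default `"trait_biosynthesis"`) or a single
#'   family name such as `"phdA"`.
#' @return Named numeric vector of fractions summing to 1 (or empty).
#' @export
taxon_breakdown <- function(hits, catalog,
                            level = c("species", "genus", "order"),
                            trait = "trait_biosynthesis") {
  level <- match.arg(level)
  w <- .taxon_signal(hits, catalog, level, trait)
  if (length(w) == 0L || sum(w) == 0) return(setNames(numeric(0), character(0)))
  w <- w[w > 0]
  w / sum(w)
}

# unnormalized per-taxon size-normalized trait signal (used for pooling
# across samples in the survey layer)
.taxon_signal <- function(hits, catalog, level, trait = "trait_biosynthesis") {
  stopifnot(inherits(hits, "hit_table"), inherits(catalog, "ref_catalog"))
  p <- catalog$proteins
  fams <- if (trait %in% c("trait_biosynthesis", "phz")) {
    catalog$config$phz_families
  } else if (trait %in% c("trait_degradation")) {
    catalog$config$degradation_families
  } else trait
  idx <- match(hits$target_id, p$protein_id)
  if (anyNA(idx)) {
    stop("hit targets protein absent from catalog: ",
         hits$target_id[is.na(idx)][1L])
  }
  sel <- p$family[idx] %in% fams
  if (!any(sel)) return(setNames(numeric(0), character(0)))
  idx <- idx[sel]
  fam_kb <- catalog$families$mean_length_aa * 3 / 1000
  names(fam_kb) <- catalog$families$name
  weight <- 1 / fam_kb[p$family[idx]]
  taxon <- p[[level]][idx]
  vapply(split(weight, taxon), sum, numeric(1))
}

#' Classify a sample by its producer fraction
#'
#' A sample is "phz+ rich" at a producer fraction of at least 0.25% and
#' "high" at a fraction of at least 0.5% of total bacteria; both thresholds
#' are inclusive, and `high` implies `phz_rich`.
#'
#' @param fraction Producer fraction as a proportion (0.004 = 0.4%).
#' @return Logical vector with elements `phz_rich` and `high`.
#' @export
classify_sample <- function(fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0) {
    stop("fraction must be a single non-negative number")
  }
  c(phz_rich = fraction >= .PHZ_RICH_THRESHOLD,
    high = fraction >= .HIGH_THRESHOLD)
}

#' Extrapolate total bacterial load from counts of a quantified subgroup
#'
#' Combines a culture-based count of a trait-positive subpopulation
#' (cfu per gram) with that subpopulation's metagenomically estimated
#' fraction of all bacteria to extrapolate the total bacterial load per
#' gram of sample.
#'
#' @param cfu_per_gram Colony-forming units per gram for the subgroup.
#' @param fraction The subgroup's estimated fraction of all bacteria
#'   (proportion, > 0).
#' @return List with `load` (bacteria per gram) and `order_of_magnitude`
#'   (`round(log10(load))`).
#' @examples
#' extrapolate_bacterial_load(6.5e6, 0.004)  # ~1.6e9, order 9
#' @export
extrapolate_bacterial_load <- function(cfu_per_gram, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction <= 0) {
    stop("fraction must be > 0")
  }
  if (!is.numeric(cfu_per_gram) || cfu_per_gram < 0) {
    stop("cfu_per_gram must be non-negative")
  }
  load <- cfu_per_gram / fraction
  list(load = load, order_of_magnitude = as.integer(round(log10(load))))
}

#' Quantify a sample from its best-hit table
#'
#' The full per-sample estimator: pools filtered hits into family RPKs,
#' computes the marker (total-bacteria) score, the producer score (median
#' over the merged core biosynthesis families), per-gene degrader scores,
#' the corresponding fractions of total bacteria, taxonomic breakdowns of
#' the producer signal, and classification flags.
#'
#' @param hits A `hit_table`. If no identity filter has been applied yet,
#'   [filter_hits()] is applied at `min_identity`.
#' @param catalog A `ref_catalog`.
#' @param sample_id Sample label carried into outputs.
#' @param min_identity Percent identity filter applied to unfiltered input
#'   (default 80).
#' @return A `sample_quant` object: list with `sample_id`, `marker_score`,
#'   `phz_score`, `phz_fraction`, `degrader_fractions` (named by gene),
#'   `taxon_breakdown` (list with `species`, `genus`, `order`), `flags`,
#'   `counts` and `n_hits`.
#' @export
quantify_sample <- function(hits, catalog, sample_id = "sample",
                            min_identity = 80) {
  stopifnot(inherits(hits, "hit_table"), inherits(catalog, "ref_catalog"))
  if (is.na(attr(hits, "identity_threshold"))) {
    hits <- filter_hits(hits, min_identity)
  }
  counts <- count_by_family(hits, catalog)
  ms <- marker_score(counts, catalog$config$n_markers)
  ps <- trait_score(counts, "trait_biosynthesis")
  frac <- if (ms > 0) trait_fraction(ps, ms) else NA_real_
  deg <- vapply(catalog$config$degradation_families, function(g) {
    s <- trait_score(counts, g)
    if (ms > 0) s / ms else NA_real_
  }, numeric(1))
  tb <- lapply(c(species = "species", genus = "genus", order = "order"),
               function(lv) taxon_breakdown(hits, catalog, lv))
  structure(list(
    sample_id = sample_id,
    marker_score = ms,
    phz_score = ps,
    phz_fraction = frac,
    degrader_fractions = deg,
    taxon_breakdown = tb,
    taxon_signal = .taxon_signal(hits, catalog, "species"),
    flags = if (is.na(frac)) c(phz_rich = NA, high = NA)
            else classify_sample(frac),
    counts = counts,
    n_hits = nrow(hits),
    identity_threshold = attr(hits, "identity_threshold")
  ), class = "sample_quant")
}

#' @export
print.sample_quant <- function(x, ...) {
  cat("Sample quantification:", x$sample_id, "\n")
  cat(sprintf("  filtered hits: %d (identity >= %g%%)\n", x$n_hits,
              x$identity_threshold))
  cat(sprintf("  marker (total-bacteria) score: %.4g RPK\n", x$marker_score))
  cat(sprintf("  phz+ score: %.4g RPK -> fraction %.4g (%.3g%% of bacteria)\n",
              x$phz_score, x$phz_fraction, 100 * x$phz_fraction))
  for (g in names(x$degrader_fractions)) {
    cat(sprintf("  %s fraction: %.3g%%\n", g, 100 * x$degrader_fractions[[g]]))
  }
  cat(sprintf("  flags: phz_rich=%s high=%s\n", x$flags[["phz_rich"]],
              x$flags[["high"]]))
  ord <- x$taxon_breakdown$order
  if (length(ord)) {
    ord <- sort(ord, decreasing = TRUE)
    cat("  phz+ signal by order:",
        paste(sprintf("%s %.1f%%", names(ord), 100 * ord), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.sample_quant <- function(object, ...) {
  print(object)
  cat("\nFamily counts:\n")
  print(object$counts, row.names = FALSE)
  invisible(object$counts)
}

#' Write per-sample quantifications to TSV
#'
#' Writes one row per sample: `sample_id`, `marker_score`, `phz_score`,
#' `phz_fraction_pct`, `phdA_fraction_pct`, `podA_fraction_pct`, `phz_rich`,
#' `high`.
#'
#' @param quants A `sample_quant` or list of them.
#' @param out Output TSV path.
#' @return `out`, invisibly.
#' @export
write_quantification <- function(quants, out) {
  if (inherits(quants, "sample_quant")) quants <- list(quants)
  rows <- lapply(quants, function(q) {
    data.frame(sample_id = q$sample_id,
               marker_score = q$marker_score,
               phz_score = q$phz_score,
               phz_fraction_pct = 100 * q$phz_fraction,
               phdA_fraction_pct = 100 * q$degrader_fractions[["phdA"]],
               podA_fraction_pct = 100 * q$degrader_fractions[["podA"]],
               phz_rich = q$flags[["phz_rich"]],
               high = q$flags[["high"]],
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), out, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(out)
}

#' Write long-format taxonomy breakdowns to TSV
#'
#' Columns: `sample_id`, `level`, `taxon`, `fraction`.
#'
#' @param quants A `sample_quant` or list of them.
#' @param out Output TSV path.
#' @return `out`, invisibly.
#' @export
write_taxonomy <- function(quants, out) {
  if (inherits(quants, "sample_quant")) quants <- list(quants)
  rows <- list()
  for (q in quants) {
    for (lv in names(q$taxon_breakdown)) {
      tb <- q$taxon_breakdown[[lv]]
      if (!length(tb)) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = q$sample_id, level = lv, taxon = names(tb),
        fraction = as.numeric(tb), stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), level = character(),
               taxon = character(), fraction = numeric())
  write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
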