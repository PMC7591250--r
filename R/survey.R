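# Survey layer: quantify many samples and aggregate by habitat
# (bulk soil vs rhizosphere).

.HABITAT_CLASSES <- c("soil", "rhizosphere")

#' Quantify a batch of samples
#'
#' Runs [quantify_sample()] over per-sample inputs (tabular hit files, hit
#' tables, or read vectors searched internally) and joins the results with
#' sample metadata. Individual sample failures are collected and reported,
#' not silently dropped; only zero successes is an error.
#'
#' @param inputs Named list (names are sample ids) whose elements are each
#'   one of: a path to a BLAST outfmt-6 hits file, a `hit_table`, or a
#'   character vector of reads.
#' @param catalog A `ref_catalog`.
#' @param metadata Data frame with columns `sample_id`, `habitat_class`
#'   (`"soil"` or `"rhizosphere"`) and optionally `sub_habitat`; every
#'   quantified sample must have a row.
#' @param min_identity Percent identity filter (default 80).
#' @param ... Passed to [best_hit_search()] for read inputs.
#'
#' @return A `survey_table` data frame (one row per successful sample:
#'   metadata columns plus `marker_score`, `phz_score`, `phz_fraction`,
#'   `phdA_fraction`, `podA_fraction`, `phz_rich`, `high`) with attributes
#'   `quants` (the underlying `sample_quant` objects) and `failures`
#'   (named character vector of error messages).
#' @export
quantify_batch <- function(inputs, catalog, metadata, min_identity = 80,
                           ...) {
  stopifnot(inherits(catalog, "ref_catalog"), length(inputs) > 0)
  if (is.null(names(inputs)) || any(!nzchar(names(inputs)))) {
    stop("inputs must be named by sample id")
  }
  needed <- c("sample_id", "habitat_class")
  if (!all(needed %in% names(metadata))) {
    stop("metadata needs columns: ", paste(needed, collapse = ", "))
  }
  bad_class <- setdiff(unique(metadata$habitat_class), .HABITAT_CLASSES)
  if (length(bad_class)) {
    stop("habitat_class must be one of ",
         paste(.HABITAT_CLASSES, collapse = ", "), "; found: ",
         paste(bad_class, collapse = ", "))
  }
  quants <- list()
  failures <- character(0)
  for (sid in names(inputs)) {
    q <- tryCatch({
      x <- inputs[[sid]]
      hits <- if (inherits(x, "hit_table")) {
        x
      } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
        parse_hit_table(x)
      } else if (is.character(x)) {
        best_hit_search(x, catalog, ...)
      } else {
        stop("unsupported input type for sample ", sid)
      }
      quantify_sample(hits, catalog, sample_id = sid,
                      min_identity = min_identity)
    }, error = function(e) conditionMessage(e))
    if (inherits(q, "sample_quant")) quants[[sid]] <- q
    else failures[sid] <- q
  }
  if (length(quants) == 0L) {
    stop("no sample quantified successfully; first failure: ", failures[1L])
  }
  no_meta <- setdiff(names(quants), metadata$sample_id)
  if (length(no_meta)) {
    stop("sample(s) without metadata row: ", paste(no_meta, collapse = ", "))
  }
  m <- metadata[match(names(quants), metadata$sample_id), , drop = FALSE]
  df <- data.frame(
    sample_id = names(quants),
    habitat_class = m$habitat_class,
    sub_habitat = if ("sub_habitat" %in% names(m)) m$sub_habitat
                  else NA_character_,
    marker_score = vapply(quants, `[[`, numeric(1), "marker_score"),
    phz_score = vapply(quants, `[[`, numeric(1), "phz_score"),
    phz_fraction = vapply(quants, `[[`, numeric(1), "phz_fraction"),
    phdA_fraction = vapply(quants, function(q)
      q$degrader_fractions[["phdA"]], numeric(1)),
    podA_fraction = vapply(quants, function(q)
      q$degrader_fractions[["podA"]], numeric(1)),
    phz_rich = vapply(quants, function(q) q$flags[["phz_rich"]], logical(1)),
    high = vapply(quants, function(q) q$flags[["high"]], logical(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(df, quants = quants, failures = failures,
            class = c("survey_table", "data.frame"))
}

#' Aggregate a survey by habitat class
#'
#' Summarizes producer fractions per habitat class (mean, median, n),
#' computes the fold difference of means (rhizosphere over soil), a
#' two-sided Wilcoxon rank-sum test between the classes, and the enrichment
#' of high-phz samples: the proportion of rhizosphere samples at or above
#' 0.5 percent divided by the corresponding soil proportion (reported as
#' `NA` with a note when the soil proportion is zero).
#'
#' @param table A `survey_table` (both habitat classes must be present).
#' @return A `habitat_summary` object: list with `per_class` (data frame),
#'   `fold_mean`, `wilcoxon_p`, `high_enrichment` and
#'   `high_enrichment_note`.
#' @export
aggregate_by_habitat <- function(table) {
  stopifnot(inherits(table, "data.frame"),
            all(c("habitat_class", "phz_fraction") %in% names(table)))
  present <- .HABITAT_CLASSES %in% table$habitat_class
  if (!all(present)) {
    stop("habitat class with zero samples: ",
         paste(.HABITAT_CLASSES[!present], collapse = ", "))
  }
  cls <- factor(table$habitat_class, levels = .HABITAT_CLASSES)
  per_class <- data.frame(
    habitat_class = .HABITAT_CLASSES,
    n = as.integer(table(cls)),
    mean_fraction = as.numeric(tapply(table$phz_fraction, cls, mean)),
    median_fraction = as.numeric(tapply(table$phz_fraction, cls, median)),
    prop_high = as.numeric(tapply(table$phz_fraction >= .HIGH_THRESHOLD,
                                  cls, mean)),
    stringsAsFactors = FALSE)
  soil <- per_class[per_class$habitat_class == "soil", ]
  rhiz <- per_class[per_class$habitat_class == "rhizosphere", ]
  fold <- rhiz$mean_fraction / soil$mean_fraction
  # two-sided rank-sum with normal approximation and tie correction
  p <- suppressWarnings(wilcox.test(
    table$phz_fraction[cls == "rhizosphere"],
    table$phz_fraction[cls == "soil"],
    alternative = "two.sided", exact = FALSE, correct = TRUE)$p.value)
  if (soil$prop_high > 0) {
    enrich <- rhiz$prop_high / soil$prop_high
    note <- NA_character_
  } else {
    enrich <- NA_real_
    note <- "undefined: no high-phz soil samples"
  }
  structure(list(per_class = per_class, fold_mean = fold, wilcoxon_p = p,
                 high_enrichment = enrich, high_enrichment_note = note),
            class = "habitat_summary")
}

#' @export
print.habitat_summary <- function(x, ...) {
  cat("Habitat summary\n")
  print(x$per_class, row.names = FALSE)
  cat(sprintf("  fold difference of means (rhizosphere/soil): %.3g\n",
              x$fold_mean))
  cat(sprintf("  Wilcoxon rank-sum p: %.3g\n", x$wilcoxon_p))
  cat(sprintf("  high-sample enrichment: %s\n",
              if (is.na(x$high_enrichment)) x$high_enrichment_note
              else sprintf("%.3g", x$high_enrichment)))
  invisible(x)
}

#' Taxon-by-habitat matrix of producer signal
#'
#' Pools the size-normalized trait signal of all samples within each
#' habitat class and renormalizes per habitat, yielding the relative
#' abundance of each taxon out of all trait-positive bacteria in that
#' habitat. Pooling hit-level signal (rather than averaging per-sample
#' breakdowns) weights samples by their trait signal; per-sample averaging
#' is available via `method = "mean"`.
#'
#' @param table A `survey_table` produced by [quantify_batch()].
#' @param level `"order"`, `"genus"` or `"species"`.
#' @param method `"pooled"` (default) or `"mean"`.
#' @return Matrix taxon x habitat of fractions; non-degenerate columns sum
#'   to 1. Habitats with zero trait signal give a zero column, flagged in
#'   the `zero_habitats` attribute.
#' @export
taxon_habitat_matrix <- function(table, level = c("order", "genus", "species"),
                                 method = c("pooled", "mean")) {
  level <- match.arg(level)
  method <- match.arg(method)
  quants <- attr(table, "quants")
  if (is.null(quants)) stop("table carries no per-sample quantifications")
  habitats <- .HABITAT_CLASSES[.HABITAT_CLASSES %in% table$habitat_class]
  signals <- lapply(setNames(nm = table$sample_id), function(sid) {
    q <- quants[[sid]]
    if (method == "pooled") {
      # species-level raw signal rolled up to the requested level needs the
      # per-quant breakdown at that level scaled by total signal
      tb <- q$taxon_breakdown[[level]]
      tot <- sum(q$taxon_signal)
      if (!length(tb) || tot == 0) return(numeric(0))
      tb * tot
    } else {
      q$taxon_breakdown[[level]]
    }
  })
  taxa <- sort(unique(unlist(lapply(signals, names))))
  m <- matrix(0, nrow = length(taxa), ncol = length(habitats),
              dimnames = list(taxa, habitats))
  zero <- character(0)
  for (h in habitats) {
    sids <- table$sample_id[table$habitat_class == h]
    acc <- setNames(rep(0, length(taxa)), taxa)
    nused <- 0L
    for (sid in sids) {
      s <- signals[[sid]]
      if (!length(s)) next
      acc[names(s)] <- acc[names(s)] + s
      nused <- nused + 1L
    }
    if (sum(acc) > 0) {
      m[, h] <- if (method == "mean" && nused > 0) acc / nused else acc
      m[, h] <- m[, h] / sum(m[, h])
    } else {
      zero <- c(zero, h)
    }
  }
  structure(m, zero_habitats = zero)
}

#' Write a habitat summary to TSV (and optionally JSON)
#'
#' @param summary A `habitat_summary`.
#' @param out Output TSV path for the per-class table; fold, rank-sum p and
#'   enrichment are appended as comment lines.
#' @param json Optional JSON output path (requires jsonlite).
#' @return `out`, invisibly.
#' @export
write_habitat_summary <- function(summary, out, json = NULL) {
  write.table(summary$per_class, out, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cat(sprintf("# fold_mean\t%g\n# wilcoxon_p\t%g\n# high_enrichment\t%s\n",
              summary$fold_mean, summary$wilcoxon_p,
              format(summary$high_enrichment)),
      file = out, append = TRUE)
  if (!is.null(json)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("writing JSON requires the jsonlite package")
    }
    jsonlite::write_json(
      list(per_class = summary$per_class, fold_mean = summary$fold_mean,
           wilcoxon_p = summary$wilcoxon_p,
           high_enrichment = summary$high_enrichment),
      json, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(out)
}
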