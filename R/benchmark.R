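# Simulated-community validation: run the full pipeline over a factorial
# design and compare estimates with the exact ground truth.

# family counts from filtered target indices (fast path used by the
# benchmark driver; same arithmetic as count_by_family)
.counts_from_targets <- function(target_idx, catalog) {
  fam_of <- factor(catalog$proteins$family, levels = catalog$families$name)
  counts <- tabulate(as.integer(fam_of)[target_idx],
                     nbins = nrow(catalog$families))
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

# species-level share of the producer signal (size-normalized), from
# filtered target indices
.producer_shares <- function(target_idx, catalog) {
  p <- catalog$proteins
  sel <- p$family[target_idx] %in% catalog$config$phz_families
  if (!any(sel)) return(setNames(numeric(0), character(0)))
  idx <- target_idx[sel]
  kb <- catalog$families$mean_length_aa * 3 / 1000
  names(kb) <- catalog$families$name
  w <- vapply(split(1 / kb[p$family[idx]], p$species[idx]), sum, numeric(1))
  w / sum(w)
}

#' Run the spike-in benchmark over a community design
#'
#' For every community in the design: sample reads, run the translated
#' best-hit search against the catalog, apply the identity filter
#' (80 percent by default), quantify, and pair the estimate with the exact
#' ground truth. Fully deterministic given the design seeds.
#'
#' @param design List of `community_spec` objects (see
#'   [factorial_design()]).
#' @param catalog The `ref_catalog` the communities were built against.
#' @param min_identity Percent amino-acid identity filter (default 80).
#' @param kmer,band,min_aln_len Search parameters, see [best_hit_search()].
#' @param verbose Print per-community progress.
#'
#' @return A `phz_benchmark` data frame with one row per community:
#'   condition columns (`community_id`, `coverage`, `abundance`, `combo`,
#'   `replicate`), `known_total` and `est_total` producer fractions,
#'   per-producer `known_<id>` / `est_<id>` columns, `known_degrader`, and
#'   per-gene degrader estimates `est_phdA`, `est_podA`.
#' @export
run_benchmark <- function(design, catalog, min_identity = 80, kmer = 6L,
                          band = 3L, min_aln_len = 15L, verbose = FALSE) {
  stopifnot(length(design) > 0, inherits(catalog, "ref_catalog"))
  producer_ids <- sort(unique(unlist(lapply(design, function(s) {
    names(s$ground_truth$producer_fractions)
  }))))
  prots <- catalog$proteins$sequence
  rows <- vector("list", length(design))
  for (i in seq_along(design)) {
    spec <- design[[i]]
    cid <- if (!is.null(spec$community_id)) spec$community_id
           else sprintf("c%04d", i)
    row <- tryCatch({
      rs <- sample_reads(spec)
      res <- cpp_search_fragments(rs$genomes, rs$species_idx, rs$start,
                                  rs$strand, rs$read_length, prots,
                                  as.integer(kmer), as.integer(band),
                                  as.integer(min_aln_len))
      keep <- res$pident >= min_identity
      targets <- res$target[keep]
      counts <- .counts_from_targets(targets, catalog)
      ms <- marker_score(counts, catalog$config$n_markers)
      ps <- trait_score(counts, "trait_biosynthesis")
      if (ms <= 0) stop("no marker signal")
      est_total <- ps / ms
      shares <- .producer_shares(targets, catalog)
      est_prod <- setNames(rep(0, length(producer_ids)), producer_ids)
      if (est_total > 0 && length(shares)) {
        est_prod[names(shares)] <- est_total * shares
      }
      est_deg <- vapply(catalog$config$degradation_families,
                        function(g) trait_score(counts, g) / ms, numeric(1))
      gt <- spec$ground_truth
      known_prod <- setNames(rep(0, length(producer_ids)), producer_ids)
      known_prod[names(gt$producer_fractions)] <- gt$producer_fractions
      cond <- spec$condition
      if (is.null(cond)) {
        cond <- list(coverage = spec$library_size,
                     abundance = gt$total_producer_fraction,
                     combo = paste(names(which(gt$producer_fractions > 0)),
                                   collapse = "+"),
                     replicate = NA_integer_)
      }
      out <- data.frame(community_id = cid,
                        coverage = cond$coverage,
                        abundance = cond$abundance,
                        combo = cond$combo,
                        replicate = cond$replicate,
                        known_total = gt$total_producer_fraction,
                        est_total = est_total,
                        known_degrader = gt$degrader_fraction,
                        stringsAsFactors = FALSE)
      for (p in producer_ids) {
        out[[paste0("known_", p)]] <- known_prod[[p]]
        out[[paste0("est_", p)]] <- est_prod[[p]]
      }
      for (g in names(est_deg)) out[[paste0("est_", g)]] <- est_deg[[g]]
      out
    }, error = function(e) {
      stop("community ", cid, " failed quantification: ",
           conditionMessage(e), call. = FALSE)
    })
    if (verbose) {
      message(sprintf("[%d/%d] %s known=%.4g est=%.4g", i, length(design),
                      cid, row$known_total, row$est_total))
    }
    rows[[i]] <- row
  }
  structure(do.call(rbind, rows),
            producer_ids = producer_ids,
            min_identity = min_identity,
            class = c("phz_benchmark", "data.frame"))
}

#' Accuracy metrics for a benchmark run
#'
#' Computes the Pearson correlation between known and estimated total
#' producer fractions, the distribution of per-species errors (known minus
#' estimated, restricted to species spiked above `error_floor`), the
#' maximum estimate over negative controls, and the operational detection
#' limit: the lowest designed abundance level whose replicate estimates all
#' strictly exceed that maximum.
#'
#' @param records A `phz_benchmark` table.
#' @param error_floor Per-species known fraction below which pairs are
#'   excluded from the error distribution (default 0.001, i.e. 0.1%).
#' @return A `benchmark_metrics` object: list with `pearson_r`,
#'   `per_species_error` (numeric vector), `negative_control_max`,
#'   `detection_limit` (a proportion, or `NA` if no level qualifies) and
#'   `n_records`.
#' @export
accuracy_metrics <- function(records, error_floor = 0.001) {
  stopifnot(inherits(records, "data.frame"),
            all(c("known_total", "est_total") %in% names(records)))
  known <- records$known_total
  est <- records$est_total
  if (length(unique(known)) < 2L || stats::sd(known) == 0) {
    stop("correlation undefined: known fractions are constant")
  }
  if (nrow(records) < 3L) stop("need at least 3 records")
  r <- cor(known, est, method = "pearson")

  producer_ids <- attr(records, "producer_ids")
  if (is.null(producer_ids)) {
    producer_ids <- sub("^known_", "",
                        grep("^known_producer", names(records), value = TRUE))
  }
  errs <- numeric(0)
  for (p in producer_ids) {
    kc <- records[[paste0("known_", p)]]
    ec <- records[[paste0("est_", p)]]
    if (is.null(kc) || is.null(ec)) next
    sel <- kc > error_floor
    errs <- c(errs, kc[sel] - ec[sel])
  }

  neg <- records$est_total[records$known_total == 0]
  neg_max <- if (length(neg)) max(neg) else NA_real_
  levels_pos <- sort(unique(records$known_total[records$known_total > 0]))
  detection <- NA_real_
  if (length(neg)) {
    for (lv in levels_pos) {
      if (all(records$est_total[records$known_total == lv] > neg_max)) {
        detection <- lv
        break
      }
    }
  }
  structure(list(pearson_r = r,
                 per_species_error = errs,
                 negative_control_max = neg_max,
                 detection_limit = detection,
                 n_records = nrow(records)),
            class = "benchmark_metrics")
}

#' @export
print.benchmark_metrics <- function(x, ...) {
  cat("Benchmark metrics over", x$n_records, "communities\n")
  cat(sprintf("  Pearson r (known vs estimated): %.4f\n", x$pearson_r))
  if (length(x$per_species_error)) {
    cat(sprintf("  per-species error (known - est): mean %.3g, sd %.3g (n=%d)\n",
                mean(x$per_species_error), stats::sd(x$per_species_error),
                length(x$per_species_error)))
  }
  cat(sprintf("  negative-control max estimate: %s\n",
              format(x$negative_control_max)))
  cat(sprintf("  detection limit: %s\n",
              if (is.na(x$detection_limit)) "not reached"
              else sprintf("%.3g%%", 100 * x$detection_limit)))
  invisible(x)
}

#' Per-gene degrader recovery
#'
#' Pairs the known degrader fraction of every community with the estimates
#' obtained independently from each degradation gene, and reports a Pearson
#' correlation per gene.
#'
#' @param records A `phz_benchmark` table.
#' @param genes Degradation gene names (default phdA and podA).
#' @return List with `table` (community_id, gene, known, estimated) and
#'   `pearson_r` (named per gene; `NA` when the known values are constant).
#'   The table is empty when the design contains no degrader.
#' @export
degrader_recovery <- function(records, genes = .DEG_FAMILIES) {
  stopifnot(inherits(records, "data.frame"))
  if (!"known_degrader" %in% names(records) ||
      all(records$known_degrader == 0)) {
    return(list(table = data.frame(community_id = character(),
                                   gene = character(), known = numeric(),
                                   estimated = numeric()),
                pearson_r = setNames(rep(NA_real_, length(genes)), genes)))
  }
  tabs <- lapply(genes, function(g) {
    est <- records[[paste0("est_", g)]]
    if (is.null(est)) return(NULL)
    data.frame(community_id = records$community_id, gene = g,
               known = records$known_degrader, estimated = est,
               stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, tabs)
  r <- vapply(genes, function(g) {
    sub <- table[table$gene == g, ]
    if (nrow(sub) < 3L || stats::sd(sub$known) == 0) return(NA_real_)
    cor(sub$known, sub$estimated)
  }, numeric(1))
  list(table = table, pearson_r = r)
}

#' @export
print.phz_benchmark <- function(x, ...) {
  cat("Benchmark results:", nrow(x), "communities\n")
  print(head(as.data.frame(x), 8L), row.names = FALSE)
  if (nrow(x) > 8L) cat("...", nrow(x) - 8L, "more rows\n")
  invisible(x)
}

#' @export
summary.phz_benchmark <- function(object, ...) {
  accuracy_metrics(object)
}

#' Scatter plot of known versus estimated producer fractions
#'
#' @param x A `phz_benchmark` table.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.phz_benchmark <- function(x, ...) {
  graphics::plot(100 * x$known_total, 100 * x$est_total,
                 xlab = "known phz+ fraction (%)",
                 ylab = "estimated phz+ fraction (%)",
                 pch = 19, col = "#00000088", ...)
  graphics::abline(0, 1, lty = 2, col = "red3")
  invisible(x)
}

#' Write benchmark records to TSV
#'
#' @param records A `phz_benchmark` table.
#' @param out Output TSV path.
#' @return `out`, invisibly.
#' @export
write_benchmark <- function(records, out) {
  write.table(as.data.frame(records), out, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(out)
}

#' Write benchmark metrics as JSON
#'
#' @param metrics A `benchmark_metrics` object.
#' @param out Output JSON path.
#' @return `out`, invisibly.
#' @export
write_metrics_json <- function(metrics, out) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("writing JSON requires the jsonlite package")
  }
  x <- list(pearson_r = metrics$pearson_r,
            per_species_error_mean = if (length(metrics$per_species_error))
              mean(metrics$per_species_error) else NA,
            per_species_error_sd = if (length(metrics$per_species_error) > 1)
              stats::sd(metrics$per_species_error) else NA,
            negative_control_max = metrics$negative_control_max,
            detection_limit = metrics$detection_limit,
            n_records = metrics$n_records)
  jsonlite::write_json(x, out, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out)
}
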