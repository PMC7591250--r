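meta8 <- data.frame(
  sample_id = c(paste0("wr", 1:5), paste0("bs", 1:3)),
  habitat_class = c(rep("rhizosphere", 5), rep("soil", 3)),
  sub_habitat = c(rep("wheat", 5), rep("field_soil", 3)),
  stringsAsFactors = FALSE)

# seeded 8-sample fixture: 5 rhizosphere samples with high producer levels,
# 3 bulk-soil samples with low levels
survey_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    refs <- small_refs()
    fr <- c(wr1 = 0.010, wr2 = 0.013, wr3 = 0.008, wr4 = 0.011, wr5 = 0.015,
            bs1 = 0.003, bs2 = 0.002, bs3 = 0.004)
    inputs <- lapply(seq_along(fr), function(i) {
      spec <- compose_community(refs, producer_fraction = unname(fr[i]),
                                degrader_fraction = 0.001, seed = 200 + i,
                                library_size = 5e4)
      sample_reads(spec, as_strings = TRUE)$reads
    })
    names(inputs) <- names(fr)
    cache <<- quantify_batch(inputs, refs$catalog, meta8)
    cache
  }
})

test_that("batch quantification joins metadata and keeps all samples", {
  tab <- survey_fixture()
  expect_s3_class(tab, "survey_table")
  expect_equal(nrow(tab), 8L)
  expect_length(attr(tab, "failures"), 0L)
  expect_true(all(tab$phz_fraction > 0))
  expect_true(all(tab$marker_score > 0))
})

test_that("failures are logged, not silently dropped", {
  cat <- tiny_catalog(seed = 81, n_markers = 25L)
  ok1 <- write_outfmt6(outfmt6_line("r1", "marker_01|ref", 95, 50))
  ok2 <- write_outfmt6(outfmt6_line("r1", "marker_02|ref", 95, 50))
  bad <- write_outfmt6("this is not\ta valid line")
  meta <- data.frame(sample_id = c("s1", "s2", "s3"),
                     habitat_class = c("soil", "soil", "rhizosphere"),
                     stringsAsFactors = FALSE)
  tab <- quantify_batch(list(s1 = ok1, s2 = bad, s3 = ok2), cat, meta)
  expect_equal(nrow(tab), 2L)
  expect_named(attr(tab, "failures"), "s2")

  expect_error(quantify_batch(list(s2 = bad), cat, meta), "no sample")
  badmeta <- meta
  badmeta$habitat_class[1] <- "ocean"
  expect_error(quantify_batch(list(s1 = ok1), cat, badmeta), "habitat_class")
})

test_that("habitat aggregation computes folds, rank-sum and enrichment", {
  tab <- survey_fixture()
  agg <- aggregate_by_habitat(tab)
  pc <- agg$per_class
  expect_equal(pc$n, c(3L, 5L))
  expect_gt(agg$fold_mean, 1)

  # synthetic tables exercise the exact arithmetic
  mk <- function(soil, rhizo) {
    structure(data.frame(
      sample_id = sprintf("s%02d", seq_len(length(soil) + length(rhizo))),
      habitat_class = c(rep("soil", length(soil)),
                        rep("rhizosphere", length(rhizo))),
      phz_fraction = c(soil, rhizo), stringsAsFactors = FALSE),
      class = c("survey_table", "data.frame"))
  }
  vals <- c(0.001, 0.002, 0.004, 0.006, 0.008)
  same <- aggregate_by_habitat(mk(vals, vals))
  expect_equal(same$fold_mean, 1)
  expect_equal(same$high_enrichment, 1)

  doubled <- aggregate_by_habitat(mk(vals, 2 * vals))
  expect_equal(doubled$fold_mean, 2)

  # scale invariance of fold and enrichment under a common factor
  f1 <- aggregate_by_habitat(mk(vals, 2 * vals))
  f2 <- aggregate_by_habitat(mk(0.5 * vals, vals))
  expect_equal(f1$fold_mean, f2$fold_mean)

  # zero high-phz soil samples: enrichment undefined, reported as such
  und <- aggregate_by_habitat(mk(c(0.001, 0.002), c(0.006, 0.007)))
  expect_true(is.na(und$high_enrichment))
  expect_match(und$high_enrichment_note, "undefined")

  expect_error(aggregate_by_habitat(mk(vals, numeric(0))), "zero samples")
})

test_that("a designed shift is detected by the rank-sum test at n=20", {
  set.seed(90)
  soil <- 0.001 * rexp(20) + 0.0005
  rhiz <- 3 * soil[sample(20)]
  tab <- structure(data.frame(
    sample_id = sprintf("s%02d", 1:40),
    habitat_class = rep(c("soil", "rhizosphere"), each = 20),
    phz_fraction = c(soil, rhiz), stringsAsFactors = FALSE),
    class = c("survey_table", "data.frame"))
  agg <- aggregate_by_habitat(tab)
  expect_lt(agg$wilcoxon_p, 0.05)
  expect_equal(agg$fold_mean, 3, tolerance = 0.3)
})

test_that("aggregation is invariant to sample order and zero-signal updates", {
  tab <- survey_fixture()
  shuf <- tab[sample(nrow(tab)), ]
  attr(shuf, "quants") <- attr(tab, "quants")
  class(shuf) <- class(tab)
  a <- aggregate_by_habitat(tab)
  b <- aggregate_by_habitat(shuf)
  expect_equal(a$per_class, b$per_class)
  expect_equal(a$wilcoxon_p, b$wilcoxon_p)

  # adding a zero-signal soil sample moves the soil mean as predicted
  extra <- tab[1, ]
  extra$sample_id <- "bs_zero"
  extra$habitat_class <- "soil"
  extra$phz_fraction <- 0
  tab2 <- rbind(as.data.frame(tab), as.data.frame(extra))
  class(tab2) <- class(tab)
  m_old <- a$per_class$mean_fraction[a$per_class$habitat_class == "soil"]
  n_old <- a$per_class$n[a$per_class$habitat_class == "soil"]
  c2 <- aggregate_by_habitat(tab2)$per_class
  expect_equal(c2$mean_fraction[c2$habitat_class == "soil"],
               m_old * n_old / (n_old + 1))
})

test_that("taxon-by-habitat pooling recovers a designed contrast", {
  tab <- survey_fixture()
  m <- taxon_habitat_matrix(tab, level = "order")
  expect_true(all(abs(colSums(m) - 1) < 1e-12))

  # hand-built contrast: producer_A signal in rhizosphere, producer_B in soil
  refs <- small_refs()
  mkreads <- function(frac, seed) {
    spec <- compose_community(refs, producer_fraction = frac, seed = seed,
                              library_size = 4e4)
    sample_reads(spec, as_strings = TRUE)$reads
  }
  inputs <- list(
    r1 = mkreads(c(producer_A = 0.02), 301),
    r2 = mkreads(c(producer_A = 0.02), 302),
    s1 = mkreads(c(producer_B = 0.02), 303),
    s2 = mkreads(c(producer_B = 0.02), 304))
  meta <- data.frame(sample_id = c("r1", "r2", "s1", "s2"),
                     habitat_class = c("rhizosphere", "rhizosphere",
                                       "soil", "soil"),
                     stringsAsFactors = FALSE)
  tab2 <- quantify_batch(inputs, refs$catalog, meta)
  m2 <- taxon_habitat_matrix(tab2, level = "species")
  expect_gt(m2["producer_A", "rhizosphere"], 0.95)
  expect_gt(m2["producer_B", "soil"], 0.95)
})
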