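test_that("largest-remainder read allocation is exact and conserved", {
  spec_counts <- phzscan:::.largest_remainder(c(0.25, 0.75), 1000)
  expect_identical(spec_counts, c(250L, 750L))
  thirds <- phzscan:::.largest_remainder(rep(1, 3) / 3, 100)
  expect_equal(sum(thirds), 100L)
  set.seed(30)
  for (i in 1:20) {
    k <- sample(2:40, 1)
    w <- rexp(k); w <- w / sum(w)
    L <- sample(10:5000, 1)
    n <- phzscan:::.largest_remainder(w, L)
    expect_equal(sum(n), L)
    expect_true(all(abs(n / L - w) <= 1 / L + 1e-12))
  }
})

test_that("community composition is exact, seeded and validated", {
  refs <- small_refs()
  spec <- compose_community(refs, producer_fraction = 0.05,
                            degrader_fraction = 0.01, seed = 41)
  expect_equal(sum(spec$members$fraction), 1, tolerance = 1e-12)
  gt <- spec$ground_truth
  expect_equal(sum(gt$producer_fractions), 0.05, tolerance = 1e-12)
  expect_equal(gt$degrader_fraction, 0.01)
  expect_true(all(spec$members$fraction >= 0))

  # same seed, same community; different seed, different background
  spec2 <- compose_community(refs, producer_fraction = 0.05,
                             degrader_fraction = 0.01, seed = 41)
  expect_identical(spec$members, spec2$members)
  spec3 <- compose_community(refs, producer_fraction = 0.05,
                             degrader_fraction = 0.01, seed = 42)
  expect_false(identical(spec$members$fraction, spec3$members$fraction))

  neg <- compose_community(refs, producer_fraction = 0, seed = 43)
  expect_true(all(neg$ground_truth$producer_fractions == 0))

  expect_error(compose_community(refs, producer_fraction = 0.7,
                                 degrader_fraction = 0.5, seed = 1),
               "more than 1")
  expect_error(compose_community(refs,
                                 producer_fraction = c(background_01 = 0.1),
                                 seed = 1),
               "not a producer")
})

test_that("read sampling conserves counts and matches the truth sidecar", {
  refs <- small_refs()
  spec <- compose_community(refs, producer_fraction = 0.02, seed = 44,
                            library_size = 5000)
  rs <- sample_reads(spec)
  expect_equal(sum(rs$truth$realized_reads), 5000L)
  expect_true(all(abs(rs$truth$realized_reads / 5000 -
                        rs$truth$requested_fraction) <= 1 / 5000 + 1e-12))
  expect_equal(length(rs$start), 5000L)
})

test_that("identical seeds give byte-identical reads files", {
  refs <- small_refs()
  spec <- compose_community(refs, producer_fraction = 0.03, seed = 45,
                            library_size = 1500)
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  sample_reads(spec, out = f1)
  sample_reads(spec, out = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(file.exists(paste0(f1, ".truth.tsv")))
  # a different seed gives different reads
  spec2 <- compose_community(refs, producer_fraction = 0.03, seed = 46,
                             library_size = 1500)
  f3 <- tempfile(fileext = ".fasta")
  sample_reads(spec2, out = f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("negative controls contain no reads overlapping trait loci", {
  refs <- small_refs()
  spec <- compose_community(refs, producer_fraction = 0, seed = 47,
                            library_size = 20000)
  rs <- sample_reads(spec)
  for (i in seq_along(rs$species_ids)) {
    sp <- refs$species[[rs$species_ids[i]]]
    trait_loci <- sp$embedded_families[
      !grepl("^marker_", sp$embedded_families$family), , drop = FALSE]
    if (nrow(trait_loci) == 0) next
    starts <- rs$start[rs$species_idx == i]
    for (j in seq_len(nrow(trait_loci))) {
      overlap <- starts <= trait_loci$end[j] &
        (starts + spec$read_length - 1L) >= trait_loci$start[j]
      expect_equal(sum(overlap), 0L)
    }
  }
  # and the pipeline sees zero trait signal
  res <- run_benchmark(list(spec), refs$catalog)
  expect_equal(res$est_total, 0)
})

test_that("divergence 0 maps embedded genes at 100% identity", {
  refs0 <- make_synthetic_references(seed = 55, n_background = 2L,
                                     n_producers = 1L, n_degraders = 0L,
                                     divergence = 0,
                                     length_range = c(120L, 200L))
  spec <- compose_community(refs0, producer_fraction = 0.2, seed = 56,
                            library_size = 4000)
  rs <- sample_reads(spec, as_strings = TRUE)
  hits <- best_hit_search(rs$reads, refs0$catalog)
  expect_gt(nrow(hits), 100)
  # fragments fully inside a gene align end to end without mismatch;
  # alignments crossing a gene boundary may pick up chance-positive columns
  expect_true(all(hits$pident[hits$aln_len == 50] == 100))
  expect_gt(mean(hits$pident == 100), 0.9)
})

test_that("excessive divergence warns and collapses trait signal", {
  expect_warning(
    refs25 <- make_synthetic_references(seed = 57, n_background = 4L,
                                        divergence = 0.25,
                                        marker_divergence = 0.05,
                                        length_range = c(120L, 240L)),
    "below the standard 80%")
  spec <- compose_community(refs25, producer_fraction = 0.04, seed = 58,
                            library_size = 1e5)
  res <- run_benchmark(list(spec), refs25$catalog)
  # at ~75% expected identity most trait reads fall below the 80% filter
  expect_lt(res$est_total, 0.5 * res$known_total)
})

test_that("factorial designs have the right cardinality and are seeded", {
  refs <- small_refs()
  d <- factorial_design(refs, coverages = 1e5,
                        abundances = c(0.001, 0.01),
                        combos = list("producer_A"),
                        replicates = 3L, seed = 9)
  expect_length(d, 6L)
  expect_identical(
    vapply(d, function(s) s$condition$combo, ""), rep("producer_A", 6))
  d2 <- factorial_design(refs, coverages = 1e5,
                         abundances = c(0.001, 0.01),
                         combos = list("producer_A"),
                         replicates = 3L, seed = 9)
  expect_identical(lapply(d, `[[`, "members"), lapply(d2, `[[`, "members"))
  # background is re-randomized between replicates
  expect_false(identical(d[[1]]$members$fraction, d[[2]]$members$fraction))
  # replicates of one condition share the exact designed abundance
  expect_equal(unique(vapply(d[1:3], function(s)
    s$ground_truth$total_producer_fraction, numeric(1))), 0.001)
})
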