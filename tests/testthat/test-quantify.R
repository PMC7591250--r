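test_that("family counting pools hits and normalizes by family size", {
  set.seed(20)
  # one family with mean length 300 aa (0.9 kb), two member proteins
  rows <- data.frame(
    protein_id = c("pA", "pB", "m1"),
    family = c("phzD", "phzD", "marker_01"),
    category = c("trait_biosynthesis", "trait_biosynthesis", "marker"),
    species = "sp", order = "o", genus = "g",
    sequence = c(random_protein(280), random_protein(320),
                 random_protein(200)),
    stringsAsFactors = FALSE)
  cat <- make_catalog(rows, n_markers = 1L)
  # 100 hits split 60/40 between the two phzD proteins
  hits <- hits_for(cat, c(rep("pA", 60), rep("pB", 40)))
  counts <- count_by_family(hits, cat)
  phzD <- counts[counts$family == "phzD", ]
  expect_equal(phzD$read_count, 100L)
  expect_equal(phzD$rpk, 100 / 0.9)
  expect_equal(counts$rpk[counts$family == "marker_01"], 0)

  bad <- hits
  bad$target_id[1] <- "not_in_catalog"
  expect_error(count_by_family(bad, cat), "not_in_catalog")
})

test_that("marker score is the median of marker RPKs and is robust", {
  cat <- tiny_catalog(seed = 21)
  counts <- counts_from_rpk(
    setNames(1:25, sprintf("marker_%02d", 1:25)), cat)
  expect_equal(marker_score(counts), 13)

  flat <- counts_from_rpk(
    setNames(rep(10, 25), sprintf("marker_%02d", 1:25)), cat)
  expect_equal(marker_score(flat), 10)
  # inflating two families 1000x over the flat baseline changes nothing
  infl <- counts_from_rpk(
    setNames(c(rep(10, 23), 1e4, 1e4), sprintf("marker_%02d", 1:25)), cat)
  expect_equal(marker_score(infl), 10)

  zero <- counts_from_rpk(
    setNames(rep(0, 25), sprintf("marker_%02d", 1:25)), cat)
  expect_equal(marker_score(zero), 0)

  short <- counts[counts$family != "marker_01", ]
  class(short) <- class(counts)
  expect_error(marker_score(short), "expected 25")
})

test_that("producer score is a median over the five merged families", {
  cat <- tiny_catalog(seed = 22)
  fams <- c("phzA_B", "phzD", "phzE", "phzF", "phzG")
  # only two of five families carry (huge) signal: median is exactly 0
  spiky <- counts_from_rpk(setNames(c(0, 0, 0, 5e4, 5e4), fams), cat)
  expect_equal(trait_score(spiky, "trait_biosynthesis"), 0)

  flat <- counts_from_rpk(setNames(rep(2, 5), fams), cat)
  expect_equal(trait_score(flat, "trait_biosynthesis"), 2)

  deg <- counts_from_rpk(c(phdA = 0.7), cat)
  expect_equal(trait_score(deg, "phdA"), 0.7)
  expect_error(trait_score(flat, "phzQ"), "unknown trait")
})

test_that("trait fraction is a scale-invariant ratio with guarded zeros", {
  expect_equal(trait_fraction(0.05, 10), 0.005)
  expect_equal(trait_fraction(0, 10), 0)
  expect_equal(trait_fraction(7 * 0.05, 7 * 10), trait_fraction(0.05, 10))
  expect_error(trait_fraction(0.05, 0), "no bacterial signal")
  expect_warning(trait_fraction(20, 10), "exceeds 1")
})

test_that("ratio is invariant to uniform count rescaling and null reads", {
  cat <- tiny_catalog(seed = 23)
  targets <- c(rep("phzD|spA", 6), rep("phzA_B|spA", 5), rep("phzE|spA", 4),
               rep("phzF|spA", 5), rep("phzG|spA", 6),
               unlist(lapply(sprintf("marker_%02d|ref", 1:25), rep, 40)))
  h1 <- hits_for(cat, targets)
  c1 <- count_by_family(h1, cat)
  f1 <- trait_fraction(trait_score(c1), marker_score(c1))
  h7 <- hits_for(cat, rep(targets, 7))
  c7 <- count_by_family(h7, cat)
  f7 <- trait_fraction(trait_score(c7), marker_score(c7))
  expect_equal(f1, f7)
})

test_that("taxon breakdown normalizes size-corrected signal to 1", {
  set.seed(24)
  # two orders, equal-length families, signal 3:1
  rows <- data.frame(
    protein_id = c("a1", "b1", "m1"),
    family = c("phzD", "phzE", "marker_01"),
    category = c("trait_biosynthesis", "trait_biosynthesis", "marker"),
    species = c("spA", "spB", "ref"),
    order = c("OrderA", "OrderB", "unassigned"),
    genus = c("GenA", "GenB", "unassigned"),
    sequence = c(random_protein(200), random_protein(200),
                 random_protein(200)),
    stringsAsFactors = FALSE)
  cat <- make_catalog(rows, n_markers = 1L)
  hits <- hits_for(cat, c(rep("a1", 30), rep("b1", 10)))
  tb <- taxon_breakdown(hits, cat, "order")
  expect_equal(sum(tb), 1, tolerance = 1e-12)
  expect_equal(unname(tb[c("OrderA", "OrderB")]), c(0.75, 0.25))

  one <- taxon_breakdown(hits_for(cat, rep("a1", 5)), cat, "species")
  expect_equal(unname(one), 1)
  expect_named(one, "spA")

  none <- taxon_breakdown(hits_for(cat, rep("m1", 5)), cat, "order")
  expect_length(none, 0L)
})

test_that("classification thresholds are inclusive and ordered", {
  expect_equal(classify_sample(0.003), c(phz_rich = TRUE, high = FALSE))
  expect_equal(classify_sample(0.005), c(phz_rich = TRUE, high = TRUE))
  expect_equal(classify_sample(0.0025), c(phz_rich = TRUE, high = FALSE))
  expect_equal(classify_sample(0), c(phz_rich = FALSE, high = FALSE))
  expect_error(classify_sample(-0.1), "non-negative")
  # high implies phz_rich across a grid
  for (f in seq(0, 0.02, by = 0.0005)) {
    fl <- classify_sample(f)
    expect_true(!fl[["high"]] || fl[["phz_rich"]])
  }
})

test_that("bacterial load extrapolation reproduces the worked example", {
  res <- extrapolate_bacterial_load(6.5e6, 0.004)
  expect_equal(res$load, 1.625e9)
  expect_equal(res$order_of_magnitude, 9L)
  expect_equal(extrapolate_bacterial_load(1e6, 1)$load, 1e6)
  expect_equal(extrapolate_bacterial_load(1e6, 1)$order_of_magnitude, 6L)
  expect_error(extrapolate_bacterial_load(1e6, 0), "fraction")
})

test_that("two producers spiked 1%:4% are recovered in proportion", {
  refs <- small_refs()
  spec <- compose_community(
    refs, producer_fraction = c(producer_A = 0.01, producer_B = 0.04),
    seed = 33, library_size = 2e5)
  rs <- sample_reads(spec, as_strings = TRUE)
  hits <- filter_hits(best_hit_search(rs$reads, refs$catalog), 80)
  q <- quantify_sample(hits, refs$catalog, "mix")
  shares <- q$taxon_breakdown$species
  expect_equal(unname(shares["producer_A"]), 0.2, tolerance = 0.25)
  expect_lt(abs(shares[["producer_A"]] - 0.2), 0.05)
  expect_lt(abs(shares[["producer_B"]] - 0.8), 0.05)
  expect_equal(q$phz_fraction, 0.05, tolerance = 0.15)
  expect_true(q$flags[["high"]])
})
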