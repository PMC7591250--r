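# Synthetic reference catalogs, genomes and spike-in communities with exact
# ground truth. Everything is driven by explicit integer seeds; the RNG state
# of the caller is always restored.

.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

# synonymous codon sets from the standard genetic code
.codon_sets <- function() {
  gc <- Biostrings::GENETIC_CODE
  lapply(setNames(nm = .AA20), function(a) names(gc)[gc == a])
}

# mutate a fraction of amino-acid positions to a different residue
.mutate_protein <- function(aa, divergence) {
  if (divergence <= 0) return(aa)
  n <- length(aa)
  hit <- which(runif(n) < divergence)
  for (i in hit) {
    aa[i] <- sample(setdiff(.AA20, aa[i]), 1L)
  }
  aa
}

# reverse-translate an amino-acid vector using random synonymous codons
.reverse_translate <- function(aa, codons) {
  paste(vapply(aa, function(a) {
    cs <- codons[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1)), collapse = "")
}

.random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# fixed panel of plausible taxonomy labels for background species
.BG_TAXA <- data.frame(
  order = c("Bacillales", "Rhizobiales", "Burkholderiales", "Actinomycetales",
            "Sphingomonadales", "Xanthomonadales", "Myxococcales",
            "Flavobacteriales", "Clostridiales", "Nitrosomonadales",
            "Caulobacterales", "Cytophagales", "Planctomycetales",
            "Verrucomicrobiales"),
  genus = c("Bacillus", "Rhizobium", "Burkholderia", "Arthrobacter",
            "Sphingomonas", "Lysobacter", "Myxococcus",
            "Flavobacterium", "Clostridium", "Nitrosomonas",
            "Caulobacter", "Cytophaga", "Planctomyces",
            "Verrucomicrobium"),
  stringsAsFactors = FALSE)

#' Generate a synthetic reference catalog and matching genomes
#'
#' Builds the fixture universe for simulation: a reference protein catalog
#' (universal single-copy marker families present in every genome, merged
#' core biosynthesis families carried only by producer species, and
#' degradation genes carried only by degrader species) together with
#' synthetic genomes in which each species embeds diverged copies of its
#' gene families.
#'
#' For each family a random ancestor protein is drawn (length uniform in
#' `length_range`). Trait families get a catalog-side variant per carrier
#' species (at `between_species_divergence` from the ancestor) so that
#' trait hits carry species-level taxonomy; each genome then embeds a copy
#' at `divergence` from its own catalog sequence, so reads map at
#' approximately `100 * (1 - divergence)` percent identity. Marker families
#' are represented in the catalog by the ancestor itself and embedded at
#' `marker_divergence` (markers are slow-evolving by construction, which is
#' what makes them usable as a universal baseline). Genes are embedded on a
#' random strand with random intergenic spacers, and all genomes are padded
#' with random sequence to a common length, so a species' read fraction
#' equals its cell fraction.
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param n_markers Number of marker families (default 25).
#' @param phz_families Names of the merged core biosynthesis families.
#' @param n_background Number of trait-free background species (default 28).
#' @param n_producers Number of producer species (default 2).
#' @param n_degraders Number of degrader species (default 1); each carries
#'   both phdA and podA.
#' @param divergence Amino-acid divergence between a trait gene copy and its
#'   catalog sequence (default 0.1). Values above 0.2 put expected mapping
#'   identity below the standard 80 percent threshold and trigger a warning
#'   (useful for threshold experiments).
#' @param marker_divergence Divergence of embedded marker copies from the
#'   catalog marker sequences (default `divergence / 2`).
#' @param between_species_divergence Divergence between trait catalog
#'   variants of different carrier species (default 0.15), which keeps
#'   species attribution of trait hits unambiguous.
#' @param length_range Ancestor protein length range in amino acids.
#' @param spacer_range Intergenic spacer length range in nucleotides.
#'
#' @return A `synthetic_references` object: list with `catalog`
#'   (a `ref_catalog`) and `species` (list of species records with fields
#'   `species_id`, `role`, `order`, `genus`, `genome` and
#'   `embedded_families`, a data frame of genomic gene coordinates).
#' @export
make_synthetic_references <- function(seed = 1L,
                                      n_markers = 25L,
                                      phz_families = .PHZ_FAMILIES,
                                      n_background = 28L,
                                      n_producers = 2L,
                                      n_degraders = 1L,
                                      divergence = 0.1,
                                      marker_divergence = divergence / 2,
                                      between_species_divergence = 0.15,
                                      length_range = c(150L, 450L),
                                      spacer_range = c(100L, 400L)) {
  stopifnot(n_markers >= 1L, n_background >= 0L, n_producers >= 0L,
            n_degraders >= 0L, divergence >= 0, divergence < 0.5)
  if (100 * (1 - divergence) < 80) {
    warning("divergence ", divergence, " puts expected mapping identity (",
            round(100 * (1 - divergence), 1), "%) below the standard 80% ",
            "threshold; trait reads will largely be filtered")
  }
  .with_seed(seed, {
    codons <- .codon_sets()
    marker_fams <- sprintf("marker_%02d", seq_len(n_markers))
    deg_fams <- .DEG_FAMILIES
    fams <- c(marker_fams, phz_families, deg_fams)
    anc <- lapply(setNames(nm = fams), function(f) {
      sample(.AA20, sample(length_range[1L]:length_range[2L], 1L),
             replace = TRUE)
    })

    producer_ids <- if (n_producers > 0)
      paste0("producer_", LETTERS[seq_len(n_producers)]) else character(0)
    degrader_ids <- if (n_degraders > 0)
      sprintf("degrader_%02d", seq_len(n_degraders)) else character(0)
    background_ids <- if (n_background > 0)
      sprintf("background_%02d", seq_len(n_background)) else character(0)

    prod_taxa <- data.frame(
      order = rep(c("Pseudomonadales", "Streptomycetales",
                    "Xanthomonadales", "Enterobacterales"),
                  length.out = max(n_producers, 1L)),
      genus = rep(c("Pseudomonas", "Streptomyces", "Dyella", "Serratia"),
                  length.out = max(n_producers, 1L)),
      stringsAsFactors = FALSE)
    bg_taxa <- .BG_TAXA[rep(seq_len(nrow(.BG_TAXA)),
                            length.out = max(n_background, 1L)), ]

    # catalog-side sequences
    prot <- list()
    add_prot <- function(id, family, category, species, ord, genus, aa) {
      prot[[length(prot) + 1L]] <<- list(id = id, family = family,
                                         category = category,
                                         species = species, ord = ord,
                                         genus = genus, aa = aa)
    }
    for (f in marker_fams) {
      add_prot(paste0(f, "|ref"), f, "marker", "reference_consensus",
               "unassigned", "unassigned", anc[[f]])
    }
    trait_variant <- list()  # [[species]][[family]] catalog-side aa
    for (i in seq_along(producer_ids)) {
      sp <- producer_ids[i]
      trait_variant[[sp]] <- list()
      for (f in phz_families) {
        v <- .mutate_protein(anc[[f]], between_species_divergence)
        trait_variant[[sp]][[f]] <- v
        add_prot(paste0(f, "|", sp), f, "trait_biosynthesis", sp,
                 prod_taxa$order[i], prod_taxa$genus[i], v)
      }
    }
    for (i in seq_along(degrader_ids)) {
      sp <- degrader_ids[i]
      trait_variant[[sp]] <- list()
      for (f in deg_fams) {
        v <- .mutate_protein(anc[[f]], between_species_divergence)
        trait_variant[[sp]][[f]] <- v
        add_prot(paste0(f, "|", sp), f, "trait_degradation", sp,
                 "Corynebacteriales", "Mycobacterium", v)
      }
    }

    # species definitions: which families each genome embeds
    species_defs <- c(
      lapply(seq_along(producer_ids), function(i) {
        list(id = producer_ids[i], role = "producer",
             ord = prod_taxa$order[i], genus = prod_taxa$genus[i],
             traits = phz_families)
      }),
      lapply(seq_along(degrader_ids), function(i) {
        list(id = degrader_ids[i], role = "degrader",
             ord = "Corynebacteriales", genus = "Mycobacterium",
             traits = deg_fams)
      }),
      lapply(seq_along(background_ids), function(i) {
        list(id = background_ids[i], role = "background",
             ord = bg_taxa$order[i], genus = bg_taxa$genus[i],
             traits = character(0))
      })
    )

    # assemble genomes: markers then trait genes, random strand, random
    # spacers; pad everything to a common length afterwards
    species <- lapply(species_defs, function(sd) {
      parts <- character(0)
      coords <- list()
      pos <- 0L
      for (f in c(marker_fams, sd$traits)) {
        spacer <- .random_nt(sample(spacer_range[1L]:spacer_range[2L], 1L))
        parts <- c(parts, spacer)
        pos <- pos + nchar(spacer)
        aa <- if (f %in% marker_fams) {
          .mutate_protein(anc[[f]], marker_divergence)
        } else {
          .mutate_protein(trait_variant[[sd$id]][[f]], divergence)
        }
        nt <- .reverse_translate(aa, codons)
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") nt <- cpp_revcomp(nt)
        parts <- c(parts, nt)
        coords[[length(coords) + 1L]] <- data.frame(
          family = f, start = pos + 1L, end = pos + nchar(nt),
          strand = strand, stringsAsFactors = FALSE)
        pos <- pos + nchar(nt)
      }
      list(species_id = sd$id, role = sd$role, order = sd$ord,
           genus = sd$genus, genome = paste(parts, collapse = ""),
           embedded_families = do.call(rbind, coords))
    })
    common_len <- max(vapply(species, function(s) nchar(s$genome),
                             numeric(1))) + 2000L
    species <- lapply(species, function(s) {
      pad <- common_len - nchar(s$genome)
      if (pad > 0) s$genome <- paste0(s$genome, .random_nt(pad))
      s
    })
    names(species) <- vapply(species, `[[`, "", "species_id")

    # write catalog through the standard loader so invariants hold
    fa <- tempfile(fileext = ".faa")
    tsv <- tempfile(fileext = ".tsv")
    on.exit(unlink(c(fa, tsv)), add = TRUE)
    writeLines(unlist(lapply(prot, function(p) {
      c(paste0(">", p$id), paste(p$aa, collapse = ""))
    })), fa)
    meta <- do.call(rbind, lapply(prot, function(p) {
      data.frame(protein_id = p$id, family = p$family, category = p$category,
                 species = p$species, order = p$ord, genus = p$genus,
                 stringsAsFactors = FALSE)
    }))
    write.table(meta, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    catalog <- load_catalog(fa, tsv, n_markers = n_markers)

    structure(list(catalog = catalog, species = species,
                   params = list(seed = as.integer(seed),
                                 divergence = divergence,
                                 marker_divergence = marker_divergence,
                                 between_species_divergence =
                                   between_species_divergence,
                                 genome_length = common_len)),
              class = "synthetic_references")
  })
}

#' @export
print.synthetic_references <- function(x, ...) {
  roles <- table(vapply(x$species, `[[`, "", "role"))
  cat("Synthetic reference set:", length(x$species), "species (",
      paste(names(roles), as.integer(roles), collapse = ", "), ")\n")
  cat("  genome length:", x$params$genome_length, "nt; trait divergence:",
      x$params$divergence, "; marker divergence:",
      x$params$marker_divergence, "\n")
  print(x$catalog)
  invisible(x)
}

# largest-remainder apportionment of library_size reads to fractions;
# exact conservation, deterministic tie-breaking by index
.largest_remainder <- function(fractions, total) {
  raw <- fractions * total
  base <- floor(raw)
  deficit <- as.integer(round(total - sum(base)))
  if (deficit > 0) {
    rem <- raw - base
    add <- order(-rem, seq_along(rem))[seq_len(deficit)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Compose a simulated community with known ground truth
#'
#' Sets the exact total producer fraction, splits it among the selected
#' producer species (uniformly at random unless an explicit named split is
#' given), assigns the degrader fraction, and distributes the remaining
#' mass over background species by a symmetric Dirichlet(1) draw, freshly
#' randomized per community.
#'
#' @param refs A `synthetic_references` object (or a list of species records
#'   of the same shape).
#' @param producer_fraction Either a single total producer read fraction, or
#'   a named vector of per-producer fractions (names are producer species
#'   ids; the total is their sum).
#' @param degrader_fraction Total degrader read fraction (default 0); split
#'   equally among degrader species.
#' @param seed Integer seed; identical seeds give identical communities.
#' @param library_size Number of reads to sample (default 5e5).
#' @param read_length Fragment length in nt (default 150).
#' @param producers Producer species ids receiving the spike when
#'   `producer_fraction` is a single total (default: all producers).
#'
#' @return A `community_spec`: list with `members` (species_id, role,
#'   fraction), `library_size`, `read_length`, `seed`, `ground_truth` (list
#'   with `total_producer_fraction`, `producer_fractions`,
#'   `degrader_fraction`) and a reference to the species set.
#' @export
compose_community <- function(refs, producer_fraction = 0,
                              degrader_fraction = 0, seed = 1L,
                              library_size = 5e5, read_length = 150L,
                              producers = NULL) {
  species <- if (inherits(refs, "synthetic_references")) refs$species else refs
  roles <- vapply(species, `[[`, "", "role")
  ids <- vapply(species, `[[`, "", "species_id")
  all_producers <- ids[roles == "producer"]
  all_degraders <- ids[roles == "degrader"]
  background <- ids[roles == "background"]

  if (!is.null(names(producer_fraction)) && length(producer_fraction) >= 1L &&
      all(nzchar(names(producer_fraction)))) {
    unknown <- setdiff(names(producer_fraction), all_producers)
    if (length(unknown)) stop("not a producer species: ",
                              paste(unknown, collapse = ", "))
    split <- producer_fraction
    total_prod <- sum(split)
  } else {
    stopifnot(length(producer_fraction) == 1L, producer_fraction >= 0)
    total_prod <- as.numeric(producer_fraction)
    split <- NULL
  }
  stopifnot(degrader_fraction >= 0)
  if (total_prod + degrader_fraction > 1) {
    stop("producer and degrader fractions sum to more than 1")
  }

  .with_seed(seed, {
    if (is.null(split)) {
      use <- if (is.null(producers)) all_producers else producers
      if (length(use) == 0L && total_prod > 0) {
        stop("no producer species available for a non-zero producer fraction")
      }
      if (length(use)) {
        w <- runif(length(use))
        split <- setNames(total_prod * w / sum(w), use)
      } else {
        split <- setNames(numeric(0), character(0))
      }
    }
    deg_split <- if (length(all_degraders) && degrader_fraction > 0) {
      setNames(rep(degrader_fraction / length(all_degraders),
                   length(all_degraders)), all_degraders)
    } else setNames(rep(0, length(all_degraders)), all_degraders)
    remaining <- 1 - total_prod - degrader_fraction
    bg_w <- rexp(length(background))           # symmetric Dirichlet(1)
    bg_split <- setNames(remaining * bg_w / sum(bg_w), background)

    fractions <- setNames(rep(0, length(ids)), ids)
    fractions[names(split)] <- split
    fractions[names(deg_split)] <- deg_split
    fractions[names(bg_split)] <- bg_split
    stopifnot(abs(sum(fractions) - 1) < 1e-9)

    structure(list(
      members = data.frame(species_id = ids, role = roles,
                           fraction = as.numeric(fractions[ids]),
                           stringsAsFactors = FALSE, row.names = NULL),
      library_size = as.integer(library_size),
      read_length = as.integer(read_length),
      seed = as.integer(seed),
      ground_truth = list(
        total_producer_fraction = total_prod,
        producer_fractions = {
          pf <- setNames(rep(0, length(all_producers)), all_producers)
          pf[names(split)] <- split
          pf
        },
        degrader_fraction = degrader_fraction),
      species = species
    ), class = "community_spec")
  })
}

#' @export
print.community_spec <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf("Community spec: %d reads x %d nt, seed %d\n",
              x$library_size, x$read_length, x$seed))
  cat(sprintf("  producers: %.4g%% total (%s); degraders: %.4g%%\n",
              100 * gt$total_producer_fraction,
              paste(sprintf("%s %.3g%%", names(gt$producer_fractions),
                            100 * gt$producer_fractions), collapse = ", "),
              100 * gt$degrader_fraction))
  cat("  members:", nrow(x$members), "species\n")
  invisible(x)
}

#' Sample shotgun reads from a simulated community
#'
#' Realizes per-species read counts by largest-remainder rounding of
#' `fraction * library_size` (ground truth is exact and conserved), then
#' samples error-free fragments of `read_length` nt with uniform start
#' positions and uniform strand. With `out` set, reads are written as FASTA
#' together with a ground-truth sidecar TSV (`<out>.truth.tsv` by default);
#' otherwise fragments are kept as genome coordinates, which the benchmark
#' consumes directly without materializing read strings.
#'
#' @param spec A `community_spec`.
#' @param out Optional FASTA output path.
#' @param truth_out Optional truth sidecar path.
#' @param as_strings Materialize read strings in memory even without `out`.
#' @return A `read_set`: list with `truth` (species_id, role,
#'   requested_fraction, realized_reads), `species_ids`, `species_idx`,
#'   `start`, `strand` (per read), `read_length`, and `reads` (character
#'   vector, only when materialized).
#' @export
sample_reads <- function(spec, out = NULL, truth_out = NULL,
                         as_strings = FALSE) {
  stopifnot(inherits(spec, "community_spec"))
  genomes <- vapply(spec$species, `[[`, "", "genome")
  glen <- nchar(genomes)
  if (any(glen < spec$read_length)) {
    stop("genome shorter than read length: ",
         names(genomes)[glen < spec$read_length][1L])
  }
  counts <- .largest_remainder(spec$members$fraction, spec$library_size)
  .with_seed(.derive_seed(spec$seed, 7L), {
    species_idx <- rep.int(seq_len(nrow(spec$members)), counts)
    n <- length(species_idx)
    start <- integer(n)
    off <- 0L
    for (i in seq_len(nrow(spec$members))) {
      if (counts[i] == 0L) next
      start[(off + 1L):(off + counts[i])] <-
        sample.int(glen[i] - spec$read_length + 1L, counts[i], replace = TRUE)
      off <- off + counts[i]
    }
    strand <- sample(c(1L, -1L), n, replace = TRUE)
    truth <- data.frame(species_id = spec$members$species_id,
                        role = spec$members$role,
                        requested_fraction = spec$members$fraction,
                        realized_reads = counts,
                        stringsAsFactors = FALSE)
    rs <- structure(list(truth = truth,
                         species_ids = spec$members$species_id,
                         species_idx = species_idx,
                         start = start, strand = strand,
                         read_length = spec$read_length,
                         genomes = unname(genomes),
                         reads = NULL),
                    class = "read_set")
    if (!is.null(out) || as_strings) {
      seqs <- cpp_extract_fragments(unname(genomes), species_idx, start,
                                    strand, spec$read_length)
      ids <- sprintf("%s_r%07d", spec$members$species_id[species_idx],
                     seq_len(n))
      names(seqs) <- ids
      rs$reads <- seqs
      if (!is.null(out)) {
        writeLines(paste0(">", ids, "\n", seqs), out)
        if (is.null(truth_out)) truth_out <- paste0(out, ".truth.tsv")
        write.table(truth, truth_out, sep = "\t", quote = FALSE,
                    row.names = FALSE)
      }
    }
    rs
  })
}

#' Factorial benchmark design
#'
#' Expands the full factorial of library coverages, total producer
#' abundances, producer combinations and technical replicates into a list
#' of community specifications. Background composition is re-randomized in
#' every replicate, and each community receives a random degrader frequency
#' drawn log-uniformly from `degrader_range` (when degrader species exist).
#' Deterministic given `seed`.
#'
#' With the default paper-scale arguments (4 coverages, 9 abundance levels
#' spanning 0 to 5 percent, 3 producer combinations, 12 replicates) the
#' design contains 1296 communities.
#'
#' @param refs A `synthetic_references` object.
#' @param coverages Library sizes in reads.
#' @param abundances Total producer fractions (proportions).
#' @param combos List of producer-species-id vectors; default: each producer
#'   alone plus all producers together.
#' @param replicates Technical replicates per condition (default 12).
#' @param seed Integer seed.
#' @param degrader_range Range for the log-uniform degrader frequency
#'   (default 0.05 to 5 percent); `NULL` for no degraders.
#' @param read_length Fragment length (default 150).
#' @return List of `community_spec` objects (class `community_design`), each
#'   carrying a `condition` field (coverage, abundance, combo, replicate).
#' @export
factorial_design <- function(refs,
                             coverages = c(5e6, 1e7, 1.5e7, 2e7),
                             abundances = c(0, 0.1, 0.25, 0.5, 1, 1.5,
                                            2.5, 3.5, 5) / 100,
                             combos = NULL,
                             replicates = 12L,
                             seed = 1L,
                             degrader_range = c(5e-4, 0.05),
                             read_length = 150L) {
  species <- if (inherits(refs, "synthetic_references")) refs$species else refs
  stopifnot(length(coverages) > 0, length(abundances) > 0, replicates >= 1L)
  roles <- vapply(species, `[[`, "", "role")
  ids <- vapply(species, `[[`, "", "species_id")
  producers <- ids[roles == "producer"]
  has_degrader <- any(roles == "degrader")
  if (is.null(combos)) {
    combos <- c(as.list(producers),
                if (length(producers) > 1L) list(producers))
  }
  if (length(combos) == 0L) stop("no producer combinations in design")
  combo_names <- vapply(combos, paste, "", collapse = "+")

  grid <- expand.grid(replicate = seq_len(replicates),
                      combo = seq_along(combos),
                      abundance = abundances,
                      coverage = coverages)
  design <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    seed_i <- .derive_seed(seed, i)
    deg <- if (has_degrader && !is.null(degrader_range)) {
      .with_seed(.derive_seed(seed_i, 13L),
                 10^runif(1, log10(degrader_range[1L]),
                          log10(degrader_range[2L])))
    } else 0
    spec <- compose_community(species, producer_fraction = g$abundance,
                              degrader_fraction = deg, seed = seed_i,
                              library_size = g$coverage,
                              read_length = read_length,
                              producers = combos[[g$combo]])
    spec$community_id <- sprintf("c%04d", i)
    spec$condition <- list(coverage = g$coverage, abundance = g$abundance,
                           combo = combo_names[g$combo],
                           replicate = g$replicate)
    design[[i]] <- spec
  }
  structure(design, class = c("community_design", "list"))
}

#' @export
print.community_design <- function(x, ...) {
  cov <- unique(vapply(x, function(s) s$condition$coverage, numeric(1)))
  ab <- unique(vapply(x, function(s) s$condition$abundance, numeric(1)))
  cb <- unique(vapply(x, function(s) s$condition$combo, character(1)))
  cat(sprintf("Factorial design: %d communities (%d coverages x %d abundances x %d combos)\n",
              length(x), length(cov), length(ab), length(cb)))
  invisible(x)
}

#' Desk-scale benchmark design
#'
#' The reduced factorial used for routine validation: coverages of 0.5M and
#' 1M reads, abundances 0, 0.1, 0.25, 0.5, 1, 2.5 and 5 percent, every
#' producer combination, three replicates. The full-scale design (5-20M
#' reads, nine abundance levels, twelve replicates; 1296 communities) is
#' available through [factorial_design()] directly.
#'
#' @param refs A `synthetic_references` object.
#' @param seed Integer seed.
#' @param replicates Technical replicates per condition (default 3).
#' @return List of `community_spec` objects.
#' @export
desk_design <- function(refs, seed = 1L, replicates = 3L) {
  factorial_design(refs,
                   coverages = c(5e5, 1e6),
                   abundances = c(0, 0.1, 0.25, 0.5, 1, 2.5, 5) / 100,
                   replicates = replicates,
                   seed = seed)
}
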