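test_that("identical configs give byte-identical outputs", {
  set.seed(21)
  ref100 <- sample(c("A", "C", "G", "T"), 600, replace = TRUE)[100]
  cfg <- simulation_config(seed = 21, subst_rate = 0.1, gap_rate = 0.02,
                           planted_shared = data.frame(
                             variant_id = "p1", pos = 100L,
                             alt = setdiff(c("A", "C", "G", "T"), ref100)[1],
                             species = "sp1", stringsAsFactors = FALSE))
  s1 <- simulate_alignment(cfg)
  s2 <- simulate_alignment(cfg)
  expect_identical(s1$maf, s2$maf)
  expect_identical(s1$truth, s2$truth)
  pan <- data.frame(variant_id = "p1", chrom = "chrT", pos = 100L,
                    ref = "C", alt = "A", stringsAsFactors = FALSE)
  a1 <- simulate_ancient(cfg, s1$ref_seq, pan)
  a2 <- simulate_ancient(cfg, s1$ref_seq, pan)
  expect_identical(a1$sams, a2$sams)
  expect_identical(a1$truth, a2$truth)
  p1 <- make_panel(50, seed = 9)
  p2 <- make_panel(50, seed = 9)
  expect_identical(p1$variants, p2$variants)
  expect_identical(p1$genome, p2$genome)
})

test_that("zero rates with no planting give an all-WILDTYPE truth and matrix", {
  cfg <- simulation_config(seed = 4, subst_rate = 0, gap_rate = 0,
                           probe_variants = data.frame(
                             variant_id = paste0("q", 1:5),
                             pos = c(30L, 90L, 150L, 310L, 550L),
                             alt = "N", stringsAsFactors = FALSE))
  # choose alts different from the (seed-determined) reference bases
  set.seed(4)
  ref <- sample(c("A", "C", "G", "T"), cfg$L, replace = TRUE)
  cfg$probe_variants$alt <- vapply(cfg$probe_variants$pos, function(p)
    setdiff(c("A", "C", "G", "T"), ref[p])[1], character(1))
  sim <- simulate_alignment(cfg)
  expect_true(all(sim$truth$state == "WILDTYPE"))
  m <- build_state_matrix(sim$variants, parse_maf(sim$maf))
  expect_true(all(m == "WILDTYPE"))
})

test_that("planted shared alleles are SHARED exactly at their cells", {
  cfg <- simulation_config(seed = 12, subst_rate = 0.15, gap_rate = 0.02,
                           planted_shared = data.frame(
                             variant_id = c("p1", "p2"),
                             pos = c(80L, 440L), alt = c("T", "G"),
                             species = c("sp1,sp3", "sp4"),
                             stringsAsFactors = FALSE))
  # avoid planting an alt equal to the reference base
  set.seed(12)
  ref <- sample(c("A", "C", "G", "T"), cfg$L, replace = TRUE)
  cfg$planted_shared$alt <- vapply(seq_len(2), function(i)
    setdiff(c("A", "C", "G", "T"), ref[cfg$planted_shared$pos[i]])[1],
    character(1))
  sim <- simulate_alignment(cfg)
  tr <- sim$truth
  shared <- tr[tr$state == "SHARED", c("variant_id", "species")]
  expect_setequal(paste(shared$variant_id, shared$species),
                  c("p1 sp1", "p1 sp3", "p2 sp4"))
  # and the pipeline recovers the truth cell-exactly end to end
  m <- build_state_matrix(sim$variants, parse_maf(sim$maf))
  got <- mapply(function(v, s) m[match(v, sim$variants$variant_id), s],
                tr$variant_id, tr$species)
  expect_equal(unname(got), tr$state)
})

test_that("planting validates species names and allele collisions", {
  bad_sp <- simulation_config(seed = 1, planted_shared = data.frame(
    variant_id = "x", pos = 10L, alt = "A", species = "nosuch",
    stringsAsFactors = FALSE))
  expect_error(simulate_alignment(bad_sp), "not in tree")
  out_of_range <- simulation_config(seed = 1, planted_shared = data.frame(
    variant_id = "x", pos = 10000L, alt = "A", species = "sp1",
    stringsAsFactors = FALSE))
  expect_error(simulate_alignment(out_of_range), "outside")
})

test_that("unequal-length planted gaps never come back SHARED", {
  cfg <- simulation_config(seed = 6, subst_rate = 0.05, gap_rate = 0.01,
                           planted_indels = data.frame(
                             variant_id = "d1", pos = 250L, k = 2L,
                             species = "sp1,sp2", unequal_species = "sp3,sp4",
                             stringsAsFactors = FALSE))
  sim <- simulate_alignment(cfg)
  tr <- sim$truth
  expect_equal(tr$state[tr$species %in% c("sp1", "sp2")], c("SHARED", "SHARED"))
  expect_equal(tr$state[tr$species %in% c("sp3", "sp4")], c("OTHER", "OTHER"))
  m <- build_state_matrix(sim$variants, parse_maf(sim$maf))
  row <- m[match("d1", sim$variants$variant_id), ]
  expect_equal(unname(row), tr$state[match(colnames(m), tr$species)])
})

test_that("e-lined blocks propagate their absence status to the truth", {
  cfg <- simulation_config(seed = 33, subst_rate = 0.05, gap_rate = 0,
                           n_blocks = 3L, eline_prob = 0.5,
                           probe_variants = data.frame(
                             variant_id = paste0("q", 1:3),
                             pos = c(100L, 300L, 500L), alt = "A",
                             stringsAsFactors = FALSE))
  sim <- simulate_alignment(cfg)
  m <- build_state_matrix(sim$variants, parse_maf(sim$maf))
  tr <- sim$truth
  got <- mapply(function(v, s) m[match(v, sim$variants$variant_id), s],
                tr$variant_id, tr$species)
  expect_equal(unname(got), tr$state)
  expect_true(any(tr$state %in% c("NO_ALIGN", "GAP_UNALIGNED")))
})

test_that("per-branch divergence matches the Jukes-Cantor closed form", {
  L <- 2000L
  rate <- 0.3
  for (b in c(0.2, 0.5)) {
    cfg <- simulation_config(seed = 77, L = L, subst_rate = rate,
                             gap_rate = 0,
                             tree = sprintf("(sp1:%g,sp2:%g);", b, b))
    sim <- simulate_alignment(cfg)
    p_expect <- 0.75 * (1 - exp(-4 / 3 * rate * b))
    se <- sqrt(p_expect * (1 - p_expect) / L)
    ref <- strsplit(sim$ref_seq, "")[[1]]
    for (s in c("sp1", "sp2")) {
      p_obs <- mean(sim$tips[[s]] != ref)
      expect_lt(abs(p_obs - p_expect), 3 * se)
    }
  }
})

test_that("carrier read sets show a binomial alt fraction near 0.5", {
  pan <- data.frame(variant_id = "v1", chrom = "chrT", pos = 300L,
                    ref = "C", alt = "T", gene = "G", stringsAsFactors = FALSE)
  cfg <- simulation_config(seed = 15, L = 600L,
                           ancient = list(n_samples = 1, coverage = 20,
                                          read_len = 60, damage_rate = 0,
                                          carriers = data.frame(
                                            sample_id = "anc001",
                                            variant_id = "v1",
                                            stringsAsFactors = FALSE)))
  genome <- paste(rep("C", 600), collapse = "")
  sim <- simulate_ancient(cfg, genome, pan)
  tmp <- tempfile(fileext = ".sam")
  writeLines(sim$sams$anc001, tmp)
  s <- read_sam(tmp, sample_id = "anc001")
  p <- pileup(s, "chrT", 300, min_bq = 0)
  n <- p$depth_total
  x <- p$counts[["T"]]
  # binomial(n, 0.5) check at ~3 sigma
  expect_gt(x / n, 0.5 - 3 * sqrt(0.25 / n))
  expect_lt(x / n, 0.5 + 3 * sqrt(0.25 / n))
})

test_that("coverage zero gives empty SAM bodies and no expected matches", {
  pan <- data.frame(variant_id = "v1", chrom = "chrT", pos = 50L, ref = "A",
                    alt = "G", gene = "G", stringsAsFactors = FALSE)
  cfg <- simulation_config(seed = 2, L = 200L,
                           ancient = list(n_samples = 2, coverage = 0,
                                          read_len = 40))
  sim <- simulate_ancient(cfg, paste(rep("A", 200), collapse = ""), pan)
  expect_true(all(vapply(sim$sams, length, integer(1)) == 2))  # header only
  expect_false(any(sim$truth$expected))
})

test_that("damage-induced false positives are confined to C>T / G>A variants", {
  # non-carrier sample; panel holds a C>T, a G>A, and a C>A control variant
  pan <- data.frame(variant_id = c("ct", "ga", "ca"), chrom = "chrT",
                    pos = c(100L, 200L, 300L), ref = c("C", "G", "C"),
                    alt = c("T", "A", "A"), gene = "G",
                    stringsAsFactors = FALSE)
  genome <- paste(c(rep("C", 150), rep("G", 100), rep("C", 150)),
                  collapse = "")
  cfg <- simulation_config(seed = 28, L = 400L,
                           ancient = list(n_samples = 20, coverage = 15,
                                          read_len = 40, damage_rate = 0.6))
  sim <- simulate_ancient(cfg, genome, pan)
  matches <- do.call(rbind, lapply(names(sim$sams), function(id) {
    tmp <- tempfile(fileext = ".sam")
    writeLines(sim$sams[[id]], tmp)
    match_variants(read_sam(tmp, sample_id = id), pan)
  }))
  expect_false(any(sim$truth$expected))        # nobody carries anything
  expect_gt(nrow(matches), 0)                  # but damage creates matches
  cls <- paste0(matches$ref, ">", matches$alt)
  expect_true(all(cls %in% c("C>T", "G>A")))
})

test_that("panel generation follows the requested category mix", {
  pan <- make_panel(1000, seed = 7)
  ann <- annotate_panel(pan$variants, pan$transcript)
  counts <- table(factor(ann$consequence, CONSEQUENCE_CATEGORIES))
  # multinomial 99% band per category around the published fractions
  n <- nrow(ann)
  for (k in CONSEQUENCE_CATEGORIES) {
    p <- DEFAULT_TYPE_PROPORTIONS[[k]]
    half <- 2.576 * sqrt(p * (1 - p) / n)
    expect_gte(counts[[k]] / n, max(0, p - half) - 1e-9)
    expect_lte(counts[[k]] / n, p + half + 1e-9)
  }
  # generated labels are true by construction
  expect_true(all(ann$consequence %in% CONSEQUENCE_CATEGORIES))
})

test_that("panel generator edge cases: n = 1 and bad proportions", {
  pan <- make_panel(1, seed = 3)
  expect_equal(nrow(pan$variants), 1)
  ann <- annotate_panel(pan$variants, pan$transcript)
  expect_true(ann$consequence %in% CONSEQUENCE_CATEGORIES)
  expect_error(make_panel(10, proportions = c("splice site" = 0.4)),
               "sum to 1")
})

test_that("noise records exercise the significance filter end to end", {
  pan <- make_panel(60, noise_frac = 0.5, seed = 13)
  kept <- filter_plp(pan$variants)
  expect_equal(nrow(kept), 60)
  expect_true(all(kept$clin_sig %in% c("pathogenic", "likely_pathogenic",
                                       "pathogenic/likely_pathogenic")))
})
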