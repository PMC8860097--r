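test_that("pileup applies the quality floor inclusively and walks CIGARs", {
  # three reads over pos 10: A@q30, A@q0, G@q20; min_bq=1 drops only the q0 base
  lines <- sam_lines(
    sam_read("r1", 8, "5M", "TTATT", qstr(c(30, 30, 30, 30, 30))),
    sam_read("r2", 10, "3M", "ATT", qstr(c(0, 30, 30))),
    sam_read("r3", 6, "6M", "TTTTGT", qstr(rep(20, 6))))
  tmp <- tempfile(fileext = ".sam"); writeLines(lines, tmp)
  s <- read_sam(tmp, sample_id = "t1")
  p <- pileup(s, "chrS", 10, min_bq = 1)
  expect_equal(p$depth_total, 3)
  expect_equal(p$counts[["A"]], 1)
  expect_equal(p$counts[["G"]], 1)
  expect_false("T" %in% names(p$counts) && p$counts[["T"]] > 1)
  # at min_bq = 0 the q0 base comes back
  expect_equal(pileup(s, "chrS", 10, min_bq = 0)$counts[["A"]], 2)
  # no coverage
  p0 <- pileup(s, "chrS", 90, min_bq = 1)
  expect_equal(p0$depth_total, 0)
  expect_length(p0$counts, 0)
})

test_that("a position inside a deletion contributes depth but no base", {
  lines <- sam_lines(sam_read("r1", 5, "3M2D3M", "AAACCC", qstr(rep(30, 6))))
  tmp <- tempfile(fileext = ".sam"); writeLines(lines, tmp)
  s <- read_sam(tmp)
  p <- pileup(s, "chrS", 9, min_bq = 1)   # ref pos 8-9 are deleted
  expect_equal(p$depth_total, 1)
  expect_length(p$counts, 0)
  # and the base after the deletion maps correctly (pos 10 = first C)
  expect_equal(pileup(s, "chrS", 10, min_bq = 1)$counts[["C"]], 1)
})

test_that("malformed reads are skipped with a warning, not fatal", {
  lines <- sam_lines(
    sam_read("ok", 5, "4M", "ACGT", qstr(rep(30, 4))),
    "short\trow",
    sam_read("bad", 5, "4M", "ACGT", qstr(rep(30, 3))))
  tmp <- tempfile(fileext = ".sam"); writeLines(lines, tmp)
  expect_warning(expect_warning(s <- read_sam(tmp), "fewer than 11"),
                 "seq.*qual|qual")
  expect_equal(nrow(s$reads), 1)
})

test_that("pileup agrees exactly with the per-read expansion oracle", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    reads <- do.call(rbind, lapply(seq_len(n), function(i) {
      pos <- sample(1:60, 1)
      len <- sample(5:15, 1)
      cigar <- if (runif(1) < 0.7) paste0(len, "M")
      else if (runif(1) < 0.5)
        paste0(sample(2:4, 1), "M", sample(1:3, 1), "D", len, "M")
      else paste0(sample(2:4, 1), "M", sample(1:3, 1), "I", len, "M")
      ops <- plptrace:::cigar_ops(cigar)
      qlen <- sum(ops$len[ops$op %in% c("M", "I", "S")])
      data.frame(qname = paste0("r", i), flag = 0L, rname = "chrR",
                 pos = pos, mapq = 30L, cigar = cigar,
                 seq = paste(sample(c("A", "C", "G", "T"), qlen, TRUE),
                             collapse = ""),
                 qual = qstr(sample(c(0L, 1L, 20L, 30L), qlen, TRUE)),
                 stringsAsFactors = FALSE)
    }))
    s <- ancient_sample(reads, "rand")
    norm <- function(x) if (length(x) == 0) integer(0) else x[order(names(x))]
    for (pos in sample(1:70, 10)) {
      got <- pileup(s, "chrR", pos, min_bq = 1)
      exp <- bf_pileup(reads, "chrR", pos, min_bq = 1)
      expect_equal(got$depth_total, exp$depth_total,
                   info = paste("rep", rep, "pos", pos))
      expect_equal(norm(got$counts), norm(exp$counts),
                   info = paste("rep", rep, "pos", pos))
    }
  }
})

test_that("pileup agrees with Rsamtools on a converted BAM", {
  skip_if_not_installed("Rsamtools")
  set.seed(8)
  reads <- do.call(rbind, lapply(1:30, function(i) {
    pos <- sample(1:40, 1); len <- 10L
    data.frame(qname = paste0("r", i), flag = 0L, rname = "chrS",
               pos = pos, mapq = 30L, cigar = "10M",
               seq = paste(sample(c("A", "C", "G", "T"), len, TRUE),
                           collapse = ""),
               qual = qstr(sample(c(0L, 2L, 30L), len, TRUE)),
               stringsAsFactors = FALSE)
  }))
  reads <- reads[order(reads$pos), ]
  tmp <- tempfile(fileext = ".sam")
  writeLines(sam_lines(
    apply(reads, 1, function(r) paste(r["qname"], r["flag"], r["rname"],
                                      as.integer(r["pos"]), r["mapq"],
                                      r["cigar"], "*", 0L, 0L, r["seq"],
                                      r["qual"], sep = "\t"))), tmp)
  bam <- Rsamtools::asBam(tmp, tempfile(), overwrite = TRUE)
  s <- read_sam(tmp)
  pp <- Rsamtools::PileupParam(max_depth = 500, min_base_quality = 1,
                               min_mapq = 0, min_nucleotide_depth = 1,
                               distinguish_strands = FALSE,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  rs <- Rsamtools::pileup(bam, pileupParam = pp)
  for (pos in unique(rs$pos)) {
    ours <- pileup(s, "chrS", pos, min_bq = 1)$counts
    theirs <- rs[rs$pos == pos, ]
    theirs <- setNames(theirs$count, as.character(theirs$nucleotide))
    expect_equal(ours[order(names(ours))],
                 theirs[order(names(theirs))], info = paste("pos", pos))
  }
})

test_that("panel matching fires on planted carriers and respects thresholds", {
  panel <- data.frame(chrom = "chrS", pos = 10L, ref = "T", alt = "A",
                      gene = "G1", stringsAsFactors = FALSE)
  lines <- sam_lines(
    sam_read("alt1", 8, "5M", "TTATT", qstr(rep(30, 5))),
    sam_read("alt2", 9, "4M", "TATT", qstr(rep(30, 4))),
    sam_read("refr", 10, "3M", "TTT", qstr(rep(30, 3))))
  tmp <- tempfile(fileext = ".sam"); writeLines(lines, tmp)
  s <- read_sam(tmp, sample_id = "carrier", age_bp = 1000, site = "X")
  m1 <- match_variants(s, panel)
  expect_equal(nrow(m1), 1)
  expect_equal(m1$alt_count, 2)
  expect_equal(m1$depth, 3)
  expect_equal(m1$sample_id, "carrier")
  # monotonicity: stricter thresholds never add matches
  expect_equal(nrow(match_variants(s, panel, min_alt_reads = 3)), 0)
  # a q0-only alt base does not count at min_bq = 1
  lines0 <- sam_lines(sam_read("alt0", 8, "5M", "TTATT",
                               qstr(c(30, 30, 0, 30, 30))))
  writeLines(lines0, tmp)
  s0 <- read_sam(tmp)
  expect_equal(nrow(match_variants(s0, panel, min_bq = 1)), 0)
  expect_equal(nrow(match_variants(s0, panel, min_bq = 0)), 1)
})

test_that("indel panel variants need an explicit equal-length CIGAR op", {
  panel <- data.frame(chrom = "chrS", pos = 7L, ref = "TAC", alt = "T",
                      gene = "G1", stringsAsFactors = FALSE)
  lines <- sam_lines(
    sam_read("del2", 5, "3M2D3M", "AAACCC", qstr(rep(30, 6))),   # 2-bp del at 8-9
    sam_read("del3", 5, "3M3D3M", "AAACCC", qstr(rep(30, 6))),   # wrong length
    sam_read("flat", 5, "8M", "AAATTCCC", qstr(rep(30, 8))))
  tmp <- tempfile(fileext = ".sam"); writeLines(lines, tmp)
  s <- read_sam(tmp)
  m <- match_variants(s, panel)
  expect_equal(nrow(m), 1)
  expect_equal(m$alt_count, 1)   # only the equal-length deletion supports it
})

test_that("raising min_bq or min_alt_reads never enlarges the match set", {
  pan <- data.frame(variant_id = "v1", chrom = "chrT", pos = 50L, ref = "A",
                    alt = "G", gene = "G", stringsAsFactors = FALSE)
  cfg <- simulation_config(seed = 5, L = 200L,
                           ancient = list(n_samples = 6, coverage = 6,
                                          read_len = 40,
                                          carriers = data.frame(
                                            sample_id = sprintf("anc%03d", 1:3),
                                            variant_id = "v1",
                                            stringsAsFactors = FALSE)))
  genome <- paste(c(rep("A", 49), "A", rep("C", 150)), collapse = "")
  sim <- simulate_ancient(cfg, genome, pan)
  samples <- lapply(names(sim$sams), function(id) {
    tmp <- tempfile(fileext = ".sam"); writeLines(sim$sams[[id]], tmp)
    read_sam(tmp, sample_id = id)
  })
  count_matches <- function(bq, ar) sum(vapply(samples, function(s)
    nrow(match_variants(s, pan, min_bq = bq, min_alt_reads = ar)),
    integer(1)))
  base <- count_matches(1, 1)
  expect_lte(count_matches(20, 1), base)
  expect_lte(count_matches(1, 3), base)
  expect_lte(count_matches(30, 4), count_matches(30, 2))
})

test_that("published ancient-match table summarises to its printed counts", {
  tab <- load_published_ancient_matches()
  expect_equal(nrow(tab), 50)                    # 46 variants in 50 records
  s <- summarize_matches(tab)
  expect_equal(s$BRCA1$n_records, 28)
  expect_equal(s$BRCA1$n_variants, 24)
  expect_equal(s$BRCA1$n_recurrent, 4)           # four variants in two people
  expect_equal(s$BRCA2$n_records, 22)
  expect_equal(s$BRCA2$n_variants, 22)
  expect_equal(s$BRCA2$n_recurrent, 0)
  # verbatim "stopgain" labels: 14/24 and 15/22
  expect_equal(unname(s$BRCA1$by_type[["stopgain"]]), 14)
  expect_equal(unname(s$BRCA2$by_type[["stopgain"]]), 15)
  expect_equal(pct_round1(14, 24), 58.3)
  expect_equal(pct_round1(15, 22), 68.2)
  # six distinct BRCA1 variants in the BRCT domain; three BRCA2 in NAB
  expect_equal(unname(s$BRCA1$by_domain[["BRCT"]]), 6)
  expect_equal(unname(s$BRCA2$by_domain[["NAB"]]), 3)
  # age extremes of the records
  expect_equal(s$BRCA1$oldest_age_bp, 37470)
  expect_equal(s$BRCA1$youngest_age_bp, 307.5)
  expect_equal(s$BRCA2$oldest_age_bp, 7874)
  expect_equal(s$BRCA2$youngest_age_bp, 350)
})

test_that("a single match gives degenerate but consistent summaries", {
  one <- load_published_ancient_matches()[1, ]
  s <- summarize_matches(one)
  expect_equal(s$BRCA1$n_records, 1)
  expect_equal(s$BRCA1$n_variants, 1)
  expect_equal(s$BRCA1$oldest_age_bp, s$BRCA1$youngest_age_bp)
  empty <- summarize_matches(one[0, ])
  expect_equal(empty$overall$n_records, 0)
})
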