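test_that("a hand-written block round-trips with recoverable coordinates", {
  a <- parse_maf(toy_maf_lines())
  expect_length(a$blocks, 1)
  expect_equal(a$ref_species, "hg")
  # ref row covers chr1:11-23 (start0 10, 13 bases)
  expect_equal(a$index$gstart, 11)
  expect_equal(a$index$gend, 23)
  # identical species row reproduces the reference base
  obs <- species_base_at(a, "chr1", 11, "pan")
  expect_equal(obs$status, "ALIGNED")
  expect_equal(obs$bases, "G")
  # mus has a gap at the 4th column = ref position 14
  expect_equal(species_base_at(a, "chr1", 14, "mus")$status, "GAP_IN_BLOCK")
  # outside every block
  expect_equal(species_base_at(a, "chr1", 99, "pan")$status, "NO_ALIGN")
})

test_that("parser rejects ragged blocks and flags size mismatches", {
  bad <- c("##maf version=1", "a", "s hg.chr1 0 3 + 10 ACG",
           "s sp.chr1 0 4 + 10 ACGT")
  expect_error(parse_maf(bad), "row-length mismatch")
  bad2 <- c("##maf version=1", "a", "s hg.chr1 0 4 + 10 ACG")
  expect_error(parse_maf(bad2), "ungapped length")
  expect_error(parse_maf(c("no header")), "##maf")
  expect_warning(parse_maf(c("##maf version=1", "a",
                             "s hg.chr1 0 3 + 10 ACG", "z strange line")),
                 "unknown MAF line")
})

test_that("minus-strand rows keep recoverable genomic intervals", {
  lines <- c("##maf version=1", "a",
             "s hg.chr1 10 4 + 100 ACGT",
             "s sp.chr2 20 4 - 50  ACGT")
  a <- parse_maf(lines)
  row <- a$blocks[[1]]$rows[[2]]
  # start s=20, size k=4, srcSize L=50: genomic interval [L-s-k+1, L-s] = [27, 30]
  expect_equal(row$gstart, 27)
  expect_equal(row$gend, 30)
})

test_that("e-line statuses map to the two absence states", {
  lines <- c("##maf version=1", "a",
             "s hg.chr1 0 4 + 100 ACGT",
             "s pan.chr1 0 4 + 90 ACGT",
             "e mus.chr5 3 0 + 80 C",
             "e rat.chr2 3 0 + 80 I")
  a <- parse_maf(lines)
  expect_equal(species_base_at(a, "chr1", 2, "mus")$status, "NO_ALIGN")
  expect_equal(species_base_at(a, "chr1", 2, "rat")$status, "GAP_UNALIGNED")
  # species entirely unknown to the block
  expect_equal(species_base_at(a, "chr1", 2, "dog")$status, "NO_ALIGN")
})

test_that("classify_state is a total function over the six states", {
  obs <- function(bases, status) structure(
    list(species = "sp", bases = bases, status = status), class = "species_obs")
  expect_equal(classify_state("C", "T", obs("T", "ALIGNED")), "SHARED")
  expect_equal(classify_state("C", "T", obs("t", "ALIGNED")), "SHARED")
  expect_equal(classify_state("C", "T", obs("C", "ALIGNED")), "WILDTYPE")
  expect_equal(classify_state("C", "T", obs("G", "ALIGNED")), "OTHER")
  expect_equal(classify_state("C", "T", obs("N", "ALIGNED")), "OTHER")
  expect_equal(classify_state("C", "T", obs("", "GAP_IN_BLOCK")), "GAP")
  expect_equal(classify_state("C", "T", obs("", "NO_ALIGN")), "NO_ALIGN")
  expect_equal(classify_state("C", "T", obs("", "GAP_UNALIGNED")),
               "GAP_UNALIGNED")
})

test_that("indel matching enforces the equal-length gap rule", {
  #                 ref pos: 123456789
  lines <- c("##maf version=1", "a",
             "s hg.chr1  0 9 + 9 ACGTACGTA",
             "s eq.chr1  0 7 + 7 AC--ACGTA",   # 2-col gap at pos 3-4
             "s un.chr1  0 6 + 6 AC---CGTA",   # 3-col gap
             "s no.chr1  0 9 + 9 ACTTACGTA")   # no gap
  a <- parse_maf(lines)
  # human deletion of 2 bases: anchor pos 2, ref A + CG deleted -> "ACG">"A"
  expect_true(match_indel(a, "chr1", 2, "ACG", "A", "eq")$match)
  r_un <- match_indel(a, "chr1", 2, "ACG", "A", "un")
  expect_false(r_un$match)
  expect_true(r_un$differs)
  r_no <- match_indel(a, "chr1", 2, "ACG", "A", "no")
  expect_false(r_no$match)
  expect_false(r_no$differs)
  # locus not covered at all
  expect_equal(match_indel(a, "chr1", 40, "ACG", "A", "eq")$status, "NO_ALIGN")
})

test_that("insertion matching needs the same number of extra species bases", {
  lines <- c("##maf version=1", "a",
             "s hg.chr1  0 4 + 4 AC--GT",
             "s two.chr1 0 6 + 6 ACTTGT",      # 2 inserted bases
             "s one.chr1 0 5 + 5 ACT-GT",      # 1 inserted base
             "s non.chr1 0 4 + 4 AC--GT")      # no insertion
  a <- parse_maf(lines)
  expect_true(match_indel(a, "chr1", 2, "C", "CTT", "two")$match)
  expect_false(match_indel(a, "chr1", 2, "C", "CTT", "one")$match)
  r <- match_indel(a, "chr1", 2, "C", "CTT", "non")
  expect_false(r$match)
  expect_false(r$differs)
})

test_that("state matrix handles identity alignments and absent contigs", {
  lines <- c("##maf version=1", "a",
             "s hg.chr1 0 8 + 8 ACGTACGT",
             "s s1.chr1 0 8 + 8 ACGTACGT",
             "s s2.chr1 0 8 + 8 ACGTACGT")
  a <- parse_maf(lines)
  v <- data.frame(chrom = "chr1", pos = c(2L, 5L), ref = c("C", "A"),
                  alt = c("T", "G"), stringsAsFactors = FALSE)
  m <- build_state_matrix(v, a)
  expect_true(all(m == "WILDTYPE"))
  v2 <- data.frame(chrom = "chrX", pos = 2L, ref = "C", alt = "T",
                   stringsAsFactors = FALSE)
  expect_warning(m2 <- build_state_matrix(v2, a), "absent")
  expect_true(all(m2 == "NO_ALIGN"))
})

test_that("every cell gets exactly one of the six states (partition)", {
  for (seed in 1:5) {
    inst <- random_maf_instance(seed)
    a <- parse_maf(inst$lines)
    m <- build_state_matrix(inst$variants, a, inst$species)
    expect_true(all(m %in% ALIGNMENT_STATES))
    expect_false(any(is.na(m)))
    # row counts sum to the number of species
    tab <- apply(m, 1, function(r) sum(table(factor(r, ALIGNMENT_STATES))))
    expect_true(all(tab == length(inst$species)))
  }
})

test_that("state matrix agrees cell-for-cell with the column-walk oracle", {
  for (seed in 1:100) {
    inst <- random_maf_instance(seed)
    a <- parse_maf(inst$lines)
    m <- build_state_matrix(inst$variants, a, inst$species)
    bf <- bf_state_matrix(inst$lines, inst$variants, inst$species)
    expect_equal(unname(unclass(m)), unname(bf),
                 info = paste("seed", seed))
  }
})

test_that("relabelling a species row as minus strand changes no state", {
  inst <- random_maf_instance(17)
  a <- parse_maf(inst$lines)
  m <- build_state_matrix(inst$variants, a, inst$species)
  # flip sp2's row to its minus-strand representation: same text, mirrored
  # start against srcSize; alignment-oriented text means states cannot move
  flipped <- inst$lines
  i <- grep("^s sp2", flipped)
  f <- strsplit(flipped[i], "\\s+")[[1]]
  start0 <- as.integer(f[3]); size <- as.integer(f[4]); src <- as.integer(f[6])
  flipped[i] <- sprintf("s %s %d %d - %d %s", f[2], src - start0 - size,
                        size, src, f[7])
  m2 <- build_state_matrix(inst$variants, parse_maf(flipped), inst$species)
  expect_identical(unclass(m), unclass(m2))
})

test_that("wide and long TSV exports carry the legend codes", {
  inst <- random_maf_instance(3)
  a <- parse_maf(inst$lines)
  m <- build_state_matrix(inst$variants, a, inst$species)
  fw <- tempfile(); fl <- tempfile()
  write_state_matrix(m, fw, fl)
  wide <- read.delim(fw, check.names = FALSE)
  expect_equal(nrow(wide), nrow(m))
  expect_true(all(unlist(wide[, -1]) %in% unname(STATE_CODES)))
  long <- read.delim(fl)
  expect_equal(nrow(long), length(m))
  expect_true(all(long$state %in% ALIGNMENT_STATES))
})
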