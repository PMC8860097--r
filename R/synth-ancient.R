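#' Simulate ancient-human read sets with planted carriers and damage
#'
#' Draws reads uniformly over a contig at a target coverage. Carrier
#' samples are heterozygous for their assigned panel variant: each
#' overlapping read comes from the alternate haplotype with probability
#' 0.5. Post-mortem deamination is emulated as terminal 5' C->T flips at
#' rate `damage_rate` (reads simulated from the reverse strand show the
#' complementary G->A change in reference orientation). Base qualities are
#' drawn from a configured distribution so that quality filtering is
#' exercised. The truth table lists, per (sample, variant), whether the
#' default match criterion (>= 1 alternate-supporting base of quality >= 1)
#' would fire on the *pre-damage* reads — i.e. what a damage-free run must
#' recover exactly.
#'
#' @param cfg a [simulation_config()]; the `ancient` sub-list is used, and
#'   the seed is offset so alignment and read simulation are independent.
#' @param genome reference contig sequence (string).
#' @param panel data.frame of SNV panel variants (`variant_id`, `chrom`,
#'   `pos`, `ref`, `alt`).
#' @return list with `sams` (named list of SAM line vectors), `metadata`
#'   (sample metadata data.frame), `truth` (data.frame `sample_id`,
#'   `variant_id`, `expected`).
#' @export
simulate_ancient <- function(cfg, genome, panel) {
  stopifnot(inherits(cfg, "simulation_config"), is.character(genome))
  anc <- cfg$ancient
  set.seed(cfg$seed + 10007L)
  Lg <- nchar(genome)
  rl <- as.integer(anc$read_len)
  if (rl > Lg) stop("read length ", rl, " exceeds contig length ", Lg)
  genome_chars <- strsplit(toupper(genome), "")[[1]]
  chrom <- if (nrow(panel) > 0) panel$chrom[1] else cfg$chrom
  qvals <- as.integer(names(anc$bq_probs))

  carriers <- anc$carriers
  if (!is.null(carriers))
    stopifnot(all(carriers$variant_id %in% panel$variant_id))

  sample_ids <- sprintf("anc%03d", seq_len(anc$n_samples))
  ages <- round(runif(anc$n_samples, anc$age_range[1], anc$age_range[2]))
  metadata <- data.frame(
    sample_id = sample_ids, age_bp = ages,
    age_sd = round(ages * 0.02), site = paste0("Site_", seq_along(sample_ids)),
    lat = round(runif(anc$n_samples, -60, 70), 3),
    lon = round(runif(anc$n_samples, -180, 180), 3),
    stringsAsFactors = FALSE)

  sams <- list(); truth_rows <- list()
  for (si in seq_along(sample_ids)) {
    sid <- sample_ids[si]
    my_vars <- if (is.null(carriers)) character(0)
               else carriers$variant_id[carriers$sample_id == sid]
    vrows <- panel[panel$variant_id %in% my_vars, , drop = FALSE]
    n_reads <- max(0L, as.integer(round(anc$coverage * Lg / rl)))
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                sprintf("@SQ\tSN:%s\tLN:%d", chrom, Lg))
    body <- character(0)
    # pre-damage alt support per carried variant, at quality >= 1
    alt_support <- setNames(rep(0L, nrow(vrows)), vrows$variant_id)
    if (n_reads > 0) {
      starts <- sort(sample.int(Lg - rl + 1L, n_reads, replace = TRUE))
      for (j in seq_len(n_reads)) {
        st <- starts[j]
        seq_chars <- genome_chars[st:(st + rl - 1L)]
        hap_alt <- runif(1) < 0.5
        quals <- sample(qvals, rl, replace = TRUE, prob = anc$bq_probs)
        if (hap_alt && nrow(vrows) > 0) {
          for (v in seq_len(nrow(vrows))) {
            p <- vrows$pos[v]
            if (p >= st && p <= st + rl - 1L) {
              seq_chars[p - st + 1L] <- vrows$alt[v]
              if (quals[p - st + 1L] >= 1L)
                alt_support[vrows$variant_id[v]] <-
                  alt_support[vrows$variant_id[v]] + 1L
            }
          }
        }
        reverse <- runif(1) < 0.5
        if (anc$damage_rate > 0) {
          dmg <- min(2L, rl)
          if (!reverse) {
            for (t in seq_len(dmg))
              if (seq_chars[t] == "C" && runif(1) < anc$damage_rate)
                seq_chars[t] <- "T"
          } else {
            for (t in seq(rl - dmg + 1L, rl))
              if (seq_chars[t] == "G" && runif(1) < anc$damage_rate)
                seq_chars[t] <- "A"
          }
        }
        body <- c(body, paste(
          sprintf("%s_r%05d", sid, j), if (reverse) 16L else 0L, chrom, st,
          30L, paste0(rl, "M"), "*", 0L, 0L,
          paste(seq_chars, collapse = ""),
          intToUtf8(quals + 33L), sep = "\t"))
      }
    }
    sams[[sid]] <- c(header, body)
    for (v in seq_len(nrow(panel))) {
      vid <- panel$variant_id[v]
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        sample_id = sid, variant_id = vid,
        expected = vid %in% names(alt_support) && alt_support[[vid]] >= 1L,
        stringsAsFactors = FALSE)
    }
  }
  list(sams = sams, metadata = metadata, truth = do.call(rbind, truth_rows))
}
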