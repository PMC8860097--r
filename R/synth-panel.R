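#' Default consequence-category mix for generated panels
#'
#' Proportions of the ten categories as observed in the published count
#' table of the ClinVar BRCA PLP set (counts 2926, 1506, 1360, 366, 163,
#' 202, 66, 22, 11, 2 of 6,624), in [CONSEQUENCE_CATEGORIES] order.
#' @export
DEFAULT_TYPE_PROPORTIONS <- setNames(
  c(2926, 1506, 1360, 366, 163, 202, 66, 22, 11, 2) / 6624,
  CONSEQUENCE_CATEGORIES)

# significance mix of the same published set (6163 / 265 / 196 of 6,624)
DEFAULT_SIG_PROPORTIONS <- setNames(
  c(6163, 265, 196) / 6624, ELIGIBLE_CLIN_SIG)

#' Generate a variant panel, toy transcript and domain intervals
#'
#' Builds a multi-exon toy transcript (with two protein-domain intervals) on
#' a random contig and draws `n_variants` distinct variants whose
#' consequence categories follow `proportions` (default: the published type
#' mix). Every emitted variant is verified against
#' [classify_consequence()], so the generated category labels are true by
#' construction. Identical seeds give byte-identical output.
#'
#' @param n_variants number of variants (>= 1).
#' @param proportions named numeric over [CONSEQUENCE_CATEGORIES]; must sum
#'   to 1.
#' @param sig_proportions named numeric over the three eligible
#'   significance classes; must sum to 1.
#' @param noise_frac additional fraction of non-eligible records (benign /
#'   conflicting) appended to exercise the significance filter.
#' @param seed integer seed.
#' @return list with `variants` (data.frame), `transcript`
#'   (a [transcript_model()]), and `genome` (contig sequence string).
#' @export
make_panel <- function(n_variants, proportions = DEFAULT_TYPE_PROPORTIONS,
                       sig_proportions = DEFAULT_SIG_PROPORTIONS,
                       noise_frac = 0, seed = 1L) {
  stopifnot(n_variants >= 1)
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("category proportions must sum to 1 (got ", sum(proportions), ")")
  if (abs(sum(sig_proportions) - 1) > 1e-8)
    stop("significance proportions must sum to 1")
  if (!all(names(proportions) %in% CONSEQUENCE_CATEGORIES))
    stop("unknown category in proportions")
  set.seed(seed)

  # twelve 250-bp exons separated by 100-bp introns; UTRs at both ends.
  # the 950-codon CDS gives every category (including stopgain, which only
  # ~0.45 single-base changes per codon can produce) enough distinct
  # variants to draw the published mix without repeats
  Lg <- 4400L
  genome <- paste(sample(c("A", "C", "G", "T"), Lg, replace = TRUE),
                  collapse = "")
  exon_starts <- 101L + 350L * (0:11)
  exon_ends <- exon_starts + 249L
  n_exon <- length(exon_starts)
  t <- transcript_model(
    gene = "GENE1", chrom = "chrP", strand = "+",
    exons = data.frame(start = exon_starts, end = exon_ends),
    cds_start = 151L, cds_end = 4100L,
    domains = data.frame(label = c("DOM_A", "DOM_B"),
                         start_res = c(100L, 400L), end_res = c(250L, 600L),
                         stringsAsFactors = FALSE),
    ref_seq = genome)

  geom <- list(
    splice_pos = sort(c(outer(exon_ends[-n_exon], 1:2, `+`),
                        outer(exon_starts[-1], 1:2, `-`))),
    intron_pos = unlist(lapply(seq_len(n_exon - 1), function(i)
      (exon_ends[i] + 5L):(exon_starts[i + 1] - 5L))),
    utr_pos = c(101:148, 4103:4198),
    coding = coding_intervals(t))
  gpos_by_cds <- unlist(mapply(seq, geom$coding$start, geom$coding$end,
                               SIMPLIFY = FALSE))
  snv_opts <- snv_option_table(cds_seq(t))

  cats <- sample(names(proportions), n_variants, replace = TRUE,
                 prob = proportions)
  sigs <- sample(names(sig_proportions), n_variants, replace = TRUE,
                 prob = sig_proportions)
  sig_display <- c(pathogenic = "Pathogenic",
                   likely_pathogenic = "Likely_pathogenic",
                   "pathogenic/likely_pathogenic" = "Pathogenic/Likely_pathogenic")

  used <- new.env(parent = emptyenv())
  draw_unique <- function(category) {
    for (try in 1:500) {
      v <- draw_variant(category, genome, gpos_by_cds, snv_opts, geom)
      key <- paste(v$pos, v$ref, v$alt)
      if (exists(key, envir = used)) next
      got <- classify_consequence("chrP", v$pos, v$ref, v$alt, t)
      if (got == category) {
        assign(key, TRUE, envir = used)
        return(v)
      }
    }
    stop("could not construct a distinct '", category, "' variant")
  }

  rows <- vector("list", n_variants)
  for (i in seq_len(n_variants)) {
    v <- draw_unique(cats[i])
    rows[[i]] <- data.frame(
      chrom = "chrP", pos = v$pos, ref = v$ref, alt = v$alt, gene = "GENE1",
      clin_sig_raw = sig_display[[sigs[i]]],
      hgvs_c = v$hgvs_c, hgvs_p = NA_character_,
      rsid = sprintf("rs%06d", 100000L + i), stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, rows)
  variants$clin_sig <- normalize_clin_sig(variants$clin_sig_raw)

  if (noise_frac > 0) {
    n_noise <- ceiling(n_variants * noise_frac)
    noise_sig <- sample(c("Benign", "Likely_benign",
                          "Conflicting_interpretations_of_pathogenicity",
                          "Uncertain_significance"), n_noise, replace = TRUE)
    noise <- vector("list", n_noise)
    for (j in seq_len(n_noise)) {
      v <- draw_unique("nonsynonymous SNV")
      noise[[j]] <- data.frame(
        chrom = "chrP", pos = v$pos, ref = v$ref, alt = v$alt, gene = "GENE1",
        clin_sig_raw = noise_sig[j], hgvs_c = v$hgvs_c,
        hgvs_p = NA_character_, rsid = sprintf("rs%06d", 200000L + j),
        stringsAsFactors = FALSE)
    }
    noise <- do.call(rbind, noise)
    noise$clin_sig <- normalize_clin_sig(noise$clin_sig_raw)
    variants <- rbind(variants, noise)
  }

  variants <- variants[, c("chrom", "pos", "ref", "alt", "gene", "clin_sig",
                           "clin_sig_raw", "hgvs_c", "hgvs_p", "rsid")]
  variants$variant_id <- sprintf("v%04d", seq_len(nrow(variants)))
  list(variants = variants, transcript = t, genome = genome)
}

# all single-base codon changes, classified (positions are CDS coordinates)
snv_option_table <- function(cds) {
  code <- Biostrings::GENETIC_CODE
  n_codon <- nchar(cds) %/% 3L
  out <- list(stopgain = list(), nonsyn = list())
  bases <- c("A", "C", "G", "T")
  for (ci in seq_len(n_codon)) {
    codon <- substr(cds, (ci - 1) * 3 + 1, ci * 3)
    aa <- unname(code[codon])
    if (is.na(aa) || aa == "*") next
    for (w in 1:3) {
      refb <- substr(codon, w, w)
      for (b in setdiff(bases, refb)) {
        mut <- codon
        substr(mut, w, w) <- b
        aa2 <- unname(code[mut])
        cpos <- (ci - 1L) * 3L + w
        if (aa2 == "*")
          out$stopgain[[length(out$stopgain) + 1]] <- c(cpos, b)
        else if (aa2 != aa)
          out$nonsyn[[length(out$nonsyn) + 1]] <- c(cpos, b)
      }
    }
  }
  list(stopgain = do.call(rbind, out$stopgain),
       nonsyn = do.call(rbind, out$nonsyn))
}

draw_variant <- function(category, genome, gpos_by_cds, snv_opts, geom) {
  gchar <- function(p) substr(genome, p, p)
  gsub_ <- function(p, q) substr(genome, p, q)
  rand_base <- function(not) sample(setdiff(c("A", "C", "G", "T"), not), 1)
  rand_seq <- function(k) paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                                collapse = "")
  # coding anchor whose k-base footprint stays inside one coding exon,
  # clear of the splice windows
  coding_anchor <- function(k) {
    ci <- geom$coding[sample(nrow(geom$coding), 1), ]
    sample((ci$start + 4L):(ci$end - k - 4L), 1)
  }
  snv_from <- function(opts) {
    o <- opts[sample(nrow(opts), 1), ]
    p <- gpos_by_cds[as.integer(o[1])]
    list(pos = p, ref = gchar(p), alt = o[2],
         hgvs_c = sprintf("c.%s%s>%s", o[1], gchar(p), o[2]))
  }
  plain_snv <- function(p) {
    r <- gchar(p)
    a <- rand_base(r)
    list(pos = p, ref = r, alt = a, hgvs_c = sprintf("g.%d%s>%s", p, r, a))
  }
  switch(category,
    "stopgain/nonsense" = snv_from(snv_opts$stopgain),
    "nonsynonymous SNV" = snv_from(snv_opts$nonsyn),
    "splice site" = plain_snv(sample(geom$splice_pos, 1)),
    "intron variant" = plain_snv(sample(geom$intron_pos, 1)),
    "5'/3' UTR" = plain_snv(sample(geom$utr_pos, 1)),
    "frameshift deletion" = {
      k <- sample(c(1L, 2L, 4L), 1)
      p <- coding_anchor(k)
      list(pos = p, ref = gsub_(p, p + k), alt = gchar(p),
           hgvs_c = sprintf("c.%d_%ddel", p, p + k))
    },
    "nonframeshift deletion" = {
      p <- coding_anchor(3L)
      list(pos = p, ref = gsub_(p, p + 3L), alt = gchar(p),
           hgvs_c = sprintf("c.%d_%ddel", p, p + 3L))
    },
    "frameshift insertion" = {
      k <- sample(c(1L, 2L), 1)
      p <- coding_anchor(1L)
      list(pos = p, ref = gchar(p), alt = paste0(gchar(p), rand_seq(k)),
           hgvs_c = sprintf("c.%dins%d", p, k))
    },
    "frameshift substitution" = {
      p <- coding_anchor(2L)
      r <- gsub_(p, p + 1L)
      a <- paste0(rand_base(substr(r, 1, 1)), rand_seq(1),
                  rand_base(substr(r, 2, 2)))
      list(pos = p, ref = r, alt = a,
           hgvs_c = sprintf("c.%ddelins%s", p, a))
    },
    "nonframeshift substitution" = {
      p <- coding_anchor(3L)
      r <- gsub_(p, p + 2L)
      a <- paste0(rand_base(substr(r, 1, 1)), rand_seq(1),
                  rand_base(substr(r, 3, 3)))
      list(pos = p, ref = r, alt = a,
           hgvs_c = sprintf("c.%ddelins%s", p, a))
    },
    stop("unknown category: ", category))
}
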