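#' Build a transcript model
#'
#' A minimal exon/CDS model of a single transcript, carrying the reference
#' sequence of its contig so that coding consequences can be derived by
#' translating mutated codons. Intervals are 1-based and closed throughout
#' (the native R / IRanges convention); VCF and MAF coordinates are converted
#' once, at their parsers.
#'
#' @param gene gene symbol.
#' @param chrom contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (genomic, ascending,
#'   non-overlapping).
#' @param cds_start,cds_end genomic bounds of the coding sequence (first and
#'   last coding base irrespective of strand; `cds_start <= cds_end`).
#' @param domains optional data.frame with columns `label`, `start_res`,
#'   `end_res` (protein residues, closed intervals).
#' @param ref_seq reference sequence of the contig, position 1 = first base.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(gene, chrom, strand, exons, cds_start, cds_end,
                             domains = NULL, ref_seq) {
  stopifnot(strand %in% c("+", "-"),
            is.data.frame(exons), all(c("start", "end") %in% names(exons)),
            cds_start <= cds_end, cds_start >= 1,
            is.character(ref_seq), length(ref_seq) == 1)
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  if (any(exons$end < exons$start))
    stop("exon with end < start")
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("exons overlap or touch; merge before building the model")
  t <- structure(list(gene = gene, chrom = chrom, strand = strand,
                      exons = exons, cds_start = cds_start, cds_end = cds_end,
                      domains = domains, ref_seq = toupper(ref_seq)),
                 class = "transcript_model")
  n_cds <- cds_length(t)
  if (n_cds %% 3L != 0L)
    stop("CDS length ", n_cds, " is not a multiple of 3")
  if (!is.null(domains)) {
    stopifnot(all(c("label", "start_res", "end_res") %in% names(domains)))
    plen <- n_cds %/% 3L
    if (any(domains$start_res < 1 | domains$end_res > plen |
            domains$start_res > domains$end_res))
      stop("domain interval outside [1, ", plen, "]")
  }
  t
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s %s(%s) %d exon(s), CDS %d-%d, %d domain(s)\n",
              x$gene, x$chrom, x$strand, nrow(x$exons), x$cds_start, x$cds_end,
              if (is.null(x$domains)) 0L else nrow(x$domains)))
  invisible(x)
}

# genomic intervals of the coding part of each exon (ascending)
coding_intervals <- function(t) {
  s <- pmax(t$exons$start, t$cds_start)
  e <- pmin(t$exons$end, t$cds_end)
  keep <- s <= e
  data.frame(start = s[keep], end = e[keep])
}

cds_length <- function(t) {
  ci <- coding_intervals(t)
  sum(ci$end - ci$start + 1L)
}

protein_length <- function(t) cds_length(t) %/% 3L

transcript_span <- function(t) c(min(t$exons$start), max(t$exons$end))

# 1-based position within the spliced CDS (5' end of the mRNA = 1), or NA
genomic_to_cds <- function(t, gpos) {
  ci <- coding_intervals(t)
  vapply(gpos, function(p) {
    hit <- which(ci$start <= p & p <= ci$end)
    if (length(hit) == 0) return(NA_integer_)
    if (t$strand == "+") {
      before <- if (hit > 1) sum(ci$end[seq_len(hit - 1)] - ci$start[seq_len(hit - 1)] + 1L) else 0L
      as.integer(before + (p - ci$start[hit]) + 1L)
    } else {
      after <- if (hit < nrow(ci)) sum(ci$end[seq(hit + 1, nrow(ci))] - ci$start[seq(hit + 1, nrow(ci))] + 1L) else 0L
      as.integer(after + (ci$end[hit] - p) + 1L)
    }
  }, integer(1))
}

# spliced coding sequence in translation orientation
cds_seq <- function(t) {
  ci <- coding_intervals(t)
  parts <- substring(t$ref_seq, ci$start, ci$end)
  s <- paste(parts, collapse = "")
  if (t$strand == "-") revcomp(s) else s
}

# TRUE where gpos lies in any exon
in_exon <- function(t, gpos) {
  vapply(gpos, function(p) any(t$exons$start <= p & p <= t$exons$end),
         logical(1))
}

# intronic positions within `window` bases of an internal exon boundary
in_splice_window <- function(t, gpos, window = 2L) {
  if (window < 1L || nrow(t$exons) < 2) return(rep(FALSE, length(gpos)))
  donors <- t$exons$end[-nrow(t$exons)]      # intron starts at donor+1
  acceptors <- t$exons$start[-1]             # intron ends at acceptor-1
  vapply(gpos, function(p) {
    any(p > donors & p <= donors + window) ||
      any(p < acceptors & p >= acceptors - window)
  }, logical(1))
}

#' Protein residue affected by a coding variant
#'
#' @param t a [transcript_model()].
#' @param gpos genomic position of the first changed coding base.
#' @return residue number (1-based), or `NA` for non-coding positions.
#' @export
residue_at <- function(t, gpos) {
  cpos <- genomic_to_cds(t, gpos)
  ifelse(is.na(cpos), NA_integer_, as.integer((cpos - 1L) %/% 3L + 1L))
}
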