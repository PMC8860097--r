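#' Round a percentage half away from zero to one decimal
#'
#' Published count tables round half away from zero (so 5.75 prints as 5.8),
#' which differs from R's banker's rounding in `round()`.
#'
#' @param num,den numerator and denominator counts.
#' @return numeric percentage rounded to one decimal.
#' @export
pct_round1 <- function(num, den) {
  x <- 100 * num / den
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

# reverse complement of plain character DNA (alignment gaps preserved)
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgtNn", "TGCAtgcaNn", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# phred+33 decoding of a QUAL string
qual_to_phred <- function(qual) {
  if (qual == "*") return(integer(0))
  utf8ToInt(qual) - 33L
}

#' Stable key identifying a normalized variant
#'
#' `chrom:pos:ref:alt` when genomic columns are present, otherwise
#' `gene:hgvs_c` (transcribed published tables carry no genomic columns).
#'
#' @param df data.frame of variant records.
#' @return character vector of keys.
#' @export
variant_key <- function(df) {
  if (all(c("chrom", "pos", "ref", "alt") %in% names(df))) {
    paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  } else {
    paste(df$gene, df$hgvs_c, sep = ":")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
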