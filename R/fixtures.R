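#' Path to a bundled reference table
#' @param name file name under `extdata/`.
#' @return absolute path.
#' @export
plp_fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "plptrace")
  if (p == "") stop("no bundled fixture named ", name)
  p
}

#' Bundled published sharing-count table
#'
#' Verbatim transcription of the published cross-species summary of the
#' ClinVar BRCA PLP set: section A (the panel by significance and type),
#' section B (variants shared with at least one species, by type), section C
#' (number of variants shared with exactly k species). See the comment
#' header of the file for the transcription notes on the cells whose printed
#' values are internally inconsistent.
#'
#' @return data.frame with columns `section`, `label`, `brca1`, `brca2`,
#'   `total`.
#' @export
load_published_type_counts <- function() {
  read.delim(plp_fixture_path("vertebrate_sharing_counts.tsv"),
             comment.char = "#", stringsAsFactors = FALSE,
             colClasses = c("character", "character", "numeric", "numeric",
                            "numeric"))
}

#' Bundled published ancient-match table
#'
#' One row per (ancient individual, variant) detection record, with the
#' verbatim type labels and domain annotations of the published table.
#'
#' @return data.frame with columns `gene`, `age_bp`, `age_sd`, `site`,
#'   `hgvs_c`, `hgvs_p`, `type`, `rsid`, `domain`.
#' @export
load_published_ancient_matches <- function() {
  d <- read.delim(plp_fixture_path("ancient_plp_matches.tsv"),
                  comment.char = "#", stringsAsFactors = FALSE, fill = TRUE)
  for (col in c("hgvs_p", "rsid", "domain"))
    d[[col]][is.na(d[[col]])] <- ""
  d
}

#' Bundled published founder-variant table
#'
#' One row per founder record (the same variant in two populations counts
#' twice); ages are literature values dated by haplotype analysis and are
#' never recomputed.
#'
#' @return data.frame with columns `gene`, `age_bp`, `age_bp_min`,
#'   `population`, `hgvs_c`, `legacy_name`, `hgvs_p`, `type`.
#' @export
load_published_founders <- function() {
  read.delim(plp_fixture_path("founder_plp_variants.tsv"),
             comment.char = "#", stringsAsFactors = FALSE, fill = TRUE)
}
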