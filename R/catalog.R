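#' The ten consequence categories of the published type table
#'
#' Classification of a coding/noncoding change relative to a transcript.
#' `classify_consequence()` may additionally return `"nonframeshift
#' insertion"` or `"synonymous SNV"` for inputs the published pathogenic set
#' happens not to contain; the panel generators never emit those.
#' @export
CONSEQUENCE_CATEGORIES <- c(
  "frameshift deletion", "stopgain/nonsense", "frameshift insertion",
  "splice site", "nonsynonymous SNV", "frameshift substitution",
  "intron variant", "nonframeshift deletion", "nonframeshift substitution",
  "5'/3' UTR"
)

ELIGIBLE_CLIN_SIG <- c("pathogenic", "likely_pathogenic",
                       "pathogenic/likely_pathogenic")

# canonical lower-case significance label; spellings vary by ClinVar release
normalize_clin_sig <- function(x) {
  y <- tolower(trimws(x))
  y <- gsub("[ ,]+", "_", y)
  out <- character(length(y))
  for (i in seq_along(y)) {
    s <- y[i]
    out[i] <-
      if (grepl("conflict", s)) "conflicting"
      else if (grepl("^pathogenic([/_]|_and_)likely_pathogenic$", s))
        "pathogenic/likely_pathogenic"
      else if (grepl("^likely_pathogenic$", s)) "likely_pathogenic"
      else if (grepl("^pathogenic$", s)) "pathogenic"
      else s
  }
  out
}

# minimal VCF-style normalization without a reference genome: right-trim the
# shared suffix, then left-trim the shared prefix, keeping the anchor base
normalize_allele_pair <- function(pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

empty_panel <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), gene = character(0), clin_sig = character(0),
             clin_sig_raw = character(0), hgvs_c = character(0),
             hgvs_p = character(0), rsid = character(0),
             stringsAsFactors = FALSE)
}

#' Parse a candidate-variant table from VCF or TSV
#'
#' Reads a ClinVar-style table of candidate variants. VCF 4.x input is read
#' through \pkg{vcfR}; the clinical significance is taken from an INFO key
#' (default `CLNSIG`). TSV input needs columns
#' `chrom,pos,ref,alt,clin_sig` and may carry `gene,hgvs_c,hgvs_p,rsid`.
#' Multi-allelic rows are split into one record per alternate allele and
#' alleles are trimmed to their minimal anchored representation, so that
#' `(chrom,pos,ref,alt)` is a stable key. Malformed body rows are dropped
#' with a warning; an unparsable header is fatal.
#'
#' @param path path to a `.vcf` or tab-separated file.
#' @param format `"auto"` (default), `"vcf"`, or `"tsv"`.
#' @param info_key INFO key holding the clinical significance (VCF input).
#' @return data.frame with one row per `(pos, ref, alt)` record; original
#'   significance strings are kept in `clin_sig_raw`, canonical lower-case
#'   labels in `clin_sig`.
#' @export
parse_variant_table <- function(path, format = c("auto", "vcf", "tsv"),
                                info_key = "CLNSIG") {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (length(lines) > 0 && grepl("^##fileformat=VCF", lines[1]))
      "vcf" else "tsv"
  }
  raw <- if (format == "vcf") parse_vcf_body(lines, info_key)
         else parse_tsv_body(path)
  if (nrow(raw) == 0) return(empty_panel())
  split_and_normalize(raw)
}

parse_vcf_body <- function(lines, info_key) {
  if (length(lines) == 0 || !grepl("^##fileformat=VCFv?4", lines[1]))
    stop("unparsable VCF header at line 1: ",
         if (length(lines)) substr(lines[1], 1, 60) else "<empty file>")
  body_idx <- which(!startsWith(lines, "#"))
  nf <- vapply(strsplit(lines[body_idx], "\t", fixed = TRUE), length, integer(1))
  bad <- body_idx[nf < 8]
  if (length(bad) > 0) {
    warning("dropping ", length(bad), " malformed VCF row(s) at line(s) ",
            paste(head(bad, 5), collapse = ", "))
    lines <- lines[-bad]
  }
  tmp <- tempfile(fileext = ".vcf")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  v <- vcfR::read.vcfR(tmp, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))              # single-record files drop dimensions
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    out <- empty_panel()
    return(out[, c("chrom", "pos", "ref", "alt", "gene", "clin_sig_raw",
                   "hgvs_c", "hgvs_p", "rsid")])
  }
  clnsig <- vcfR::extract.info(v, element = info_key)
  geneinfo <- vcfR::extract.info(v, element = "GENEINFO")
  gene <- ifelse(is.na(geneinfo), NA_character_,
                 sub(":.*$", "", geneinfo))
  data.frame(chrom = fix$CHROM, pos = suppressWarnings(as.integer(fix$POS)),
             ref = fix$REF, alt = fix$ALT, gene = gene,
             clin_sig_raw = ifelse(is.na(clnsig), "", clnsig),
             hgvs_c = NA_character_, hgvs_p = NA_character_,
             rsid = ifelse(fix$ID %in% c(".", ""), NA_character_, fix$ID),
             stringsAsFactors = FALSE)
}

parse_tsv_body <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "clin_sig")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0)
    stop("unparsable header: TSV lacks column(s) ",
         paste(missing_cols, collapse = ", "))
  for (opt in c("gene", "hgvs_c", "hgvs_p", "rsid"))
    if (!opt %in% names(d)) d[[opt]] <- NA_character_
  data.frame(chrom = as.character(d$chrom),
             pos = suppressWarnings(as.integer(d$pos)),
             ref = as.character(d$ref), alt = as.character(d$alt),
             gene = as.character(d$gene), clin_sig_raw = as.character(d$clin_sig),
             hgvs_c = as.character(d$hgvs_c), hgvs_p = as.character(d$hgvs_p),
             rsid = as.character(d$rsid), stringsAsFactors = FALSE)
}

split_and_normalize <- function(raw) {
  alt_list <- strsplit(raw$alt, ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(raw)), lengths(alt_list))
  out <- raw[idx, , drop = FALSE]
  out$alt <- unlist(alt_list)
  rownames(out) <- NULL

  ok <- !is.na(out$pos) & out$pos >= 1 &
    grepl("^[ACGTacgt]+$", out$ref) & grepl("^[ACGTacgt]+$", out$alt) &
    toupper(out$ref) != toupper(out$alt)
  if (any(!ok))
    warning("dropping ", sum(!ok), " malformed record(s) ",
            "(bad position, non-ACGT allele, or ref == alt)")
  out <- out[ok, , drop = FALSE]

  for (i in seq_len(nrow(out))) {
    n <- normalize_allele_pair(out$pos[i], out$ref[i], out$alt[i])
    out$pos[i] <- n$pos; out$ref[i] <- n$ref; out$alt[i] <- n$alt
  }
  out$clin_sig <- normalize_clin_sig(out$clin_sig_raw)
  out[, c("chrom", "pos", "ref", "alt", "gene", "clin_sig", "clin_sig_raw",
          "hgvs_c", "hgvs_p", "rsid")]
}

#' Keep only pathogenic / likely pathogenic records
#'
#' Retains the three eligible significance classes (pathogenic, likely
#' pathogenic, and the combined pathogenic/likely-pathogenic label);
#' everything else — benign, VUS, and in particular records with conflicting
#' interpretations — is removed. Duplicate `(chrom,pos,ref,alt)` records
#' collapse to their first occurrence; input order is preserved. The filter
#' is total and idempotent.
#'
#' @param records data.frame from [parse_variant_table()].
#' @return the filtered data.frame.
#' @export
filter_plp <- function(records) {
  keep <- records$clin_sig %in% ELIGIBLE_CLIN_SIG
  out <- records[keep, , drop = FALSE]
  key <- paste(out$chrom, out$pos, out$ref, out$alt, sep = ":")
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# shape of a normalized allele pair
variant_shape <- function(ref, alt) {
  if (nchar(ref) == 1 && nchar(alt) == 1) "snv"
  else if (nchar(alt) == 1 && nchar(ref) > 1 &&
           substr(ref, 1, 1) == alt) "deletion"
  else if (nchar(ref) == 1 && nchar(alt) > 1 &&
           substr(alt, 1, 1) == ref) "insertion"
  else "substitution"
}

# genomic positions whose reference bases are changed/removed by the variant
variant_footprint <- function(pos, ref, alt) {
  switch(variant_shape(ref, alt),
         snv = pos,
         deletion = seq(pos + 1L, pos + nchar(ref) - 1L),
         insertion = c(pos, pos + 1L),   # flanks of the insertion point
         substitution = seq(pos, pos + nchar(ref) - 1L))
}

#' Classify a variant's consequence against a transcript model
#'
#' Assigns exactly one category, applying a fixed precedence when several
#' could fit: splice site (within the canonical window of an internal exon
#' boundary) beats everything; then coding categories (stopgain, frameshift
#' and non-frameshift indels/substitutions, amino-acid changes); then UTR;
#' then intron. The splice window (default +/-2 intronic bases) is
#' configurable because published type tables rarely state theirs.
#'
#' @param chrom,pos,ref,alt the normalized variant.
#' @param t a [transcript_model()].
#' @param splice_window intronic bases flanking each internal exon boundary
#'   that count as splice-site territory.
#' @param flank how far beyond the transcript span a variant may lie before
#'   it is rejected as unannotatable.
#' @return one category string.
#' @export
classify_consequence <- function(chrom, pos, ref, alt, t,
                                 splice_window = 2L, flank = 1000L) {
  stopifnot(inherits(t, "transcript_model"))
  norm <- normalize_allele_pair(pos, ref, alt)
  pos <- norm$pos; ref <- norm$ref; alt <- norm$alt
  span <- transcript_span(t)
  if (!identical(chrom, t$chrom) || pos < span[1] - flank || pos > span[2] + flank)
    stop("unannotatable: ", chrom, ":", pos, " outside ", t$gene,
         " span +/- ", flank)

  shape <- variant_shape(ref, alt)
  fp <- variant_footprint(pos, ref, alt)

  if (any(in_splice_window(t, fp, splice_window)))
    return("splice site")

  coding <- !is.na(genomic_to_cds(t, fp))
  if (shape == "insertion") {
    # an insertion is coding only if it lands strictly inside the CDS
    coding_ins <- all(!is.na(genomic_to_cds(t, c(pos, pos + 1L))))
    if (coding_ins) {
      k <- nchar(alt) - 1L
      return(if (k %% 3L != 0L) "frameshift insertion" else "nonframeshift insertion")
    }
  } else if (any(coding)) {
    if (shape == "deletion") {
      k <- nchar(ref) - 1L
      return(if (k %% 3L != 0L) "frameshift deletion" else "nonframeshift deletion")
    }
    if (shape == "substitution") {
      d <- nchar(alt) - nchar(ref)
      return(if (d %% 3L != 0L) "frameshift substitution" else "nonframeshift substitution")
    }
    return(classify_coding_snv(pos, ref, alt, t))
  }

  if (any(in_exon(t, fp))) return("5'/3' UTR")
  "intron variant"
}

classify_coding_snv <- function(pos, ref, alt, t) {
  ref_base <- substr(t$ref_seq, pos, pos)
  if (ref_base != toupper(ref))
    warning("reference mismatch at ", pos, ": model has ", ref_base,
            ", variant claims ", ref)
  cpos <- genomic_to_cds(t, pos)
  cds <- cds_seq(t)
  alt_tx <- if (t$strand == "-") revcomp(toupper(alt)) else toupper(alt)
  codon_i <- (cpos - 1L) %/% 3L
  codon <- substr(cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
  within <- (cpos - 1L) %% 3L + 1L
  mutated <- codon
  substr(mutated, within, within) <- alt_tx
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[codon]); aa_alt <- unname(code[mutated])
  if (is.na(aa_alt)) stop("cannot translate mutated codon ", mutated)
  if (aa_alt == "*" && aa_ref != "*") "stopgain/nonsense"
  else if (aa_alt != aa_ref) "nonsynonymous SNV"
  else "synonymous SNV"
}

#' Assign a protein domain to a coding variant
#'
#' Maps the variant's first affected coding base to a protein residue and
#' returns the label of the domain interval containing it. Domain intervals
#' are closed on both ends, matching how domain tables are published.
#'
#' @inheritParams classify_consequence
#' @return the domain label, or `NA` for variants outside every domain or
#'   outside the coding sequence entirely (not an error).
#' @export
assign_domain <- function(chrom, pos, ref, alt, t) {
  stopifnot(inherits(t, "transcript_model"))
  if (is.null(t$domains) || nrow(t$domains) == 0) return(NA_character_)
  norm <- normalize_allele_pair(pos, ref, alt)
  fp <- variant_footprint(norm$pos, norm$ref, norm$alt)
  res <- residue_at(t, fp)
  res <- res[!is.na(res)]
  if (length(res) == 0) return(NA_character_)
  r <- min(res)   # first affected residue in protein coordinates
  hit <- which(t$domains$start_res <= r & r <= t$domains$end_res)
  if (length(hit) == 0) NA_character_ else t$domains$label[hit[1]]
}

#' Annotate a panel with consequence and domain columns
#'
#' @param records normalized, filtered variant data.frame.
#' @param transcripts a single [transcript_model()] or a named list of them
#'   (names = gene symbols); rows are matched by gene, falling back to the
#'   transcript whose contig matches.
#' @param splice_window passed to [classify_consequence()].
#' @return `records` with `consequence` and `domain` columns appended.
#' @export
annotate_panel <- function(records, transcripts, splice_window = 2L) {
  if (inherits(transcripts, "transcript_model"))
    transcripts <- setNames(list(transcripts), transcripts$gene)
  chroms <- vapply(transcripts, function(t) t$chrom, character(1))
  records$consequence <- NA_character_
  records$domain <- NA_character_
  for (i in seq_len(nrow(records))) {
    g <- records$gene[i]
    t <- if (!is.na(g) && g %in% names(transcripts)) transcripts[[g]]
         else transcripts[[match(records$chrom[i], chroms)]]
    if (is.null(t))
      stop("no transcript model for record ", i, " (gene ", g, ", contig ",
           records$chrom[i], ")")
    records$consequence[i] <- classify_consequence(
      records$chrom[i], records$pos[i], records$ref[i], records$alt[i],
      t, splice_window = splice_window)
    records$domain[i] <- assign_domain(
      records$chrom[i], records$pos[i], records$ref[i], records$alt[i], t)
    if (is.na(records$gene[i])) records$gene[i] <- t$gene
  }
  records
}

#' Write a normalized panel as TSV
#' @param records annotated panel data.frame.
#' @param path output file.
#' @export
write_panel <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
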