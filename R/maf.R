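#' Alignment states of a (variant, species) cell
#'
#' Six exhaustive, mutually exclusive states: the species' aligned base
#' equals the human alternate allele (`SHARED`), equals the human reference
#' (`WILDTYPE`), differs from both (`OTHER`), is a gap inside an alignment
#' block (`GAP`), has no aligned base at all (`NO_ALIGN`), or falls in a gap
#' with at least one unaligned species base (`GAP_UNALIGNED`).
#' @export
ALIGNMENT_STATES <- c("SHARED", "WILDTYPE", "OTHER", "GAP", "NO_ALIGN",
                      "GAP_UNALIGNED")

#' Single-character display codes for the six states (heatmap legend order)
#' @export
STATE_CODES <- c(SHARED = "R", WILDTYPE = ".", OTHER = "B", GAP = "G",
                 NO_ALIGN = "-", GAP_UNALIGNED = "=")

# UCSC e-line statuses: C (contiguous deletion) and M (missing data) mean the
# species simply has no aligned base; I (insertion between blocks) and n
# (unaligned new sequence) mean the gap contains unaligned species sequence
eline_status_map <- function(status) {
  if (status %in% c("I", "n")) "GAP_UNALIGNED" else "NO_ALIGN"
}

#' Parse a MAF 1.0 multiple alignment
#'
#' Reads `a`/`s`/`e` lines; `i` and `q` lines are ignored, any other line
#' type is skipped with a warning. The first `s` row of each block is the
#' reference (human) row and must be on the `+` strand; blocks are indexed by
#' the reference row's genomic interval. Minus-strand species rows keep
#' MAF's strand-relative start together with the source size, so their
#' genomic coordinates stay recoverable; their text is already in alignment
#' orientation and is compared as-is.
#'
#' @param path path to a MAF file (optionally gzip-compressed), or a
#'   character vector of MAF lines.
#' @return an object of class `maf_alignment`: a list of blocks plus a
#'   reference-coordinate index.
#' @export
parse_maf <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path))
    readLines(path, warn = FALSE) else path
  if (length(lines) == 0 || !grepl("^##maf", lines[1]))
    stop("not a MAF file: missing ##maf header line")

  blocks <- list()
  cur <- NULL
  flush_block <- function(cur) {
    if (is.null(cur) || length(cur$rows) == 0) return(NULL)
    widths <- vapply(cur$rows, function(r) nchar(r$text), integer(1))
    if (length(unique(widths)) != 1)
      stop("row-length mismatch within block ", length(blocks) + 1)
    cur
  }
  for (ln in lines[-1]) {
    if (grepl("^\\s*$", ln) || startsWith(ln, "#")) next
    type <- substr(ln, 1, 1)
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (type == "a") {
      b <- flush_block(cur)
      if (!is.null(b)) blocks[[length(blocks) + 1]] <- b
      cur <- list(rows = list(), elines = list())
    } else if (type == "s") {
      if (is.null(cur)) stop("s line before any a line")
      if (length(f) != 7) stop("malformed s line: ", ln)
      src <- f[2]
      sp <- sub("\\..*$", "", src)
      chrom <- sub("^[^.]*\\.", "", src)
      start0 <- as.numeric(f[3]); size <- as.numeric(f[4])
      strand <- f[5]; src_size <- as.numeric(f[6]); text <- f[7]
      ungapped <- nchar(gsub("-", "", text, fixed = TRUE))
      if (ungapped != size)
        stop("declared size ", size, " != ungapped length ", ungapped,
             " for ", src)
      gstart <- if (strand == "+") start0 + 1 else src_size - start0 - size + 1
      cur$rows[[length(cur$rows) + 1]] <-
        list(species = sp, chrom = chrom, start0 = start0, size = size,
             strand = strand, src_size = src_size, text = text,
             gstart = gstart, gend = gstart + size - 1)
    } else if (type == "e") {
      if (is.null(cur)) stop("e line before any a line")
      sp <- sub("\\..*$", "", f[2])
      cur$elines[[sp]] <- f[7]
    } else if (type %in% c("i", "q")) {
      next
    } else {
      warning("skipping unknown MAF line type '", type, "'")
    }
  }
  b <- flush_block(cur)
  if (!is.null(b)) blocks[[length(blocks) + 1]] <- b
  if (length(blocks) == 0) stop("MAF contains no alignment blocks")

  ref_rows <- lapply(blocks, function(b) b$rows[[1]])
  for (r in ref_rows)
    if (r$strand != "+")
      stop("reference row on '-' strand is not supported (", r$species, ")")
  idx <- data.frame(
    chrom = vapply(ref_rows, function(r) r$chrom, character(1)),
    gstart = vapply(ref_rows, function(r) r$gstart, numeric(1)),
    gend = vapply(ref_rows, function(r) r$gend, numeric(1)),
    block = seq_along(blocks), stringsAsFactors = FALSE)
  for (ch in unique(idx$chrom)) {
    sub <- idx[idx$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$gstart), , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$gstart[-1] <= sub$gend[-nrow(sub)]))
      stop("reference rows overlap on ", ch)
  }
  species <- unique(unlist(lapply(blocks, function(b)
    c(vapply(b$rows, function(r) r$species, character(1)),
      names(b$elines)))))
  structure(list(blocks = blocks, index = idx,
                 ref_species = ref_rows[[1]]$species,
                 species = species),
            class = "maf_alignment")
}

#' @export
print.maf_alignment <- function(x, ...) {
  cat(sprintf("<maf_alignment> %d block(s), reference %s, %d species\n",
              length(x$blocks), x$ref_species, length(x$species)))
  invisible(x)
}

# block index covering a reference position, or NA
find_block <- function(a, chrom, pos) {
  hit <- a$index$block[a$index$chrom == chrom &
                         a$index$gstart <= pos & pos <= a$index$gend]
  if (length(hit) == 0) NA_integer_ else hit[1]
}

# alignment column where the reference row has its pos-th genomic base
ref_column <- function(block, pos) {
  ref <- block$rows[[1]]
  chars <- strsplit(ref$text, "")[[1]]
  base_cols <- which(chars != "-")
  base_cols[pos - ref$gstart + 1]
}

species_row <- function(block, species) {
  hits <- which(vapply(block$rows, function(r) r$species, character(1)) == species)
  if (length(hits) == 0) return(NULL)
  if (length(hits) > 1)
    message("duplicated rows for ", species, " in block; using the first")
  block$rows[[hits[1]]]
}

#' Aligned base of a species at a human genomic position
#'
#' Finds the alignment column where the reference row carries `pos` and
#' reports the species' character there: a base (`ALIGNED`), a within-block
#' gap (`GAP_IN_BLOCK`), or — when the species has no row in the covering
#' block — the e-line-derived absence status (`NO_ALIGN` or
#' `GAP_UNALIGNED`). Positions outside every block are `NO_ALIGN`.
#'
#' @param a a [parse_maf()] alignment.
#' @param chrom,pos 1-based reference coordinates.
#' @param species species name (MAF source prefix).
#' @return list with `species`, `bases` (empty unless `ALIGNED`), `status`.
#' @export
species_base_at <- function(a, chrom, pos, species) {
  stopifnot(inherits(a, "maf_alignment"))
  obs <- function(bases, status)
    structure(list(species = species, bases = bases, status = status),
              class = "species_obs")
  bi <- find_block(a, chrom, pos)
  if (is.na(bi)) return(obs("", "NO_ALIGN"))
  block <- a$blocks[[bi]]
  row <- species_row(block, species)
  if (is.null(row)) {
    st <- block$elines[[species]]
    if (is.null(st)) return(obs("", "NO_ALIGN"))
    return(obs("", eline_status_map(st)))
  }
  col <- ref_column(block, pos)
  ch <- substr(row$text, col, col)
  if (ch == "-") obs("", "GAP_IN_BLOCK") else obs(toupper(ch), "ALIGNED")
}

#' Classify a species observation against a human SNV
#'
#' Total function over the observation statuses: an aligned base equal to the
#' alternate allele is `SHARED`, equal to the reference is `WILDTYPE`, any
#' other base (including `N`, which matches neither allele) is `OTHER`;
#' gap/absence statuses map to `GAP`, `NO_ALIGN`, `GAP_UNALIGNED`.
#' Comparison is case-insensitive (MAF soft-masks with lowercase).
#'
#' @param ref_allele,alt_allele single-base human alleles.
#' @param obs observation from [species_base_at()].
#' @return one of [ALIGNMENT_STATES].
#' @export
classify_state <- function(ref_allele, alt_allele, obs) {
  switch(obs$status,
         ALIGNED = {
           b <- toupper(obs$bases)
           if (b == toupper(alt_allele)) "SHARED"
           else if (b == toupper(ref_allele)) "WILDTYPE"
           else "OTHER"
         },
         GAP_IN_BLOCK = "GAP",
         NO_ALIGN = "NO_ALIGN",
         GAP_UNALIGNED = "GAP_UNALIGNED",
         stop("unknown observation status: ", obs$status))
}

# split block texts into character matrices once per block (cached per call)
block_chars <- function(block) {
  lapply(block$rows, function(r) strsplit(r$text, "")[[1]])
}

#' Does a species carry an equal-length gap at a human indel locus?
#'
#' A species is considered to share a human indel only when, over the
#' alignment columns spanning the locus, the species row differs from the
#' human row by a gap run of exactly the same length as the indel, with
#' aligned bases on both flanks. A gap run of any other length — which
#' would shift the reading frame differently — never matches.
#'
#' @param a a [parse_maf()] alignment.
#' @param chrom,pos,ref,alt the normalized (anchored) indel.
#' @param species species name.
#' @return list with `match` (logical), `status` (`ALIGNED`, or the absence
#'   status — `NO_ALIGN` when the locus is not covered), and `differs`
#'   (TRUE when the species shows an indel-like difference at the locus
#'   that is *not* an equal-length match, e.g. a gap run of another length).
#' @export
match_indel <- function(a, chrom, pos, ref, alt, species) {
  stopifnot(inherits(a, "maf_alignment"))
  shape <- variant_shape(toupper(ref), toupper(alt))
  if (!shape %in% c("deletion", "insertion"))
    stop("match_indel expects an anchored insertion or deletion")
  k <- abs(nchar(ref) - nchar(alt))
  last_ref <- if (shape == "deletion") pos + k else pos + 1L

  bi <- find_block(a, chrom, pos)
  if (is.na(bi) || !identical(bi, find_block(a, chrom, last_ref)))
    return(list(match = FALSE, status = "NO_ALIGN", differs = FALSE))
  block <- a$blocks[[bi]]
  row <- species_row(block, species)
  if (is.null(row)) {
    st <- block$elines[[species]]
    return(list(match = FALSE,
                status = if (is.null(st)) "NO_ALIGN" else eline_status_map(st),
                differs = FALSE))
  }
  ref_chars <- strsplit(block$rows[[1]]$text, "")[[1]]
  sp_chars <- strsplit(row$text, "")[[1]]

  if (shape == "deletion") {
    cols <- vapply(seq(pos, pos + k), function(p) ref_column(block, p),
                   integer(1))
    anchor <- cols[1]; del_cols <- cols[-1]
    any_gap <- any(sp_chars[cols] == "-")
    if (sp_chars[anchor] == "-" || any(sp_chars[del_cols] != "-"))
      return(list(match = FALSE, status = "ALIGNED", differs = any_gap))
    # the species gap run containing the deleted columns must remove exactly
    # k reference bases: extend over contiguous species gaps and count the
    # columns where the human row has a base
    run_l <- min(del_cols); run_r <- max(del_cols)
    while (run_l > 1 && sp_chars[run_l - 1] == "-") run_l <- run_l - 1
    while (run_r < length(sp_chars) && sp_chars[run_r + 1] == "-") run_r <- run_r + 1
    gap_len <- sum(ref_chars[run_l:run_r] != "-")
    ok <- gap_len == k
    list(match = ok, status = "ALIGNED", differs = !ok)
  } else {
    c_left <- ref_column(block, pos)
    c_right <- ref_column(block, pos + 1L)
    if (sp_chars[c_left] == "-" || sp_chars[c_right] == "-")
      return(list(match = FALSE, status = "ALIGNED", differs = TRUE))
    between <- if (c_right - c_left > 1) seq(c_left + 1, c_right - 1) else integer(0)
    ins_cols <- between[ref_chars[between] == "-"]
    n_ins <- sum(sp_chars[ins_cols] != "-")
    ok <- n_ins == k && length(ins_cols) >= 1
    list(match = ok, status = "ALIGNED", differs = !ok && n_ins > 0)
  }
}

#' Build the variants-by-species state matrix
#'
#' One of the six [ALIGNMENT_STATES] per (variant, species) cell. SNVs (and
#' equal-length substitutions) go through [species_base_at()] /
#' [classify_state()]; insertions and deletions through the equal-length
#' gap rule of [match_indel()], where a matching gap is `SHARED`, an
#' ungapped species row is `WILDTYPE`, and a gap of the wrong length is
#' `OTHER`. Variants on contigs absent from the alignment get a whole row
#' of `NO_ALIGN` with a warning.
#'
#' @param variants normalized variant data.frame (`chrom,pos,ref,alt`).
#' @param a a [parse_maf()] alignment.
#' @param species_list species to include as columns.
#' @return character matrix of class `state_matrix`, rows named by variant
#'   key, columns by species.
#' @export
build_state_matrix <- function(variants, a, species_list = NULL) {
  stopifnot(inherits(a, "maf_alignment"))
  if (is.null(species_list))
    species_list <- setdiff(a$species, a$ref_species)
  m <- matrix(NA_character_, nrow = nrow(variants), ncol = length(species_list),
              dimnames = list(variant_key(variants), species_list))
  for (i in seq_len(nrow(variants))) {
    chrom <- variants$chrom[i]; pos <- variants$pos[i]
    ref <- toupper(variants$ref[i]); alt <- toupper(variants$alt[i])
    if (!chrom %in% a$index$chrom) {
      warning("contig ", chrom, " absent from alignment; row is NO_ALIGN")
      m[i, ] <- "NO_ALIGN"
      next
    }
    shape <- variant_shape(ref, alt)
    for (s in species_list) {
      m[i, s] <- if (shape %in% c("insertion", "deletion")) {
        res <- match_indel(a, chrom, pos, ref, alt, s)
        if (res$match) "SHARED"
        else if (res$status != "ALIGNED") res$status
        else if (res$differs) "OTHER"
        else "WILDTYPE"
      } else if (shape == "substitution" && nchar(ref) == nchar(alt)) {
        classify_mnv(a, chrom, pos, ref, alt, s)
      } else {
        classify_state(ref, alt, species_base_at(a, chrom, pos, s))
      }
    }
  }
  structure(m, class = c("state_matrix", class(m)))
}

# equal-length multi-base substitution: compare the concatenated aligned bases
classify_mnv <- function(a, chrom, pos, ref, alt, species) {
  obs <- lapply(seq(pos, pos + nchar(ref) - 1L), function(p)
    species_base_at(a, chrom, p, species))
  statuses <- vapply(obs, function(o) o$status, character(1))
  if (any(statuses == "GAP_IN_BLOCK")) return("GAP")
  if (any(statuses == "GAP_UNALIGNED")) return("GAP_UNALIGNED")
  if (any(statuses == "NO_ALIGN")) return("NO_ALIGN")
  b <- paste(vapply(obs, function(o) o$bases, character(1)), collapse = "")
  if (b == alt) "SHARED" else if (b == ref) "WILDTYPE" else "OTHER"
}

#' Write a state matrix as wide (display codes) and long TSVs
#'
#' @param m a [build_state_matrix()] result.
#' @param path_wide,path_long output paths (`NULL` to skip either).
#' @export
write_state_matrix <- function(m, path_wide = NULL, path_long = NULL) {
  if (!is.null(path_wide)) {
    codes <- matrix(STATE_CODES[m], nrow = nrow(m), dimnames = dimnames(m))
    df <- data.frame(variant = rownames(m), codes, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path_wide, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_long)) {
    long <- data.frame(variant = rep(rownames(m), times = ncol(m)),
                       species = rep(colnames(m), each = nrow(m)),
                       state = as.vector(m), stringsAsFactors = FALSE)
    long <- long[order(long$variant, long$species), ]
    write.table(long, path_long, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(m)
}
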