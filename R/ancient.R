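#' Read a plain-text SAM file into an ancient sample
#'
#' Light tab parser for the eleven mandatory SAM columns; header `@SQ` lines
#' provide contig lengths. Body rows with fewer than eleven fields, or whose
#' sequence and quality strings disagree in length, are skipped with a
#' warning rather than aborting the screen.
#'
#' @param path SAM file.
#' @param sample_id,age_bp,age_sd,site sample metadata carried into matches.
#' @return an object of class `ancient_sample`.
#' @export
read_sam <- function(path, sample_id = basename(path), age_bp = NA_real_,
                     age_sd = NA_real_, site = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  contigs <- list()
  for (h in hdr[startsWith(hdr, "@SQ")]) {
    f <- strsplit(h, "\t", fixed = TRUE)[[1]]
    sn <- sub("^SN:", "", f[startsWith(f, "SN:")][1])
    ln <- as.integer(sub("^LN:", "", f[startsWith(f, "LN:")][1]))
    contigs[[sn]] <- ln
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 11
  if (any(!ok))
    warning("skipping ", sum(!ok), " SAM row(s) with fewer than 11 fields")
  fields <- fields[ok]
  reads <- data.frame(
    qname = vapply(fields, `[`, "", 1),
    flag = as.integer(vapply(fields, `[`, "", 2)),
    rname = vapply(fields, `[`, "", 3),
    pos = as.integer(vapply(fields, `[`, "", 4)),
    mapq = as.integer(vapply(fields, `[`, "", 5)),
    cigar = vapply(fields, `[`, "", 6),
    seq = vapply(fields, `[`, "", 10),
    qual = vapply(fields, `[`, "", 11),
    stringsAsFactors = FALSE)
  bad_len <- reads$qual != "*" & nchar(reads$seq) != nchar(reads$qual)
  if (any(bad_len)) {
    warning("skipping ", sum(bad_len), " read(s) with |seq| != |qual|")
    reads <- reads[!bad_len, , drop = FALSE]
  }
  structure(list(sample_id = sample_id, age_bp = age_bp, age_sd = age_sd,
                 site = site, contigs = contigs, reads = reads),
            class = "ancient_sample")
}

#' Construct an ancient sample from in-memory reads
#' @param reads data.frame with SAM-like columns
#'   `qname,flag,rname,pos,mapq,cigar,seq,qual`.
#' @inheritParams read_sam
#' @param contigs named list of contig lengths.
#' @return an `ancient_sample`.
#' @export
ancient_sample <- function(reads, sample_id, age_bp = NA_real_,
                           age_sd = NA_real_, site = NA_character_,
                           contigs = list()) {
  need <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  stopifnot(all(need %in% names(reads)))
  structure(list(sample_id = sample_id, age_bp = age_bp, age_sd = age_sd,
                 site = site, contigs = contigs, reads = reads),
            class = "ancient_sample")
}

#' @export
print.ancient_sample <- function(x, ...) {
  cat(sprintf("<ancient_sample> %s: %d read(s), age %s BP, site %s\n",
              x$sample_id, nrow(x$reads), format(x$age_bp), x$site))
  invisible(x)
}

# parse a CIGAR string into (length, op) pairs
cigar_ops <- function(cigar) {
  if (cigar == "*") return(data.frame(len = integer(0), op = character(0)))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  data.frame(len = lens, op = ops, stringsAsFactors = FALSE)
}

# reference span consumed by a CIGAR
cigar_ref_len <- function(ops) sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])
# query length consumed by a CIGAR
cigar_query_len <- function(ops) sum(ops$len[ops$op %in% c("M", "=", "X", "I", "S")])

# query index (1-based) aligned to reference position rpos, or:
#   0  -> rpos falls in a deletion/skip (read covers it, no base)
#   NA -> read does not cover rpos
query_index_at <- function(read_pos, ops, rpos) {
  r <- read_pos; q <- 1L
  for (i in seq_len(nrow(ops))) {
    len <- ops$len[i]; op <- ops$op[i]
    if (op %in% c("M", "=", "X")) {
      if (rpos < r + len && rpos >= r) return(q + (rpos - r))
      r <- r + len; q <- q + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      if (rpos < r + len && rpos >= r) return(0L)
      r <- r + len
    }                                   # H, P consume nothing
  }
  NA_integer_
}

#' Base-quality-filtered pileup at one position
#'
#' Counts the read bases aligned over a reference position, resolved through
#' each read's CIGAR (M/=/X contribute a base; I and S are skipped; a
#' position inside D/N contributes none), keeping only bases whose quality
#' is at least `min_bq` (inclusive: the threshold reads as a floor, so
#' quality 1 passes at `min_bq = 1` and only quality 0 is excluded). Reads
#' whose CIGAR and sequence lengths disagree are skipped with a warning.
#'
#' @param sample an `ancient_sample`.
#' @param chrom,pos reference position (1-based).
#' @param min_bq minimum base quality (phred), inclusive.
#' @param min_mapq minimum mapping quality; 0 disables the filter.
#' @return list with `chrom`, `pos`, `depth_total` (reads overlapping),
#'   `counts` (named base counts after filters), `min_bq`.
#' @export
pileup <- function(sample, chrom, pos, min_bq = 1L, min_mapq = 0L) {
  stopifnot(inherits(sample, "ancient_sample"), min_bq >= 0)
  reads <- sample$reads
  counts <- integer(0)
  depth <- 0L
  cand <- which(reads$rname == chrom & reads$pos <= pos & reads$cigar != "*")
  for (i in cand) {
    ops <- cigar_ops(reads$cigar[i])
    if (cigar_query_len(ops) != nchar(reads$seq[i])) {
      warning("skipping read ", reads$qname[i],
              ": CIGAR/sequence length mismatch")
      next
    }
    if (pos >= reads$pos[i] + cigar_ref_len(ops)) next
    qi <- query_index_at(reads$pos[i], ops, pos)
    if (is.na(qi)) next
    depth <- depth + 1L
    if (qi == 0L) next                      # deletion spans the position
    if (min_mapq > 0 && reads$mapq[i] < min_mapq) next
    bq <- qual_to_phred(reads$qual[i])
    if (length(bq) >= qi && bq[qi] < min_bq) next
    b <- toupper(substr(reads$seq[i], qi, qi))
    counts[b] <- (if (b %in% names(counts)) counts[[b]] else 0L) + 1L
  }
  list(chrom = chrom, pos = pos, depth_total = depth, counts = counts,
       min_bq = as.integer(min_bq))
}

# reads supporting an indel allele via an explicit I/D CIGAR op of identical
# length at the locus (mirrors the alignment-side equal-length rule)
indel_support <- function(sample, chrom, pos, ref, alt, min_mapq = 0L) {
  shape <- variant_shape(toupper(ref), toupper(alt))
  k <- abs(nchar(ref) - nchar(alt))
  reads <- sample$reads
  n <- 0L; depth <- 0L
  cand <- which(reads$rname == chrom & reads$pos <= pos & reads$cigar != "*")
  for (i in cand) {
    ops <- cigar_ops(reads$cigar[i])
    if (pos >= reads$pos[i] + cigar_ref_len(ops)) next
    depth <- depth + 1L
    if (min_mapq > 0 && reads$mapq[i] < min_mapq) next
    r <- reads$pos[i]
    for (j in seq_len(nrow(ops))) {
      op <- ops$op[j]; len <- ops$len[j]
      if (shape == "deletion" && op == "D" && r == pos + 1L && len == k) n <- n + 1L
      if (shape == "insertion" && op == "I" && r == pos + 1L && len == k) n <- n + 1L
      if (op %in% c("M", "=", "X", "D", "N")) r <- r + len
    }
  }
  list(alt_count = n, depth = depth)
}

#' Screen an ancient sample against a variant panel
#'
#' Runs a quality-filtered pileup at every panel position and reports one
#' match per panel variant with at least `min_alt_reads` alternate-supporting
#' read bases. SNVs match on the pileup base counts; insertions and
#' deletions match only through explicit I/D CIGAR operations of identical
#' length at the locus. Evidence (`alt_count`, `depth`) is carried in the
#' output so stricter post-filters remain possible; zero matches is a valid
#' result.
#'
#' @param sample an `ancient_sample`.
#' @param panel normalized, annotated variant data.frame.
#' @param min_bq minimum base quality, inclusive.
#' @param min_alt_reads minimum alternate-supporting reads.
#' @param min_mapq minimum mapping quality (0 = off).
#' @return data.frame of matches (possibly zero rows) with sample metadata,
#'   variant annotation, `alt_count` and `depth`.
#' @export
match_variants <- function(sample, panel, min_bq = 1L, min_alt_reads = 1L,
                           min_mapq = 0L) {
  stopifnot(inherits(sample, "ancient_sample"), min_alt_reads >= 1)
  rows <- list()
  for (i in seq_len(nrow(panel))) {
    ref <- toupper(panel$ref[i]); alt <- toupper(panel$alt[i])
    shape <- variant_shape(ref, alt)
    if (shape %in% c("insertion", "deletion")) {
      res <- indel_support(sample, panel$chrom[i], panel$pos[i], ref, alt,
                           min_mapq)
      alt_count <- res$alt_count; depth <- res$depth
    } else {
      p <- pileup(sample, panel$chrom[i], panel$pos[i], min_bq, min_mapq)
      alt_count <- if (alt %in% names(p$counts)) p$counts[[alt]] else 0L
      depth <- p$depth_total
    }
    if (alt_count >= min_alt_reads) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sample$sample_id, age_bp = sample$age_bp,
        age_sd = sample$age_sd, site = sample$site,
        chrom = panel$chrom[i], pos = panel$pos[i], ref = ref, alt = alt,
        gene = if ("gene" %in% names(panel)) panel$gene[i] else NA_character_,
        hgvs_c = if ("hgvs_c" %in% names(panel)) panel$hgvs_c[i] else NA_character_,
        hgvs_p = if ("hgvs_p" %in% names(panel)) panel$hgvs_p[i] else NA_character_,
        type = if ("consequence" %in% names(panel)) panel$consequence[i] else NA_character_,
        rsid = if ("rsid" %in% names(panel)) panel$rsid[i] else NA_character_,
        domain = if ("domain" %in% names(panel)) panel$domain[i] else NA_character_,
        alt_count = alt_count, depth = depth, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty_matches())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_matches <- function() {
  data.frame(sample_id = character(0), age_bp = numeric(0),
             age_sd = numeric(0), site = character(0), chrom = character(0),
             pos = integer(0), ref = character(0), alt = character(0),
             gene = character(0), hgvs_c = character(0), hgvs_p = character(0),
             type = character(0), rsid = character(0), domain = character(0),
             alt_count = integer(0), depth = integer(0),
             stringsAsFactors = FALSE)
}

#' Per-gene summary of ancient matches
#'
#' Each input row is one (individual, variant) detection record; matches may
#' span samples. Per gene the summary reports the number of records, the
#' number of distinct variants, the recurrent variants (detected in at least
#' two individuals), the oldest and youngest record by age, and — over
#' distinct variants, as published summaries count them — the breakdown by
#' verbatim type label and by domain. Because published tables label the
#' same molecular class both "stopgain" and "nonsense", a merged
#' `n_stopgain_like` count is reported alongside the verbatim counts.
#'
#' @param matches data.frame of match records ([match_variants()] output, or
#'   a transcription of a published match table with `gene`, `hgvs_c`,
#'   `type`, `domain`, `age_bp` columns).
#' @return list keyed by gene plus an `overall` entry.
#' @export
summarize_matches <- function(matches) {
  if (nrow(matches) == 0)
    return(list(overall = list(n_records = 0L, n_variants = 0L)))
  matches$.key <- variant_key(matches)
  genes <- sort(unique(matches$gene))
  out <- list()
  for (g in genes) {
    mg <- matches[matches$gene == g, , drop = FALSE]
    first <- mg[!duplicated(mg$.key), , drop = FALSE]   # one row per variant
    per_var_records <- table(mg$.key)
    recurrent <- names(per_var_records)[per_var_records >= 2]
    type_tab <- table(first$type)
    in_dom <- !is.na(first$domain) & first$domain != "" & first$domain != "—"
    dom_tab <- table(first$domain[in_dom])
    out[[g]] <- list(
      gene = g,
      n_records = nrow(mg),
      n_variants = nrow(first),
      n_recurrent = length(recurrent),
      recurrent = recurrent,
      by_type = setNames(as.integer(type_tab), names(type_tab)),
      n_stopgain_like = sum(first$type %in%
                              c("stopgain", "nonsense", "stopgain/nonsense")),
      by_domain = setNames(as.integer(dom_tab), names(dom_tab)),
      n_in_domain = sum(in_dom),
      oldest_age_bp = max(mg$age_bp, na.rm = TRUE),
      youngest_age_bp = min(mg$age_bp, na.rm = TRUE))
  }
  out$overall <- list(
    n_records = nrow(matches),
    n_variants = length(unique(matches$.key)))
  out
}
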