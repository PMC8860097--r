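# ---- independent oracles -------------------------------------------------
# These re-derive expected values through deliberately different code paths
# (column-by-column string walks, per-read expansion tables, closed-form
# rank formulas) so the package implementation is checked against something
# it does not share code with.

# minimal MAF reader for the oracle: list of blocks, each a list with
# ref (species,start,chars) and rows (named list species -> chars) + elines
bf_read_maf <- function(lines) {
  blocks <- list(); cur <- NULL
  for (ln in lines) {
    if (grepl("^a", ln)) {
      if (!is.null(cur)) blocks[[length(blocks) + 1]] <- cur
      cur <- list(rows = list(), elines = list(), order = character(0))
    } else if (grepl("^s ", ln)) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      sp <- sub("\\..*", "", f[2])
      cur$rows[[sp]] <- list(start0 = as.integer(f[3]),
                             chars = strsplit(f[7], "")[[1]])
      cur$order <- c(cur$order, sp)
    } else if (grepl("^e ", ln)) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      cur$elines[[sub("\\..*", "", f[2])]] <- f[7]
    }
  }
  if (!is.null(cur)) blocks[[length(blocks) + 1]] <- cur
  blocks
}

# per-column walk: vector mapping reference position -> (block, column)
bf_locate <- function(blocks) {
  ref_sp <- blocks[[1]]$order[1]
  loc <- list()
  for (bi in seq_along(blocks)) {
    ref <- blocks[[bi]]$rows[[ref_sp]]
    p <- ref$start0
    for (col in seq_along(ref$chars)) {
      if (ref$chars[col] != "-") {
        p <- p + 1L
        loc[[as.character(p)]] <- c(bi, col)
      }
    }
  }
  loc
}

bf_eline_state <- function(st) if (st %in% c("I", "n")) "GAP_UNALIGNED" else "NO_ALIGN"

# brute-force state of one (variant, species) cell by walking gapped strings
bf_state <- function(blocks, loc, pos, ref, alt, species) {
  ref_sp <- blocks[[1]]$order[1]
  at <- loc[[as.character(pos)]]
  if (is.null(at)) return("NO_ALIGN")
  blk <- blocks[[at[1]]]
  if (!species %in% names(blk$rows)) {
    st <- blk$elines[[species]]
    return(if (is.null(st)) "NO_ALIGN" else bf_eline_state(st))
  }
  sp_chars <- blk$rows[[species]]$chars
  ref_chars <- blk$rows[[ref_sp]]$chars
  if (nchar(ref) == 1 && nchar(alt) == 1) {
    ch <- toupper(sp_chars[at[2]])
    if (ch == "-") return("GAP")
    if (ch == toupper(alt)) return("SHARED")
    if (ch == toupper(ref)) return("WILDTYPE")
    return("OTHER")
  }
  # anchored deletion: walk the columns of the deleted bases
  k <- nchar(ref) - 1L
  locs <- lapply(pos:(pos + k), function(p) loc[[as.character(p)]])
  if (any(vapply(locs, is.null, logical(1))) ||
      length(unique(vapply(locs, `[`, 0, 1))) != 1)
    return("NO_ALIGN")
  cols <- vapply(locs, `[`, 0, 2)
  spch <- toupper(sp_chars)
  if (!any(spch[cols] == "-")) return("WILDTYPE")
  if (spch[cols[1]] != "-" && all(spch[cols[-1]] == "-")) {
    l <- min(cols[-1]); r <- max(cols[-1])
    while (l > 1 && spch[l - 1] == "-") l <- l - 1
    while (r < length(spch) && spch[r + 1] == "-") r <- r + 1
    if (sum(ref_chars[l:r] != "-") == k) return("SHARED")
  }
  "OTHER"
}

bf_state_matrix <- function(maf_lines, variants, species_list) {
  blocks <- bf_read_maf(maf_lines)
  loc <- bf_locate(blocks)
  m <- matrix(NA_character_, nrow(variants), length(species_list),
              dimnames = list(NULL, species_list))
  for (i in seq_len(nrow(variants)))
    for (s in species_list)
      m[i, s] <- bf_state(blocks, loc, variants$pos[i], variants$ref[i],
                          variants$alt[i], s)
  m
}

# random small MAF instance + SNV/deletion probes for oracle equivalence
random_maf_instance <- function(seed, n_species = 3, n_cols = 60) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  sp <- paste0("sp", seq_len(n_species))
  ref_chars <- sample(bases, n_cols, replace = TRUE)
  ref_chars[runif(n_cols) < 0.05] <- "-"        # insertions in some species
  rows <- list()
  for (s in sp) {
    ch <- ref_chars
    mut <- runif(n_cols) < 0.25
    ch[mut] <- sample(bases, sum(mut), replace = TRUE)
    gap <- runif(n_cols) < 0.12
    ch[gap] <- "-"
    ch[ref_chars == "-" & runif(n_cols) < 0.5] <- "-"
    rows[[s]] <- ch
  }
  start0 <- sample(0:50, 1)
  fmt_row <- function(name, chars, src_size = 1000) {
    n <- sum(chars != "-")
    sprintf("s %s.chrR %d %d + %d %s", name, start0, n, src_size,
            paste(chars, collapse = ""))
  }
  lines <- c("##maf version=1", "", "a score=0",
             fmt_row("hg", ref_chars),
             vapply(sp, function(s) fmt_row(s, rows[[s]]), character(1)), "")
  ref_positions <- (start0 + 1):(start0 + sum(ref_chars != "-"))
  n_pos <- length(ref_positions)
  ref_base_at <- ref_chars[ref_chars != "-"]
  probes <- list()
  for (j in 1:6) {   # SNV probes
    i <- sample(n_pos, 1)
    rb <- ref_base_at[i]
    probes[[j]] <- data.frame(chrom = "chrR", pos = ref_positions[i], ref = rb,
                              alt = sample(setdiff(bases, rb), 1),
                              stringsAsFactors = FALSE)
  }
  for (j in 1:3) {   # deletion probes (anchor + k deleted bases)
    k <- sample(1:3, 1)
    i <- sample(n_pos - k - 1, 1)
    probes[[6 + j]] <- data.frame(
      chrom = "chrR", pos = ref_positions[i],
      ref = paste(ref_base_at[i:(i + k)], collapse = ""),
      alt = ref_base_at[i], stringsAsFactors = FALSE)
  }
  list(lines = lines, variants = do.call(rbind, probes), species = sp)
}

# ---- pileup oracle: expand reads into a long (refpos, base, qual) table ----
bf_pileup <- function(reads, chrom, pos, min_bq = 1L) {
  tab <- list()
  depth <- 0L
  for (i in seq_len(nrow(reads))) {
    if (reads$rname[i] != chrom) next
    lens <- as.integer(regmatches(reads$cigar[i],
                                  gregexpr("[0-9]+", reads$cigar[i]))[[1]])
    ops <- regmatches(reads$cigar[i], gregexpr("[A-Z=]", reads$cigar[i]))[[1]]
    r <- reads$pos[i]; q <- 1L
    covered <- FALSE; base <- NULL; bq <- NULL
    for (j in seq_along(ops)) {
      if (ops[j] %in% c("M", "=", "X")) {
        for (t in seq_len(lens[j])) {
          if (r == pos) {
            covered <- TRUE
            base <- toupper(substr(reads$seq[i], q, q))
            bq <- utf8ToInt(substr(reads$qual[i], q, q)) - 33L
          }
          r <- r + 1L; q <- q + 1L
        }
      } else if (ops[j] %in% c("I", "S")) q <- q + lens[j]
      else if (ops[j] %in% c("D", "N")) {
        if (pos >= r && pos < r + lens[j]) covered <- TRUE
        r <- r + lens[j]
      }
    }
    if (covered) {
      depth <- depth + 1L
      if (!is.null(base) && bq >= min_bq)
        tab[[length(tab) + 1]] <- base
    }
  }
  counts <- table(unlist(tab))
  list(depth_total = depth, counts = setNames(as.integer(counts),
                                              names(counts)))
}

# ---- closed-form statistics -----------------------------------------------
kw_hand <- function(groups) {
  x <- unlist(groups); N <- length(x)
  r <- rank(x)
  ni <- lengths(groups)
  cuts <- rep(seq_along(groups), ni)
  Ri <- tapply(r, cuts, mean)
  H <- 12 / (N * (N + 1)) * sum(ni * (Ri - (N + 1) / 2)^2)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

chisq_hand <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}
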