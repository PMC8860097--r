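#' Configuration for the synthetic-data generators
#'
#' Collects every knob of the alignment, panel and ancient-read simulators
#' in one validated list. The seed is mandatory: no generator output may
#' depend on hidden randomness.
#'
#' @param seed integer seed; identical configs give byte-identical outputs.
#' @param tree Newick string with branch lengths; tips are the non-reference
#'   species, the root carries the reference (human) sequence.
#' @param subst_rate substitutions per site per unit branch length
#'   (Jukes-Cantor).
#' @param gap_rate per-site probability that a species gap run starts.
#' @param gap_mean_len mean length of a geometric gap run.
#' @param L number of reference sites simulated.
#' @param root_seq optional reference (root) sequence string; defaults to a
#'   random sequence of length `L`. Supplying the panel generator's contig
#'   here keeps variant alleles and alignment columns consistent across
#'   modules.
#' @param chrom,ref_species names used in the emitted MAF.
#' @param n_blocks number of alignment blocks the contig is split into.
#' @param eline_prob per (species, block) probability that the species is
#'   absent from the block and represented by an e-line instead.
#' @param planted_shared data.frame of planted shared SNVs: `variant_id`,
#'   `pos`, `alt`, `species` (comma-separated species carrying the alt).
#' @param planted_indels data.frame of planted deletions: `variant_id`,
#'   `pos` (anchor), `k` (deleted bases), `species` (comma-separated set
#'   with an equal-length gap), `unequal_species` (comma-separated set
#'   given a gap of length k+1, exercising the length rule).
#' @param probe_variants data.frame of unplanted SNV probes (`variant_id`,
#'   `pos`, `alt`) whose truth is whatever the neutral process produced.
#' @param ancient list of ancient-read settings: `n_samples`, `coverage`,
#'   `read_len`, `damage_rate` (5' terminal C->T probability),
#'   `bq_probs` (named vector, names = phred values), `carriers`
#'   (data.frame `sample_id`, `variant_id`), `age_range`.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              tree = "((sp1:0.1,sp2:0.1):0.1,(sp3:0.15,sp4:0.15):0.05);",
                              subst_rate = 0.1, gap_rate = 0.01,
                              gap_mean_len = 3, L = 600L, root_seq = NULL,
                              chrom = "chrT", ref_species = "hg",
                              n_blocks = 2L, eline_prob = 0,
                              planted_shared = NULL, planted_indels = NULL,
                              probe_variants = NULL, ancient = list()) {
  stopifnot(is.numeric(seed), length(seed) == 1, !is.na(seed))
  rates <- c(subst_rate = subst_rate, gap_rate = gap_rate,
             eline_prob = eline_prob)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  # base qualities: modern callers emit q0 ("no confidence") rarely; 2%
  # keeps the quality-floor path exercised without dominating the screen
  anc_defaults <- list(n_samples = 10L, coverage = 10, read_len = 76L,
                       damage_rate = 0, bq_probs = c("37" = 0.90, "20" = 0.08, "0" = 0.02),
                       carriers = NULL, age_range = c(300, 40000))
  ancient <- utils::modifyList(anc_defaults, ancient)
  if (ancient$damage_rate < 0 || ancient$damage_rate > 1)
    stop("damage_rate must lie in [0, 1]")
  if (!is.null(root_seq)) {
    stopifnot(is.character(root_seq), length(root_seq) == 1)
    L <- nchar(root_seq)
  }
  structure(list(seed = as.integer(seed), tree = tree,
                 subst_rate = subst_rate, gap_rate = gap_rate,
                 gap_mean_len = gap_mean_len, L = as.integer(L),
                 root_seq = root_seq,
                 chrom = chrom, ref_species = ref_species,
                 n_blocks = as.integer(n_blocks), eline_prob = eline_prob,
                 planted_shared = planted_shared,
                 planted_indels = planted_indels,
                 probe_variants = probe_variants, ancient = ancient),
            class = "simulation_config")
}

split_species <- function(x) {
  if (is.na(x) || x == "") character(0) else strsplit(x, ",", fixed = TRUE)[[1]]
}

# Jukes-Cantor substitution probability over a branch
jc_p_diff <- function(rate, branch) 0.75 * (1 - exp(-4 / 3 * rate * branch))

# evolve tip sequences from a root sequence along an ape phylo tree
evolve_jc <- function(tree, root_seq, rate) {
  n_tip <- length(tree$tip.label)
  seqs <- vector("list", n_tip + tree$Nnode)
  root <- n_tip + 1L
  seqs[[root]] <- root_seq
  bases <- c("A", "C", "G", "T")
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (i in seq_len(nrow(edges))) {
    parent <- edges[i, 1]; child <- edges[i, 2]
    s <- seqs[[parent]]
    p <- jc_p_diff(rate, lens[i])
    hit <- which(runif(length(s)) < p)
    for (j in hit) s[j] <- sample(setdiff(bases, s[j]), 1)
    seqs[[child]] <- s
  }
  setNames(seqs[seq_len(n_tip)], tree$tip.label)
}

#' Simulate a MAF alignment with a known truth table
#'
#' The reference row is the ancestral sequence; each tree tip evolves from
#' it under Jukes-Cantor at `subst_rate` per unit branch length. Planted
#' shared alleles override the neutral process at their cells (species not
#' in a planted set are reverted to the reference base if the neutral
#' process happened to hit the alternate), planted deletions insert
#' equal-length (or deliberately unequal) gap runs, and random gap runs of
#' geometric length exercise the gap states. The truth table records the
#' resulting state of every (variant, species) cell, derived from the
#' simulated arrays independently of the MAF writer/parser.
#'
#' @param cfg a [simulation_config()].
#' @return list with `maf` (character vector of MAF lines), `truth`
#'   (data.frame `variant_id`, `species`, `state`), `variants` (the panel
#'   data.frame for the planted + probe variants), `ref_seq` (reference
#'   sequence string), and `tips` (species sequences, gaps as `-`).
#' @export
simulate_alignment <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  tree <- ape::read.tree(text = cfg$tree)
  if (is.null(tree$edge.length))
    stop("tree must carry branch lengths")
  L <- cfg$L
  bases <- c("A", "C", "G", "T")
  root_seq <- if (!is.null(cfg$root_seq))
    strsplit(toupper(cfg$root_seq), "")[[1]]
  else sample(bases, L, replace = TRUE)
  tips <- evolve_jc(tree, root_seq, cfg$subst_rate)
  species <- names(tips)

  planted <- cfg$planted_shared
  if (!is.null(planted)) {
    if (any(planted$pos < 1 | planted$pos > L))
      stop("planted variant outside the simulated contig")
    for (i in seq_len(nrow(planted))) {
      p <- planted$pos[i]; alt <- planted$alt[i]
      carriers <- split_species(planted$species[i])
      missing_sp <- setdiff(carriers, species)
      if (length(missing_sp) > 0)
        stop("planted species not in tree: ", paste(missing_sp, collapse = ", "))
      if (alt == root_seq[p])
        stop("planted alt equals the reference base at ", p)
      for (s in species) {
        if (s %in% carriers) tips[[s]][p] <- alt
        else if (tips[[s]][p] == alt) tips[[s]][p] <- root_seq[p]
      }
    }
  }

  indels <- cfg$planted_indels
  protected <- rep(FALSE, L)   # sites no random gap run may touch
  if (!is.null(planted)) protected[planted$pos] <- TRUE
  if (!is.null(cfg$probe_variants)) protected[cfg$probe_variants$pos] <- TRUE
  if (!is.null(indels)) {
    for (i in seq_len(nrow(indels))) {
      lo <- indels$pos[i]; hi <- min(L, indels$pos[i] + indels$k[i] + 2L)
      protected[lo:hi] <- TRUE
    }
  }

  gaps <- setNames(lapply(species, function(s) rep(FALSE, L)), species)
  for (s in species) {
    starts <- which(runif(L) < cfg$gap_rate & !protected)
    for (st in starts) {
      placed <- FALSE
      for (try in 1:20) {   # bounded retries when a run collides with a planted cell
        len <- rgeom(1, 1 / cfg$gap_mean_len) + 1L
        run <- st:min(L, st + len - 1L)
        if (!any(protected[run])) { gaps[[s]][run] <- TRUE; placed <- TRUE; break }
      }
      if (!placed) gaps[[s]][st] <- TRUE   # length-1 run never collides here
    }
  }

  if (!is.null(indels)) {
    for (i in seq_len(nrow(indels))) {
      p <- indels$pos[i]; k <- indels$k[i]
      if (p + k + 1L > L) stop("planted indel extends past the contig")
      for (s in split_species(indels$species[i]))
        gaps[[s]][(p + 1L):(p + k)] <- TRUE
      for (s in split_species(indels$unequal_species[i]))
        gaps[[s]][(p + 1L):(p + k + 1L)] <- TRUE
    }
  }

  # block layout and e-lines
  bounds <- floor(seq(0, L, length.out = cfg$n_blocks + 1L))
  block_of <- findInterval(seq_len(L), bounds[-1] + 1L) + 1L
  elines <- matrix(NA_character_, nrow = length(species), ncol = cfg$n_blocks,
                   dimnames = list(species, NULL))
  all_variants <- variants_frame(cfg, root_seq)
  if (cfg$eline_prob > 0) {
    for (s in species) for (b in seq_len(cfg$n_blocks)) {
      has_planted_cell <- any(vapply(seq_len(nrow(all_variants)), function(i)
        block_of[all_variants$pos[i]] == b &&
          s %in% split_species(all_variants$planted_species[i]), logical(1)))
      if (!has_planted_cell && runif(1) < cfg$eline_prob)
        elines[s, b] <- sample(c("C", "I"), 1)
    }
  }

  maf <- write_maf_lines(cfg, root_seq, tips, gaps, block_of, elines)
  truth <- derive_truth(cfg, all_variants, root_seq, tips, gaps, block_of,
                        elines)
  list(maf = maf, truth = truth,
       variants = all_variants[, c("variant_id", "chrom", "pos", "ref", "alt")],
       ref_seq = paste(root_seq, collapse = ""), tips = tips, gaps = gaps)
}

# unified table of planted SNVs, planted deletions and neutral probes
variants_frame <- function(cfg, root_seq) {
  rows <- list()
  add <- function(id, pos, ref, alt, planted_sp, unequal_sp = "") {
    rows[[length(rows) + 1]] <<- data.frame(
      variant_id = id, chrom = cfg$chrom, pos = as.integer(pos), ref = ref,
      alt = alt, planted_species = planted_sp, unequal_species = unequal_sp,
      stringsAsFactors = FALSE)
  }
  if (!is.null(cfg$planted_shared))
    for (i in seq_len(nrow(cfg$planted_shared))) {
      v <- cfg$planted_shared[i, ]
      add(v$variant_id, v$pos, root_seq[v$pos], v$alt, v$species)
    }
  if (!is.null(cfg$planted_indels))
    for (i in seq_len(nrow(cfg$planted_indels))) {
      v <- cfg$planted_indels[i, ]
      ref <- paste(root_seq[v$pos:(v$pos + v$k)], collapse = "")
      add(v$variant_id, v$pos, ref, root_seq[v$pos], v$species,
          if ("unequal_species" %in% names(v)) v$unequal_species else "")
    }
  if (!is.null(cfg$probe_variants))
    for (i in seq_len(nrow(cfg$probe_variants))) {
      v <- cfg$probe_variants[i, ]
      add(v$variant_id, v$pos, root_seq[v$pos], v$alt, "")
    }
  if (length(rows) == 0)
    return(data.frame(variant_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      planted_species = character(0),
                      unequal_species = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# truth derived from the simulated arrays (independent of the MAF writer)
derive_truth <- function(cfg, variants, root_seq, tips, gaps, block_of,
                         elines) {
  species <- names(tips)
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    is_del <- nchar(v$ref) > 1
    k <- nchar(v$ref) - 1L
    for (s in species) {
      el <- elines[s, block_of[v$pos]]
      state <- if (!is.na(el)) {
        eline_status_map(el)
      } else if (!is_del) {
        if (gaps[[s]][v$pos]) "GAP"
        else {
          b <- tips[[s]][v$pos]
          if (b == v$alt) "SHARED" else if (b == v$ref) "WILDTYPE" else "OTHER"
        }
      } else {
        locus <- v$pos:(v$pos + k)
        if (length(unique(block_of[locus])) > 1) "NO_ALIGN"
        else {
          g <- gaps[[s]]
          if (!any(g[locus])) "WILDTYPE"
          else if (!g[v$pos] && all(g[(v$pos + 1L):(v$pos + k)])) {
            run_l <- v$pos + 1L; run_r <- v$pos + k
            while (run_r < cfg$L && g[run_r + 1L]) run_r <- run_r + 1L
            if (run_r - run_l + 1L == k) "SHARED" else "OTHER"
          } else "OTHER"
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        variant_id = v$variant_id, species = s, state = state,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# emit MAF text: one s row per species per block, all-gap rows dropped
write_maf_lines <- function(cfg, root_seq, tips, gaps, block_of, elines) {
  species <- names(tips)
  lines <- c("##maf version=1 scoring=none", "")
  sp_offset <- setNames(rep(0L, length(species)), species)
  src_size <- vapply(species, function(s) sum(!gaps[[s]]), integer(1))
  for (b in seq_len(max(block_of))) {
    posns <- which(block_of == b)
    lines <- c(lines, "a score=0.0")
    ref_text <- paste(root_seq[posns], collapse = "")
    lines <- c(lines, sprintf("s %s.%s %d %d + %d %s",
                              cfg$ref_species, cfg$chrom, posns[1] - 1L,
                              length(posns), cfg$L, ref_text))
    for (s in species) {
      if (!is.na(elines[s, b])) {
        lines <- c(lines, sprintf("e %s.%s %d 0 + %d %s",
                                  s, cfg$chrom, sp_offset[s], src_size[s],
                                  elines[s, b]))
        next
      }
      chars <- ifelse(gaps[[s]][posns], "-", tips[[s]][posns])
      n_bases <- sum(chars != "-")
      lines <- c(lines, sprintf("s %s.%s %d %d + %d %s",
                                s, cfg$chrom, sp_offset[s], n_bases,
                                src_size[s], paste(chars, collapse = "")))
      sp_offset[s] <- sp_offset[s] + n_bases
    }
    lines <- c(lines, "")
  }
  lines
}
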