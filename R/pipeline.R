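#' Ingest a founder-variant table
#'
#' Founder variants are recurrent population-specific PLP variants whose
#' arisen times were dated by haplotype analysis in the original studies;
#' the ages are data, never recomputed. Each row is one founder record:
#' the same variant reported in two populations counts as two records.
#'
#' @param x data.frame, or path to a TSV with columns
#'   `gene, age_bp, population, hgvs_c` (plus optional `hgvs_p`, `type`).
#' @return list with `records` (the accepted rows), `per_gene` (record
#'   counts), `n_records`, `oldest_age_bp` / `youngest_age_bp` (overall and
#'   per gene), and `by_type`.
#' @export
ingest_founders <- function(x) {
  d <- if (is.character(x))
    read.delim(x, comment.char = "#", stringsAsFactors = FALSE, fill = TRUE)
  else x
  if (nrow(d) == 0)
    return(list(records = d, per_gene = integer(0), n_records = 0L,
                oldest_age_bp = NA_real_, youngest_age_bp = NA_real_,
                by_type = integer(0), age_range_by_gene = list()))
  stopifnot(all(c("gene", "age_bp", "population") %in% names(d)))
  age <- suppressWarnings(as.numeric(d$age_bp))
  bad <- is.na(age)
  if (any(bad)) {
    warning("rejecting ", sum(bad), " founder row(s) with non-numeric age")
    d <- d[!bad, , drop = FALSE]
    age <- age[!bad]
  }
  d$age_bp <- age
  # the youngest bound of a dated range, where the table gives one
  young <- if ("age_bp_min" %in% names(d))
    ifelse(is.na(suppressWarnings(as.numeric(d$age_bp_min))), d$age_bp,
           suppressWarnings(as.numeric(d$age_bp_min)))
  else d$age_bp
  per_gene <- table(d$gene)
  age_range_by_gene <- lapply(split(seq_len(nrow(d)), d$gene), function(i)
    c(oldest = max(d$age_bp[i]), youngest = min(young[i])))
  ttab <- if ("type" %in% names(d)) table(d$type[!is.na(d$type) & d$type != ""])
          else table(character(0))
  list(records = d,
       per_gene = setNames(as.integer(per_gene), names(per_gene)),
       n_records = nrow(d),
       oldest_age_bp = max(d$age_bp),
       youngest_age_bp = min(young),
       age_range_by_gene = age_range_by_gene,
       by_type = setNames(as.integer(ttab), names(ttab)))
}

#' Build the published-style summary table from an annotated panel
#'
#' Section A counts the panel by significance class and consequence type;
#' section B counts the variants shared with at least one species, by type;
#' section C is the histogram of species counts per shared variant.
#'
#' @param variants annotated panel (needs `gene`, `clin_sig`, `consequence`).
#' @param per_variant_shared integer vector, species sharing each variant.
#' @return data.frame with `section`, `label`, one column per gene, `total`,
#'   `total_pct`.
#' @export
build_type_table <- function(variants, per_variant_shared) {
  stopifnot(length(per_variant_shared) == nrow(variants))
  genes <- sort(unique(variants$gene))
  n_total <- nrow(variants)
  count_row <- function(section, label, sel) {
    counts <- vapply(genes, function(g) sum(sel & variants$gene == g),
                     integer(1))
    out <- data.frame(section = section, label = label,
                      stringsAsFactors = FALSE)
    for (g in genes) out[[g]] <- sum(sel & variants$gene == g)
    out$total <- sum(sel)
    out$total_pct <- pct_round1(sum(sel), n_total)
    out
  }
  rows <- list(count_row("A", "total", rep(TRUE, n_total)))
  for (s in ELIGIBLE_CLIN_SIG)
    rows[[length(rows) + 1]] <- count_row("A", s, variants$clin_sig == s)
  cats <- CONSEQUENCE_CATEGORIES[CONSEQUENCE_CATEGORIES %in% variants$consequence]
  for (k in cats)
    rows[[length(rows) + 1]] <- count_row("A", k, variants$consequence == k)
  shared <- per_variant_shared >= 1
  rows[[length(rows) + 1]] <- count_row("B", "shared_mutation", shared)
  for (k in cats)
    rows[[length(rows) + 1]] <- count_row("B", k, shared & variants$consequence == k)
  for (k in sort(unique(per_variant_shared[shared])))
    rows[[length(rows) + 1]] <- count_row("C", as.character(k),
                                          per_variant_shared == k)
  do.call(rbind, rows)
}

# depth-first tip order of a Newick tree, used to order species columns
tree_tip_order <- function(tree) {
  if (is.character(tree))
    tree <- ape::read.tree(text = if (file.exists(tree[1]))
      paste(readLines(tree[1], warn = FALSE), collapse = "") else tree)
  tree$tip.label
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full screening pipeline and write its report bundle
#'
#' Orchestrates panel ingestion and filtering, consequence/domain
#' annotation, the cross-species state matrix, the sharing summary with
#' clade and domain tests, the ancient-sample screen, and the
#' founder-table ingest, writing fixed-format TSV/JSON reports. Report
#' ordering is stable (variants by chromosome/position/alt, species in tree
#' tip order when a tree is given, ancient matches by age descending), so
#' re-running with identical inputs is byte-identical. Any stage failure
#' aborts with the stage name.
#'
#' @param cfg a list with entries: `panel` (data.frame or VCF/TSV path),
#'   `transcripts` ([transcript_model()] or named list), `maf` (path, lines,
#'   or [parse_maf()] object), `clade_map` (data.frame or TSV path),
#'   `tree` (Newick string/path, optional), `samples` (list of
#'   `ancient_sample` objects, optional), `founders` (data.frame or TSV
#'   path, optional), `out_dir`, `seed` (recorded in provenance), and
#'   thresholds `min_bq`, `min_alt_reads`, `splice_window`.
#' @return invisibly, a list with the in-memory results (`panel`, `matrix`,
#'   `summary`, `clade_test`, `domain`, `ancient_matches`,
#'   `ancient_summary`, `founders`, `paths`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$out_dir))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  min_bq <- cfg$min_bq %||% 1L
  min_alt_reads <- cfg$min_alt_reads %||% 1L
  splice_window <- cfg$splice_window %||% 2L
  out <- function(f) file.path(cfg$out_dir, f)

  panel <- run_stage("panel", {
    p <- if (is.character(cfg$panel)) parse_variant_table(cfg$panel)
         else cfg$panel
    p <- filter_plp(p)
    if (!"consequence" %in% names(p)) {
      if (is.null(cfg$transcripts))
        stop("panel lacks consequence annotation and no transcripts given")
      p <- annotate_panel(p, cfg$transcripts, splice_window = splice_window)
    }
    p <- p[order(p$chrom, p$pos, p$alt), , drop = FALSE]
    rownames(p) <- NULL
    p
  })
  write_panel(panel, out("panel.tsv"))

  aln <- run_stage("alignment", {
    if (inherits(cfg$maf, "maf_alignment")) cfg$maf else parse_maf(cfg$maf)
  })
  species <- setdiff(aln$species, aln$ref_species)
  if (!is.null(cfg$tree)) {
    ord <- tree_tip_order(cfg$tree)
    species <- c(intersect(ord, species), setdiff(species, ord))
  }
  m <- run_stage("state_matrix",
                 build_state_matrix(panel, aln, species_list = species))
  write_state_matrix(m, out("state_matrix.tsv"), out("state_matrix_long.tsv"))

  clade_map <- run_stage("clade_map", {
    cm <- if (is.character(cfg$clade_map))
      read.delim(cfg$clade_map, stringsAsFactors = FALSE) else cfg$clade_map
    cm
  })
  summ <- run_stage("summaries", summarize_sharing(m, panel, clade_map))
  t1 <- build_type_table(panel, summ$per_variant)
  write.table(t1, out("type_table.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  clade_test <- run_stage("clade_test", clade_comparison(summ))
  jsonlite::write_json(
    list(method = clade_test$method,
         statistic = round(clade_test$statistic, 6),
         df = clade_test$df, p_value = signif(clade_test$p_value, 6),
         groups = clade_test$groups),
    out("clade_test.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  dom <- run_stage("domain_test", {
    tab <- summ$domain_table
    if (!is.null(tab) && all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      list(table = tab, test = chi_squared(tab))
    else list(table = tab, test = NULL)
  })
  dom_json <- list(table = if (is.null(dom$table)) NULL else as.data.frame.matrix(dom$table))
  if (!is.null(dom$test))
    dom_json <- c(dom_json, list(statistic = round(dom$test$statistic, 6),
                                 df = dom$test$df,
                                 p_value = signif(dom$test$p_value, 6)))
  jsonlite::write_json(dom_json, out("domain_test.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  matches <- run_stage("ancient", {
    if (is.null(cfg$samples) || length(cfg$samples) == 0) empty_matches()
    else {
      ml <- lapply(cfg$samples, match_variants, panel = panel,
                   min_bq = min_bq, min_alt_reads = min_alt_reads)
      mm <- do.call(rbind, ml)
      mm <- mm[order(-mm$age_bp, mm$sample_id, mm$pos), , drop = FALSE]
      rownames(mm) <- NULL
      mm
    }
  })
  write.table(matches, out("ancient_matches.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  anc_sum <- summarize_matches(matches)
  jsonlite::write_json(anc_sum, out("ancient_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  founders <- run_stage("founders", {
    if (is.null(cfg$founders)) NULL else ingest_founders(cfg$founders)
  })
  if (!is.null(founders))
    jsonlite::write_json(
      founders[c("per_gene", "n_records", "oldest_age_bp",
                 "youngest_age_bp", "by_type")],
      out("founder_summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)

  prov <- list(
    package = "plptrace",
    version = as.character(utils::packageVersion("plptrace")),
    seed = cfg$seed %||% NA,
    n_variants = nrow(panel), n_species = ncol(m),
    config_hash = config_hash(cfg))
  jsonlite::write_json(prov, out("provenance.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(panel = panel, matrix = m, summary = summ,
                 clade_test = clade_test, domain = dom,
                 ancient_matches = matches, ancient_summary = anc_sum,
                 founders = founders,
                 paths = vapply(c("panel.tsv", "state_matrix.tsv",
                                  "state_matrix_long.tsv", "type_table.tsv",
                                  "clade_test.json", "domain_test.json",
                                  "ancient_matches.tsv",
                                  "ancient_summary.json", "provenance.json"),
                                out, character(1))))
}

# md5 over the deterministic parts of the config (paths and thresholds)
config_hash <- function(cfg) {
  keep <- cfg[intersect(names(cfg), c("min_bq", "min_alt_reads",
                                      "splice_window", "seed"))]
  cfg$out_dir <- NULL                   # the hash describes inputs, not where
  paths <- cfg[vapply(cfg, is.character, logical(1))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(c(keep, paths)), tmp)
  unname(tools::md5sum(tmp))
}
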