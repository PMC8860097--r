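#' Cross-tabulate sharing from a state matrix
#'
#' Builds the per-variant / per-species / per-clade sharing counts, the
#' histogram of how many species share each variant (k >= 1 only; unshared
#' variants are counted separately), the consequence-type table among all
#' and among shared variants, and the 2x2 shared-by-domain table. Percents
#' are rounded half away from zero to one decimal, matching published count
#' tables. Internal conservation checks assert that the histogram and the
#' per-species totals recount the same set of `SHARED` cells.
#'
#' @param m a [build_state_matrix()] result.
#' @param variants the annotated variant data.frame behind the matrix rows
#'   (must carry `consequence`; `domain` is used when present).
#' @param clade_map data.frame with columns `species`, `clade`; every matrix
#'   column must be mapped to exactly one clade.
#' @return a `sharing_summary` list.
#' @export
summarize_sharing <- function(m, variants, clade_map) {
  stopifnot(inherits(m, "state_matrix"), nrow(m) == nrow(variants),
            all(c("species", "clade") %in% names(clade_map)))
  unmapped <- setdiff(colnames(m), clade_map$species)
  if (length(unmapped) > 0)
    stop("species missing from clade map: ", paste(unmapped, collapse = ", "))
  dup <- clade_map$species[duplicated(clade_map$species)]
  if (length(dup) > 0)
    stop("species mapped to more than one clade: ", paste(dup, collapse = ", "))

  shared_cells <- m == "SHARED"
  per_variant <- rowSums(shared_cells)
  per_species <- colSums(shared_cells)
  clades <- clade_map$clade[match(colnames(m), clade_map$species)]
  per_clade <- split(unname(per_species), clades)

  hist_tab <- table(per_variant[per_variant >= 1])
  histogram <- setNames(as.integer(hist_tab), names(hist_tab))

  # conservation: both margins recount the same SHARED cell set
  stopifnot(sum(per_variant) == sum(shared_cells),
            sum(per_species) == sum(shared_cells),
            sum(as.integer(names(histogram)) * histogram) == sum(shared_cells))

  shared_variant <- per_variant >= 1
  type_table <- type_crosstab(variants$consequence, shared_variant)

  domain_table <- NULL
  if ("domain" %in% names(variants)) {
    in_domain <- !is.na(variants$domain) & variants$domain != "" &
      variants$domain != "—"
    domain_table <- table(
      factor(ifelse(shared_variant, "shared", "not_shared"),
             levels = c("shared", "not_shared")),
      factor(ifelse(in_domain, "in_domain", "outside"),
             levels = c("in_domain", "outside")))
  }

  structure(list(per_variant = per_variant, per_species = per_species,
                 per_clade = per_clade, histogram = histogram,
                 n_variants = nrow(m),
                 n_shared_variants = sum(shared_variant),
                 shared_pct = pct_round1(sum(shared_variant), nrow(m)),
                 type_table = type_table, domain_table = domain_table),
            class = "sharing_summary")
}

# counts and percents per consequence category, among all and among shared
type_crosstab <- function(consequence, shared) {
  cats <- unique(c(CONSEQUENCE_CATEGORIES, sort(unique(consequence))))
  cats <- cats[cats %in% consequence]
  n_all <- vapply(cats, function(k) sum(consequence == k), integer(1))
  n_shared <- vapply(cats, function(k) sum(consequence == k & shared), integer(1))
  data.frame(consequence = cats, n = n_all,
             pct = pct_round1(n_all, length(consequence)),
             n_shared = n_shared,
             pct_shared_of_all = pct_round1(n_shared, length(consequence)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.sharing_summary <- function(x, ...) {
  cat(sprintf("<sharing_summary> %d variants, %d shared (%.1f%%) across %d species\n",
              x$n_variants, x$n_shared_variants, x$shared_pct,
              length(x$per_species)))
  invisible(x)
}

#' Kruskal-Wallis rank test across groups
#'
#' Thin, validated surface over [stats::kruskal.test()] returning the
#' tie-corrected H statistic and its chi-squared approximation with
#' `groups - 1` degrees of freedom. The degenerate case where every
#' observation is identical returns H = 0, p = 1 rather than a 0/0 tie
#' correction.
#'
#' @param groups list (length >= 2) of non-empty numeric vectors.
#' @return a `plp_test` list: `method`, `statistic`, `df`, `p_value`,
#'   `group_sizes`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) == 0)) stop("empty group")
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1) {
    res <- list(statistic = 0, df = length(groups) - 1L, p_value = 1)
  } else {
    kt <- stats::kruskal.test(x, g)
    res <- list(statistic = unname(kt$statistic), df = unname(kt$parameter),
                p_value = kt$p.value)
  }
  structure(c(list(method = "kruskal_wallis"), res,
              list(group_sizes = lengths(groups))),
            class = "plp_test")
}

#' Pearson chi-squared test on a contingency table
#'
#' Surface over [stats::chisq.test()] without Yates continuity correction by
#' default (a `correct` flag is available). Tables with a zero row or
#' column margin are rejected as degenerate rather than returning NaN.
#'
#' @param tab matrix of counts, at least 2x2, all >= 0.
#' @param correct apply the continuity correction (2x2 only).
#' @return a `plp_test` list.
#' @export
chi_squared <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) >= 2, ncol(tab) >= 2, all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate margin: zero row or column total")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  structure(list(method = "chi_squared", statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 group_sizes = dim(tab)),
            class = "plp_test")
}

#' @export
print.plp_test <- function(x, ...) {
  cat(sprintf("<plp_test> %s: statistic = %.4f, df = %d, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Compare per-species sharing counts between clades
#'
#' The comparison unit is the number of shared variants per species, grouped
#' by clade, compared with a Kruskal-Wallis rank test — the only reading of
#' "shared between clades" consistent with a rank test over clades.
#'
#' @param summary a [summarize_sharing()] result.
#' @return a `plp_test`, with the per-clade groups attached as `groups`.
#' @export
clade_comparison <- function(summary) {
  stopifnot(inherits(summary, "sharing_summary"))
  res <- kruskal_wallis(summary$per_clade)
  res$groups <- summary$per_clade
  res
}

#' Shared-by-domain 2x2 table and its chi-squared test
#'
#' Tests whether shared variants are enriched in annotated protein domains:
#' counts (shared vs not shared) x (inside any domain vs outside) and the
#' Pearson chi-squared result.
#'
#' @param variants annotated variant data.frame (needs `domain`).
#' @param m matching [build_state_matrix()] result.
#' @return list with `table` (2x2) and `test` (`plp_test`).
#' @export
domain_distribution <- function(variants, m) {
  stopifnot(nrow(variants) == nrow(m), "domain" %in% names(variants))
  shared <- rowSums(m == "SHARED") >= 1
  in_domain <- !is.na(variants$domain) & variants$domain != "" &
    variants$domain != "—"
  tab <- table(factor(ifelse(shared, "shared", "not_shared"),
                      levels = c("shared", "not_shared")),
               factor(ifelse(in_domain, "in_domain", "outside"),
                      levels = c("in_domain", "outside")))
  list(table = tab, test = chi_squared(tab))
}
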