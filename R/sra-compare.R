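# Rearranged-vs-control comparison of expression and chromatin metrics.
#
# Continuous metrics (HEB, TPM, HPHB, summit FE) are tested with the
# Kruskal-Wallis rank test globally and the unpaired two-sample rank-sum
# (Mann-Whitney) test per region; categorical metrics (expressed
# proportion, dominance category distribution, peak status) with chi-square
# contingency tests. P-values are Benjamini-Hochberg adjusted.

#' Kruskal-Wallis rank test
#'
#' Wrapper around [stats::kruskal.test()] (rank-based H statistic with tie
#' correction, chi-square reference with k-1 df). When every value in every
#' group is identical the statistic is 0 and p = 1.
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups).
#' @return list `statistic` (H), `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) == 0))
    stop("kruskal_wallis needs >= 2 non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1) return(list(statistic = 0, p_value = 1))
  k <- kruskal.test(groups)
  list(statistic = unname(k$statistic), p_value = k$p.value)
}

#' Two-sample rank-sum (Mann-Whitney) test
#'
#' Two-sided; exact enumeration when both groups have at most
#' `exact_max` observations and there are no ties, otherwise the normal
#' approximation with tie correction (no continuity correction, so
#' identical groups give p = 1).
#'
#' @param a,b numeric vectors.
#' @param exact_max maximum group size for the exact null distribution.
#' @return list `statistic` (U), `p_value`.
#' @export
rank_sum <- function(a, b, exact_max = 8) {
  if (length(a) == 0 || length(b) == 0) stop("rank_sum: empty group")
  use_exact <- length(a) <= exact_max && length(b) <= exact_max &&
    !anyDuplicated(c(a, b))
  w <- suppressWarnings(wilcox.test(a, b, exact = use_exact,
                                    correct = FALSE))
  list(statistic = unname(w$statistic), p_value = min(w$p.value, 1))
}

#' Chi-square contingency test of category proportions
#'
#' Test of independence on a groups x categories count table, without
#' continuity correction. A warning is raised when any expected count is
#' below 1 (the p-value is still returned).
#'
#' @param counts integer matrix (rows = groups, columns = categories), or
#'   four scalars `k1, n1, k2, n2` giving successes/totals of two groups.
#' @param n1,k2,n2 see above (scalar form).
#' @return list `statistic` (chi-square), `p_value`.
#' @export
proportion_test <- function(counts, n1 = NULL, k2 = NULL, n2 = NULL) {
  if (!is.null(n1)) {
    k1 <- counts
    counts <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  }
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2 || ncol(counts) < 2)
    return(list(statistic = 0, p_value = 1))
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  if (any(ct$expected < 1))
    warning("expected cell count below 1; chi-square approximation is poor")
  list(statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment via [stats::p.adjust()]; output in input order.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  p.adjust(p, method = "BH")
}

sig_stars <- function(p) ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "ns"))

comparison_row <- function(metric, scope, n_control, n_rearranged,
                           statistic, p_raw, direction, low_n = FALSE) {
  data.frame(metric = metric, scope = scope, n_control = n_control,
             n_rearranged = n_rearranged, statistic = statistic,
             p_raw = p_raw, direction = direction, low_n = low_n,
             stringsAsFactors = FALSE)
}

cont_direction <- function(x_rearr, x_ctrl) {
  d <- median(x_rearr) - median(x_ctrl)
  if (d > 0) "up" else if (d < 0) "down" else "none"
}

# assemble the seven metric tests for one rearranged group against the
# control; `test_cont(ra, ctrl)` supplies the continuous test
metric_tests <- function(gene_metrics, dyad_metrics, is_rearr_gene,
                         is_rearr_dyad, scope, test_cont,
                         allow_empty = FALSE) {
  rows <- list()
  na_row <- function(metric, n_control, n_rearranged) {
    rows[[length(rows) + 1]] <<- comparison_row(
      metric, scope, n_control, n_rearranged, NA_real_, NA_real_,
      "none", low_n = TRUE)
  }
  add_cont <- function(metric, values, rearr) {
    v <- values
    r <- rearr
    ok <- !is.na(v)
    a <- v[ok & r]
    b <- v[ok & !r]
    if (length(a) == 0 || length(b) == 0) {
      if (allow_empty) return(na_row(metric, length(b), length(a)))
      stop("empty group for metric ", metric)
    }
    t <- test_cont(a, b)
    rows[[length(rows) + 1]] <<- comparison_row(
      metric, scope, length(b), length(a), t$statistic, t$p_value,
      cont_direction(a, b), low_n = length(a) < 5)
  }
  add_cat <- function(metric, cat, rearr) {
    ok <- !is.na(cat)
    cl <- if (is.logical(cat)) factor(cat[ok], levels = c(FALSE, TRUE))
          else factor(cat[ok])
    tab <- table(factor(rearr[ok], levels = c(FALSE, TRUE)), cl)
    if (any(rowSums(tab) == 0)) {
      if (allow_empty) return(na_row(metric, sum(tab[1, ]), sum(tab[2, ])))
      stop("empty group for metric ", metric)
    }
    t <- proportion_test(unclass(tab))
    dir <- "none"
    if (is.logical(cat)) {
      pr <- prop.table(tab, 1)[, "TRUE"]
      dir <- if (pr[2] > pr[1]) "up" else if (pr[2] < pr[1]) "down" else "none"
    }
    rows[[length(rows) + 1]] <<- comparison_row(
      metric, scope, sum(tab[1, ]), sum(tab[2, ]), t$statistic, t$p_value,
      dir, low_n = sum(tab[2, ]) < 5)
  }
  add_cont("HEB", dyad_metrics$heb, is_rearr_dyad)
  add_cont("TPM", gene_metrics$global_tpm, is_rearr_gene)
  add_cont("HPHB", dyad_metrics$hphb, is_rearr_dyad)
  add_cont("H3K4me3_summit", gene_metrics$summit, is_rearr_gene)
  add_cat("prop_expressed", gene_metrics$expressed, is_rearr_gene)
  add_cat("DCB", dyad_metrics$dominance, is_rearr_dyad)
  add_cat("H3K4me3_status", gene_metrics$peak, is_rearr_gene)
  do.call(rbind, rows)
}

#' Global rearranged-vs-control comparison (Table 1 analogue)
#'
#' Tests seven metrics between all rearranged and all non-rearranged
#' features: HEB, HPHB and dominance-category bias (DCB) at the dyad level;
#' TPM, summit FE, expressed proportion and peak status at the gene level.
#' Continuous metrics use the Kruskal-Wallis test, categorical ones the
#' chi-square contingency test; p-values are BH-adjusted across the seven
#' metrics.
#'
#' @param gene_metrics data.frame with columns `gene_id`, `label`
#'   (`rearranged` / `non_rearranged`), `global_tpm`, `summit`, `expressed`
#'   (logical), `peak` (logical).
#' @param dyad_metrics data.frame with columns `dyad_id`, `label`, `heb`,
#'   `hphb`, `dominance`.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame of comparison results, one row per metric, with
#'   `p_adj`, `significant` and `stars`.
#' @export
compare_global <- function(gene_metrics, dyad_metrics, alpha = 0.05) {
  if (!any(gene_metrics$label == "rearranged"))
    stop("no rearranged group: every gene is labelled non_rearranged")
  res <- metric_tests(gene_metrics, dyad_metrics,
                      gene_metrics$label == "rearranged",
                      dyad_metrics$label == "rearranged",
                      scope = "global",
                      test_cont = function(a, b) kruskal_wallis(list(a, b)))
  res$p_adj <- bh_adjust(res$p_raw)
  res$significant <- res$p_adj <= alpha
  res$stars <- sig_stars(res$p_adj)
  res$direction[!res$significant] <- "none"
  res
}

#' Per-region comparison against the pooled control (Figure 3 analogue)
#'
#' Each rearrangement region is tested against the pooled non-rearranged
#' control with the unpaired rank-sum test (continuous metrics) or the
#' chi-square contingency test (categorical); BH adjustment is applied
#' within each metric across regions. Regions with fewer than 5 rearranged
#' dyads are flagged `low_n` but still tested.
#'
#' @inheritParams compare_global
#' @param gene_metrics as in [compare_global()], plus a `region_id` column.
#' @param dyad_metrics as in [compare_global()], plus a `region_id` column.
#' @return data.frame of comparison results, one row per region x metric.
#' @export
compare_per_region <- function(gene_metrics, dyad_metrics, alpha = 0.05) {
  regions <- sort(unique(stats::na.omit(c(gene_metrics$region_id,
                                          dyad_metrics$region_id))))
  if (length(regions) == 0) stop("no regions to compare")
  ctrl_g <- gene_metrics$label == "non_rearranged"
  ctrl_d <- dyad_metrics$label == "non_rearranged"
  res <- do.call(rbind, lapply(regions, function(r) {
    in_g <- !is.na(gene_metrics$region_id) & gene_metrics$region_id == r
    in_d <- !is.na(dyad_metrics$region_id) & dyad_metrics$region_id == r
    metric_tests(gene_metrics[ctrl_g | in_g, , drop = FALSE],
                 dyad_metrics[ctrl_d | in_d, , drop = FALSE],
                 in_g[ctrl_g | in_g], in_d[ctrl_d | in_d],
                 scope = r, test_cont = rank_sum, allow_empty = TRUE)
  }))
  res$p_adj <- NA_real_
  for (m in unique(res$metric)) {
    i <- res$metric == m & !is.na(res$p_raw)
    res$p_adj[i] <- bh_adjust(res$p_raw[i])
  }
  res$significant <- !is.na(res$p_adj) & res$p_adj <= alpha
  res$stars <- ifelse(is.na(res$p_adj), "na", sig_stars(res$p_adj))
  res$direction[!res$significant] <- "none"
  res
}
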