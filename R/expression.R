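# Expression filtering, CV classification, and homoeolog expression bias.
#
# Conventions: a gene is "expressed" in a tissue when TPM >= 1; a gene is
# retained for analysis when its cumulative TPM across tissues is >= 10;
# its global TPM is the mean over the tissues in which it is expressed.

#' Cumulative-TPM expression filter
#'
#' @param tpm gene x tissue TPM matrix.
#' @param min_cumulative minimum cumulative TPM across tissues (inclusive).
#' @return named logical vector: gene retained?
#' @export
filter_expressed <- function(tpm, min_cumulative = 10.0) {
  if (ncol(tpm) == 0) stop("TPM matrix has no tissue columns")
  rowSums(tpm) >= min_cumulative
}

#' Per-tissue expressed flags (TPM >= threshold)
#'
#' @param tpm gene x tissue TPM matrix.
#' @param threshold expression threshold in TPM.
#' @return logical matrix of the same shape.
#' @export
expressed_flags <- function(tpm, threshold = 1.0) tpm >= threshold

#' Global TPM: mean over expressed tissues
#'
#' Tissues with TPM below the expression threshold do not contribute; a gene
#' expressed in no tissue gets global TPM 0 (silenced).
#'
#' @param tpm gene x tissue TPM matrix.
#' @param threshold per-tissue expression threshold.
#' @return named numeric vector of global TPM per gene.
#' @export
global_tpm <- function(tpm, threshold = 1.0) {
  ex <- tpm >= threshold
  n <- rowSums(ex)
  out <- ifelse(n > 0, rowSums(tpm * ex) / pmax(n, 1L), 0)
  setNames(as.numeric(out), rownames(tpm))
}

#' Coefficient-of-variation classification of expression variability
#'
#' CV = sd/mean across all tissues (zeros included, sample sd with n-1
#' denominator). Classes: conserved (CV < 0.35), intermediate
#' (0.35 <= CV <= 1), highly variable (CV > 1); the printed class bounds are
#' strict inequalities, so exact boundary values close onto the middle
#' class. Genes with mean 0 have undefined CV and are dropped with a
#' warning.
#'
#' @param tpm gene x tissue TPM matrix (usually already filtered with
#'   [filter_expressed()]).
#' @param bounds lower/upper CV class bounds.
#' @return data.frame `gene_id`, `mean_tpm`, `sd_tpm`, `cv`, `cv_class`.
#' @export
cv_classify <- function(tpm, bounds = c(0.35, 1)) {
  mu <- rowMeans(tpm)
  if (any(mu == 0)) {
    warning(sum(mu == 0), " gene(s) with zero mean TPM excluded from CV ",
            "classification")
    tpm <- tpm[mu > 0, , drop = FALSE]
    mu <- mu[mu > 0]
  }
  s <- apply(tpm, 1, sd)
  cv <- s / mu
  cls <- ifelse(cv < bounds[1], "conserved",
                ifelse(cv > bounds[2], "highly_variable", "intermediate"))
  data.frame(gene_id = rownames(tpm), mean_tpm = unname(mu),
             sd_tpm = unname(s), cv = unname(cv), cv_class = unname(cls),
             stringsAsFactors = FALSE)
}

#' Homoeolog expression bias (HEB)
#'
#' `HEB = log2(TPM_M / TPM_U)`, with copies below `silenced_value` floored
#' to `silenced_value` so the ratio stays finite when one copy is silenced.
#' Positive values indicate M-biased, negative U-biased expression;
#' antisymmetric under swapping the homoeologs.
#'
#' @param tpm_m,tpm_u TPM of the M and U homoeolog (vectors allowed).
#' @param silenced_value pseudo-TPM substituted for a silenced copy.
#' @return numeric HEB value(s); `NA` when both copies are 0 (the dyad is
#'   excluded from bias analyses upstream).
#' @export
heb <- function(tpm_m, tpm_u, silenced_value = 1e-6) {
  out <- log2(pmax(tpm_m, silenced_value) / pmax(tpm_u, silenced_value))
  out[tpm_m == 0 & tpm_u == 0] <- NA_real_
  out
}

#' Within-dyad normalised expression
#'
#' `normTPM_M = TPM_M / (TPM_M + TPM_U)` and symmetrically for U; the pair
#' sums to 1 and is invariant to rescaling both inputs.
#'
#' @param tpm_m,tpm_u TPM of the two homoeologs (vectors allowed).
#' @return list with numeric components `p_m`, `p_u` (`NA` when both are 0).
#' @export
norm_tpm <- function(tpm_m, tpm_u) {
  tot <- tpm_m + tpm_u
  p_m <- ifelse(tot > 0, tpm_m / tot, NA_real_)
  list(p_m = p_m, p_u = 1 - p_m)
}

#' Dominance classification of a dyad
#'
#' Assigns the nearest of the expected (normTPM_M, normTPM_U) ratios in
#' Euclidean distance: balanced (0.5, 0.5), M-dominant (1, 0), U-dominant
#' (0, 1). The decision reduces to thresholds at normTPM_M = 0.25 / 0.75;
#' exact ties close onto balanced.
#'
#' @param p_m normTPM of the M homoeolog (vector allowed).
#' @return character vector in `{balanced, M_dominant, U_dominant}` (`NA`
#'   propagates).
#' @export
classify_dominance <- function(p_m) {
  ifelse(is.na(p_m), NA_character_,
         ifelse(p_m > 0.75, "M_dominant",
                ifelse(p_m < 0.25, "U_dominant", "balanced")))
}

#' Per-tissue and dyad-level expression bias table
#'
#' Combines a dyad list with a TPM matrix. Per-tissue rows carry TPM, HEB,
#' normTPM, dominance and an expression status; bias quantities are only
#' computed in tissues where at least one homoeolog is expressed
#' (TPM >= `threshold`). The dyad-level summary uses each gene's global TPM.
#' Dyads with both copies below the threshold everywhere are `silenced` and
#' carry `NA` bias values.
#'
#' @param dyads data.frame `m_gene`, `u_gene`.
#' @param tpm gene x tissue TPM matrix covering all dyad genes.
#' @param threshold per-tissue expression threshold in TPM.
#' @param silenced_value pseudocount for [heb()].
#' @return list with `per_tissue` and `summary` data.frames.
#' @export
dyad_expression <- function(dyads, tpm, threshold = 1.0,
                            silenced_value = 1e-6) {
  miss <- setdiff(c(dyads$m_gene, dyads$u_gene), rownames(tpm))
  if (length(miss)) stop("dyad gene(s) missing from TPM matrix: ", miss[1])
  tissues <- colnames(tpm)
  nd <- nrow(dyads)
  nt <- length(tissues)
  tm <- tpm[dyads$m_gene, , drop = FALSE]
  tu <- tpm[dyads$u_gene, , drop = FALSE]
  dyad_id <- paste(dyads$m_gene, dyads$u_gene, sep = "|")
  # long format: one row per dyad x tissue
  pt <- data.frame(
    dyad_id = rep(dyad_id, nt),
    m_gene = rep(dyads$m_gene, nt), u_gene = rep(dyads$u_gene, nt),
    tissue = rep(tissues, each = nd),
    tpm_m = as.vector(tm), tpm_u = as.vector(tu),
    stringsAsFactors = FALSE
  )
  em <- pt$tpm_m >= threshold
  eu <- pt$tpm_u >= threshold
  pt$status <- ifelse(em & eu, "both_expressed",
                      ifelse(em, "M_only", ifelse(eu, "U_only", "silenced")))
  any_ex <- em | eu
  np <- norm_tpm(pt$tpm_m, pt$tpm_u)
  pt$heb <- ifelse(any_ex, heb(pt$tpm_m, pt$tpm_u, silenced_value), NA_real_)
  pt$norm_tpm_m <- ifelse(any_ex, np$p_m, NA_real_)
  pt$norm_tpm_u <- ifelse(any_ex, np$p_u, NA_real_)
  pt$dominance <- ifelse(any_ex, classify_dominance(pt$norm_tpm_m),
                         NA_character_)
  # dyad-level summary from global TPM
  g <- global_tpm(tpm, threshold)
  gm <- unname(g[dyads$m_gene])
  gu <- unname(g[dyads$u_gene])
  sm <- gm > 0
  su <- gu > 0
  any_g <- sm | su
  npg <- norm_tpm(gm, gu)
  summary <- data.frame(
    dyad_id = dyad_id, m_gene = dyads$m_gene, u_gene = dyads$u_gene,
    global_tpm_m = gm, global_tpm_u = gu,
    status = ifelse(sm & su, "both_expressed",
                    ifelse(sm, "M_only", ifelse(su, "U_only", "silenced"))),
    heb = ifelse(any_g, heb(gm, gu, silenced_value), NA_real_),
    norm_tpm_m = ifelse(any_g, npg$p_m, NA_real_),
    norm_tpm_u = ifelse(any_g, npg$p_u, NA_real_),
    stringsAsFactors = FALSE
  )
  summary$dominance <- ifelse(any_g, classify_dominance(summary$norm_tpm_m),
                              NA_character_)
  list(per_tissue = pt, summary = summary)
}
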