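# Stable / intermediate / dynamic classification of dyads from the
# across-tissue deviation of homoeolog expression ratios (CMD deciles).
#
# Each expressed tissue contributes the Euclidean distance between the
# tissue-level and the global (normTPM_M, normTPM_U) vector; the dyad's
# coefficient of mean distance (CMD) is the mean of these distances. Dyads
# are decile-ranked by CMD: the lowest two deciles are stable, the top two
# dynamic, the rest intermediate.

#' Per-tissue ratio distance
#'
#' Euclidean distance between the tissue-level and global normalised
#' expression vectors of a dyad. Since both vectors sum to 1 this equals
#' `sqrt(2) * |p_tissue - p_global|`; the range is `[0, sqrt(2)]`.
#'
#' @param p_tissue tissue-level normTPM of the M homoeolog.
#' @param p_global global normTPM of the M homoeolog.
#' @return numeric distance(s).
#' @export
tissue_distance <- function(p_tissue, p_global) {
  sqrt((p_tissue - p_global)^2 + ((1 - p_tissue) - (1 - p_global))^2)
}

#' Coefficient of mean distance (CMD) per dyad
#'
#' Averages [tissue_distance()] over the tissues in which the dyad is
#' expressed (rows with non-`NA` normTPM in the per-tissue table from
#' [dyad_expression()]). Dyads expressed in no tissue are excluded.
#'
#' @param per_tissue per-tissue table from [dyad_expression()].
#' @param summary dyad summary table from [dyad_expression()] (supplies the
#'   global ratios).
#' @return data.frame `dyad_id`, `n_tissues`, `cmd`.
#' @export
cmd <- function(per_tissue, summary) {
  ok <- !is.na(per_tissue$norm_tpm_m)
  pt <- per_tissue[ok, , drop = FALSE]
  pg <- summary$norm_tpm_m[match(pt$dyad_id, summary$dyad_id)]
  keep <- !is.na(pg)
  pt <- pt[keep, , drop = FALSE]
  d <- tissue_distance(pt$norm_tpm_m, pg[keep])
  agg <- tapply(d, pt$dyad_id, mean)
  n <- tapply(d, pt$dyad_id, length)
  out <- data.frame(dyad_id = names(agg), n_tissues = as.integer(n),
                    cmd = as.numeric(agg), stringsAsFactors = FALSE)
  out[match(unique(pt$dyad_id), out$dyad_id), , drop = FALSE]
}

#' Decile classification of dyad expression dynamics
#'
#' Dyads are ranked ascending by CMD (ties broken by `dyad_id` for
#' determinism); the decile index is `floor(10 * (rank - 1) / n)`. Deciles
#' 0-1 are `stable`, 8-9 `dynamic`, the rest `intermediate`, giving exact
#' 20/60/20 splits when `n` is divisible by 10. The classification is
#' invariant to any strictly monotone transform of CMD and to input order.
#'
#' @param cmds data.frame `dyad_id`, `cmd` (at least 10 rows).
#' @return the input plus `rank`, `decile`, `dynamics_class`, in input
#'   order.
#' @export
classify_dynamics <- function(cmds) {
  n <- nrow(cmds)
  if (n < 10) stop("decile classification needs at least 10 dyads, got ", n)
  if (anyNA(cmds$cmd)) stop("NA cmd values")
  ord <- order(cmds$cmd, cmds$dyad_id, method = "radix")
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  decile <- (10L * (rank - 1L)) %/% n
  cls <- ifelse(decile <= 1L, "stable",
                ifelse(decile >= 8L, "dynamic", "intermediate"))
  out <- cmds
  out$rank <- rank
  out$decile <- decile
  out$dynamics_class <- cls
  out
}
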