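# H3K4me3 signal quantification per gene and homoeolog chromatin bias.
#
# The fold-enrichment (FE) track is a step function (non-overlapping
# bedGraph intervals); positions outside any interval have FE 0. All areas
# are in FE * bp.

# split a signal track into per-chromosome pieces with a cumulative
# integral, enabling O(log n) evaluation of int_0^x FE
track_index <- function(track) {
  lapply(split(track[c("start", "end", "score")], track$chrom), function(p) {
    p <- p[order(p$start), , drop = FALSE]
    len <- p$end - p$start
    list(start = p$start, end = p$end, score = p$score,
         cum = c(0, cumsum(p$score * len)))
  })
}

# integral of the step function from 0 to x (vectorized in x)
step_integral <- function(idx, x) {
  if (is.null(idx)) return(rep(0, length(x)))
  x <- pmax(x, 0)
  k <- findInterval(x, idx$start)           # last interval starting <= x
  part <- ifelse(k > 0,
                 idx$cum[pmax(k, 1)] +
                   idx$score[pmax(k, 1)] *
                   pmax(pmin(x, idx$end[pmax(k, 1)]) - idx$start[pmax(k, 1)], 0),
                 0)
  part
}

#' Area under the FE curve over a flanked gene window
#'
#' Integrates the FE step function over `[start - flank, end + flank)`
#' (clipped at position 0); the window is symmetric, so strand does not
#' matter. Vectorised over the gene table.
#'
#' @param track signal-track data.frame from [read_bedgraph()].
#' @param genes gene table (rows define the windows).
#' @param flank flank size in bp on each side.
#' @return numeric vector of areas (FE * bp), named by `gene_id`.
#' @export
fe_area <- function(track, genes, flank = 2000) {
  idx <- track_index(track)
  lo <- pmax(genes$start - flank, 0)
  hi <- genes$end + flank
  out <- numeric(nrow(genes))
  for (chr in unique(genes$chrom)) {
    sel <- genes$chrom == chr
    ci <- idx[[chr]]
    out[sel] <- step_integral(ci, hi[sel]) - step_integral(ci, lo[sel])
  }
  setNames(out, genes$gene_id)
}

#' Maximum FE value within a flanked gene window
#'
#' The per-gene signal summit: the largest FE value of any track interval
#' overlapping `[start - flank, end + flank)`; 0 when nothing overlaps.
#'
#' @inheritParams fe_area
#' @return numeric vector named by `gene_id`.
#' @export
gene_summit <- function(track, genes, flank = 2000) {
  lo <- pmax(genes$start - flank, 0)
  win <- GRanges(genes$chrom, IRanges(start = lo + 1L, end = genes$end + flank))
  tg <- df0_to_gr(track)
  ov <- suppressWarnings(findOverlaps(win, tg))
  out <- rep(0, nrow(genes))
  if (length(ov)) {
    mx <- tapply(track$score[subjectHits(ov)], queryHits(ov), max)
    out[as.integer(names(mx))] <- as.numeric(mx)
  }
  setNames(out, genes$gene_id)
}

#' Binned FE profile of one gene
#'
#' Strand-aware metagene profile: `flank/flank_bin` upstream bins of
#' `flank_bin` bp, the gene body rescaled to `body_bins` bins (genes
#' shorter than `body_bins` bp use one bin per bp), then the downstream
#' flank. Each bin holds the length-weighted mean FE over its bp span; bins
#' truncated at position 0 report the reduced bp weight. For `-` strand
#' genes the profile runs 5' to 3' (i.e. it is the reverse of the `+`
#' profile over the same span).
#'
#' @param track signal-track data.frame.
#' @param gene one-row gene table.
#' @param flank flank size in bp.
#' @param body_bins number of gene-body bins.
#' @param flank_bin flank bin width in bp.
#' @return data.frame `bin`, `zone` (upstream/body/downstream), `fe`
#'   (weighted mean), `weight` (bp covered).
#' @export
gene_profile <- function(track, gene, flank = 2000, body_bins = 100,
                         flank_bin = 20) {
  stopifnot(nrow(gene) == 1)
  idx <- track_index(track)[[gene$chrom]]
  L <- gene$end - gene$start
  nb <- if (L >= body_bins) body_bins else L
  left <- seq(gene$start - flank, gene$start, by = flank_bin)
  body <- gene$start + (L / nb) * (0:nb)
  right <- seq(gene$end, gene$end + flank, by = flank_bin)
  edges <- c(left, body[-1], right[-1])
  zone <- c(rep("left", length(left) - 1), rep("body", nb),
            rep("right", length(right) - 1))
  cl <- pmax(edges, 0)
  integral <- diff(step_integral(idx, cl))
  weight <- diff(cl)
  fe <- ifelse(weight > 0, integral / weight, 0)
  if (gene$strand == "-") {
    fe <- rev(fe)
    weight <- rev(weight)
    zone <- rev(zone)
    map <- c(left = "downstream", body = "body", right = "upstream")
  } else {
    map <- c(left = "upstream", body = "body", right = "downstream")
  }
  data.frame(bin = seq_along(fe), zone = unname(map[zone]), fe = fe,
             weight = weight, stringsAsFactors = FALSE)
}

#' H3K4me3 peak homoeolog bias (HPHB)
#'
#' `HPHB = log2((area_M + c) / (area_U + c))` with a small constant `c`
#' keeping the ratio defined when signal is absent in one or both
#' homoeologs. Positive values indicate stronger enrichment on the M copy;
#' antisymmetric under swapping the homoeologs.
#'
#' @param area_m,area_u FE-curve areas of the two homoeologs (vectors
#'   allowed).
#' @param c pseudocount.
#' @return numeric HPHB value(s).
#' @export
hphb <- function(area_m, area_u, c = 1e-6) {
  log2((area_m + c) / (area_u + c))
}

#' Peak presence near the coding start
#'
#' TRUE when any peak interval overlaps the half-open window
#' `[cds_start - window, cds_start + window)` around the strand-aware
#' coding start.
#'
#' @param peaks peak data.frame from [read_bed()].
#' @param genes gene table.
#' @param window half-width of the window in bp.
#' @return logical vector named by `gene_id`.
#' @export
peak_presence <- function(peaks, genes, window = 500) {
  out <- rep(FALSE, nrow(genes))
  if (nrow(peaks) > 0) {
    lo <- pmax(genes$cds_start - window, 0)
    hi <- genes$cds_start + window
    win <- GRanges(genes$chrom, IRanges(start = lo + 1L, end = hi))
    # absent chromosomes simply yield no overlap
    ov <- suppressWarnings(findOverlaps(win, df0_to_gr(peaks)))
    out[unique(queryHits(ov))] <- TRUE
  }
  setNames(out, genes$gene_id)
}

#' Per-dyad chromatin bias table
#'
#' @param track_m,track_u signal tracks for the M and U subgenomes (a single
#'   combined track can be passed to both arguments).
#' @param peaks reproducible peak intervals.
#' @param genes gene table.
#' @param dyads dyad data.frame (`m_gene`, `u_gene`).
#' @param flank flank size for [fe_area()].
#' @param window window for [peak_presence()].
#' @return data.frame `dyad_id`, `area_m`, `area_u`, `hphb`, `peak_m`,
#'   `peak_u`.
#' @export
chromatin_bias <- function(track_m, track_u, peaks, genes, dyads,
                           flank = 2000, window = 500) {
  gm <- genes[match(dyads$m_gene, genes$gene_id), , drop = FALSE]
  gu <- genes[match(dyads$u_gene, genes$gene_id), , drop = FALSE]
  if (anyNA(gm$gene_id) || anyNA(gu$gene_id))
    stop("dyad gene(s) missing from gene table")
  am <- fe_area(track_m, gm, flank)
  au <- fe_area(track_u, gu, flank)
  pm <- peak_presence(peaks, gm, window)
  pu <- peak_presence(peaks, gu, window)
  data.frame(dyad_id = paste(dyads$m_gene, dyads$u_gene, sep = "|"),
             m_gene = dyads$m_gene, u_gene = dyads$u_gene,
             area_m = unname(am), area_u = unname(au),
             hphb = hphb(unname(am), unname(au)),
             peak_m = unname(pm), peak_u = unname(pu),
             stringsAsFactors = FALSE)
}
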