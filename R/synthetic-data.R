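# Synthetic allotetraploid dataset generator.
#
# Emulates a two-subgenome (M/U) tetraploid with 7 homoeologous chromosome
# groups: planted homoeolog dyads placed collinearly, genome-unique genes,
# structural-rearrangement (SRA) blocks that relocate dyad partners to a
# different U chromosome, BLAST-style hit tables with paralog decoys and
# dropout, a balanced / M-dominant / U-dominant expression mixture across
# seven tissues, silenced homoeologs, H3K4me3 plateaus and peaks at
# expressed genes, disomic-addition-line skim coverage and single- or
# double-peaked CENH3 coverage. A truth table records every planted fact.
#
# One global seed drives independent per-stage substreams, so regenerating
# one stage does not perturb the others.

#' Simulation configuration
#'
#' Defaults define the study conditions emulated throughout the package:
#' a 2000-dyad tetraploid, seven tissues, an 80/10/10
#' balanced/M-dominant/U-dominant dominance mixture, 5% homoeolog
#' silencing, 39% of dyads inside SRA blocks (the share of dyads the real
#' tetraploid holds in rearranged regions) where expression is halved
#' (`sra_tpm_factor = 0.5`) with 5% extra silencing, and hit tables with
#' 20% paralog decoys and 2% one-direction dropout. The abundance
#' distribution (`tpm_log_mean = 0.65`, `tpm_log_sd = 1.2`) is calibrated
#' so that about half the genes pass the cumulative-10-TPM expression
#' filter, the retention rate reported for real multi-tissue data.
#'
#' @param n_dyads number of homoeolog dyads.
#' @param n_unique_per_genome genome-unique genes per subgenome.
#' @param n_tissues number of tissues (>= 2).
#' @param tissues tissue names (length `n_tissues`).
#' @param dominance_mixture probabilities of balanced / M-dominant /
#'   U-dominant dyads (sum to 1).
#' @param dominance_jitter Beta concentration of the within-dyad expression
#'   split (0 = exact 0.5 / 1 / 0 ratios). Dominant classes draw from a
#'   Beta centred at 0.95 rather than exactly 1, so bias stays finite;
#'   exact silencing is a separate flag.
#' @param silencing_prob probability a homoeolog is silenced (TPM 0).
#' @param tpm_log_mean,tpm_log_sd lognormal meanlog/sdlog of dyad base
#'   abundance (TPM).
#' @param tissue_effect_sd lognormal sdlog of per-dyad per-tissue
#'   multipliers (shared by the two homoeologs).
#' @param gene_noise_sd lognormal sdlog of per-gene per-tissue noise.
#' @param sra_fraction fraction of dyads inside SRA blocks.
#' @param n_sra_blocks number of SRA blocks the SRA dyads are split into.
#' @param sra_tpm_factor multiplicative TPM effect applied to both members
#'   of an SRA dyad.
#' @param sra_extra_silencing added per-gene silencing probability in SRA
#'   dyads.
#' @param identity_sd sd of true-hit percent identity around 98.
#' @param decoy_rate per-direction probability of a paralog decoy hit.
#' @param dropout_rate probability the true hit is missing in one
#'   direction.
#' @param peak_prob probability an expressed gene gets an H3K4me3 peak at
#'   its coding start.
#' @param fe_base FE plateau scale: plateau height = `fe_base *
#'   log1p(global TPM)` above background.
#' @param background_fe background fold enrichment.
#' @param cov_bin_bp depth-bin width of the coverage simulations.
#' @param da_noise_sd relative depth noise of the addition-line skim
#'   coverage.
#' @param cen_noise_sd relative baseline noise of the CENH3 coverage.
#' @param cen_amplitude CENH3 bump height over baseline (depth units).
#' @param seed integer seed.
#' @return validated config list of class `sim_config`.
#' @export
sim_config <- function(n_dyads = 2000, n_unique_per_genome = 300,
                       n_tissues = 7,
                       tissues = c("seedling_leaf", "seedling_root",
                                   "flag_leaf", "leaf_sheath", "whole_spike",
                                   "preanthesis_spike", "stem")[seq_len(n_tissues)],
                       dominance_mixture = c(balanced = 0.8,
                                             M_dominant = 0.1,
                                             U_dominant = 0.1),
                       dominance_jitter = 100, silencing_prob = 0.05,
                       tpm_log_mean = 0.65, tpm_log_sd = 1.2,
                       tissue_effect_sd = 0.3, gene_noise_sd = 0.2,
                       sra_fraction = 0.39, n_sra_blocks = 13,
                       sra_tpm_factor = 0.5, sra_extra_silencing = 0.05,
                       identity_sd = 1, decoy_rate = 0.2,
                       dropout_rate = 0.02, peak_prob = 0.9, fe_base = 1.5,
                       background_fe = 1, cov_bin_bp = 1e6,
                       da_noise_sd = 0.1, cen_noise_sd = 0.1,
                       cen_amplitude = 50, seed = 1) {
  cfg <- as.list(environment())
  probs <- c(cfg$dominance_mixture, cfg$silencing_prob, cfg$sra_fraction,
             cfg$sra_extra_silencing, cfg$decoy_rate, cfg$dropout_rate,
             cfg$peak_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (abs(sum(cfg$dominance_mixture) - 1) > 1e-9)
    stop("dominance_mixture must sum to 1")
  if (cfg$n_tissues < 2) stop("n_tissues must be >= 2")
  if (length(cfg$tissues) != cfg$n_tissues)
    stop("tissues must have length n_tissues")
  class(cfg) <- "sim_config"
  cfg
}

stage_seed <- function(config, stage) {
  set.seed(config$seed + 1009L * stage)
}

#' Simulate the synthetic tetraploid annotation
#'
#' Places dyad partners collinearly on the 7 M / 7 U chromosomes with
#' identical gene lengths, intersperses genome-unique genes, and relocates
#' the U member of each SRA dyad into one of `n_sra_blocks` contiguous
#' blocks on a different U chromosome; those blocks define the SRA region
#' set.
#'
#' @param config [sim_config()].
#' @return list: `genes` (gene table), `regions` (SRA regions), `truth`
#'   (list with `dyads` and `genes` truth tables, chromosome lengths).
#' @export
simulate_genome <- function(config = sim_config()) {
  stage_seed(config, 1L)
  nd <- config$n_dyads
  nu <- config$n_unique_per_genome
  group <- rep(1:7, length.out = nd)
  m_gene <- sprintf("gM%04d", seq_len(nd))
  u_gene <- sprintf("gU%04d", seq_len(nd))
  len <- round(runif(nd, 600, 5000))
  strand <- sample(c("+", "-"), nd, replace = TRUE)
  # SRA membership: contiguous runs of dyads within a group, relocated to
  # the next group's U chromosome
  n_sra <- round(config$sra_fraction * nd)
  if (config$sra_fraction > 0 && n_sra < 1) {
    warning("sra_fraction too small: zero SRA genes")
    n_sra <- 0L
  }
  nb <- if (n_sra > 0) min(config$n_sra_blocks, n_sra) else 0L
  sra_block <- rep(NA_integer_, nd)
  if (nb > 0) {
    per_block <- diff(round(seq(0, n_sra, length.out = nb + 1)))
    for (b in seq_len(nb)) {
      g <- ((b - 1L) %% 7L) + 1L
      cand <- which(group == g & is.na(sra_block))
      take <- cand[seq_len(min(per_block[b], length(cand)))]
      sra_block[take] <- b
    }
  }
  is_sra <- !is.na(sra_block)
  um_gene <- sprintf("uM%04d", seq_len(nu))
  uu_gene <- sprintf("uU%04d", seq_len(nu))
  ug <- rep(1:7, length.out = nu)
  ulen <- round(runif(nu, 600, 5000))
  ustrand <- sample(c("+", "-"), nu, replace = TRUE)

  place <- function(ids, lens, strands) {
    n <- length(ids)
    gaps <- round(runif(n, 2000, 20000))
    starts <- cumsum(gaps) + cumsum(c(0, lens[-n]))
    ends <- starts + lens
    off <- round(runif(n, 90, 300))
    off <- pmin(off, lens - 1)
    cds <- ifelse(strands == "+", starts + off, ends - 1 - off)
    data.frame(gene_id = ids, start = starts, end = ends, strand = strands,
               cds_start = cds, stringsAsFactors = FALSE)
  }

  genes <- list()
  regions <- list()
  for (g in 1:7) {
    # M chromosome: all group-g M dyad members + unique M genes, shuffled
    mi <- which(group == g)
    ui <- which(ug == g)
    ord <- sample(length(mi) + length(ui))
    ids <- c(m_gene[mi], um_gene[ui])[ord]
    lens <- c(len[mi], ulen[ui])[ord]
    strs <- c(strand[mi], ustrand[ui])[ord]
    pm <- place(ids, lens, strs)
    pm$chrom <- paste0(g, "M")
    pm$subgenome <- "M"
    # U chromosome: collinear non-SRA U members (same order as their M
    # partners) + unique U genes, then relocated SRA blocks appended
    keep <- mi[!is_sra[mi]]
    ord_u <- sample(length(keep) + length(ui))
    ids_u <- c(u_gene[keep], uu_gene[ui])[ord_u]
    lens_u <- c(len[keep], ulen[ui])[ord_u]
    strs_u <- c(strand[keep], ustrand[ui])[ord_u]
    blocks_here <- which(seq_len(max(nb, 0)) %% 7L + 1L == g)
    for (b in blocks_here) {
      bi <- which(sra_block == b)
      ids_u <- c(ids_u, u_gene[bi])
      lens_u <- c(lens_u, len[bi])
      strs_u <- c(strs_u, strand[bi])
    }
    pu <- place(ids_u, lens_u, strs_u)
    pu$chrom <- paste0(g, "U")
    pu$subgenome <- "U"
    for (b in blocks_here) {
      bi <- u_gene[which(sra_block == b)]
      rows <- match(bi, pu$gene_id)
      regions[[length(regions) + 1]] <- data.frame(
        chrom = paste0(g, "U"), start = min(pu$start[rows]) - 500,
        end = max(pu$end[rows]) + 500, region_id = sprintf("SRA%02d", b),
        stringsAsFactors = FALSE)
    }
    genes[[2 * g - 1]] <- pm
    genes[[2 * g]] <- pu
  }
  genes <- do.call(rbind, genes)
  genes <- new_gene_table(genes$gene_id, genes$subgenome, genes$chrom,
                          genes$start, genes$end, genes$strand,
                          genes$cds_start)
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               region_id = character(0), stringsAsFactors = FALSE)
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  chrom_len <- tapply(genes$end, genes$chrom, max) + 5000
  truth_dyads <- data.frame(
    dyad_id = paste(m_gene, u_gene, sep = "|"), m_gene = m_gene,
    u_gene = u_gene, group = group, length = len, sra = is_sra,
    sra_block = sra_block, stringsAsFactors = FALSE)
  truth_genes <- data.frame(
    gene_id = c(m_gene, u_gene, um_gene, uu_gene),
    partner = c(u_gene, m_gene, rep(NA_character_, nu + nu)),
    stringsAsFactors = FALSE)
  list(genes = genes, regions = regions,
       truth = list(dyads = truth_dyads, genes = truth_genes,
                    chrom_lengths = setNames(as.numeric(chrom_len),
                                             names(chrom_len))))
}

#' Simulate BLAST-style hit tables for the planted dyads
#'
#' Each dyad emits reciprocal hits with identity ~ Normal(98, identity_sd)
#' truncated to \[90, 100\], target coverage >= 0.9 and e-value <= 1e-20.
#' Paralog decoy hits (rate `decoy_rate` per direction) have identity in
#' \[90, 97\] and strictly lower bit score than the true hit; with
#' probability `dropout_rate` the true hit is removed in one (random)
#' direction.
#'
#' @param genome output of [simulate_genome()].
#' @param config [sim_config()].
#' @return list `mu`, `um` of hit data.frames (14-column layout).
#' @export
simulate_hits <- function(genome, config = sim_config()) {
  stage_seed(config, 2L)
  td <- genome$truth$dyads
  nd <- nrow(td)
  genes <- genome$genes
  glen <- setNames(genes$end - genes$start, genes$gene_id)
  u_pool <- genes$gene_id[genes$subgenome == "U"]
  m_pool <- genes$gene_id[genes$subgenome == "M"]

  true_dir <- function(q, s) {
    n <- length(q)
    qlen <- unname(glen[q])
    slen <- unname(glen[s])
    ident <- pmin(pmax(rnorm(n, 98, config$identity_sd), 90), 100)
    alen <- pmax(ceiling(runif(n, 0.92, 1) * slen), ceiling(0.9 * slen))
    ev <- 10^-runif(n, 30, 180)
    bit <- 2 * alen * ident / 100
    data.frame(query_id = q, subject_id = s, pct_identity = round(ident, 2),
               aln_length = alen,
               mismatches = round(alen * (100 - ident) / 100),
               gap_opens = 0L, q_start = 1L, q_end = pmin(alen, qlen),
               s_start = 1L, s_end = alen, e_value = ev, bit_score = bit,
               query_length = qlen, subject_length = slen,
               stringsAsFactors = FALSE)
  }
  decoy_dir <- function(q, pool, partner, true_bit) {
    n <- length(q)
    s <- vapply(seq_len(n), function(i) {
      repeat {
        cand <- pool[sample.int(length(pool), 1)]
        if (cand != partner[i]) return(cand)
      }
    }, "")
    qlen <- unname(glen[q])
    slen <- unname(glen[s])
    ident <- runif(n, 90, 97)
    alen <- pmax(ceiling(runif(n, 0.9, 1) * slen), ceiling(0.9 * slen))
    bit <- true_bit * runif(n, 0.5, 0.85)
    data.frame(query_id = q, subject_id = s, pct_identity = round(ident, 2),
               aln_length = alen,
               mismatches = round(alen * (100 - ident) / 100),
               gap_opens = 0L, q_start = 1L, q_end = pmin(alen, qlen),
               s_start = 1L, s_end = alen,
               e_value = 10^-runif(n, 10, 30), bit_score = bit,
               query_length = qlen, subject_length = slen,
               stringsAsFactors = FALSE)
  }
  mu <- true_dir(td$m_gene, td$u_gene)
  um <- true_dir(td$u_gene, td$m_gene)
  dmu <- which(runif(nd) < config$decoy_rate)
  dum <- which(runif(nd) < config$decoy_rate)
  mu_extra <- if (length(dmu)) decoy_dir(td$m_gene[dmu], u_pool,
                                         td$u_gene[dmu],
                                         mu$bit_score[dmu]) else NULL
  um_extra <- if (length(dum)) decoy_dir(td$u_gene[dum], m_pool,
                                         td$m_gene[dum],
                                         um$bit_score[dum]) else NULL
  drop <- which(runif(nd) < config$dropout_rate)
  drop_mu <- drop[runif(length(drop)) < 0.5]
  drop_um <- setdiff(drop, drop_mu)
  if (length(drop_mu)) mu <- mu[-drop_mu, , drop = FALSE]
  if (length(drop_um)) um <- um[-drop_um, , drop = FALSE]
  mu <- rbind(mu, mu_extra)
  um <- rbind(um, um_extra)
  mu <- mu[order(mu$query_id, -mu$bit_score), , drop = FALSE]
  um <- um[order(um$query_id, -um$bit_score), , drop = FALSE]
  rownames(mu) <- rownames(um) <- NULL
  list(mu = mu, um = um)
}

#' Simulate the gene x tissue TPM matrix
#'
#' Per dyad: a lognormal base abundance, a dominance class drawn from the
#' mixture setting the M:U split (with Beta jitter), per-tissue multipliers
#' shared within the dyad, and per-gene noise. Silenced copies are 0 in all
#' tissues. Both members of SRA dyads are multiplied by `sra_tpm_factor`
#' and silenced with extra probability `sra_extra_silencing` (the
#' rearrangement perturbs the dyad's dosage symmetrically). Genome-unique
#' genes get independent abundances.
#'
#' @param genome output of [simulate_genome()].
#' @param config [sim_config()].
#' @return list: `tpm` (matrix over all genes), `truth` (data.frame per
#'   dyad: class, split, silenced flags).
#' @export
simulate_expression <- function(genome, config = sim_config()) {
  stage_seed(config, 3L)
  td <- genome$truth$dyads
  nd <- nrow(td)
  nt <- config$n_tissues
  classes <- c("balanced", "M_dominant", "U_dominant")
  cls <- sample(classes, nd, replace = TRUE, prob = config$dominance_mixture)
  k <- config$dominance_jitter
  p_m <- numeric(nd)
  split_mean <- c(balanced = 0.5, M_dominant = 0.95, U_dominant = 0.05)
  for (cc in classes) {
    i <- cls == cc
    mu <- split_mean[[cc]]
    p_m[i] <- if (k > 0) rbeta(sum(i), mu * k, (1 - mu) * k) else
      c(balanced = 0.5, M_dominant = 1, U_dominant = 0)[[cc]]
  }
  base <- rlnorm(nd, config$tpm_log_mean, config$tpm_log_sd)
  tis <- matrix(rlnorm(nd * nt, 0, config$tissue_effect_sd), nd, nt)
  em <- matrix(rlnorm(nd * nt, 0, config$gene_noise_sd), nd, nt)
  eu <- matrix(rlnorm(nd * nt, 0, config$gene_noise_sd), nd, nt)
  tpm_m <- 2 * base * p_m * tis * em
  tpm_u <- 2 * base * (1 - p_m) * tis * eu
  sil_m <- runif(nd) < config$silencing_prob
  sil_u <- runif(nd) < config$silencing_prob
  if (any(td$sra)) {
    tpm_m[td$sra, ] <- tpm_m[td$sra, ] * config$sra_tpm_factor
    tpm_u[td$sra, ] <- tpm_u[td$sra, ] * config$sra_tpm_factor
    sil_m <- sil_m | (td$sra & runif(nd) < config$sra_extra_silencing)
    sil_u <- sil_u | (td$sra & runif(nd) < config$sra_extra_silencing)
  }
  tpm_m[sil_m, ] <- 0
  tpm_u[sil_u, ] <- 0
  # genome-unique genes
  tg <- genome$truth$genes
  uniq <- tg$gene_id[is.na(tg$partner)]
  nu <- length(uniq)
  tpm_q <- rlnorm(nu, config$tpm_log_mean, config$tpm_log_sd) *
    matrix(rlnorm(nu * nt, 0, config$tissue_effect_sd), nu, nt) *
    matrix(rlnorm(nu * nt, 0, config$gene_noise_sd), nu, nt)
  sil_q <- runif(nu) < config$silencing_prob
  tpm_q[sil_q, ] <- 0
  tpm <- rbind(tpm_m, tpm_u, tpm_q)
  rownames(tpm) <- c(td$m_gene, td$u_gene, uniq)
  colnames(tpm) <- config$tissues
  tpm <- tpm[genome$genes$gene_id, , drop = FALSE]
  truth <- data.frame(dyad_id = td$dyad_id, class = cls, p_m = p_m,
                      silenced_m = sil_m, silenced_u = sil_u,
                      stringsAsFactors = FALSE)
  list(tpm = tpm, truth = truth,
       silenced = setNames(c(sil_m, sil_u, sil_q) ,
                           c(td$m_gene, td$u_gene, uniq)))
}

#' Simulate H3K4me3 fold-enrichment tracks and peaks
#'
#' Expressed genes receive an FE plateau over the gene body, of height
#' `fe_base * log1p(global TPM)` above the background (`background_fe`
#' everywhere else), and an H3K4me3 peak interval within 500 bp of the
#' coding start with probability `peak_prob`. Silenced genes stay at
#' background.
#'
#' @param genome output of [simulate_genome()].
#' @param tpm TPM matrix from [simulate_expression()].
#' @param config [sim_config()].
#' @return list: `track` (signal-track data.frame over all chromosomes),
#'   `peaks` (BED-like data.frame), `truth` (planted peak flag per gene).
#' @export
simulate_chromatin <- function(genome, tpm, config = sim_config()) {
  stage_seed(config, 4L)
  genes <- genome$genes
  g <- global_tpm(tpm)[genes$gene_id]
  height <- config$fe_base * log1p(unname(g))
  bg <- config$background_fe
  track <- list()
  for (chr in names(genome$truth$chrom_lengths)) {
    gi <- which(genes$chrom == chr)
    gi <- gi[order(genes$start[gi])]
    s <- genes$start[gi]
    e <- genes$end[gi]
    h <- height[gi]
    clen <- genome$truth$chrom_lengths[[chr]]
    edges <- c(0, as.vector(rbind(s, e)), clen)
    score <- c(bg, as.vector(rbind(bg + h, bg)))
    track[[chr]] <- data.frame(
      chrom = chr, start = edges[-length(edges)], end = edges[-1],
      score = score, stringsAsFactors = FALSE)
  }
  track <- do.call(rbind, track)
  track <- track[track$end > track$start, , drop = FALSE]
  rownames(track) <- NULL
  expressed <- unname(g) > 0
  planted <- expressed & runif(nrow(genes)) < config$peak_prob
  lo <- pmax(genes$cds_start - 100, 0)
  peaks <- data.frame(chrom = genes$chrom[planted], start = lo[planted],
                      end = genes$cds_start[planted] + 250,
                      name = paste0("peak_", genes$gene_id[planted]),
                      stringsAsFactors = FALSE)
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  list(track = track, peaks = peaks,
       truth = data.frame(gene_id = genes$gene_id, planted_peak = planted,
                          plateau_height = height,
                          stringsAsFactors = FALSE))
}

#' Simulate addition-line and CENH3 window coverage
#'
#' Thirteen disomic-addition (DA) lines (every chromosome except 6U) with
#' the added chromosome at twice the baseline depth, and a CENH3 ChIP
#' coverage profile with one Gaussian bump per chromosome — two closely
#' spaced bumps (5 windows apart) on 5M. Depths are emitted per
#' `cov_bin_bp` bin.
#'
#' @param config [sim_config()].
#' @param chrom_sizes named vector of chromosome sizes in bp (defaults to
#'   14 chromosomes of 380-560 Mb).
#' @return list: `da` (named list of depth tables per DA line), `cenh3`
#'   (depth table), `truth` (added chromosome per line, centromere
#'   midpoints per chromosome).
#' @export
simulate_window_coverage <- function(config = sim_config(),
                                     chrom_sizes = NULL) {
  stage_seed(config, 5L)
  if (is.null(chrom_sizes)) {
    chroms <- paste0(rep(1:7, 2), rep(c("M", "U"), each = 7))
    chrom_sizes <- setNames(seq(380e6, 560e6, length.out = 14)[
      order(order(chroms))], chroms)
    chrom_sizes <- round(chrom_sizes / config$cov_bin_bp) * config$cov_bin_bp
  }
  bin <- config$cov_bin_bp
  pos <- lapply(chrom_sizes, function(L) seq(0, L - bin, by = bin))
  grid <- data.frame(chrom = rep(names(pos), lengths(pos)),
                     pos = unlist(pos, use.names = FALSE),
                     stringsAsFactors = FALSE)
  baseline <- 10
  lines <- setdiff(names(chrom_sizes), "6U")
  da <- lapply(lines, function(chr) {
    d <- grid
    fold <- ifelse(d$chrom == chr, 2, 1)
    d$depth <- pmax(baseline * fold * (1 + rnorm(nrow(d),
                                                 sd = config$da_noise_sd)), 0)
    d
  })
  names(da) <- paste0("DA_", lines)
  cen_base <- 5
  centers <- lapply(names(chrom_sizes), function(chr) {
    L <- chrom_sizes[[chr]]
    c0 <- round(runif(1, 0.35, 0.65) * L / bin) * bin + bin / 2
    if (chr == "5M") c(c0 - 2.5 * bin, c0 + 2.5 * bin) else c0
  })
  names(centers) <- names(chrom_sizes)
  cen <- grid
  mid <- cen$pos + bin / 2
  bump <- numeric(nrow(cen))
  sigma <- 1.2 * bin
  for (chr in names(centers)) {
    i <- cen$chrom == chr
    for (cc in centers[[chr]])
      bump[i] <- bump[i] + config$cen_amplitude *
        exp(-(mid[i] - cc)^2 / (2 * sigma^2))
  }
  cen$depth <- pmax(cen_base * (1 + rnorm(nrow(cen),
                                          sd = config$cen_noise_sd)) + bump, 0)
  list(da = da, cenh3 = cen,
       truth = list(da_chrom = setNames(lines, names(da)),
                    centromeres = centers, chrom_sizes = chrom_sizes))
}

#' Simulate the full dataset
#'
#' Runs every simulation stage off one seed and returns all components
#' plus the combined truth table.
#'
#' @param config [sim_config()].
#' @return list `config`, `genes`, `regions`, `hits`, `tpm`, `chromatin`,
#'   `coverage`, `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  genome <- simulate_genome(config)
  hits <- simulate_hits(genome, config)
  expr <- simulate_expression(genome, config)
  chrom <- simulate_chromatin(genome, expr$tpm, config)
  cov <- simulate_window_coverage(config)
  truth <- genome$truth
  truth$expression <- expr$truth
  truth$silenced <- expr$silenced
  truth$chromatin <- chrom$truth
  truth$coverage <- cov$truth
  list(config = config, genes = genome$genes, regions = genome$regions,
       hits = hits, tpm = expr$tpm,
       chromatin = list(track = chrom$track, peaks = chrom$peaks),
       coverage = list(da = cov$da, cenh3 = cov$cenh3), truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits `genes.gff3`, `sra.bed`, `hits_mu.tsv`, `hits_um.tsv`, `tpm.tsv`,
#' `h3k4me3_M.bedgraph`, `h3k4me3_U.bedgraph`, `peaks.bed`,
#' `da_line_<chrom>.tsv`, `cenh3.tsv` and truth tables, all readable by the
#' package's readers. Output is byte-deterministic given the seed.
#'
#' @param sim output of [simulate_dataset()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(outdir, x)
  write_gff3(sim$genes, fp("genes.gff3"))
  reg <- sim$regions
  reg$name <- reg$region_id
  write_bed(reg, fp("sra.bed"))
  write_hits_table(sim$hits$mu, fp("hits_mu.tsv"))
  write_hits_table(sim$hits$um, fp("hits_um.tsv"))
  write_tpm_matrix(sim$tpm, fp("tpm.tsv"))
  tr <- sim$chromatin$track
  sub <- subgenome_from_chrom(tr$chrom)
  write_bedgraph(tr[sub == "M", , drop = FALSE], fp("h3k4me3_M.bedgraph"))
  write_bedgraph(tr[sub == "U", , drop = FALSE], fp("h3k4me3_U.bedgraph"))
  write_bed(sim$chromatin$peaks, fp("peaks.bed"))
  for (ln in names(sim$coverage$da))
    write_results(sim$coverage$da[[ln]],
                  fp(paste0("da_line_", sub("DA_", "", ln), ".tsv")))
  write_results(sim$coverage$cenh3, fp("cenh3.tsv"))
  write_results(sim$truth$dyads, fp("truth_dyads.tsv"))
  write_results(sim$truth$expression, fp("truth_expression.tsv"))
  invisible(outdir)
}
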