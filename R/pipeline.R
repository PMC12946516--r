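# End-to-end orchestration: simulate -> pair -> expression -> dynamics ->
# chromatin -> rearrangement comparison -> window analyses, with a run
# manifest for reproducibility.

#' Assemble the gene- and dyad-level metrics tables
#'
#' Computes everything the rearranged-vs-control comparison consumes.
#' Gene rows cover both members of every dyad; a gene counts as expressed
#' when it passes the cumulative-TPM filter (>= 10 TPM summed over
#' tissues, the analysis-level expression definition). Dyad rows are
#' restricted to dyads with at least one expressed member (the bias
#' metrics are undefined otherwise). Each gene is labelled by its own
#' midpoint — of a rearranged dyad only the physically relocated member
#' counts as rearranged at the gene level — while a dyad is rearranged
#' when either member is.
#'
#' @param genes gene table.
#' @param regions SRA region set.
#' @param dyads dyad data.frame (`m_gene`, `u_gene`).
#' @param tpm TPM matrix.
#' @param track signal track covering all chromosomes (or rbind of the
#'   per-subgenome tracks).
#' @param peaks peak intervals.
#' @param flank flank for [fe_area()] / [gene_summit()].
#' @param window window for [peak_presence()].
#'
#' @return list `gene_metrics`, `dyad_metrics`, `expression` (the
#'   [dyad_expression()] output), `chromatin` (the [chromatin_bias()]
#'   table).
#' @export
pipeline_metrics <- function(genes, regions, dyads, tpm, track, peaks,
                             flank = 2000, window = 500) {
  lab <- assign_genes_to_regions(genes, regions, dyads)
  expr <- dyad_expression(dyads, tpm)
  retained <- filter_expressed(tpm)
  keep <- retained[dyads$m_gene] | retained[dyads$u_gene]
  summ <- expr$summary[keep, , drop = FALSE]
  dl <- lab$dyads[keep, , drop = FALSE]
  cb <- chromatin_bias(track, track, peaks, genes,
                       dyads[keep, , drop = FALSE], flank, window)
  dyad_metrics <- data.frame(
    dyad_id = summ$dyad_id, label = dl$label, region_id = dl$region_id,
    heb = summ$heb, hphb = cb$hphb, dominance = summ$dominance,
    stringsAsFactors = FALSE)
  member <- c(dyads$m_gene, dyads$u_gene)
  gi <- match(member, genes$gene_id)
  g <- global_tpm(tpm)[member]
  summit <- gene_summit(track, genes[gi, , drop = FALSE], flank)
  pk <- peak_presence(peaks, genes[gi, , drop = FALSE], window)
  gene_metrics <- data.frame(
    gene_id = member, label = lab$genes$label[gi],
    region_id = lab$genes$region_id[gi], global_tpm = unname(g),
    summit = unname(summit), expressed = unname(retained[member]),
    peak = unname(pk), stringsAsFactors = FALSE)
  list(gene_metrics = gene_metrics, dyad_metrics = dyad_metrics,
       expression = expr, chromatin = cb)
}

#' Run the full synthetic study end to end
#'
#' Simulates a dataset, writes it to `outdir/data`, reads it back through
#' the package's file readers, and runs pairing, expression bias, dyad
#' dynamics, chromatin bias, the global and per-region rearrangement
#' comparisons and the window analyses. All result tables land in
#' `outdir/results`, together with a JSON manifest (seed, parameters,
#' file checksums) that makes re-runs byte-identical and verifiable.
#'
#' @param config [sim_config()]; `config$seed` drives every stage.
#' @param outdir run directory (created).
#' @param stages subset of
#'   `c("simulate", "pair", "expr", "dynamics", "chromatin", "compare",
#'   "windows")` to run; later stages require the earlier ones' outputs in
#'   `outdir`.
#' @param cen_min_prominence prominence threshold for centromere calls, in
#'   normalised-depth units.
#' @return list of in-memory results, invisibly.
#' @export
run_all <- function(config = sim_config(), outdir,
                    stages = c("simulate", "pair", "expr", "dynamics",
                               "chromatin", "compare", "windows"),
                    cen_min_prominence = 2) {
  t0 <- Sys.time()
  data_dir <- file.path(outdir, "data")
  res_dir <- file.path(outdir, "results")
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  need <- function(path, stage) {
    if (!file.exists(path))
      stop("stage '", stage, "': missing input ", path,
           " (run the earlier stages first)")
    path
  }
  res <- list()
  if ("simulate" %in% stages) {
    sim <- simulate_dataset(config)
    write_dataset(sim, data_dir)
  }
  genes <- read_gff3(need(file.path(data_dir, "genes.gff3"), "pair"))
  regions <- read_bed(file.path(data_dir, "sra.bed"))
  names(regions)[names(regions) == "name"] <- "region_id"
  if ("pair" %in% stages) {
    hits_mu <- read_hits_table(need(file.path(data_dir, "hits_mu.tsv"), "pair"))
    hits_um <- read_hits_table(need(file.path(data_dir, "hits_um.tsv"), "pair"))
    rbh <- iterative_rbh(hits_mu, hits_um, genes = genes)
    write_results(rbh$dyads, file.path(res_dir, "dyads.tsv"))
    res$pairing <- rbh
  }
  downstream <- c("expr", "dynamics", "chromatin", "compare")
  if (any(downstream %in% stages)) {
    st <- intersect(downstream, stages)[1]
    dyads <- read.delim(need(file.path(res_dir, "dyads.tsv"), st),
                        stringsAsFactors = FALSE)
    tpm <- read_tpm_matrix(need(file.path(data_dir, "tpm.tsv"), st))
  }
  if ("expr" %in% stages) {
    retained <- filter_expressed(tpm)
    cv <- cv_classify(tpm[retained, , drop = FALSE])
    write_results(cv, file.path(res_dir, "cv.tsv"))
    expr <- dyad_expression(dyads, tpm)
    write_results(expr$per_tissue, file.path(res_dir, "expr_bias.tsv"))
    write_results(expr$summary, file.path(res_dir, "dyad_summary.tsv"))
    res$cv <- cv
    res$expression <- expr
  }
  if ("dynamics" %in% stages) {
    if (is.null(res$expression)) res$expression <- dyad_expression(dyads, tpm)
    cmds <- cmd(res$expression$per_tissue, res$expression$summary)
    dyn <- classify_dynamics(cmds)
    write_results(dyn, file.path(res_dir, "dynamics.tsv"))
    res$dynamics <- dyn
  }
  if (any(c("chromatin", "compare") %in% stages)) {
    track <- rbind(
      read_bedgraph(need(file.path(data_dir, "h3k4me3_M.bedgraph"),
                         "chromatin")),
      read_bedgraph(need(file.path(data_dir, "h3k4me3_U.bedgraph"),
                         "chromatin")))
    peaks <- read_bed(file.path(data_dir, "peaks.bed"))
  }
  if ("chromatin" %in% stages) {
    cb <- chromatin_bias(track, track, peaks, genes, dyads)
    write_results(cb, file.path(res_dir, "chromatin.tsv"))
    res$chromatin <- cb
  }
  if ("compare" %in% stages) {
    met <- pipeline_metrics(genes, regions, dyads, tpm, track, peaks)
    tab1 <- compare_global(met$gene_metrics, met$dyad_metrics)
    fig3 <- compare_per_region(met$gene_metrics, met$dyad_metrics)
    write_results(tab1, file.path(res_dir, "table1.tsv"))
    write_results(fig3, file.path(res_dir, "fig3.tsv"))
    res$metrics <- met
    res$compare_global <- tab1
    res$compare_per_region <- fig3
  }
  if ("windows" %in% stages) {
    da_files <- list.files(data_dir, pattern = "^da_line_.*\\.tsv$",
                           full.names = TRUE)
    if (length(da_files) == 0) stop("stage 'windows': no da_line_*.tsv in ",
                                    data_dir)
    assigns <- vapply(sort(da_files), function(f) {
      d <- read.delim(f, stringsAsFactors = FALSE)
      cov <- normalize_to_median(window_means(d, 50e6))
      a <- assign_addition_line(cov)
      if (is.na(a)) "none" else a
    }, "")
    da_tab <- data.frame(line = sub("^da_line_(.*)\\.tsv$", "\\1",
                                    basename(names(assigns))),
                         assigned_chrom = unname(assigns),
                         stringsAsFactors = FALSE)
    write_results(da_tab, file.path(res_dir, "da_assignments.tsv"))
    cen_depth <- read.delim(need(file.path(data_dir, "cenh3.tsv"),
                                 "windows"), stringsAsFactors = FALSE)
    cen <- centromere_midpoints(cen_depth, window_bp = 1e6,
                                min_prominence = cen_min_prominence)
    write_results(cen$calls, file.path(res_dir, "centromeres.tsv"))
    res$da_assignments <- da_tab
    res$centromeres <- cen
  }
  manifest <- list(
    seed = config$seed,
    parameters = unclass(config),
    stages = stages,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    result_md5 = as.list(tools::md5sum(sort(list.files(res_dir,
                                                       full.names = TRUE)))))
  names(manifest$result_md5) <- basename(names(manifest$result_md5))
  manifest_static <- manifest
  manifest_static$elapsed_sec <- NULL
  jsonlite::write_json(manifest_static,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
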