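# Properties of the synthetic-data generator.

test_that("configuration is validated", {
  expect_error(sim_config(dominance_mixture = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(sim_config(silencing_prob = 1.5), "probabilities")
  expect_error(sim_config(n_tissues = 1), "n_tissues")
})

test_that("simulation is byte-deterministic under a fixed seed", {
  cfg <- sim_config(n_dyads = 120, n_unique_per_genome = 20, seed = 303)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("emitted files are accepted by the readers without warnings", {
  cfg <- sim_config(n_dyads = 120, n_unique_per_genome = 20, seed = 304)
  out <- withr::local_tempdir()
  write_dataset(simulate_dataset(cfg), out)
  expect_no_warning({
    genes <- read_gff3(file.path(out, "genes.gff3"))
    read_bed(file.path(out, "sra.bed"))
    read_hits_table(file.path(out, "hits_mu.tsv"))
    read_bedgraph(file.path(out, "h3k4me3_M.bedgraph"))
    read_bed(file.path(out, "peaks.bed"))
    tpm <- read_tpm_matrix(file.path(out, "tpm.tsv"))
  })
  expect_equal(nrow(genes), 2 * 120 + 2 * 20)
  expect_equal(ncol(tpm), 7)
  expect_setequal(rownames(tpm), genes$gene_id)
})

test_that("SRA gene counts and collinearity follow the configuration", {
  cfg0 <- sim_config(n_dyads = 100, sra_fraction = 0, seed = 11)
  g0 <- simulate_genome(cfg0)
  expect_equal(nrow(g0$regions), 0)
  expect_false(any(g0$truth$dyads$sra))
  # collinear: dyad partners sit on the homoeologous chromosome pair
  grp <- sub("[MU]$", "", g0$genes$chrom)
  m_grp <- grp[match(g0$truth$dyads$m_gene, g0$genes$gene_id)]
  u_grp <- grp[match(g0$truth$dyads$u_gene, g0$genes$gene_id)]
  expect_equal(m_grp, u_grp)

  cfg1 <- sim_config(n_dyads = 1000, sra_fraction = 0.15, seed = 12)
  g1 <- simulate_genome(cfg1)
  expect_equal(sum(g1$truth$dyads$sra), 150)
  # relocated partners moved off the homoeologous chromosome, inside regions
  lab <- assign_genes_to_regions(g1$genes, g1$regions,
                                 g1$truth$dyads)
  expect_equal(sum(lab$dyads$label == "rearranged"), 150)
})

test_that("clean hit tables let pairing recover the truth exactly", {
  cfg <- sim_config(n_dyads = 150, decoy_rate = 0, dropout_rate = 0,
                    seed = 31)
  genome <- simulate_genome(cfg)
  hits <- simulate_hits(genome, cfg)
  res <- iterative_rbh(hits$mu, hits$um, genes = genome$genes)
  acc <- pair_accuracy(res$dyads, genome$truth$dyads)
  expect_equal(acc$precision, 1)
  expect_equal(acc$recall, 1)

  cfg_drop <- sim_config(n_dyads = 50, dropout_rate = 1, seed = 32)
  hits_drop <- simulate_hits(simulate_genome(cfg_drop), cfg_drop)
  expect_equal(nrow(iterative_rbh(hits_drop$mu, hits_drop$um)$dyads), 0)

  cfg_id <- sim_config(n_dyads = 50, identity_sd = 0, decoy_rate = 0,
                       seed = 33)
  hits_id <- simulate_hits(simulate_genome(cfg_id), cfg_id)
  expect_true(all(hits_id$mu$pct_identity == 98))
})

test_that("expression truth marginals match the configured rates", {
  cfg <- sim_config(n_dyads = 2000, silencing_prob = 0.05,
                    sra_fraction = 0, seed = 41)
  genome <- simulate_genome(cfg)
  sim <- simulate_expression(genome, cfg)
  # silenced fraction within the binomial 99% CI of silencing_prob
  sil <- c(sim$truth$silenced_m, sim$truth$silenced_u)
  ci <- qbinom(c(0.005, 0.995), length(sil), 0.05) / length(sil)
  expect_gte(mean(sil), ci[1])
  expect_lte(mean(sil), ci[2])
  # dominance truth frequencies within multinomial 99% CI of the mixture
  for (cls in c("balanced", "M_dominant", "U_dominant")) {
    p <- cfg$dominance_mixture[[cls]]
    k <- sum(sim$truth$class == cls)
    expect_gte(k, qbinom(0.005, 2000, p))
    expect_lte(k, qbinom(0.995, 2000, p))
  }
  # silenced genes are zero everywhere
  zeroed <- rownames(sim$tpm)[rowSums(sim$tpm) == 0]
  expect_true(all(names(sim$silenced)[sim$silenced] %in% zeroed))
})

test_that("exact balanced mixture gives identical homoeolog TPMs", {
  cfg <- sim_config(n_dyads = 60, dominance_mixture = c(1, 0, 0),
                    dominance_jitter = 0, gene_noise_sd = 0,
                    silencing_prob = 0, sra_fraction = 0, seed = 51)
  genome <- simulate_genome(cfg)
  sim <- simulate_expression(genome, cfg)
  td <- genome$truth$dyads
  expect_equal(sim$tpm[td$m_gene, ], sim$tpm[td$u_gene, ],
               ignore_attr = TRUE)
})

test_that("full silencing empties the matrix", {
  cfg <- sim_config(n_dyads = 40, silencing_prob = 1, seed = 52)
  sim <- simulate_expression(simulate_genome(cfg), cfg)
  expect_true(all(sim$tpm == 0))
})

test_that("the SRA TPM factor scales rearranged dyad expression", {
  cfg <- sim_config(n_dyads = 2000, sra_fraction = 0.15,
                    sra_tpm_factor = 0.5, sra_extra_silencing = 0,
                    silencing_prob = 0, seed = 61)
  genome <- simulate_genome(cfg)
  sim <- simulate_expression(genome, cfg)
  td <- genome$truth$dyads
  dyad_mean <- (rowMeans(sim$tpm[td$m_gene, ]) +
                  rowMeans(sim$tpm[td$u_gene, ])) / 2
  ratio <- mean(dyad_mean[td$sra]) / mean(dyad_mean[!td$sra])
  expect_equal(ratio, 0.5, tolerance = 0.1)
})

test_that("planted H3K4me3 peaks land at expressed genes as configured", {
  cfg <- sim_config(n_dyads = 150, peak_prob = 1, silencing_prob = 0.2,
                    seed = 71)
  genome <- simulate_genome(cfg)
  expr <- simulate_expression(genome, cfg)
  chrom <- simulate_chromatin(genome, expr$tpm, cfg)
  g <- global_tpm(expr$tpm)[genome$genes$gene_id]
  found <- peak_presence(chrom$peaks, genome$genes)
  expect_true(all(found[g > 0]))       # peak_prob = 1
  expect_false(any(found[g == 0]))     # silenced genes carry no peak
  # silenced genes stay at background FE over their span
  sil_genes <- genome$genes[g == 0, , drop = FALSE]
  if (nrow(sil_genes)) {
    area <- fe_area(chrom$track, sil_genes, flank = 0)
    expect_equal(unname(area),
                 cfg$background_fe * (sil_genes$end - sil_genes$start),
                 tolerance = 1e-9)
  }
})

test_that("DA and CENH3 coverage truths are planted as described", {
  cfg <- sim_config(da_noise_sd = 0, cen_noise_sd = 0, seed = 81)
  cov <- simulate_window_coverage(cfg)
  expect_equal(length(cov$da), 13)
  expect_false("DA_6U" %in% names(cov$da))
  # noise-free assignment is exact for every line
  for (ln in names(cov$da)) {
    w <- normalize_to_median(window_means(cov$da[[ln]], 50e6))
    expect_equal(assign_addition_line(w), cov$truth$da_chrom[[ln]])
  }
  expect_equal(lengths(cov$truth$centromeres)[["5M"]], 2L)
  expect_true(all(lengths(cov$truth$centromeres)[
    setdiff(names(cov$truth$centromeres), "5M")] == 1L))
})
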