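# FE-track integration, HPHB and peak presence.

test_that("FE area integrates the step function over the flanked window", {
  gene <- make_genes("g1", "1M", 10000L, 11000L)
  # FE = 2 over exactly the gene body, 0 elsewhere -> area 2 * 1000
  track <- make_track("1M", 10000L, 11000L, 2)
  expect_equal(unname(fe_area(track, gene)), 2000)
  expect_equal(unname(fe_area(make_track("1M", 0L, 1L, 0), gene)), 0)
  # two abutting intervals spanning the body: 500 * 1 + 500 * 3
  track2 <- make_track(c("1M", "1M"), c(10000L, 10500L),
                       c(10500L, 11000L), c(1, 3))
  expect_equal(unname(fe_area(track2, gene)), 2000)
})

test_that("FE area is additive over disjoint intervals and invariant to splits", {
  set.seed(17)
  for (i in 1:5) {
    edges <- sort(sample(0:20000, 9))
    score <- runif(8, 0, 5)
    track <- make_track("1M", edges[-9], edges[-1], score)
    gene <- make_genes("g", "1M", 4000L, 9000L)
    whole <- unname(fe_area(track, gene))
    # split every interval in half at integer midpoints
    mids <- (track$start + track$end) %/% 2
    ok <- mids > track$start & mids < track$end
    split_track <- rbind(
      make_track("1M", track$start[ok], mids[ok], track$score[ok]),
      make_track("1M", mids[ok], track$end[ok], track$score[ok]),
      track[!ok, ])
    expect_equal(unname(fe_area(split_track, gene)), whole,
                 tolerance = 1e-9)
    # additivity: area over [a,b) + [b,c) windows = area over [a,c)
    g1 <- make_genes("a", "1M", 4000L, 6000L)
    g2 <- make_genes("b", "1M", 6000L, 9000L)
    expect_equal(unname(fe_area(track, g1, flank = 0)) +
                   unname(fe_area(track, g2, flank = 0)),
                 unname(fe_area(track, gene, flank = 0)), tolerance = 1e-9)
  }
})

test_that("gene profiles are length-weighted and strand-symmetric", {
  gene <- make_genes("g1", "1M", 10000L, 11000L)
  flat <- make_track("1M", 0L, 50000L, 2)
  prof <- gene_profile(flat, gene)
  expect_true(all(abs(prof$fe - 2) < 1e-12))
  expect_equal(sum(prof$zone == "body"), 100)
  expect_equal(sum(prof$zone == "upstream"), 100)  # 2000 / 20

  body_only <- make_track("1M", 10000L, 11000L, 3)
  p2 <- gene_profile(body_only, gene)
  expect_true(all(p2$fe[p2$zone == "body"] == 3))
  expect_true(all(p2$fe[p2$zone != "body"] == 0))

  set.seed(3)
  edges <- sort(sample(5000:16000, 7))
  rough <- make_track("1M", edges[-7], edges[-1], runif(6, 0, 4))
  minus <- gene
  minus$strand <- "-"
  expect_equal(gene_profile(rough, minus)$fe,
               rev(gene_profile(rough, gene)$fe))
})

test_that("HPHB follows the log2 area ratio with pseudocount", {
  expect_equal(hphb(100, 100), 0)
  expect_equal(hphb(200, 50), 2.0)
  expect_equal(hphb(0, 100), log2(1e-6 / (100 + 1e-6)), tolerance = 1e-9)
  set.seed(2)
  a <- runif(1000, 0, 1e4)
  b <- runif(1000, 0, 1e4)
  expect_equal(hphb(a, b), -hphb(b, a))
})

test_that("peak presence uses a half-open window around the coding start", {
  gene <- make_genes("g1", "1M", 9000L, 12000L, cds_start = 10000L)
  near <- data.frame(chrom = "1M", start = 9800L, end = 9900L)
  expect_true(unname(peak_presence(near, gene)))
  # peak ending exactly at the window start [9500, 10500) does not overlap
  at_edge <- data.frame(chrom = "1M", start = 9400L, end = 9500L)
  expect_false(unname(peak_presence(at_edge, gene)))
  none <- data.frame(chrom = "2M", start = 9800L, end = 9900L)
  expect_false(unname(peak_presence(none, gene)))
})

test_that("planted equal chromatin gives near-zero HPHB, doubled M signal shifts it", {
  cfg <- sim_config(n_dyads = 400, dominance_mixture = c(1, 0, 0),
                    dominance_jitter = 0, gene_noise_sd = 0,
                    silencing_prob = 0, sra_fraction = 0, seed = 21)
  genome <- simulate_genome(cfg)
  expr <- simulate_expression(genome, cfg)
  chrom <- simulate_chromatin(genome, expr$tpm, cfg)
  cb <- chromatin_bias(chrom$track, chrom$track, chrom$peaks, genome$genes,
                       genome$truth$dyads)
  expect_lt(mean(abs(cb$hphb)), 0.1)
  # doubling the whole M-subgenome signal doubles every M area
  doubled <- chrom$track
  is_m <- subgenome_from_chrom(doubled$chrom) == "M"
  doubled$score[is_m] <- doubled$score[is_m] * 2
  cb2 <- chromatin_bias(doubled, doubled, chrom$peaks, genome$genes,
                        genome$truth$dyads)
  expect_equal(median(cb2$hphb), 1.0, tolerance = 0.2)
})
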