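# Reciprocal-best-hit pairing and rearrangement-region bookkeeping.

test_that("hit filter applies inclusive coverage/identity/e-value thresholds", {
  at_boundary <- make_hit("m", "u", pct_identity = 90.0, aln_length = 900,
                          subject_length = 1000, e_value = 1e-5)
  expect_equal(nrow(filter_hits(at_boundary)), 1)
  expect_equal(nrow(filter_hits(make_hit("m", "u", pct_identity = 89.9))), 0)
  just_under <- make_hit("m", "u", aln_length = 899, subject_length = 1000)
  expect_equal(nrow(filter_hits(just_under)), 0)
  expect_error(filter_hits(make_hit("m", "u", subject_length = 0)),
               "subject_length")
})

test_that("best hit uses the bit-score > e-value > identity > subject-id tie chain", {
  h <- rbind(make_hit("q", "u_hi", bit_score = 500),
             make_hit("q", "u_lo", bit_score = 450))
  expect_equal(unname(best_hits(h)["q"]), "u_hi")
  h <- rbind(make_hit("q", "u_e40", bit_score = 500, e_value = 1e-40),
             make_hit("q", "u_e50", bit_score = 500, e_value = 1e-50))
  expect_equal(unname(best_hits(h)["q"]), "u_e50")
  h <- rbind(make_hit("q", "gU3"), make_hit("q", "gU1"))
  expect_equal(unname(best_hits(h)["q"]), "gU1")
})

test_that("reciprocal_best keeps only mutual top matches", {
  expect_equal(reciprocal_best(c(A = "B"), c(B = "A")),
               data.frame(m_gene = "A", u_gene = "B",
                          stringsAsFactors = FALSE))
  expect_equal(nrow(reciprocal_best(c(A = "B"), c(B = "C"))), 0)
  expect_equal(nrow(reciprocal_best(setNames(character(0), character(0)),
                                    setNames(character(0), character(0)))), 0)
})

test_that("iterative pairing finds second-choice partners after removal", {
  # A2's best hit is B1, which pairs with A1 in round 1; once A1/B1 are
  # removed, A2 and B2 become mutual best in round 2
  mu <- rbind(make_hit("A1", "B1", bit_score = 700),
              make_hit("A2", "B1", bit_score = 600),
              make_hit("A2", "B2", bit_score = 500))
  um <- rbind(make_hit("B1", "A1", bit_score = 700),
              make_hit("B1", "A2", bit_score = 600),
              make_hit("B2", "A2", bit_score = 500))
  res <- iterative_rbh(mu, um)
  expect_equal(res$dyads$m_gene, c("A1", "A2"))
  expect_equal(res$dyads$u_gene, c("B1", "B2"))
  expect_equal(res$dyads$round, c(1L, 2L))
  expect_equal(res$n_rounds, 3L)
  expect_equal(res$unique_m, character(0))
})

test_that("an empty direction yields no dyads and all genes unique", {
  mu <- make_hit(c("A1", "A2"), c("B1", "B2"))
  um <- mu[0, ]
  res <- iterative_rbh(mu, um)
  expect_equal(nrow(res$dyads), 0)
  expect_setequal(res$unique_m, c("A1", "A2"))
  expect_setequal(res$unique_u, c("B1", "B2"))
  expect_equal(res$n_rounds, 1L)
})

test_that("round-1 output matches a brute-force all-pairs RBH oracle on random tables", {
  set.seed(42)
  for (i in 1:20) {
    mu <- random_hit_table(40, 40, 150)
    um <- random_hit_table(40, 40, 150)
    res <- iterative_rbh(mu, um)
    r1 <- res$dyads[res$dyads$round == 1, c("m_gene", "u_gene")]
    r1 <- r1[order(r1$m_gene), , drop = FALSE]
    oracle <- rbh_oracle_round1(mu, um)
    expect_equal(r1, oracle, ignore_attr = TRUE)
    # no gene is ever paired twice across rounds
    expect_false(anyDuplicated(c(res$dyads$m_gene, res$dyads$u_gene)) > 0)
  }
})

test_that("relaxing any filter threshold never decreases the dyad count", {
  set.seed(99)
  for (i in 1:10) {
    mu <- random_hit_table(30, 30, 120)
    um <- random_hit_table(30, 30, 120)
    strict <- nrow(iterative_rbh(mu, um)$dyads)
    expect_gte(nrow(iterative_rbh(mu, um, min_target_coverage = 0.8)$dyads),
               strict)
    expect_gte(nrow(iterative_rbh(mu, um, min_identity = 85)$dyads), strict)
    expect_gte(nrow(iterative_rbh(mu, um, max_evalue = 1e-3)$dyads), strict)
  }
})

test_that("collinear blocks merge across gaps up to the threshold", {
  b <- data.frame(chrom = c("4U", "4U"), start = c(0L, 150L),
                  end = c(100L, 300L))
  merged <- merge_collinear_blocks(b, max_gap_bp = 100)
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(0L, 300L))

  b2 <- data.frame(chrom = c("4U", "4U"), start = c(0L, 201L),
                   end = c(100L, 300L))
  expect_equal(nrow(merge_collinear_blocks(b2, max_gap_bp = 100)), 2)

  single <- data.frame(chrom = "4U", start = 10L, end = 20L)
  m1 <- merge_collinear_blocks(single, max_gap_bp = 100)
  expect_equal(c(m1$start, m1$end), c(10L, 20L))
  expect_error(merge_collinear_blocks(single, max_gap_bp = -1),
               "non-negative")
})

test_that("genes and dyads are labelled by midpoint membership in regions", {
  genes <- make_genes(c("gM1", "gU1", "gU2"), c("1M", "1U", "1U"),
                      start = c(100L, 100L, 1990L),
                      end = c(200L, 200L, 2010L))
  regions <- data.frame(chrom = "1U", start = 0L, end = 2000L,
                        region_id = "SRA01")
  dyads <- data.frame(m_gene = "gM1", u_gene = "gU1",
                      stringsAsFactors = FALSE)
  lab <- assign_genes_to_regions(genes, regions, dyads)
  expect_equal(lab$genes$label, c("non_rearranged", "rearranged",
                                  "non_rearranged"))
  # gU2 midpoint is exactly the half-open region end -> outside
  expect_equal(lab$dyads$label, "rearranged")
  expect_equal(lab$dyads$region_id, "SRA01")
})
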