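# Shared fixture builders and independent oracles.

make_genes <- function(gene_id, chrom, start, end, strand = "+",
                       cds_start = NULL) {
  if (is.null(cds_start))
    cds_start <- ifelse(strand == "-", end - 1L, start)
  data.frame(gene_id = gene_id,
             subgenome = subgenome_from_chrom(chrom),
             chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, cds_start = as.integer(cds_start),
             stringsAsFactors = FALSE)
}

make_track <- function(chrom, start, end, score) {
  data.frame(chrom = chrom, start = start, end = end, score = score,
             stringsAsFactors = FALSE)
}

# minimal hit row with sane defaults; override any field
make_hit <- function(query_id, subject_id, bit_score = 500,
                     e_value = 1e-50, pct_identity = 98,
                     aln_length = 1000, subject_length = 1000,
                     query_length = 1000) {
  data.frame(query_id = query_id, subject_id = subject_id,
             pct_identity = pct_identity, aln_length = aln_length,
             mismatches = 0L, gap_opens = 0L, q_start = 1L,
             q_end = aln_length, s_start = 1L, s_end = aln_length,
             e_value = e_value, bit_score = bit_score,
             query_length = query_length, subject_length = subject_length,
             stringsAsFactors = FALSE)
}

# random hit table between n_m M-genes and n_u U-genes, with deliberate
# bit-score ties and a share of rows failing each filter
random_hit_table <- function(n_m, n_u, n_hits) {
  q <- sprintf("M%03d", sample.int(n_m, n_hits, replace = TRUE))
  s <- sprintf("U%03d", sample.int(n_u, n_hits, replace = TRUE))
  slen <- sample(500:2000, n_hits, replace = TRUE)
  make_hit(q, s,
           bit_score = sample(100:120, n_hits, replace = TRUE) * 5,
           e_value = 10^-sample(3:60, n_hits, replace = TRUE),
           pct_identity = round(runif(n_hits, 85, 100), 1),
           aln_length = round(runif(n_hits, 0.8, 1) * slen),
           subject_length = slen,
           query_length = sample(500:2000, n_hits, replace = TRUE))
}

# Independent single-pass all-pairs RBH oracle: plain loops, same filter
# and tie-break definition as documented, no shared code with the package
# implementation.
rbh_oracle_round1 <- function(hits_mu, hits_um, min_cov = 0.9,
                              min_id = 90, max_e = 1e-5) {
  pick_best <- function(h) {
    keep <- h$aln_length / h$subject_length >= min_cov &
      h$pct_identity >= min_id & h$e_value <= max_e
    h <- h[keep, , drop = FALSE]
    out <- list()
    for (q in unique(h$query_id)) {
      cand <- h[h$query_id == q, , drop = FALSE]
      cand <- cand[order(-cand$bit_score, cand$e_value, -cand$pct_identity,
                         cand$subject_id), , drop = FALSE]
      out[[q]] <- cand$subject_id[1]
    }
    out
  }
  bm <- pick_best(hits_mu)
  bu <- pick_best(hits_um)
  pairs <- list()
  for (m in names(bm)) {
    u <- bm[[m]]
    if (!is.null(bu[[u]]) && bu[[u]] == m)
      pairs[[length(pairs) + 1]] <- c(m, u)
  }
  if (!length(pairs))
    return(data.frame(m_gene = character(0), u_gene = character(0)))
  df <- as.data.frame(do.call(rbind, pairs), stringsAsFactors = FALSE)
  names(df) <- c("m_gene", "u_gene")
  df[order(df$m_gene), , drop = FALSE]
}

# precision/recall of recovered dyads against the planted truth
pair_accuracy <- function(found, truth) {
  key_f <- paste(found$m_gene, found$u_gene)
  key_t <- paste(truth$m_gene, truth$u_gene)
  tp <- sum(key_f %in% key_t)
  list(precision = tp / nrow(found), recall = tp / nrow(truth))
}
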