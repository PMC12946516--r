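# Iterative reciprocal-best-hit pairing of homoeologs.
#
# Each round: filter hits, take the best hit per query in both directions,
# keep mutual pairs, remove all hits touching paired genes, repeat until a
# round yields nothing.

#' Filter alignment hits on coverage, identity and e-value
#'
#' A hit is retained when its target coverage (`aln_length / subject_length`),
#' percent identity and e-value all pass; boundaries are inclusive
#' (`>=` / `<=`). Coverage is evaluated on the subject (target) gene only.
#'
#' @param hits hits data.frame from [read_hits_table()].
#' @param min_target_coverage minimum `aln_length / subject_length`.
#' @param min_identity minimum percent identity.
#' @param max_evalue maximum e-value.
#' @return filtered hits data.frame.
#' @export
filter_hits <- function(hits, min_target_coverage = 0.90, min_identity = 90.0,
                        max_evalue = 1e-5) {
  if (nrow(hits) == 0) return(hits)
  if (any(hits$subject_length == 0)) stop("hit with subject_length = 0")
  keep <- hits$aln_length / hits$subject_length >= min_target_coverage &
    hits$pct_identity >= min_identity &
    hits$e_value <= max_evalue
  hits[keep, , drop = FALSE]
}

#' Best hit per query
#'
#' Selects, for each query, the single hit with maximal bit score. Ties are
#' broken by lower e-value, then higher identity, then lexicographically
#' smallest subject id, so the result is deterministic.
#'
#' @param hits filtered hits data.frame.
#' @return named character vector: `query_id -> subject_id`.
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0) return(setNames(character(0), character(0)))
  ord <- order(hits$query_id, -hits$bit_score, hits$e_value,
               -hits$pct_identity, hits$subject_id, method = "radix")
  h <- hits[ord, ]
  first <- !duplicated(h$query_id)
  setNames(h$subject_id[first], h$query_id[first])
}

#' Reciprocal best hits
#'
#' @param best_mu named vector from [best_hits()] in the M -> U direction.
#' @param best_um named vector in the U -> M direction.
#' @return data.frame `m_gene`, `u_gene` of mutual best pairs.
#' @export
reciprocal_best <- function(best_mu, best_um) {
  m <- names(best_mu)
  mutual <- !is.na(best_um[best_mu]) & best_um[best_mu] == m
  data.frame(m_gene = m[mutual], u_gene = unname(best_mu[mutual]),
             stringsAsFactors = FALSE)
}

#' Iterative reciprocal-best-hit pairing
#'
#' Runs filter / best-hit / reciprocal rounds, removing every hit that
#' involves a paired gene after each round, until a round finds no new pair.
#' Removing paired genes lets genes whose best match was already taken pair
#' with their next-best reciprocal partner in a later round.
#'
#' @param hits_mu,hits_um hit tables for the two alignment directions.
#' @param min_target_coverage,min_identity,max_evalue filter thresholds,
#'   see [filter_hits()].
#' @param genes optional gene table; when given, `unique_m` / `unique_u`
#'   cover all annotated genes of each subgenome, not just genes with hits.
#' @return list with `dyads` (data.frame `m_gene`, `u_gene`, `round`),
#'   `unique_m`, `unique_u` (character vectors of never-paired genes) and
#'   `n_rounds` (rounds executed, including the final empty one).
#' @export
iterative_rbh <- function(hits_mu, hits_um, min_target_coverage = 0.90,
                          min_identity = 90.0, max_evalue = 1e-5,
                          genes = NULL) {
  hmu <- filter_hits(hits_mu, min_target_coverage, min_identity, max_evalue)
  hum <- filter_hits(hits_um, min_target_coverage, min_identity, max_evalue)
  dyads <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    found <- reciprocal_best(best_hits(hmu), best_hits(hum))
    if (nrow(found) == 0) break
    found$round <- round
    dyads[[round]] <- found
    paired <- c(found$m_gene, found$u_gene)
    hmu <- hmu[!(hmu$query_id %in% paired | hmu$subject_id %in% paired), ,
               drop = FALSE]
    hum <- hum[!(hum$query_id %in% paired | hum$subject_id %in% paired), ,
               drop = FALSE]
  }
  dyads <- if (length(dyads)) do.call(rbind, dyads) else
    data.frame(m_gene = character(0), u_gene = character(0),
               round = integer(0), stringsAsFactors = FALSE)
  if (anyDuplicated(c(dyads$m_gene, dyads$u_gene)))
    stop("internal error: gene paired twice")
  if (!is.null(genes)) {
    all_m <- genes$gene_id[genes$subgenome == "M"]
    all_u <- genes$gene_id[genes$subgenome == "U"]
  } else {
    all_m <- unique(c(hits_mu$query_id, hits_um$subject_id))
    all_u <- unique(c(hits_mu$subject_id, hits_um$query_id))
  }
  list(dyads = dyads,
       unique_m = sort(setdiff(all_m, dyads$m_gene)),
       unique_u = sort(setdiff(all_u, dyads$u_gene)),
       n_rounds = round)
}

#' Merge nearby collinear blocks into rearrangement regions
#'
#' Blocks on the same chromosome separated by at most `max_gap_bp` are
#' unioned; the result is sorted and non-overlapping.
#'
#' @param blocks interval data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open), e.g. collinear blocks from an external synteny tool.
#' @param max_gap_bp maximum gap to bridge, in bp.
#' @return data.frame `chrom`, `start`, `end`, `region_id`.
#' @export
merge_collinear_blocks <- function(blocks, max_gap_bp = 1e7) {
  if (max_gap_bp < 0) stop("max_gap_bp must be non-negative")
  if (nrow(blocks) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), region_id = character(0),
                      stringsAsFactors = FALSE))
  gr <- df0_to_gr(blocks)
  merged <- reduce(gr, min.gapwidth = max_gap_bp + 1)
  df <- gr_to_df0(merged)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df$region_id <- sprintf("SRA%02d", seq_len(nrow(df)))
  df
}

#' Label genes and dyads by rearrangement status
#'
#' A gene is `rearranged` when its midpoint (`floor((start+end)/2)`) lies in
#' a region (half-open: a midpoint exactly at a region end is outside). A
#' dyad is rearranged when either member is. Genes on chromosomes absent
#' from the region set are `non_rearranged`.
#'
#' @param genes gene table.
#' @param regions region data.frame (`chrom`, `start`, `end`, optionally
#'   `region_id`).
#' @param dyads optional dyad data.frame (`m_gene`, `u_gene`).
#' @return list with `genes` (gene table plus `label` and `region_id`) and,
#'   when `dyads` is given, `dyads` (plus `label`, `region_id`).
#' @export
assign_genes_to_regions <- function(genes, regions, dyads = NULL) {
  label <- rep("non_rearranged", nrow(genes))
  region_id <- rep(NA_character_, nrow(genes))
  if (nrow(regions) > 0) {
    mid <- (genes$start + genes$end) %/% 2L
    gq <- GRanges(genes$chrom, IRanges(start = mid + 1L, width = 1L))
    rid <- if (!is.null(regions$region_id)) regions$region_id else
      sprintf("SRA%02d", seq_len(nrow(regions)))
    ov <- suppressWarnings(findOverlaps(gq, df0_to_gr(regions),
                                        select = "first"))
    hit <- !is.na(ov)
    label[hit] <- "rearranged"
    region_id[hit] <- rid[ov[hit]]
  }
  out <- genes
  out$label <- label
  out$region_id <- region_id
  res <- list(genes = out)
  if (!is.null(dyads)) {
    lm <- label[match(dyads$m_gene, genes$gene_id)]
    lu <- label[match(dyads$u_gene, genes$gene_id)]
    rm_ <- region_id[match(dyads$m_gene, genes$gene_id)]
    ru <- region_id[match(dyads$u_gene, genes$gene_id)]
    d <- dyads
    d$label <- ifelse(lm == "rearranged" | lu == "rearranged",
                      "rearranged", "non_rearranged")
    d$region_id <- ifelse(!is.na(rm_), rm_, ru)
    res$dyads <- d
  }
  res
}
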