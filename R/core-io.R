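#' @importFrom stats median sd mad rnorm runif rbeta rbinom rlnorm setNames
#'   kruskal.test wilcox.test chisq.test p.adjust quantile
#' @importFrom utils read.delim write.table head
#' @importFrom GenomicRanges GRanges findOverlaps reduce seqnames
#' @importFrom IRanges IRanges CharacterList
#' @importFrom S4Vectors queryHits subjectHits mcols
NULL

# Internal coordinate convention: 0-based half-open everywhere.
# GFF3 (1-based closed) and GRanges (1-based closed) are converted at the
# boundary; BED/bedGraph already match the internal convention.

#' Derive the subgenome from a chromosome name
#'
#' Chromosomes of the two subgenomes are expected to carry an `M` or `U`
#' suffix (e.g. `"1M"`, `"7U"`, optionally with decorations such as
#' `"chr1M"`). A named override map can replace the suffix rule for
#' non-conforming assemblies.
#'
#' @param chrom character vector of chromosome names.
#' @param override optional named character vector mapping chromosome name to
#'   `"M"` or `"U"`; takes precedence over the suffix rule.
#' @return character vector of `"M"`/`"U"` (NA where underivable).
#' @export
subgenome_from_chrom <- function(chrom, override = NULL) {
  out <- rep(NA_character_, length(chrom))
  m <- regmatches(chrom, regexpr("[MU](?=[^MU]*$)", chrom, perl = TRUE))
  has <- grepl("[MU]", chrom)
  out[has] <- m
  if (!is.null(override)) {
    hit <- chrom %in% names(override)
    out[hit] <- unname(override[chrom[hit]])
  }
  out
}

new_gene_table <- function(gene_id, subgenome, chrom, start, end, strand, cds_start) {
  df <- data.frame(
    gene_id = as.character(gene_id), subgenome = as.character(subgenome),
    chrom = as.character(chrom), start = as.integer(start),
    end = as.integer(end), strand = as.character(strand),
    cds_start = as.integer(cds_start), stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id: ", df$gene_id[duplicated(df$gene_id)][1])
  if (any(df$start >= df$end)) stop("gene with start >= end")
  bad <- df$cds_start < df$start | df$cds_start >= df$end
  if (any(bad)) stop("cds_start outside gene span for ", df$gene_id[bad][1])
  df
}

#' Read a gene annotation from GFF3
#'
#' Parses `gene` and `CDS` features (CDS linked to gene directly or through
#' an mRNA) and returns one row per gene with 0-based half-open coordinates
#' and the strand-aware coding start: the leftmost CDS base for `+` genes,
#' the rightmost for `-` genes. Genes lacking CDS children fall back to the
#' gene boundary (`start` for `+`, `end - 1` for `-`), or always when
#' `cds_start_from = "gene"`.
#'
#' @param path GFF3 file (gzip transparent).
#' @param cds_start_from `"cds"` (default) or `"gene"`.
#' @param subgenome_map optional override for [subgenome_from_chrom()].
#' @return data.frame with columns `gene_id`, `subgenome`, `chrom`, `start`,
#'   `end`, `strand`, `cds_start`.
#' @export
read_gff3 <- function(path, cds_start_from = c("cds", "gene"), subgenome_map = NULL) {
  cds_start_from <- match.arg(cds_start_from)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  if (!any(body)) {
    warning("empty GFF3: ", path)
    return(new_gene_table(character(), character(), character(),
                          integer(), integer(), character(), integer()))
  }
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9))
    stop("malformed GFF3 line ", which(body)[nf != 9][1], " in ", path,
         ": expected 9 tab-separated fields, got ", nf[nf != 9][1])
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  gi <- which(typ == "gene")
  if (length(gi) == 0) stop("no gene features in ", path)
  gid <- as.character(gr$ID[gi])
  if (anyDuplicated(gid)) stop("duplicate gene_id in ", path, ": ",
                               gid[duplicated(gid)][1])
  # map every feature up to its gene through Parent chains (depth <= 2)
  id2gene <- setNames(gid, gid)
  par1 <- vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  feat_id <- as.character(gr$ID)
  up <- function(ids) {
    res <- id2gene[ids]
    miss <- is.na(res) & !is.na(ids)
    if (any(miss)) {
      # one more hop via the parent feature's own Parent
      idx <- match(ids[miss], feat_id)
      res[miss] <- id2gene[ifelse(is.na(idx), NA_character_, par1[idx])]
    }
    res
  }
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  strand_g <- as.character(GenomicRanges::strand(gr))[gi]
  cds_start <- ifelse(strand_g == "-", end0[gi] - 1L, start0[gi])
  if (cds_start_from == "cds") {
    ci <- which(typ == "CDS")
    if (length(ci)) {
      cg <- up(par1[ci])
      ok <- !is.na(cg)
      if (any(ok)) {
        lo <- tapply(start0[ci][ok], cg[ok], min)
        hi <- tapply(end0[ci][ok], cg[ok], max)
        j <- match(gid, names(lo))
        has <- !is.na(j)
        cds_start[has] <- ifelse(strand_g[has] == "-",
                                 as.integer(hi[j[has]]) - 1L,
                                 as.integer(lo[j[has]]))
      }
    }
  }
  new_gene_table(gid, subgenome_from_chrom(as.character(seqnames(gr))[gi], subgenome_map),
                 as.character(seqnames(gr))[gi], start0[gi], end0[gi],
                 strand_g, cds_start)
}

#' Write a gene table as GFF3
#'
#' Emits gene, mRNA and single-exon CDS features reconstructing the
#' coordinates and coding starts held in a gene table (the inverse of
#' [read_gff3()] for the synthetic annotation this package generates).
#' Volatile header lines (date stamps) are stripped so output is
#' byte-deterministic.
#'
#' @param genes gene table as returned by [read_gff3()].
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  n <- nrow(genes)
  neg <- genes$strand == "-"
  # CDS runs from cds_start to the gene edge on the 3' side
  cds_lo <- ifelse(neg, genes$start, genes$cds_start)
  cds_hi <- ifelse(neg, genes$cds_start + 1L, genes$end)
  gr <- GRanges(
    rep(genes$chrom, 3L),
    IRanges(start = c(genes$start + 1L, genes$start + 1L, cds_lo + 1L),
            end = c(genes$end, genes$end, cds_hi)),
    strand = rep(genes$strand, 3L),
    type = rep(c("gene", "mRNA", "CDS"), each = n),
    ID = c(genes$gene_id, paste0(genes$gene_id, ".m1"), rep(NA_character_, n)),
    Parent = CharacterList(c(replicate(n, character(0), simplify = FALSE),
                             as.list(genes$gene_id),
                             as.list(paste0(genes$gene_id, ".m1")))),
    phase = c(rep(NA_integer_, 2L * n), rep(0L, n))
  )
  ord <- order(rep(seq_len(n), 3L))  # keep each gene's features together
  rtracklayer::export(gr[ord], path, format = "gff3")
  lines <- readLines(path)
  keep <- !grepl("^##(date|source-version)", lines)
  writeLines(lines[keep], path)
  invisible(path)
}

#' Read a 14-column tabular alignment hits file
#'
#' Expects the 12 standard tabular alignment columns (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query/subject
#' start/end, e-value, bit score) plus `query_length` and `subject_length`.
#' Lines starting with `#` are skipped.
#'
#' @param path TSV file (gzip transparent).
#' @return data.frame of alignment hits in file order.
#' @export
read_hits_table <- function(path) {
  cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "e_value", "bit_score", "query_length", "subject_length")
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) != 14L)
    stop("expected 14 tab-separated columns (std 12 + query_length + ",
         "subject_length); got ", ncol(df), " in ", path,
         " - regenerate the alignment with 'std qlen slen' output columns")
  names(df) <- cols
  num <- cols[-(1:2)]
  for (cn in num) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v) && !anyNA(df[[cn]]))
      stop("non-numeric value in column '", cn, "' of ", path)
    df[[cn]] <- v
  }
  df[1:2] <- lapply(df[1:2], as.character)
  df
}

#' @rdname read_hits_table
#' @param hits hits data.frame.
#' @export
write_hits_table <- function(hits, path) {
  out <- hits
  out$e_value <- format(out$e_value, digits = 6, trim = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

gr_to_df0 <- function(gr, extra = NULL) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  for (cn in extra) df[[cn]] <- mcols(gr)[[cn]]
  df
}

df0_to_gr <- function(df, score = NULL, name = NULL) {
  gr <- GRanges(df$chrom, IRanges(start = df$start + 1L, end = df$end))
  if (!is.null(score)) gr$score <- score
  if (!is.null(name)) gr$name <- name
  gr
}

#' Read a bedGraph fold-enrichment track
#'
#' The track must be a step function: overlapping intervals on one
#' chromosome are rejected. Positions not covered by any interval have
#' signal 0.
#'
#' @param path bedGraph file (gzip transparent).
#' @return data.frame `chrom`, `start`, `end`, `score` (0-based half-open),
#'   sorted by chromosome and start.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- gr_to_df0(gr, "score")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  ov <- which(df$chrom[-1] == df$chrom[-nrow(df)] &
                df$start[-1] < df$end[-nrow(df)])
  if (length(ov))
    stop("overlapping bedGraph intervals on ", df$chrom[ov[1] + 1],
         " near position ", df$start[ov[1] + 1],
         " in ", path, ": signal must be a step function")
  df
}

#' @rdname read_bedgraph
#' @param track signal-track data.frame.
#' @export
write_bedgraph <- function(track, path) {
  rtracklayer::export(df0_to_gr(track, score = track$score), path,
                      format = "bedGraph")
  invisible(path)
}

#' Read / write peak or region intervals (BED)
#'
#' @param path BED file (gzip transparent).
#' @return data.frame `chrom`, `start`, `end` plus `name` when present
#'   (0-based half-open).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  extra <- intersect("name", names(mcols(gr)))
  df <- gr_to_df0(gr, extra)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_bed
#' @param intervals interval data.frame (optionally with `name`).
#' @export
write_bed <- function(intervals, path) {
  rtracklayer::export(df0_to_gr(intervals, name = intervals$name), path,
                      format = "BED")
  invisible(path)
}

#' Read a gene x tissue TPM matrix
#'
#' First column holds gene ids, remaining columns one tissue each.
#' Missing values are rejected by default: the expression-filtering and
#' bias rules assume a complete matrix.
#'
#' @param path TSV file (gzip transparent).
#' @param allow_missing keep `NA` cells instead of erroring.
#' @return numeric matrix, rownames = gene ids, colnames = tissues.
#' @export
read_tpm_matrix <- function(path, allow_missing = FALSE) {
  df <- read.delim(path, header = TRUE, row.names = 1, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 1) stop("TPM matrix has no tissue columns: ", path)
  m <- as.matrix(df)
  mode(m) <- "numeric"
  if (anyNA(m) && !allow_missing)
    stop(sum(is.na(m)), " missing TPM value(s) in ", path,
         " (use allow_missing = TRUE to keep them)")
  if (any(m < 0, na.rm = TRUE)) stop("negative TPM in ", path)
  m
}

#' @rdname read_tpm_matrix
#' @param tpm numeric gene x tissue matrix.
#' @export
write_tpm_matrix <- function(tpm, path) {
  df <- data.frame(gene_id = rownames(tpm), tpm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a results table as TSV
#'
#' @param table data.frame.
#' @param path output file.
#' @export
write_results <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
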