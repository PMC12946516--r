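# Window-based read-depth analyses: chromosome assignment of disomic
# addition lines from skim-seq coverage, and centromere midpoint detection
# from CENH3 ChIP coverage.
#
# Depth tables are data.frames with columns `chrom`, `pos` (0-based start
# of an equal-width depth bin) and `depth`.

#' Mean depth in fixed genomic windows
#'
#' Windows are tiled from position 0; the last window of a chromosome is
#' truncated at the chromosome end (taken as the end of the last depth bin
#' unless `chrom_lengths` is given). The window mean is the mean of the
#' depth bins falling in the window.
#'
#' @param depth depth table (`chrom`, `pos`, `depth`).
#' @param window_bp window size in bp (> 0).
#' @param bin_bp width of the input depth bins (default: inferred from the
#'   most common position step).
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return data.frame `chrom`, `window_index`, `start`, `end`,
#'   `mean_depth`.
#' @export
window_means <- function(depth, window_bp, bin_bp = NULL,
                         chrom_lengths = NULL) {
  if (window_bp <= 0) stop("window_bp must be positive")
  if (is.null(bin_bp)) {
    steps <- unlist(lapply(split(depth$pos, depth$chrom),
                           function(p) diff(sort(unique(p)))))
    bin_bp <- if (length(steps)) as.numeric(names(sort(table(steps),
                                                       decreasing = TRUE))[1])
              else window_bp
  }
  wi <- depth$pos %/% window_bp
  key <- paste(depth$chrom, wi, sep = "\r")
  mean_depth <- tapply(depth$depth, key, mean)
  parts <- strsplit(names(mean_depth), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    window_index = as.integer(vapply(parts, `[`, "", 2)),
    mean_depth = as.numeric(mean_depth), stringsAsFactors = FALSE
  )
  out$start <- out$window_index * window_bp
  last_bin <- tapply(depth$pos, depth$chrom, max)
  clen <- if (is.null(chrom_lengths))
    setNames(as.numeric(last_bin) + bin_bp, names(last_bin))
  else chrom_lengths
  out$end <- pmin(out$start + window_bp, clen[out$chrom])
  out <- out[order(out$chrom, out$window_index),
             c("chrom", "window_index", "start", "end", "mean_depth")]
  rownames(out) <- NULL
  out
}

#' Normalise window depths to the genome-wide median
#'
#' Adds `norm_depth = mean_depth / median(mean_depth)` over all windows.
#' Idempotent up to floating tolerance: renormalising changes nothing.
#'
#' @param coverage window table from [window_means()].
#' @return the input plus a `norm_depth` column.
#' @export
normalize_to_median <- function(coverage) {
  if (nrow(coverage) == 0) stop("empty window set")
  med <- median(coverage$mean_depth)
  if (med == 0) stop("genome-wide median window depth is 0")
  coverage$norm_depth <- coverage$mean_depth / med
  coverage
}

#' Assign an addition line to its added chromosome
#'
#' The added chromosome of a disomic addition line shows elevated
#' normalised coverage along its whole length. Returns the chromosome with
#' the highest median normalised depth, provided it reaches
#' `fold_threshold`; otherwise `NA` with a warning.
#'
#' @param coverage normalised window table (from [normalize_to_median()]).
#' @param fold_threshold minimum median normalised depth of the called
#'   chromosome.
#' @return chromosome name, or `NA_character_`.
#' @export
assign_addition_line <- function(coverage, fold_threshold = 1.5) {
  med <- tapply(coverage$norm_depth, coverage$chrom, median)
  best <- names(med)[which.max(med)]
  if (med[best] < fold_threshold) {
    warning("no chromosome reaches fold threshold ", fold_threshold,
            " (best: ", best, " at ", round(med[best], 2), ")")
    return(NA_character_)
  }
  best
}

# peak prominence on a 1-d profile: height minus the higher of the two
# valley minima separating the peak from higher terrain (or the profile
# edge)
peak_prominence <- function(h, i) {
  n <- length(h)
  left <- if (i > 1) {
    j <- i - 1
    lo <- h[j]
    while (j > 1 && h[j] <= h[i]) { j <- j - 1; lo <- min(lo, h[j]) }
    lo
  } else h[i]
  right <- if (i < n) {
    j <- i + 1
    lo <- h[j]
    while (j < n && h[j] <= h[i]) { j <- j + 1; lo <- min(lo, h[j]) }
    lo
  } else h[i]
  h[i] - max(left, right)
}

#' Centromere midpoints from CENH3 ChIP coverage
#'
#' Computes window means of the ChIP depth, normalises to the genome-wide
#' median and reports, per chromosome, every local maximum with prominence
#' at least `min_prominence` (default: 3 x the median absolute deviation
#' of the normalised profile). Terminal windows are ineligible as peaks
#' (guards against end-of-chromosome coverage artifacts). The midpoint is
#' the centre of the summit window; chromosomes whose profile yields no
#' qualifying peak are reported with `n_peaks = 0`.
#'
#' @param depth CENH3 depth table (`chrom`, `pos`, `depth`).
#' @param window_bp window size in bp.
#' @param min_prominence minimum peak prominence in normalised-depth units.
#' @param chrom_lengths optional named chromosome lengths.
#' @return list with `calls` (data.frame `chrom`, `midpoint`, `height`) and
#'   `n_peaks` (named integer vector per chromosome).
#' @export
centromere_midpoints <- function(depth, window_bp = 1e6,
                                 min_prominence = NULL,
                                 chrom_lengths = NULL) {
  cov <- normalize_to_median(window_means(depth, window_bp,
                                          chrom_lengths = chrom_lengths))
  if (is.null(min_prominence))
    min_prominence <- 3 * mad(cov$norm_depth)
  calls <- list()
  n_peaks <- integer(0)
  for (chr in unique(cov$chrom)) {
    p <- cov[cov$chrom == chr, , drop = FALSE]
    p <- p[order(p$window_index), , drop = FALSE]
    h <- p$norm_depth
    n <- length(h)
    found <- integer(0)
    if (n >= 3) {
      for (i in 2:(n - 1)) {
        if (h[i] > h[i - 1] && h[i] >= h[i + 1] &&
            peak_prominence(h, i) >= min_prominence)
          found <- c(found, i)
      }
    }
    n_peaks[chr] <- length(found)
    if (length(found))
      calls[[chr]] <- data.frame(
        chrom = chr,
        midpoint = (p$start[found] + p$end[found]) / 2,
        height = h[found], stringsAsFactors = FALSE)
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(0), midpoint = numeric(0),
               height = numeric(0), stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  list(calls = calls, n_peaks = n_peaks)
}
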