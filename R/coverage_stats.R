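#' Interquartile-mean coverage of a per-base depth vector
#'
#' Mean per-base read depth computed over only the second and third quartiles
#' of the sorted depths. Conserved genes shared across phage groups attract
#' reads from relatives and inflate local coverage; dropping the top (and
#' bottom) quartile of positions makes the per-contig mean robust to such
#' spikes.
#'
#' The quartile slice is deterministic, with no interpolation: sort the `L`
#' per-base depths ascending and average the positions whose 0-based rank
#' falls in the half-open interval `[ceiling(L/4), floor(3L/4))`.
#'
#' @param depths Numeric vector of per-base depths (length >= 4), or a
#'   run-length encoded vector given as a two-column object; see `run_lengths`.
#' @param run_lengths Optional integer vector of run lengths. When supplied,
#'   `depths` holds one depth value per run and the statistic is computed on
#'   the implied expanded vector without materializing it.
#' @return The interquartile mean, a single number.
#' @examples
#' iqr_mean_coverage(c(1, 1, 2, 2, 3, 3, 100, 100)) # 2.5
#' iqr_mean_coverage(c(5, 80), run_lengths = c(90L, 10L))
#' @export
iqr_mean_coverage <- function(depths, run_lengths = NULL) {
  if (is.null(run_lengths)) run_lengths <- rep(1L, length(depths))
  if (length(depths) != length(run_lengths)) {
    stop("depths and run_lengths must have equal length")
  }
  if (any(run_lengths < 1)) stop("run lengths must be >= 1")
  if (any(depths < 0)) stop("per-base depths must be nonnegative")
  L <- sum(as.numeric(run_lengths))
  if (L < 4) stop("interquartile mean undefined for fewer than 4 positions")
  lo <- ceiling(L / 4)    # 0-based rank of first position kept
  hi <- floor(3 * L / 4)  # 0-based rank one past the last position kept
  ord <- order(depths)
  v <- depths[ord]
  w <- as.numeric(run_lengths[ord])
  cum <- cumsum(w)
  # weight of each run falling inside (lo, hi] in 1-based rank terms
  keep <- pmin(cum, hi) - pmax(cum - w, lo)
  keep[keep < 0] <- 0
  sum(v * keep) / (hi - lo)
}

#' Per-contig, per-sample coverage summaries
#'
#' Reduces a run-length-encoded per-base coverage table to the two scalars the
#' downstream statistics need: the interquartile-mean coverage and the total
#' number of nucleotides mapped (`sum(run_length * depth)`).
#'
#' @param coverage Data frame with columns `contig_id`, `sample_id`,
#'   `run_start`, `run_length`, `depth` (run-length encoded per-base depth).
#' @return Data frame with one row per (contig, sample) pair present in the
#'   input: `contig_id`, `sample_id`, `iqr_mean`, `nucleotides_mapped`.
#' @export
coverage_summaries <- function(coverage) {
  req <- c("contig_id", "sample_id", "run_length", "depth")
  if (!all(req %in% names(coverage))) {
    stop("coverage table needs columns: ", paste(req, collapse = ", "))
  }
  key <- paste(coverage$contig_id, coverage$sample_id, sep = "\r")
  idx <- split(seq_len(nrow(coverage)), key)
  out <- lapply(idx, function(i) {
    data.frame(
      contig_id = coverage$contig_id[i[1]],
      sample_id = coverage$sample_id[i[1]],
      iqr_mean = iqr_mean_coverage(coverage$depth[i], coverage$run_length[i]),
      nucleotides_mapped = sum(coverage$run_length[i] * coverage$depth[i]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pivot per-(contig, sample) summaries to a contigs x samples matrix
#'
#' Absent (contig, sample) pairs fill with 0.
#'
#' @param summaries Output of [coverage_summaries()].
#' @param value Which column to pivot (`"iqr_mean"` or `"nucleotides_mapped"`).
#' @param contig_ids,sample_ids Row/column universe (defaults to the ids seen).
#' @return A contigs x samples numeric matrix.
#' @export
summary_matrix <- function(summaries, value, contig_ids = NULL,
                           sample_ids = NULL) {
  if (is.null(contig_ids)) contig_ids <- sort(unique(summaries$contig_id))
  if (is.null(sample_ids)) sample_ids <- sort(unique(summaries$sample_id))
  m <- matrix(0, nrow = length(contig_ids), ncol = length(sample_ids),
              dimnames = list(contig_ids, sample_ids))
  keep <- summaries$contig_id %in% contig_ids &
    summaries$sample_id %in% sample_ids
  s <- summaries[keep, , drop = FALSE]
  m[cbind(s$contig_id, s$sample_id)] <- s[[value]]
  m
}

#' Relative abundance of contigs within one sample
#'
#' The proportion of nucleotides mapped to each contig, out of all nucleotides
#' mapped to the curated viral contigs in that sample. The denominator is the
#' curated viral set only, so proportions compare phage populations against
#' each other, not against the cellular background.
#'
#' @param nucleotides Named numeric vector of nucleotides mapped per contig in
#'   one sample.
#' @return Named vector of proportions summing to 1.
#' @examples
#' relative_abundance(c(a = 30000, b = 10000))
#' @export
relative_abundance <- function(nucleotides) {
  if (any(nucleotides < 0)) stop("nucleotide counts must be nonnegative")
  tot <- sum(nucleotides)
  if (tot <= 0) stop("no nucleotides mapped in this sample; abundance undefined")
  nucleotides / tot
}

#' Relative abundance matrix across samples
#'
#' Column-normalizes a contigs x samples nucleotides-mapped matrix. Samples
#' with zero total mapping are dropped with a warning.
#'
#' @param nucleotide_matrix Contigs x samples matrix of nucleotides mapped.
#' @return Contigs x (retained) samples matrix; every column sums to 1.
#' @export
relative_abundance_matrix <- function(nucleotide_matrix) {
  tot <- colSums(nucleotide_matrix)
  bad <- tot <= 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " sample(s) with zero total mapping: ",
            paste(colnames(nucleotide_matrix)[bad], collapse = ", "))
  }
  m <- nucleotide_matrix[, !bad, drop = FALSE]
  sweep(m, 2, colSums(m), "/")
}

#' Mean-normalized temporal variance (index of dispersion)
#'
#' Temporal variance of a contig's relative abundance divided by its temporal
#' mean. More abundant contigs have larger variances simply by scale; dividing
#' by the mean makes the statistic scale linearly rather than quadratically
#' with abundance, equalizing the weight of high- and low-abundance contigs in
#' depth-bin comparisons. The variance is the population flavor (divisor `T`):
#' the sampled timepoints are treated as the window of interest, not a sample
#' from a longer process.
#'
#' @param series Numeric vector of relative abundances through time (length
#'   >= 2).
#' @param sample_variance Use divisor `T - 1` instead of `T`.
#' @return Variance / mean; `NA` (with a warning) when the mean is zero.
#' @examples
#' mean_normalized_variance(c(0, 2)) # 1
#' @export
mean_normalized_variance <- function(series, sample_variance = FALSE) {
  if (length(series) < 2) stop("need at least 2 timepoints")
  if (any(series < 0)) stop("relative abundances must be nonnegative")
  m <- mean(series)
  if (m == 0) {
    warning("series mean is zero; dispersion undefined")
    return(NA_real_)
  }
  n <- length(series)
  divisor <- if (sample_variance) n - 1 else n
  v <- sum((series - m)^2) / divisor
  v / m
}

#' Rank the most abundant contigs within each depth bin
#'
#' Contigs are ranked by their mean relative abundance across the samples of
#' each depth bin; ties break by contig id so the ranking is deterministic.
#'
#' @param abundance Contigs x samples relative-abundance matrix.
#' @param samples Sample frame (`sample_id`, `depth_m`, `date`).
#' @param k How many contigs per depth bin (default 13).
#' @return Named list, one character vector of contig ids per depth.
#' @export
top_k_per_depth <- function(abundance, samples, k = 13) {
  samples <- samples[samples$sample_id %in% colnames(abundance), , drop = FALSE]
  depths <- sort(unique(samples$depth_m))
  if (k > nrow(abundance)) {
    warning("k = ", k, " exceeds the ", nrow(abundance),
            " available contigs; returning all")
    k <- nrow(abundance)
  }
  out <- lapply(depths, function(d) {
    cols <- samples$sample_id[samples$depth_m == d]
    mu <- rowMeans(abundance[, cols, drop = FALSE])
    ord <- order(-mu, rownames(abundance))
    rownames(abundance)[ord][seq_len(k)]
  })
  names(out) <- as.character(depths)
  out
}

#' Per-contig dispersion within each depth bin
#'
#' For every contig and depth, the mean-normalized variance of the contig's
#' relative abundance through that depth's time series.
#'
#' @inheritParams top_k_per_depth
#' @return Contigs x depths matrix of dispersion values (`NA` where a contig
#'   is entirely absent from a bin).
#' @export
dispersion_by_depth <- function(abundance, samples) {
  samples <- samples[samples$sample_id %in% colnames(abundance), , drop = FALSE]
  depths <- sort(unique(samples$depth_m))
  out <- sapply(depths, function(d) {
    cols <- samples$sample_id[samples$depth_m == d]
    apply(abundance[, cols, drop = FALSE], 1, function(x) {
      if (mean(x) == 0) NA_real_ else suppressWarnings(mean_normalized_variance(x))
    })
  })
  colnames(out) <- as.character(depths)
  out
}

# Depth (m) -> depth-group label used in the five-group binning.
depth_bin_group <- function(depth_m) {
  ifelse(depth_m <= 75, "surface",
         ifelse(depth_m == 125, "DCM",
                ifelse(depth_m == 200, "two_hundred", "mesopelagic")))
}

#' Assign contigs to the five depth-distribution groups
#'
#' An automatic surrogate for manual differential-coverage binning. Each
#' contig's home depth is the depth bin maximizing its mean interquartile-mean
#' coverage; the home depth maps onto surface (25-75 m), DCM (125 m), 200 m,
#' or mesopelagic (500-1,000 m). Contigs whose temporal dispersion within
#' their home bin exceeds `sporadic_threshold` are labeled sporadic instead.
#' The default threshold is the 90th percentile of all contigs' dispersion
#' values (data-adaptive); `overrides` gives exact manual control.
#'
#' @param iqr_matrix Contigs x samples matrix of interquartile-mean coverage.
#' @param abundance Contigs x samples relative-abundance matrix (for the
#'   dispersion computation).
#' @param samples Sample frame.
#' @param sporadic_threshold Dispersion above which a contig is sporadic;
#'   `NULL` uses the 90th percentile across contigs.
#' @param overrides Optional named character vector `contig_id -> group`
#'   honored verbatim.
#' @return Data frame `contig_id`, `group`, `home_depth_m`, `dispersion`.
#' @export
assign_depth_groups <- function(iqr_matrix, abundance, samples,
                                sporadic_threshold = NULL, overrides = NULL) {
  samples <- samples[samples$sample_id %in% colnames(iqr_matrix), , drop = FALSE]
  depths <- sort(unique(samples$depth_m))
  depth_mean <- sapply(depths, function(d) {
    cols <- samples$sample_id[samples$depth_m == d]
    rowMeans(iqr_matrix[, cols, drop = FALSE])
  })
  colnames(depth_mean) <- as.character(depths)
  absent <- rowSums(depth_mean) == 0
  if (any(absent)) {
    stop("contig(s) absent from every sample: ",
         paste(rownames(iqr_matrix)[absent], collapse = ", "))
  }
  home_idx <- max.col(depth_mean, ties.method = "first")
  home_depth <- depths[home_idx]
  disp_all <- dispersion_by_depth(abundance, samples)
  disp_home <- disp_all[cbind(seq_len(nrow(disp_all)), home_idx)]
  if (is.null(sporadic_threshold)) {
    sporadic_threshold <- stats::quantile(disp_home, 0.9, na.rm = TRUE,
                                          names = FALSE)
  }
  group <- depth_bin_group(home_depth)
  group[!is.na(disp_home) & disp_home > sporadic_threshold] <- "sporadic"
  out <- data.frame(
    contig_id = rownames(iqr_matrix),
    group = group,
    home_depth_m = home_depth,
    dispersion = disp_home,
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    hit <- match(out$contig_id, names(overrides))
    out$group[!is.na(hit)] <- overrides[hit[!is.na(hit)]]
  }
  rownames(out) <- NULL
  out
}
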