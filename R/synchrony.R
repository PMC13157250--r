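# Spike-train synchrony: Pearson correlation matrices of firing rates
# counted in fixed-width bins (default 10 ms), plus within/between-group
# summaries for developmental contrasts. Undefined correlations (cells with
# zero-variance binned counts, e.g. silent cells) are reported as missing,
# never as zero.

#' Bin spike times into fixed-width count sequences
#'
#' `counts[k]` is the number of spikes in `[k * bin_s, (k+1) * bin_s)`; the
#' total count is preserved. Firing rates are `counts / bin_s` and give
#' identical Pearson correlations.
#'
#' @param spike_times list of numeric spike-time vectors (seconds), one per
#'   cell; every time must lie in `[0, duration_s)`.
#' @param duration_s recording length (s).
#' @param bin_s bin width (s, default 0.010).
#' @return integer matrix `n_bins x n_cells` (named columns when the list
#'   is named).
#' @export
bin_spike_counts <- function(spike_times, duration_s, bin_s = 0.010) {
  check_that(bin_s > 0, "bin_s must be positive")
  check_that(is.list(spike_times), "spike_times must be a list of numeric vectors")
  n_bins <- ceiling(duration_s / bin_s)
  counts <- vapply(spike_times, function(st) {
    if (length(st)) {
      check_that(all(st >= 0 & st < duration_s),
                 "spike time outside [0, duration_s)")
      tabulate(floor(st / bin_s) + 1L, nbins = n_bins)
    } else integer(n_bins)
  }, integer(n_bins))
  colnames(counts) <- names(spike_times)
  counts
}

#' Pairwise Pearson correlation matrix of binned firing rates
#'
#' Zero-variance columns (silent or perfectly regular cells) yield `NA`
#' rows/columns rather than fabricated zeros; the diagonal is 1 wherever a
#' cell's counts have positive variance.
#'
#' @param counts matrix `n_bins x n_cells` from [bin_spike_counts()] (counts
#'   or rates; the correlation is identical).
#' @param labels optional cell labels; defaults to column names.
#' @param bin_s bin width used (s), carried as an attribute for reporting.
#' @return object of class `synchrony_matrix`: the `n x n` matrix plus
#'   `bin_s` and `n_bins` attributes.
#' @export
correlation_matrix <- function(counts, labels = colnames(counts),
                               bin_s = NA_real_) {
  check_that(is.matrix(counts) && ncol(counts) >= 2,
             "counts must be a matrix with >= 2 cells")
  check_that(nrow(counts) >= 2, "need at least 2 bins")
  if (is.null(labels)) labels <- paste0("cell", seq_len(ncol(counts)))
  vars <- apply(counts, 2, stats::var)
  m <- suppressWarnings(stats::cor(counts))
  m[vars == 0, ] <- NA_real_
  m[, vars == 0] <- NA_real_
  diag(m)[vars > 0] <- 1
  dimnames(m) <- list(labels, labels)
  structure(m, class = c("synchrony_matrix", "matrix"),
            bin_s = bin_s, n_bins = nrow(counts))
}

#' @export
print.synchrony_matrix <- function(x, ...) {
  cat(sprintf("synchrony_matrix: %d cells, %s bins%s\n", nrow(x),
              attr(x, "n_bins"),
              if (!is.na(attr(x, "bin_s")))
                sprintf(" of %g ms", attr(x, "bin_s") * 1000) else ""))
  print(round(unclass(x)[, , drop = FALSE], 3))
  invisible(x)
}

#' Synchrony from spike trains in one call
#'
#' Bins the trains and correlates them; the standard detect -> bin ->
#' correlate order of the neuronal pipeline (pass ground-truth trains for
#' simulator validation).
#'
#' @inheritParams bin_spike_counts
#' @return a [correlation_matrix()] result.
#' @export
synchrony_matrix <- function(spike_times, duration_s, bin_s = 0.010) {
  counts <- bin_spike_counts(spike_times, duration_s, bin_s)
  correlation_matrix(counts, bin_s = bin_s)
}

#' Within- and between-group synchrony summary
#'
#' Means of the defined off-diagonal correlations within each group
#' assignment and across groups; undefined (NA) pairs are excluded and
#' counted.
#'
#' @param mat a `synchrony_matrix` (or plain correlation matrix with labels).
#' @param groups named character/factor vector mapping cell label to group.
#' @return list with `within_mean`, `between_mean`, `n_within`, `n_between`,
#'   `n_undefined`.
#' @export
synchrony_summary <- function(mat, groups) {
  labs <- rownames(mat)
  check_that(!is.null(labs) && all(labs %in% names(groups)),
             "groups must name every cell in the matrix")
  g <- as.character(groups[labs])
  n <- nrow(mat)
  within <- c(); between <- c(); n_undef <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- mat[i, j]
    if (is.na(r)) { n_undef <- n_undef + 1L; next }
    if (g[i] == g[j]) within <- c(within, r) else between <- c(between, r)
  }
  check_that(length(within) >= 1, "no defined within-group pairs")
  list(within_mean = mean(within),
       between_mean = if (length(between)) mean(between) else NA_real_,
       n_within = length(within), n_between = length(between),
       n_undefined = n_undef)
}

#' Write a synchrony matrix as labeled CSV
#'
#' @param mat a `synchrony_matrix`.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_synchrony <- function(mat, path) {
  utils::write.csv(as.data.frame(unclass(mat)), path, row.names = TRUE)
  invisible(path)
}
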