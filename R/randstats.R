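#' Mean absolute difference between two amino-acid matrices
#'
#' Sums the absolute cellwise differences over the 380 informative
#' (off-diagonal) grid positions and divides by 380. This is the package's
#' matrix-level distance: 0 exactly when the matrices agree on every
#' informative cell, 1 when they differ by the full unit range everywhere.
#'
#' @param a,b 20 x 20 numeric matrices on the same label order.
#' @param check_labels If `TRUE` (default), require identical dimnames.
#'   Row-randomized matrices carry permuted row labels, so the randomization
#'   machinery compares by grid position with `check_labels = FALSE`.
#' @return A single number in `[0, 1]`.
#' @export
matrix_distance <- function(a, b, check_labels = TRUE) {
  stopifnot(is.matrix(a), is.matrix(b),
            identical(dim(a), c(20L, 20L)), identical(dim(b), c(20L, 20L)))
  if (check_labels &&
      (!identical(rownames(a), rownames(b)) ||
       !identical(colnames(a), colnames(b)))) {
    stop("matrix labels do not match", call. = FALSE)
  }
  mask <- offdiag_mask()
  sum(abs(unclass(a)[mask] - unclass(b)[mask])) / N_INFORMATIVE_CELLS
}

#' Permute the row order of a matrix
#'
#' Row `i` of the output is row `permutation[i]` of the input; columns are
#' untouched, so the output is in general asymmetric. Row labels travel with
#' their rows; column labels stay.
#'
#' @param m A matrix.
#' @param permutation A permutation (bijection) of `1:nrow(m)`.
#' @return The row-permuted matrix.
#' @export
row_randomize <- function(m, permutation) {
  stopifnot(is.matrix(m))
  permutation <- as.integer(permutation)
  if (length(permutation) != nrow(m) ||
      !identical(sort(permutation), seq_len(nrow(m)))) {
    stop("`permutation` must be a bijection of the row indices",
         call. = FALSE)
  }
  unclass(m)[permutation, , drop = FALSE]
}

# Precompute the 20 x 20 placement-cost matrix C with
# C[g, i] = sum over columns j != g of |fixed[g, j] - shuffled[i, j]|,
# so the distance under a row permutation pi is sum_g C[g, pi(g)] / 380.
# Diagonal grid positions are excluded by the j != g restriction, matching
# the 380-cell convention even though permutation moves informative values
# onto the diagonal.
placement_cost <- function(fixed, shuffled) {
  fixed <- unclass(fixed); shuffled <- unclass(shuffled)
  n <- nrow(fixed)
  C <- matrix(0, n, n)
  for (g in seq_len(n)) {
    cols <- setdiff(seq_len(n), g)
    diffs <- abs(sweep(shuffled[, cols, drop = FALSE], 2L,
                       fixed[g, cols], `-`))
    C[g, ] <- rowSums(diffs)
  }
  C
}

#' Row-order randomization test of matrix agreement
#'
#' Measures whether two 20 x 20 amino-acid distance matrices agree more than
#' expected by chance, with a conservative Mantel-style null: only the row
#' order of one matrix is permuted (columns keep their structure), `n`
#' uniform permutations of the 20 rows are drawn (with replacement from all
#' 20! orderings, so the identity can recur), and the matrix distance to the
#' fixed matrix is recorded for each. The empirical p-value uses the add-one
#' estimator (1 + count of null samples at or below the observed distance)
#' divided by (n + 1), so it is never exactly 0.
#'
#' @param fixed Matrix held fixed.
#' @param shuffled Matrix whose rows are permuted.
#' @param n Number of random permutations (>= 1).
#' @param seed Integer seed; the full sample sequence is reproducible.
#' @param mode Free-text tag recording which matrix was randomized (stored
#'   in the report).
#' @param keep_samples If `TRUE`, attach the vector of null distances.
#' @return Object of class `randomization_report`: a list with `observed`,
#'   `null_mean`, `null_min`, `null_max`, `p_value`, `n`, `seed`, `mode`,
#'   and optionally `samples`.
#' @export
randomization_test <- function(fixed, shuffled, n, seed,
                               mode = "rows_of_second", keep_samples = FALSE) {
  if (!is.numeric(n) || n < 1L) stop("`n` must be >= 1", call. = FALSE)
  n <- as.integer(n)
  observed <- matrix_distance(fixed, shuffled, check_labels = FALSE)
  C <- placement_cost(fixed, shuffled)
  samples <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      p <- sample.int(20L)
      sum(C[cbind(seq_len(20L), p)])
    }, numeric(1))
  }) / N_INFORMATIVE_CELLS
  report <- list(
    observed = observed,
    null_mean = mean(samples),
    null_min = min(samples),
    null_max = max(samples),
    p_value = (1 + sum(samples <= observed)) / (n + 1),
    n = n,
    seed = as.integer(seed),
    mode = mode
  )
  if (keep_samples) report$samples <- samples
  structure(report, class = "randomization_report")
}

#' @export
print.randomization_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<randomization_report> mode=%s n=%d seed=%d\n",
    "  observed distance: %.4f\n",
    "  null mean/min/max: %.4f / %.4f / %.4f\n",
    "  empirical p-value: %.3g\n"),
    x$mode, x$n, x$seed, x$observed,
    x$null_mean, x$null_min, x$null_max, x$p_value))
  invisible(x)
}

#' Principal components analysis of an alphabet similarity matrix
#'
#' Treats each alphabet's row of pairwise similarities as its feature
#' vector: columns are mean-centered (no variance scaling) and the
#' covariance matrix is eigendecomposed. If every row is identical the
#' total variance is 0 and the variance fractions are undefined (`NaN`),
#' reported distinctly via the `total_variance` field.
#'
#' @param s An `alphabet_similarity` matrix (n >= 3 alphabets), or any
#'   numeric matrix with observations in rows.
#' @return Object of class `alphabet_pca`: list with `variance_fractions`
#'   (non-increasing, summing to 1 when total variance is positive),
#'   `scores` (one row per alphabet), `sdev` and `total_variance`.
#' @export
alphabet_pca <- function(s) {
  stopifnot(is.matrix(s))
  if (nrow(s) < 3L) stop("need at least 3 alphabets", call. = FALSE)
  x <- unclass(s)
  centered <- scale(x, center = TRUE, scale = FALSE)
  total_var <- sum(centered^2) / (nrow(x) - 1L)
  if (total_var <= 0) {
    return(structure(list(
      variance_fractions = rep(NaN, min(dim(x))),
      scores = centered[, integer(0), drop = FALSE],
      sdev = rep(0, min(dim(x))),
      total_variance = 0
    ), class = "alphabet_pca"))
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  structure(list(
    variance_fractions = p$sdev^2 / sum(p$sdev^2),
    scores = p$x,
    sdev = p$sdev,
    total_variance = total_var
  ), class = "alphabet_pca")
}

#' @export
print.alphabet_pca <- function(x, ...) {
  if (x$total_variance == 0) {
    cat("<alphabet_pca> degenerate input: total variance 0\n")
  } else {
    vf <- x$variance_fractions
    cat(sprintf(
      "<alphabet_pca> %d alphabets; PC1 %.1f%%, PC2 %.1f%% (PC1+PC2 %.1f%%)\n",
      nrow(x$scores), 100 * vf[1], 100 * vf[2], 100 * sum(vf[1:2])))
  }
  invisible(x)
}

#' Serialize a randomization report to JSON
#'
#' @param report A `randomization_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_randomization_report <- function(report, path) {
  stopifnot(inherits(report, "randomization_report"))
  keep <- c("observed", "null_mean", "null_min", "null_max",
            "p_value", "n", "seed", "mode")
  jsonlite::write_json(report[keep], path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
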