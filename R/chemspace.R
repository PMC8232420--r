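# Descriptor-matrix hygiene before chemical-space PCA: drop near-zero
# variance columns, then exact linear combinations, then mean-centered PCA
# with a fixed sign convention.

#' Near-zero-variance descriptor filter
#'
#' Drops constant columns, and columns that are simultaneously dominated
#' by one value (most-frequent / second-most-frequent count ratio above
#' `freq_ratio_max`) and nearly discrete (percent distinct values below
#' `unique_pct_min`). Defaults are the conventional 95/5 -> 19 ratio and
#' 10 percent distinct.
#'
#' @param X numeric matrix/data.frame with named columns, >= 2 rows.
#' @param freq_ratio_max frequency-ratio cutoff.
#' @param unique_pct_min percent-distinct cutoff.
#' @return list with `kept` and `dropped` (named character vector: column
#'   -> rule that dropped it).
#' @export
near_zero_variance_filter <- function(X, freq_ratio_max = 19,
                                      unique_pct_min = 10) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  dropped <- character(0)
  keep <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    tab <- sort(table(X[, j]), decreasing = TRUE)
    if (length(tab) == 1L) {
      dropped[colnames(X)[j]] <- "constant"
      next
    }
    freq_ratio <- as.numeric(tab[1]) / as.numeric(tab[2])
    unique_pct <- 100 * length(tab) / nrow(X)
    if (freq_ratio > freq_ratio_max && unique_pct < unique_pct_min) {
      dropped[colnames(X)[j]] <- sprintf(
        "near-zero variance (freq ratio %.3g, unique %.3g%%)",
        freq_ratio, unique_pct)
    } else keep[j] <- TRUE
  }
  list(kept = colnames(X)[keep], dropped = dropped)
}

#' Exact linear-combination filter
#'
#' Scans columns left to right and removes each column that is an exact
#' linear combination (within a relative tolerance) of the columns kept so
#' far, so the remaining matrix has full column rank. A duplicated column
#' loses its later copy.
#'
#' @param X numeric matrix/data.frame, typically post-NZV.
#' @param tol relative tolerance for the rank decision.
#' @return list with `kept` and `dropped` (named: column -> message).
#' @export
linear_combination_filter <- function(X, tol = 1e-8) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  kept <- integer(0)
  dropped <- character(0)
  Q <- matrix(numeric(0), nrow = nrow(X), ncol = 0)   # orthonormal basis
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    scale <- sqrt(sum(v^2))
    r <- v - Q %*% crossprod(Q, v)
    r <- r - Q %*% crossprod(Q, r)      # second pass for stability
    if (sqrt(sum(r^2)) <= tol * max(scale, 1)) {
      dropped[colnames(X)[j]] <- "linear combination of earlier columns"
    } else {
      kept <- c(kept, j)
      Q <- cbind(Q, r / sqrt(sum(r^2)))
    }
  }
  list(kept = colnames(X)[kept], dropped = dropped)
}

#' PCA of a filtered descriptor matrix
#'
#' Mean-centered (no variance scaling by default, matching the R
#' convention the analysis follows), via singular value decomposition.
#' Component signs are fixed by making the largest-magnitude entry of each
#' loading vector positive, so results are deterministic across platforms.
#'
#' @param X numeric matrix/data.frame (filtered).
#' @param n_components number of score columns to return.
#' @param scale. also scale columns to unit variance.
#' @return object of class `pca_result`: list with `scores`, `loadings`,
#'   `explained` (variance fractions over all components), `center`,
#'   `scale`.
#' @export
pca_scores <- function(X, n_components = 3L, scale. = FALSE) {
  X <- as.matrix(X)
  if (n_components > min(nrow(X), ncol(X)))
    stop("n_components exceeds min(n_samples, n_features)")
  pr <- stats::prcomp(X, center = TRUE, scale. = scale.)
  flip <- apply(pr$rotation, 2, function(v) {
    s <- sign(v[which.max(abs(v))]); if (s == 0) 1 else s
  })
  rot <- sweep(pr$rotation, 2, flip, "*")
  scores <- sweep(pr$x, 2, flip, "*")
  expl <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(
    scores = scores[, seq_len(n_components), drop = FALSE],
    loadings = rot[, seq_len(n_components), drop = FALSE],
    explained = expl,
    center = pr$center,
    scale = if (isTRUE(scale.)) pr$scale else FALSE
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- ncol(x$scores)
  cat("<pca_result>", nrow(x$scores), "samples,", k, "components;",
      "explained:", paste(sprintf("%.1f%%", 100 * x$explained[seq_len(k)]),
                          collapse = " "), "\n")
  invisible(x)
}

#' Run the full descriptor filter + PCA chain
#'
#' Convenience wrapper: near-zero-variance filter, linear-combination
#' filter, then PCA. The filter decisions are returned as a log.
#'
#' @inheritParams pca_scores
#' @param freq_ratio_max,unique_pct_min see [near_zero_variance_filter()].
#' @return list with `pca` (`pca_result`), `kept`, and `log` (named
#'   character vector of dropped columns -> rule).
#' @export
chemspace_pipeline <- function(X, n_components = 3L, scale. = FALSE,
                               freq_ratio_max = 19, unique_pct_min = 10) {
  X <- as.matrix(X)
  nzv <- near_zero_variance_filter(X, freq_ratio_max, unique_pct_min)
  X1 <- X[, nzv$kept, drop = FALSE]
  lcf <- linear_combination_filter(X1)
  X2 <- X1[, lcf$kept, drop = FALSE]
  list(pca = pca_scores(X2, n_components = min(n_components, ncol(X2)),
                        scale. = scale.),
       kept = lcf$kept,
       log = c(nzv$dropped, lcf$dropped))
}
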