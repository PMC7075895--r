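# Group-level inference: paired Wilcoxon signed-rank tests with
# Benjamini-Hochberg FDR control, shrinkage-regularized partial
# correlations, and a low-dimensional embedding of condition-wise
# correlation structure.

#' Paired Wilcoxon signed-rank tests per feature
#'
#' Two-sided paired Wilcoxon signed-rank test for every feature between
#' two conditions of one task. Zero differences are dropped (the classic
#' signed-rank convention); the exact null distribution is used for n <=
#' 25 non-zero pairs without ties, the normal approximation with
#' continuity correction otherwise. A feature whose differences are all
#' zero is reported with p = 1 and flagged degenerate.
#'
#' @param table feature table (imputed).
#' @param condition_a,condition_b condition labels (differences are
#'   condition_a minus condition_b).
#' @param task task label.
#' @return data.frame: `feature`, `statistic` (V), `n_pairs` (non-zero),
#'   `median_diff`, `p_value`, `degenerate`.
#' @export
wilcoxon_paired <- function(table, condition_a, condition_b, task) {
  fc <- feature_columns(table)
  tt <- table[table$task == task, ]
  ra <- tt[tt$condition == condition_a, ]
  rb <- tt[tt$condition == condition_b, ]
  common <- intersect(ra$subject_id, rb$subject_id)
  if (length(common) < 2)
    stop("need at least 2 subjects with both conditions", call. = FALSE)
  ra <- ra[match(common, ra$subject_id), ]
  rb <- rb[match(common, rb$subject_id), ]
  out <- lapply(fc, function(f) {
    d <- ra[[f]] - rb[[f]]
    nz <- d[d != 0]
    if (length(nz) == 0)
      return(data.frame(feature = f, statistic = NA_real_, n_pairs = 0L,
                        median_diff = 0, p_value = 1, degenerate = TRUE))
    wt <- suppressWarnings(stats::wilcox.test(
      nz, mu = 0, exact = length(nz) <= 25, correct = TRUE))
    data.frame(feature = f, statistic = unname(wt$statistic),
               n_pairs = length(nz), median_diff = stats::median(d),
               p_value = wt$p.value, degenerate = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up BH procedure: with p-values sorted ascending, the largest k
#' with p_(k) <= k q / m determines the rejections; equivalently a
#' hypothesis is rejected iff its BH-adjusted p-value is at most q.
#'
#' @param p numeric p-values in \[0, 1\].
#' @param q target false-discovery rate.
#' @return data.frame `p`, `adjusted`, `reject` in the input order.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adj <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, adjusted = adj, reject = adj <= q)
}

# Schafer-Strimmer-style analytic shrinkage intensity toward the
# diagonal target: lambda* = sum Var(s_ij) / sum s_ij^2 over i != j,
# clamped to [0, 1], with Var(s_ij) estimated from the centered
# cross-product terms.
shrinkage_intensity <- function(X) {
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(Xc) / (n - 1)
  num <- 0; den <- 0
  p <- ncol(X)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    w <- Xc[, i] * Xc[, j]
    v <- n / ((n - 1)^3) * sum((w - mean(w))^2)
    num <- num + v
    den <- den + S[i, j]^2
  }
  if (den <= 0) return(1)
  min(1, max(0, num / den))
}

#' Shrinkage-regularized partial correlations
#'
#' Estimates the partial-correlation matrix from the inverse of a shrunk
#' covariance Sigma* = (1 - lambda) S + lambda diag(S): rho_ij =
#' -Theta_ij / sqrt(Theta_ii Theta_jj) with Theta = (Sigma*)^-1. The
#' shrinkage intensity defaults to an analytic estimate; lambda = 0 is
#' the sample covariance (singular when n <= p) and lambda = 1 gives zero
#' off-diagonal partials.
#'
#' @param data numeric matrix, rows = observations, columns = features.
#' @param lambda shrinkage in \[0, 1\], or NULL for the analytic estimate.
#' @return partial-correlation matrix with unit diagonal; the intensity
#'   used is attached as attribute `lambda`.
#' @export
partial_correlations <- function(data, lambda = NULL) {
  X <- as.matrix(data)
  if (nrow(X) < 3) stop("need at least 3 observations", call. = FALSE)
  if (is.null(lambda)) lambda <- shrinkage_intensity(X)
  stopifnot(lambda >= 0, lambda <= 1)
  S <- stats::cov(X)
  Sstar <- (1 - lambda) * S + lambda * diag(diag(S), ncol(S))
  Theta <- tryCatch(solve(Sstar), error = function(e)
    stop("shrunk covariance is singular (n <= p with lambda = 0); ",
         "use lambda > 0", call. = FALSE))
  d <- sqrt(diag(Theta))
  R <- -Theta / tcrossprod(d)
  diag(R) <- 1
  dimnames(R) <- list(colnames(X), colnames(X))
  attr(R, "lambda") <- lambda
  R
}

#' Embed correlation matrices by classical multidimensional scaling
#'
#' Represents each input matrix (e.g. one partial-correlation matrix per
#' condition) as a point in a low-dimensional space via classical MDS on
#' pairwise Frobenius distances. Matrices must share their feature sets;
#' identical matrices map to coincident points. Axis signs from an
#' eigendecomposition are arbitrary, so each coordinate axis is flipped to
#' make its largest-magnitude entry positive, giving a deterministic
#' orientation.
#'
#' @param matrices named list of >= 3 square matrices with identical
#'   dimnames.
#' @param k embedding dimension (default 2, capped at n - 1).
#' @return list of class `sc_mds`: `points` (n x k coordinates),
#'   `distances` (Frobenius distance matrix), `stress` (residual
#'   sum-of-squares fraction of the distance matrix not captured).
#' @export
mds_embed <- function(matrices, k = 2) {
  n <- length(matrices)
  if (n < 3) stop("need at least 3 matrices to embed", call. = FALSE)
  nms <- names(matrices) %||% paste0("M", seq_len(n))
  ref <- dimnames(matrices[[1]])
  for (m in matrices) {
    if (!is.matrix(m) || nrow(m) != ncol(m))
      stop("all inputs must be square matrices", call. = FALSE)
    if (!identical(dimnames(m), ref))
      stop("matrices must share identical feature sets (dimnames)",
           call. = FALSE)
  }
  D <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- sqrt(sum((matrices[[i]] - matrices[[j]])^2))
  k <- min(k, n - 1)
  fit <- stats::cmdscale(D, k = k, eig = TRUE)
  pts <- fit$points
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1)
  # pad with zero columns when the configuration is lower-rank than k
  if (ncol(pts) < k)
    pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  for (j in seq_len(ncol(pts))) {
    i_max <- which.max(abs(pts[, j]))
    if (pts[i_max, j] < 0) pts[, j] <- -pts[, j]
  }
  dimnames(pts) <- list(nms, paste0("dim", seq_len(ncol(pts))))
  Dhat <- as.matrix(stats::dist(pts))
  stress <- if (sum(D^2) > 0) sum((D - Dhat)^2) / sum(D^2) else 0
  structure(list(points = pts, distances = D, stress = stress),
            class = "sc_mds")
}
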