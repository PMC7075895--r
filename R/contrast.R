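# Within-subject paired-contrast construction, standardization, and
# t-test feature ranking.

#' Standardization parameters from training rows
#'
#' Per-column mean and (n-1)-denominator standard deviation; zero-variance
#' columns are flagged for dropping within the fold that produced them.
#'
#' @param X numeric matrix (training rows).
#' @return list `mean`, `sd`, `keep` (logical, sd > 0).
#' @export
standardize_fit <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  s <- sqrt(pmax(colSums(X^2) - n * m^2, 0) / (n - 1))
  list(mean = m, sd = s, keep = s > 0)
}

#' @rdname standardize_fit
#' @param params from `standardize_fit` (training rows only — test rows are
#'   always transformed with training parameters).
#' @export
standardize_apply <- function(params, X) {
  Z <- sweep(sweep(X, 2, params$mean), 2, pmax(params$sd, 1e-300), "/")
  Z[, params$keep, drop = FALSE]
}

#' Standardize the feature columns of a table
#'
#' Convenience whole-table z-transform (mean 0, sd 1 per column). Inside
#' cross-validation the fold-wise [standardize_fit()]/[standardize_apply()]
#' pair is used instead so that no test information leaks into the
#' transform.
#'
#' @param table feature table.
#' @return table with standardized feature columns; zero-variance columns
#'   dropped (named in attribute `dropped`).
#' @export
standardize <- function(table) {
  stopifnot(nrow(table) >= 2)
  fc <- feature_columns(table)
  X <- as.matrix(table[fc])
  p <- standardize_fit(X)
  Z <- standardize_apply(p, X)
  out <- cbind(table[key_columns()], as.data.frame(Z))
  attr(out, "dropped") <- fc[!p$keep]
  attr(out, "params") <- p
  out
}

#' Build within-subject paired-contrast samples
#'
#' For every subject holding both condition rows for the task, emits the
#' signed difference d = x_A - x_B with label +1 and its negation with
#' label -1: classifying condition A vs B is the same problem as
#' classifying (A - B) vs (B - A), and the subtraction removes each
#' speaker's baseline.
#'
#' @param table feature table (imputed).
#' @param condition_a,condition_b condition labels.
#' @param task task label.
#' @return list of class `sc_contrasts`: `X` (2n x p matrix), `y` (+1/-1),
#'   `subject` (length 2n), `features` (colnames), `excluded` (subjects
#'   missing a condition).
#' @export
make_contrasts <- function(table, condition_a, condition_b, task) {
  fc <- feature_columns(table)
  tt <- table[table$task == task, ]
  subs <- sort(unique(tt$subject_id))
  X <- NULL
  y <- integer(0)
  subject <- character(0)
  excluded <- character(0)
  for (s in subs) {
    ra <- tt[tt$subject_id == s & tt$condition == condition_a, fc]
    rb <- tt[tt$subject_id == s & tt$condition == condition_b, fc]
    if (nrow(ra) != 1 || nrow(rb) != 1) {
      excluded <- c(excluded, s)
      warning("subject ", s, " excluded from contrast ", condition_a, ":",
              condition_b, " (missing condition row)", call. = FALSE)
      next
    }
    d <- as.numeric(ra) - as.numeric(rb)
    X <- rbind(X, d, -d)
    y <- c(y, 1L, -1L)
    subject <- c(subject, s, s)
  }
  if (is.null(X)) stop("no subject has both conditions for task ", task,
                       call. = FALSE)
  dimnames(X) <- list(NULL, fc)
  structure(list(X = X, y = y, subject = subject, features = fc,
                 condition_a = condition_a, condition_b = condition_b,
                 task = task, excluded = excluded),
            class = "sc_contrasts")
}

#' Rank features by two-sample t-test between contrast classes
#'
#' Features are ordered by ascending Welch t-test p-value between the +1
#' and -1 samples of the training set; ties break by feature-name
#' lexicographic order.
#'
#' @param X training sample matrix (columns = features).
#' @param y +1/-1 labels.
#' @return integer ordering of columns (best first), with the p-values as
#'   attribute `p`.
#' @export
rank_features <- function(X, y) {
  stopifnot(length(unique(y)) == 2)
  A <- X[y > 0, , drop = FALSE]
  B <- X[y < 0, , drop = FALSE]
  na <- nrow(A); nb <- nrow(B)
  col_var <- function(M) {
    mm <- colMeans(M)
    pmax(colSums(M^2) - nrow(M) * mm^2, 0) / (nrow(M) - 1)
  }
  va <- col_var(A) / na
  vb <- col_var(B) / nb
  tstat <- (colMeans(A) - colMeans(B)) / sqrt(pmax(va + vb, 1e-300))
  df <- (va + vb)^2 / pmax(va^2 / (na - 1) + vb^2 / (nb - 1), 1e-300)
  # a feature constant within both classes carries no evidence: t = 0,
  # df = 0 would make pt() warn, so give it a proper df and p = 1
  df[va + vb <= 0] <- 1
  p <- 2 * stats::pt(-abs(tstat), df)
  nm <- colnames(X) %||% as.character(seq_len(ncol(X)))
  ord <- order(p, nm)
  attr(ord, "p") <- p
  ord
}
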