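#' Intraclass correlation: two-way, absolute agreement
#'
#' ICC for a complete subjects x raters matrix under the two-way
#' (mixed-effects) model with absolute agreement, in both the single-rating
#' ICC(A,1) and the mean-rating ICC(A,k) form used for inter-observer
#' reliability. From the ANOVA decomposition with row (subject), column
#' (rater) and error mean squares,
#' `ICC(A,k) = (MSR - MSE) / (MSR + (MSC - MSE)/n)`.
#' The F test of no subject effect uses `F = MSR/MSE` with `(n-1)` and
#' `(n-1)(k-1)` degrees of freedom; the 95% confidence bounds follow the
#' standard F-distribution (Satterthwaite) derivation for absolute-agreement
#' coefficients, transformed to the mean-rating scale.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns, no
#'   missing cells.
#' @param conf Confidence level for the interval.
#' @return List with `icc` (A,k), `icc_single` (A,1), `F`, `df1`, `df2`,
#'   `p`, `ci95` (length-2 vector for the mean-rating ICC), and the mean
#'   squares.
#' @export
icc_absolute_agreement <- function(ratings, conf = 0.95) {
  m <- as.matrix(ratings)
  if (any(is.na(m))) stop("ratings matrix must have no missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  grand <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  MSR <- k * sum((rowm - grand)^2) / (n - 1)
  MSC <- n * sum((colm - grand)^2) / (k - 1)
  SSE <- sum((m - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR == 0) {
    warning("zero between-subject variance: ICC undefined")
    return(list(icc = NA_real_, icc_single = NA_real_, F = NA_real_,
                df1 = n - 1, df2 = (n - 1) * (k - 1), p = NA_real_,
                ci95 = c(NA_real_, NA_real_),
                ms = c(MSR = MSR, MSC = MSC, MSE = MSE)))
  }
  icc_k <- (MSR - MSE) / (MSR + (MSC - MSE) / n)
  icc_1 <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  Fstat <- if (MSE > 0) MSR / MSE else Inf
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  # Satterthwaite df for the CI of ICC(A,1), then Spearman-Brown to (A,k)
  alpha <- 1 - conf
  r <- icc_1
  if (MSE > 0 && r < 1) {
    a <- k * r / (n * (1 - r))
    b <- 1 + k * r * (n - 1) / (n * (1 - r))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    F1 <- qf(1 - alpha / 2, n - 1, v)
    F2 <- qf(1 - alpha / 2, v, n - 1)
    lo1 <- n * (MSR - F1 * MSE) /
      (F1 * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    up1 <- n * (F2 * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * F2 * MSR)
    sb <- function(r1) k * r1 / (1 + (k - 1) * r1)
    ci <- c(sb(lo1), sb(up1))
  } else {
    ci <- c(1, 1)
  }
  list(icc = icc_k, icc_single = icc_1, F = Fstat, df1 = df1, df2 = df2,
       p = p, ci95 = ci, ms = c(MSR = MSR, MSC = MSC, MSE = MSE))
}
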