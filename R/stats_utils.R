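#' Spearman rank correlation with degrees of freedom and t-approximation p
#'
#' Rank correlation computed as the Pearson correlation of average ranks
#' (midranks for ties), with `df = n - 2` and a two-sided p-value from the
#' t approximation `t = r * sqrt(df / (1 - r^2))`. Pairs with missing values
#' are dropped. A constant input vector has no defined rank correlation and
#' yields `r = NA` rather than an error, so callers can report the entry as
#' undefined.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `df`, `p`, `n`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  df <- n - 2L
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(r = NA_real_, df = df, p = NA_real_, n = n))
  }
  r <- stats::cor(rank(x), rank(y))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df)
  }
  list(r = r, df = df, p = p, n = n)
}

#' Welch two-sample t-test from first principles
#'
#' Direct evaluation of the Welch statistic and Satterthwaite degrees of
#' freedom. When both groups have zero variance the standard error is floored
#' at a machine-epsilon scale so that a planted mean difference still yields
#' a finite, very large statistic instead of 0/0.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @keywords internal
welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("both groups need at least 2 observations")
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  sa2 <- va / na; sb2 <- vb / nb
  se2 <- sa2 + sb2
  if (se2 == 0) {
    se2 <- .Machine$double.eps * (abs(ma) + abs(mb) + 1)^2
    df <- na + nb - 2
  } else {
    df <- se2^2 / (sa2^2 / (na - 1) + sb2^2 / (nb - 1))
  }
  tval <- (ma - mb) / sqrt(se2)
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
       mean_a = ma, mean_b = mb)
}
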