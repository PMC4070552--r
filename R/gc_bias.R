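#' Regress windowed coverage on GC content
#'
#' Ordinary least squares of window mean coverage on window GC fraction
#' (degree 1) or on GC and GC squared (degree 2). The AIC uses the Gaussian
#' profile form `n * log(RSS/n) + 2 * (degree + 2)`, counting the residual
#' variance as a parameter; the RSS is floored at
#' `machine_eps * n * var(y)` so that noiseless fixtures stay finite.
#' For degree 2 the stationary point of the fitted parabola is reported as
#' `vertex_gc = -b1 / (2 * b2)`.
#'
#' @param table a window table from [window_profile()] (columns `gc`,
#'   `mean_cov`).
#' @param degree 1 (linear) or 2 (quadratic).
#' @return object of class `gc_fit`: list with `degree`, `coefficients`,
#'   `F`, `R2`, `df`, `p`, `aic`, `rss`, `n`, and `vertex_gc` (degree 2).
#' @export
fit_gc_regression <- function(table, degree = 1L) {
  stopifnot(degree %in% c(1L, 2L))
  gc <- table$gc; y <- table$mean_cov
  keep <- is.finite(gc) & is.finite(y)
  gc <- gc[keep]; y <- y[keep]
  n <- length(y)
  if (n <= degree + 1L) stop("need more than ", degree + 1L, " windows")
  if (length(unique(gc)) < degree + 1L) stop("gc is (nearly) constant; cannot fit")
  fit <- if (degree == 1L) stats::lm(y ~ gc) else stats::lm(y ~ gc + I(gc^2))
  sm <- summary(fit)
  rss <- sum(stats::residuals(fit)^2)
  rss_floor <- max(rss, .Machine$double.eps * n * stats::var(y))
  aic <- n * log(rss_floor / n) + 2 * (degree + 2)
  co <- stats::coef(fit)
  out <- list(
    degree = degree,
    coefficients = co,
    F = unname(sm$fstatistic["value"]),
    R2 = sm$r.squared,
    df = n - (degree + 1L),
    p = stats::pf(sm$fstatistic["value"], sm$fstatistic["numdf"],
                  sm$fstatistic["dendf"], lower.tail = FALSE),
    aic = aic, rss = rss, n = n
  )
  if (degree == 2L) {
    b2 <- unname(co[3L])
    out$vertex_gc <- if (b2 != 0) -unname(co[2L]) / (2 * b2) else NA_real_
  }
  structure(out, class = "gc_fit")
}

#' @export
print.gc_fit <- function(x, ...) {
  cat(sprintf("GC regression (degree %d): F = %.2f, R2 = %.3f, df = %d, AIC = %.1f\n",
              x$degree, x$F, x$R2, x$df, x$aic))
  if (!is.null(x$vertex_gc)) cat(sprintf("  vertex at GC = %.3f\n", x$vertex_gc))
  invisible(x)
}

#' AIC comparison of the linear and quadratic GC fits
#'
#' @param fit_lin,fit_quad `gc_fit` objects fitted to the same windows.
#' @return `aic(quad) - aic(lin)`; negative values favour the quadratic.
#' @export
compare_models_aic <- function(fit_lin, fit_quad) {
  if (fit_lin$n != fit_quad$n) {
    stop("fits are based on different numbers of windows (",
         fit_lin$n, " vs ", fit_quad$n, ")")
  }
  fit_quad$aic - fit_lin$aic
}

#' Welch t-test of per-site coverage, A/T sites versus G/C sites
#'
#' Sites are grouped by their (consensus) base identity; `N` sites are
#' excluded. The sign convention is `t > 0` when A/T coverage exceeds G/C
#' coverage. Welch's unequal-variance form is used, giving fractional
#' Satterthwaite degrees of freedom.
#'
#' @param coverage per-site coverage.
#' @param sequence per-site base identity (string or base vector).
#' @return list with `t`, `df`, `p`, `mean_AT`, `mean_GC`, `n_AT`, `n_GC`.
#' @export
at_gc_coverage_ttest <- function(coverage, sequence) {
  bases <- as_base_vector(sequence)
  if (length(bases) != length(coverage)) stop("sequence and coverage lengths differ")
  at <- coverage[bases %in% c("A", "T")]
  gc <- coverage[bases %in% c("G", "C")]
  if (length(at) < 2L || length(gc) < 2L) {
    stop("both base groups need at least 2 sites")
  }
  w <- welch_t(at, gc)
  list(t = w$t, df = w$df, p = w$p, mean_AT = w$mean_a, mean_GC = w$mean_b,
       n_AT = length(at), n_GC = length(gc))
}

#' Site-level ANCOVA of coverage on base identity, gene type and local GC
#'
#' Fits `coverage ~ base + gene_type + gc50` by OLS with treatment-coded
#' categorical terms and reports per-term F statistics from Type II sums of
#' squares (each term adjusted for the others, no interactions). The
#' reference level of each factor is stated in the output so the coefficient
#' table is interpretable.
#'
#' @param coverage per-site coverage.
#' @param base per-site base identity (A/C/G/T; N sites dropped).
#' @param gene_type per-site gene-type class.
#' @param gc50 per-site GC fraction of the surrounding window
#'   (see [gc_by_site()]).
#' @return list with `anova` (per-term F table), `coefficients`,
#'   `reference_levels`, `n`.
#' @export
site_ancova <- function(coverage, base, gene_type, gc50) {
  bases <- as_base_vector(base)
  dat <- data.frame(coverage = coverage, base = bases,
                    gene_type = as.character(gene_type), gc50 = gc50,
                    stringsAsFactors = FALSE)
  dat <- dat[dat$base %in% c("A", "C", "G", "T") & is.finite(dat$gc50), ]
  for (term in c("base", "gene_type")) {
    if (length(unique(dat[[term]])) < 2L) {
      stop("categorical term '", term, "' has fewer than 2 levels")
    }
  }
  if (length(unique(dat$gc50)) < 2L) stop("term 'gc50' is constant")
  dat$base <- factor(dat$base)
  dat$gene_type <- factor(dat$gene_type)
  fit <- stats::lm(coverage ~ base + gene_type + gc50, data = dat)
  aov2 <- car::Anova(fit, type = 2)
  list(anova = aov2,
       coefficients = summary(fit)$coefficients,
       reference_levels = c(base = levels(dat$base)[1L],
                            gene_type = levels(dat$gene_type)[1L]),
       n = nrow(dat))
}
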