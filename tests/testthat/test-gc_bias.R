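test_that("exact fixtures are fitted exactly", {
  lin <- fit_gc_regression(data.frame(gc = c(0.2, 0.4, 0.6),
                                      mean_cov = c(10, 20, 30)), 1L)
  expect_equal(unname(lin$coefficients[2]), 50)
  expect_equal(lin$R2, 1)
  expect_equal(lin$rss, 0, tolerance = 1e-20)

  # y = (10 gc)^2: curvature 100, stationary point at gc = 0
  quad <- fit_gc_regression(data.frame(gc = seq(0.1, 0.5, 0.1),
                                       mean_cov = c(1, 4, 9, 16, 25)), 2L)
  expect_equal(unname(quad$coefficients[3]), 100)
  expect_equal(quad$vertex_gc, 0, tolerance = 1e-9)
  expect_equal(quad$R2, 1)
  expect_equal(quad$df, 2L)

  expect_error(fit_gc_regression(data.frame(gc = rep(0.4, 10),
                                            mean_cov = rnorm(10)), 1L),
               "constant")
  expect_error(fit_gc_regression(data.frame(gc = c(0.1, 0.2),
                                            mean_cov = c(1, 2)), 2L), "windows")
})

test_that("the generator's quadratic GC model is recovered from windows", {
  # window GC centered on the vertex so the stationary point is identifiable
  cfg <- sim_config(seed = 202, L_ref = 15050, gc_target = 0.27,
                    n_individuals = 1, n_motifs = 0, n_heteroplasmic = 0)
  sim <- simulate_site_profiles(generate_reference(cfg), cfg)
  cons <- sim$profiles$ref
  wins <- window_profile(cons, sim$profiles$depth, 50, 50)
  expect_gte(nrow(wins), 300)
  fit <- fit_gc_regression(wins, 2L)
  expect_lt(abs(fit$vertex_gc - cfg$vertex_gc), 0.03)
})

test_that("AIC comparison penalises the unneeded quadratic term by 2", {
  tab <- data.frame(gc = seq(0.2, 0.6, length.out = 40))
  tab$mean_cov <- 5 + 10 * tab$gc  # noiseless line: RSS floor engages
  d <- compare_models_aic(fit_gc_regression(tab, 1L), fit_gc_regression(tab, 2L))
  expect_equal(d, 2)

  tab$mean_cov <- (10 * tab$gc)^2  # noiseless parabola
  expect_lt(compare_models_aic(fit_gc_regression(tab, 1L),
                               fit_gc_regression(tab, 2L)), -50)

  f <- fit_gc_regression(tab, 2L)
  expect_equal(f$aic - f$aic, 0)
  f1 <- fit_gc_regression(tab[1:30, ], 1L)
  expect_error(compare_models_aic(f1, f), "different numbers")
})

test_that("quadratic RSS never exceeds linear RSS on the same windows", {
  set.seed(55)
  for (i in 1:15) {
    tab <- data.frame(gc = runif(30, 0.2, 0.6))
    tab$mean_cov <- rnorm(30, 100 - 50 * tab$gc, 5)
    expect_lte(fit_gc_regression(tab, 2L)$rss,
               fit_gc_regression(tab, 1L)$rss + 1e-8)
  }
})

test_that("fitted values are invariant to affine rescaling of gc", {
  set.seed(56)
  tab <- data.frame(gc = runif(40, 0.2, 0.6))
  tab$mean_cov <- rnorm(40, 80 - 30 * tab$gc, 4)
  for (deg in 1:2) {
    f0 <- fit_gc_regression(tab, deg)
    tab2 <- transform(tab, gc = 10 * gc - 3)
    f1 <- fit_gc_regression(tab2, deg)
    expect_equal(f0$R2, f1$R2, tolerance = 1e-10)
    expect_equal(f0$rss, f1$rss, tolerance = 1e-8)
    if (deg == 2) {
      expect_equal(10 * f0$vertex_gc - 3, f1$vertex_gc, tolerance = 1e-6)
    }
  }
})

test_that("AT/GC coverage t-test uses the Welch form with the stated sign", {
  eq <- at_gc_coverage_ttest(rep(10, 8), "ATGCATGC")
  expect_equal(eq$t, 0)

  d <- at_gc_coverage_ttest(c(12, 12, 12, 12, 10, 10, 10, 10), "AATTGGCC")
  expect_gt(d$t, 1e3)  # variance floor keeps a planted difference finite but huge
  expect_equal(d$mean_AT - d$mean_GC, 2)

  set.seed(77)
  cov <- rpois(60, 90)
  seqs <- sample(c("A", "C", "G", "T"), 60, TRUE)
  got <- at_gc_coverage_ttest(cov, seqs)
  want <- oracle_welch(cov[seqs %in% c("A", "T")], cov[seqs %in% c("G", "C")])
  expect_equal(got$t, want$t, tolerance = 1e-10)
  expect_equal(got$df, want$df, tolerance = 1e-10)
  # and agrees with the reference implementation
  tt <- t.test(cov[seqs %in% c("A", "T")], cov[seqs %in% c("G", "C")])
  expect_equal(got$t, unname(tt$statistic), tolerance = 1e-10)
  expect_error(at_gc_coverage_ttest(c(1, 2), "AG"), "at least 2")
})

test_that("ANCOVA isolates a planted continuous GC effect", {
  set.seed(78)
  n <- 400
  gc50 <- runif(n, 0.2, 0.6)
  base <- sample(c("A", "C", "G", "T"), n, TRUE)
  gt <- sample(c("protein_coding", "rRNA", "tRNA"), n, TRUE)
  cov <- 100 - 50 * gc50 + rnorm(n, 0, 0.01)
  fit <- site_ancova(cov, base, gt, gc50)
  a <- fit$anova
  expect_gt(a["gc50", "F value"], 1e4)
  expect_lt(a["base", "F value"], 10)
  expect_equal(fit$coefficients["gc50", "Estimate"], -50, tolerance = 1e-3)
})

test_that("ANCOVA recovers planted gene-type offsets", {
  set.seed(79)
  n <- 15000
  gc50 <- runif(n, 0.2, 0.6)
  base <- sample(c("A", "C", "G", "T"), n, TRUE)
  gt <- sample(c("protein_coding", "rRNA", "intergenic"), n, TRUE)
  off <- c(protein_coding = 5, rRNA = -5, intergenic = 0)
  cov <- rnorm(n, 100 - 20 * gc50 + off[gt], 10)
  fit <- site_ancova(cov, base, gt, gc50)
  co <- fit$coefficients
  # treatment coding with intergenic as reference level
  expect_equal(fit$reference_levels[["gene_type"]], "intergenic")
  est_pc <- co["gene_typeprotein_coding", ]
  est_rr <- co["gene_typerRNA", ]
  expect_lt(abs(est_pc["Estimate"] - 5), 2 * est_pc["Std. Error"])
  expect_lt(abs(est_rr["Estimate"] + 5), 2 * est_rr["Std. Error"])
})

test_that("ANCOVA rejects degenerate factors", {
  expect_error(site_ancova(1:10, rep("A", 10), rep(c("tRNA", "rRNA"), 5),
                           runif(10)), "'base'")
  expect_error(site_ancova(1:10, rep(c("A", "G"), 5), rep("tRNA", 10),
                           runif(10)), "'gene_type'")
})
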