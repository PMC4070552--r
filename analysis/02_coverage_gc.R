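#!/usr/bin/env Rscript
# Stage 2: coverage windows and GC-dependence of coverage.
#
# Windows the main individual's coverage with local GC in non-overlapping
# 50-bp windows, fits linear and quadratic regressions (AIC-compared),
# tests per-base A/T vs G/C coverage, and runs the site-level ANCOVA with
# base identity, gene type and surrounding GC.

suppressPackageStartupMessages(library(mitocovbias))

out <- "results"
cfg_meta <- jsonlite::read_json(file.path(out, "sim_config.json"))
cfg <- sim_config(seed = cfg_meta$seed)
gen <- generate_reference(cfg)
sim <- simulate_site_profiles(gen, cfg)

main <- sim$profiles[sim$profiles$individual == "ind1", ]
bases <- main$ref
wins <- window_profile(bases, main$depth, 50, 50)
utils::write.table(wins, file.path(out, "gc_windows.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

fit1 <- fit_gc_regression(wins, 1L)
fit2 <- fit_gc_regression(wins, 2L)
daic <- compare_models_aic(fit1, fit2)
tt <- at_gc_coverage_ttest(main$depth, bases)
anc <- site_ancova(main$depth, bases, gen$reference$gene_type_by_site,
                   gc_by_site(bases, 50, circular = TRUE))

cat(sprintf("%d windows of 50 bp\n", nrow(wins)))
cat(sprintf("linear:    F = %.2f, R2 = %.3f, df = %d, slope = %.0f\n",
            fit1$F, fit1$R2, fit1$df, fit1$coefficients[2]))
cat(sprintf("quadratic: F = %.2f, R2 = %.3f, df = %d, vertex at GC = %.3f\n",
            fit2$F, fit2$R2, fit2$df, fit2$vertex_gc))
cat(sprintf("delta AIC (quad - lin) = %.1f -> %s\n", daic,
            if (daic < 0) "quadratic preferred" else "linear preferred"))
cat(sprintf("A/T mean %.0fX vs G/C mean %.0fX: Welch t = %.2f, df = %.0f\n",
            tt$mean_AT, tt$mean_GC, tt$t, tt$df))
cat("ANCOVA (Type II) F values:\n")
print(anc$anova[, "F value", drop = FALSE])

jsonlite::write_json(
  list(n_windows = nrow(wins),
       linear = fit1[c("coefficients", "F", "R2", "df", "p", "aic")],
       quadratic = fit2[c("coefficients", "F", "R2", "df", "p", "aic",
                          "vertex_gc")],
       delta_aic = daic,
       at_gc_ttest = tt,
       ancova_F = as.list(stats::setNames(anc$anova[, "F value"],
                                          rownames(anc$anova)))),
  file.path(out, "gc_fits.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE, force = TRUE)
cat("wrote gc_windows.tsv and gc_fits.json\n")
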