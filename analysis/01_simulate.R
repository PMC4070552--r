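#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Eleven individuals over a 16.5-kb circular reference with a GC-dependent
# coverage bias (peak at GC = 0.27), a shared per-site effect, 22 planted
# CCNGCC motif copies (3 active: focal error 2% and an upstream coverage
# dip), baseline error 0.11%, and six heteroplasmic sites at carrier
# frequencies 1.3-67.9%. All downstream stages regenerate this cohort
# deterministically from the seed recorded here, so only the small
# ground-truth tables and the reference are materialised.

suppressPackageStartupMessages(library(mitocovbias))

seed <- 101L
out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
gen <- generate_reference(cfg)
sim <- simulate_site_profiles(gen, cfg)

write_fasta(stats::setNames(gen$reference$sequence, gen$reference$name),
            file.path(out, "synthetic_reference.fa"))
write_annotation_bed(gen$reference, file.path(out, "synthetic_genes.bed"))
utils::write.table(sim$truth$heteroplasmy,
                   file.path(out, "truth_heteroplasmy.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(sim$truth$active_motifs,
                   file.path(out, "truth_active_motifs.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(seed = seed, L_ref = cfg$L_ref,
                          n_individuals = cfg$n_individuals,
                          mean_depth = cfg$mean_depth[1],
                          gc_target = cfg$gc_target,
                          vertex_gc = cfg$vertex_gc,
                          curvature = cfg$curvature,
                          e0 = cfg$e0, e_motif = cfg$e_motif,
                          n_motifs = cfg$n_motifs,
                          n_active_motifs = cfg$n_active_motifs,
                          n_heteroplasmic = cfg$n_heteroplasmic),
                     file.path(out, "sim_config.json"),
                     auto_unbox = TRUE, pretty = TRUE)

m <- coverage_matrix(sim$profiles)
cat(sprintf("cohort: %d individuals x %d sites\n", ncol(m), nrow(m)))
cat(sprintf("mean depth (ind1): %.0fX; per-site range %d-%dX\n",
            mean(m[, 1]), min(m[, 1]), max(m[, 1])))
cat(sprintf("planted: %d motifs (%d active), %d heteroplasmic sites\n",
            cfg$n_motifs, cfg$n_active_motifs, nrow(sim$truth$heteroplasmy)))
cat("wrote reference, annotation and truth tables to", out, "\n")
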