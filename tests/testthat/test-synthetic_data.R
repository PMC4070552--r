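test_that("generated references hit the GC target and carry planted motifs", {
  cfg <- sim_config(seed = 81, L_ref = 16500, gc_target = 0.4, n_motifs = 22)
  ref <- generate_reference(cfg)
  bases <- strsplit(ref$reference$sequence, "")[[1]]
  gc <- mean(bases %in% c("G", "C"))
  expect_lt(abs(gc - 0.4), 0.02)

  hits <- scan_iupac_motifs(ref$reference$sequence, "CCNGCC")
  expect_gte(nrow(hits), 22)
  # every planted copy is found on its planted strand
  key <- paste(ref$motifs$start, ref$motifs$strand)
  expect_true(all(key %in% paste(hits$start, hits$strand)))

  ref2 <- generate_reference(cfg)
  expect_identical(ref2$reference$sequence, ref$reference$sequence)

  # annotation tiles every position with exactly one class
  expect_equal(length(ref$reference$gene_type_by_site), 16500L)
  expect_setequal(unique(ref$reference$gene_type_by_site),
                  c("protein_coding", "tRNA", "rRNA", "intergenic"))
})

test_that("impossible motif placement errors out", {
  expect_error(generate_reference(sim_config(L_ref = 250, n_motifs = 50,
                                             motif_dip_range = 10)),
               "cannot place")
})

test_that("with all biases off, depth is Poisson around the mean", {
  cfg <- sim_config(seed = 82, L_ref = 5000, n_individuals = 2,
                    mean_depth = 400, curvature = 0, site_effect_sd = 0,
                    individual_noise_sd = 0, n_motifs = 0,
                    n_heteroplasmic = 0, e0 = 0)
  sim <- simulate_site_profiles(generate_reference(cfg), cfg)
  d <- sim$profiles$depth[sim$profiles$individual == "ind1"]
  expect_lt(abs(mean(d) - 400), 400 * 0.02)
  expect_lt(abs(sd(d) / mean(d) - 1 / sqrt(400)), 0.006)
  # exchangeability across individuals: near-identical moments
  d2 <- sim$profiles$depth[sim$profiles$individual == "ind2"]
  expect_lt(abs(mean(d) - mean(d2)) / mean(d), 0.02)
})

test_that("zero error rate and no heteroplasmy yield zero error rates", {
  cfg <- sim_config(seed = 83, L_ref = 800, mean_depth = 300,
                    n_individuals = 2, n_motifs = 2, e0 = 0, e_motif = 0,
                    n_heteroplasmic = 0)
  ref <- generate_reference(cfg)
  sim <- simulate_site_profiles(ref, cfg)
  er <- site_error_rates(sim$profiles, ref$reference$sequence)
  expect_true(all(er$rates$e == 0))
})

test_that("planted coverage dips sit upstream of active plus-strand motifs", {
  cfg <- sim_config(seed = 84, L_ref = 4000, n_individuals = 1,
                    mean_depth = 5000, site_effect_sd = 0,
                    individual_noise_sd = 0, curvature = 0,
                    n_motifs = 6, n_active_motifs = 6,
                    motif_dip_depth = 0.5, n_heteroplasmic = 0)
  sim <- simulate_site_profiles(generate_reference(cfg), cfg)
  act <- sim$truth$active_motifs
  expect_equal(nrow(act), 6L)
  d <- sim$profiles$depth
  for (i in seq_len(nrow(act))) {
    edge <- if (act$strand[i] == "+") act$start[i] - 1L else act$end[i]
    far <- (edge + 2000L) %% cfg$L_ref
    expect_lt(d[edge + 1L], 0.65 * d[far + 1L])
  }
})

test_that("simulated reads are deterministic, circular and error-planted", {
  cfg <- sim_config(seed = 85, L_ref = 600, n_motifs = 0, n_heteroplasmic = 0)
  ref <- generate_reference(cfg)
  r1 <- simulate_reads(ref, depth = 10, read_len = 80, e0 = 0.01, seed = 2)
  r2 <- simulate_reads(ref, depth = 10, read_len = 80, e0 = 0.01, seed = 2)
  expect_identical(r1, r2)
  expect_equal(length(r1), round(10 * 600 / 80))
  expect_true(all(nchar(r1) == 80))

  expect_equal(length(simulate_reads(ref, depth = 0, read_len = 80, e0 = 0)),
               0L)

  # error-free reads are exact substrings of the doubled reference
  clean <- simulate_reads(ref, depth = 5, read_len = 60, e0 = 0, seed = 3)
  doubled <- paste0(ref$reference$sequence, ref$reference$sequence)
  expect_true(all(vapply(clean, function(r) grepl(r, doubled, fixed = TRUE),
                         TRUE)))
  f <- tempfile(fileext = ".fq")
  write_fastq(clean, f)
  expect_equal(readLines(f)[2], clean[1])
})

test_that("emitted pileups and truth tables round-trip", {
  cfg <- sim_config(seed = 86, L_ref = 300, mean_depth = 60,
                    n_individuals = 11, n_motifs = 2, n_heteroplasmic = 3)
  sim <- simulate_site_profiles(generate_reference(cfg), cfg)
  dir <- tempfile()
  paths <- emit_truth_and_pileups(sim, dir)
  expect_equal(sum(grepl("\\.pileup$", paths)), 11L)

  back <- do.call(rbind, lapply(sprintf("ind%d", 1:11), function(id) {
    parse_pileup(file.path(dir, paste0(id, ".pileup")), id,
                 ref_length = cfg$L_ref)
  }))
  a <- sim$profiles[order(sim$profiles$individual, sim$profiles$pos), ]
  b <- back[order(back$individual, back$pos), ]
  keep <- a$depth > 0  # zero-depth sites lose their reference base
  expect_equal(b[keep, names(a)], a[keep, ], ignore_attr = TRUE)

  truth_het <- read.delim(file.path(dir, "truth_heteroplasmy.tsv"))
  expect_equal(nrow(truth_het), 3L)
})

test_that("the default configuration reproduces the assumed data structure", {
  cfg <- sim_config(seed = 87)
  sim <- simulate_site_profiles(generate_reference(cfg), cfg)
  m <- coverage_matrix(sim$profiles)
  # few-fold coverage variation across sites (extremes of the per-site mean)
  shared <- rowMeans(m)
  fold <- quantile(shared, 0.999) / quantile(shared, 0.001)
  expect_gt(fold, 2)
  expect_lt(fold, 10)
  # cross-individual rank correlations in the repeatable regime
  pc <- pairwise_profile_correlation(m[seq(1, nrow(m), by = 4), ])
  off <- pc$r[upper.tri(pc$r)]
  expect_gt(min(off), 0.4)
  expect_lt(max(off), 0.95)
})
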