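test_that("consensus follows pooled majority with the documented tie rules", {
  tab <- make_site_table(rbind(c(99, 0, 1, 0),
                               c(50, 0, 50, 0),
                               c(0, 0, 0, 0)),
                         ref = c("A", "G", "A"))
  expect_message(cons <- consensus_from_counts(tab), "zero-depth")
  expect_equal(cons, c("A", "G", "N"))  # tie at site 2 broken toward ref G
  # alphabetical tie-break when the reference is not among the tied bases
  tab2 <- make_site_table(rbind(c(0, 30, 30, 0)), ref = "T")
  expect_equal(consensus_from_counts(tab2), "C")
})

test_that("site error rates are substitution counts over depth", {
  tab <- make_site_table(rbind(c(9990, 0, 10, 0), c(100, 0, 0, 0)),
                         ref = c("A", "A"))
  er <- site_error_rates(tab, c("A", "A"))
  expect_equal(er$rates$e, c(0.001, 0))
  expect_equal(unname(er$summary["max"]), 0.001)
  expect_error(site_error_rates(tab, "A"), "length")
})

test_that("a planted baseline error rate is recovered at depth", {
  set.seed(21)
  n <- 15000
  depth <- rep(100000L, n)
  e0 <- 0.001
  n_err <- rbinom(n, depth, e0)
  g <- rbinom(n, n_err, 1 / 3)
  c_ <- rbinom(n, n_err - g, 1 / 2)
  tab <- make_site_table(cbind(depth - n_err, c_, g, n_err - g - c_),
                         ref = rep("A", n))
  er <- site_error_rates(tab, rep("A", n))
  expect_gt(unname(er$summary["mean"]), 0.0009)
  expect_lt(unname(er$summary["mean"]), 0.0011)
})

test_that("mean error rate equals pooled mismatch fraction at constant depth", {
  set.seed(22)
  for (i in 1:10) {
    n <- 50
    depth <- rep(sample(500:2000, 1), n)
    n_err <- rbinom(n, depth, 0.01)
    tab <- make_site_table(cbind(depth - n_err, n_err, 0, 0), rep("A", n))
    er <- site_error_rates(tab, rep("A", n))
    expect_equal(unname(er$summary["mean"]), sum(n_err) / sum(depth),
                 tolerance = 1e-12)
  }
})

test_that("substitution spectrum rows normalise and ti/tv tends to 0.5", {
  tab <- make_site_table(rbind(c(99, 0, 1, 0)), ref = "A")
  sp <- substitution_spectrum(tab, "A")
  expect_equal(sp$rates["A", "G"], 0.01)
  expect_equal(sum(sp$counts) - sp$counts["A", "A"] - sp$counts["A", "G"], 0)
  expect_true(all(is.na(sp$rates["C", ])))  # no C-consensus sites: undefined

  set.seed(23)
  n <- 4000
  ref <- sample(c("A", "C", "G", "T"), n, TRUE)
  depth <- rep(10000L, n)
  n_err <- rbinom(n, depth, 0.01)
  a1 <- rbinom(n, n_err, 1 / 3)
  a2 <- rbinom(n, n_err - a1, 1 / 2)
  cnt <- matrix(0L, n, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(n)) {
    alts <- setdiff(c("A", "C", "G", "T"), ref[i])
    cnt[i, ref[i]] <- depth[i] - n_err[i]
    cnt[i, alts] <- c(a1[i], a2[i], n_err[i] - a1[i] - a2[i])
  }
  sp <- substitution_spectrum(make_site_table(cnt, ref), ref)
  expect_equal(sp$titv, 0.5, tolerance = 0.05)
  expect_equal(unname(rowSums(sp$rates)), rep(1, 4), tolerance = 1e-12)
})

test_that("per-site substitution counts plus consensus count equal depth", {
  cfg <- sim_config(seed = 9, L_ref = 300, mean_depth = 200,
                    n_individuals = 2, n_motifs = 1, n_heteroplasmic = 1)
  sim <- simulate_site_profiles(generate_reference(cfg), cfg)
  tab <- sim$profiles
  expect_true(all(tab$n_A + tab$n_C + tab$n_G + tab$n_T == tab$depth))
})

test_that("IUPAC motif scanning finds both strands and wrapped hits", {
  hits <- scan_iupac_motifs("TTCCAGCCTT", "CCNGCC")
  expect_equal(hits$start, 2L)
  expect_equal(hits$strand, "+")

  hits <- scan_iupac_motifs("TTGGCTGGTT", "CCNGCC")
  expect_equal(hits$start, 2L)
  expect_equal(hits$strand, "-")

  hits <- scan_iupac_motifs("GCCTTTTCCA", "CCNGCC", circular = TRUE)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 7L)  # CCA|GCC spans the origin
  expect_equal(hits$end, 13L)

  expect_error(scan_iupac_motifs("ACGT", "CCJGCC"), "IUPAC")
})

test_that("linear motif scan agrees with a regex oracle on random sequences", {
  set.seed(41)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE,
                      prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
    hits <- scan_iupac_motifs(s, "CCNGCC")
    expect_equal(sort(hits$start[hits$strand == "+"]),
                 oracle_motif_starts(s, "CCNGCC"))
    expect_equal(sort(hits$start[hits$strand == "-"]),
                 oracle_motif_starts(s, oracle_revcomp("CCNGCC")))
  }
})

test_that("circular hit counts are invariant under sequence rotation", {
  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE,
                    prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
  n0 <- nrow(scan_iupac_motifs(s, "CCNGCC", circular = TRUE))
  for (k in c(1, 57, 150, 299)) {
    rot <- paste0(substr(s, k + 1, 300), substr(s, 1, k))
    expect_equal(nrow(scan_iupac_motifs(rot, "CCNGCC", circular = TRUE)), n0)
  }
})

test_that("motif proximity relates coverage to distance on the error-prone side", {
  hits <- data.frame(start = 200L, end = 206L, strand = "+",
                     pattern = "CCNGCC", stringsAsFactors = FALSE)
  L <- 400
  cov <- rep(100, L)
  cov[101:200] <- 100:1  # coverage rises with distance from the motif edge
  res <- motif_proximity_analysis(cov, hits, flank = 100)
  expect_equal(res$r, 1)
  expect_equal(res$df, 98L)
  expect_equal(nrow(res$table), 100L)

  res <- motif_proximity_analysis(rep(5, L), hits, flank = 100)
  expect_equal(res$r, 0)

  # minus-strand flank lies downstream
  hits_m <- data.frame(start = 50L, end = 56L, strand = "-",
                       pattern = "CCNGCC", stringsAsFactors = FALSE)
  res <- motif_proximity_analysis(seq_len(L), hits_m, flank = 20)
  expect_equal(res$table$pos, 56:75)
  expect_equal(res$table$dist, 1:20)
  expect_error(motif_proximity_analysis(cov, hits, flank = 0), "positive")
  expect_error(motif_proximity_analysis(cov, hits[0, ]), "no motif hits")
})

test_that("overlapping flanks count each site once at its minimum distance", {
  hits <- data.frame(start = c(100L, 110L), end = c(106L, 116L),
                     strand = c("+", "+"), pattern = "CCNGCC",
                     stringsAsFactors = FALSE)
  res <- motif_proximity_analysis(rnorm(300, 100), hits, flank = 50)
  expect_equal(nrow(res$table), length(unique(res$table$pos)))
  # site 99 is 1 bp from the second motif start minus 10 -> distance to
  # nearest edge is min(100-99, 110-99) = 1
  expect_equal(res$table$dist[res$table$pos == 99], 1)
  expect_equal(res$table$dist[res$table$pos == 104], 6)
})

test_that("error/coverage correlation has textbook behaviour and df", {
  cov <- seq(100, 1089, length.out = 50)
  res <- error_coverage_correlation(1 / cov, cov)
  expect_equal(res$r, -1)

  res <- error_coverage_correlation(runif(15788), rpois(15788, 50))
  expect_equal(res$df, 15786L)

  set.seed(43)
  x <- rpois(40, 10); y <- rnorm(40)
  res <- error_coverage_correlation(y, x)
  expect_equal(res$r, oracle_spearman(x, y), tolerance = 1e-12)
  expect_true(is.na(error_coverage_correlation(rep(1, 10), rpois(10, 5))$r))
})

test_that("heteroplasmy calling separates single carriers from shared variants", {
  set.seed(44)
  n <- 20; ni <- 11
  tabs <- lapply(seq_len(ni), function(j) {
    depth <- rep(4000L, n)
    make_site_table(cbind(depth, 0L, 0L, 0L), rep("A", n), paste0("i", j))
  })
  tab <- do.call(rbind, tabs)
  # one carrier with G at 30% at site 5; trace G (<= 0.05%) elsewhere
  sel <- tab$individual == "i3" & tab$pos == 4
  tab$n_G[sel] <- 1200L; tab$n_A[sel] <- 2800L
  trace <- tab$individual != "i3" & tab$pos == 4
  tab$n_G[trace] <- 2L; tab$n_A[trace] <- 3998L
  tab$depth <- tab$n_A + tab$n_C + tab$n_G + tab$n_T
  res <- call_heteroplasmy(tab, rep("A", n))
  expect_equal(nrow(res$heteroplasmy), 1L)
  expect_equal(res$heteroplasmy$pos, 4L)
  expect_equal(res$heteroplasmy$carrier_individual, "i3")
  expect_equal(res$heteroplasmy$alt_base, "G")
  expect_equal(res$heteroplasmy$alt_freq, 0.3)
  expect_equal(nrow(res$shared), 0L)

  # a second carrier turns the site into a shared variant
  sel2 <- tab$individual == "i7" & tab$pos == 4
  tab$n_G[sel2] <- 1200L; tab$n_A[sel2] <- 2800L
  res <- call_heteroplasmy(tab, rep("A", n))
  expect_equal(nrow(res$heteroplasmy), 0L)
  expect_equal(res$shared$pos, 4L)
  expect_equal(res$shared$n_carriers, 2L)

  expect_error(call_heteroplasmy(tabs[[1]], rep("A", n)), "2 individuals")
})

test_that("planted heteroplasmic sites are recovered exactly at high depth", {
  cfg <- sim_config(seed = 5, L_ref = 4000, mean_depth = 25000,
                    n_individuals = 11, n_motifs = 4, n_heteroplasmic = 6)
  sim <- simulate_site_profiles(generate_reference(cfg), cfg)
  cons <- consensus_from_counts(sim$profiles)
  res <- call_heteroplasmy(sim$profiles, cons)
  got <- res$heteroplasmy[order(res$heteroplasmy$pos), ]
  want <- sim$truth$heteroplasmy[order(sim$truth$heteroplasmy$pos), ]
  expect_equal(got$pos, want$pos)                      # recall = 1, precision = 1
  expect_equal(got$carrier_individual, want$individual)
  expect_equal(got$alt_base, want$alt)
  expect_equal(got$alt_freq, want$freq, tolerance = 0.05)
})
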