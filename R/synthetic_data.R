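#' Simulation configuration for synthetic ultra-deep mtDNA data
#'
#' Defaults emulate the structure of ultra-deep mitochondrial resequencing
#' of a small vertebrate cohort: one circular ~16.5-kb reference at ~38.5%
#' GC, eleven individuals at a few-thousand-fold mean depth, a shared
#' quadratic GC-dependence of log-mean coverage peaking at GC = 0.27, a
#' shared lognormal per-site effect plus individual lognormal noise,
#' 22 planted copies of the error-prone motif CCNGCC of which 3 are
#' "active" (elevated focal error rate and a localized coverage dip on the
#' high-error side), a baseline per-base error rate of 0.11%, and six
#' heteroplasmic sites with carrier frequencies drawn from the observed
#' range 1.3-67.9%.
#'
#' @param seed integer RNG seed.
#' @param L_ref reference length (bp).
#' @param gc_target target GC fraction of the simulated reference.
#' @param n_individuals cohort size.
#' @param mean_depth per-individual mean depth (X); scalar or vector of
#'   length `n_individuals`.
#' @param vertex_gc,curvature quadratic log-mean coverage model
#'   `log q = curvature * (gc50 - vertex_gc)^2` (curvature < 0 puts a
#'   coverage peak at `vertex_gc`).
#' @param site_effect_sd SD of the shared lognormal per-site effect.
#' @param individual_noise_sd SD of the per-site, per-individual lognormal
#'   noise.
#' @param n_motifs planted CCNGCC copies; `n_active_motifs` of them get the
#'   error/coverage anomaly (set from `p_motif_active` when `NULL`).
#' @param p_motif_active fraction of planted motifs that are active.
#' @param motif_dip_depth maximal fractional coverage drop at the motif
#'   edge (in `[0, 1)`).
#' @param motif_dip_range extent of the coverage dip upstream of the motif
#'   (bp).
#' @param e0 baseline per-base error rate.
#' @param e_motif error rate at the focal site of an active motif.
#' @param n_heteroplasmic planted heteroplasmic sites.
#' @param het_freq_range carrier allele-frequency range (uniform draw).
#' @param substitution_matrix 4x4 row-stochastic matrix of error target
#'   probabilities given the true base (diagonal ignored); default uniform
#'   over the three alternatives.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       L_ref = 16500L,
                       gc_target = 0.385,
                       n_individuals = 11L,
                       mean_depth = 4000,
                       vertex_gc = 0.27,
                       curvature = -8,
                       site_effect_sd = 0.20,
                       individual_noise_sd = 0.12,
                       n_motifs = 22L,
                       p_motif_active = 3 / 22,
                       n_active_motifs = NULL,
                       motif_dip_depth = 0.4,
                       motif_dip_range = 100L,
                       e0 = 0.0011,
                       e_motif = 0.02,
                       n_heteroplasmic = 6L,
                       het_freq_range = c(0.013, 0.679),
                       substitution_matrix = NULL) {
  if (is.null(n_active_motifs)) n_active_motifs <- round(p_motif_active * n_motifs)
  if (is.null(substitution_matrix)) {
    substitution_matrix <- matrix(1 / 3, 4, 4, dimnames = list(BASES, BASES))
    diag(substitution_matrix) <- 0
  }
  cfg <- list(seed = as.integer(seed), L_ref = as.integer(L_ref),
              gc_target = gc_target, n_individuals = as.integer(n_individuals),
              mean_depth = rep_len(mean_depth, n_individuals),
              vertex_gc = vertex_gc, curvature = curvature,
              site_effect_sd = site_effect_sd,
              individual_noise_sd = individual_noise_sd,
              n_motifs = as.integer(n_motifs),
              n_active_motifs = as.integer(n_active_motifs),
              motif_dip_depth = motif_dip_depth,
              motif_dip_range = as.integer(motif_dip_range),
              e0 = e0, e_motif = e_motif,
              n_heteroplasmic = as.integer(n_heteroplasmic),
              het_freq_range = het_freq_range,
              substitution_matrix = substitution_matrix)
  stopifnot(cfg$L_ref > 200L, cfg$gc_target >= 0, cfg$gc_target <= 1,
            all(cfg$mean_depth > 0), cfg$motif_dip_depth >= 0,
            cfg$motif_dip_depth < 1, cfg$e0 >= 0, cfg$e0 <= 1,
            cfg$e_motif >= 0, cfg$e_motif <= 1,
            all(cfg$het_freq_range >= 0), all(cfg$het_freq_range <= 1),
            cfg$n_active_motifs <= cfg$n_motifs)
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic annotated circular reference with planted motifs
#'
#' Bases are drawn i.i.d. at the target GC; `n_motifs` copies of CCNGCC
#' (random N base, random strand) are overwritten at non-overlapping
#' positions; a simple gene annotation tiles the sequence with alternating
#' protein-coding, tRNA and rRNA features separated by short intergenic
#' gaps.
#'
#' @param config a [sim_config()].
#' @return list with `reference` (list: `name`, `sequence`, `circular`,
#'   `features`, `gene_type_by_site`) and `motifs` (data.frame `start`,
#'   `end`, `strand` of the planted copies).
#' @export
generate_reference <- function(config) {
  set.seed(config$seed)
  L <- config$L_ref
  gt <- config$gc_target
  bases <- sample(BASES, L, replace = TRUE,
                  prob = c((1 - gt) / 2, gt / 2, gt / 2, (1 - gt) / 2))
  # plant motifs at non-overlapping positions, away from the origin so the
  # linear-coordinate analyses see whole flanks
  margin <- config$motif_dip_range + 6L
  starts <- integer(0)  # 0-based motif starts
  tries <- 0L
  while (length(starts) < config$n_motifs) {
    cand <- sample.int(L - 2L * margin, 1L) + margin - 1L
    if (all(abs(cand - starts) >= 12L)) starts <- c(starts, cand)
    tries <- tries + 1L
    if (tries > 1000L * config$n_motifs) {
      stop("cannot place ", config$n_motifs, " non-overlapping motifs on ",
           L, " bp")
    }
  }
  starts <- sort(starts)
  strands <- sample(c("+", "-"), length(starts), replace = TRUE)
  for (i in seq_along(starts)) {
    motif <- sub("N", sample(BASES, 1L), "CCNGCC")
    if (strands[i] == "-") motif <- revcomp(motif)
    bases[(starts[i] + 1L):(starts[i] + 6L)] <- strsplit(motif, "")[[1L]]
  }
  feats <- tile_annotation(L)
  list(reference = list(name = "synthetic_mtDNA", sequence = paste(bases, collapse = ""),
                        circular = TRUE, features = feats$features,
                        gene_type_by_site = feats$gene_type_by_site),
       motifs = data.frame(start = starts, end = starts + 6L, strand = strands,
                           stringsAsFactors = FALSE))
}

# alternating gene blocks with small intergenic gaps, mtDNA-like sizes
tile_annotation <- function(L) {
  pattern <- list(c("tRNA", 70L), c("rRNA", 960L), c("tRNA", 70L),
                  c("rRNA", 1550L), c("tRNA", 75L), c("protein_coding", 950L),
                  c("tRNA", 70L), c("protein_coding", 1040L),
                  c("tRNA", 68L), c("protein_coding", 680L))
  rows <- list(); pos <- 0L; i <- 1L
  while (pos < L) {
    gene <- pattern[[(i - 1L) %% length(pattern) + 1L]]
    len <- min(as.integer(gene[2L]), L - pos)
    rows[[i]] <- data.frame(start = pos, end = pos + len,
                            gene_type = gene[1L],
                            strand = if (i %% 2L) "+" else "-",
                            name = paste0(tolower(substr(gene[1L], 1L, 1L)), i),
                            stringsAsFactors = FALSE)
    pos <- pos + len + 25L  # intergenic gap
    i <- i + 1L
  }
  feats <- do.call(rbind, rows)
  site_type <- rep("intergenic", L)
  for (j in seq_len(nrow(feats))) {
    site_type[(feats$start[j] + 1L):feats$end[j]] <- feats$gene_type[j]
  }
  list(features = feats, gene_type_by_site = site_type)
}

#' Write the generated annotation as a BED file
#'
#' @param reference the `reference` element of [generate_reference()].
#' @param path output BED path (7 columns; column 7 is the gene type).
#' @export
write_annotation_bed <- function(reference, path) {
  f <- reference$features
  lines <- paste(reference$name, f$start, f$end, f$name, 0L, f$strand,
                 f$gene_type, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Simulate multi-individual per-site base-count profiles
#'
#' Expected coverage at site i for individual j is
#' `mu_ij = mean_depth_j * q(gc50_i) * s_i * dip_i * eta_ij` with
#' `q` the quadratic-in-GC log-mean (normalised to mean 1 across sites),
#' `s_i` a shared lognormal site effect, `dip_i` the linear-decay coverage
#' dip on the high-error side of active motifs, and `eta_ij` individual
#' lognormal noise; realised depth is Poisson. Base counts are multinomial
#' around the reference base with per-site error rate `e0` (or `e_motif` at
#' the focal site of an active motif); planted heteroplasmic (site,
#' individual) pairs receive their alternative base at the drawn frequency.
#'
#' @param reference output of [generate_reference()] (the full list, with
#'   `motifs`).
#' @param config the [sim_config()] used to generate the reference.
#' @return list with `profiles` (stacked site table for all individuals),
#'   `truth` (list: `site_multiplier`, `active_motifs`, `heteroplasmy`,
#'   `e_true`, `mu`), and `gc50` (per-site GC covariate used).
#' @export
simulate_site_profiles <- function(reference, config) {
  set.seed(config$seed + 1L)
  ref <- reference$reference
  motifs <- reference$motifs
  L <- config$L_ref
  ni <- config$n_individuals
  bases <- as_base_vector(ref$sequence)
  gc50 <- gc_by_site(bases, width = 50L, circular = TRUE)

  logq <- config$curvature * (gc50 - config$vertex_gc)^2
  q <- exp(logq); q <- q / mean(q)
  s <- exp(stats::rnorm(L, 0, config$site_effect_sd))

  # active motifs: fixed count, sampled without replacement
  act_idx <- if (config$n_active_motifs > 0L && nrow(motifs) > 0L) {
    sort(sample.int(nrow(motifs), min(config$n_active_motifs, nrow(motifs))))
  } else integer(0)
  active <- motifs[act_idx, , drop = FALSE]
  dip <- rep(1, L)
  e_true <- rep(config$e0, L)
  rng <- config$motif_dip_range
  for (i in seq_len(nrow(active))) {
    d <- seq_len(rng)
    p <- if (active$strand[i] == "+") active$start[i] - d else active$end[i] - 1L + d
    p <- p %% L
    mult <- 1 - config$motif_dip_depth * (rng - d + 1) / rng
    dip[p + 1L] <- pmin(dip[p + 1L], mult)
    focal <- if (active$strand[i] == "+") active$start[i] - 1L else active$end[i]
    e_true[(focal %% L) + 1L] <- config$e_motif
  }

  # heteroplasmic sites: outside motif flanks, one carrier each
  flanked <- which(dip < 1 | e_true > config$e0)
  free <- setdiff(seq_len(L), flanked)
  n_het <- config$n_heteroplasmic
  het_sites <- if (n_het > 0L) sort(sample(free, n_het)) else integer(0)
  het <- data.frame(
    pos = het_sites - 1L,
    individual = sprintf("ind%d", sample.int(ni, n_het, replace = TRUE)),
    alt = vapply(bases[het_sites],
                 function(b) sample(setdiff(BASES, b), 1L), "",
                 USE.NAMES = FALSE),
    freq = stats::runif(n_het, config$het_freq_range[1L],
                        config$het_freq_range[2L]),
    stringsAsFactors = FALSE)

  shared_mu <- q * s * dip  # per-site, before individual terms
  cons_idx <- match(bases, BASES)
  sub <- config$substitution_matrix

  tabs <- vector("list", ni)
  for (j in seq_len(ni)) {
    id <- paste0("ind", j)
    eta <- exp(stats::rnorm(L, 0, config$individual_noise_sd))
    mu <- config$mean_depth[j] * shared_mu * eta
    depth <- stats::rpois(L, mu)
    counts <- matrix(0L, L, 4L, dimnames = list(NULL, BASES))
    # heteroplasmic draws first: carrier sites take the alt base at freq
    alt_het <- integer(L)
    mine <- het[het$individual == id, , drop = FALSE]
    if (nrow(mine)) {
      i1 <- mine$pos + 1L
      alt_het[i1] <- stats::rbinom(nrow(mine), depth[i1], mine$freq)
    }
    rest <- depth - alt_het
    n_err <- stats::rbinom(L, rest, e_true)
    # split errors over the three alternatives by the substitution matrix
    for (x in seq_len(4L)) {
      sel <- which(cons_idx == x & n_err > 0L)
      if (!length(sel)) next
      alts <- setdiff(seq_len(4L), x)
      pr <- sub[x, alts]; pr <- pr / sum(pr)
      a1 <- stats::rbinom(length(sel), n_err[sel], pr[1L])
      a2 <- stats::rbinom(length(sel), n_err[sel] - a1, pr[2L] / (pr[2L] + pr[3L]))
      a3 <- n_err[sel] - a1 - a2
      counts[cbind(sel, alts[1L])] <- counts[cbind(sel, alts[1L])] + a1
      counts[cbind(sel, alts[2L])] <- counts[cbind(sel, alts[2L])] + a2
      counts[cbind(sel, alts[3L])] <- counts[cbind(sel, alts[3L])] + a3
    }
    counts[cbind(seq_len(L), cons_idx)] <-
      counts[cbind(seq_len(L), cons_idx)] + (rest - n_err)
    if (nrow(mine)) {
      i1 <- mine$pos + 1L
      ai <- match(mine$alt, BASES)
      counts[cbind(i1, ai)] <- counts[cbind(i1, ai)] + alt_het[i1]
    }
    tabs[[j]] <- data.frame(
      individual = id, pos = seq_len(L) - 1L, ref = bases,
      n_A = counts[, "A"], n_C = counts[, "C"],
      n_G = counts[, "G"], n_T = counts[, "T"],
      n_del = 0L, depth = rowSums(counts),
      stringsAsFactors = FALSE)
  }
  list(profiles = do.call(rbind, tabs),
       truth = list(site_multiplier = shared_mu,
                    active_motifs = active,
                    heteroplasmy = het,
                    e_true = e_true),
       gc50 = gc50)
}

#' Simulate error-bearing reads from a circular reference
#'
#' Uniform start positions on the circular sequence; substitution errors are
#' planted per base at rate `e0`. The expected k-mer coverage of the
#' resulting set is `depth * (read_len - k + 1) / read_len`.
#'
#' @param reference reference list (or the output of
#'   [generate_reference()]).
#' @param depth target base-level depth (X).
#' @param read_len read length (bp), at most the reference length.
#' @param e0 per-base substitution error rate.
#' @param seed RNG seed.
#' @return character vector of read sequences (use [write_fastq()] to emit
#'   a FASTQ file).
#' @export
simulate_reads <- function(reference, depth, read_len, e0, seed = 1L) {
  if (!is.null(reference$reference)) reference <- reference$reference
  set.seed(seed)
  seq <- reference$sequence
  L <- nchar(seq)
  if (read_len > L) stop("read length exceeds reference length")
  n_reads <- round(depth * L / read_len)
  if (n_reads == 0L) return(character())
  doubled <- paste0(seq, seq)
  starts <- sample.int(L, n_reads, replace = TRUE)
  reads <- substring(doubled, starts, starts + read_len - 1L)
  if (e0 > 0) {
    n_err <- stats::rbinom(1L, n_reads * read_len, e0)
    if (n_err > 0L) {
      at_read <- sample.int(n_reads, n_err, replace = TRUE)
      at_pos <- sample.int(read_len, n_err, replace = TRUE)
      for (i in seq_len(n_err)) {
        old <- substr(reads[at_read[i]], at_pos[i], at_pos[i])
        substr(reads[at_read[i]], at_pos[i], at_pos[i]) <-
          sample(setdiff(BASES, old), 1L)
      }
    }
  }
  reads
}

#' Write reads as FASTQ
#'
#' @param reads character vector of read sequences.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  if (!length(reads)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  lines <- as.vector(rbind(paste0("@read", seq_along(reads)),
                           reads, "+", strrep("I", nchar(reads))))
  writeLines(lines, path)
  invisible(path)
}

#' Emit simulated profiles as per-individual pileup files plus truth TSVs
#'
#' Pileup emission is inverse-consistent with [parse_pileup()]. Truth files:
#' `truth_sites.tsv` (`pos`, `site_multiplier`, `e_true`),
#' `truth_heteroplasmy.tsv` (`pos`, `individual`, `alt`, `freq`), and
#' `truth_motifs.tsv` (active motif coordinates).
#'
#' @param sim output of [simulate_site_profiles()].
#' @param out_dir output directory (created if needed).
#' @param chrom chromosome name for the pileup files.
#' @return invisibly, the paths written.
#' @export
emit_truth_and_pileups <- function(sim, out_dir, chrom = "chrM") {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory ", out_dir)
  }
  paths <- character()
  for (id in unique(sim$profiles$individual)) {
    p <- file.path(out_dir, paste0(id, ".pileup"))
    write_pileup(sim$profiles[sim$profiles$individual == id, ], p, chrom = chrom)
    paths <- c(paths, p)
  }
  ts <- file.path(out_dir, "truth_sites.tsv")
  utils::write.table(
    data.frame(pos = seq_along(sim$truth$site_multiplier) - 1L,
               site_multiplier = sim$truth$site_multiplier,
               e_true = sim$truth$e_true),
    ts, sep = "\t", quote = FALSE, row.names = FALSE)
  th <- file.path(out_dir, "truth_heteroplasmy.tsv")
  utils::write.table(sim$truth$heteroplasmy, th, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tm <- file.path(out_dir, "truth_motifs.tsv")
  utils::write.table(sim$truth$active_motifs, tm, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, ts, th, tm))
}
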