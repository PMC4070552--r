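#' Run the full coverage-bias and error-profile pipeline
#'
#' Orchestrates the stages in a fixed order: input (or simulation) ->
#' circular-overlap folding -> end trimming -> consensus -> coverage
#' windows -> GC regressions (linear, quadratic, AIC comparison; AT/GC
#' t-test; site ANCOVA) -> error rates, substitution spectrum, motif scan
#' and proximity analysis -> heteroplasmy calls -> within-cohort
#' concordance -> optional k-mer error estimation. Deterministic given the
#' seed. Every reported statistic carries its n and df.
#'
#' @param config either a [sim_config()] (synthetic mode) or a list with
#'   `pileups` (named paths), `reference` (FASTA path), optional `bed`,
#'   and optional `overlap` (bp folded from the linearisation extension).
#' @param keep optional 1-based inclusive retained region `c(first, last)`;
#'   `NULL` keeps everything.
#' @param window_size,window_step coverage/GC window parameters (bp).
#' @param motif IUPAC motif scanned for the proximity analysis.
#' @param flank error-prone flank width (bp).
#' @param high_freq,low_freq,min_depth heteroplasmy thresholds
#'   (see [call_heteroplasmy()]).
#' @param kmer_reads optional read sequences (or FASTQ path) for the k-mer
#'   stage; in synthetic mode `TRUE` simulates a read set.
#' @param k k-mer length for the k-mer stage.
#' @return a `run_report` list with one element per stage.
#' @export
run_pipeline <- function(config = sim_config(),
                         keep = NULL,
                         window_size = 50L, window_step = window_size,
                         motif = "CCNGCC", flank = 100L,
                         high_freq = 0.01, low_freq = 0.001, min_depth = 100L,
                         kmer_reads = NULL, k = 25L) {
  report <- list(config = config, seed = NULL)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (inherits(config, "sim_config")) {
    report$seed <- config$seed
    gen <- stage("simulate", generate_reference(config))
    sim <- stage("simulate", simulate_site_profiles(gen, config))
    profiles <- sim$profiles
    ref_seq <- gen$reference$sequence
    gene_type <- gen$reference$gene_type_by_site
    report$truth <- sim$truth
  } else {
    if (is.null(config$pileups) || is.null(config$reference)) {
      stop("config must supply 'pileups' and 'reference' (or be a sim_config)")
    }
    fa <- stage("input", read_fasta(config$reference, single = TRUE))
    ref_seq <- fa$sequence
    L <- nchar(ref_seq)
    o <- config$overlap %||% 0L
    tabs <- lapply(names(config$pileups), function(id) {
      tab <- stage("parse", parse_pileup(config$pileups[[id]], id,
                                         ref_length = L + o))
      if (o > 0L) {
        for (col in c("n_A", "n_C", "n_G", "n_T", "n_del", "depth")) {
          tab[[col]] <- as.integer(fold_circular_overlap(tab[[col]], L, o))
        }
        tab <- tab[seq_len(L), ]
      }
      tab
    })
    profiles <- do.call(rbind, tabs)
    gene_type <- if (!is.null(config$bed)) {
      stage("input", read_annotation_bed(config$bed, L))$gene_type_by_site
    } else rep("intergenic", L)
  }

  L <- nchar(ref_seq)
  bases <- as_base_vector(ref_seq)
  consensus <- stage("consensus", consensus_from_counts(profiles, ref = bases))

  covmat <- stage("coverage", coverage_matrix(profiles))
  first <- if (is.null(keep)) 1L else keep[1L]
  last <- if (is.null(keep)) L else keep[2L]
  sel <- first:last
  n_trimmed <- L - length(sel)
  cov_kept <- covmat[sel, , drop = FALSE]
  cons_kept <- consensus[sel]
  gtype_kept <- gene_type[sel]
  main_id <- colnames(covmat)[1L]
  scaled <- stage("coverage", scale_to_reference_mean(cov_kept, main_id))

  windows <- stage("windows", window_profile(cons_kept, cov_kept[, main_id],
                                             w = window_size, s = window_step))
  fit1 <- stage("gcfit", fit_gc_regression(windows, 1L))
  fit2 <- stage("gcfit", fit_gc_regression(windows, 2L))
  gc50 <- gc_by_site(cons_kept, width = 50L)
  report$coverage <- list(
    n_sites = length(sel), n_trimmed = n_trimmed,
    mean_depth = colMeans(cov_kept),
    range = range(cov_kept[, main_id]))
  report$gc <- list(
    n_windows = nrow(windows),
    linear = unclass(fit1), quadratic = unclass(fit2),
    delta_aic = compare_models_aic(fit1, fit2),
    at_gc_ttest = stage("gcfit", at_gc_coverage_ttest(cov_kept[, main_id], cons_kept)),
    ancova = if (length(unique(gtype_kept)) >= 2L) {
      stage("ancova", site_ancova(cov_kept[, main_id], cons_kept,
                                  gtype_kept, gc50))
    })

  err <- stage("errors", site_error_rates(
    profiles[profiles$individual == main_id & profiles$pos %in% (sel - 1L), ],
    cons_kept))
  spec_tab <- stage("errors", substitution_spectrum(
    profiles[profiles$pos %in% (sel - 1L), ], cons_kept))
  hits <- stage("motifs", scan_iupac_motifs(paste(cons_kept, collapse = ""), motif))
  prox <- if (nrow(hits)) {
    stage("motifs", motif_proximity_analysis(cov_kept[, main_id], hits, flank))
  }
  ecorr <- stage("errors", error_coverage_correlation(err$rates$e, cov_kept[, main_id]))
  report$errors <- list(
    summary = err$summary, n_sites = sum(!is.na(err$rates$e)),
    substitution = spec_tab$rates, titv = spec_tab$titv,
    n_motif_hits = nrow(hits),
    motif_proximity = if (!is.null(prox)) prox[c("r", "df", "p")],
    error_coverage = ecorr)

  report$heteroplasmy <- stage("heteroplasmy", {
    hp <- call_heteroplasmy(
      profiles[profiles$pos %in% (sel - 1L), ],
      cons_kept, high_freq = high_freq, low_freq = low_freq,
      min_depth = min_depth)
    list(calls = hp$heteroplasmy, shared = hp$shared,
         n_calls = nrow(hp$heteroplasmy))
  })

  report$concordance <- stage("concordance", {
    pc <- pairwise_profile_correlation(scaled)
    off <- pc$r[upper.tri(pc$r)]
    list(r = pc$r, df = pc$df,
         r_range = range(off, na.rm = TRUE),
         mean_off_diagonal = mean(off, na.rm = TRUE))
  })

  if (!is.null(kmer_reads)) {
    report$kmer <- stage("kmer", {
      if (isTRUE(kmer_reads)) {
        if (!inherits(config, "sim_config")) {
          stop("kmer_reads = TRUE requires synthetic mode")
        }
        kmer_reads <- simulate_reads(list(sequence = ref_seq), depth = 60,
                                     read_len = 100L, e0 = config$e0,
                                     seed = config$seed + 2L)
      }
      sp <- count_kmers(kmer_reads, k = k)
      cut <- find_error_threshold(sp)
      er <- kmer_error_rate(sp, cut)
      M <- spectrum_peak(sp, cut)
      list(k = k, cutoff = cut, peak_multiplicity = M,
           per_base_error = er$per_base_error,
           depth = depth_from_peak(M, 100, k),
           total_instances = sp$total_instances)
    })
  }
  structure(report, class = "run_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run report as JSON
#'
#' Matrices become row-wise lists; the config's substitution matrix and any
#' truth tables are carried along so a report is self-describing.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param path output JSON path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(strip_for_json(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

strip_for_json <- function(x) {
  if (inherits(x, "anova")) return(as.data.frame(x))
  if (is.list(x)) return(lapply(x, strip_for_json))
  x
}
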