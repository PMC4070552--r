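BASES <- c("A", "C", "G", "T")

# pool base counts across individuals; returns matrix sites x 4 plus pos/ref
pool_counts <- function(tab) {
  pos <- sort(unique(tab$pos))
  m <- matrix(0, length(pos), 4L, dimnames = list(NULL, BASES))
  idx <- match(tab$pos, pos)
  for (b in BASES) {
    m[, b] <- as.numeric(tapply(tab[[paste0("n_", b)]], idx, sum))
  }
  ref <- tab$ref[!duplicated(tab$pos)][order(unique(tab$pos))]
  list(pos = pos, counts = m, ref = ref)
}

#' Majority-rule consensus from pooled base counts
#'
#' Per site, the base with the maximal count pooled over individuals. Ties
#' are broken toward the supplied reference base when it is among the tied
#' bases, otherwise alphabetically. Zero-depth sites yield `N`.
#'
#' @param tab multi-individual site table.
#' @param ref optional per-position reference base used for tie-breaking
#'   (defaults to the table's `ref` column).
#' @return character vector of consensus bases, one per position.
#' @export
consensus_from_counts <- function(tab, ref = NULL) {
  p <- pool_counts(tab)
  if (is.null(ref)) ref <- p$ref
  ref <- as_base_vector(ref)
  n <- nrow(p$counts)
  if (length(ref) != n) stop("reference length does not match the site table")
  best <- max.col(p$counts, ties.method = "first")  # alphabetical tie-break
  cons <- BASES[best]
  maxc <- p$counts[cbind(seq_len(n), best)]
  # prefer the reference base when it ties the maximum
  ref_idx <- match(ref, BASES)
  has_ref <- !is.na(ref_idx)
  ref_count <- rep(-1, n)
  ref_count[has_ref] <- p$counts[cbind(which(has_ref), ref_idx[has_ref])]
  tie_to_ref <- has_ref & ref_count == maxc
  cons[tie_to_ref] <- ref[tie_to_ref]
  zero <- rowSums(p$counts) == 0
  if (any(zero)) {
    message(sum(zero), " zero-depth site(s); consensus set to N")
    cons[zero] <- "N"
  }
  cons
}

#' Per-site sequencing error rates
#'
#' The error rate at a site is the count of non-consensus read bases divided
#' by the total depth there: `e = (depth - n_consensus) / depth`. Deletion
#' placeholders are excluded from both numerator and depth (substitutions
#' only). Sites with zero depth, or an `N` consensus, have no defined rate
#' and are returned as `NA`.
#'
#' @param tab site table (one individual, or several to pool).
#' @param consensus per-position consensus base (string or base vector).
#' @return list with `rates` (per-site data.frame: `pos`, `depth`, `e`) and
#'   `summary` (`mean`, `min`, `max` over defined sites).
#' @export
site_error_rates <- function(tab, consensus) {
  p <- pool_counts(tab)
  cons <- as_base_vector(consensus)
  if (length(cons) != nrow(p$counts)) {
    stop("consensus length (", length(cons), ") does not match the site table (",
         nrow(p$counts), " positions)")
  }
  depth <- rowSums(p$counts)
  ci <- match(cons, BASES)
  n_cons <- ifelse(is.na(ci), NA_real_, p$counts[cbind(seq_len(nrow(p$counts)), ci)])
  e <- ifelse(depth > 0 & !is.na(n_cons), (depth - n_cons) / depth, NA_real_)
  ok <- !is.na(e)
  list(rates = data.frame(pos = p$pos, depth = depth, e = e),
       summary = c(mean = mean(e[ok]), min = min(e[ok]), max = max(e[ok])))
}

#' Substitution spectrum and transition/transversion ratio
#'
#' Entry (x, y) is the pooled count of read base y at consensus-x sites
#' divided by the pooled depth at consensus-x sites; the diagonal holds the
#' match rates. The ti/tv ratio divides transition counts (A<->G, C<->T) by
#' all other substitution counts. Under uniform random sequencing error the
#' ratio tends to 0.5 (one transition versus two transversions per base),
#' far from the ratios typical of true biological variation.
#'
#' @param tab multi-individual site table.
#' @param consensus per-position consensus base.
#' @return list with `rates` (4x4 matrix, rows = consensus base; `NA` rows
#'   where no sites have that consensus), `counts` (4x4 substitution
#'   counts), `titv`.
#' @export
substitution_spectrum <- function(tab, consensus) {
  p <- pool_counts(tab)
  cons <- as_base_vector(consensus)
  if (length(cons) != nrow(p$counts)) stop("consensus length does not match the site table")
  counts <- matrix(0, 4L, 4L, dimnames = list(BASES, BASES))
  for (x in BASES) {
    sel <- cons == x
    if (any(sel)) counts[x, ] <- colSums(p$counts[sel, , drop = FALSE])
  }
  depth_by_cons <- rowSums(counts)
  rates <- counts / depth_by_cons
  rates[depth_by_cons == 0, ] <- NA_real_
  sub <- counts; diag(sub) <- 0
  ti <- sub["A", "G"] + sub["G", "A"] + sub["C", "T"] + sub["T", "C"]
  tv <- sum(sub) - ti
  list(rates = rates, counts = counts,
       titv = if (tv > 0) ti / tv else NA_real_)
}

IUPAC_MAP <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
               R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
               B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Scan a sequence for an IUPAC motif on both strands
#'
#' Finds every (possibly overlapping) occurrence of `pattern` on the plus
#' strand and of its reverse complement (reported as strand `-`). With
#' `circular = TRUE`, matches spanning the origin are also found; their
#' `start` is the wrapped 0-based coordinate and `end = start + nchar(pattern)`
#' may exceed the sequence length.
#'
#' @param sequence subject sequence (A/C/G/T/N string).
#' @param pattern IUPAC motif (e.g. `"CCNGCC"`); `N` matches any base.
#'   Ambiguity codes are wildcards in the pattern only; `N` in the subject
#'   matches nothing.
#' @param circular treat the sequence as circular.
#' @return data.frame with `start` (0-based), `end` (exclusive), `strand`,
#'   `pattern`.
#' @export
scan_iupac_motifs <- function(sequence, pattern, circular = FALSE) {
  pattern <- toupper(pattern)
  pl <- nchar(pattern)
  pat_chars <- strsplit(pattern, "")[[1L]]
  if (any(!pat_chars %in% names(IUPAC_MAP))) {
    stop("invalid IUPAC character in pattern: ",
         pat_chars[!pat_chars %in% names(IUPAC_MAP)][1L])
  }
  if (length(sequence) > 1L) sequence <- paste(sequence, collapse = "")
  L <- nchar(sequence)
  subj_str <- if (circular && L > 1L) {
    paste0(sequence, substr(sequence, 1L, min(pl - 1L, L)))
  } else {
    sequence
  }
  subj <- Biostrings::DNAString(subj_str)
  scan_one <- function(pat, strand) {
    hits <- Biostrings::matchPattern(pat, subj, fixed = "subject")
    st <- BiocGenerics::start(hits) - 1L
    st <- st[st < L]  # wrapped duplicates start beyond the original length
    if (!length(st)) return(NULL)
    data.frame(start = st, end = st + pl, strand = strand, pattern = pattern,
               stringsAsFactors = FALSE)
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
  out <- rbind(scan_one(pattern, "+"),
               if (rc != pattern) scan_one(rc, "-"))
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(),
                      strand = character(), pattern = character(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Coverage versus distance from error-prone motifs
#'
#' For each motif occurrence the error-prone flank is the `flank` positions
#' on the high-error side: upstream of a plus-strand hit (`[start - flank,
#' start)`) and downstream of a minus-strand hit (`[end, end + flank)`); the
#' motif `CCNGCC` sits directly downstream of the high-error base on the
#' plus strand. Every site falling in at least one flank enters the analysis
#' once, with distance equal to the minimum 1-based distance to its nearest
#' motif edge; the result is the Spearman rank correlation between coverage
#' and that distance (positive when coverage rises away from the motif).
#'
#' @param coverage per-site coverage over the region.
#' @param hits motif hits from [scan_iupac_motifs()] (coordinates within the
#'   region).
#' @param flank flank width in bp (default 100).
#' @param circular wrap flanks around the region ends.
#' @return list with `table` (`pos`, `dist`, `coverage`), `r`, `df`, `p`.
#' @export
motif_proximity_analysis <- function(coverage, hits, flank = 100L,
                                     circular = FALSE) {
  if (flank <= 0) stop("flank must be positive")
  if (!nrow(hits)) stop("no motif hits supplied")
  L <- length(coverage)
  dist_at <- rep(Inf, L)
  for (i in seq_len(nrow(hits))) {
    d <- seq_len(flank)
    p <- if (hits$strand[i] == "+") hits$start[i] - d else hits$end[i] - 1L + d
    if (circular) {
      p <- p %% L
    } else {
      keep <- p >= 0L & p < L
      p <- p[keep]; d <- d[keep]
    }
    upd <- d < dist_at[p + 1L]
    dist_at[p[upd] + 1L] <- d[upd]
  }
  in_flank <- is.finite(dist_at)
  tab <- data.frame(pos = which(in_flank) - 1L, dist = dist_at[in_flank],
                    coverage = coverage[in_flank])
  ct <- spearman_test(tab$coverage, tab$dist)
  # all-tied coverage carries no ordering information: no association, r = 0
  if (is.na(ct$r) && length(unique(tab$coverage)) == 1L) {
    ct$r <- 0; ct$p <- 1
  }
  list(table = tab, r = ct$r, df = ct$df, p = ct$p)
}

#' Correlation between per-site error rate and coverage
#'
#' Spearman rank correlation over retained sites with a defined error rate;
#' `df = n - 2`. Constant inputs give an undefined (`NA`) correlation.
#'
#' @param error_rates per-site error rates (`NA` allowed).
#' @param coverage per-site coverage (same length).
#' @return list with `r`, `df`, `p`, `n`.
#' @export
error_coverage_correlation <- function(error_rates, coverage) {
  if (length(error_rates) != length(coverage)) stop("input lengths differ")
  spearman_test(coverage, error_rates)
}

#' Call candidate heteroplasmic sites from a multi-individual site table
#'
#' A site is called heteroplasmic when exactly one individual carries one
#' specific non-consensus base at frequency at least `high_freq` (with depth
#' at least `min_depth`) while every other individual shows that base at
#' frequency at most `low_freq`. Sites where two or more individuals exceed
#' `high_freq` for the same base are reported separately as shared variants
#' (candidate polymorphisms, not heteroplasmy).
#'
#' @param tab site table with at least two individuals.
#' @param consensus per-position consensus base.
#' @param high_freq minimum carrier frequency (default 0.01).
#' @param low_freq maximum frequency in every other individual
#'   (default 0.001).
#' @param min_depth minimum carrier depth (default 100).
#' @return list with `heteroplasmy` (data.frame: `pos`,
#'   `carrier_individual`, `alt_base`, `alt_freq`, `max_other_freq`) and
#'   `shared` (data.frame: `pos`, `base`, `n_carriers`).
#' @export
call_heteroplasmy <- function(tab, consensus, high_freq = 0.01,
                              low_freq = 0.001, min_depth = 100L) {
  inds <- unique(tab$individual)
  if (length(inds) < 2L) stop("heteroplasmy criterion needs at least 2 individuals")
  cons <- as_base_vector(consensus)
  pos <- sort(unique(tab$pos))
  if (length(cons) != length(pos)) stop("consensus length does not match the site table")
  pidx <- match(tab$pos, pos)
  iidx <- match(tab$individual, inds)
  np <- length(pos); ni <- length(inds)
  depth <- matrix(0, np, ni); depth[cbind(pidx, iidx)] <- tab$depth
  het <- list(); shared <- list()
  for (b in BASES) {
    cnt <- matrix(0, np, ni)
    cnt[cbind(pidx, iidx)] <- tab[[paste0("n_", b)]]
    freq <- ifelse(depth > 0, cnt / depth, NA_real_)
    eligible <- cons != b & cons %in% BASES
    over <- freq >= high_freq & depth >= min_depth
    over[is.na(over)] <- FALSE
    n_over <- rowSums(over)
    # shared variants: two or more carriers of the same non-consensus base
    sh <- eligible & n_over >= 2L
    if (any(sh)) {
      shared[[b]] <- data.frame(pos = pos[sh], base = b,
                                n_carriers = n_over[sh],
                                stringsAsFactors = FALSE)
    }
    cand <- which(eligible & n_over == 1L)
    for (s in cand) {
      carrier <- which(over[s, ])
      others <- freq[s, -carrier]
      if (anyNA(others)) next  # zero-depth individual: not callable
      if (all(others <= low_freq)) {
        het[[length(het) + 1L]] <- data.frame(
          pos = pos[s], carrier_individual = inds[carrier], alt_base = b,
          alt_freq = freq[s, carrier], max_other_freq = max(others),
          stringsAsFactors = FALSE)
      }
    }
  }
  empty_het <- data.frame(pos = integer(), carrier_individual = character(),
                          alt_base = character(), alt_freq = numeric(),
                          max_other_freq = numeric(), stringsAsFactors = FALSE)
  empty_sh <- data.frame(pos = integer(), base = character(),
                         n_carriers = integer(), stringsAsFactors = FALSE)
  het <- if (length(het)) do.call(rbind, het) else empty_het
  shared <- if (length(shared)) do.call(rbind, shared) else empty_sh
  list(heteroplasmy = het[order(het$pos), , drop = FALSE],
       shared = shared[order(shared$pos), , drop = FALSE])
}
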