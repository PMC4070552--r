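#' Fold the circular-mapping overlap back onto the reference
#'
#' Circular genomes are mapped against a linearised reference extended by `o`
#' bases copied from its start, so that reads spanning the origin still map.
#' This adds the coverage observed on the extension back onto the first `o`
#' reference positions. Total coverage mass is conserved.
#'
#' @param extended_values per-site depth over `L_ref + o` sites.
#' @param L_ref reference length (sites).
#' @param o overlap length in bp (`0 <= o < L_ref`).
#' @return per-site depth over `L_ref` sites.
#' @export
fold_circular_overlap <- function(extended_values, L_ref, o) {
  if (o < 0 || o >= L_ref) stop("overlap must satisfy 0 <= o < L_ref")
  if (length(extended_values) != L_ref + o) {
    stop("extended profile has length ", length(extended_values),
         ", expected L_ref + o = ", L_ref + o)
  }
  out <- extended_values[seq_len(L_ref)]
  if (o > 0) {
    out[seq_len(o)] <- out[seq_len(o)] + extended_values[L_ref + seq_len(o)]
  }
  out
}

#' Trim a coverage profile to the retained region
#'
#' Ends of the linearised circular reference (and the repeat-rich control
#' region) accumulate mapping artefacts; downstream analyses use only the
#' retained span. Bounds are 1-based inclusive.
#'
#' @param values per-site values over the full reference.
#' @param first_kept,last_kept 1-based inclusive retained span.
#' @return list with `values` (retained span) and `n_trimmed` (sites removed).
#' @export
trim_retained_region <- function(values, first_kept, last_kept) {
  L <- length(values)
  if (first_kept < 1 || last_kept < first_kept || last_kept > L) {
    stop("retained region [", first_kept, ", ", last_kept,
         "] is not within 1..", L)
  }
  kept <- values[first_kept:last_kept]
  list(values = kept, n_trimmed = L - length(kept),
       first_kept = first_kept, last_kept = last_kept)
}

#' Percentage of reads mapping to the target
#'
#' @param n_mapped,n_total read counts, `0 <= n_mapped <= n_total`.
#' @return `100 * n_mapped / n_total` (percent).
#' @export
mapped_read_fraction <- function(n_mapped, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_mapped < 0 || n_mapped > n_total) stop("n_mapped must be in [0, n_total]")
  100 * n_mapped / n_total
}

#' Scale coverage profiles to a common mean
#'
#' Multiplies every profile by `mean(reference)/mean(self)` so that all
#' profiles share the reference individual's mean coverage; the reference
#' itself is unchanged. Used before visual and rank-based comparison of
#' individuals sequenced to very different depths.
#'
#' @param profiles numeric matrix, sites x individuals, with column names.
#' @param reference_id column name of the reference individual.
#' @return matrix of the same shape with rescaled columns.
#' @export
scale_to_reference_mean <- function(profiles, reference_id) {
  if (!reference_id %in% colnames(profiles)) {
    stop("reference individual '", reference_id, "' not found")
  }
  means <- colMeans(profiles)
  if (any(means <= 0)) {
    stop("profile(s) with non-positive mean cannot be scaled: ",
         paste(colnames(profiles)[means <= 0], collapse = ", "))
  }
  sweep(profiles, 2L, means[reference_id] / means, `*`)
}

#' Window a region into GC fraction and mean coverage
#'
#' Slides a window of `w` bp with step `s` across the region (use `s = w`
#' for non-overlapping windows); a trailing partial window is discarded. The
#' GC fraction excludes `N` bases from both numerator and denominator.
#'
#' @param sequence character string (or character vector of single bases)
#'   over the region.
#' @param coverage per-site coverage over the same region.
#' @param w window size (bp); `s` step (bp).
#' @return data.frame with `window_start` (0-based), `gc`, `mean_cov`;
#'   attributes `w` and `s`.
#' @export
window_profile <- function(sequence, coverage, w, s = w) {
  bases <- as_base_vector(sequence)
  L <- length(bases)
  if (length(coverage) != L) stop("sequence and coverage lengths differ")
  if (w > L) stop("window size ", w, " exceeds region length ", L)
  if (s < 1) stop("step must be >= 1")
  starts <- seq(0L, L - w, by = s)
  is_g_or_c <- bases %in% c("G", "C")
  is_known <- bases != "N"
  cum_gc <- cumsum(c(0L, is_g_or_c))
  cum_known <- cumsum(c(0L, is_known))
  cum_cov <- cumsum(c(0, coverage))
  gc_num <- cum_gc[starts + w + 1L] - cum_gc[starts + 1L]
  gc_den <- cum_known[starts + w + 1L] - cum_known[starts + 1L]
  out <- data.frame(
    window_start = starts,
    gc = ifelse(gc_den > 0L, gc_num / gc_den, NA_real_),
    mean_cov = (cum_cov[starts + w + 1L] - cum_cov[starts + 1L]) / w
  )
  attr(out, "w") <- w
  attr(out, "s") <- s
  out
}

# Accept either a single string or a per-base character vector.
as_base_vector <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    strsplit(sequence, "", fixed = TRUE)[[1L]]
  } else {
    as.character(sequence)
  }
}

#' Per-site GC fraction of a centered window
#'
#' GC fraction of the `width`-bp window centered on each site, used as the
#' continuous covariate in the site-level ANCOVA and as the coverage model's
#' GC input in the simulator. The window is truncated at the region edges
#' unless `circular = TRUE`, in which case it wraps.
#'
#' @param sequence region sequence (string or base vector).
#' @param width window width in bp.
#' @param circular wrap around the ends instead of truncating.
#' @return numeric vector of per-site GC fractions (Ns excluded).
#' @export
gc_by_site <- function(sequence, width = 50L, circular = FALSE) {
  bases <- as_base_vector(sequence)
  isgc <- as.numeric(bases %in% c("G", "C"))
  known <- as.numeric(bases != "N")
  kern <- rep(1, width)
  if (circular) {
    num <- as.numeric(stats::filter(isgc, kern, circular = TRUE))
    den <- as.numeric(stats::filter(known, kern, circular = TRUE))
  } else {
    half_lo <- floor((width - 1) / 2)
    half_hi <- width - 1 - half_lo
    L <- length(bases)
    cg <- cumsum(c(0, isgc)); ck <- cumsum(c(0, known))
    lo <- pmax(1L, seq_len(L) - half_lo)
    hi <- pmin(L, seq_len(L) + half_hi)
    num <- cg[hi + 1L] - cg[lo]
    den <- ck[hi + 1L] - ck[lo]
  }
  ifelse(den > 0, num / den, NA_real_)
}

#' Build a sites-by-individuals coverage matrix from a site table
#'
#' @param tab multi-individual site table (see [parse_pileup()]).
#' @return numeric matrix with one row per position (ascending) and one
#'   column per individual, filled with `depth`.
#' @export
coverage_matrix <- function(tab) {
  inds <- unique(tab$individual)
  pos <- sort(unique(tab$pos))
  mat <- matrix(NA_real_, length(pos), length(inds),
                dimnames = list(NULL, inds))
  pidx <- match(tab$pos, pos)
  iidx <- match(tab$individual, inds)
  mat[cbind(pidx, iidx)] <- tab$depth
  if (anyNA(mat)) stop("site table does not cover every position for every individual")
  attr(mat, "pos") <- pos
  mat
}
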