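#' Pairwise Spearman correlation of coverage profiles
#'
#' Rank correlation of per-site coverage for every unordered pair of
#' individuals (profiles should first be scaled to a common mean, although
#' rank correlation is invariant to the scaling itself). Constant profiles
#' give undefined (`NA`) entries.
#'
#' @param profiles sites x individuals matrix with column names.
#' @return list with matrices `r` and `p` (unit diagonal / zero diagonal)
#'   and the common `df = n - 2`.
#' @export
pairwise_profile_correlation <- function(profiles) {
  ni <- ncol(profiles)
  if (ni < 2L) stop("need at least 2 profiles")
  if (nrow(profiles) < 3L) stop("need at least 3 sites")
  ids <- colnames(profiles)
  r <- matrix(NA_real_, ni, ni, dimnames = list(ids, ids))
  p <- matrix(NA_real_, ni, ni, dimnames = list(ids, ids))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(ni - 1L)) {
    for (j in (i + 1L):ni) {
      ct <- spearman_test(profiles[, i], profiles[, j])
      r[i, j] <- r[j, i] <- ct$r
      p[i, j] <- p[j, i] <- ct$p
    }
  }
  list(r = r, p = p, df = nrow(profiles) - 2L)
}

#' Rank windows by cross-individual concordance of coverage
#'
#' Within each window of `w` sites, the coefficient of variation (sd/mean)
#' of the window-mean coverage across individuals. Profiles must already be
#' scaled to a common mean (see [scale_to_reference_mean()]); low CV marks
#' regions where independently sequenced individuals agree.
#'
#' @param profiles sites x individuals matrix (scaled).
#' @param w window width in sites; trailing partial window discarded.
#' @return data.frame `window_start` (0-based), `cv`, sorted ascending by
#'   `cv` (most concordant first).
#' @export
concordance_windows <- function(profiles, w) {
  L <- nrow(profiles)
  if (w > L) stop("window width ", w, " exceeds profile length ", L)
  starts <- seq(0L, L - w, by = w)
  cv <- vapply(starts, function(s) {
    wm <- colMeans(profiles[(s + 1L):(s + w), , drop = FALSE])
    stats::sd(wm) / mean(wm)
  }, 0)
  out <- data.frame(window_start = starts, cv = cv)
  out[order(out$cv), , drop = FALSE]
}

#' Column map of a pairwise alignment read from multi-FASTA blocks
#'
#' The input carries one aligned block per pair of consecutive records (two
#' equal-length gapped rows, gap character `-`). Per column the 0-based
#' coordinate in each species advances only on non-gap characters; identity
#' is the fraction of matching bases among columns ungapped in both rows.
#'
#' @param input path to an aligned multi-FASTA or character vector of its
#'   lines.
#' @return list with `map` (data.frame `block`, `column`, `pos_a`, `pos_b`;
#'   `NA` at gaps) and `identity` (overall, over both-ungapped columns).
#' @export
alignment_column_map <- function(input) {
  path <- input
  if (!(length(input) == 1L && file.exists(input))) {
    path <- tempfile(fileext = ".fa")
    on.exit(unlink(path))
    writeLines(input, path)
  }
  set <- Biostrings::readBStringSet(path)  # block ids may repeat across rows
  seqs <- toupper(as.character(set))
  if (length(seqs) %% 2L != 0L) {
    stop("alignment input must contain two records per block; found ",
         length(seqs), " records")
  }
  maps <- list(); match_n <- 0; ungapped_n <- 0
  for (b in seq_len(length(seqs) / 2L)) {
    a <- strsplit(seqs[[2L * b - 1L]], "", fixed = TRUE)[[1L]]
    bb <- strsplit(seqs[[2L * b]], "", fixed = TRUE)[[1L]]
    if (length(a) != length(bb)) {
      stop("block ", b, ": aligned rows have unequal lengths (",
           length(a), " vs ", length(bb), ")")
    }
    ga <- a == "-"; gb <- bb == "-"
    pos_a <- cumsum(!ga) - 1L; pos_a[ga] <- NA_integer_
    pos_b <- cumsum(!gb) - 1L; pos_b[gb] <- NA_integer_
    both <- !ga & !gb
    match_n <- match_n + sum(a[both] == bb[both])
    ungapped_n <- ungapped_n + sum(both)
    maps[[b]] <- data.frame(block = b, column = seq_along(a) - 1L,
                            pos_a = pos_a, pos_b = pos_b)
  }
  list(map = do.call(rbind, maps),
       identity = if (ungapped_n > 0) match_n / ungapped_n else NA_real_)
}

#' Cross-species coverage correlation over homologous aligned sites
#'
#' Spearman rank correlation of per-site coverage between two species over
#' alignment columns ungapped in both, pooled across blocks (per-block
#' correlations are reported alongside). Coordinates in the map are relative
#' to each profile's first site.
#'
#' @param profile_a,profile_b per-site coverage vectors for the two species.
#' @param map column map from [alignment_column_map()] (its `map` element or
#'   the full return value).
#' @return list with `r`, `df`, `p`, `n_sites`, and `per_block`
#'   (data.frame `block`, `r`, `n_sites`).
#' @export
cross_species_site_correlation <- function(profile_a, profile_b, map) {
  if (is.list(map) && !is.data.frame(map)) map <- map$map
  use <- !is.na(map$pos_a) & !is.na(map$pos_b)
  m <- map[use, , drop = FALSE]
  if (any(m$pos_a >= length(profile_a)) || any(m$pos_b >= length(profile_b))) {
    stop("alignment positions fall outside the coverage profiles")
  }
  if (nrow(m) < 3L) stop("fewer than 3 usable alignment columns")
  xa <- profile_a[m$pos_a + 1L]
  xb <- profile_b[m$pos_b + 1L]
  ct <- spearman_test(xa, xb)
  per_block <- do.call(rbind, lapply(split(seq_len(nrow(m)), m$block), function(i) {
    rb <- if (length(i) >= 3L) spearman_test(xa[i], xb[i])$r else NA_real_
    data.frame(block = m$block[i[1L]], r = rb, n_sites = length(i))
  }))
  rownames(per_block) <- NULL
  list(r = ct$r, df = ct$df, p = ct$p, n_sites = nrow(m),
       per_block = per_block)
}
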