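#' Count k-mers in a set of reads
#'
#' Exact hash-based counting of all length-`k` substrings of the reads.
#' K-mers spanning a non-ACGT base contribute nothing. In canonical mode
#' (the default) each k-mer is identified with the lexicographic minimum of
#' itself and its reverse complement, so the strand of origin does not
#' matter. The result is the k-mer spectrum: the histogram of multiplicities
#' (how many distinct k-mers were seen 1x, 2x, ...).
#'
#' Counting is exact and in-memory; it is intended for desk-scale read sets
#' (up to roughly 1e7 k-mer instances), not production genome data.
#'
#' @param reads character vector of read sequences, or a path to a FASTQ or
#'   FASTA file.
#' @param k k-mer length in bp.
#' @param canonical collapse each k-mer with its reverse complement.
#' @return object of class `kmer_spectrum`: list with `k`, `canonical`,
#'   `histogram` (data.frame `multiplicity`, `n_kmers`),
#'   `total_instances`.
#' @export
count_kmers <- function(reads, k, canonical = TRUE) {
  if (k < 1) stop("k must be >= 1")
  if (length(reads) == 1L && file.exists(reads)) reads <- read_reads(reads)
  reads <- toupper(reads)
  lens <- nchar(reads)
  usable <- lens >= k
  if (!any(usable)) {
    warning("k = ", k, " exceeds every read length; empty spectrum")
    return(new_spectrum(integer(), k, canonical))
  }
  reads <- reads[usable]; lens <- lens[usable]
  km <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    n <- lens[i] - k + 1L
    starts <- seq_len(n)
    fwd <- substring(reads[i], starts, starts + k - 1L)
    if (canonical) {
      rc <- revcomp(reads[i])
      rck <- substring(rc, lens[i] - k + 2L - starts, lens[i] + 1L - starts)
      fwd <- pmin(fwd, rck)
    }
    km[[i]] <- fwd
  }
  km <- unlist(km, use.names = FALSE)
  km <- km[!grepl("[^ACGT]", km)]
  mult <- table(km)
  new_spectrum(as.integer(table(as.integer(mult))), k, canonical,
               mult_levels = as.integer(names(table(as.integer(mult)))))
}

new_spectrum <- function(counts, k, canonical, mult_levels = integer()) {
  hist <- data.frame(multiplicity = mult_levels, n_kmers = counts)
  structure(list(k = k, canonical = canonical, histogram = hist,
                 total_instances = sum(as.numeric(hist$multiplicity) * hist$n_kmers)),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("k-mer spectrum: k = %d, %s, %d distinct multiplicities, %.0f instances\n",
              x$k, if (x$canonical) "canonical" else "stranded",
              nrow(x$histogram), x$total_instances))
  invisible(x)
}

#' Build a spectrum object from an explicit multiplicity histogram
#'
#' @param multiplicity,n_kmers parallel vectors: each multiplicity and the
#'   number of distinct k-mers seen that many times.
#' @param k k-mer length the histogram refers to.
#' @param canonical whether the underlying counting was canonical.
#' @return a `kmer_spectrum` object.
#' @export
spectrum_from_histogram <- function(multiplicity, n_kmers, k = 25L,
                                    canonical = TRUE) {
  ord <- order(multiplicity)
  new_spectrum(as.integer(n_kmers[ord]), k, canonical,
               mult_levels = as.integer(multiplicity[ord]))
}

# reverse complement of a single sequence string
revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

read_reads <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(character())
  if (startsWith(lines[1L], "@")) {
    if (length(lines) %% 4L != 0L) stop("FASTQ line count is not a multiple of 4")
    lines[seq(2L, length(lines), by = 4L)]
  } else if (startsWith(lines[1L], ">")) {
    unname(read_fasta(lines, single = FALSE))
  } else {
    stop("reads file is neither FASTQ nor FASTA")
  }
}

#' Locate the error/signal multiplicity cutoff in a bimodal spectrum
#'
#' Sequencing errors create a mass of low-multiplicity k-mers well below the
#' main peak at the mean k-mer coverage; the boundary is the first local
#' minimum of the smoothed histogram between the two modes. The histogram is
#' expanded onto a dense multiplicity grid, `log1p`-transformed, smoothed
#' with a 3-bin moving median, and scanned left to right for the first bin
#' that is no higher than its left neighbour and strictly lower than its
#' right neighbour, with some later bin rising above it (the main peak). A
#' spectrum with no such valley (e.g. strictly decreasing) is an error,
#' prompting a manual cutoff. An explicit `cutoff` bypasses detection and is
#' returned verbatim.
#'
#' @param spectrum a `kmer_spectrum`.
#' @param cutoff optional user-supplied multiplicity cutoff.
#' @return the multiplicity cutoff: k-mers with multiplicity strictly below
#'   it are treated as error k-mers.
#' @export
find_error_threshold <- function(spectrum, cutoff = NULL) {
  if (!is.null(cutoff)) return(cutoff)
  h <- spectrum$histogram
  if (!nrow(h)) stop("empty spectrum")
  maxm <- max(h$multiplicity)
  dense <- numeric(maxm)
  dense[h$multiplicity] <- h$n_kmers
  sm <- as.numeric(stats::runmed(log1p(dense), 3L))
  valley <- NA_integer_
  for (v in seq.int(2L, length.out = max(0L, length(sm) - 2L))) {
    if (sm[v] <= sm[v - 1L] && sm[v] < sm[v + 1L]) { valley <- v; break }
  }
  if (is.na(valley) || !any(sm[(valley + 1L):length(sm)] > sm[valley])) {
    stop("spectrum has no detectable valley between an error mode and a main ",
         "peak; supply an explicit cutoff")
  }
  valley
}

#' Error fraction and per-base error rate from a k-mer spectrum
#'
#' K-mer instances with multiplicity strictly below the cutoff are
#' attributed to sequencing errors. Since a single base miscall corrupts up
#' to `k` overlapping k-mers, the per-base error rate is the error-instance
#' fraction divided by `k`.
#'
#' @param spectrum a `kmer_spectrum`.
#' @param cutoff multiplicity cutoff (see [find_error_threshold()]).
#' @return list with `error_instances`, `total_instances`,
#'   `error_fraction`, `per_base_error`.
#' @export
kmer_error_rate <- function(spectrum, cutoff) {
  if (cutoff < 1) stop("cutoff must be >= 1")
  h <- spectrum$histogram
  if (!nrow(h)) stop("empty spectrum")
  err <- sum(as.numeric(h$multiplicity[h$multiplicity < cutoff]) *
               h$n_kmers[h$multiplicity < cutoff])
  tot <- spectrum$total_instances
  frac <- err / tot
  list(error_instances = err, total_instances = tot,
       error_fraction = frac, per_base_error = frac / spectrum$k)
}

#' Peak multiplicity (mean k-mer coverage) of a spectrum
#'
#' The mean multiplicity of the k-mers at or above the error cutoff (each
#' distinct k-mer weighted once). For a unimodal genuine-k-mer mode this is
#' the mean k-mer coverage M and coincides with the histogram peak, while
#' being much less noisy than the raw argmax on finite data.
#'
#' @param spectrum a `kmer_spectrum`.
#' @param cutoff error cutoff; bins below it are ignored.
#' @return the peak multiplicity M (mean k-mer coverage).
#' @export
spectrum_peak <- function(spectrum, cutoff = 1L) {
  h <- spectrum$histogram
  h <- h[h$multiplicity >= cutoff, , drop = FALSE]
  if (!nrow(h)) stop("no spectrum mass at or above the cutoff")
  sum(as.numeric(h$multiplicity) * h$n_kmers) / sum(h$n_kmers)
}

#' Base-level sequencing depth from the k-mer coverage peak
#'
#' A read of length L contains L - k + 1 k-mers, so the mean k-mer coverage
#' M understates the base-level depth N by the factor (L - k + 1)/L; the
#' inverse correction is `N = M * L / (L - k + 1)`. (This is the form
#' consistent with reported value pairs such as M = 52,000 with N = 68,000
#' at k = 25.)
#'
#' @param M mean k-mer coverage (peak multiplicity).
#' @param L mean read length in bp (`L > k`).
#' @param k k-mer length in bp.
#' @return base-level depth N (X).
#' @export
depth_from_peak <- function(M, L, k) {
  if (M <= 0) stop("M must be positive")
  if (L <= k) stop("mean read length must exceed k")
  M * L / (L - k + 1)
}
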