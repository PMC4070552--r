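# Independent oracles, deliberately naive and separate from the package code.

# Exhaustive-rank Spearman: midranks by pairwise counting, Pearson by the
# explicit sum formula.
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(seq_along(v), function(i) {
      1 + sum(v < v[i]) + (sum(v == v[i]) - 1) / 2
    }, 0)
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# Welch statistic straight from the formula.
oracle_welch <- function(a, b) {
  se2 <- var(a) / length(a) + var(b) / length(b)
  tval <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((var(a) / length(a))^2 / (length(a) - 1) +
                   (var(b) / length(b))^2 / (length(b) - 1))
  list(t = tval, df = df)
}

# Regex-based overlapping IUPAC motif scan (one strand, linear).
oracle_motif_starts <- function(sequence, pattern) {
  cls <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  rex <- paste0("(?=", paste(cls[strsplit(pattern, "")[[1]]], collapse = ""), ")")
  m <- gregexpr(rex, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Random legal pileup base string for a given count vector; returns the
# string with decorations (starts, ends, indels, skips) sprinkled in.
random_base_string <- function(n_ref, nA, nC, nG, nT, ndel, ref) {
  syms <- c(rep(".", n_ref), rep("A", nA), rep("C", nC), rep("G", nG),
            rep("T", nT), rep("*", ndel))
  syms <- sample(syms)
  out <- character(0)
  for (s in syms) {
    if (runif(1) < 0.1) s <- paste0("^", rawToChar(as.raw(sample(33:90, 1))), s)
    if (runif(1) < 0.1) s <- paste0(s, "$")
    if (runif(1) < 0.08) {
      len <- sample(1:3, 1)
      s <- paste0(s, sample(c("+", "-"), 1), len,
                  paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""))
    }
    out <- c(out, s)
  }
  paste(out, collapse = "")
}

# Small deterministic site table: one individual, explicit counts.
make_site_table <- function(counts, ref, individual = "ind1") {
  # counts: matrix with columns A,C,G,T (rows = sites)
  data.frame(individual = individual, pos = seq_len(nrow(counts)) - 1L,
             ref = ref,
             n_A = counts[, 1], n_C = counts[, 2],
             n_G = counts[, 3], n_T = counts[, 4],
             n_del = 0L, depth = rowSums(counts),
             stringsAsFactors = FALSE)
}
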