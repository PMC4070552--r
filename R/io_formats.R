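#' Parse samtools mpileup text into a per-site base-count table
#'
#' Decodes the mpileup base-string dialect into strand-summed per-site counts
#' of A, C, G, T and deletion placeholders. Read-start markers (`^` plus the
#' following mapping-quality character) and read-end markers (`$`) are
#' consumed; indel runs (`+n<seq>` / `-n<seq>`) are consumed without
#' contributing site bases; `*` is counted as a deletion placeholder;
#' reference-skip symbols (`<`, `>`) are ignored. `.` and `,` count toward
#' the reference base. Positions are converted from the 1-based pileup
#' convention to 0-based internal coordinates.
#'
#' Depth is recomputed from the decoded bases rather than trusted from the
#' pileup depth column; a mismatch is reported with a message and the decoded
#' value wins. When `ref_length` is given, positions absent from the stream
#' yield zero-count records (reference base `N`) so that the table always has
#' one record per reference position.
#'
#' @param input path to a pileup file, or a character vector of pileup lines.
#' @param individual_id identifier recorded in the `individual` column.
#' @param ref_length optional declared reference length (sites); missing
#'   positions are filled with zero-count records.
#' @return a site table: `data.frame` with columns `individual`, `pos`
#'   (0-based), `ref`, `n_A`, `n_C`, `n_G`, `n_T`, `n_del`, `depth`.
#' @export
parse_pileup <- function(input, individual_id, ref_length = NULL) {
  lines <- if (length(input) == 1L && file.exists(input)) readLines(input) else input
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    tab <- empty_site_table(individual_id)
    if (!is.null(ref_length)) tab <- fill_missing_sites(tab, individual_id, ref_length)
    return(tab)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop("pileup line ", which(nf < 6L)[1L], ": fewer than 6 tab-separated columns")
  }
  pos1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  if (anyNA(pos1)) stop("pileup line ", which(is.na(pos1))[1L], ": non-integer position")
  ref <- toupper(vapply(fields, `[[`, "", 3L))
  bad_ref <- !(ref %in% c("A", "C", "G", "T", "N"))
  if (any(bad_ref)) {
    stop("pileup line ", which(bad_ref)[1L], ": reference base '",
         ref[bad_ref][1L], "' is not one of A/C/G/T/N")
  }
  depth_col <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  bases <- vapply(fields, `[[`, "", 5L)

  dec <- decode_base_strings(bases, ref)
  if (!is.null(depth_col) && any(ok <- !is.na(depth_col) & depth_col != dec$depth)) {
    message(sum(ok), " pileup line(s) with depth column differing from decoded depth; ",
            "decoded value used")
  }
  tab <- data.frame(
    individual = individual_id, pos = pos1 - 1L, ref = ref,
    n_A = dec$A, n_C = dec$C, n_G = dec$G, n_T = dec$T,
    n_del = dec$del, depth = dec$depth,
    stringsAsFactors = FALSE
  )
  if (is.unsorted(tab$pos, strictly = TRUE)) {
    stop("pileup positions are not strictly increasing")
  }
  if (!is.null(ref_length)) tab <- fill_missing_sites(tab, individual_id, ref_length)
  tab
}

empty_site_table <- function(individual_id) {
  data.frame(individual = character(), pos = integer(), ref = character(),
             n_A = integer(), n_C = integer(), n_G = integer(), n_T = integer(),
             n_del = integer(), depth = integer(), stringsAsFactors = FALSE)
}

fill_missing_sites <- function(tab, individual_id, ref_length) {
  if (nrow(tab) && max(tab$pos) >= ref_length) {
    stop("pileup position ", max(tab$pos) + 1L, " exceeds declared reference length ",
         ref_length)
  }
  missing <- setdiff(seq_len(ref_length) - 1L, tab$pos)
  if (!length(missing)) return(tab)
  zero <- data.frame(individual = individual_id, pos = missing, ref = "N",
                     n_A = 0L, n_C = 0L, n_G = 0L, n_T = 0L,
                     n_del = 0L, depth = 0L, stringsAsFactors = FALSE)
  out <- rbind(tab, zero)
  out[order(out$pos), , drop = FALSE]
}

# Vectorised decoder for mpileup base strings. Start/end markers and indel
# runs are stripped first; what remains must consist solely of countable
# symbols, otherwise the offending line is reported.
decode_base_strings <- function(bases, ref) {
  s <- gsub("\\^.", "", bases, perl = TRUE)
  s <- gsub("$", "", s, fixed = TRUE)
  has_indel <- grepl("[+-][0-9]", s)
  for (i in which(has_indel)) {
    x <- s[i]
    repeat {
      m <- regexpr("[+-][0-9]+", x)
      if (m == -1L) break
      len <- as.integer(substr(x, m + 1L, m + attr(m, "match.length") - 1L))
      cut_end <- m + attr(m, "match.length") - 1L + len
      if (cut_end > nchar(x)) {
        stop("pileup line ", i, ": indel run of length ", len,
             " overruns the base string")
      }
      x <- paste0(substr(x, 1L, m - 1L), substr(x, cut_end + 1L, nchar(x)))
    }
    s[i] <- x
  }
  count_sym <- function(str, cls) nchar(str) - nchar(gsub(cls, "", str))
  n_ref_sym <- count_sym(s, "[.,]")
  nA <- count_sym(s, "[Aa]"); nC <- count_sym(s, "[Cc]")
  nG <- count_sym(s, "[Gg]"); nT <- count_sym(s, "[Tt]")
  ndel <- count_sym(s, "[*]")
  nskip <- count_sym(s, "[<>]")
  leftover <- nchar(s) - (n_ref_sym + nA + nC + nG + nT + ndel + nskip)
  if (any(leftover != 0L)) {
    i <- which(leftover != 0L)[1L]
    stop("pileup line ", i, ": base string contains ", leftover[i],
         " undecodable character(s)")
  }
  # '.'/',' accrue to the reference base; at an N reference they are dropped
  at_n <- ref == "N" & n_ref_sym > 0L
  if (any(at_n)) {
    message(sum(at_n), " line(s) with reference-match symbols at an N reference base; dropped")
    n_ref_sym[at_n] <- 0L
  }
  nA <- nA + ifelse(ref == "A", n_ref_sym, 0L)
  nC <- nC + ifelse(ref == "C", n_ref_sym, 0L)
  nG <- nG + ifelse(ref == "G", n_ref_sym, 0L)
  nT <- nT + ifelse(ref == "T", n_ref_sym, 0L)
  list(A = nA, C = nC, G = nG, T = nT, del = ndel, depth = nA + nC + nG + nT)
}

#' Write a site table as an mpileup-dialect text file
#'
#' Inverse of [parse_pileup()] for the symbols this pipeline uses: consensus
#' matches are emitted as `.`, substitutions as upper-case letters, deletion
#' placeholders as `*`; the quality column is a run of `I`. Round-trips
#' exactly through [parse_pileup()].
#'
#' @param tab a single-individual site table (see [parse_pileup()]).
#' @param path output file path.
#' @param chrom chromosome name written in column 1.
#' @export
write_pileup <- function(tab, path, chrom = "chrM") {
  stopifnot(length(unique(tab$individual)) <= 1L)
  tab <- tab[order(tab$pos), , drop = FALSE]
  base_str <- character(nrow(tab))
  for (b in c("A", "C", "G", "T")) {
    n <- tab[[paste0("n_", b)]]
    is_ref <- tab$ref == b
    base_str <- paste0(base_str,
                       ifelse(is_ref, strrep(".", n), strrep(b, n)))
  }
  base_str <- paste0(base_str, strrep("*", tab$n_del))
  # a site with nothing aligned still needs a non-empty column: use the
  # reference-skip symbol, which decodes back to zero counts
  base_str[!nzchar(base_str)] <- "<"
  lines <- paste(chrom, tab$pos + 1L, tab$ref, tab$depth, base_str,
                 strrep("I", pmax(1L, tab$depth)),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a (single- or multi-record) FASTA file
#'
#' Sequences are upper-cased and `U` is converted to `T`. In single-record
#' mode more than one record is an error, as is an empty file or duplicated
#' record names.
#'
#' @param input path to a FASTA file or character vector of FASTA lines.
#' @param single require exactly one record and return it directly.
#' @return in single mode, a list with `name` and `sequence`; otherwise a
#'   named character vector of sequences.
#' @export
read_fasta <- function(input, single = TRUE) {
  path <- input
  if (!(length(input) == 1L && file.exists(input))) {
    path <- tempfile(fileext = ".fa")
    on.exit(unlink(path))
    writeLines(input, path)
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot read FASTA: ", conditionMessage(e)))
  if (length(set) == 0L) stop("empty or headerless FASTA input")
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate FASTA record name: ", ids[duplicated(ids)][1L])
  seqs <- chartr("U", "T", toupper(as.character(set)))
  names(seqs) <- ids
  if (single) {
    if (length(seqs) != 1L) {
      stop("expected exactly one FASTA record, found ", length(seqs))
    }
    return(list(name = names(seqs), sequence = unname(seqs)))
  }
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences (or a list with `name` and
#'   `sequence` as returned by [read_fasta()]).
#' @param path output path.
#' @param width line-wrap width in bases.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.list(seqs) && !is.null(seqs$sequence)) {
    seqs <- stats::setNames(seqs$sequence, seqs$name)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (nchar(s)) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}

GENE_TYPES <- c("protein_coding", "tRNA", "rRNA", "intergenic")

#' Read a BED gene annotation and fill intergenic gaps
#'
#' BED intervals are 0-based half-open. The gene type is taken from column 7
#' when present, otherwise from a `gene|gene_type` tag in the name column.
#' Positions covered by no feature are assigned `intergenic`; where features
#' overlap, the first-listed feature wins (a warning reports the overlap).
#'
#' @param input path to a BED file or character vector of BED lines.
#' @param L_ref reference length (sites).
#' @return a list with `features` (data.frame `start`, `end`, `gene_type`,
#'   `strand`, `name`) covering every position exactly once, and
#'   `gene_type_by_site` (character vector of length `L_ref`).
#' @export
read_annotation_bed <- function(input, L_ref) {
  lines <- if (length(input) == 1L && file.exists(input)) readLines(input) else input
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines)) {
    feats <- data.frame(start = 0L, end = L_ref, gene_type = "intergenic",
                        strand = "+", name = ".", stringsAsFactors = FALSE)
    return(list(features = feats,
                gene_type_by_site = rep("intergenic", L_ref)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, "")
  }
  start <- as.integer(get(2L)); end <- as.integer(get(3L))
  name <- get(4L, ".")
  strand <- get(6L, "+"); strand[is.na(strand) | !(strand %in% c("+", "-"))] <- "+"
  gtype <- get(7L)
  miss <- is.na(gtype)
  if (any(miss)) {
    tag <- sub("^.*\\|", "", name[miss])
    gtype[miss] <- tag
  }
  if (any(bad <- !(gtype %in% GENE_TYPES))) {
    stop("BED line ", which(bad)[1L], ": gene_type '", gtype[bad][1L],
         "' not one of ", paste(GENE_TYPES, collapse = ", "))
  }
  if (any(bad <- start >= end)) stop("BED line ", which(bad)[1L], ": start >= end")
  if (any(bad <- end > L_ref)) {
    stop("BED line ", which(bad)[1L], ": end ", end[bad][1L],
         " exceeds reference length ", L_ref)
  }
  site_type <- rep(NA_character_, L_ref)
  overlapped <- FALSE
  for (i in seq_along(start)) {
    idx <- (start[i] + 1L):end[i]
    free <- is.na(site_type[idx])
    if (!all(free)) overlapped <- TRUE
    site_type[idx[free]] <- gtype[i]
  }
  if (overlapped) warning("overlapping BED features; first-listed feature wins")
  site_type[is.na(site_type)] <- "intergenic"
  list(features = data.frame(start = start, end = end, gene_type = gtype,
                             strand = strand, name = name,
                             stringsAsFactors = FALSE),
       gene_type_by_site = site_type)
}

SITE_TABLE_COLS <- c("individual", "pos", "ref", "n_A", "n_C", "n_G", "n_T",
                     "n_del", "depth")

#' Write / read the internal per-site count table as TSV
#'
#' Columns, in fixed order: `individual`, `pos` (0-based), `ref`, `n_A`,
#' `n_C`, `n_G`, `n_T`, `n_del`, `depth`. Reading verifies presence of every
#' column and the depth identity `depth == n_A + n_C + n_G + n_T`.
#'
#' @param tab site table (possibly several individuals stacked).
#' @param path TSV path.
#' @export
write_site_table <- function(tab, path) {
  missing <- setdiff(SITE_TABLE_COLS, names(tab))
  if (length(missing)) stop("site table is missing column(s): ",
                            paste(missing, collapse = ", "))
  utils::write.table(tab[SITE_TABLE_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c(individual = "character",
                                          ref = "character"),
                           stringsAsFactors = FALSE)
  missing <- setdiff(SITE_TABLE_COLS, names(tab))
  if (length(missing)) stop("site table is missing column(s): ",
                            paste(missing, collapse = ", "))
  tab <- tab[SITE_TABLE_COLS]
  bad <- tab$depth != tab$n_A + tab$n_C + tab$n_G + tab$n_T
  if (any(bad)) stop("site table row ", which(bad)[1L],
                     ": depth does not equal the sum of base counts")
  tab
}
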