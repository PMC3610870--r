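# Direct-repeat / excision-element sequence utilities: Hamming distance
# between repeats, genome-wide k-mer occurrence counting, and detection of
# direct repeats flanking an element. `N` in the genome never matches any
# k-mer or repeat base, so draft-genome gaps cannot create phantom repeats.

#' Hamming distance between two equal-length nucleotide strings
#'
#' Case-insensitive count of mismatching positions.
#'
#' @param a,b nucleotide strings of equal length.
#' @return integer mismatch count.
#' @export
#' @examples
#' hamming("GGATTACTCCG", "GGAATACTCCG")  # the two nifD flanking repeats: 1
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    length_error(sprintf("unequal lengths: %d vs %d", nchar(a), nchar(b)))
  }
  if (nchar(a) == 0L) return(0L)
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  sum(av != bv)
}

#' Count exact occurrences of a k-mer in a genome sequence
#'
#' Overlapping occurrences are counted by default. `N` in the genome matches
#' nothing; IUPAC ambiguity codes in the k-mer match their base sets.
#'
#' @param genome a sequence: character scalar, named character vector, or
#'   [Biostrings::DNAStringSet] (single contig, or give `contig_id`).
#' @param kmer the query k-mer (IUPAC alphabet).
#' @param both_strands also count occurrences of the reverse complement;
#'   palindromic sites are not double-counted.
#' @param overlapping count overlapping occurrences (default `TRUE`).
#' @param contig_id contig to scan when `genome` has several.
#' @return integer occurrence count.
#' @export
count_kmer <- function(genome, kmer, both_strands = FALSE,
                       overlapping = TRUE, contig_id = NULL) {
  seq_chr <- genome_as_character(genome, contig_id)
  kmer <- toupper(kmer)
  if (!nzchar(kmer) || nchar(kmer) > nchar(seq_chr)) {
    parameter_error("need 1 <= |kmer| <= genome length")
  }
  if (!is_iupac(kmer)) {
    format_error(sprintf("non-IUPAC character in k-mer '%s'", kmer))
  }
  pos_f <- kmer_positions(seq_chr, kmer, overlapping)
  if (!both_strands) return(length(pos_f))
  rc <- revcomp(kmer)
  pos_r <- kmer_positions(seq_chr, rc, overlapping)
  if (rc == kmer) {
    # palindrome: the same site on both strands is one occurrence
    return(length(union(pos_f, pos_r)))
  }
  length(pos_f) + length(pos_r)
}

kmer_positions <- function(seq_chr, kmer, overlapping) {
  re <- iupac_regex(kmer)
  if (overlapping) {
    m <- gregexpr(paste0("(?=", re, ")"), seq_chr, perl = TRUE)[[1]]
  } else {
    m <- gregexpr(re, seq_chr)[[1]]
  }
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Find direct repeats flanking an element
#'
#' Searches for equal-length sequence pairs, one ending within
#' `search_margin` nt left of the element and one starting within
#' `search_margin` nt right of it, whose Hamming distance is at most
#' `max_mismatch`. Only maximal pairs are reported: a pair contained in a
#' longer reported pair at the same left/right alignment is suppressed.
#'
#' @param genome sequence input as in [count_kmer()].
#' @param element_start,element_end 1-based inclusive element coordinates.
#' @param min_len,max_len repeat length range in nt (defaults 8 and 20).
#' @param max_mismatch maximum mismatches between the two copies (default 1).
#' @param search_margin how far from the element boundaries to search
#'   (default 100 nt); truncated with a warning at contig ends.
#' @param contig_id contig to scan when `genome` has several.
#' @return data.frame sorted by `length` descending then `mismatches`
#'   ascending: `left_start`, `left_end`, `right_start`, `right_end`
#'   (1-based inclusive), `left_seq`, `right_seq`, `length`, `mismatches`.
#' @export
find_flanking_repeats <- function(genome, element_start, element_end,
                                  min_len = 8L, max_len = 20L,
                                  max_mismatch = 1L, search_margin = 100L,
                                  contig_id = NULL) {
  seq_chr <- genome_as_character(genome, contig_id)
  L <- nchar(seq_chr)
  if (element_start < 1L || element_end > L || element_start > element_end) {
    coordinate_error("element outside the genome")
  }
  if (min_len < 1L || max_len < min_len) {
    parameter_error("need 1 <= min_len <= max_len")
  }
  left_lo <- element_start - search_margin
  right_hi <- element_end + search_margin
  if (left_lo < 1L || right_hi > L) {
    warning("search margin truncated at contig boundary")
    left_lo <- max(1L, left_lo)
    right_hi <- min(L, right_hi)
  }
  left_win <- c(left_lo, element_start - 1L)     # repeat fully left of element
  right_win <- c(element_end + 1L, right_hi)     # repeat fully right of it

  out <- list()
  for (len in seq(min_len, max_len)) {
    ls_range <- seq2(left_win[1], left_win[2] - len + 1L)
    rs_range <- seq2(right_win[1], right_win[2] - len + 1L)
    if (length(ls_range) == 0 || length(rs_range) == 0) next
    left_seqs <- substring(seq_chr, ls_range, ls_range + len - 1L)
    right_seqs <- substring(seq_chr, rs_range, rs_range + len - 1L)
    for (a in seq_along(ls_range)) {
      la <- left_seqs[a]
      if (grepl("N", la, fixed = TRUE)) next
      for (b in seq_along(rs_range)) {
        rb <- right_seqs[b]
        if (grepl("N", rb, fixed = TRUE)) next
        mm <- hamming(la, rb)
        if (mm <= max_mismatch) {
          out[[length(out) + 1L]] <- c(ls_range[a], rs_range[b], len, mm)
        }
      }
    }
  }
  cols <- c("left_start", "left_end", "right_start", "right_end",
            "left_seq", "right_seq", "length", "mismatches")
  if (length(out) == 0) {
    res <- data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      left_seq = character(), right_seq = character(),
                      length = integer(), mismatches = integer(),
                      stringsAsFactors = FALSE)
    return(res)
  }
  m <- do.call(rbind, out)
  df <- data.frame(left_start = m[, 1], right_start = m[, 2],
                   length = m[, 3], mismatches = m[, 4])
  # maximal pairs only: drop (ls, rs, len) if a reported pair (ls', rs',
  # len') with len' > len contains it at the same left/right alignment.
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    contained <- df$length > df$length[i] &
      df$left_start <= df$left_start[i] &
      df$left_start + df$length >= df$left_start[i] + df$length[i] &
      (df$left_start[i] - df$left_start) == (df$right_start[i] - df$right_start)
    if (any(contained)) keep[i] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  res <- data.frame(
    left_start = df$left_start,
    left_end = df$left_start + df$length - 1L,
    right_start = df$right_start,
    right_end = df$right_start + df$length - 1L,
    left_seq = substring(seq_chr, df$left_start, df$left_start + df$length - 1L),
    right_seq = substring(seq_chr, df$right_start, df$right_start + df$length - 1L),
    length = as.integer(df$length),
    mismatches = as.integer(df$mismatches),
    stringsAsFactors = FALSE)
  res <- res[order(-res$length, res$mismatches, res$left_start,
                   res$right_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# seq() that returns integer(0) when from > to
seq2 <- function(from, to) {
  if (from > to) integer(0) else seq.int(from, to)
}
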