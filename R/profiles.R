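# Strand-specific read 5'-end and coverage tracks.
#
# A `strand_profiles` object is a named list (one element per contig), each a
# list of four integer vectors of contig length — starts_plus, starts_minus,
# coverage_plus, coverage_minus — plus the contig length. Vectors are indexed
# 1..L over 0-based genome positions 0..L-1 (index = position + 1).

#' Build strand-specific start and coverage profiles from alignments
#'
#' For each contig and strand, `starts[p]` counts reads whose 5' end is at
#' 0-based position `p` (the leftmost aligned base for a plus-strand read, the
#' rightmost for a minus-strand read) and `coverage[p]` counts reads whose
#' aligned span overlaps `p` on that strand.
#'
#' @param alignments data.frame from [read_alignments()] (0-based half-open).
#' @param contigs a [Biostrings::DNAStringSet] or named vector of contig
#'   lengths.
#' @return a `strand_profiles` object.
#' @export
build_profiles <- function(alignments, contigs) {
  lens <- if (is.numeric(contigs)) contigs else contig_lengths(contigs)
  if (is.null(names(lens)) || any(names(lens) == "")) {
    parameter_error("contigs must be named")
  }
  aln <- as.data.frame(alignments)
  if (nrow(aln) > 0) {
    unknown <- setdiff(unique(aln$contig_id), names(lens))
    if (length(unknown) > 0) {
      coordinate_error(sprintf("alignment on unknown contig '%s'", unknown[1]))
    }
    L <- lens[aln$contig_id]
    if (any(aln$start < 0 | aln$end > L | aln$start >= aln$end)) {
      coordinate_error("alignment beyond contig bounds or empty interval")
    }
    if (any(!aln$strand %in% c("+", "-"))) {
      parameter_error("alignment strand must be '+' or '-'")
    }
  }
  prof <- lapply(names(lens), function(cid) {
    L <- unname(lens[[cid]])
    sub <- aln[aln$contig_id == cid, , drop = FALSE]
    tracks <- list(
      starts_plus = integer(L), starts_minus = integer(L),
      coverage_plus = integer(L), coverage_minus = integer(L)
    )
    for (s in c("+", "-")) {
      rr <- sub[sub$strand == s, , drop = FALSE]
      key <- if (s == "+") "plus" else "minus"
      if (nrow(rr) == 0) next
      five <- if (s == "+") rr$start else rr$end - 1L
      tracks[[paste0("starts_", key)]] <-
        tabulate(five + 1L, nbins = L)
      ir <- IRanges::IRanges(start = rr$start + 1L, end = rr$end)
      cov <- as.integer(IRanges::coverage(ir, width = L))
      tracks[[paste0("coverage_", key)]] <- cov
    }
    c(tracks, list(length = L))
  })
  names(prof) <- names(lens)
  structure(prof, class = "strand_profiles")
}

#' @export
print.strand_profiles <- function(x, ...) {
  cat(sprintf("strand_profiles: %d contig(s)\n", length(x)))
  for (cid in names(x)) {
    cat(sprintf("  %s (%d nt): %d plus / %d minus read starts\n", cid,
                x[[cid]]$length, sum(x[[cid]]$starts_plus),
                sum(x[[cid]]$starts_minus)))
  }
  invisible(x)
}

validate_profiles <- function(profiles) {
  if (!inherits(profiles, "strand_profiles")) {
    parameter_error("expected a strand_profiles object")
  }
  for (cid in names(profiles)) {
    p <- profiles[[cid]]
    for (s in c("plus", "minus")) {
      st <- p[[paste0("starts_", s)]]
      cv <- p[[paste0("coverage_", s)]]
      if (length(st) != p$length || length(cv) != p$length) {
        state_error(sprintf("track length mismatch on contig '%s'", cid))
      }
      if (any(st < 0) || any(cv < 0) || any(cv < st)) {
        state_error(sprintf(
          "invalid tracks on contig '%s': need coverage >= starts >= 0", cid))
      }
    }
  }
  invisible(profiles)
}
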