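# Spaced-dyad promoter motif scanning upstream of TSS.
#
# Offset convention: the TSS base is offset 0, the first upstream base is -1.
# A motif of length M starting at offset o occupies offsets o .. o+M-1 on the
# TSS strand; its reported center is offset o + floor((M-1)/2) (left-of-center
# base for even M). For the 14-nt GTA-N8-TAC dyad a hit whose first base is
# 47 nt upstream of the TSS therefore has start_offset -47 and center_offset
# -41, the canonical placement of an NtcA box.

#' Specify a spaced-dyad motif
#'
#' @param left_box IUPAC string, e.g. `"GTA"`.
#' @param spacer_length number of unconstrained positions between the boxes.
#' @param right_box IUPAC string, e.g. `"TAC"`.
#' @param variants optional alternate left boxes (e.g. `"GTG"`), scanned
#'   alongside the canonical one; hits record which box matched.
#' @return a `dyad_motif` list with the derived motif length.
#' @export
dyad_motif <- function(left_box = "GTA", spacer_length = 8L,
                       right_box = "TAC", variants = character()) {
  if (!nzchar(left_box) || !nzchar(right_box)) {
    parameter_error("motif boxes must be non-empty")
  }
  if (spacer_length < 0) parameter_error("`spacer_length` must be >= 0")
  boxes <- c(left_box, variants)
  if (length(unique(nchar(boxes))) != 1L) {
    parameter_error("all left-box variants must share the same length")
  }
  for (b in c(boxes, right_box)) {
    if (!is_iupac(b)) format_error(sprintf("non-IUPAC box '%s'", b))
  }
  structure(list(left_box = toupper(left_box),
                 spacer_length = as.integer(spacer_length),
                 right_box = toupper(right_box),
                 variants = toupper(variants),
                 motif_length = nchar(left_box) + spacer_length +
                   nchar(right_box)),
            class = "dyad_motif")
}

# Strand-aware upstream window: positions at offsets [from, to + M - 1]
# relative to the TSS, reverse-complemented for minus-strand TSS so that the
# returned string reads 5'->3' on the TSS strand. Truncated (with a warning)
# at contig boundaries.
extract_upstream <- function(seq_chr, position, strand, from, to_incl) {
  L <- nchar(seq_chr)
  if (strand == "+") {
    lo <- position + from
    hi <- position + to_incl
  } else {
    lo <- position - to_incl
    hi <- position - from
  }
  clipped_lo <- max(1L, lo)
  clipped_hi <- min(L, hi)
  if (clipped_lo > clipped_hi) {
    warning("search window lies entirely outside the contig")
    return(list(seq = "", from = from))
  }
  if (clipped_lo != lo || clipped_hi != hi) {
    warning("search window truncated at contig boundary")
  }
  s <- substr(seq_chr, clipped_lo, clipped_hi)
  if (strand == "-") s <- revcomp(s)
  # offset of the first character of `s`
  first_off <- if (strand == "+") clipped_lo - position else position - clipped_hi
  list(seq = s, from = first_off)
}

#' Scan upstream of TSS for a spaced-dyad motif
#'
#' @param genome a [Biostrings::DNAStringSet] or named character vector.
#' @param tss a TSS data.frame (any number of rows) with `contig_id`,
#'   `position`, `strand`.
#' @param motif a [dyad_motif()] specification.
#' @param search_from,search_to allowed range (inclusive) of the motif
#'   `start_offset`; both non-positive, `search_from < search_to`. Default
#'   `[-60, -20]` covers canonical NtcA positioning around -41.
#' @return data.frame with one row per hit: `tss_index`, `contig_id`,
#'   `tss_position`, `strand`, `matched_left_box`, `start_offset`,
#'   `center_offset`, sorted by TSS then `center_offset` ascending.
#' @export
scan_upstream <- function(genome, tss, motif = dyad_motif(),
                          search_from = -60L, search_to = -20L) {
  if (!inherits(motif, "dyad_motif")) {
    parameter_error("`motif` must be a dyad_motif()")
  }
  if (!(search_from < search_to) || search_to > 0) {
    parameter_error("need search_from < search_to <= 0")
  }
  tss <- as.data.frame(tss)
  seqs <- if (is(genome, "DNAStringSet")) toupper(as.character(genome)) else
    toupper(genome)
  M <- motif$motif_length
  boxes <- c(motif$left_box, motif$variants)
  box_res <- vapply(boxes, iupac_regex, character(1))
  spacer_re <- strrep("[ACGT]", motif$spacer_length)
  right_re <- iupac_regex(motif$right_box)
  nL <- nchar(motif$left_box)

  hits <- list()
  for (i in seq_len(nrow(tss))) {
    cid <- tss$contig_id[i]
    if (!cid %in% names(seqs)) {
      coordinate_error(sprintf("unknown contig '%s'", cid))
    }
    win <- extract_upstream(seqs[[cid]], tss$position[i], tss$strand[i],
                            search_from, search_to + M - 1L)
    if (!nzchar(win$seq)) next
    n <- nchar(win$seq)
    for (o in search_from:search_to) {
      j <- o - win$from + 1L           # 1-based index into the window
      if (j < 1L || j + M - 1L > n) next
      frag <- substr(win$seq, j, j + M - 1L)
      for (b in seq_along(boxes)) {
        re <- paste0("^", box_res[b], spacer_re, right_re, "$")
        if (grepl(re, frag)) {
          hits[[length(hits) + 1L]] <- data.frame(
            tss_index = i, contig_id = cid,
            tss_position = tss$position[i], strand = tss$strand[i],
            matched_left_box = substr(frag, 1L, nL),
            start_offset = o,
            center_offset = o + (M - 1L) %/% 2L,
            stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(tss_index = integer(), contig_id = character(),
                      tss_position = integer(), strand = character(),
                      matched_left_box = character(), start_offset = integer(),
                      center_offset = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, hits)
  res <- res[order(res$tss_index, res$center_offset), , drop = FALSE]
  rownames(res) <- NULL
  res
}
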