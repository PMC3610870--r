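# Positional TSS classification against a gene annotation.
#
# Candidate labels per TSS:
#   gTSS — same strand, within `upstream_max` nt upstream of a gene's
#          strand-aware start (offset 0 allowed: leaderless transcripts);
#   iTSS — same strand, strictly inside the gene body (first base excluded);
#   aTSS — opposite strand, within the gene body extended by
#          `antisense_flank` nt on both sides;
#   nTSS — none of the above (intergenic).
# Exactly one class is assigned using the priority order; the reported gene
# is the nearest qualifying one (smaller |offset|, then lexicographic id).

#' Classification parameters
#'
#' @param upstream_max maximum distance (nt) upstream of a gene start for a
#'   gene TSS (default 200).
#' @param antisense_flank extension (nt) of the gene body for the antisense
#'   test (default 0).
#' @param priority permutation of `c("gTSS","aTSS","iTSS","nTSS")` giving the
#'   exclusive assignment order.
#' @return a `classification_params` list.
#' @export
classification_params <- function(upstream_max = 200L, antisense_flank = 0L,
                                  priority = c("gTSS", "aTSS", "iTSS", "nTSS")) {
  if (upstream_max < 0) parameter_error("`upstream_max` must be >= 0")
  if (antisense_flank < 0) parameter_error("`antisense_flank` must be >= 0")
  if (!setequal(priority, c("gTSS", "aTSS", "iTSS", "nTSS")) ||
      length(priority) != 4L) {
    parameter_error("`priority` must be a permutation of the four classes")
  }
  structure(list(upstream_max = as.integer(upstream_max),
                 antisense_flank = as.integer(antisense_flank),
                 priority = priority),
            class = "classification_params")
}

#' Classify TSS records against annotated genes
#'
#' @param tss data.frame of TSS records from [detect_tss()].
#' @param genes data.frame of gene features from [read_gff()].
#' @param params a [classification_params()] list.
#' @return the TSS data.frame with `tss_class`, `gene_id` and `offset`
#'   filled. `offset` is signed nt relative to the associated gene's
#'   strand-aware start (negative = upstream); empty for nTSS.
#' @export
classify_tss <- function(tss, genes, params = classification_params()) {
  if (!inherits(params, "classification_params")) {
    params <- do.call(classification_params, as.list(params))
  }
  tss <- as.data.frame(tss)
  genes <- as.data.frame(genes)
  if (nrow(tss) == 0) return(empty_tss())
  if (nrow(genes) > 0) {
    unknown <- setdiff(unique(tss$contig_id), unique(genes$contig_id))
    if (length(unknown) > 0) {
      coordinate_error(sprintf(
        "TSS on contig '%s' absent from the annotation", unknown[1]))
    }
  }
  gstart <- ifelse(genes$strand == "+", genes$start, genes$end)

  tss$tss_class <- "nTSS"
  tss$gene_id <- ""
  tss$offset <- NA_integer_

  for (i in seq_len(nrow(tss))) {
    pos <- tss$position[i]
    s <- tss$strand[i]
    on_contig <- genes$contig_id == tss$contig_id[i]
    if (!any(on_contig)) next
    g <- which(on_contig)
    off <- ifelse(genes$strand[g] == "+", pos - gstart[g], gstart[g] - pos)
    same <- genes$strand[g] == s
    in_body <- pos >= genes$start[g] & pos <= genes$end[g]
    in_flank <- pos >= genes$start[g] - params$antisense_flank &
      pos <= genes$end[g] + params$antisense_flank
    qual <- list(
      gTSS = same & off <= 0L & off >= -params$upstream_max,
      iTSS = same & in_body & off >= 1L,
      aTSS = !same & in_flank,
      nTSS = rep(FALSE, length(g))
    )
    assigned <- FALSE
    for (cls in params$priority) {
      if (cls == "nTSS") break
      hit <- which(qual[[cls]])
      if (length(hit) == 0) next
      cand <- g[hit]
      o <- off[hit]
      ord <- order(abs(o), genes$gene_id[cand])
      tss$tss_class[i] <- cls
      tss$gene_id[i] <- genes$gene_id[cand][ord[1]]
      tss$offset[i] <- as.integer(o[ord[1]])
      assigned <- TRUE
      break
    }
    if (!assigned) {
      tss$tss_class[i] <- "nTSS"
    }
  }
  rownames(tss) <- NULL
  tss
}

#' Count TSS per positional class
#'
#' @param tss data.frame of classified TSS records.
#' @param path optional path; when given the table is written as TSV.
#' @return data.frame with one row per class (`gTSS`, `aTSS`, `iTSS`,
#'   `nTSS`) plus a `total` row, column `count`.
#' @export
summarize_classes <- function(tss, path = NULL) {
  tss <- as.data.frame(tss)
  if (nrow(tss) > 0 && any(tss$tss_class == "unclassified")) {
    state_error("unclassified TSS present; run classify_tss() first")
  }
  classes <- c("gTSS", "aTSS", "iTSS", "nTSS")
  counts <- vapply(classes, function(cl) sum(tss$tss_class == cl), integer(1))
  out <- data.frame(tss_class = c(classes, "total"),
                    count = c(counts, sum(counts)),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) write_tsv_with_header(out, path)
  out
}
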