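# TSS detection from strand-specific start/coverage profiles.
#
# Rule (per contig, per strand):
#  1. W(p): sum of read starts over a centred window of `window` nt,
#     truncated at contig ends.
#  2. p is a candidate iff starts[p] >= 1, W(p) >= min_window_reads, and
#     starts[p] is the maximum of starts within the window (ties broken
#     toward the 5'-most position on that strand).
#  3. Read-through enrichment: starts[p] >= (1 + enrichment_factor) x the
#     coverage at the first position strand-upstream of the window
#     (p - (window+1)/2 on '+', mirrored on '-'); reads starting inside the
#     window cannot cover that base, so it measures pure read-through.
#     Zero upstream coverage passes automatically.
#  4. Among surviving candidates closer than `window` nt apart on the same
#     strand, keep the one with greater starts (tie -> 5'-most).

#' Detection parameters
#'
#' @param min_window_reads minimum read starts within the window (default 280,
#'   matched to a ~40 M-read dRNA-seq library).
#' @param window odd window width in nt (default 7).
#' @param enrichment_factor required excess of starts over upstream
#'   read-through coverage (default 0.5, i.e. "50 percent larger").
#' @param normalize_per_million if `TRUE`, `min_window_reads` is interpreted
#'   as reads per million and scaled by `library_size / 1e6`.
#' @param library_size total mapped reads; required when normalizing.
#' @return a `detection_params` list.
#' @export
detection_params <- function(min_window_reads = 280L, window = 7L,
                             enrichment_factor = 0.5,
                             normalize_per_million = FALSE,
                             library_size = NULL) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L) {
    parameter_error("`window` must be an odd integer >= 1")
  }
  if (enrichment_factor < 0) {
    parameter_error("`enrichment_factor` must be >= 0")
  }
  if (min_window_reads < 0) {
    parameter_error("`min_window_reads` must be >= 0")
  }
  if (normalize_per_million && is.null(library_size)) {
    parameter_error("`library_size` is required when normalizing per million")
  }
  structure(list(min_window_reads = min_window_reads, window = window,
                 enrichment_factor = enrichment_factor,
                 normalize_per_million = normalize_per_million,
                 library_size = library_size),
            class = "detection_params")
}

empty_tss <- function() {
  data.frame(contig_id = character(), position = integer(),
             strand = character(), starts = integer(),
             window_reads = integer(), enrichment = numeric(),
             tss_class = character(), gene_id = character(),
             offset = integer(), stringsAsFactors = FALSE)
}

#' Detect transcriptional start sites
#'
#' @param profiles a `strand_profiles` object from [build_profiles()].
#' @param params a [detection_params()] list.
#' @return data.frame of unclassified TSS records sorted by contig then
#'   position: `contig_id`, `position` (1-based), `strand`, `starts`,
#'   `window_reads`, `enrichment` (`Inf` when upstream coverage is 0),
#'   `tss_class` (`"unclassified"`), `gene_id`, `offset`.
#' @export
detect_tss <- function(profiles, params = detection_params()) {
  validate_profiles(profiles)
  if (!inherits(params, "detection_params")) {
    params <- do.call(detection_params, as.list(params))
  }
  thr <- params$min_window_reads
  if (params$normalize_per_million) {
    thr <- thr * params$library_size / 1e6
  }
  w <- params$window
  h <- (w - 1L) %/% 2L
  out <- list()
  for (cid in names(profiles)) {
    p <- profiles[[cid]]
    L <- p$length
    for (s in c("+", "-")) {
      key <- if (s == "+") "plus" else "minus"
      st <- p[[paste0("starts_", key)]]
      cv <- p[[paste0("coverage_", key)]]
      if (L == 0 || sum(st) == 0) next
      cs <- cumsum(st)
      idx <- seq_len(L)
      hi <- pmin(idx + h, L)
      lo <- pmax(idx - h, 1L)
      W <- cs[hi] - c(0L, cs)[lo]          # prefix sum; c(0,cs)[lo] = cs[lo-1]
      cand <- which(st >= 1L & W >= thr)
      if (length(cand) == 0) next
      keep <- logical(length(cand))
      enr <- numeric(length(cand))
      for (k in seq_along(cand)) {
        i <- cand[k]
        win <- st[lo[i]:hi[i]]
        m <- max(win)
        if (st[i] < m) next
        if (s == "+") {
          if (i > lo[i] && any(st[lo[i]:(i - 1L)] == m)) next
          u <- i - (h + 1L)
        } else {
          if (i < hi[i] && any(st[(i + 1L):hi[i]] == m)) next
          u <- i + (h + 1L)
        }
        ucov <- if (u >= 1L && u <= L) cv[u] else 0L
        if (st[i] < (1 + params$enrichment_factor) * ucov) next
        keep[k] <- TRUE
        enr[k] <- if (ucov == 0L) Inf else st[i] / ucov
      }
      surv <- cand[keep]
      if (length(surv) == 0) next
      enr <- enr[keep]
      sel <- dedup_candidates(surv, st[surv], s, w)
      out[[length(out) + 1L]] <- data.frame(
        contig_id = cid, position = surv[sel], strand = s,
        starts = st[surv][sel], window_reads = as.integer(W[surv][sel]),
        enrichment = enr[sel], tss_class = "unclassified",
        gene_id = "", offset = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty_tss())
  res <- do.call(rbind, out)
  res <- res[order(res$contig_id, res$position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Greedy suppression of candidates closer than `window` nt: highest starts
# first, ties toward the 5'-most position on the strand. Returns logical
# selection aligned with `pos`.
dedup_candidates <- function(pos, starts, strand, window) {
  tie <- if (strand == "+") pos else -pos
  ord <- order(-starts, tie)
  accepted <- integer(0)
  sel <- logical(length(pos))
  for (k in ord) {
    if (length(accepted) == 0 || all(abs(accepted - pos[k]) >= window)) {
      accepted <- c(accepted, pos[k])
      sel[k] <- TRUE
    }
  }
  sel
}
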