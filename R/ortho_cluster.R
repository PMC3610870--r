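# Comparative-proteome orthology pipeline: merge HSPs per protein pair,
# recompute identity/length/coverage, apply the coverage and windowed
# best-hit filters, cluster with Markov clustering (MCL), and categorise
# clusters by genome membership.

#' Read BLAST tabular (outfmt 6) hits
#'
#' Expects the standard 12 columns: qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore.
#'
#' @param path path to the tabular file.
#' @return data.frame of HSP records.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "query_start", "query_end",
            "subject_start", "subject_end", "evalue", "bitscore")
  df <- tryCatch(
    utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                      comment.char = "#", quote = ""),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) return(NULL)
      format_error(sprintf("bad BLAST table: %s", conditionMessage(e)))
    })
  if (is.null(df)) {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), 12), cols), stringsAsFactors = FALSE)
    return(df)
  }
  if (ncol(df) < 12) format_error("BLAST table must have 12 columns")
  df <- df[, 1:12]
  names(df) <- cols
  df
}

#' Build a protein catalog
#'
#' @param protein_id,genome_id,length parallel vectors, or a single
#'   data.frame with these columns as `protein_id`.
#' @return data.frame with columns `protein_id`, `genome_id`, `length`.
#' @export
protein_catalog <- function(protein_id, genome_id = NULL, length = NULL) {
  if (is.data.frame(protein_id)) {
    df <- protein_id[, c("protein_id", "genome_id", "length")]
  } else {
    df <- data.frame(protein_id = as.character(protein_id),
                     genome_id = as.character(genome_id),
                     length = as.integer(length), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(df$protein_id)) {
    format_error("protein ids must be unique across genomes")
  }
  if (any(df$length <= 0)) format_error("protein lengths must be positive")
  df
}

#' Merge HSPs per protein pair and recompute identity, length, coverage
#'
#' HSPs for the same unordered protein pair are merged: the merged alignment
#' length is the total length of the union of their intervals on one
#' consistent axis (the coordinates of the lexicographically smaller id, so
#' that both hit directions merge symmetrically), the merged identity is the
#' length-weighted mean of the HSP identities, and coverage is the merged
#' length as a percentage of the longer sequence. Self-hits are dropped, as
#' are HSPs above the e-value cut-off.
#'
#' @param hsps data.frame of HSP records (see [read_blast_tab()]).
#' @param catalog protein catalog from [protein_catalog()].
#' @param max_evalue e-value pre-filter (default `1e-8`).
#' @return data.frame with columns `query_id`, `subject_id` (query is the
#'   lexicographically smaller id), `merged_identity`, `merged_length`,
#'   `coverage`.
#' @export
merge_hsps <- function(hsps, catalog, max_evalue = 1e-8) {
  hsps <- as.data.frame(hsps)
  empty <- data.frame(query_id = character(), subject_id = character(),
                      merged_identity = numeric(), merged_length = integer(),
                      coverage = numeric(), stringsAsFactors = FALSE)
  if (nrow(hsps) == 0) return(empty)
  ids <- unique(c(hsps$query_id, hsps$subject_id))
  missing <- setdiff(ids, catalog$protein_id)
  if (length(missing) > 0) {
    format_error(sprintf("protein '%s' absent from catalog", missing[1]))
  }
  hsps <- hsps[hsps$query_id != hsps$subject_id, , drop = FALSE]
  hsps <- hsps[hsps$evalue <= max_evalue, , drop = FALSE]
  if (nrow(hsps) == 0) return(empty)

  lens <- stats::setNames(catalog$length, catalog$protein_id)
  flip <- hsps$query_id > hsps$subject_id
  a <- ifelse(flip, hsps$subject_id, hsps$query_id)
  b <- ifelse(flip, hsps$query_id, hsps$subject_id)
  # interval on the axis of `a`
  int_start <- ifelse(flip, hsps$subject_start, hsps$query_start)
  int_end <- ifelse(flip, hsps$subject_end, hsps$query_end)
  if (any(int_start > int_end)) {
    format_error("HSP with start > end on the merge axis")
  }
  key <- paste(a, b, sep = "\r")
  groups <- split(seq_len(nrow(hsps)), key)
  out <- lapply(groups, function(ix) {
    qa <- a[ix[1]]; qb <- b[ix[1]]
    ir <- IRanges::reduce(IRanges::IRanges(int_start[ix], int_end[ix]))
    mlen <- sum(IRanges::width(ir))
    wl <- hsps$alignment_length[ix]
    mid <- sum(hsps$percent_identity[ix] * wl) / sum(wl)
    longer <- max(lens[[qa]], lens[[qb]])
    if (mlen > longer) {
      format_error(sprintf(
        "merged alignment (%d) exceeds longer sequence (%d) for %s-%s",
        mlen, longer, qa, qb))
    }
    data.frame(query_id = qa, subject_id = qb, merged_identity = mid,
               merged_length = as.integer(mlen),
               coverage = 100 * mlen / longer, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$query_id, res$subject_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter parameters for merged hits
#'
#' @param min_coverage minimum coverage of the longer sequence, in percent (10).
#' @param identity_window retained hits may be at most this many identity
#'   percentage points below the group's best hit (10).
#' @param coverage_window retained hits may be at most this many coverage
#'   percentage points below the best hit's coverage (20).
#' @return a `filter_params` list.
#' @export
filter_params <- function(min_coverage = 10, identity_window = 10,
                          coverage_window = 20) {
  if (min_coverage < 0 || identity_window < 0 || coverage_window < 0) {
    parameter_error("filter parameters must be non-negative")
  }
  structure(list(min_coverage = min_coverage,
                 identity_window = identity_window,
                 coverage_window = coverage_window),
            class = "filter_params")
}

#' Apply coverage and windowed best-hit filters to merged hits
#'
#' Hits below `min_coverage` are removed. Then, in the hit group of every
#' protein, the best hit (highest merged identity; ties broken by higher
#' coverage, then lexicographic partner id) anchors two windows: retained
#' hits must be within `identity_window` identity points and within
#' `coverage_window` coverage points of it. A hit survives only if retained
#' in the groups of both of its proteins. The rule is applied to a fixed
#' point so the operation is idempotent.
#'
#' @param hits data.frame from [merge_hsps()].
#' @param params a [filter_params()] list.
#' @return filtered data.frame, same columns.
#' @export
filter_hits <- function(hits, params = filter_params()) {
  if (!inherits(params, "filter_params")) {
    params <- do.call(filter_params, as.list(params))
  }
  hits <- as.data.frame(hits)
  hits <- hits[hits$coverage >= params$min_coverage, , drop = FALSE]
  repeat {
    if (nrow(hits) == 0) break
    keep <- rep(TRUE, nrow(hits))
    for (col in c("query_id", "subject_id")) {
      prot <- unique(hits[[col]])
      for (p in prot) {
        ix <- which(hits$query_id == p | hits$subject_id == p)
        partner <- ifelse(hits$query_id[ix] == p,
                          hits$subject_id[ix], hits$query_id[ix])
        ord <- order(-hits$merged_identity[ix], -hits$coverage[ix], partner)
        best <- ix[ord[1]]
        ok <- hits$merged_identity[ix] >=
          hits$merged_identity[best] - params$identity_window &
          hits$coverage[ix] >= hits$coverage[best] - params$coverage_window
        keep[ix[!ok]] <- FALSE
      }
    }
    if (all(keep)) break
    hits <- hits[keep, , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

#' Markov clustering of filtered hits
#'
#' Builds an undirected graph over the catalog's proteins with edge weight
#' equal to the merged identity, adds a self-loop at each node (weight = the
#' node's maximum incident edge weight, or 1 for isolated proteins), and
#' iterates expansion (matrix squaring) and inflation (elementwise power with
#' column renormalisation), pruning entries below `prune`, until the matrix
#' changes by less than `tol` or `max_iter` iterations. Clusters are the
#' weakly connected components of the converged matrix's nonzero pattern;
#' proteins without hits become singletons. Node order is canonicalised so
#' the result is invariant under input permutation.
#'
#' @param hits filtered data.frame from [filter_hits()].
#' @param catalog protein catalog from [protein_catalog()].
#' @param inflation inflation exponent (> 1; default 2, the canonical MCL
#'   default).
#' @param prune entries below this are dropped each iteration (1e-6).
#' @param tol convergence threshold on the max elementwise change (1e-8).
#' @param max_iter iteration cap (200); non-convergence warns and returns the
#'   current interpretation.
#' @return a `cluster_set`: data.frame with columns `cluster_id`,
#'   `protein_id`, `genome_id`.
#' @export
mcl_cluster <- function(hits, catalog, inflation = 2.0, prune = 1e-6,
                        tol = 1e-8, max_iter = 200L) {
  if (inflation <= 1) parameter_error("`inflation` must be > 1")
  hits <- as.data.frame(hits)
  nodes <- sort(unique(catalog$protein_id))
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  if (nrow(hits) > 0) {
    missing <- setdiff(unique(c(hits$query_id, hits$subject_id)), nodes)
    if (length(missing) > 0) {
      format_error(sprintf("protein '%s' absent from catalog", missing[1]))
    }
    i <- unname(idx[hits$query_id])
    j <- unname(idx[hits$subject_id])
    # duplicate pair entries (both hit directions) keep the max weight
    A <- symmetric_max_adjacency(i, j, hits$merged_identity, n)
  } else {
    A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
  }
  loop <- apply_self_loops(A)
  M <- normalize_columns(loop)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                       # expansion
    M2 <- methods::as(M2, "CsparseMatrix")
    M2@x <- M2@x ^ inflation            # inflation
    M2@x[M2@x < prune] <- 0
    M2 <- Matrix::drop0(M2)
    M2 <- normalize_columns(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("MCL did not converge in %d iterations; returning the current interpretation", max_iter))
  }
  pattern <- methods::as(M != 0 | Matrix::t(M) != 0, "CsparseMatrix")
  g <- igraph::graph_from_adjacency_matrix(pattern, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # deterministic cluster ids: ordered by each component's smallest member
  first <- tapply(nodes, comp, min)
  relabel <- stats::setNames(rank(first, ties.method = "first"), names(first))
  cl <- relabel[as.character(comp)]
  gmap <- stats::setNames(catalog$genome_id, catalog$protein_id)
  res <- data.frame(cluster_id = sprintf("C%05d", cl),
                    protein_id = nodes,
                    genome_id = unname(gmap[nodes]),
                    stringsAsFactors = FALSE)
  res <- res[order(res$cluster_id, res$protein_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("cluster_set", class(res))
  res
}

symmetric_max_adjacency <- function(i, j, w, n) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  w_max <- tapply(w, key, max)
  parts <- strsplit(names(w_max), " ", fixed = TRUE)
  ii <- as.integer(vapply(parts, `[`, character(1), 1))
  jj <- as.integer(vapply(parts, `[`, character(1), 2))
  Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii),
                       x = c(w_max, w_max), dims = c(n, n))
}

apply_self_loops <- function(A) {
  n <- nrow(A)
  col_max <- apply_col_max(A)
  loop_w <- ifelse(col_max > 0, col_max, 1)
  A + Matrix::Diagonal(n, loop_w)
}

apply_col_max <- function(A) {
  n <- ncol(A)
  A <- methods::as(A, "CsparseMatrix")
  out <- numeric(n)
  p <- A@p
  for (col in seq_len(n)) {
    if (p[col + 1] > p[col]) {
      out[col] <- max(A@x[(p[col] + 1):p[col + 1]])
    }
  }
  out
}

normalize_columns <- function(M) {
  sums <- Matrix::colSums(M)
  sums[sums == 0] <- 1
  M %*% Matrix::Diagonal(ncol(M), 1 / sums)
}

#' Categorise clusters by the genomes they span
#'
#' @param clusters a `cluster_set` from [mcl_cluster()].
#' @param catalog protein catalog; every member must be present.
#' @return data.frame with one row per non-empty genome subset observed:
#'   `subset` (genome ids sorted, comma-joined), `n_clusters`, `n_proteins`.
#'   Cluster counts sum to the number of clusters and protein counts to the
#'   number of proteins.
#' @export
venn_categorize <- function(clusters, catalog) {
  clusters <- as.data.frame(clusters)
  missing <- setdiff(clusters$protein_id, catalog$protein_id)
  if (length(missing) > 0) {
    format_error(sprintf("cluster member '%s' missing from catalog",
                         missing[1]))
  }
  gmap <- stats::setNames(catalog$genome_id, catalog$protein_id)
  clusters$genome_id <- unname(gmap[clusters$protein_id])
  per_cluster <- split(clusters$genome_id, clusters$cluster_id)
  subset_of <- vapply(per_cluster, function(g)
    paste(sort(unique(g)), collapse = ","), character(1))
  sizes <- lengths(per_cluster)
  agg <- tapply(seq_along(subset_of), subset_of, function(ix)
    c(n_clusters = length(ix), n_proteins = sum(sizes[ix])))
  res <- data.frame(subset = names(agg),
                    n_clusters = vapply(agg, `[[`, numeric(1), "n_clusters"),
                    n_proteins = vapply(agg, `[[`, numeric(1), "n_proteins"),
                    stringsAsFactors = FALSE)
  res <- res[order(res$subset), , drop = FALSE]
  rownames(res) <- NULL
  res
}
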