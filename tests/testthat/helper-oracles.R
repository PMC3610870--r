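# Independent oracles used to cross-check the implementation. These are
# deliberately written as plain, slow enumerations that share no code with
# the package internals.

# Exhaustive per-position TSS detector: tests every position independently,
# then deduplicates by repeatedly selecting the strongest remaining
# candidate and discarding its close neighbours.
oracle_detect_tss <- function(profiles, min_window_reads = 280,
                              window = 7L, enrichment_factor = 0.5) {
  h <- (window - 1L) %/% 2L
  rows <- list()
  for (cid in names(profiles)) {
    prof <- profiles[[cid]]
    L <- prof$length
    for (s in c("+", "-")) {
      st <- if (s == "+") prof$starts_plus else prof$starts_minus
      cv <- if (s == "+") prof$coverage_plus else prof$coverage_minus
      cand <- list()
      for (p in which(st > 0)) {
        lo <- max(1L, p - h); hi <- min(L, p + h)
        if (sum(st[lo:hi]) < min_window_reads) next
        m <- max(st[lo:hi])
        if (st[p] != m) next
        # 5'-most tie-break within the window
        five_side <- if (s == "+") {
          if (p > lo) st[lo:(p - 1L)] else integer(0)
        } else {
          if (p < hi) st[(p + 1L):hi] else integer(0)
        }
        if (length(five_side) > 0 && any(five_side == m)) next
        u <- if (s == "+") p - h - 1L else p + h + 1L
        ucov <- if (u >= 1L && u <= L) cv[u] else 0L
        if (st[p] < (1 + enrichment_factor) * ucov) next
        cand[[length(cand) + 1L]] <- c(pos = p, starts = st[p])
      }
      if (length(cand) == 0) next
      cm <- do.call(rbind, cand)
      # iterative suppression: strongest first, 5'-most on ties
      remaining <- as.data.frame(cm)
      while (nrow(remaining) > 0) {
        pref <- if (s == "+") remaining$pos else -remaining$pos
        top <- which(remaining$starts == max(remaining$starts))
        top <- top[which.min(pref[top])]
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = cid, position = remaining$pos[top], strand = s,
          starts = remaining$starts[top], stringsAsFactors = FALSE)
        remaining <- remaining[abs(remaining$pos - remaining$pos[top]) >=
                                 window, , drop = FALSE]
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(contig_id = character(), position = integer(),
                      strand = character(), starts = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$contig_id, out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force per-position tally of read starts and coverage.
oracle_profiles <- function(alignments, len) {
  tr <- list()
  for (s in c("+", "-")) {
    starts <- integer(len); coverage <- integer(len)
    sub <- alignments[alignments$strand == s, , drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      five0 <- if (s == "+") sub$start[r] else sub$end[r] - 1L
      starts[five0 + 1L] <- starts[five0 + 1L] + 1L
      for (p0 in sub$start[r]:(sub$end[r] - 1L)) {
        coverage[p0 + 1L] <- coverage[p0 + 1L] + 1L
      }
    }
    tr[[s]] <- list(starts = starts, coverage = coverage)
  }
  tr
}

# Per-column membership count for the union of 1-based inclusive intervals.
oracle_union_length <- function(starts, ends) {
  covered <- logical(max(ends))
  for (k in seq_along(starts)) covered[starts[k]:ends[k]] <- TRUE
  sum(covered)
}

# All-pairs scan for flanking direct repeats (no maximal-pair suppression;
# comparisons use the containment-filtered implementation output).
oracle_flanking_pairs <- function(seq_chr, element_start, element_end,
                                  min_len, max_len, max_mismatch,
                                  search_margin) {
  L <- nchar(seq_chr)
  res <- list()
  for (len in min_len:max_len) {
    for (ls in max(1, element_start - search_margin):(element_start - len)) {
      left <- substr(seq_chr, ls, ls + len - 1L)
      if (grepl("N", left)) next
      for (rs in (element_end + 1L):
           min(L - len + 1L, element_end + search_margin - len + 1L)) {
        right <- substr(seq_chr, rs, rs + len - 1L)
        if (grepl("N", right)) next
        mm <- sum(strsplit(left, "")[[1]] != strsplit(right, "")[[1]])
        if (mm <= max_mismatch) {
          res[[length(res) + 1L]] <- data.frame(
            left_start = ls, right_start = rs, length = len,
            mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(left_start = integer(), right_start = integer(),
                      length = integer(), mismatches = integer()))
  }
  do.call(rbind, res)
}

# Adjusted Rand index between two labelings of the same objects.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Random alignment sets with hot spots, for oracle-equivalence testing.
random_alignments <- function(seed, len, n_background = 400, n_spikes = 6,
                              spike_height_range = c(50, 400)) {
  withr::with_seed(seed, {
    rows <- list()
    five <- sample.int(len, n_background, replace = TRUE)
    strand <- sample(c("+", "-"), n_background, replace = TRUE)
    for (k in seq_len(n_spikes)) {
      p <- sample.int(len, 1)
      ht <- sample(spike_height_range[1]:spike_height_range[2], 1)
      jit <- sample(c(0L, 0L, 0L, -1L, 1L), ht, replace = TRUE)
      five <- c(five, pmin(pmax(p + jit, 1L), len))
      strand <- c(strand, rep(sample(c("+", "-"), 1), ht))
    }
    rl <- 80L
    plus <- strand == "+"
    data.frame(
      contig_id = "c1",
      start = ifelse(plus, five - 1L, pmax(0L, five - rl)),
      end = ifelse(plus, pmin(len, five - 1L + rl), five),
      strand = strand, stringsAsFactors = FALSE)
  })
}

key_pos <- function(d) paste(d$position, d$strand)

# Candidate set before the close-neighbour suppression step (steps 1-3 only).
oracle_candidates <- function(profiles, min_window_reads, window = 7L,
                              enrichment_factor = 0.5) {
  h <- (window - 1L) %/% 2L
  rows <- list()
  for (cid in names(profiles)) {
    prof <- profiles[[cid]]
    L <- prof$length
    for (s in c("+", "-")) {
      st <- if (s == "+") prof$starts_plus else prof$starts_minus
      cv <- if (s == "+") prof$coverage_plus else prof$coverage_minus
      for (p in which(st > 0)) {
        lo <- max(1L, p - h); hi <- min(L, p + h)
        if (sum(st[lo:hi]) < min_window_reads) next
        m <- max(st[lo:hi])
        if (st[p] != m) next
        five_side <- if (s == "+") {
          if (p > lo) st[lo:(p - 1L)] else integer(0)
        } else {
          if (p < hi) st[(p + 1L):hi] else integer(0)
        }
        if (length(five_side) > 0 && any(five_side == m)) next
        u <- if (s == "+") p - h - 1L else p + h + 1L
        ucov <- if (u >= 1L && u <= L) cv[u] else 0L
        if (st[p] < (1 + enrichment_factor) * ucov) next
        rows[[length(rows) + 1L]] <- data.frame(
          position = p, strand = s, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(position = integer(), strand = character()))
  }
  do.call(rbind, rows)
}
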