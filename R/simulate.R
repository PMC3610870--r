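# Seeded synthetic data with the statistical structure the pipeline assumes:
# a random genome carrying non-overlapping genes on both strands, planted TSS
# of every positional class, NtcA-type dyad motifs at center -41, a
# direct-repeat-flanked element, and multi-genome protein families emitted as
# BLAST-style HSP tables. Everything is bit-reproducible under (params, seed)
# and never touches the session RNG.

#' Simulate a genome with planted genes, TSS, motifs and a repeat element
#'
#' Layout: genes are placed left to right with intergenic gaps drawn from
#' `gap_range`; each gene gets one gTSS at an offset drawn uniformly from
#' -150..-20 nt of its strand-aware start. Quotas of iTSS (inside gene
#' bodies, same strand), aTSS (inside gene bodies, opposite strand) and nTSS
#' (intergenic gap midpoints) are planted with separations chosen so that
#' every planted class is recovered by [classify_tss()] under default
#' parameters and no planted site's read-through probe is shadowed by
#' another site's reads at the default 100-nt read length.
#'
#' @param n_genes number of genes.
#' @param genome_length genome length in nt.
#' @param seed integer seed.
#' @param motif_fraction fraction of gTSS that receive a planted GTA-N8-TAC
#'   motif centered at -41 (default 0.5).
#' @param itss_fraction,atss_fraction,ntss_fraction quotas of planted
#'   iTSS/aTSS/nTSS as fractions of `n_genes` (defaults 0.3/0.3/0.2).
#' @param gene_length_range,gap_range integer ranges for gene lengths and
#'   intergenic gaps (defaults 800-1600 and 600-1000 nt).
#' @param n_elements number of direct-repeat-flanked elements planted after
#'   the last gene (default 1; repeat length 11, one mismatch, mirroring the
#'   nifD configuration).
#' @return a `simulation_truth` list: `genome` (DNAStringSet, one contig
#'   `"chr"`), `genes`, `true_tss` (position, strand, expected class,
#'   gene_id), `planted_motifs`, `planted_elements`, `params`.
#' @export
simulate_genome <- function(n_genes, genome_length, seed,
                            motif_fraction = 0.5,
                            itss_fraction = 0.3, atss_fraction = 0.3,
                            ntss_fraction = 0.2,
                            gene_length_range = c(800L, 1600L),
                            gap_range = c(600L, 1000L),
                            n_elements = 1L) {
  if (n_genes < 0 || genome_length < 1) {
    parameter_error("need n_genes >= 0 and genome_length >= 1")
  }
  with_seed(seed, {
    seq_v <- sample(c("A", "C", "G", "T"), genome_length, replace = TRUE)

    genes <- data.frame(gene_id = character(), contig_id = character(),
                        start = integer(), end = integer(),
                        strand = character(), feature_type = character(),
                        stringsAsFactors = FALSE)
    tss <- list(); motifs <- list(); elements <- list()
    cursor <- 0L
    if (n_genes > 0) {
      starts <- ends <- integer(n_genes)
      strands <- character(n_genes)
      for (i in seq_len(n_genes)) {
        gap <- sample(gap_range[1]:gap_range[2], 1L)
        len <- sample(gene_length_range[1]:gene_length_range[2], 1L)
        starts[i] <- cursor + gap + 1L
        ends[i] <- starts[i] + len - 1L
        strands[i] <- sample(c("+", "-"), 1L)
        cursor <- ends[i]
      }
      if (cursor + gap_range[1] > genome_length) {
        parameter_error(sprintf(
          "gene density infeasible: layout needs %d nt, genome is %d nt",
          cursor + gap_range[1], genome_length))
      }
      genes <- data.frame(
        gene_id = sprintf("g%04d", seq_len(n_genes)), contig_id = "chr",
        start = starts, end = ends, strand = strands,
        feature_type = "CDS", stringsAsFactors = FALSE)

      # one gTSS per gene, offset uniform in [-150, -20]
      g_off <- sample(-150:-20, n_genes, replace = TRUE)
      g_pos <- ifelse(strands == "+", starts + g_off, ends - g_off)
      tss[[1]] <- data.frame(position = g_pos, strand = strands,
                             tss_class = "gTSS",
                             gene_id = genes$gene_id,
                             stringsAsFactors = FALSE)

      n_i <- round(itss_fraction * n_genes)
      n_a <- round(atss_fraction * n_genes)
      n_n <- round(ntss_fraction * n_genes)
      # iTSS and aTSS hosts are disjoint genes so planted sites stay apart
      hosts <- sample(seq_len(n_genes))
      i_hosts <- hosts[seq2(1L, min(n_i, n_genes))]
      a_hosts <- hosts[seq2(n_i + 1L, min(n_i + n_a, n_genes))]
      body_pos <- function(k) {
        len <- ends[k] - starts[k] + 1L
        off <- vapply(len, function(l) sample(300:(l - 300L), 1L), integer(1))
        ifelse(strands[k] == "+", starts[k] + off, ends[k] - off)
      }
      if (length(i_hosts) > 0) {
        tss[[length(tss) + 1L]] <- data.frame(
          position = body_pos(i_hosts), strand = strands[i_hosts],
          tss_class = "iTSS", gene_id = genes$gene_id[i_hosts],
          stringsAsFactors = FALSE)
      }
      if (length(a_hosts) > 0) {
        tss[[length(tss) + 1L]] <- data.frame(
          position = body_pos(a_hosts),
          strand = ifelse(strands[a_hosts] == "+", "-", "+"),
          tss_class = "aTSS", gene_id = genes$gene_id[a_hosts],
          stringsAsFactors = FALSE)
      }
      if (n_n > 0 && n_genes >= 2) {
        gaps <- sample(2:n_genes, min(n_n, n_genes - 1L))
        mid <- (ends[gaps - 1L] + starts[gaps]) %/% 2L
        tss[[length(tss) + 1L]] <- data.frame(
          position = mid,
          strand = sample(c("+", "-"), length(gaps), replace = TRUE),
          tss_class = "nTSS", gene_id = "", stringsAsFactors = FALSE)
      }
    }
    true_tss <- if (length(tss) > 0) do.call(rbind, tss) else
      data.frame(position = integer(), strand = character(),
                 tss_class = character(), gene_id = character(),
                 stringsAsFactors = FALSE)
    if (nrow(true_tss) > 0) {
      true_tss$contig_id <- "chr"
      true_tss <- true_tss[order(true_tss$position), , drop = FALSE]
      rownames(true_tss) <- NULL
    }

    # plant GTA-N8-TAC (center -41 => first base -47) at a fraction of gTSS
    g_rows <- which(true_tss$tss_class == "gTSS")
    n_m <- round(motif_fraction * length(g_rows))
    motif_df <- data.frame(tss_index = integer(), center_offset = integer(),
                           stringsAsFactors = FALSE)
    if (n_m > 0) {
      chosen <- sort(sample(g_rows, n_m))
      for (r in chosen) {
        motif <- c("G", "T", "A",
                   sample(c("A", "C", "G", "T"), 8L, replace = TRUE),
                   "T", "A", "C")
        p <- true_tss$position[r]
        if (true_tss$strand[r] == "+") {
          at <- (p - 47L):(p - 34L)
          seq_v[at] <- motif
        } else {
          at <- (p + 34L):(p + 47L)
          seq_v[at] <- rev(chartr("ACGT", "TGCA", motif))
        }
      }
      motif_df <- data.frame(tss_index = chosen, center_offset = -41L,
                             stringsAsFactors = FALSE)
    }

    # direct-repeat-flanked element(s) after the last gene
    element_df <- data.frame(element_start = integer(), element_end = integer(),
                             left_start = integer(), right_start = integer(),
                             length = integer(), mismatches = integer(),
                             stringsAsFactors = FALSE)
    rep_len <- 11L; elem_len <- 200L
    for (e in seq2(1L, if (n_genes > 0) n_elements else 0L)) {
      es <- cursor + 400L + rep_len + 1L
      ee <- es + elem_len - 1L
      if (ee + rep_len + 400L > genome_length) break
      left <- sample(c("A", "C", "G", "T"), rep_len, replace = TRUE)
      right <- left
      mm_at <- sample(rep_len, 1L)
      right[mm_at] <- sample(setdiff(c("A", "C", "G", "T"), left[mm_at]), 1L)
      seq_v[(es - rep_len):(es - 1L)] <- left
      seq_v[(ee + 1L):(ee + rep_len)] <- right
      element_df <- rbind(element_df, data.frame(
        element_start = es, element_end = ee,
        left_start = es - rep_len, right_start = ee + 1L,
        length = rep_len, mismatches = 1L, stringsAsFactors = FALSE))
      cursor <- ee + rep_len + 400L
    }

    genome <- Biostrings::DNAStringSet(paste0(seq_v, collapse = ""))
    names(genome) <- "chr"
    structure(list(genome = genome, genes = genes, true_tss = true_tss,
                   planted_motifs = motif_df, planted_elements = element_df,
                   params = list(n_genes = n_genes,
                                 genome_length = genome_length,
                                 seed = seed,
                                 motif_fraction = motif_fraction)),
              class = "simulation_truth")
  })
}

#' Simulate dRNA-seq read alignments over a simulation truth
#'
#' Each planted TSS sheds `Poisson(mean_tss_starts)` reads whose 5' ends are
#' jittered by a rounded `Normal(0, jitter_sd)` and which extend
#' `read_length` nt downstream on the TSS strand. Background reads arrive as
#' a per-strand Poisson process of `background_rate` reads per nt with
#' uniform 5' ends, emulating residual processed transcripts that survive
#' the primary-transcript enrichment.
#'
#' @param truth a `simulation_truth` from [simulate_genome()].
#' @param mean_tss_starts expected reads per TSS (default 600).
#' @param jitter_sd 5'-end positional jitter, nt (default 1).
#' @param background_rate background reads per nt per strand (default 0.2).
#' @param read_length read length in nt (default 100, clipped at contig
#'   ends).
#' @param seed integer seed.
#' @return alignment data.frame (0-based half-open) as from
#'   [read_alignments()].
#' @export
simulate_reads <- function(truth, mean_tss_starts = 600, jitter_sd = 1,
                           background_rate = 0.2, read_length = 100L,
                           seed = 1L) {
  if (!inherits(truth, "simulation_truth")) {
    parameter_error("`truth` must come from simulate_genome()")
  }
  L <- Biostrings::width(truth$genome)[1]
  with_seed(seed, {
    five <- integer(0); strand <- character(0)
    for (i in seq_len(nrow(truth$true_tss))) {
      n <- rpois(1L, mean_tss_starts)
      if (n == 0) next
      p <- truth$true_tss$position[i] +
        as.integer(round(rnorm(n, 0, jitter_sd)))
      p <- pmin(pmax(p, 1L), L)
      five <- c(five, p)
      strand <- c(strand, rep(truth$true_tss$strand[i], n))
    }
    for (s in c("+", "-")) {
      n_bg <- rpois(1L, background_rate * L)
      if (n_bg == 0) next
      five <- c(five, sample.int(L, n_bg, replace = TRUE))
      strand <- c(strand, rep(s, n_bg))
    }
    if (length(five) == 0) {
      empty_alignments()
    } else {
      plus <- strand == "+"
      start0 <- ifelse(plus, five - 1L, pmax(0L, five - read_length))
      end0 <- ifelse(plus, pmin(L, five - 1L + read_length), five)
      data.frame(contig_id = "chr", start = as.integer(start0),
                 end = as.integer(end0), strand = strand,
                 stringsAsFactors = FALSE)
    }
  })
}

#' Simulate multi-genome protein families as HSP tables
#'
#' One protein per present genome per family; each genome is present with
#' probability `1 - dropout` (at least one per family). Each family draws a
#' characteristic identity from `Normal(within_identity_mean,
#' within_identity_sd)` and a characteristic coverage from `Uniform(65, 95)`
#' percent of the longer sequence; individual pairs jitter around these by
#' at most 1 identity point and 5 coverage points, mirroring how ortholog
#' pairs within one family share a common divergence. All within-family
#' pairs are emitted as HSPs in both directions; there are no between-family
#' hits, so the planted families are recoverable by construction: the
#' within-family spread stays inside the default best-hit filter windows.
#'
#' @param n_families number of families (>= 1).
#' @param genomes character vector of genome ids.
#' @param within_identity_mean,within_identity_sd identity distribution in
#'   percent (defaults 80 and 5; clamped to 30-100).
#' @param dropout probability a family misses a genome (in [0, 1)).
#' @param seed integer seed.
#' @return list with `hsps` (HSP data.frame), `catalog`
#'   ([protein_catalog()] data.frame) and `family_truth` (named character
#'   vector protein_id -> family id).
#' @export
simulate_hsp_tables <- function(n_families, genomes = paste0("G", 1:4),
                                within_identity_mean = 80,
                                within_identity_sd = 5,
                                dropout = 0, seed = 1L) {
  if (n_families < 1) parameter_error("`n_families` must be >= 1")
  if (dropout < 0 || dropout >= 1) {
    parameter_error("`dropout` must be in [0, 1)")
  }
  with_seed(seed, {
    cat_rows <- list(); hsp_rows <- list(); fam_truth <- character(0)
    for (f in seq_len(n_families)) {
      present <- genomes[runif(length(genomes)) >= dropout]
      if (length(present) == 0) present <- sample(genomes, 1L)
      ids <- sprintf("%s|p%04d", present, f)
      lens <- sample(100:600, length(ids), replace = TRUE)
      cat_rows[[f]] <- data.frame(protein_id = ids, genome_id = present,
                                  length = lens, stringsAsFactors = FALSE)
      fam_truth[ids] <- sprintf("F%04d", f)
      fam_ident <- min(95, max(35, rnorm(1, within_identity_mean,
                                         within_identity_sd)))
      fam_cov <- runif(1, 65, 95)
      if (length(ids) >= 2) {
        pairs <- utils::combn(seq_along(ids), 2)
        for (k in seq_len(ncol(pairs))) {
          a <- pairs[1, k]; b <- pairs[2, k]
          ident <- min(100, max(30, fam_ident + runif(1, -1, 1)))
          cov <- min(100, max(60, fam_cov + runif(1, -5, 5)))
          alen <- as.integer(round(cov / 100 * max(lens[a], lens[b])))
          alen <- max(alen, 1L)
          row <- data.frame(
            query_id = ids[a], subject_id = ids[b],
            percent_identity = round(ident, 2), alignment_length = alen,
            mismatches = as.integer(round((100 - ident) / 100 * alen)),
            gap_opens = 0L, query_start = 1L, query_end = alen,
            subject_start = 1L, subject_end = alen,
            evalue = 1e-50, bitscore = 2 * alen, stringsAsFactors = FALSE)
          rev <- row
          rev$query_id <- row$subject_id; rev$subject_id <- row$query_id
          hsp_rows[[length(hsp_rows) + 1L]] <- rbind(row, rev)
        }
      }
    }
    catalog <- protein_catalog(do.call(rbind, cat_rows))
    hsps <- if (length(hsp_rows) > 0) do.call(rbind, hsp_rows) else
      read_blast_tab(tempfile_empty())
    rownames(hsps) <- NULL
    list(hsps = hsps, catalog = catalog, family_truth = fam_truth)
  })
}

tempfile_empty <- function() {
  f <- tempfile()
  file.create(f)
  f
}
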