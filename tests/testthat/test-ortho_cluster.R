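hsp_row <- function(q, s, ident, len, qs, qe, ss = qs, se = qe,
                    evalue = 1e-50) {
  data.frame(query_id = q, subject_id = s, percent_identity = ident,
             alignment_length = len, mismatches = 0L, gap_opens = 0L,
             query_start = qs, query_end = qe, subject_start = ss,
             subject_end = se, evalue = evalue, bitscore = 2 * len,
             stringsAsFactors = FALSE)
}

two_prot <- protein_catalog(c("A", "B"), c("g1", "g2"), c(200L, 300L))

test_that("merge_hsps recomputes identity, length and coverage", {
  m <- merge_hsps(hsp_row("A", "B", 90, 100, 1, 100), two_prot)
  expect_equal(m$merged_identity, 90)
  expect_equal(m$merged_length, 100L)
  expect_equal(m$coverage, 100 * 100 / 300, tolerance = 1e-12)

  # two disjoint HSPs: length-weighted identity
  m2 <- merge_hsps(rbind(hsp_row("A", "B", 90, 100, 1, 100),
                         hsp_row("A", "B", 80, 50, 101, 150)), two_prot)
  expect_equal(m2$merged_length, 150L)
  expect_equal(m2$merged_identity, (90 * 100 + 80 * 50) / 150)
  expect_equal(m2$coverage, 50)

  # 20-column overlap on the merge axis
  m3 <- merge_hsps(rbind(hsp_row("A", "B", 90, 100, 1, 100),
                         hsp_row("A", "B", 90, 100, 81, 180)), two_prot)
  expect_equal(m3$merged_length, 180L)

  # both directions of the same pair merge into one record on one axis
  m4 <- merge_hsps(rbind(hsp_row("A", "B", 90, 100, 1, 100),
                         hsp_row("B", "A", 90, 100, 1, 100, 1, 100)),
                   two_prot)
  expect_equal(nrow(m4), 1L)
  expect_equal(m4$merged_length, 100L)

  # self-hits and weak e-values are dropped
  expect_equal(nrow(merge_hsps(hsp_row("A", "A", 100, 200, 1, 200),
                               two_prot)), 0L)
  expect_equal(nrow(merge_hsps(hsp_row("A", "B", 90, 100, 1, 100,
                                       evalue = 1e-3), two_prot)), 0L)
  # id missing from the catalog
  expect_error(merge_hsps(hsp_row("A", "Z", 90, 100, 1, 100), two_prot),
               class = "nodtx_format_error")
  # alignment exceeding the longer sequence is inconsistent input
  expect_error(merge_hsps(hsp_row("A", "B", 90, 400, 1, 400), two_prot),
               class = "nodtx_format_error")
})

test_that("interval union length matches a per-column brute force", {
  for (seed in 1:20) {
    hs <- withr::with_seed(seed, {
      k <- sample(1:8, 1)
      qs <- sample.int(900, k)
      qe <- pmin(qs + sample(5:120, k, TRUE), 1000L)
      do.call(rbind, lapply(seq_len(k), function(i)
        hsp_row("A", "B", 90, qe[i] - qs[i] + 1L, qs[i], qe[i])))
    })
    cat_big <- protein_catalog(c("A", "B"), c("g1", "g2"), c(1000L, 1000L))
    m <- merge_hsps(hs, cat_big)
    expect_equal(m$merged_length,
                 oracle_union_length(hs$query_start, hs$query_end),
                 info = seed)
  }
})

test_that("filter_hits applies the coverage floor and best-hit windows", {
  mk <- function(q, s, ident, cov) data.frame(
    query_id = q, subject_id = s, merged_identity = ident,
    merged_length = 100L, coverage = cov, stringsAsFactors = FALSE)

  expect_equal(nrow(filter_hits(mk("A", "B", 90, 9.9))), 0L)
  expect_equal(nrow(filter_hits(mk("A", "B", 90, 10))), 1L)

  # identities {95, 86, 84}: keep 95 and 86
  grp <- rbind(mk("A", "B", 95, 90), mk("A", "C", 86, 90), mk("A", "D", 84, 90))
  out <- filter_hits(grp)
  expect_setequal(out$subject_id, c("B", "C"))

  # coverage window: 69 < 90 - 20
  grp2 <- rbind(mk("A", "B", 95, 90), mk("A", "C", 94, 69))
  expect_equal(filter_hits(grp2)$subject_id, "B")

  # dual-group survival: a hit acceptable to its query can die in the
  # partner's group
  grp3 <- rbind(mk("A", "B", 95, 90),   # best for both A and B
                mk("B", "C", 84, 90))   # best for C, but 84 < 95-10 in B's
  expect_equal(nrow(filter_hits(grp3)), 1L)
})

test_that("filter_hits is idempotent", {
  for (seed in 1:10) {
    hits <- withr::with_seed(seed, {
      n <- 40
      ids <- sprintf("p%02d", 1:12)
      pairs <- t(replicate(n, sort(sample(ids, 2))))
      unique(data.frame(query_id = pairs[, 1], subject_id = pairs[, 2],
                        merged_identity = round(runif(n, 40, 100), 2),
                        merged_length = 100L,
                        coverage = round(runif(n, 5, 100), 2),
                        stringsAsFactors = FALSE))
    })
    once <- filter_hits(hits)
    twice <- filter_hits(once)
    expect_identical(once, twice, info = seed)
  }
})

test_that("mcl_cluster handles cliques, singletons and determinism", {
  cat6 <- protein_catalog(sprintf("p%d", 1:6), rep(c("gA", "gB"), each = 3),
                          rep(200L, 6))
  clique <- function(ids, w = 80) {
    cb <- t(utils::combn(ids, 2))
    data.frame(query_id = cb[, 1], subject_id = cb[, 2], merged_identity = w,
               merged_length = 100L, coverage = 50, stringsAsFactors = FALSE)
  }
  hits <- rbind(clique(sprintf("p%d", 1:3)), clique(sprintf("p%d", 4:6)))
  cl <- mcl_cluster(hits, cat6)
  expect_equal(length(unique(cl$cluster_id)), 2L)
  expect_equal(unname(table(cl$cluster_id)[unique(cl$cluster_id)]),
               c(3L, 3L), ignore_attr = TRUE)

  # empty hits: every protein its own cluster
  cl0 <- mcl_cluster(hits[0, ], cat6)
  expect_equal(length(unique(cl0$cluster_id)), 6L)

  # input-order permutation invariance
  perm <- withr::with_seed(1, hits[sample.int(nrow(hits)), ])
  expect_identical(mcl_cluster(perm, cat6), cl)
  # catalog order invariance
  expect_identical(mcl_cluster(hits, cat6[c(4, 2, 6, 1, 3, 5), ]), cl)

  expect_error(mcl_cluster(hits, cat6, inflation = 1),
               class = "nodtx_parameter_error")
})

test_that("mcl_cluster never merges disconnected components", {
  for (seed in 1:5) {
    sim <- simulate_hsp_tables(12, paste0("G", 1:3), seed = seed)
    merged <- merge_hsps(sim$hsps, sim$catalog)
    cl <- mcl_cluster(merged, sim$catalog)
    g <- igraph::graph_from_data_frame(
      merged[, c("query_id", "subject_id")], directed = FALSE,
      vertices = sim$catalog$protein_id)
    comp <- igraph::components(g)$membership[cl$protein_id]
    # cluster labels refine the connected components
    expect_true(all(tapply(comp, cl$cluster_id,
                           function(x) length(unique(x))) == 1L))
  }
})

test_that("venn_categorize counts subsets and conserves totals", {
  cat3 <- protein_catalog(c("A1", "A2", "A3", "B1", "B2", "C1"),
                          c("A", "A", "A", "B", "B", "C"), rep(100L, 6))
  clusters <- data.frame(
    cluster_id = c("C1", "C1", "C2", "C3", "C3", "C3"),
    protein_id = c("A1", "B1", "A2", "A3", "B2", "C1"),
    genome_id = c("A", "B", "A", "A", "B", "C"), stringsAsFactors = FALSE)
  vn <- venn_categorize(clusters, cat3)
  expect_equal(stats::setNames(vn$n_clusters, vn$subset),
               c("A" = 1, "A,B" = 1, "A,B,C" = 1))
  expect_equal(sum(vn$n_clusters), 3)
  expect_equal(sum(vn$n_proteins), 6)

  # all singletons: only single-genome subsets
  singles <- data.frame(cluster_id = sprintf("S%d", 1:6),
                        protein_id = cat3$protein_id,
                        genome_id = cat3$genome_id, stringsAsFactors = FALSE)
  vs <- venn_categorize(singles, cat3)
  expect_true(all(!grepl(",", vs$subset)))
  expect_equal(sum(vs$n_clusters), 6)

  bad <- clusters; bad$protein_id[1] <- "ZZ"
  expect_error(venn_categorize(bad, cat3), class = "nodtx_format_error")
})

test_that("planted subset structure is recovered end to end", {
  # 4-genome world: core families, families missing genome 1, and
  # genome-1-only singletons
  sim_core <- simulate_hsp_tables(40, paste0("G", 1:4), dropout = 0, seed = 7)
  cl <- mcl_cluster(filter_hits(merge_hsps(sim_core$hsps, sim_core$catalog)),
                    sim_core$catalog)
  vn <- venn_categorize(cl, sim_core$catalog)
  expect_equal(vn$subset, "G1,G2,G3,G4")
  expect_equal(vn$n_clusters, 40)
  expect_equal(vn$n_proteins, 160)

  ari_all <- adjusted_rand_index(
    stats::setNames(cl$cluster_id, cl$protein_id)[sim_core$catalog$protein_id],
    sim_core$family_truth[sim_core$catalog$protein_id])
  expect_equal(ari_all, 1.0)
})

test_that("BLAST tabular reader round-trips with the writer", {
  sim <- simulate_hsp_tables(5, c("X", "Y"), seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_blast_tab(sim$hsps, f)
  back <- read_blast_tab(f)
  expect_equal(back, sim$hsps, tolerance = 1e-9)
  file.create(f2 <- withr::local_tempfile())
  expect_equal(nrow(read_blast_tab(f2)), 0L)
})
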