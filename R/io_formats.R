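# Readers and writers for the standard formats the pipeline touches.
# Internal coordinates are 0-based half-open; every reader/writer converts
# from/to the native convention of its format (FASTA/GFF3/TSV 1-based
# inclusive, BED/bedGraph 0-based half-open, SAM 1-based via Rsamtools).

#' Read a nucleotide FASTA file
#'
#' Sequences are uppercased and RNA `U` is mapped to `T`. Characters outside
#' the IUPAC nucleotide alphabet raise a format error naming the offending
#' line.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] (empty for an empty file); names are
#'   the first whitespace-delimited token of each header.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^;", lines)
  lines <- lines[keep]
  line_no <- seq_along(lines)
  nonblank <- nzchar(trimws(lines))
  if (!any(nonblank)) {
    return(Biostrings::DNAStringSet())
  }
  first <- which(nonblank)[1]
  if (!startsWith(lines[first], ">")) {
    format_error(sprintf("line %d: expected FASTA header starting with '>'",
                         line_no[first]))
  }
  is_header <- startsWith(lines, ">")
  ids <- sub("\\s.*$", "", sub("^>", "", lines[is_header]))
  if (any(ids == "")) {
    bad <- line_no[is_header][ids == ""][1]
    format_error(sprintf("line %d: malformed (empty) FASTA header", bad))
  }
  if (anyDuplicated(ids)) {
    format_error(sprintf("duplicate contig id '%s'", ids[duplicated(ids)][1]))
  }
  seq_lines <- toupper(lines)
  seq_lines[is_header] <- ""
  bad_char <- grepl("[^ACGTUNRYSWKMBDHV[:space:]]", seq_lines)
  if (any(bad_char)) {
    format_error(sprintf("line %d: non-IUPAC nucleotide character",
                         line_no[bad_char][1]))
  }
  grp <- cumsum(is_header)
  body <- gsub("[[:space:]]", "", seq_lines)
  seqs <- vapply(split(body, grp)[as.character(seq_len(sum(is_header)))],
                 paste0, character(1), collapse = "")
  seqs <- chartr("U", "T", seqs)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Read gene features from a GFF3 file
#'
#' @param path path to a GFF3 file.
#' @param feature_types character vector of feature types to retain
#'   (column 3); default `"CDS"`.
#' @return data.frame with columns `gene_id`, `contig_id`, `start`, `end`
#'   (1-based inclusive), `strand`, `feature_type`. `gene_id` is taken from
#'   the `ID` attribute, falling back to `locus_tag`.
#' @export
read_gff <- function(path, feature_types = "CDS") {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) format_error(sprintf("GFF3 parse failure: %s",
                                             conditionMessage(e)))
  )
  gr <- gr[as.character(gr$type) %in% feature_types]
  if (length(gr) == 0) {
    return(data.frame(gene_id = character(), contig_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), feature_type = character(),
                      stringsAsFactors = FALSE))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    format_error("feature with unknown strand symbol (need + or -)")
  }
  id <- if ("ID" %in% names(S4Vectors::mcols(gr))) gr$ID else
    rep(NA_character_, length(gr))
  if ("locus_tag" %in% names(S4Vectors::mcols(gr))) {
    lt <- gr$locus_tag
    if (is(lt, "List") || is.list(lt)) lt <- vapply(lt, function(x)
      if (length(x)) x[[1]] else NA_character_, character(1))
    id <- ifelse(is.na(id) | id == "", lt, id)
  }
  if (anyNA(id) || any(id == "")) {
    format_error("feature without ID or locus_tag attribute")
  }
  if (anyDuplicated(id)) {
    format_error(sprintf("duplicate feature identifier '%s'",
                         id[duplicated(id)][1]))
  }
  data.frame(
    gene_id = as.character(id),
    contig_id = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = strand,
    feature_type = as.character(gr$type),
    stringsAsFactors = FALSE
  )
}

empty_alignments <- function() {
  data.frame(contig_id = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Read mapped reads as alignment intervals
#'
#' Only mapped, primary, non-supplementary records are kept for SAM/BAM.
#' Soft-clipped bases do not contribute: the aligned reference span is used.
#' Duplicate intervals are retained — dRNA-seq 5' pile-ups are signal.
#'
#' @param path path to the alignment file.
#' @param format one of `"sam"`, `"bam"`, `"bed"`; default guessed from the
#'   file extension.
#' @return data.frame with columns `contig_id`, `start`, `end` (0-based
#'   half-open) and `strand`.
#' @export
read_alignments <- function(path, format = c("auto", "sam", "bam", "bed")) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sam = "sam", bam = "bam", bed = "bed",
                     format_error(sprintf("cannot guess format of '%s'", path)))
  }
  if (format == "bed") {
    return(read_bed6(path))
  }
  bam_path <- path
  if (format == "sam") {
    bam_path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                                 indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flags, what = c("rname", "pos", "cigar", "strand"))
  rec <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  if (length(rec$pos) == 0) return(empty_alignments())
  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar)
  data.frame(
    contig_id = as.character(rec$rname),
    start = rec$pos - 1L,                    # SAM pos is 1-based
    end = rec$pos - 1L + ref_width,
    strand = as.character(rec$strand),
    stringsAsFactors = FALSE
  )
}

read_bed6 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0) return(empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    format_error(sprintf(
      "BED line %d has %d columns; 6 required (strand in column 6)",
      which(nf < 6L)[1], nf[nf < 6L][1]))
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  strand <- m[, 6]
  if (any(!strand %in% c("+", "-"))) {
    format_error("BED strand column must be '+' or '-'")
  }
  data.frame(
    contig_id = m[, 1],
    start = as.integer(m[, 2]),
    end = as.integer(m[, 3]),
    strand = strand,
    stringsAsFactors = FALSE
  )
}

#' Write detected/classified TSS to TSV and GFF3
#'
#' The TSV begins with comment lines capturing the tool version and any
#' parameters supplied; a round-trip through [read_tss_tsv()] reproduces the
#' records. The GFF3 file uses feature type `TSS` with the class, read counts
#' and associated gene in the attribute column.
#'
#' @param records TSS data.frame as produced by [detect_tss()] /
#'   [classify_tss()].
#' @param path_prefix output prefix; files `<prefix>.tsv` and `<prefix>.gff3`
#'   are written.
#' @param params named list recorded in the TSV header comments.
#' @return invisibly, a character vector of the two paths written.
#' @export
write_tss_outputs <- function(records, path_prefix, params = list()) {
  tsv <- paste0(path_prefix, ".tsv")
  gff <- paste0(path_prefix, ".gff3")
  cols <- c("contig_id", "position", "strand", "window_reads", "starts",
            "enrichment", "tss_class", "gene_id", "offset")
  df <- as.data.frame(records)[, cols, drop = FALSE]
  write_tsv_with_header(df, tsv, params)

  con <- file(gff, open = "wt")
  writeLines("##gff-version 3", con)
  if (nrow(df) > 0) {
    attrs <- sprintf(
      "ID=TSS%06d;tss_class=%s;starts=%d;window_reads=%d%s",
      seq_len(nrow(df)), df$tss_class, df$starts, df$window_reads,
      ifelse(is.na(df$gene_id) | df$gene_id == "", "",
             sprintf(";gene_id=%s;offset=%d", df$gene_id, df$offset)))
    writeLines(sprintf("%s\tnodtx\tTSS\t%d\t%d\t.\t%s\t.\t%s",
                       df$contig_id, df$position, df$position,
                       df$strand, attrs), con)
  }
  close(con)
  invisible(c(tsv = tsv, gff3 = gff))
}

#' Read a TSS table written by [write_tss_outputs()]
#' @param path path to the `.tsv` file.
#' @return TSS data.frame.
#' @export
read_tss_tsv <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  df <- read_tsv_skip_comments(path)
  if (nrow(df) > 0) {
    df$enrichment <- as.numeric(df$enrichment)
    df$gene_id <- ifelse(is.na(df$gene_id), "", as.character(df$gene_id))
    df$offset <- suppressWarnings(as.integer(df$offset))
  } else {
    df$gene_id <- as.character(df$gene_id)
  }
  df
}

#' Build strand profiles directly from per-strand bedGraph tracks
#'
#' Alternative input path for precomputed tracks (0-based half-open bedGraph
#' intervals; column 4 is the per-position value over the interval).
#'
#' @param starts_plus,starts_minus,coverage_plus,coverage_minus paths to the
#'   four bedGraph files.
#' @param contigs a [Biostrings::DNAStringSet] or named lengths vector giving
#'   contig lengths.
#' @return a `strand_profiles` object (see [build_profiles()]).
#' @export
profiles_from_bedgraph <- function(starts_plus, starts_minus,
                                   coverage_plus, coverage_minus, contigs) {
  lens <- if (is.numeric(contigs)) contigs else contig_lengths(contigs)
  tracks <- lapply(
    list(sp = starts_plus, sm = starts_minus,
         cp = coverage_plus, cm = coverage_minus),
    function(p) read_bedgraph_track(p, lens))
  prof <- lapply(names(lens), function(cid) {
    list(starts_plus = tracks$sp[[cid]], starts_minus = tracks$sm[[cid]],
         coverage_plus = tracks$cp[[cid]], coverage_minus = tracks$cm[[cid]],
         length = unname(lens[[cid]]))
  })
  names(prof) <- names(lens)
  structure(prof, class = "strand_profiles")
}

read_bedgraph_track <- function(path, lens) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  out <- lapply(lens, function(L) integer(L))
  df <- tryCatch(
    utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                      col.names = c("contig", "start", "end", "value")),
    error = function(e) format_error(sprintf("bad bedGraph '%s': %s", path,
                                             conditionMessage(e))))
  for (i in seq_len(nrow(df))) {
    cid <- df$contig[i]
    if (!cid %in% names(out)) coordinate_error(sprintf("unknown contig '%s'", cid))
    if (df$end[i] > length(out[[cid]]) || df$start[i] < 0) {
      coordinate_error(sprintf("bedGraph interval outside contig '%s'", cid))
    }
    idx <- (df$start[i] + 1L):df$end[i]
    out[[cid]][idx] <- out[[cid]][idx] + as.integer(df$value[i])
  }
  out
}

#' Write sequences to FASTA
#' @param seqs a [Biostrings::DNAStringSet] or named character vector.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write gene features to GFF3
#' @param genes gene data.frame (see [read_gff()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes) > 0) {
    writeLines(sprintf("%s\tnodtx\t%s\t%d\t%d\t.\t%s\t0\tID=%s",
                       genes$contig_id, genes$feature_type, genes$start,
                       genes$end, genes$strand, genes$gene_id), con)
  }
  invisible(path)
}

#' Write alignments as BED6
#' @param alignments alignment data.frame (0-based half-open).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed6 <- function(alignments, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(alignments) > 0) {
    writeLines(sprintf("%s\t%d\t%d\tread%d\t0\t%s",
                       alignments$contig_id, alignments$start,
                       alignments$end, seq_len(nrow(alignments)),
                       alignments$strand), con)
  }
  invisible(path)
}

#' Write HSP records as 12-column BLAST tabular
#' @param hsps HSP data.frame (see [read_blast_tab()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_blast_tab <- function(hsps, path) {
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "query_start", "query_end",
            "subject_start", "subject_end", "evalue", "bitscore")
  utils::write.table(as.data.frame(hsps)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
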