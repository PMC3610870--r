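#' @keywords internal
"_PACKAGE"

#' @importFrom methods is
#' @importFrom stats rnorm rpois runif
#' @importFrom utils read.table write.table
NULL

# Condition constructors ------------------------------------------------------

nodtx_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "nodtx_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

format_error     <- function(msg) nodtx_error(msg, "nodtx_format_error")
parameter_error  <- function(msg) nodtx_error(msg, "nodtx_parameter_error")
coordinate_error <- function(msg) nodtx_error(msg, "nodtx_coordinate_error")
state_error      <- function(msg) nodtx_error(msg, "nodtx_state_error")
length_error     <- function(msg) nodtx_error(msg, "nodtx_length_error")

# Seeded evaluation without touching the caller's RNG stream ------------------

#' Evaluate an expression under a fixed seed, restoring global RNG state
#'
#' All generators in the package route their randomness through this helper so
#' that a call is bit-reproducible under `(params, seed)` and never perturbs
#' the session RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    parameter_error("`seed` must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Sequence helpers ------------------------------------------------------------

IUPAC_MAP <- c(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

is_iupac <- function(x) {
  all(strsplit(toupper(x), "", fixed = TRUE)[[1]] %in% names(IUPAC_MAP))
}

#' Reverse complement of a nucleotide string
#' @param x character scalar over the IUPAC alphabet.
#' @return character scalar.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Translate an IUPAC motif into a regular expression over {A,C,G,T}.
# `N` in the scanned sequence matches nothing: the character classes never
# include N, so draft-genome gap characters cannot create phantom hits.
iupac_regex <- function(motif) {
  chars <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), names(IUPAC_MAP))
  if (length(bad) > 0) {
    format_error(sprintf("non-IUPAC character(s) in motif: %s",
                         paste(bad, collapse = ", ")))
  }
  paste0(vapply(chars, function(ch) {
    opts <- IUPAC_MAP[[ch]]
    if (nchar(opts) == 1L) opts else paste0("[", opts, "]")
  }, character(1)), collapse = "")
}

# Extract a genome sequence as an uppercase character scalar, accepting a
# DNAStringSet, a named character vector, or a single string.
genome_as_character <- function(genome, contig_id = NULL) {
  if (is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else if (is.character(genome)) {
    seqs <- genome
  } else {
    parameter_error("`genome` must be a DNAStringSet or a character vector")
  }
  seqs <- toupper(seqs)
  if (is.null(contig_id)) {
    if (length(seqs) != 1L) {
      parameter_error("multiple contigs present; supply `contig_id`")
    }
    return(unname(seqs))
  }
  if (!contig_id %in% names(seqs)) {
    coordinate_error(sprintf("unknown contig '%s'", contig_id))
  }
  unname(seqs[[contig_id]])
}

contig_lengths <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else {
    stats::setNames(nchar(genome), names(genome))
  }
}

# Output header comment lines: tool version plus parameter capture ------------

nodtx_header <- function(params = list()) {
  ver <- tryCatch(as.character(utils::packageVersion("nodtx")),
                  error = function(e) "dev")
  lines <- c(sprintf("# nodtx %s", ver))
  if (length(params) > 0) {
    kv <- vapply(names(params), function(k) {
      sprintf("# %s=%s", k, paste(format(params[[k]]), collapse = ","))
    }, character(1))
    lines <- c(lines, kv)
  }
  lines
}

write_tsv_with_header <- function(df, path, params = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(nodtx_header(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_skip_comments <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, quote = "",
                    colClasses = NA, check.names = FALSE)
}
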