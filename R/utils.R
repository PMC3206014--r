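# Internal helpers shared across modules.  All genomic coordinates inside the
# package are 0-based half-open; GFF3 I/O converts to/from 1-based inclusive.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream.  seed = NULL means "draw from the ambient stream" (used by the
# scenario generator so that all sub-operations consume one documented
# stream).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

sense_codons <- function() {
  all64 <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  setdiff(all64, STOP_CODONS)
}

#' Generate a random coding sequence
#'
#' Draws a stop-free coding sequence: an ATG start codon followed by
#' uniformly sampled sense codons.  Used by the scenario generator and by
#' simulation tests as neutral starting material.
#'
#' @param n_codons total codon count (including the start codon).
#' @param seed optional integer seed; `NULL` draws from the current RNG
#'   stream.
#' @return a single upper-case DNA string of length `3 * n_codons` with no
#'   in-frame stop codon.
#' @export
random_cds <- function(n_codons, seed = NULL) {
  stopifnot(n_codons >= 2)
  with_seed(seed, {
    body <- sample(sense_codons(), n_codons - 1L, replace = TRUE)
    paste0("ATG", paste(body, collapse = ""))
  })
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

codons_of <- function(s, frame = 0L) {
  n <- nchar(s)
  if (n - frame < 3L) return(character(0))
  starts <- seq.int(frame + 1L, n - 2L, by = 3L)
  substring(s, starts, starts + 2L)
}

translate_nt <- function(s, frame = 0L) {
  cod <- codons_of(s, frame)
  if (!length(cod)) return("")
  aa <- unname(Biostrings::GENETIC_CODE[cod])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Gap between two 0-based half-open intervals on the same sequence
# (0 if they overlap or touch).
interval_gap0 <- function(s1, e1, s2, e2) {
  pmax(pmax(s2 - e1, s1 - e2), 0L)
}

# Reciprocal overlap fraction of two 0-based half-open intervals.
reciprocal_overlap <- function(s1, e1, s2, e2) {
  inter <- pmax(0L, pmin(e1, e2) - pmax(s1, s2))
  pmin(inter / (e1 - s1), inter / (e2 - s2))
}

# Apply uniform random substitutions (no reading-frame awareness); used for
# non-coding flank sequences in the scenario generator.
mutate_dna <- function(s, rate) {
  if (rate <= 0) return(s)
  x <- seq_chars(s)
  hit <- which(runif(length(x)) < rate)
  for (p in hit) {
    x[p] <- sample(setdiff(BASES, x[p]), 1L)
  }
  paste(x, collapse = "")
}

empty_hits <- function() {
  data.frame(
    hit_id = character(0), exon_id = character(0), gene_id = character(0),
    contig = character(0), start0 = integer(0), end0 = integer(0),
    strand = character(0), score = numeric(0),
    query_start = integer(0), query_end = integer(0),
    stringsAsFactors = FALSE
  )
}

ann_granges <- function(ann, types = NULL) {
  keep <- if (is.null(types)) rep(TRUE, nrow(ann)) else ann$type %in% types
  a <- ann[keep, , drop = FALSE]
  if (!nrow(a)) {
    return(GenomicRanges::GRanges())
  }
  gr <- GenomicRanges::GRanges(
    seqnames = a$contig,
    ranges = IRanges::IRanges(start = a$start0 + 1L, end = a$end0),
    strand = a$strand
  )
  S4Vectors::mcols(gr)$feature_id <- a$feature_id
  S4Vectors::mcols(gr)$gene_id <- a$gene_id
  S4Vectors::mcols(gr)$type <- a$type
  gr
}

hits_granges <- function(hits) {
  if (!nrow(hits)) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(
    seqnames = hits$contig,
    ranges = IRanges::IRanges(start = hits$start0 + 1L, end = hits$end0),
    strand = "*"
  )
  S4Vectors::mcols(gr)$hit_id <- hits$hit_id
  gr
}
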