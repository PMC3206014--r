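# Cross-species characterisation of RR candidates: frame scans, global
# alignment, nucleotide identity vs amino-acid similarity, and Ka/Ks
# (Nei-Gojobori counting with Jukes-Cantor correction) after indel and
# stop-codon stripping.

#' Scan one reading frame for stop codons
#'
#' @param sequence nucleotide sequence.
#' @param frame frame offset 0, 1 or 2.
#' @param strand `"+"` scans the sequence as given, `"-"` scans its reverse
#'   complement (positions reported on the scanned strand).
#' @return data frame with `codon` (1-based codon index) and `pos0`
#'   (0-based nt position of the stop codon's first base); zero rows iff
#'   the frame is stop free.
#' @export
scan_frame_stops <- function(sequence, frame = 0L, strand = "+") {
  stopifnot(frame %in% 0:2)
  s <- toupper(sequence)
  if (strand == "-") s <- revcomp_chr(s)
  cod <- codons_of(s, frame)
  idx <- which(cod %in% STOP_CODONS)
  data.frame(codon = idx, pos0 = frame + 3L * (idx - 1L))
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment under the package's standard
#' nucleotide scheme (match 5, mismatch -4 — a 65% similarity cost matrix —
#' gap open 12, gap extension 3).  Traceback is deterministic (the
#' implementation's fixed preference order), so repeated calls return the
#' identical alignment.
#'
#' @param a,b nucleotide sequences (non-empty).
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return a `pairwise_alignment`: list with gapped sequences `a` and `b`,
#'   `score`, and the scoring `params`.
#' @export
global_align <- function(a, b, match = 5, mismatch = -4, gap_open = 12,
                         gap_extend = 3) {
  if (!nzchar(a) || !nzchar(b)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  scoring <- list(match = match, mismatch = mismatch,
                  gap_open = gap_open, gap_extend = gap_extend)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
    type = "global", substitutionMatrix = nt_submat(scoring),
    gapOpening = gap_open, gapExtension = gap_extend)
  out <- structure(list(
    a = as.character(Biostrings::alignedPattern(aln)),
    b = as.character(Biostrings::alignedSubject(aln)),
    score = Biostrings::score(aln),
    params = scoring
  ), class = "pairwise_alignment")
  stopifnot(gsub("-", "", out$a) == toupper(a),
            gsub("-", "", out$b) == toupper(b))
  out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("pairwise_alignment (score ", x$score, ")\n", sep = "")
  cat("  ", x$a, "\n  ", x$b, "\n", sep = "")
  invisible(x)
}

aa_of_codon <- function(cod) {
  aa <- unname(Biostrings::GENETIC_CODE[cod])
  aa[is.na(aa)] <- "X"
  aa
}

#' Nucleotide identity and amino-acid similarity of an alignment
#'
#' Computes the percentage nucleotide identity (identical aligned columns)
#' and the amino-acid similarity (aligned codon pairs with a positive
#' BLOSUM62 score, translated in the reference reading frame), each
#' relative to the alignable reference length (default) or to the shorter
#' of the two sequences.
#'
#' @param aln a `pairwise_alignment` from [global_align()].
#' @param reference which input (1 or 2) is the reference exon.
#' @param frame_offset frame offset of the reference's first complete codon.
#' @param denominator `"reference"` (alignable reference length) or
#'   `"shortest"`.
#' @param species optional species label carried into the result.
#' @return an `identity_profile`: list with `species`, `nt_identity_pct`,
#'   `aa_similarity_pct`, `alignable_length`.
#' @export
identity_profile <- function(aln, reference = 1L, frame_offset = 0L,
                             denominator = c("reference", "shortest"),
                             species = NA_character_) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(aln, "pairwise_alignment"))
  A <- seq_chars(if (reference == 1L) aln$a else aln$b)
  B <- seq_chars(if (reference == 1L) aln$b else aln$a)
  ref_len <- sum(A != "-")
  other_len <- sum(B != "-")
  den_nt <- if (denominator == "reference") ref_len else min(ref_len, other_len)
  matches <- sum(A == B & A != "-")
  nt_pct <- 100 * matches / den_nt

  data("BLOSUM62", package = "Biostrings", envir = environment())
  ref_cols <- which(A != "-")
  n_cod <- (length(ref_cols) - frame_offset) %/% 3L
  similar <- 0L
  for (k in seq_len(n_cod)) {
    cols <- ref_cols[frame_offset + (3L * (k - 1L) + 1L):(3L * k)]
    cb <- B[cols]
    if (any(cb == "-") || (cols[3] - cols[1]) != 2L) next
    aa1 <- aa_of_codon(paste(A[cols], collapse = ""))
    aa2 <- aa_of_codon(paste(cb, collapse = ""))
    if (BLOSUM62[aa1, aa2] > 0) similar <- similar + 1L
  }
  den_cod <- max(1L, (den_nt - frame_offset) %/% 3L)
  structure(list(
    species = species,
    nt_identity_pct = nt_pct,
    aa_similarity_pct = 100 * min(similar, den_cod) / den_cod,
    alignable_length = den_nt
  ), class = "identity_profile")
}

#' Strip indels and stop codons from an aligned pair
#'
#' Prepares a codon alignment for Ka/Ks: reference codons whose aligned
#' columns contain a gap in either sequence (or are interrupted by an
#' insertion) are dropped, as are codons that are stop codons in either
#' sequence.  The counts of removed codons are reported — for an RR the
#' stop count is the frame-disruption evidence itself.
#'
#' @param aln a `pairwise_alignment`.
#' @param reference which input (1 or 2) is the reference exon.
#' @param frame_offset reference frame offset.
#' @return list with gap-free codon-aligned `reference` and `query`
#'   strings, `codons_used`, and `removed` (named counts `indel_codons`,
#'   `stop_codons`).
#' @export
strip_indels_and_stops <- function(aln, reference = 1L, frame_offset = 0L) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  A <- seq_chars(if (reference == 1L) aln$a else aln$b)
  B <- seq_chars(if (reference == 1L) aln$b else aln$a)
  ref_cols <- which(A != "-")
  n_cod <- (length(ref_cols) - frame_offset) %/% 3L
  keep_a <- character(0)
  keep_b <- character(0)
  removed <- c(indel_codons = 0L, stop_codons = 0L)
  for (k in seq_len(n_cod)) {
    cols <- ref_cols[frame_offset + (3L * (k - 1L) + 1L):(3L * k)]
    ca <- paste(A[cols], collapse = "")
    cb <- paste(B[cols], collapse = "")
    if (grepl("-", cb, fixed = TRUE) || (cols[3] - cols[1]) != 2L) {
      removed["indel_codons"] <- removed["indel_codons"] + 1L
      next
    }
    if (ca %in% STOP_CODONS || cb %in% STOP_CODONS) {
      removed["stop_codons"] <- removed["stop_codons"] + 1L
      next
    }
    keep_a <- c(keep_a, ca)
    keep_b <- c(keep_b, cb)
  }
  if (length(keep_a) < 3L) {
    stop("insufficient data: fewer than 3 codons remain after stripping",
         call. = FALSE)
  }
  list(reference = paste(keep_a, collapse = ""),
       query = paste(keep_b, collapse = ""),
       codons_used = length(keep_a), removed = removed)
}

# memoisation for the per-codon NG86 quantities (4096 pairs at most)
.ng86_cache <- new.env(parent = emptyenv())

# Synonymous site count of one codon (Nei-Gojobori): at each position, the
# fraction of the three possible changes that are synonymous.  Changes to a
# stop codon count as nonsynonymous.
ng86_syn_sites <- function(cod) {
  hit <- .ng86_cache[[paste0("s", cod)]]
  if (!is.null(hit)) return(hit)
  x <- seq_chars(cod)
  aa <- aa_of_codon(cod)
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(BASES, x[p])) {
      y <- x
      y[p] <- b
      cod2 <- paste(y, collapse = "")
      if (!(cod2 %in% STOP_CODONS) && aa_of_codon(cod2) == aa) {
        s <- s + 1 / 3
      }
    }
  }
  .ng86_cache[[paste0("s", cod)]] <- s
  s
}

perms_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Average synonymous/nonsynonymous substitution counts between two codons
# over all mutational pathways; pathways through stop codons are excluded
# when possible (if all pathways are blocked they are re-admitted, with
# steps to or from a stop counted as nonsynonymous).
ng86_path_counts <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .ng86_cache[[key]]
  if (!is.null(hit)) return(hit)
  x1 <- seq_chars(c1)
  x2 <- seq_chars(c2)
  dif <- which(x1 != x2)
  if (!length(dif)) return(c(syn = 0, nonsyn = 0))
  walk <- function(skip_stops) {
    acc <- matrix(NA_real_, nrow = 0L, ncol = 2L)
    for (path in perms_of(dif)) {
      cur <- x1
      sy <- 0
      ns <- 0
      ok <- TRUE
      for (p in path) {
        nxt <- cur
        nxt[p] <- x2[p]
        cod_a <- paste(cur, collapse = "")
        cod_b <- paste(nxt, collapse = "")
        if (skip_stops && (cod_b %in% STOP_CODONS) && cod_b != c2) {
          ok <- FALSE
          break
        }
        if (aa_of_codon(cod_a) == aa_of_codon(cod_b) &&
            !(cod_b %in% STOP_CODONS) && !(cod_a %in% STOP_CODONS)) {
          sy <- sy + 1
        } else {
          ns <- ns + 1
        }
        cur <- nxt
      }
      if (ok) acc <- rbind(acc, c(sy, ns))
    }
    acc
  }
  acc <- walk(TRUE)
  if (!nrow(acc)) acc <- walk(FALSE)
  out <- c(syn = mean(acc[, 1]), nonsyn = mean(acc[, 2]))
  .ng86_cache[[key]] <- out
  out
}

jc_correct <- function(p) {
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Ka/Ks by Nei-Gojobori counting with Jukes-Cantor correction
#'
#' Counts synonymous and nonsynonymous sites (averaged over both sequences)
#' and substitutions (equal-weight averaging over mutational pathways for
#' multi-hit codons), then applies the Jukes-Cantor multiple-hit correction
#' to both proportions.  A Ka/Ks well below 1 is the protein-level
#' purifying-selection signature of a coding exon; an elevated ratio at an
#' alignable exon relic indicates loss of coding constraint — the RR
#' diagnosis.
#'
#' @param pair either the list returned by [strip_indels_and_stops()] or a
#'   character vector of two equal-length, gap-free, stop-free in-frame
#'   sequences.
#' @param query second sequence when `pair` is a single string.
#' @return a `kaks_result`: list with `ka`, `ks`, `ratio`, `ratio_class`
#'   (`"defined"`, `"undefined_no_sites"`, `"infinite_ks_zero"`,
#'   `"saturated"`), site and substitution counts, `codons_used` and any
#'   `removed` counts carried over from stripping.
#' @export
compute_kaks <- function(pair, query = NULL) {
  removed <- NULL
  if (is.list(pair) && !is.null(pair$reference)) {
    a <- pair$reference
    b <- pair$query
    removed <- pair$removed
  } else {
    a <- pair
    b <- query
  }
  a <- toupper(a)
  b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences must have equal length", call. = FALSE)
  if (nchar(a) %% 3L != 0L) stop("length must be divisible by 3", call. = FALSE)
  if (grepl("-", paste0(a, b), fixed = TRUE)) {
    stop("sequences must be gap free (see strip_indels_and_stops)", call. = FALSE)
  }
  cod_a <- codons_of(a)
  cod_b <- codons_of(b)
  if (any(c(cod_a, cod_b) %in% STOP_CODONS)) {
    stop("sequences must be stop free (see strip_indels_and_stops)", call. = FALSE)
  }
  S <- (sum(vapply(cod_a, ng86_syn_sites, numeric(1))) +
          sum(vapply(cod_b, ng86_syn_sites, numeric(1)))) / 2
  N <- 3 * length(cod_a) - S
  counts <- vapply(seq_along(cod_a), function(i) {
    ng86_path_counts(cod_a[i], cod_b[i])
  }, numeric(2))
  Sd <- sum(counts["syn", ])
  Nd <- sum(counts["nonsyn", ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  ks <- jc_correct(ps)
  ka <- jc_correct(pn)
  ratio_class <- if (is.na(ka) || is.na(ks)) {
    "saturated"
  } else if (Sd == 0 && Nd == 0) {
    "undefined_no_sites"
  } else if (ks == 0) {
    "infinite_ks_zero"
  } else {
    "defined"
  }
  structure(list(
    ka = ka, ks = ks,
    ratio = if (ratio_class == "defined") ka / ks else NA_real_,
    ratio_class = ratio_class,
    syn_sites = S, nonsyn_sites = N, syn_subs = Sd, nonsyn_subs = Nd,
    codons_used = length(cod_a), removed = removed
  ), class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("Ka = %.4f  Ks = %.4f  Ka/Ks = %s (%s)\n",
              x$ka %||% NA, x$ks %||% NA,
              if (is.na(x$ratio)) "-" else sprintf("%.4f", x$ratio),
              x$ratio_class))
  invisible(x)
}

#' Contrast the Ka/Ks of an RR against its coding homolog
#'
#' @param rr,coding `kaks_result` objects.
#' @return list with both ratios, their difference, which locus shows the
#'   coding (low Ka/Ks) signature, and an `indeterminate` flag when either
#'   ratio is undefined.
#' @export
contrast_kaks <- function(rr, coding) {
  indeterminate <- rr$ratio_class != "defined" || coding$ratio_class != "defined"
  list(
    ratio_rr = rr$ratio, ratio_coding = coding$ratio,
    difference = if (indeterminate) NA_real_ else rr$ratio - coding$ratio,
    coding_signature = if (indeterminate) NA_character_ else
      if (coding$ratio <= rr$ratio) "coding" else "rr",
    indeterminate = indeterminate
  )
}
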