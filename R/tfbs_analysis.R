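# PWM scanning at a relative-score threshold, Fitch parsimony ancestral
# reconstruction, teleost-specific binding-site calling, and the S200 /
# regulatory-potential statistics.

IUPAC_SETS <- strsplit(Biostrings::IUPAC_CODE_MAP, "")

#' Build a PWM from a position frequency matrix
#'
#' Adds a background-distributed pseudocount (default 0.8, a common
#' convention) to the counts, converts to log2 odds against the background,
#' and records the per-matrix score range used for relative scoring.
#'
#' @param counts 4 x L non-negative count matrix with rows A, C, G, T.
#' @param matrix_id,name identifiers.
#' @param background base composition (must sum to 1; default uniform).
#' @param pseudocount total pseudocount distributed by background.
#' @return a `pwm` object: counts, `log_odds`, `min_score`, `max_score`,
#'   and an `uninformative` flag when the score range is empty.
#' @export
pwm_from_counts <- function(counts, matrix_id = "PWM", name = matrix_id,
                            background = rep(0.25, 4), pseudocount = 0.8) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("`counts` must have 4 rows (A, C, G, T)", call. = FALSE)
  if (ncol(counts) < 1L) stop("`counts` must have at least one column", call. = FALSE)
  if (any(counts < 0)) stop("`counts` must be non-negative", call. = FALSE)
  if (any(colSums(counts) <= 0)) stop("zero-sum column in `counts`", call. = FALSE)
  if (abs(sum(background) - 1) > 1e-6) stop("`background` must sum to 1", call. = FALSE)
  storage.mode(counts) <- "double"
  rownames(counts) <- BASES
  probs <- sweep(counts + pseudocount * background, 2L,
                 colSums(counts) + pseudocount, "/")
  lo <- log2(sweep(probs, 1L, background, "/"))
  structure(list(
    matrix_id = matrix_id, name = name, counts = counts, log_odds = lo,
    background = background, pseudocount = pseudocount,
    min_score = sum(apply(lo, 2L, min)),
    max_score = sum(apply(lo, 2L, max)),
    uninformative = isTRUE(all.equal(sum(apply(lo, 2L, min)),
                                     sum(apply(lo, 2L, max))))
  ), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (%s), width %d, score range [%.2f, %.2f]\n",
              x$matrix_id, x$name, ncol(x$counts), x$min_score, x$max_score))
  invisible(x)
}

#' Read position frequency matrices in JASPAR format
#'
#' Parses the JASPAR PFM text layout (`>ID NAME` followed by four
#' `A [ ... ]`-style count rows).  Matrices with an empty score range are
#' rejected as uninformative, with a warning.
#'
#' @param path PFM file.
#' @inheritParams pwm_from_counts
#' @return list of `pwm` objects.
#' @export
read_jaspar_pfm <- function(path, background = rep(0.25, 4),
                            pseudocount = 0.8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- which(startsWith(lines, ">"))
  if (!length(heads)) stop("no PFM records found in ", path, call. = FALSE)
  out <- list()
  for (h in seq_along(heads)) {
    from <- heads[h] + 1L
    to <- if (h < length(heads)) heads[h + 1L] - 1L else length(lines)
    hdr <- strsplit(sub("^>", "", lines[heads[h]]), "\\s+")[[1]]
    block <- lines[from:to]
    if (length(block) != 4L) {
      stop("PFM record ", hdr[1], " must have 4 count rows", call. = FALSE)
    }
    rows <- lapply(block, function(ln) {
      ln <- gsub("[][]", " ", ln)
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (f[1] %in% BASES) f <- f[-1]
      as.numeric(f)
    })
    if (length(unique(lengths(rows))) != 1L) {
      stop("ragged count rows in PFM record ", hdr[1], call. = FALSE)
    }
    counts <- do.call(rbind, rows)
    letters <- substr(trimws(block), 1L, 1L)
    if (all(letters %in% BASES)) counts <- counts[match(BASES, letters), ]
    pwm <- pwm_from_counts(counts, matrix_id = hdr[1],
                           name = if (length(hdr) > 1L) hdr[2] else hdr[1],
                           background = background, pseudocount = pseudocount)
    if (pwm$uninformative) {
      warning("PFM ", hdr[1], " is uninformative (flat score range); dropped")
      next
    }
    out[[length(out) + 1L]] <- pwm
  }
  out
}

#' Write PWMs in JASPAR PFM format
#'
#' @param pwms list of `pwm` objects.
#' @param path output file.
#' @export
write_jaspar_pfm <- function(pwms, path) {
  lines <- unlist(lapply(pwms, function(p) {
    c(paste0(">", p$matrix_id, " ", p$name),
      vapply(seq_len(4L), function(r) {
        paste0(BASES[r], " [ ", paste(format(p$counts[r, ], trim = TRUE),
                                      collapse = " "), " ]")
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

# Per-position log-odds score of a character under each PWM column, with
# IUPAC ambiguity resolved optimistically (maximum over compatible bases)
# so that "present in any disambiguation" is decidable on ancestral
# sequences.  Unknown characters (including gaps) score -Inf.
score_positions <- function(x, lo) {
  L <- ncol(lo)
  out <- matrix(-Inf, nrow = length(x), ncol = L)
  for (ch in unique(x)) {
    rows <- which(x == ch)
    if (ch %in% BASES) {
      out[rows, ] <- matrix(lo[ch, ], nrow = length(rows), ncol = L,
                            byrow = TRUE)
    } else if (ch %in% names(IUPAC_SETS)) {
      bs <- intersect(IUPAC_SETS[[ch]], BASES)
      if (length(bs)) {
        v <- apply(lo[bs, , drop = FALSE], 2L, max)
        out[rows, ] <- matrix(v, nrow = length(rows), ncol = L, byrow = TRUE)
      }
    }
  }
  out
}

#' Scan a sequence with a PWM at a relative-score threshold
#'
#' Scores every window on both strands; the relative score is
#' `(raw - min_score) / (max_score - min_score)` and windows at or above
#' `rel_threshold` (default 0.8, the usual "80% relative profile score")
#' are reported.  IUPAC ambiguity codes score as the best compatible base,
#' so a hit on an ambiguous (e.g. reconstructed ancestral) sequence means
#' some disambiguation reaches the threshold.
#'
#' @param sequence nucleotide sequence (may contain IUPAC codes).
#' @param pwm a `pwm` object.
#' @param rel_threshold relative score threshold in (0, 1].
#' @param sequence_id label carried into the hit table.
#' @param strands strands to scan.
#' @return data frame `matrix_id`, `sequence_id`, `pos0` (0-based start on
#'   the forward strand), `strand`, `score`, `rel_score`.
#' @export
scan_pwm <- function(sequence, pwm, rel_threshold = 0.8,
                     sequence_id = "seq", strands = c("+", "-")) {
  if (rel_threshold <= 0 || rel_threshold > 1) {
    stop("`rel_threshold` must be in (0, 1]", call. = FALSE)
  }
  empty <- data.frame(matrix_id = character(0), sequence_id = character(0),
                      pos0 = integer(0), strand = character(0),
                      score = numeric(0), rel_score = numeric(0),
                      stringsAsFactors = FALSE)
  s <- toupper(sequence)
  w <- ncol(pwm$log_odds)
  n <- nchar(s)
  if (n < w) return(empty)
  rng <- pwm$max_score - pwm$min_score
  if (rng <= 0) return(empty)
  out <- list()
  for (strand in strands) {
    sc <- if (strand == "+") s else revcomp_chr(s)
    x <- seq_chars(sc)
    ps <- score_positions(x, pwm$log_odds)
    nw <- n - w + 1L
    raw <- vapply(seq_len(nw), function(i) {
      sum(ps[cbind(i:(i + w - 1L), 1:w)])
    }, numeric(1))
    rel <- (raw - pwm$min_score) / rng
    hit <- which(rel >= rel_threshold)
    if (length(hit)) {
      pos0 <- if (strand == "+") hit - 1L else n - (hit - 1L) - w
      out[[length(out) + 1L]] <- data.frame(
        matrix_id = pwm$matrix_id, sequence_id = sequence_id,
        pos0 = pos0, strand = strand, score = raw[hit], rel_score = rel[hit],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  out <- do.call(rbind, out)
  out <- out[order(out$pos0, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan an aligned (gapped) sequence and report alignment-column positions
#'
#' Degaps the row, scans it with [scan_pwm()], and maps every hit back to
#' 0-based half-open alignment-column coordinates so hits from different
#' species are positionally comparable.
#'
#' @param aligned_seq one gapped row of an MSA.
#' @inheritParams scan_pwm
#' @return the [scan_pwm()] hit table with added `col_start0`, `col_end0`.
#' @export
scan_aligned <- function(aligned_seq, pwm, rel_threshold = 0.8,
                         sequence_id = "seq", strands = c("+", "-")) {
  x <- seq_chars(toupper(aligned_seq))
  keep <- which(x != "-")
  hits <- scan_pwm(paste(x[keep], collapse = ""), pwm,
                   rel_threshold = rel_threshold, sequence_id = sequence_id,
                   strands = strands)
  w <- ncol(pwm$log_odds)
  hits$col_start0 <- if (nrow(hits)) keep[hits$pos0 + 1L] - 1L else integer(0)
  hits$col_end0 <- if (nrow(hits)) keep[hits$pos0 + w] else integer(0)
  hits
}

site_present <- function(hits, matrix_id, cs, ce) {
  any(hits$matrix_id == matrix_id & hits$col_start0 < ce & hits$col_end0 > cs)
}

#' Call lineage-specific binding sites
#'
#' Reports sites (same matrix, overlapping alignment columns) present in
#' every teleost sequence and absent from every non-teleost sequence and
#' from the reconstructed ancestor — the definition of a binding site that
#' arose on the teleost branch after duplication.
#'
#' @param teleost_hits named list of hit tables from [scan_aligned()], one
#'   per teleost sequence (non-empty list).
#' @param other_hits named list of hit tables for the non-teleost species.
#' @param ancestor_hits hit table of the reconstructed ancestral sequence.
#' @param require `"all"` (default: present in every teleost) or `"any"`.
#' @return the qualifying hits (rows of the first teleost's table, or of
#'   the union when `require = "any"`).
#' @export
lineage_specific_sites <- function(teleost_hits, other_hits,
                                   ancestor_hits = NULL,
                                   require = c("all", "any")) {
  require <- match.arg(require)
  if (!length(teleost_hits)) {
    stop("`teleost_hits` must contain at least one hit table", call. = FALSE)
  }
  proposals <- if (require == "all") teleost_hits[[1]] else {
    do.call(rbind, teleost_hits)
  }
  if (!nrow(proposals)) return(proposals[0, , drop = FALSE])
  keep <- vapply(seq_len(nrow(proposals)), function(i) {
    m <- proposals$matrix_id[i]
    cs <- proposals$col_start0[i]
    ce <- proposals$col_end0[i]
    if (require == "all") {
      in_teleosts <- all(vapply(teleost_hits, site_present, logical(1),
                                matrix_id = m, cs = cs, ce = ce))
      if (!in_teleosts) return(FALSE)
    }
    in_others <- any(vapply(other_hits, site_present, logical(1),
                            matrix_id = m, cs = cs, ce = ce))
    if (in_others) return(FALSE)
    if (!is.null(ancestor_hits) && site_present(ancestor_hits, m, cs, ce)) {
      return(FALSE)
    }
    TRUE
  }, logical(1))
  out <- proposals[keep, , drop = FALSE]
  # de-duplicate sites found in several teleosts (require = "any")
  if (nrow(out) > 1L) {
    dup <- logical(nrow(out))
    for (i in 2:nrow(out)) {
      for (j in 1:(i - 1L)) {
        if (!dup[j] && out$matrix_id[i] == out$matrix_id[j] &&
            out$col_start0[i] < out$col_end0[j] &&
            out$col_end0[i] > out$col_start0[j]) {
          dup[i] <- TRUE
          break
        }
      }
    }
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

mask_of_char <- function(ch) {
  bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  vapply(ch, function(c1) {
    if (c1 %in% BASES) return(bits[[c1]])
    set <- IUPAC_SETS[[c1]]
    if (is.null(set)) return(15L)  # gap / unknown: uninformative
    sum(bits[intersect(set, BASES)])
  }, integer(1), USE.NAMES = FALSE)
}

char_of_mask <- function(mask) {
  bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  codes <- vapply(names(Biostrings::IUPAC_CODE_MAP), function(code) {
    sum(bits[strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1]]])
  }, integer(1))
  lookup <- setNames(names(codes), codes)
  unname(lookup[as.character(mask)])
}

#' Ancestral sequence reconstruction by Fitch parsimony
#'
#' Per-column Fitch parsimony (uniform cost) on a rooted binary tree: the
#' standard post-order intersection/union pass followed by the pre-order
#' (Fitch final state) pass, so that internal nodes are resolved by the
#' context of the rest of the tree — an outgroup agreeing with one clade
#' pulls the ancestral state towards it.  The reported state at the
#' requested node is its final state set, written as an IUPAC ambiguity
#' code when more than one base is equally parsimonious.  Gaps and unknown
#' characters are treated as uninformative (full base set).  Deterministic
#' by construction.
#'
#' @param msa named character vector (or `DNAStringSet`) of equal-length
#'   aligned sequences; names must match the tree's tip labels (extra
#'   sequences are ignored).
#' @param tree an `ape::phylo` object, a Newick string, or a Newick file
#'   path.
#' @param node internal node label to reconstruct (`"root"` = the root).
#' @return an `ancestral_sequence`: list with `label`, `sequence` (IUPAC),
#'   `method`, `parsimony_score` (total Fitch substitution count over the
#'   whole tree) and `ambiguous_columns`.
#' @export
reconstruct_ancestor <- function(msa, tree, node = "root") {
  if (methods::is(msa, "XStringSet")) msa <- as.character(msa)
  if (is.null(names(msa))) stop("`msa` must be named", call. = FALSE)
  if (length(unique(nchar(msa))) != 1L) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  tr <- if (inherits(tree, "phylo")) {
    tree
  } else if (grepl("(", tree[1], fixed = TRUE)) {
    ape::read.tree(text = tree[1])
  } else {
    ape::read.tree(file = tree)
  }
  missing <- setdiff(tr$tip.label, names(msa))
  if (length(missing)) {
    stop("sequences missing for tree tips: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n_tip <- length(tr$tip.label)
  n_node <- tr$Nnode
  root_id <- n_tip + 1L
  node_id <- if (identical(node, "root")) {
    root_id
  } else {
    hit <- which(tr$node.label == node)
    if (!length(hit)) stop("internal node not found: ", node, call. = FALSE)
    n_tip + hit[1]
  }
  L <- nchar(msa[[1]])
  n_all <- n_tip + n_node
  prelim <- matrix(0L, nrow = n_all, ncol = L)
  for (k in seq_len(n_tip)) {
    prelim[k, ] <- mask_of_char(seq_chars(toupper(msa[[tr$tip.label[k]]])))
  }
  score <- integer(L)
  edge <- tr$edge[order(tr$edge[, 1L], tr$edge[, 2L]), , drop = FALSE]
  children <- split(edge[, 2L], edge[, 1L])
  post <- unique(stats::reorder(tr, "postorder")$edge[, 1L])
  union_col <- matrix(FALSE, nrow = n_all, ncol = L)   # prelim formed by union
  kid_union <- matrix(0L, nrow = n_all, ncol = L)      # union of children prelims
  for (nd in post) {
    kids <- children[[as.character(nd)]]
    st <- prelim[kids[1], ]
    uni <- prelim[kids[1], ]
    was_union <- rep(FALSE, L)
    for (k in kids[-1]) {
      inter <- bitwAnd(st, prelim[k, ])
      un <- bitwOr(st, prelim[k, ])
      empty <- inter == 0L
      score <- score + as.integer(empty)
      st <- ifelse(empty, un, inter)
      was_union <- was_union | empty
      uni <- bitwOr(uni, prelim[k, ])
    }
    prelim[nd, ] <- st
    union_col[nd, ] <- was_union
    kid_union[nd, ] <- uni
  }
  # pre-order final-state pass (Fitch 1971 / Swofford & Maddison rules)
  final <- matrix(0L, nrow = n_all, ncol = L)
  final[root_id, ] <- prelim[root_id, ]
  for (nd in rev(post)) {           # parents before children
    fu <- final[nd, ]
    for (v in children[[as.character(nd)]]) {
      if (v <= n_tip) next
      x <- bitwAnd(fu, prelim[v, ])
      same <- x == fu
      alt <- ifelse(union_col[v, ],
                    bitwOr(prelim[v, ], fu),
                    bitwOr(prelim[v, ], bitwAnd(fu, kid_union[v, ])))
      final[v, ] <- ifelse(same, x, alt)
    }
  }
  seqc <- char_of_mask(final[node_id, ])
  structure(list(
    label = node, sequence = paste(seqc, collapse = ""),
    method = "fitch_parsimony", parsimony_score = sum(score),
    ambiguous_columns = sum(!seqc %in% BASES)
  ), class = "ancestral_sequence")
}

#' @export
print.ancestral_sequence <- function(x, ...) {
  cat(sprintf("ancestral_sequence at '%s' (%s): %d nt, %d ambiguous, score %d\n",
              x$label, x$method, nchar(x$sequence), x$ambiguous_columns,
              x$parsimony_score))
  invisible(x)
}

#' Binding sites per 200 bp (S200)
#'
#' For each sequence, counts PWM hits (all matrices, both strands, at the
#' relative threshold) and normalises to sites per 200 bp.  The S200
#' distribution of a sequence set is the ingredient of the
#' regulatory-potential comparison.
#'
#' @param sequences named character vector of sequences.
#' @param pwms list of `pwm` objects.
#' @param rel_threshold relative score threshold.
#' @param bin_width histogram bin width in sites/200 bp.
#' @param label set label.
#' @return an `s200_distribution`: `label`, per-sequence `values`, histogram
#'   `breaks` and `counts`, `bin_width`.
#' @export
s200 <- function(sequences, pwms, rel_threshold = 0.8, bin_width = 1,
                 label = "set") {
  if (!length(sequences)) stop("`sequences` must be non-empty", call. = FALSE)
  zero <- nchar(sequences) == 0L
  if (any(zero)) {
    warning(sum(zero), " zero-length sequence(s) skipped")
    sequences <- sequences[!zero]
  }
  values <- vapply(seq_along(sequences), function(i) {
    nh <- sum(vapply(pwms, function(p) {
      nrow(scan_pwm(sequences[[i]], p, rel_threshold = rel_threshold,
                    sequence_id = names(sequences)[i] %||% "seq"))
    }, numeric(1)))
    nh * 200 / nchar(sequences[[i]])
  }, numeric(1))
  names(values) <- names(sequences)
  breaks <- seq(0, (floor(max(values) / bin_width) + 1L) * bin_width,
                by = bin_width)
  counts <- tabulate(findInterval(values, breaks), nbins = length(breaks) - 1L)
  structure(list(label = label, values = values, breaks = breaks,
                 counts = counts, bin_width = bin_width),
            class = "s200_distribution")
}

#' Overlap ("regulatory potential") of two S200 distributions
#'
#' The overlap coefficient of the two binned distributions: the sum over
#' bins of the minimum bin proportion, as a percentage.  When a query set's
#' S200 distribution is compared against a validated-enhancer reference,
#' this overlap is the set's regulatory potential.  Symmetric and bounded
#' in `[0, 100]`.
#'
#' @param query,enhancer_ref `s200_distribution` objects.
#' @return overlap percentage.
#' @export
regulatory_potential <- function(query, enhancer_ref) {
  stopifnot(inherits(query, "s200_distribution"),
            inherits(enhancer_ref, "s200_distribution"))
  if (!length(query$values) || !length(enhancer_ref$values)) {
    stop("both distributions must be non-empty", call. = FALSE)
  }
  if (!identical(query$breaks, enhancer_ref$breaks)) {
    warning("bin edges differ; rebinning to common edges")
    bw <- min(query$bin_width, enhancer_ref$bin_width)
    top <- max(c(query$values, enhancer_ref$values))
    breaks <- seq(0, (floor(top / bw) + 1L) * bw, by = bw)
    rebin <- function(v) tabulate(findInterval(v, breaks),
                                  nbins = length(breaks) - 1L)
    cq <- rebin(query$values)
    cr <- rebin(enhancer_ref$values)
  } else {
    cq <- query$counts
    cr <- enhancer_ref$counts
  }
  100 * sum(pmin(cq / sum(cq), cr / sum(cr)))
}
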