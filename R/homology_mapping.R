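# Exon-to-genome homology mapping: exon loading, an external BLAST-tabular
# hit path, an internal seeded local aligner, and 1 kb hit fusion.

default_scoring <- function() {
  list(match = 5, mismatch = -4, gap_open = 12, gap_extend = 3)
}

nt_submat <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch,
    baseOnly = FALSE, type = "DNA")
}

as_dnastringset <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    Biostrings::readDNAStringSet(x)
  } else if (methods::is(x, "DNAStringSet")) {
    x
  } else if (is.character(x)) {
    Biostrings::DNAStringSet(x)
  } else {
    stop("expected a DNAStringSet, named character vector or FASTA path",
         call. = FALSE)
  }
}

as_annotation <- function(x) {
  if (is.character(x) && length(x) == 1L) read_gff3(x) else x
}

#' Load exon records from a genome and annotation
#'
#' Extracts exon sequences from the genome and applies the minimum-length
#' rule of the mapping stage: exons of 19 bp or shorter are excluded (local
#' aligners need a minimal anchor length) and the number of exclusions is
#' reported.
#'
#' @param genome `DNAStringSet`, named character vector or FASTA path.
#' @param annotation annotation data frame (`feature_id`, `gene_id`,
#'   `contig`, `start0`, `end0`, `strand`, `type`) or GFF3 path.
#' @param min_length minimum exon length in bp retained (default 20).
#' @return data frame of exon records with columns `exon_id`, `gene_id`,
#'   `contig`, `start0`, `end0`, `strand`, `length`, `frame_offset`,
#'   `sequence`.
#' @export
load_exons <- function(genome, annotation, min_length = 20L) {
  genome <- as_dnastringset(genome)
  annotation <- as_annotation(annotation)
  ex <- annotation[annotation$type == "exon", , drop = FALSE]
  if (!nrow(ex)) {
    warning("annotation contains no exon records")
    return(data.frame(exon_id = character(0), gene_id = character(0),
                      contig = character(0), start0 = integer(0),
                      end0 = integer(0), strand = character(0),
                      length = integer(0), frame_offset = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  missing_contig <- setdiff(unique(ex$contig), names(genome))
  if (length(missing_contig)) {
    stop("annotation references contigs absent from the genome: ",
         paste(missing_contig, collapse = ", "), call. = FALSE)
  }
  widths <- setNames(Biostrings::width(genome), names(genome))
  bad <- ex$start0 < 0L | ex$end0 > widths[ex$contig]
  if (any(bad)) {
    stop("exon interval out of contig bounds: ",
         paste(ex$feature_id[bad], collapse = ", "), call. = FALSE)
  }
  seqs <- vapply(seq_len(nrow(ex)), function(k) {
    s <- as.character(Biostrings::subseq(genome[[ex$contig[k]]],
                                         ex$start0[k] + 1L, ex$end0[k]))
    if (ex$strand[k] == "-") revcomp_chr(s) else s
  }, character(1))
  out <- data.frame(
    exon_id = ex$feature_id, gene_id = ex$gene_id, contig = ex$contig,
    start0 = ex$start0, end0 = ex$end0, strand = ex$strand,
    length = ex$end0 - ex$start0, frame_offset = 0L, sequence = seqs,
    stringsAsFactors = FALSE)
  short <- out$length < min_length
  if (any(short)) {
    message(sum(short), " exon(s) shorter than ", min_length, " bp excluded")
  }
  out <- out[!short, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load alignment hits from a BLAST tabular file
#'
#' Reads 12-column BLAST outfmt-6 rows (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`), converts
#' subject coordinates to 0-based half-open with strand inferred from the
#' coordinate order, and drops hits below `min_score` (compared against the
#' bit score; score scales are tool specific, so the threshold is caller
#' supplied).
#'
#' @param path tabular hit file.
#' @param min_score minimum score retained.
#' @return a hit data frame (`exon_id`, `gene_id` = `NA`, `contig`,
#'   `start0`, `end0`, `strand`, `score`, `query_start`, `query_end`).
#' @export
load_blast_hits <- function(path, min_score = 0) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_hits())
  rows <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(seq_along(rows), function(i) {
    f <- rows[[i]]
    if (length(f) != 12L) {
      stop(sprintf("malformed hit row at line %d: expected 12 columns, got %d",
                   i, length(f)), call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(f[c(7:10, 12)]))
    if (anyNA(num)) {
      stop(sprintf("malformed hit row at line %d: non-numeric coordinates or score",
                   i), call. = FALSE)
    }
    ss <- num[3]; se <- num[4]
    data.frame(
      hit_id = NA_character_, exon_id = f[1], gene_id = NA_character_,
      contig = f[2],
      start0 = as.integer(min(ss, se)) - 1L, end0 = as.integer(max(ss, se)),
      strand = if (ss <= se) "+" else "-", score = num[5],
      query_start = as.integer(min(num[1], num[2])) - 1L,
      query_end = as.integer(max(num[1], num[2])),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[out$score >= min_score, , drop = FALSE]
  if (nrow(out)) out$hit_id <- sprintf("h%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

# Collect seed matches of every exon k-mer (both orientations) against each
# contig, cluster them, and run exact affine-gap local DP on the clustered
# windows.  This is the desk-scale internal aligner: exact DP on each window,
# seeded to keep whole-genome scans fast.
map_exons_internal <- function(exons, genome, scoring, min_score,
                               seed_length = 14L, window_margin = 200L) {
  submat <- nt_submat(scoring)
  pats <- list()
  meta <- list()
  for (k in seq_len(nrow(exons))) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") exons$sequence[k] else revcomp_chr(exons$sequence[k])
      L <- nchar(s)
      if (L < seed_length) next
      offs <- seq_len(L - seed_length + 1L)
      pats[[length(pats) + 1L]] <- substring(s, offs, offs + seed_length - 1L)
      meta[[length(meta) + 1L]] <- data.frame(
        exon = k, strand = strand, off = offs, stringsAsFactors = FALSE)
    }
  }
  if (!length(pats)) return(empty_hits())
  meta <- do.call(rbind, meta)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(unlist(pats)))
  hits <- list()
  for (contig in names(genome)) {
    subj <- genome[[contig]]
    m <- Biostrings::matchPDict(pd, subj)
    n_per <- S4Vectors::elementNROWS(m)
    idx <- which(n_per > 0L)
    if (!length(idx)) next
    seed_starts <- unlist(lapply(idx, function(i) Biostrings::start(m[[i]])))
    seed_meta <- meta[rep(idx, n_per[idx]), , drop = FALSE]
    approx0 <- seed_starts - seed_meta$off   # 0-based approximate exon start
    for (grp in split(seq_along(approx0),
                      paste(seed_meta$exon, seed_meta$strand))) {
      k <- seed_meta$exon[grp[1]]
      strand <- seed_meta$strand[grp[1]]
      exlen <- nchar(exons$sequence[k])
      a <- sort(unique(approx0[grp]))
      cl_id <- cumsum(c(1L, diff(a) > exlen))
      for (cl in split(a, cl_id)) {
        w0 <- max(0L, min(cl) - window_margin)
        w1 <- min(length(subj), max(cl) + exlen + window_margin)
        if (w1 - w0 < seed_length) next
        pat <- if (strand == "+") exons$sequence[k] else revcomp_chr(exons$sequence[k])
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(pat), Biostrings::subseq(subj, w0 + 1L, w1),
          type = "local", substitutionMatrix = submat,
          gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
        sc <- Biostrings::score(aln)
        if (sc < min_score) next
        srng <- aln@subject@range
        prng <- aln@pattern@range
        qs <- IRanges::start(prng); qe <- IRanges::end(prng)
        if (strand == "-") {
          tmp <- qs
          qs <- exlen - qe + 1L
          qe <- exlen - tmp + 1L
        }
        hits[[length(hits) + 1L]] <- data.frame(
          hit_id = NA_character_, exon_id = exons$exon_id[k],
          gene_id = exons$gene_id[k], contig = contig,
          start0 = w0 + IRanges::start(srng) - 1L,
          end0 = w0 + IRanges::end(srng),
          strand = strand, score = sc,
          query_start = qs - 1L, query_end = qe,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(empty_hits())
  out <- do.call(rbind, hits)
  # windows from nearby clusters can rediscover the same locus: keep the
  # best-scoring hit among mutually overlapping same-exon same-strand hits
  out <- out[order(out$exon_id, out$contig, out$strand, -out$score), ]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(out)) > i &
                 out$exon_id == out$exon_id[i] &
                 out$contig == out$contig[i] &
                 out$strand == out$strand[i] &
                 out$start0 < out$end0[i] & out$end0 > out$start0[i])
    keep[j] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$exon_id, out$contig, out$start0, out$strand), ]
  out$hit_id <- sprintf("h%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Map exon sequences to a genome with the internal local aligner
#'
#' Seeded, exact-on-window affine-gap local alignment of every exon against
#' every contig, on both strands.  The default score threshold is expressed
#' as a fraction of each exon's maximum attainable score
#' (`match * exon length`), since absolute local-alignment scores are
#' scheme specific.
#'
#' @param exons exon records from [load_exons()].
#' @param genome target genome (`DNAStringSet`, named character vector or
#'   FASTA path).
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @param min_score absolute score threshold; overrides `min_score_frac`.
#' @param min_score_frac fraction-of-maximum threshold (default 0.5).
#' @param seed_length k-mer length used to seed candidate windows (default 14: long enough to keep chance seeds negligible on megabase genomes, short enough that a 10%-diverged 180 bp relic still carries dozens of intact seeds).
#' @return hit data frame (0-based half-open target coordinates).
#' @export
map_exons <- function(exons, genome, scoring = default_scoring(),
                      min_score = NULL, min_score_frac = 0.5,
                      seed_length = 14L) {
  genome <- as_dnastringset(genome)
  if (!nrow(exons)) return(empty_hits())
  out <- map_exons_internal(exons, genome, scoring, min_score = 0,
                            seed_length = seed_length)
  if (!nrow(out)) return(out)
  thr <- min_score %||%
    (min_score_frac * scoring$match *
       exons$length[match(out$exon_id, exons$exon_id)])
  out <- out[out$score >= thr, , drop = FALSE]
  if (nrow(out)) out$hit_id <- sprintf("h%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Locally align one exon against a genome
#'
#' Single-exon convenience wrapper around [map_exons()].  Every reported
#' hit's score is the exact local-alignment score of the reported interval
#' under the stated scheme; both strands are searched.
#'
#' @param exon an exon record row from [load_exons()], or a plain sequence
#'   string.
#' @inheritParams map_exons
#' @export
local_align <- function(exon, genome, scoring = default_scoring(),
                        min_score = NULL, min_score_frac = 0.5,
                        seed_length = 14L) {
  if (is.character(exon)) {
    exon <- data.frame(exon_id = "query", gene_id = NA_character_,
                       contig = NA_character_, start0 = 0L,
                       end0 = nchar(exon), strand = "+",
                       length = nchar(exon), frame_offset = 0L,
                       sequence = toupper(exon), stringsAsFactors = FALSE)
  }
  map_exons(exon, genome, scoring = scoring, min_score = min_score,
            min_score_frac = min_score_frac, seed_length = seed_length)
}

#' Fuse nearby alignment hits into regulatory units
#'
#' Hits of the same exon on the same contig whose intervals lie within
#' `max_gap` of each other (single linkage, boundary inclusive) are merged
#' into one fused hit spanning their union hull, following the rule that
#' hits within 1 kb belong to the same putative regulatory unit.  Fusion
#' ignores strand; a fused hit whose members disagree is recorded as
#' strand `"mixed"`.
#'
#' @param hits hit data frame.
#' @param max_gap maximum inter-interval gap in bp (default 1000).
#' @return fused hit data frame with `n_members`, `member_ids` and
#'   `score` = maximum member score.
#' @export
fuse_hits <- function(hits, max_gap = 1000) {
  if (max_gap < 0) stop("`max_gap` must be non-negative", call. = FALSE)
  cols <- c("hit_id", "exon_id", "gene_id", "contig", "start0", "end0",
            "strand", "score", "n_members", "member_ids")
  if (!nrow(hits)) {
    out <- cbind(empty_hits()[, 1:8], n_members = integer(0),
                 member_ids = character(0))
    return(out[, cols])
  }
  hits <- hits[order(hits$exon_id, hits$contig, hits$start0, hits$end0), ]
  out <- list()
  for (grp in split(seq_len(nrow(hits)), paste(hits$exon_id, hits$contig))) {
    h <- hits[grp, , drop = FALSE]
    cl <- cumsum(c(1L, cummax(h$end0)[-nrow(h)] + max_gap < h$start0[-1]))
    for (members in split(seq_len(nrow(h)), cl)) {
      hm <- h[members, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        hit_id = NA_character_, exon_id = hm$exon_id[1],
        gene_id = hm$gene_id[1], contig = hm$contig[1],
        start0 = min(hm$start0), end0 = max(hm$end0),
        strand = if (length(unique(hm$strand)) == 1L) hm$strand[1] else "mixed",
        score = max(hm$score), n_members = nrow(hm),
        member_ids = paste(hm$hit_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$exon_id, out$contig, out$start0), , drop = FALSE]
  out$hit_id <- sprintf("f%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, cols]
}
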