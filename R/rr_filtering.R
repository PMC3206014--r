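# The RR filter funnel: ortholog presence, ortholog proximity, exon/EST
# overlap, synteny, developmental GO and reading-frame disruption, with a
# per-stage count report.

FILTER_STAGES <- c("ortholog_presence", "ortholog_proximity", "exonic_overlap",
                   "synteny", "developmental_flank", "frame")

DEFAULT_GO_ROOTS <- c("GO:0045165", "GO:0032502", "GO:0030528", "GO:0003700")

#' Configuration for the filtering funnel
#'
#' All distance thresholds are on the literal kb/Mb scale of the published
#' rules: 1 kb hit fusion, 2 Mb ortholog proximity, 300 kb synteny window,
#' 100 kb maximum hit-to-ortholog distance, at most 5 intervening genes.
#' `scale_divisor` (taken from the scenario bundle when `NULL`) divides
#' every distance threshold so that bundles generated at a compressed
#' coordinate scale are filtered with the identical comparison logic.
#'
#' @param fusion_gap maximum gap for hit fusion (bp).
#' @param min_score,min_score_frac mapping score threshold (absolute, or
#'   fraction of each exon's maximum score).
#' @param scoring local/global alignment scoring scheme.
#' @param proximity_radius hits within this distance of the source gene's
#'   ortholog locus are removed (bp).
#' @param synteny_window window around the reference exon searched for
#'   developmental neighbours, and the span of the per-gene multi-hit rule.
#' @param synteny_max_dist maximum hit-to-ortholog distance retained.
#' @param max_intervening maximum annotated genes between hit and ortholog.
#' @param go_roots GO roots whose descendant closure defines developmental
#'   genes.
#' @param coverage_threshold fraction of the hit region a single reading
#'   frame must span, stop free, for the region to count as intact.
#' @param min_exon_length minimum exon length admitted to mapping.
#' @param disabled character vector of filter stage names to skip (for
#'   decoy-admission analyses).
#' @param scale_divisor divisor applied to all distance thresholds; `NULL`
#'   means "use the bundle's `genome_scale_divisor`".
#' @return a `funnel_config` list.
#' @export
funnel_config <- function(fusion_gap = 1000,
                          min_score = NULL,
                          min_score_frac = 0.5,
                          scoring = default_scoring(),
                          proximity_radius = 2e6,
                          synteny_window = 3e5,
                          synteny_max_dist = 1e5,
                          max_intervening = 5L,
                          go_roots = DEFAULT_GO_ROOTS,
                          coverage_threshold = 0.95,
                          min_exon_length = 20L,
                          disabled = character(0),
                          scale_divisor = NULL) {
  if (fusion_gap < 0 || proximity_radius <= 0 || synteny_window <= 0 ||
      synteny_max_dist <= 0 || max_intervening < 0) {
    stop("funnel thresholds must be positive", call. = FALSE)
  }
  disabled <- unique(as.character(disabled))
  if (length(setdiff(disabled, FILTER_STAGES))) {
    stop("unknown filter stage in `disabled`; valid stages: ",
         paste(FILTER_STAGES, collapse = ", "), call. = FALSE)
  }
  structure(list(
    fusion_gap = fusion_gap, min_score = min_score,
    min_score_frac = min_score_frac, scoring = scoring,
    proximity_radius = proximity_radius, synteny_window = synteny_window,
    synteny_max_dist = synteny_max_dist,
    max_intervening = as.integer(max_intervening), go_roots = go_roots,
    coverage_threshold = coverage_threshold,
    min_exon_length = as.integer(min_exon_length),
    disabled = disabled, scale_divisor = scale_divisor
  ), class = "funnel_config")
}

#' Parse a minimal OBO ontology
#'
#' Reads `[Term]` stanzas and their `is_a` / `relationship: part_of` edges.
#'
#' @param obo character vector of OBO lines, or a file path.
#' @return list with `terms` (character vector of ids) and `edges`
#'   (data frame `child`, `parent`).
#' @export
parse_obo <- function(obo) {
  lines <- if (length(obo) == 1L && file.exists(obo)) readLines(obo) else obo
  terms <- character(0)
  edges <- list()
  cur <- NA_character_
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { in_term <- TRUE; cur <- NA_character_; next }
    if (startsWith(ln, "[")) { in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id: ")) {
      cur <- sub("^id: *", "", ln)
      terms <- c(terms, cur)
    } else if (startsWith(ln, "is_a: ")) {
      parent <- sub(" .*$", "", sub("^is_a: *", "", ln))
      edges[[length(edges) + 1L]] <- c(cur, parent)
    } else if (startsWith(ln, "relationship: part_of ")) {
      parent <- sub(" .*$", "", sub("^relationship: part_of *", "", ln))
      edges[[length(edges) + 1L]] <- c(cur, parent)
    }
  }
  edges <- if (length(edges)) {
    m <- do.call(rbind, edges)
    data.frame(child = m[, 1], parent = m[, 2], stringsAsFactors = FALSE)
  } else {
    data.frame(child = character(0), parent = character(0))
  }
  list(terms = unique(terms), edges = edges)
}

#' Developmental GO closure
#'
#' Returns the given roots plus all their descendants via `is_a` (and
#' `part_of`, when present) edges — the definition of "developmental gene"
#' used by the synteny and flanking-gene filters.
#'
#' @param obo OBO lines, file path, or the result of [parse_obo()].
#' @param roots GO term ids to close over.
#' @return character vector of term ids.
#' @export
developmental_closure <- function(obo, roots = DEFAULT_GO_ROOTS) {
  ont <- if (is.list(obo) && !is.null(obo$edges)) obo else parse_obo(obo)
  missing <- setdiff(roots, ont$terms)
  if (length(missing)) {
    stop("GO root(s) absent from the ontology: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  closure <- roots
  frontier <- roots
  while (length(frontier)) {
    children <- ont$edges$child[ont$edges$parent %in% frontier]
    frontier <- setdiff(children, closure)
    closure <- union(closure, frontier)
  }
  closure
}

#' Keep hits whose source gene has an annotated target ortholog
#'
#' @param hits hit data frame carrying `gene_id`.
#' @param orthology named list mapping reference gene ids to character
#'   vectors of target gene ids.
#' @return the retained hits.
#' @export
filter_ortholog_presence <- function(hits, orthology) {
  if (!nrow(hits)) return(hits)
  if (anyNA(hits$gene_id)) {
    stop("hit(s) with unresolvable source gene id: ",
         paste(hits$hit_id[is.na(hits$gene_id)], collapse = ", "),
         call. = FALSE)
  }
  if (!length(orthology)) {
    warning("empty orthology map: all hits dropped")
    return(hits[0, , drop = FALSE])
  }
  has <- vapply(hits$gene_id, function(g) {
    length(orthology[[g]] %||% character(0)) > 0L
  }, logical(1))
  hits[has, , drop = FALSE]
}

#' Remove hits near the source gene's ortholog locus
#'
#' A hit is removed iff it lies on the same contig as an ortholog of its
#' source gene and the gap between the two intervals is at most `radius`
#' (hits at the retained coding locus are the duplicate we are *not*
#' looking for).  Hits on other contigs are kept (infinite-distance
#' convention).
#'
#' @param hits hit data frame.
#' @param orthology named list, reference gene id to target gene ids.
#' @param target_annotation target annotation data frame.
#' @param radius distance threshold in bp (default 2 Mb).
#' @return the retained hits.
#' @export
filter_ortholog_proximity <- function(hits, orthology, target_annotation,
                                      radius = 2e6) {
  if (!nrow(hits)) return(hits)
  genes <- target_annotation[target_annotation$type == "gene", , drop = FALSE]
  near <- vapply(seq_len(nrow(hits)), function(i) {
    orth <- orthology[[hits$gene_id[i]]] %||% character(0)
    if (!length(orth)) return(FALSE)
    og <- genes[genes$gene_id %in% orth & genes$contig == hits$contig[i], ,
                drop = FALSE]
    if (!nrow(og)) return(FALSE)
    any(interval_gap0(hits$start0[i], hits$end0[i], og$start0, og$end0) <= radius)
  }, logical(1))
  hits[!near, , drop = FALSE]
}

#' Remove hits overlapping annotated exons or ESTs
#'
#' Any overlap of at least 1 bp with an annotated exon or EST disqualifies
#' a hit ("matching even partially"); intervals that merely touch under the
#' half-open convention do not overlap.
#'
#' @param hits hit data frame.
#' @param target_annotation target annotation data frame.
#' @return the retained hits.
#' @export
filter_exonic_overlap <- function(hits, target_annotation) {
  if (!nrow(hits)) return(hits)
  feats <- ann_granges(target_annotation, types = c("exon", "EST"))
  if (!length(feats)) return(hits)
  ov <- GenomicRanges::findOverlaps(hits_granges(hits), feats,
                                    minoverlap = 1L, ignore.strand = TRUE)
  qh <- unique(S4Vectors::queryHits(ov))
  if (length(qh)) hits[-qh, , drop = FALSE] else hits
}

#' Retain hits in conserved synteny with a developmental neighbour
#'
#' For each hit, the developmental genes (GO annotation inside `closure`)
#' within `window` of the source exon on the reference are mapped to their
#' target orthologs; the hit is retained iff at least one such ortholog
#' lies on the hit's contig at a distance below `max_dist` with at most
#' `max_intervening` annotated genes in between.  Afterwards, if more than
#' one retained hit of the same source gene falls within a `window`-sized
#' span, all hits of that gene are discarded (guards against unannotated
#' paralogs).
#'
#' @param hits hit data frame.
#' @param exons exon records of the reference (for source exon positions).
#' @param reference_annotation,target_annotation annotation data frames.
#' @param gene2go data frame `gene_id`, `go_id` (reference and target).
#' @param orthology named list, reference gene id to target gene ids.
#' @param closure developmental GO closure from [developmental_closure()].
#' @param window,max_dist,max_intervening synteny thresholds.
#' @return the retained hits.
#' @export
assess_synteny <- function(hits, exons, reference_annotation,
                           target_annotation, gene2go, orthology, closure,
                           window = 3e5, max_dist = 1e5,
                           max_intervening = 5L) {
  if (!nrow(hits)) return(hits)
  ref_genes <- reference_annotation[reference_annotation$type == "gene", ,
                                    drop = FALSE]
  tgt_genes <- target_annotation[target_annotation$type == "gene", ,
                                 drop = FALSE]
  dev_ids <- unique(gene2go$gene_id[gene2go$go_id %in% closure])
  ok <- vapply(seq_len(nrow(hits)), function(i) {
    ex <- exons[exons$exon_id == hits$exon_id[i], , drop = FALSE]
    if (!nrow(ex)) return(FALSE)
    nb <- ref_genes[ref_genes$contig == ex$contig &
                      ref_genes$gene_id %in% dev_ids &
                      ref_genes$gene_id != ex$gene_id, , drop = FALSE]
    if (nrow(nb)) {
      nb <- nb[interval_gap0(ex$start0, ex$end0, nb$start0, nb$end0) <= window, ,
               drop = FALSE]
    }
    if (!nrow(nb)) return(FALSE)
    orth <- unique(unlist(orthology[nb$gene_id], use.names = FALSE))
    og <- tgt_genes[tgt_genes$gene_id %in% orth &
                      tgt_genes$contig == hits$contig[i], , drop = FALSE]
    if (!nrow(og)) return(FALSE)
    any(vapply(seq_len(nrow(og)), function(j) {
      d <- interval_gap0(hits$start0[i], hits$end0[i], og$start0[j], og$end0[j])
      if (d >= max_dist) return(FALSE)
      lo <- min(hits$end0[i], og$end0[j])
      hi <- max(hits$start0[i], og$start0[j])
      between <- tgt_genes$contig == hits$contig[i] &
        tgt_genes$gene_id != og$gene_id[j] &
        tgt_genes$start0 >= lo & tgt_genes$end0 <= hi
      sum(between) <= max_intervening
    }, logical(1)))
  }, logical(1))
  kept <- hits[ok, , drop = FALSE]
  if (!nrow(kept)) return(kept)
  # per-gene multi-hit discard within a window-sized span
  drop_gene <- vapply(unique(kept$gene_id), function(g) {
    h <- kept[kept$gene_id == g, , drop = FALSE]
    if (nrow(h) < 2L) return(FALSE)
    for (i in seq_len(nrow(h) - 1L)) {
      for (j in (i + 1L):nrow(h)) {
        if (h$contig[i] == h$contig[j] &&
            interval_gap0(h$start0[i], h$end0[i],
                          h$start0[j], h$end0[j]) <= window) {
          return(TRUE)
        }
      }
    }
    FALSE
  }, logical(1))
  kept[!kept$gene_id %in% names(drop_gene)[drop_gene], , drop = FALSE]
}

# Nearest annotated gene on each side of a hit, within `window`.
flanking_genes <- function(hits, target_annotation, window = 3e5) {
  genes <- target_annotation[target_annotation$type == "gene", , drop = FALSE]
  out <- lapply(seq_len(nrow(hits)), function(i) {
    g <- genes[genes$contig == hits$contig[i], , drop = FALSE]
    left <- g[g$start0 < hits$start0[i], , drop = FALSE]
    right <- g[g$end0 > hits$end0[i], , drop = FALSE]
    pick <- function(side) {
      if (!nrow(side)) return(NA_character_)
      d <- interval_gap0(hits$start0[i], hits$end0[i], side$start0, side$end0)
      side <- side[d <= window, , drop = FALSE]
      d <- d[d <= window]
      if (!nrow(side)) return(NA_character_)
      side$gene_id[which.min(d)]
    }
    data.frame(hit_id = hits$hit_id[i], flank_left = pick(left),
               flank_right = pick(right), stringsAsFactors = FALSE)
  })
  if (!length(out)) {
    return(data.frame(hit_id = character(0), flank_left = character(0),
                      flank_right = character(0)))
  }
  do.call(rbind, out)
}

#' Keep hits flanked by at least one developmental gene
#'
#' The nearest annotated target gene on each side of the hit (within the
#' synteny window) is examined; the hit is kept iff at least one of them
#' carries a GO annotation inside the developmental closure.  These
#' flanking genes are the putative regulatory targets of the candidate RR.
#'
#' @inheritParams assess_synteny
#' @param window search window for flanking genes.
#' @return the retained hits.
#' @export
filter_developmental_flank <- function(hits, target_annotation, gene2go,
                                       closure, window = 3e5) {
  if (!nrow(hits)) return(hits)
  dev_ids <- unique(gene2go$gene_id[gene2go$go_id %in% closure])
  fl <- flanking_genes(hits, target_annotation, window)
  keep <- (fl$flank_left %in% dev_ids) | (fl$flank_right %in% dev_ids)
  no_flank <- is.na(fl$flank_left) & is.na(fl$flank_right)
  if (any(no_flank)) {
    message(sum(no_flank), " hit(s) without annotated flanking genes dropped")
  }
  hits[keep & !no_flank, , drop = FALSE]
}

#' Assess reading-frame disruption of a hit region
#'
#' Translates the hit region in all six frames and aligns each translation
#' to the peptide of the source exon.  The region is called `"intact"` iff
#' some single frame is stop free and its local peptide alignment covers at
#' least `coverage_threshold` of the region; otherwise the disruption
#' evidence (stop codon positions per frame, frameshift flag) is returned.
#' The discovery funnel keeps only disrupted regions — an intact spanning
#' frame means the region may simply be an unannotated coding exon.
#'
#' @param region nucleotide sequence of the hit region.
#' @param exon_seq nucleotide sequence of the source exon.
#' @param frame_offset frame offset of the exon's first complete codon.
#' @param coverage_threshold required aligned fraction of the region.
#' @return a list with `status` (`"intact"` or `"disrupted"`), `frames`
#'   (per-frame stop count and coverage), `stops` (stop positions: frame,
#'   strand, codon index, 0-based nt position) and `frameshift`.
#' @export
assess_frame_disruption <- function(region, exon_seq, frame_offset = 0L,
                                    coverage_threshold = 0.95) {
  stopifnot(nzchar(region), nzchar(exon_seq))
  region <- toupper(region)
  exon_pep <- translate_nt(toupper(exon_seq), frame_offset)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  frames <- list()
  stops <- list()
  intact <- FALSE
  for (strand in c("+", "-")) {
    s <- if (strand == "+") region else revcomp_chr(region)
    for (f in 0:2) {
      pep <- translate_nt(s, f)
      if (!nzchar(pep)) next
      stop_idx <- which(seq_chars(pep) == "*")
      cov <- 0
      if (!length(stop_idx)) {
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(pep), Biostrings::AAString(exon_pep),
          type = "local", substitutionMatrix = BLOSUM62,
          gapOpening = 10, gapExtension = 0.5)
        cov <- IRanges::width(aln@pattern@range) / nchar(pep)
      }
      frames[[length(frames) + 1L]] <- data.frame(
        frame = f, strand = strand, n_stops = length(stop_idx),
        coverage = cov, stringsAsFactors = FALSE)
      if (length(stop_idx)) {
        stops[[length(stops) + 1L]] <- data.frame(
          frame = f, strand = strand, codon = stop_idx,
          pos0 = f + 3L * (stop_idx - 1L), stringsAsFactors = FALSE)
      }
      if (!length(stop_idx) && cov >= coverage_threshold) intact <- TRUE
    }
  }
  frames <- do.call(rbind, frames)
  stops <- if (length(stops)) do.call(rbind, stops) else
    data.frame(frame = integer(0), strand = character(0),
               codon = integer(0), pos0 = integer(0))
  list(status = if (intact) "intact" else "disrupted",
       frames = frames, stops = stops,
       frameshift = !intact && nrow(stops) == 0L)
}

#' Run the complete RR discovery funnel
#'
#' Applies the stages in order: exon loading, mapping, hit fusion, ortholog
#' presence, ortholog proximity, exon/EST overlap, synteny, developmental
#' flanking gene, reading-frame disruption.  Counts from hit fusion onward
#' form a monotone funnel: every stage consumes exactly the survivors of
#' the previous one.
#'
#' @param bundle a `scenario_bundle` (or an equivalent list with the same
#'   fields read from files).
#' @param config a [funnel_config()].
#' @param hits optional externally produced hit data frame (e.g. from
#'   [load_blast_hits()]); replaces the internal mapping stage.
#' @return list with `candidates` (RR candidate data frame with flanking
#'   genes and frame-disruption evidence) and `report` (a `funnel_report`).
#' @export
run_funnel <- function(bundle, config = funnel_config(), hits = NULL) {
  stopifnot(inherits(config, "funnel_config"))
  divisor <- config$scale_divisor %||%
    (bundle$config$genome_scale_divisor %||% 1)
  eff <- function(x) x / divisor
  stage_ctx <- "load_exons"
  result <- tryCatch({
    exons_all <- sum(bundle$reference_annotation$type == "exon")
    exons <- load_exons(bundle$reference_genome, bundle$reference_annotation,
                        min_length = config$min_exon_length)
    stage_ctx <- "map"
    if (is.null(hits)) {
      hits <- map_exons(exons, bundle$target_genome,
                        scoring = config$scoring,
                        min_score = config$min_score,
                        min_score_frac = config$min_score_frac)
    } else {
      hits$gene_id <- exons$gene_id[match(hits$exon_id, exons$exon_id)]
    }
    stage_ctx <- "fuse"
    fused <- fuse_hits(hits, max_gap = eff(config$fusion_gap))

    closure <- developmental_closure(bundle$ontology, config$go_roots)
    stages <- data.frame(stage = c("load_exons", "map", "fuse"),
                         n_in = c(exons_all, nrow(exons), nrow(hits)),
                         n_out = c(nrow(exons), nrow(hits), nrow(fused)),
                         stringsAsFactors = FALSE)
    dropped <- list()
    kept_ids <- list(fuse = fused$hit_id)
    cur <- fused

    apply_stage <- function(name, fn) {
      stage_ctx <<- name
      if (name %in% config$disabled) return(invisible(NULL))
      kept <- fn(cur)
      drp <- cur[!cur$hit_id %in% kept$hit_id, , drop = FALSE]
      stages[nrow(stages) + 1L, ] <<- list(name, nrow(cur), nrow(kept))
      dropped[[name]] <<- drp
      kept_ids[[name]] <<- kept$hit_id
      cur <<- kept
      invisible(NULL)
    }

    apply_stage("ortholog_presence", function(h) {
      filter_ortholog_presence(h, bundle$orthology)
    })
    apply_stage("ortholog_proximity", function(h) {
      filter_ortholog_proximity(h, bundle$orthology,
                                bundle$target_annotation,
                                radius = eff(config$proximity_radius))
    })
    apply_stage("exonic_overlap", function(h) {
      filter_exonic_overlap(h, bundle$target_annotation)
    })
    apply_stage("synteny", function(h) {
      assess_synteny(h, exons, bundle$reference_annotation,
                     bundle$target_annotation, bundle$gene2go,
                     bundle$orthology, closure,
                     window = eff(config$synteny_window),
                     max_dist = eff(config$synteny_max_dist),
                     max_intervening = config$max_intervening)
    })
    apply_stage("developmental_flank", function(h) {
      filter_developmental_flank(h, bundle$target_annotation, bundle$gene2go,
                                 closure, window = eff(config$synteny_window))
    })

    # frame disruption: keep hits whose region cannot be explained by an
    # intact spanning reading frame
    frame_info <- list()
    apply_stage("frame", function(h) {
      if (!nrow(h)) return(h)
      disrupted <- logical(nrow(h))
      for (i in seq_len(nrow(h))) {
        region <- as.character(Biostrings::subseq(
          bundle$target_genome[[h$contig[i]]], h$start0[i] + 1L, h$end0[i]))
        ex <- exons[exons$exon_id == h$exon_id[i], , drop = FALSE]
        ev <- assess_frame_disruption(region, ex$sequence[1],
                                      frame_offset = ex$frame_offset[1],
                                      coverage_threshold = config$coverage_threshold)
        disrupted[i] <- ev$status == "disrupted"
        if (disrupted[i]) frame_info[[h$hit_id[i]]] <<- ev
      }
      h[disrupted, , drop = FALSE]
    })

    candidates <- cur
    fl <- flanking_genes(candidates, bundle$target_annotation,
                         window = eff(config$synteny_window))
    candidates$flank_left <- fl$flank_left[match(candidates$hit_id, fl$hit_id)]
    candidates$flank_right <- fl$flank_right[match(candidates$hit_id, fl$hit_id)]
    candidates$n_stops <- vapply(candidates$hit_id, function(id) {
      ev <- frame_info[[id]]
      if (is.null(ev)) return(NA_integer_)
      fwd <- ev$stops[ev$stops$strand == "+" & ev$stops$frame == 0L, , drop = FALSE]
      nrow(fwd)
    }, integer(1))
    candidates$stop_pos0 <- vapply(candidates$hit_id, function(id) {
      ev <- frame_info[[id]]
      if (is.null(ev)) return(NA_character_)
      fwd <- ev$stops[ev$stops$strand == "+" & ev$stops$frame == 0L, , drop = FALSE]
      paste(fwd$pos0, collapse = ",")
    }, character(1))
    candidates$frameshift <- vapply(candidates$hit_id, function(id) {
      ev <- frame_info[[id]]
      if (is.null(ev)) return(NA)
      ev$frameshift
    }, logical(1))
    rownames(candidates) <- NULL

    report <- structure(list(
      stages = stages, dropped = dropped, kept_ids = kept_ids,
      n_candidates = nrow(candidates), scale_divisor = divisor
    ), class = "funnel_report")
    list(candidates = candidates, report = report,
         frame_evidence = frame_info)
  }, error = function(e) {
    stop(sprintf("funnel stage '%s' failed: %s", stage_ctx,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("RR discovery funnel\n")
  df <- x$stages
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-20s %6d -> %6d\n", df$stage[i], df$n_in[i], df$n_out[i]))
  }
  cat(sprintf("  candidates: %d\n", x$n_candidates))
  invisible(x)
}

#' Match RR candidates against ground-truth records
#'
#' @param candidates candidate data frame from [run_funnel()].
#' @param truth truth records of a `scenario_bundle`.
#' @param min_overlap required reciprocal interval overlap.
#' @return `truth` with added columns `recovered` and `candidate_id`.
#' @export
match_candidates_to_truth <- function(candidates, truth, min_overlap = 0.8) {
  truth$recovered <- FALSE
  truth$candidate_id <- NA_character_
  for (i in seq_len(nrow(truth))) {
    if (!nrow(candidates)) break
    same <- candidates$contig == truth$contig[i]
    if (!any(same)) next
    cc <- candidates[same, , drop = FALSE]
    ro <- reciprocal_overlap(truth$start0[i], truth$end0[i],
                             cc$start0, cc$end0)
    j <- which(ro >= min_overlap)
    if (length(j)) {
      truth$recovered[i] <- TRUE
      truth$candidate_id[i] <- cc$hit_id[j[which.max(ro[j])]]
    }
  }
  truth
}

#' Find the funnel stage at which a truth interval was rejected
#'
#' @param report a `funnel_report`.
#' @param truth_row one row of a bundle's truth table.
#' @param min_overlap reciprocal overlap required to identify the hit.
#' @return the stage name, or `NA` if no dropped hit matches.
#' @export
rejection_stage <- function(report, truth_row, min_overlap = 0.5) {
  for (stage in names(report$dropped)) {
    d <- report$dropped[[stage]]
    if (!nrow(d)) next
    same <- d$contig == truth_row$contig
    if (!any(same)) next
    dd <- d[same, , drop = FALSE]
    ro <- reciprocal_overlap(truth_row$start0, truth_row$end0,
                             dd$start0, dd$end0)
    if (any(ro >= min_overlap)) return(stage)
  }
  NA_character_
}
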