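# Synthetic duplicated-genome scenarios with planted recycled regions (RRs)
# and per-filter decoys.  Every pipeline stage can be exercised against the
# ground truth these bundles carry.

DECOY_CLASSES <- c("ortholog_presence", "ortholog_proximity", "exonic_overlap",
                   "synteny", "go", "frame")

OUTGROUP_CODING <- c(mouse = 6L, chicken = 10L, frog = 14L, shark = 18L)
CODING_DIVERGENCE_TARGET <- 20L   # substitutions into the retained paralog
TELEOST_EXTRA_DIVERGENCE <- c(stickleback_rr = 6L, zebrafish_rr = 8L)

#' Configuration for a synthetic RR scenario bundle
#'
#' Parameterises [generate_scenario()].  Distances (intergenic spacers and
#' the decoy placements derived from them) are expressed on the same scale
#' as the pipeline's filtering thresholds (1 kb hit fusion, 100 kb / 300 kb
#' synteny rules, 2 Mb ortholog proximity); `genome_scale_divisor` shrinks
#' both the generated distances and, via [funnel_config()], the thresholds
#' consistently, so the comparison logic is identical at any scale.
#'
#' @param seed integer seed; a fixed seed yields a byte-identical bundle.
#' @param n_reference_genes number of planted recycled regions (one per
#'   reference gene scenario).
#' @param exon_length_codons length of each coding exon in codons
#'   (`3 * exon_length_codons` must exceed 19 bp, the minimum exon length
#'   admitted by the mapping stage).
#' @param intergenic_length spacer length in bp between annotated features.
#' @param nt_substitution_rate per-site substitution probability applied
#'   when degrading the relic copy.
#' @param indel_rate per-site indel probability for the relic copy.  The
#'   default is 0 so that frame disruption comes from the planted stop
#'   codons alone and truth records remain exact; indels are exercised
#'   directly through [degrade_coding_sequence()].
#' @param n_planted_stops number of in-frame stop codons planted in each RR
#'   relic (at least 1).
#' @param decoy_classes character vector of filter names to violate, one
#'   decoy scenario per entry; subset of
#'   `c("ortholog_presence", "ortholog_proximity", "exonic_overlap",
#'   "synteny", "go", "frame")`.
#' @param flanking_gene_count flanking genes per side of each locus.
#' @param genome_scale_divisor positive number dividing all inter-feature
#'   distances (default 1 = literal kb/Mb scale on small contigs).
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(seed = 1L,
                            n_reference_genes = 3L,
                            exon_length_codons = 60L,
                            intergenic_length = 5000L,
                            nt_substitution_rate = 0.08,
                            indel_rate = 0,
                            n_planted_stops = 2L,
                            decoy_classes = character(0),
                            flanking_gene_count = 1L,
                            genome_scale_divisor = 1) {
  bad <- function(field, msg) {
    stop(sprintf("invalid scenario configuration: `%s` %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L) bad("seed", "must be a single integer")
  if (n_reference_genes < 1L) bad("n_reference_genes", "must be >= 1")
  if (exon_length_codons * 3L <= 19L) {
    bad("exon_length_codons", "must give an exon longer than 19 bp")
  }
  if (intergenic_length <= 0) bad("intergenic_length", "must be positive")
  if (nt_substitution_rate < 0 || nt_substitution_rate > 1) {
    bad("nt_substitution_rate", "must be a probability in [0, 1]")
  }
  if (indel_rate < 0 || indel_rate > 1) bad("indel_rate", "must be a probability in [0, 1]")
  if (n_planted_stops < 1L) bad("n_planted_stops", "must be >= 1")
  decoy_classes <- unique(as.character(decoy_classes))
  if (length(setdiff(decoy_classes, DECOY_CLASSES))) {
    bad("decoy_classes", paste("must be a subset of:",
                               paste(DECOY_CLASSES, collapse = ", ")))
  }
  if (flanking_gene_count < 1L) bad("flanking_gene_count", "must be >= 1")
  if (genome_scale_divisor <= 0) bad("genome_scale_divisor", "must be positive")
  structure(list(
    seed = as.integer(seed),
    n_reference_genes = as.integer(n_reference_genes),
    exon_length_codons = as.integer(exon_length_codons),
    intergenic_length = as.integer(intergenic_length),
    nt_substitution_rate = nt_substitution_rate,
    indel_rate = indel_rate,
    n_planted_stops = as.integer(n_planted_stops),
    decoy_classes = decoy_classes,
    flanking_gene_count = as.integer(flanking_gene_count),
    genome_scale_divisor = genome_scale_divisor
  ), class = "scenario_config")
}

#' Degrade a coding sequence into an RR-like relic
#'
#' Simulates the post-duplication decay of the gene-lost copy: random
#' substitutions at `nt_rate` per site (substitutions that would create an
#' in-frame stop are redirected to a non-stop base so that the stop count is
#' controlled exactly), `n_stops` stop codons planted at uniformly chosen
#' codon positions (excluding the first and last three codons), then indels
#' at `indel_rate` per site.
#'
#' @param cds upper-case coding sequence; length divisible by 3, no internal
#'   in-frame stop codon.
#' @param nt_rate,indel_rate per-site probabilities.
#' @param n_stops number of in-frame stop codons to plant.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return a list with elements `sequence`, `log` (data frame of every edit:
#'   `op` in sub/stop/ins/del, 1-based `pos`, `from`, `to`), `stop_codons`
#'   (1-based codon indices of planted stops, in pre-indel coordinates) and
#'   `n_substitutions`.
#' @export
degrade_coding_sequence <- function(cds, nt_rate = 0, indel_rate = 0,
                                    n_stops = 0, seed = NULL) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) {
    stop("`cds` length must be divisible by 3", call. = FALSE)
  }
  if (any(codons_of(cds) %in% STOP_CODONS)) {
    stop("`cds` contains an internal in-frame stop codon", call. = FALSE)
  }
  if (nt_rate < 0 || nt_rate > 1 || indel_rate < 0 || indel_rate > 1) {
    stop("substitution and indel rates must be probabilities in [0, 1]",
         call. = FALSE)
  }
  with_seed(seed, {
    x <- seq_chars(cds)
    log <- list()
    # 1. substitutions (stop-creation redirected, count preserved)
    hit <- which(runif(length(x)) < nt_rate)
    for (p in hit) {
      ci <- (p - 1L) %/% 3L
      cod <- x[(3L * ci + 1L):(3L * ci + 3L)]
      off <- p - 3L * ci
      ok <- vapply(setdiff(BASES, x[p]), function(b) {
        cod2 <- cod
        cod2[off] <- b
        !(paste(cod2, collapse = "") %in% STOP_CODONS)
      }, logical(1))
      alt <- names(ok)[ok]
      b <- if (length(alt) == 1L) alt else sample(alt, 1L)
      log[[length(log) + 1L]] <- data.frame(op = "sub", pos = p,
                                            from = x[p], to = b,
                                            stringsAsFactors = FALSE)
      x[p] <- b
    }
    # 2. planted stop codons (frame 0, away from the edges)
    stop_idx <- integer(0)
    if (n_stops > 0L) {
      n_codons <- length(x) %/% 3L
      eligible <- seq.int(4L, n_codons - 3L)
      if (n_stops > length(eligible)) {
        stop("`n_stops` exceeds the number of eligible codon positions",
             call. = FALSE)
      }
      stop_idx <- sort(sample(eligible, n_stops))
      for (ci in stop_idx) {
        sc <- sample(STOP_CODONS, 1L)
        rng <- (3L * (ci - 1L) + 1L):(3L * ci)
        log[[length(log) + 1L]] <- data.frame(op = "stop", pos = rng[1],
                                              from = paste(x[rng], collapse = ""),
                                              to = sc, stringsAsFactors = FALSE)
        x[rng] <- seq_chars(sc)
      }
    }
    # 3. indels, applied right to left so positions stay valid
    if (indel_rate > 0) {
      ipos <- which(runif(length(x)) < indel_rate)
      for (p in rev(ipos)) {
        if (runif(1) < 0.5) {
          log[[length(log) + 1L]] <- data.frame(op = "del", pos = p,
                                                from = x[p], to = "",
                                                stringsAsFactors = FALSE)
          x <- x[-p]
        } else {
          b <- sample(BASES, 1L)
          log[[length(log) + 1L]] <- data.frame(op = "ins", pos = p,
                                                from = "", to = b,
                                                stringsAsFactors = FALSE)
          x <- append(x, b, after = p)
        }
      }
    }
    list(
      sequence = paste(x, collapse = ""),
      log = if (length(log)) do.call(rbind, log) else
        data.frame(op = character(0), pos = integer(0),
                   from = character(0), to = character(0)),
      stop_codons = stop_idx,
      n_substitutions = length(hit)
    )
  })
}

#' Evolve a sequence under a chosen selective regime
#'
#' Applies exactly `n_substitutions` accepted single-base substitutions.
#' `protein_constrained` accepts only synonymous changes (the coding
#' signature, Ka/Ks << 1); `neutral` accepts any change;
#' `nucleotide_constrained` accepts any change outside `anchor_positions`
#' (stand-ins for binding sites, the RR signature of selection at the
#' nucleotide rather than the amino-acid level).
#'
#' @param cds sequence with length divisible by 3.
#' @param mode one of `"protein_constrained"`, `"nucleotide_constrained"`,
#'   `"neutral"`.
#' @param n_substitutions number of accepted substitution events (a site may
#'   be hit more than once).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param anchor_positions 1-based positions that must not change
#'   (`nucleotide_constrained` mode).
#' @param max_attempts rejection-sampling bound before an explicit error.
#' @return the evolved sequence as a single string.
#' @export
evolve_sequence <- function(cds,
                            mode = c("protein_constrained",
                                     "nucleotide_constrained", "neutral"),
                            n_substitutions, seed = NULL,
                            anchor_positions = integer(0),
                            max_attempts = NULL) {
  mode <- match.arg(mode)
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) {
    stop("`cds` length must be divisible by 3", call. = FALSE)
  }
  n_substitutions <- as.integer(n_substitutions)
  if (n_substitutions == 0L) return(cds)
  max_attempts <- max_attempts %||% (200L * n_substitutions + 100L)
  with_seed(seed, {
    x <- seq_chars(cds)
    accepted <- 0L
    attempts <- 0L
    while (accepted < n_substitutions) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop(sprintf(
          "could not reach %d substitutions in mode '%s' after %d attempts",
          n_substitutions, mode, max_attempts), call. = FALSE)
      }
      p <- sample.int(length(x), 1L)
      b <- sample(setdiff(BASES, x[p]), 1L)
      ok <- switch(mode,
        neutral = TRUE,
        nucleotide_constrained = !(p %in% anchor_positions),
        protein_constrained = {
          ci <- (p - 1L) %/% 3L
          cod <- x[(3L * ci + 1L):(3L * ci + 3L)]
          cod2 <- cod
          cod2[p - 3L * ci] <- b
          old_aa <- Biostrings::GENETIC_CODE[[paste(cod, collapse = "")]]
          new_aa <- Biostrings::GENETIC_CODE[[paste(cod2, collapse = "")]]
          identical(old_aa, new_aa) && new_aa != "*"
        })
      if (ok) {
        x[p] <- b
        accepted <- accepted + 1L
      }
    }
    paste(x, collapse = "")
  })
}

#' Generate a synthetic set of position frequency matrices
#'
#' Builds informative synthetic PFMs around random consensus sequences
#' (consensus base count 12, others 1 per column).  The first matrix is the
#' "plantable" motif: its consensus avoids thymine so inserting it into a
#' reading frame can never create a stop codon.
#'
#' @param n number of matrices.
#' @param planted_length length of the first (plantable) motif.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return a list of `pwm` objects (see [pwm_from_counts()]).
#' @export
make_pfm_set <- function(n = 5L, planted_length = 10L, seed = NULL) {
  with_seed(seed, {
    lens <- c(planted_length, sample(8:12, n - 1L, replace = TRUE))
    lapply(seq_len(n), function(i) {
      alph <- if (i == 1L) c("A", "C", "G") else BASES
      cons <- sample(alph, lens[i], replace = TRUE)
      counts <- matrix(1L, nrow = 4L, ncol = lens[i],
                       dimnames = list(BASES, NULL))
      counts[cbind(match(cons, BASES), seq_len(lens[i]))] <- 12L
      pwm_from_counts(counts, matrix_id = sprintf("SYN%04d.1", i),
                      name = paste0("synTF", i))
    })
  })
}

# Fixed minimal ontology: a developmental branch under the four filter roots
# plus a metabolic branch outside the closure.
builtin_ontology <- function() {
  term <- function(id, name, isa = NULL) {
    c("[Term]", paste0("id: ", id), paste0("name: ", name),
      if (!is.null(isa)) paste0("is_a: ", isa, " ! parent"), "")
  }
  c("format-version: 1.2", "ontology: rrgenesis-minimal", "",
    term("GO:0032502", "developmental process"),
    term("GO:0048856", "anatomical structure development", "GO:0032502"),
    term("GO:0007420", "brain development", "GO:0048856"),
    term("GO:0045165", "cell fate commitment", "GO:0032502"),
    term("GO:0030528", "transcription regulator activity"),
    term("GO:0003700", "transcription factor activity", "GO:0030528"),
    term("GO:0008152", "metabolic process"),
    term("GO:0044237", "cellular metabolic process", "GO:0008152"),
    term("GO:0006629", "lipid metabolic process", "GO:0044237"))
}

DEV_GO <- "GO:0007420"      # inside the developmental closure
SRC_GO <- "GO:0044237"      # outside
NONDEV_GO <- "GO:0006629"   # outside

SPECIES_TREE <- paste0(
  "(shark:3,(((human:1,mouse:1):1,(chicken:1,frog:1):1)tetrapod:1,",
  "(zebrafish_rr:2,(stickleback_rr:1,medaka_rr:1):1)teleost:1)bony:1)root;")

# ---- contig assembly helpers -----------------------------------------------

loc_new <- function(contig) {
  e <- new.env(parent = emptyenv())
  e$contig <- contig
  e$parts <- list()
  e$pos <- 0L
  e$ann <- list()
  e
}

loc_add_seq <- function(loc, s) {
  loc$parts[[length(loc$parts) + 1L]] <- s
  loc$pos <- loc$pos + nchar(s)
  invisible(NULL)
}

loc_spacer <- function(loc, len) {
  if (len > 0L) loc_add_seq(loc, random_dna(len))
  invisible(NULL)
}

loc_ann <- function(loc, feature_id, gene_id, start0, end0, type) {
  loc$ann[[length(loc$ann) + 1L]] <- data.frame(
    feature_id = feature_id, gene_id = gene_id, contig = loc$contig,
    start0 = start0, end0 = end0, strand = "+", type = type,
    stringsAsFactors = FALSE)
  invisible(NULL)
}

loc_gene <- function(loc, gene_id, exon_seqs, intron_len = 200L) {
  gs <- loc$pos
  for (k in seq_along(exon_seqs)) {
    s0 <- loc$pos
    loc_add_seq(loc, exon_seqs[[k]])
    loc_ann(loc, paste0(gene_id, "_e", k), gene_id, s0, loc$pos, "exon")
    if (k < length(exon_seqs)) loc_spacer(loc, intron_len)
  }
  loc_ann(loc, gene_id, gene_id, gs, loc$pos, "gene")
  invisible(NULL)
}

loc_relic <- function(loc, s) {
  s0 <- loc$pos
  loc_add_seq(loc, s)
  c(s0, loc$pos)
}

loc_done <- function(loc) {
  list(seq = paste(unlist(loc$parts), collapse = ""),
       ann = if (length(loc$ann)) do.call(rbind, loc$ann) else NULL)
}

# Substitute a motif into the relic without disturbing planted stop codons
# and without creating or destroying in-frame stops.
plant_motif <- function(relic, motif, stop_codons, n_expected_stops) {
  L <- nchar(relic)
  ml <- nchar(motif)
  stop_nt <- unlist(lapply(stop_codons, function(ci) (3L * (ci - 1L) + 1L):(3L * ci)))
  cand <- sample(seq.int(10L, L - ml - 9L))
  for (s in cand) {
    rng <- s:(s + ml - 1L)
    if (length(intersect(rng, stop_nt))) next
    x <- seq_chars(relic)
    x[rng] <- seq_chars(motif)
    out <- paste(x, collapse = "")
    if (sum(codons_of(out) %in% STOP_CODONS) == n_expected_stops) {
      return(list(sequence = out, start0 = s - 1L, end0 = s - 1L + ml))
    }
  }
  stop("could not place the motif without disturbing the planted stops",
       call. = FALSE)
}

# ---- main generator ---------------------------------------------------------

#' Generate a synthetic RR scenario bundle
#'
#' Builds a complete toy evolutionary scenario set: a reference genome with
#' annotated coding exons and flanking genes, a duplicated target genome in
#' which one locus retains the coding gene and the other carries a
#' stop-disrupted but alignable exon relic (the planted RR), orthology and
#' GO annotation supporting the synteny and developmental filters, outgroup
#' orthologs with intact reading frames, a species tree, and a synthetic PFM
#' set with one teleost-specific motif planted into each RR.  One additional
#' scenario per requested decoy class violates exactly that filter and
#' satisfies all others.
#'
#' All randomness is drawn from a single stream seeded with `config$seed`,
#' in a fixed order (PFM set first, then scenarios: planted RRs in index
#' order, then decoys in the order given by `config$decoy_classes`), so the
#' bundle is fully reproducible.
#'
#' @param config a [scenario_config()].
#' @return a `scenario_bundle` list with the genomes (`DNAStringSet`),
#'   annotation data frames (0-based half-open coordinates), gene-to-GO
#'   tables, orthology map, OBO ontology text, per-gene outgroup sequences,
#'   Newick species tree, PFM list, planted-motif table and ground-truth
#'   records (`truth`).
#' @seealso [write_scenario_bundle()], [run_funnel()]
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  with_seed(cfg$seed, {
    scl <- function(x) max(1L, as.integer(round(x / cfg$genome_scale_divisor)))
    ig <- scl(cfg$intergenic_length)
    pwms <- make_pfm_set()
    planted_consensus <- paste(
      BASES[apply(pwms[[1]]$counts, 2L, which.max)], collapse = "")

    roles <- c(rep("planted", cfg$n_reference_genes), cfg$decoy_classes)
    acc <- list(ref_seqs = list(), tgt_seqs = list(), ann_ref = list(),
                ann_tgt = list(), g2g = list(), orth = list(), truth = list(),
                outgroups = list(), motifs = list())

    for (i in seq_along(roles)) {
      role <- roles[i]
      g <- paste0("g", i)
      cds <- random_cds(cfg$exon_length_codons)
      fl_ex <- list(random_dna(150L), random_dna(150L))
      fr_ex <- list(random_dna(150L), random_dna(150L))

      # relic (the decayed exon copy)
      if (role == "frame") {
        deg <- degrade_coding_sequence(cds, cfg$nt_substitution_rate, 0, 0)
      } else {
        deg <- degrade_coding_sequence(cds, cfg$nt_substitution_rate,
                                       cfg$indel_rate, cfg$n_planted_stops)
      }
      relic <- deg$sequence
      stop_nt <- unlist(lapply(deg$stop_codons,
                               function(ci) (3L * (ci - 1L) + 1L):(3L * ci)))
      anchors <- stop_nt
      if (role == "planted") {
        pm <- plant_motif(relic, planted_consensus, deg$stop_codons,
                          cfg$n_planted_stops)
        relic <- pm$sequence
        anchors <- c(anchors, (pm$start0 + 1L):pm$end0)
        acc$motifs[[g]] <- data.frame(
          gene_id = g, pwm_id = pwms[[1]]$matrix_id,
          start0 = pm$start0, end0 = pm$end0, stringsAsFactors = FALSE)
      }
      retained <- evolve_sequence(cds, "protein_constrained",
                                  CODING_DIVERGENCE_TARGET)

      # reference contig: flankL (developmental GO) - source gene - flankR
      ref <- loc_new(paste0("ref_", i))
      loc_spacer(ref, ig); loc_gene(ref, paste0(g, "_fL"), fl_ex)
      loc_spacer(ref, ig); loc_gene(ref, g, list(cds))
      loc_spacer(ref, ig); loc_gene(ref, paste0(g, "_fR"), fr_ex)
      loc_spacer(ref, ig)
      refd <- loc_done(ref)
      acc$ref_seqs[[ref$contig]] <- refd$seq
      acc$ann_ref[[ref$contig]] <- refd$ann

      fl_t <- function() lapply(fl_ex, mutate_dna, rate = 0.03)
      fr_t <- function() lapply(fr_ex, mutate_dna, rate = 0.03)

      has_t1 <- !(role %in% "ortholog_presence")
      relic_iv <- NULL
      relic_contig <- NULL

      if (role == "ortholog_proximity") {
        # relic on the same contig as the retained ortholog, within range
        t1 <- loc_new(paste0("t1_", i))
        loc_spacer(t1, ig); loc_gene(t1, paste0(g, "_fL_t1"), fl_t())
        loc_spacer(t1, ig); relic_iv <- loc_relic(t1, relic)
        relic_contig <- t1$contig
        loc_spacer(t1, scl(50000L)); loc_gene(t1, paste0(g, "_t1"), list(retained))
        loc_spacer(t1, ig); loc_gene(t1, paste0(g, "_fR_t1"), fr_t())
        loc_spacer(t1, ig)
        t1d <- loc_done(t1)
        acc$tgt_seqs[[t1$contig]] <- t1d$seq
        acc$ann_tgt[[t1$contig]] <- t1d$ann
      } else {
        if (has_t1) {
          t1 <- loc_new(paste0("t1_", i))
          loc_spacer(t1, ig); loc_gene(t1, paste0(g, "_fL_t1"), fl_t())
          loc_spacer(t1, ig); loc_gene(t1, paste0(g, "_t1"), list(retained))
          loc_spacer(t1, ig); loc_gene(t1, paste0(g, "_fR_t1"), fr_t())
          loc_spacer(t1, ig)
          t1d <- loc_done(t1)
          acc$tgt_seqs[[t1$contig]] <- t1d$seq
          acc$ann_tgt[[t1$contig]] <- t1d$ann
        }
        # gene-lost locus carrying the relic
        t2 <- loc_new(paste0("t2_", i))
        loc_spacer(t2, ig); loc_gene(t2, paste0(g, "_fL_t2"), fl_t())
        if (role == "synteny") {
          loc_spacer(t2, scl(150000L))
          relic_iv <- loc_relic(t2, relic)
          loc_spacer(t2, scl(150000L))
        } else if (role == "go") {
          loc_spacer(t2, scl(3000L))
          loc_gene(t2, paste0(g, "_nd1"), list(random_dna(300L)))
          loc_spacer(t2, scl(3000L))
          relic_iv <- loc_relic(t2, relic)
          loc_spacer(t2, scl(3000L))
          loc_gene(t2, paste0(g, "_nd2"), list(random_dna(300L)))
          loc_spacer(t2, scl(3000L))
        } else {
          loc_spacer(t2, ig)
          relic_iv <- loc_relic(t2, relic)
          if (role == "exonic_overlap") {
            loc_ann(t2, paste0(g, "_est1"), NA_character_,
                    relic_iv[1] + 10L, relic_iv[1] + 60L, "EST")
          }
          loc_spacer(t2, ig)
        }
        relic_contig <- t2$contig
        loc_gene(t2, paste0(g, "_fR_t2"), fr_t())
        loc_spacer(t2, ig)
        t2d <- loc_done(t2)
        acc$tgt_seqs[[t2$contig]] <- t2d$seq
        acc$ann_tgt[[t2$contig]] <- t2d$ann
      }

      # GO assignment: exactly one flanking gene (left) is developmental
      g2g <- list(c(paste0(g, "_fL"), DEV_GO), c(g, SRC_GO),
                  c(paste0(g, "_fR"), NONDEV_GO))
      tgt_copy <- function(base) {
        out <- character(0)
        if (has_t1 && role != "ortholog_presence") out <- c(out, paste0(base, "_t1"))
        if (role != "ortholog_proximity") out <- c(out, paste0(base, "_t2"))
        out
      }
      for (b in c(paste0(g, "_fL"), paste0(g, "_fR"))) {
        go <- if (grepl("_fL$", b)) DEV_GO else NONDEV_GO
        for (cp in tgt_copy(b)) g2g[[length(g2g) + 1L]] <- c(cp, go)
      }
      if (has_t1) g2g[[length(g2g) + 1L]] <- c(paste0(g, "_t1"), SRC_GO)
      if (role == "go") {
        g2g[[length(g2g) + 1L]] <- c(paste0(g, "_nd1"), NONDEV_GO)
        g2g[[length(g2g) + 1L]] <- c(paste0(g, "_nd2"), NONDEV_GO)
      }
      acc$g2g[[g]] <- do.call(rbind, g2g)

      # orthology map
      if (role != "ortholog_presence") {
        acc$orth[[g]] <- paste0(g, "_t1")
      }
      acc$orth[[paste0(g, "_fL")]] <- tgt_copy(paste0(g, "_fL"))
      acc$orth[[paste0(g, "_fR")]] <- tgt_copy(paste0(g, "_fR"))

      # outgroup orthologous sequences (equal length => trivially aligned)
      og <- c(human = cds,
              vapply(names(OUTGROUP_CODING), function(sp) {
                evolve_sequence(cds, "protein_constrained", OUTGROUP_CODING[[sp]])
              }, character(1)),
              medaka_coding = retained,
              medaka_rr = relic,
              vapply(names(TELEOST_EXTRA_DIVERGENCE), function(sp) {
                evolve_sequence(relic, "nucleotide_constrained",
                                TELEOST_EXTRA_DIVERGENCE[[sp]],
                                anchor_positions = anchors)
              }, character(1)))
      acc$outgroups[[g]] <- og

      acc$truth[[g]] <- data.frame(
        kind = if (role == "planted") "planted_rr" else "decoy",
        violated_filter = if (role == "planted") NA_character_ else role,
        contig = relic_contig, start0 = relic_iv[1], end0 = relic_iv[2],
        source_exon_id = paste0(g, "_e1"),
        n_planted_stops = length(deg$stop_codons),
        stringsAsFactors = FALSE)
    }

    truth <- do.call(rbind, acc$truth)
    rownames(truth) <- NULL
    g2g <- do.call(rbind, acc$g2g)
    g2g <- data.frame(gene_id = g2g[, 1], go_id = g2g[, 2],
                      stringsAsFactors = FALSE)

    bundle <- structure(list(
      config = cfg,
      reference_genome = Biostrings::DNAStringSet(unlist(acc$ref_seqs)),
      reference_annotation = do.call(rbind, unname(acc$ann_ref)),
      target_genome = Biostrings::DNAStringSet(unlist(acc$tgt_seqs)),
      target_annotation = do.call(rbind, unname(acc$ann_tgt)),
      gene2go = g2g,
      orthology = acc$orth,
      ontology = builtin_ontology(),
      outgroups = acc$outgroups,
      species_tree = SPECIES_TREE,
      pwms = pwms,
      planted_motifs = if (length(acc$motifs)) do.call(rbind, unname(acc$motifs)) else NULL,
      truth = truth
    ), class = "scenario_bundle")
    rownames(bundle$reference_annotation) <- NULL
    rownames(bundle$target_annotation) <- NULL
    if (!is.null(bundle$planted_motifs)) rownames(bundle$planted_motifs) <- NULL

    # bundle invariants: every planted relic keeps its in-frame stops
    planted <- truth[truth$kind == "planted_rr", , drop = FALSE]
    for (k in seq_len(nrow(planted))) {
      rs <- as.character(Biostrings::subseq(
        bundle$target_genome[[planted$contig[k]]],
        planted$start0[k] + 1L, planted$end0[k]))
      stopifnot(sum(codons_of(rs) %in% STOP_CODONS) >= 1L)
    }
    bundle
  })
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat("scenario_bundle\n")
  cat(sprintf("  reference: %d contigs, %d features\n",
              length(x$reference_genome), nrow(x$reference_annotation)))
  cat(sprintf("  target:    %d contigs, %d features\n",
              length(x$target_genome), nrow(x$target_annotation)))
  cat(sprintf("  truth:     %d planted RR(s), %d decoy(s)\n",
              sum(x$truth$kind == "planted_rr"), sum(x$truth$kind == "decoy")))
  invisible(x)
}

# ---- bundle I/O -------------------------------------------------------------

write_gff3 <- function(ann, path) {
  lines <- "##gff-version 3"
  if (!is.null(ann) && nrow(ann)) {
    attrs <- ifelse(is.na(ann$gene_id),
                    paste0("ID=", ann$feature_id),
                    paste0("ID=", ann$feature_id, ";gene_id=", ann$gene_id))
    lines <- c(lines, sprintf("%s\trrgenesis\t%s\t%d\t%d\t.\t%s\t.\t%s",
                              ann$contig, ann$type, ann$start0 + 1L, ann$end0,
                              ann$strand, attrs))
  }
  writeLines(lines, path)
}

read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  m <- S4Vectors::mcols(gr)
  data.frame(
    feature_id = as.character(m$ID),
    gene_id = if ("gene_id" %in% names(m)) as.character(m$gene_id) else NA_character_,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start0 = GenomicRanges::start(gr) - 1L,
    end0 = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(m$type),
    stringsAsFactors = FALSE)
}

#' Write a scenario bundle to standard-format files
#'
#' Writes FASTA genomes, GFF3 annotations, TSV orthology and gene-to-GO
#' tables, an OBO ontology, a Newick species tree, JASPAR-format PFMs,
#' per-gene outgroup FASTA (`gene|species` headers), JSON truth records and
#' a YAML copy of the generating configuration.  Output is byte-reproducible
#' for a fixed configuration.
#'
#' @param bundle a `scenario_bundle` from [generate_scenario()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "scenario_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(bundle$reference_genome, p("reference_genome.fa"))
  Biostrings::writeXStringSet(bundle$target_genome, p("target_genome.fa"))
  write_gff3(bundle$reference_annotation, p("reference_annotation.gff3"))
  write_gff3(bundle$target_annotation, p("target_annotation.gff3"))
  orth <- bundle$orthology
  orth_df <- data.frame(
    reference_gene = rep(names(orth), lengths(orth)),
    target_gene = unlist(orth, use.names = FALSE), stringsAsFactors = FALSE)
  write.table(orth_df, p("orthology.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(bundle$gene2go, p("gene2go.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(bundle$ontology, p("ontology.obo"))
  writeLines(bundle$species_tree, p("species_tree.nwk"))
  write_jaspar_pfm(bundle$pwms, p("pwms.pfm"))
  og <- bundle$outgroups
  seqs <- unlist(lapply(names(og), function(g) {
    setNames(og[[g]], paste0(g, "|", names(og[[g]])))
  }))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), p("outgroups.fa"))
  jsonlite::write_json(bundle$truth, p("truth.json"), dataframe = "rows",
                       na = "null", auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$planted_motifs)) {
    jsonlite::write_json(bundle$planted_motifs, p("planted_motifs.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  cfgl <- unclass(bundle$config)
  yaml::write_yaml(cfgl, p("config.yaml"))
  invisible(dir)
}

#' Read a scenario bundle back from files
#'
#' Inverse of [write_scenario_bundle()].
#'
#' @param dir directory written by [write_scenario_bundle()].
#' @return a `scenario_bundle`.
#' @export
read_scenario_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  cfgl <- yaml::read_yaml(p("config.yaml"))
  cfgl$decoy_classes <- as.character(cfgl$decoy_classes %||% character(0))
  config <- do.call(scenario_config, cfgl)
  orth_df <- read.table(p("orthology.tsv"), sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
  orthology <- split(orth_df$target_gene, orth_df$reference_gene)
  og_set <- Biostrings::readDNAStringSet(p("outgroups.fa"))
  og_keys <- strsplit(names(og_set), "|", fixed = TRUE)
  og_gene <- vapply(og_keys, `[`, character(1), 1L)
  og_sp <- vapply(og_keys, `[`, character(1), 2L)
  outgroups <- lapply(split(seq_along(og_set), og_gene), function(idx) {
    setNames(as.character(og_set[idx]), og_sp[idx])
  })
  truth <- jsonlite::fromJSON(p("truth.json"))
  motifs <- if (file.exists(p("planted_motifs.json"))) {
    jsonlite::fromJSON(p("planted_motifs.json"))
  } else NULL
  structure(list(
    config = config,
    reference_genome = Biostrings::readDNAStringSet(p("reference_genome.fa")),
    reference_annotation = read_gff3(p("reference_annotation.gff3")),
    target_genome = Biostrings::readDNAStringSet(p("target_genome.fa")),
    target_annotation = read_gff3(p("target_annotation.gff3")),
    gene2go = read.table(p("gene2go.tsv"), sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE),
    orthology = orthology,
    ontology = readLines(p("ontology.obo")),
    outgroups = outgroups,
    species_tree = readLines(p("species_tree.nwk"))[1],
    pwms = read_jaspar_pfm(p("pwms.pfm")),
    planted_motifs = motifs,
    truth = truth
  ), class = "scenario_bundle")
}
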