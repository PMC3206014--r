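# Pipeline orchestration: simulate -> discover -> evo -> tfbs -> report,
# with a run manifest capturing configuration, checksums and timings.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline.  Unknown keys are rejected so a
#' typo in a YAML configuration cannot silently fall back to a default.
#'
#' @param seed integer seed forwarded to the scenario generator.
#' @param out_dir output directory.
#' @param scenario a [scenario_config()].
#' @param funnel a [funnel_config()].
#' @param tfbs list: `rel_threshold`, `teleosts` (species treated as
#'   teleost RR carriers), `ancestor_node`.
#' @param evo list: `denominator` for [identity_profile()].
#' @param stages stages to run, in order.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = "rr_run",
                            scenario = NULL,
                            funnel = funnel_config(),
                            tfbs = list(),
                            evo = list(),
                            stages = c("simulate", "discover", "evo",
                                       "tfbs", "report")) {
  scenario <- scenario %||% scenario_config(seed = seed)
  # ancestor is reconstructed at the root of the bony vertebrates, the last
  # common ancestor preceding the teleost WGD
  tfbs_def <- list(rel_threshold = 0.8,
                   teleosts = c("medaka_rr", "stickleback_rr", "zebrafish_rr"),
                   ancestor_node = "bony")
  evo_def <- list(denominator = "reference")
  check_keys <- function(given, known, where) {
    extra <- setdiff(names(given), known)
    if (length(extra)) {
      stop("unknown ", where, " configuration key(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  check_keys(tfbs, names(tfbs_def), "tfbs")
  check_keys(evo, names(evo_def), "evo")
  bad_stage <- setdiff(stages, c("simulate", "discover", "evo", "tfbs", "report"))
  if (length(bad_stage)) {
    stop("unknown pipeline stage(s): ", paste(bad_stage, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), out_dir = out_dir, scenario = scenario,
    funnel = funnel, tfbs = utils::modifyList(tfbs_def, tfbs),
    evo = utils::modifyList(evo_def, evo), stages = stages
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with top-level keys matching [pipeline_config()]
#'   arguments (`scenario` and `funnel` given as key-value maps).
#' @param ... overrides applied on top of the file (highest precedence).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  over <- list(...)
  y <- utils::modifyList(y, over)
  if (!is.null(y$scenario) && !inherits(y$scenario, "scenario_config")) {
    y$scenario <- do.call(scenario_config, y$scenario)
  }
  if (!is.null(y$funnel) && !inherits(y$funnel, "funnel_config")) {
    y$funnel <- do.call(funnel_config, y$funnel)
  }
  do.call(pipeline_config, y)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

candidates_bed <- function(candidates, path) {
  if (nrow(candidates)) {
    bed <- data.frame(candidates$contig, candidates$start0, candidates$end0,
                      candidates$hit_id, round(candidates$score),
                      ifelse(candidates$strand %in% c("+", "-"),
                             candidates$strand, "."))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    writeLines(character(0), path)
  }
}

#' Run the complete RR pipeline
#'
#' Executes the enabled stages in order on a synthetic scenario bundle:
#' `simulate` (generate and write the bundle), `discover` (mapping plus the
#' filter funnel), `evo` (per-candidate identity profiles and Ka/Ks against
#' the outgroup set), `tfbs` (ancestral reconstruction and teleost-specific
#' binding sites, S200 and regulatory potential of the candidate set
#' against the coding exons), and `report`.  All stages are deterministic
#' given the seed; candidate and report files are byte-reproducible.
#'
#' @param config a [pipeline_config()].
#' @return a `run_manifest` list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }
  stage_files <- character(0)
  bundle <- NULL
  funnel_res <- NULL
  evo_tbl <- NULL
  kaks_tbl <- NULL
  tfbs_tbl <- NULL
  rp <- NULL

  if ("simulate" %in% config$stages) {
    bundle <- tick("simulate", {
      b <- generate_scenario(config$scenario)
      write_scenario_bundle(b, file.path(out, "bundle"))
      b
    })
  } else {
    bundle <- read_scenario_bundle(file.path(out, "bundle"))
  }

  if ("discover" %in% config$stages) {
    funnel_res <- tick("discover", run_funnel(bundle, config$funnel))
    write_tsv(funnel_res$candidates, file.path(out, "candidates.tsv"))
    candidates_bed(funnel_res$candidates, file.path(out, "candidates.bed"))
    write_tsv(funnel_res$report$stages, file.path(out, "funnel.tsv"))
    jsonlite::write_json(funnel_res$report$stages, file.path(out, "funnel.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    stage_files <- c(stage_files, "candidates.tsv", "candidates.bed",
                     "funnel.tsv", "funnel.json")
  }

  cand <- funnel_res$candidates
  genes <- if (!is.null(cand) && nrow(cand)) {
    unique(cand$gene_id[cand$gene_id %in% names(bundle$outgroups)])
  } else character(0)

  if ("evo" %in% config$stages && !is.null(funnel_res)) {
    evo_res <- tick("evo", {
      prof <- list()
      kk <- list()
      for (g in genes) {
        og <- bundle$outgroups[[g]]
        ref <- og[["human"]]
        for (sp in setdiff(names(og), "human")) {
          aln <- global_align(ref, og[[sp]])
          ip <- identity_profile(aln, reference = 1L,
                                 denominator = config$evo$denominator,
                                 species = sp)
          prof[[length(prof) + 1L]] <- data.frame(
            gene_id = g, species = sp,
            nt_identity_pct = ip$nt_identity_pct,
            aa_similarity_pct = ip$aa_similarity_pct,
            alignable_length = ip$alignable_length, stringsAsFactors = FALSE)
        }
        for (sp in c("medaka_rr", "medaka_coding")) {
          if (!sp %in% names(og)) next
          aln <- global_align(ref, og[[sp]])
          kr <- tryCatch(compute_kaks(strip_indels_and_stops(aln)),
                         error = function(e) NULL)
          if (!is.null(kr)) {
            kk[[length(kk) + 1L]] <- data.frame(
              gene_id = g, species = sp, ka = kr$ka, ks = kr$ks,
              ratio = kr$ratio, ratio_class = kr$ratio_class,
              codons_used = kr$codons_used,
              removed_indel_codons = kr$removed[["indel_codons"]],
              removed_stop_codons = kr$removed[["stop_codons"]],
              stringsAsFactors = FALSE)
          }
        }
      }
      list(prof = if (length(prof)) do.call(rbind, prof) else NULL,
           kk = if (length(kk)) do.call(rbind, kk) else NULL)
    })
    evo_tbl <- evo_res$prof
    kaks_tbl <- evo_res$kk
    if (!is.null(evo_tbl)) write_tsv(evo_tbl, file.path(out, "evo_profiles.tsv"))
    if (!is.null(kaks_tbl)) write_tsv(kaks_tbl, file.path(out, "kaks.tsv"))
    stage_files <- c(stage_files,
                     if (!is.null(evo_tbl)) "evo_profiles.tsv",
                     if (!is.null(kaks_tbl)) "kaks.tsv")
  }

  if ("tfbs" %in% config$stages && !is.null(funnel_res)) {
    tfbs_res <- tick("tfbs", {
      rows <- list()
      for (g in genes) {
        og <- bundle$outgroups[[g]]
        teleosts <- intersect(config$tfbs$teleosts, names(og))
        others <- setdiff(names(og), c(teleosts, "medaka_coding"))
        anc <- reconstruct_ancestor(og, bundle$species_tree,
                                    node = config$tfbs$ancestor_node)
        thr <- config$tfbs$rel_threshold
        for (p in bundle$pwms) {
          th <- lapply(setNames(teleosts, teleosts), function(sp) {
            scan_aligned(og[[sp]], p, thr, sequence_id = sp)
          })
          oh <- lapply(setNames(others, others), function(sp) {
            scan_aligned(og[[sp]], p, thr, sequence_id = sp)
          })
          ah <- scan_aligned(anc$sequence, p, thr, sequence_id = "ancestor")
          sp_sites <- lineage_specific_sites(th, oh, ah)
          if (nrow(sp_sites)) {
            sp_sites$gene_id <- g
            rows[[length(rows) + 1L]] <- sp_sites
          }
        }
      }
      rp_val <- NULL
      # S200 / regulatory potential: candidate RR relics vs coding exons
      if (length(genes)) {
        rr_seqs <- vapply(genes, function(g) bundle$outgroups[[g]][["medaka_rr"]],
                          character(1))
        exon_seqs <- vapply(genes, function(g) bundle$outgroups[[g]][["human"]],
                            character(1))
        s_rr <- s200(rr_seqs, bundle$pwms, config$tfbs$rel_threshold,
                     label = "candidate_rr")
        s_ex <- s200(exon_seqs, bundle$pwms, config$tfbs$rel_threshold,
                     label = "coding_exon")
        rp_val <- list(
          overlap_pct = suppressWarnings(regulatory_potential(s_rr, s_ex)),
          s200_rr = unname(s_rr$values), s200_exon = unname(s_ex$values))
      }
      list(tbl = if (length(rows)) do.call(rbind, rows) else NULL,
           rp = rp_val)
    })
    tfbs_tbl <- tfbs_res$tbl
    rp <- tfbs_res$rp
    if (!is.null(tfbs_tbl)) write_tsv(tfbs_tbl, file.path(out, "tfbs_specific.tsv"))
    if (!is.null(rp)) {
      jsonlite::write_json(rp, file.path(out, "s200_summary.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    stage_files <- c(stage_files,
                     if (!is.null(tfbs_tbl)) "tfbs_specific.tsv",
                     if (!is.null(rp)) "s200_summary.json")
  }

  run <- list(candidates = cand, report = funnel_res$report,
              evo = evo_tbl, kaks = kaks_tbl, tfbs = tfbs_tbl,
              regulatory_potential = rp)

  if ("report" %in% config$stages && !is.null(funnel_res)) {
    rep <- render_report(run)
    writeLines(rep$text, file.path(out, "report.txt"))
    jsonlite::write_json(rep$json, file.path(out, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null")
    stage_files <- c(stage_files, "report.txt", "report.json")
  }

  cfg_snapshot <- config
  cfg_snapshot$scenario <- unclass(cfg_snapshot$scenario)
  cfg_snapshot$funnel <- unclass(cfg_snapshot$funnel)
  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("rrgenesis")),
    config = unclass(cfg_snapshot),
    outputs = as.list(tools::md5sum(file.path(out, stage_files))),
    timings = timings,
    n_candidates = if (is.null(cand)) NA_integer_ else nrow(cand)
  ), class = "run_manifest")
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(manifest)
}

#' Render a human-readable run summary
#'
#' @param run the in-memory result assembled by [run_pipeline()] (list with
#'   `candidates`, `report`, `evo`, `kaks`, `tfbs`,
#'   `regulatory_potential`).
#' @return list with `text` (character lines) and a machine-readable
#'   `json` twin.
#' @export
render_report <- function(run) {
  lines <- c("Recycled Region discovery report", "")
  st <- run$report$stages
  lines <- c(lines, "Funnel (input -> output per stage):")
  for (i in seq_len(nrow(st))) {
    lines <- c(lines, sprintf("  %-20s %6d -> %6d",
                              st$stage[i], st$n_in[i], st$n_out[i]))
  }
  cand <- run$candidates
  n_cand <- if (is.null(cand)) 0L else nrow(cand)
  lines <- c(lines, "", sprintf("Candidates: %d", n_cand))
  if (n_cand == 0L && nrow(st)) {
    last_nonzero <- st$stage[max(which(st$n_out > 0), 1L)]
    lines <- c(lines, sprintf("  (last non-empty stage: %s)", last_nonzero))
  }
  if (n_cand > 0L) {
    for (i in seq_len(n_cand)) {
      lines <- c(lines, sprintf(
        "  %s  %s:%d-%d  exon %s  flanks %s/%s  stops %s  frameshift %s",
        cand$hit_id[i], cand$contig[i], cand$start0[i], cand$end0[i],
        cand$exon_id[i], cand$flank_left[i], cand$flank_right[i],
        cand$n_stops[i], cand$frameshift[i]))
    }
  }
  if (!is.null(run$kaks)) {
    lines <- c(lines, "", "Ka/Ks (vs reference exon):")
    for (i in seq_len(nrow(run$kaks))) {
      k <- run$kaks[i, ]
      lines <- c(lines, sprintf("  %s %-14s Ka %.4f Ks %.4f ratio %s",
                                k$gene_id, k$species, k$ka, k$ks,
                                if (is.na(k$ratio)) k$ratio_class else
                                  sprintf("%.3f", k$ratio)))
    }
  }
  if (!is.null(run$tfbs)) {
    lines <- c(lines, "", sprintf("Teleost-specific binding sites: %d",
                                  nrow(run$tfbs)))
  }
  if (!is.null(run$regulatory_potential)) {
    lines <- c(lines, sprintf("S200 overlap RR vs coding exons: %.1f%%",
                              run$regulatory_potential$overlap_pct))
  }
  json <- list(
    stages = st,
    candidates = if (is.null(cand)) data.frame() else cand,
    kaks = if (is.null(run$kaks)) data.frame() else run$kaks,
    n_teleost_specific_sites = if (is.null(run$tfbs)) 0L else nrow(run$tfbs),
    regulatory_potential = run$regulatory_potential
  )
  list(text = lines, json = json)
}
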