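ONT <- builtin_ontology()

test_that("developmental closure follows is_a descent", {
  cl <- developmental_closure(ONT)
  expect_true("GO:0007420" %in% cl)     # brain development, two levels down
  expect_true("GO:0003700" %in% cl)     # a root itself
  expect_false("GO:0008152" %in% cl)    # metabolic branch stays out
  expect_false("GO:0006629" %in% cl)
  # closure of a childless root is the root
  expect_identical(developmental_closure(ONT, "GO:0045165"), "GO:0045165")
  # missing root is a configuration error naming the id
  expect_error(developmental_closure(ONT, c("GO:0032502", "GO:9999999")),
               "GO:9999999")
})

test_that("ortholog presence filter drops unmapped genes", {
  hits <- rbind(mk_hit("h1", "e1", "gA", "c1", 0, 100),
                mk_hit("h2", "e2", "gB", "c1", 500, 600))
  orth <- list(gA = c("gA_t1", "gA_t2"))
  kept <- filter_ortholog_presence(hits, orth)
  expect_identical(kept$hit_id, "h1")
  expect_warning(none <- filter_ortholog_presence(hits, list()), "empty")
  expect_equal(nrow(none), 0L)
  hits$gene_id[1] <- NA
  expect_error(filter_ortholog_presence(hits, orth), "h1")
})

test_that("ortholog proximity applies the 2 Mb rule per contig", {
  ann <- mk_ann("gT", "gT", "c1", 5000000, 5010000)
  orth <- list(gA = "gT")
  near <- mk_hit("h1", "e1", "gA", "c1", 3100000, 3100200)  # 1.9 Mb away
  far <- mk_hit("h2", "e1", "gA", "c1", 2899000, 2899200)   # 2.1 Mb away
  other <- mk_hit("h3", "e1", "gA", "c2", 0, 200)               # other contig
  kept <- filter_ortholog_proximity(rbind(near, far, other), orth, ann)
  expect_setequal(kept$hit_id, c("h2", "h3"))
})

test_that("exon/EST overlap removes even 1 bp of overlap", {
  ann <- rbind(mk_ann("ex1", "gT", "c1", 199, 300, type = "exon"),
               mk_ann("est1", NA, "c1", 1000, 1100, type = "EST"))
  touching <- mk_hit("h1", "e1", "gA", "c1", 100, 199)  # half-open touch
  onebp <- mk_hit("h2", "e1", "gA", "c1", 100, 200)     # 1 bp shared
  inside_est <- mk_hit("h3", "e1", "gA", "c1", 1050, 1080)
  intron <- mk_hit("h4", "e1", "gA", "c1", 400, 500)
  kept <- filter_exonic_overlap(rbind(touching, onebp, inside_est, intron), ann)
  expect_setequal(kept$hit_id, c("h1", "h4"))
})

test_that("synteny retains hits near developmental orthologs only", {
  closure <- developmental_closure(ONT)
  # reference: source exon at 500k, developmental neighbour gDev at 600k
  ref_ann <- rbind(mk_ann("gSrc", "gSrc", "r1", 500000, 500180),
                   mk_ann("gDev", "gDev", "r1", 600000, 602000),
                   mk_ann("gFar", "gFar", "r1", 900000, 902000))
  exons <- data.frame(exon_id = "e1", gene_id = "gSrc", contig = "r1",
                      start0 = 500000, end0 = 500180, strand = "+",
                      length = 180L, frame_offset = 0L, sequence = "",
                      stringsAsFactors = FALSE)
  g2g <- data.frame(gene_id = c("gDev", "gFar", "gMet"),
                    go_id = c("GO:0007420", "GO:0007420", "GO:0006629"))
  orth <- list(gDev = "gDev_t", gFar = "gFar_t", gMet = "gMet_t")
  tgt <- rbind(mk_ann("gDev_t", "gDev_t", "t1", 200000, 202000),
               mk_ann("i1", "i1", "t1", 170000, 171000),
               mk_ann("i2", "i2", "t1", 172000, 173000),
               mk_ann("i3", "i3", "t1", 174000, 175000))
  # 50 kb from ortholog with 3 intervening genes -> retained
  ok <- mk_hit("h1", "e1", "gSrc", "t1", 149800, 150000)
  # 150 kb from the nearest ortholog -> dropped
  toofar <- mk_hit("h2", "e1", "gSrc", "t1", 49800, 50000)
  kept <- assess_synteny(rbind(ok, toofar), exons, ref_ann, tgt, g2g, orth,
                         closure)
  expect_identical(kept$hit_id, "h1")
  # more than five intervening genes -> dropped
  many <- do.call(rbind, lapply(1:6, function(i) {
    mk_ann(paste0("x", i), paste0("x", i), "t1",
           160000 + i * 1000, 160500 + i * 1000)
  }))
  kept2 <- assess_synteny(ok, exons, ref_ann, rbind(tgt, many), g2g, orth,
                          closure)
  expect_equal(nrow(kept2), 0L)
  # two hits of one gene within 300 kb -> both discarded
  twin <- rbind(ok, mk_hit("h3", "e1", "gSrc", "t1", 350000, 350200))
  tgt2 <- rbind(tgt, mk_ann("gDev_t2", "gDev_t", "t1", 400000, 402000))
  kept3 <- assess_synteny(twin, exons, ref_ann, tgt2, g2g, orth, closure)
  expect_equal(nrow(kept3), 0L)
})

test_that("developmental flanking gene filter inspects the nearest genes", {
  closure <- developmental_closure(ONT)
  g2g <- data.frame(gene_id = c("gDev", "gMet1", "gMet2"),
                    go_id = c("GO:0003700", "GO:0006629", "GO:0006629"))
  hit <- mk_hit("h1", "e1", "gSrc", "t1", 10000, 10200)
  dev_flank <- rbind(mk_ann("gDev", "gDev", "t1", 5000, 6000),
                     mk_ann("gMet1", "gMet1", "t1", 15000, 16000))
  expect_equal(nrow(filter_developmental_flank(hit, dev_flank, g2g, closure)), 1L)
  met_only <- rbind(mk_ann("gMet1", "gMet1", "t1", 5000, 6000),
                    mk_ann("gMet2", "gMet2", "t1", 15000, 16000))
  expect_equal(nrow(filter_developmental_flank(hit, met_only, g2g, closure)), 0L)
  # a developmental gene hidden behind a nearer non-developmental one
  shadowed <- rbind(mk_ann("gDev", "gDev", "t1", 2000, 3000),
                    mk_ann("gMet1", "gMet1", "t1", 5000, 6000),
                    mk_ann("gMet2", "gMet2", "t1", 15000, 16000))
  expect_equal(nrow(filter_developmental_flank(hit, shadowed, g2g, closure)), 0L)
  # no annotated flank in the window: dropped and reported
  empty_ann <- mk_ann("gX", "gX", "elsewhere", 0, 1000)
  expect_message(
    out <- filter_developmental_flank(hit, empty_ann, g2g, closure),
    "without annotated flanking")
  expect_equal(nrow(out), 0L)
})

test_that("frame disruption assessment distinguishes intact from broken", {
  cds <- random_cds(60, seed = 13)
  # the exon itself is intact (discarded by the funnel)
  expect_equal(assess_frame_disruption(cds, cds)$status, "intact")
  # one codon mutated to TAA: disrupted with a single stop at that codon
  x <- cds
  substr(x, 61, 63) <- "TAA"
  ev <- assess_frame_disruption(x, cds)
  expect_equal(ev$status, "disrupted")
  fwd0 <- ev$stops[ev$stops$strand == "+" & ev$stops$frame == 0, ]
  expect_equal(fwd0$codon, 21L)
  expect_equal(fwd0$pos0, 60L)
  # a 1 bp deletion mid-sequence: no single frame spans the region
  y <- paste0(substr(cds, 1, 90), substr(cds, 92, nchar(cds)))
  expect_equal(assess_frame_disruption(y, cds)$status, "disrupted")
})

test_that("frame calls agree with a stop-scan oracle on mutated exons", {
  set.seed(77)
  for (rep in 1:20) {
    cds <- random_cds(60)
    k <- sample(0:3, 1)
    deg <- degrade_coding_sequence(cds, 0.05, 0, k)
    ev <- assess_frame_disruption(deg$sequence, cds)
    expect_equal(ev$status == "disrupted", k > 0)
    if (k > 0) {
      fwd0 <- ev$stops[ev$stops$strand == "+" & ev$stops$frame == 0, ]
      expect_equal(nrow(fwd0), k)
    }
  }
})

test_that("the funnel recovers planted RRs and reports a consistent funnel", {
  b <- fixture_bundle(seed = 42)
  res <- fixture_funnel(seed = 42)
  expect_equal(nrow(res$candidates), 3L)
  m <- match_candidates_to_truth(res$candidates, b$truth)
  expect_true(all(m$recovered[m$kind == "planted_rr"]))
  expect_true(all(res$candidates$n_stops >= 1 | res$candidates$frameshift))
  # flanking left gene is the developmental one by construction
  expect_true(all(grepl("_fL_t2$", res$candidates$flank_left)))
  # empty hit set: zero candidates, zero-count report
  res0 <- run_funnel(b, hits = empty_hits())
  expect_equal(nrow(res0$candidates), 0L)
  st0 <- res0$report$stages
  expect_true(all(st0$n_out[st0$stage != "load_exons" & st0$stage != "map"] == 0))
})

test_that("each decoy is rejected at its designated stage and only there", {
  b <- fixture_bundle(seed = 43, decoys = ALL_DECOYS)
  res <- run_funnel(b)
  m <- match_candidates_to_truth(res$candidates, b$truth)
  expect_true(all(m$recovered[m$kind == "planted_rr"]))
  expect_false(any(m$recovered[m$kind == "decoy"]))
  for (i in which(b$truth$kind == "decoy")) {
    cls <- b$truth$violated_filter[i]
    expect_identical(rejection_stage(res$report, b$truth[i, ]),
                     unname(DECOY_STAGE[cls]), label = cls)
  }
  # disabling the violated filter admits exactly that decoy
  for (cls in c("synteny", "go", "frame")) {
    res_off <- run_funnel(b, funnel_config(disabled = DECOY_STAGE[[cls]]))
    m_off <- match_candidates_to_truth(res_off$candidates, b$truth)
    dec <- m_off[m_off$kind == "decoy", ]
    expect_true(dec$recovered[dec$violated_filter == cls], label = cls)
    expect_false(any(dec$recovered[dec$violated_filter != cls]), label = cls)
  }
})

test_that("funnel stage counts are monotone and ids chain stage to stage", {
  res <- fixture_funnel(seed = 43, decoys = ALL_DECOYS)
  st <- res$report$stages
  funnel_rows <- which(!st$stage %in% c("load_exons", "map"))
  expect_true(all(st$n_out[funnel_rows] <= st$n_in[funnel_rows]))
  # output of stage k is the input of stage k+1
  expect_equal(st$n_in[funnel_rows][-1],
               st$n_out[funnel_rows][-length(funnel_rows)])
  ids <- res$report$kept_ids
  for (k in seq_along(ids)[-1]) {
    dropped_k <- res$report$dropped[[names(ids)[k]]]$hit_id
    expect_setequal(ids[[k]], setdiff(ids[[k - 1]], dropped_k))
  }
})

test_that("a corrupt bundle aborts with the failing stage named", {
  b <- fixture_bundle(seed = 42)
  broken <- b
  broken$reference_annotation$contig[1] <- "no_such_contig"
  expect_error(run_funnel(broken), "load_exons")
})
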