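consensus_of <- function(pwm) {
  paste(rownames(pwm$counts)[apply(pwm$counts, 2, which.max)], collapse = "")
}

anticonsensus_of <- function(pwm) {
  paste(rownames(pwm$counts)[apply(pwm$log_odds, 2, which.min)], collapse = "")
}

test_that("PWM construction validates and scores its own range", {
  single <- pwm_from_counts(matrix(c(10, 0, 0, 0), ncol = 1), "M1")
  expect_equal(which.max(single$log_odds[, 1]), c(A = 1L))
  expect_equal(single$max_score, unname(single$log_odds["A", 1]))
  flat <- pwm_from_counts(matrix(rep(5, 8), nrow = 4), "M2")
  expect_true(flat$uninformative)
  expect_error(pwm_from_counts(matrix(numeric(0), nrow = 4)), "column")
  expect_error(pwm_from_counts(matrix(c(1, 1, 1), ncol = 1)), "4 rows")
  expect_error(pwm_from_counts(matrix(c(0, 0, 0, 0), ncol = 1)), "zero-sum")
})

test_that("JASPAR PFM files round trip and flat matrices are rejected", {
  pwms <- make_pfm_set(n = 4, seed = 20)
  tmp <- withr::local_tempfile(fileext = ".pfm")
  write_jaspar_pfm(pwms, tmp)
  back <- read_jaspar_pfm(tmp)
  expect_equal(length(back), length(pwms))
  for (i in seq_along(pwms)) {
    expect_equal(unname(back[[i]]$counts), unname(pwms[[i]]$counts),
                 ignore_attr = TRUE)
    expect_equal(back[[i]]$matrix_id, pwms[[i]]$matrix_id)
  }
  writeLines(c(">FLAT flat", "A [ 2 2 ]", "C [ 2 2 ]", "G [ 2 2 ]",
               "T [ 2 2 ]"), tmp)
  expect_warning(out <- read_jaspar_pfm(tmp), "uninformative")
  expect_equal(length(out), 0L)
})

test_that("consensus and anti-consensus bracket the relative score range", {
  pwms <- make_pfm_set(n = 3, seed = 21)
  for (p in pwms) {
    hit <- scan_pwm(consensus_of(p), p, rel_threshold = 0.99)
    expect_true(any(hit$rel_score >= 0.999 & hit$strand == "+"))
    # the anti-consensus scores relative 0: below any admissible threshold
    worst <- scan_pwm(anticonsensus_of(p), p, rel_threshold = 1e-9,
                      strands = "+")
    expect_equal(nrow(worst), 0L)
  }
  p <- pwms[[1]]
  expect_equal(nrow(scan_pwm("ACG", p)), 0L)     # shorter than the motif
  expect_error(scan_pwm("ACGT", p, rel_threshold = 0), "rel_threshold")
  expect_error(scan_pwm("ACGT", p, rel_threshold = 1.2), "rel_threshold")
})

test_that("scanning equals exhaustive per-position rescoring", {
  set.seed(22)
  pwms <- make_pfm_set(n = 5, seed = 23)
  for (rep in 1:10) {
    p <- pwms[[sample(length(pwms), 1)]]
    s <- random_dna(500)
    thr <- sample(c(0.7, 0.8, 0.9), 1)
    mine <- scan_pwm(s, p, rel_threshold = thr)
    oracle <- oracle_scan_pwm(s, p, rel_threshold = thr)
    expect_equal(nrow(mine), nrow(oracle))
    if (nrow(mine)) {
      expect_equal(mine$pos0, oracle$pos0)
      expect_equal(mine$strand, oracle$strand)
      expect_equal(mine$score, oracle$score, tolerance = 1e-9)
    }
  }
})

test_that("relative scores are invariant to affine log-odds rescaling", {
  p <- make_pfm_set(n = 1, seed = 24)[[1]]
  s <- random_cds(40, seed = 25)
  h1 <- scan_pwm(s, p, rel_threshold = 0.5)
  p2 <- p
  p2$log_odds <- 2 * p$log_odds + 1
  p2$min_score <- sum(apply(p2$log_odds, 2, min))
  p2$max_score <- sum(apply(p2$log_odds, 2, max))
  h2 <- scan_pwm(s, p2, rel_threshold = 0.5)
  expect_equal(h1$pos0, h2$pos0)
  expect_equal(h1$rel_score, h2$rel_score, tolerance = 1e-9)
})

test_that("Fitch reconstruction resolves hand-checkable cases", {
  # all leaves identical: ancestor identical, zero substitutions
  msa <- c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT")
  anc <- reconstruct_ancestor(msa, "((a,b),(c,d));")
  expect_equal(anc$sequence, "ACGT")
  expect_equal(anc$parsimony_score, 0L)
  # ((A,A),(C,C)): the root is ambiguous A/C = IUPAC M
  msa2 <- c(a = "A", b = "A", c = "C", d = "C")
  anc2 <- reconstruct_ancestor(msa2, "((a,b),(c,d));")
  expect_equal(anc2$sequence, "M")
  expect_equal(anc2$parsimony_score, 1L)
  expect_equal(anc2$ambiguous_columns, 1L)
  # an outgroup resolves an internal node's final state
  msa3 <- c(out = "A", x = "A", y = "A", t1 = "C", t2 = "C")
  anc3 <- reconstruct_ancestor(msa3, "(out,((x,y),(t1,t2)inner)mid);",
                               node = "mid")
  expect_equal(anc3$sequence, "A")
  # missing tip sequences are an input error listing the names
  expect_error(reconstruct_ancestor(msa2[1:3], "((a,b),(c,d));"), "d")
  expect_error(reconstruct_ancestor(msa2, "((a,b),(c,d));", node = "nope"),
               "nope")
})

test_that("parsimony scores equal exhaustive minimisation on small trees", {
  set.seed(26)
  for (rep in 1:10) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n, rooted = TRUE)
    tr$tip.label <- paste0("s", seq_len(n))
    msa <- setNames(vapply(seq_len(n), function(i) random_dna(20),
                           character(1)), tr$tip.label)
    anc <- reconstruct_ancestor(msa, tr)
    expect_equal(anc$parsimony_score, oracle_min_subs(tr, msa))
  }
})

test_that("lineage-specific site calling enforces every exclusion", {
  p <- make_pfm_set(n = 1, seed = 27)[[1]]
  cons <- consensus_of(p)
  w <- nchar(cons)
  bg <- strrep("T", 60)
  with_site <- paste0(substr(bg, 1, 20), cons,
                      substr(bg, 21 + w, 60))
  h <- function(s) scan_aligned(s, p, rel_threshold = 0.8)
  medaka <- h(with_site)
  expect_gt(nrow(medaka), 0)
  none <- h(bg)
  # present only in medaka -> reported
  out <- lineage_specific_sites(list(medaka = medaka),
                                list(shark = none, human = none), none)
  expect_equal(nrow(out), nrow(medaka))
  # present in the ancestor -> excluded
  expect_equal(nrow(lineage_specific_sites(list(medaka = medaka),
                                           list(shark = none), medaka)), 0L)
  # present in another vertebrate -> excluded
  expect_equal(nrow(lineage_specific_sites(list(medaka = medaka),
                                           list(shark = medaka), none)), 0L)
  # absent from a second teleost -> not "specific to the teleosts"
  expect_equal(nrow(lineage_specific_sites(
    list(medaka = medaka, zebrafish = none), list(shark = none), none)), 0L)
  expect_error(lineage_specific_sites(list(), list(shark = none), none),
               "teleost")
  # monotone: adding species to other_hits can only shrink the output
  out1 <- lineage_specific_sites(list(medaka = medaka), list(), none)
  out2 <- lineage_specific_sites(list(medaka = medaka),
                                 list(shark = none, mouse = medaka), none)
  expect_lte(nrow(out2), nrow(out1))
})

test_that("planted teleost motifs are recovered and nothing else is", {
  b <- fixture_bundle(seed = 42)
  tel <- c("medaka_rr", "stickleback_rr", "zebrafish_rr")
  for (g in names(b$outgroups)) {
    og <- b$outgroups[[g]]
    oth <- setdiff(names(og), c(tel, "medaka_coding"))
    anc <- reconstruct_ancestor(og, b$species_tree, node = "bony")
    found <- list()
    for (p in b$pwms) {
      th <- lapply(setNames(tel, tel), function(sp) {
        scan_aligned(og[[sp]], p, sequence_id = sp)
      })
      oh <- lapply(setNames(oth, oth), function(sp) {
        scan_aligned(og[[sp]], p, sequence_id = sp)
      })
      ah <- scan_aligned(anc$sequence, p, sequence_id = "ancestor")
      ss <- lineage_specific_sites(th, oh, ah)
      if (nrow(ss)) found[[length(found) + 1L]] <- ss
    }
    found <- do.call(rbind, found)
    planted <- b$planted_motifs[b$planted_motifs$gene_id == g, ]
    expect_equal(nrow(found), 1L, label = g)
    expect_equal(found$matrix_id, planted$pwm_id)
    expect_equal(found$pos0, planted$start0)
  }
})

test_that("S200 arithmetic and histograms are exact", {
  p <- make_pfm_set(n = 1, seed = 28)[[1]]
  cons <- consensus_of(p)
  # sequence of length 400 with a known number of planted sites
  spacer <- strrep("T", 30)
  s4 <- paste0(spacer, cons, spacer, cons, spacer, cons, spacer, cons)
  s4 <- paste0(s4, strrep("T", 400 - nchar(s4)))
  n_hits <- sum(vapply(list(p), function(pw) nrow(scan_pwm(s4, pw)), numeric(1)))
  d <- s200(c(x = s4), list(p))
  expect_equal(unname(d$values["x"]), n_hits * 200 / 400)
  expect_gte(n_hits, 4)
  # 200 bp with no sites scores 0
  d0 <- s200(c(none = strrep("T", 200)), list(p))
  expect_equal(unname(d0$values), 0)
  expect_equal(sum(d0$counts), 1L)      # histogram sums to sequence count
  expect_warning(s200(c(a = "ACGTACGTACGT", b = ""), list(p)), "zero-length")
})

test_that("regulatory potential is an overlap coefficient", {
  p <- make_pfm_set(n = 2, seed = 29)[[1]]
  set.seed(30)
  seqs <- setNames(vapply(1:6, function(i) random_dna(300), character(1)),
                   paste0("s", 1:6))
  d <- s200(seqs, list(p))
  expect_equal(regulatory_potential(d, d), 100)
  # disjoint supports overlap 0%
  a <- structure(list(label = "a", values = c(0.1, 0.2), breaks = c(0, 1, 2, 3),
                      counts = c(2L, 0L, 0L), bin_width = 1),
                 class = "s200_distribution")
  b <- structure(list(label = "b", values = c(2.1, 2.2), breaks = c(0, 1, 2, 3),
                      counts = c(0L, 0L, 2L), bin_width = 1),
                 class = "s200_distribution")
  expect_equal(regulatory_potential(a, b), 0)
  # hand-built three-bin example: p = (.5, .5, 0) vs q = (0, .5, .5) -> 50%
  q1 <- structure(list(label = "q1", values = c(0.5, 1.5), breaks = c(0, 1, 2, 3),
                       counts = c(1L, 1L, 0L), bin_width = 1),
                  class = "s200_distribution")
  q2 <- structure(list(label = "q2", values = c(1.5, 2.5), breaks = c(0, 1, 2, 3),
                       counts = c(0L, 1L, 1L), bin_width = 1),
                  class = "s200_distribution")
  expect_equal(regulatory_potential(q1, q2), 50)
  # symmetry and bounds on random distributions with matching breaks
  set.seed(31)
  for (rep in 1:10) {
    va <- runif(20, 0, 5)
    vb <- runif(20, 0, 5)
    breaks <- seq(0, 6, 1)
    mk <- function(v, lab) structure(list(
      label = lab, values = v, breaks = breaks,
      counts = tabulate(findInterval(v, breaks), nbins = 6), bin_width = 1),
      class = "s200_distribution")
    ra <- regulatory_potential(mk(va, "a"), mk(vb, "b"))
    rb <- regulatory_potential(mk(vb, "b"), mk(va, "a"))
    expect_equal(ra, rb)
    expect_gte(ra, 0)
    expect_lte(ra, 100)
  }
  # mismatched bin edges are rebinned with a warning
  wide <- structure(list(label = "w", values = c(0.5, 1.5),
                         breaks = c(0, 2, 4), counts = c(2L, 0L),
                         bin_width = 2), class = "s200_distribution")
  expect_warning(rp <- regulatory_potential(q1, wide), "rebin")
  expect_gte(rp, 0)
})
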