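test_that("frame stop scanning reports codon positions", {
  expect_equal(scan_frame_stops("ATGTAAATG", 0, "+")$codon, 2L)
  expect_equal(scan_frame_stops("ATGTAAATG", 0, "+")$pos0, 3L)
  # a sequence with no stop codon in any forward frame
  expect_equal(nrow(scan_frame_stops("ATGCATCAC", 0, "+")), 0L)
  expect_equal(nrow(scan_frame_stops("ATGCATCAC", 1, "+")), 0L)
  expect_equal(nrow(scan_frame_stops("ATGCATCAC", 2, "+")), 0L)
  # reverse strand: CAT|CAT -> revcomp ATG ATG, no stops; TTA revcomps to TAA
  expect_equal(scan_frame_stops("TTACAT", 0, "-")$codon, 2L)
})

test_that("global alignment is exact, affine and deterministic", {
  s <- "ACGTACGTACGT"
  a <- global_align(s, s)
  expect_equal(a$score, 5 * nchar(s))
  expect_false(grepl("-", a$a, fixed = TRUE))
  expect_false(grepl("-", a$b, fixed = TRUE))
  # hand DP: three matches and one mismatch
  expect_equal(global_align("ACGT", "ACGA")$score, 5 * 3 - 4)
  # a single 1 bp gap costs open + ext
  expect_equal(global_align("ACGT", "ACG")$score, 5 * 3 - (12 + 3))
  expect_error(global_align("ACGT", ""), "non-empty")
  # determinism: identical alignment strings across calls
  x <- random_cds(30, seed = 8)
  y <- evolve_sequence(x, "neutral", 12, seed = 9)
  a1 <- global_align(x, y)
  a2 <- global_align(x, y)
  expect_identical(a1$a, a2$a)
  expect_identical(a1$b, a2$b)
})

test_that("identity profile separates nucleotide and amino-acid signals", {
  x <- random_cds(40, seed = 10)
  ip0 <- identity_profile(global_align(x, x))
  expect_equal(ip0$nt_identity_pct, 100)
  expect_equal(ip0$aa_similarity_pct, 100)
  # synonymous-only evolution: protein intact, nucleotides diverged
  syn <- evolve_sequence(x, "protein_constrained", 15, seed = 11)
  ip1 <- identity_profile(global_align(x, syn))
  expect_equal(ip1$aa_similarity_pct, 100)
  expect_lt(ip1$nt_identity_pct, 100)
  # RR-like: unconstrained at the protein level -> NT identity > AA similarity
  rr <- evolve_sequence(x, "nucleotide_constrained", 40, seed = 12,
                        anchor_positions = 1:12)
  ip2 <- identity_profile(global_align(x, rr))
  expect_gt(ip2$nt_identity_pct, ip2$aa_similarity_pct)
  # bounds hold on arbitrary alignments
  for (sd in 1:10) {
    y <- evolve_sequence(x, "neutral", 30, seed = sd)
    ip <- identity_profile(global_align(x, y))
    expect_gte(ip$nt_identity_pct, 0)
    expect_lte(ip$nt_identity_pct, 100)
    expect_gte(ip$aa_similarity_pct, 0)
    expect_lte(ip$aa_similarity_pct, 100)
  }
})

test_that("indel and stop stripping is codon consistent", {
  x <- random_cds(30, seed = 14)
  aln <- global_align(x, x)
  st <- strip_indels_and_stops(aln)
  expect_identical(st$reference, x)                # gap- and stop-free input
  expect_identical(st$query, x)
  expect_equal(unname(st$removed), c(0L, 0L))
  # one clean 3 bp deletion removes exactly one codon
  y <- paste0(substr(x, 1, 30), substr(x, 34, nchar(x)))
  st2 <- strip_indels_and_stops(global_align(x, y))
  expect_equal(st2$removed[["indel_codons"]], 1L)
  expect_equal(nchar(st2$reference), nchar(x) - 3L)
  # a stop codon in the query drops that codon pair
  z <- x
  substr(z, 31, 33) <- "TGA"
  st3 <- strip_indels_and_stops(global_align(x, z))
  expect_equal(st3$removed[["stop_codons"]], 1L)
  expect_false(any(strsplit(st3$query, "")[[1]] == "-"))
  # refusing to work on nearly nothing
  expect_error(strip_indels_and_stops(global_align("ATGAAA", "ATG")),
               "fewer than 3 codons")
})

test_that("RR relics lose exactly their planted stops in stripping", {
  b <- fixture_bundle(seed = 42)
  for (g in names(b$outgroups)) {
    og <- b$outgroups[[g]]
    aln <- global_align(og[["human"]], og[["medaka_rr"]])
    st <- strip_indels_and_stops(aln)
    planted <- b$truth$n_planted_stops[b$truth$source_exon_id == paste0(g, "_e1")]
    expect_equal(st$removed[["stop_codons"]], planted)
  }
})

test_that("Ka/Ks sentinels and forced sign patterns are right", {
  x <- random_cds(20, seed = 15)
  k0 <- compute_kaks(x, x)
  expect_equal(k0$ka, 0)
  expect_equal(k0$ks, 0)
  expect_equal(k0$ratio_class, "undefined_no_sites")
  # synonymous-only changes (at adequate length): Ka = 0, Ks > 0, ratio 0
  k1 <- compute_kaks(x, evolve_sequence(x, "protein_constrained", 2, seed = 20))
  expect_equal(k1$ka, 0)
  expect_gt(k1$ks, 0)
  expect_equal(k1$ratio, 0)
  # very short sequences saturate the Jukes-Cantor correction instead
  expect_equal(compute_kaks("ATGAAACCC", "ATGAAGCCC")$ratio_class, "saturated")
  # a single nonsynonymous difference and no synonymous one: Ks = 0 sentinel
  x2 <- paste0("ATG", "AAA", strrep("CCC", 8))
  z2 <- paste0("ATG", "GAA", strrep("CCC", 8))
  k2 <- compute_kaks(x2, z2)
  expect_gt(k2$ka, 0)
  expect_equal(k2$ratio_class, "infinite_ks_zero")
  expect_error(compute_kaks("ATG-AA", "ATGAAA"), "gap")
  expect_error(compute_kaks("ATGTAA", "ATGAAA"), "stop")
  expect_error(compute_kaks("ATGAAA", "ATGAAAA"), "equal length")
})

test_that("Ka/Ks is symmetric and matches the enumeration oracle", {
  set.seed(16)
  for (rep in 1:20) {
    a <- random_cds(30)
    b <- evolve_sequence(a, "neutral", sample(5:25, 1))
    pair <- strip_indels_and_stops(global_align(a, b))
    k <- compute_kaks(pair)
    swapped <- compute_kaks(pair$query, pair$reference)
    expect_equal(k$ka, swapped$ka, tolerance = 1e-12)
    expect_equal(k$ks, swapped$ks, tolerance = 1e-12)
    o <- oracle_kaks(pair$reference, pair$query)
    expect_equal(k$syn_subs, o$syn_subs, tolerance = 1e-9)
    expect_equal(k$nonsyn_subs, o$nonsyn_subs, tolerance = 1e-9)
    expect_equal(k$syn_sites, o$syn_sites, tolerance = 1e-9)
    if (!is.na(o$ka)) expect_equal(k$ka, o$ka, tolerance = 1e-9)
    if (!is.na(o$ks)) expect_equal(k$ks, o$ks, tolerance = 1e-9)
  }
})

test_that("Ka/Ks recovers the simulated selective regime", {
  n <- 200L
  constrained_low <- 0L
  neutral_band <- 0L
  for (i in seq_len(n)) {
    cds <- random_cds(60, seed = 90000L + i)
    prot <- evolve_sequence(cds, "protein_constrained", 40, seed = 91000L + i)
    neut <- evolve_sequence(cds, "neutral", 40, seed = 92000L + i)
    kp <- compute_kaks(cds, prot)
    kn <- compute_kaks(strip_indels_and_stops(global_align(cds, neut)))
    if (kp$ratio_class == "defined" && kp$ratio < 0.5) {
      constrained_low <- constrained_low + 1L
    }
    if (kn$ratio_class == "defined" && kn$ratio >= 0.5 && kn$ratio <= 2) {
      neutral_band <- neutral_band + 1L
    }
  }
  expect_gte(constrained_low / n, 0.9)
  expect_gte(neutral_band / n, 0.9)
})

test_that("Ka/Ks contrast identifies the coding signature", {
  x <- random_cds(40, seed = 17)
  rr_seq <- evolve_sequence(x, "nucleotide_constrained", 20, seed = 18)
  rr <- compute_kaks(strip_indels_and_stops(global_align(x, rr_seq)))
  cod <- compute_kaks(x, evolve_sequence(x, "protein_constrained", 20,
                                         seed = 19))
  cmp <- contrast_kaks(rr, cod)
  expect_equal(cmp$coding_signature, "coding")
  expect_gt(cmp$difference, 0)
  same <- contrast_kaks(rr, rr)
  expect_equal(same$difference, 0)
  und <- compute_kaks(x, x)
  expect_true(contrast_kaks(rr, und)$indeterminate)
})
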