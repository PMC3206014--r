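# Independent brute-force oracles.  These deliberately re-derive results by
# exhaustive enumeration or naive dynamic programming, sharing no code path
# with the package implementations they check.

ORACLE_STOPS <- c("TAA", "TAG", "TGA")
ORACLE_BASES <- c("A", "C", "G", "T")

oracle_aa <- function(chars) {
  a <- Biostrings::GENETIC_CODE[paste(chars, collapse = "")]
  if (is.na(a)) "X" else unname(a)
}

# Synonymous site count of a codon: enumerate all nine single-base changes.
oracle_syn_sites <- function(cod) {
  x <- strsplit(cod, "")[[1]]
  ref_aa <- oracle_aa(x)
  syn <- 0
  for (p in 1:3) {
    for (b in ORACLE_BASES) {
      if (b == x[p]) next
      y <- x
      y[p] <- b
      if (paste(y, collapse = "") %in% ORACLE_STOPS) next
      if (oracle_aa(y) == ref_aa) syn <- syn + 1 / 3
    }
  }
  syn
}

# Average pathway counts between two codons by recursive enumeration of all
# substitution orderings; pathways through stop codons excluded when any
# stop-free pathway exists.
oracle_codon_counts <- function(c1, c2) {
  x1 <- strsplit(c1, "")[[1]]
  x2 <- strsplit(c2, "")[[1]]
  d <- which(x1 != x2)
  if (!length(d)) return(c(syn = 0, nonsyn = 0))
  res <- list()
  rec <- function(cur, left, sy, ns, via_stop) {
    if (!length(left)) {
      res[[length(res) + 1L]] <<- list(sy = sy, ns = ns, via = via_stop)
      return(invisible(NULL))
    }
    for (p in left) {
      nxt <- cur
      nxt[p] <- x2[p]
      cod_a <- paste(cur, collapse = "")
      cod_b <- paste(nxt, collapse = "")
      step_syn <- !(cod_a %in% ORACLE_STOPS) && !(cod_b %in% ORACLE_STOPS) &&
        oracle_aa(cur) == oracle_aa(nxt)
      rec(nxt, setdiff(left, p), sy + as.numeric(step_syn),
          ns + as.numeric(!step_syn),
          via_stop || (cod_b %in% ORACLE_STOPS && !identical(nxt, x2)))
    }
  }
  rec(x1, d, 0, 0, FALSE)
  ok <- Filter(function(r) !r$via, res)
  if (!length(ok)) ok <- res
  c(syn = mean(vapply(ok, `[[`, numeric(1), "sy")),
    nonsyn = mean(vapply(ok, `[[`, numeric(1), "ns")))
}

# Full Ka/Ks from the oracle counts (NG86 sites averaged over sequences,
# Jukes-Cantor correction).
oracle_kaks <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  S <- (sum(vapply(ca, oracle_syn_sites, numeric(1))) +
          sum(vapply(cb, oracle_syn_sites, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  cnt <- vapply(seq_along(ca), function(i) oracle_codon_counts(ca[i], cb[i]),
                numeric(2))
  Sd <- sum(cnt["syn", ])
  Nd <- sum(cnt["nonsyn", ])
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(ka = jc(if (N > 0) Nd / N else 0), ks = jc(if (S > 0) Sd / S else 0),
       syn_sites = S, nonsyn_sites = N, syn_subs = Sd, nonsyn_subs = Nd)
}

# Naive per-position PWM rescoring on both strands.
oracle_scan_pwm <- function(seq, pwm, rel_threshold) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  w <- ncol(pwm$log_odds)
  n <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    if (n < w) next
    for (i in seq_len(n - w + 1L)) {
      raw <- 0
      for (j in seq_len(w)) {
        raw <- raw + pwm$log_odds[substr(s, i + j - 1L, i + j - 1L), j]
      }
      rel <- (raw - pwm$min_score) / (pwm$max_score - pwm$min_score)
      if (rel >= rel_threshold) {
        out[[length(out) + 1L]] <- data.frame(
          pos0 = if (strand == "+") i - 1L else n - (i - 1L) - w,
          strand = strand, score = raw, rel_score = rel,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(pos0 = integer(0), strand = character(0),
                      score = numeric(0), rel_score = numeric(0)))
  }
  out <- do.call(rbind, out)
  out[order(out$pos0, out$strand), , drop = FALSE]
}

# Smith-Waterman local alignment score with affine gaps, Biostrings cost
# convention (a gap of length L costs open + ext * L).
oracle_local_score <- function(a, b, match = 5, mismatch = -4,
                               open = 12, ext = 3) {
  xa <- strsplit(a, "")[[1]]
  xb <- strsplit(b, "")[[1]]
  n <- length(xa)
  m <- length(xb)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (xa[i - 1] == xb[j - 1]) match else mismatch
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                                Iy[i - 1, j - 1]))
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Minimum substitution count over all internal labelings of a rooted tree
# (exhaustive; trees up to 6 leaves).
oracle_min_subs <- function(tr, msa) {
  n_tip <- length(tr$tip.label)
  n_int <- tr$Nnode
  G <- as.matrix(expand.grid(rep(list(1:4), n_int)))
  edges <- tr$edge
  int_e <- edges[edges[, 2] > n_tip, , drop = FALSE]
  leaf_e <- edges[edges[, 2] <= n_tip, , drop = FALSE]
  Mint <- if (nrow(int_e)) {
    rowSums(matrix(G[, int_e[, 1] - n_tip] != G[, int_e[, 2] - n_tip],
                   nrow = nrow(G)))
  } else rep(0, nrow(G))
  L <- nchar(msa[[1]])
  S <- vapply(tr$tip.label, function(tp) {
    match(strsplit(msa[[tp]], "")[[1]], ORACLE_BASES)
  }, integer(L))
  total <- matrix(Mint, nrow = nrow(G), ncol = L)
  for (e in seq_len(nrow(leaf_e))) {
    p <- leaf_e[e, 1] - n_tip
    st <- S[, leaf_e[e, 2]]
    total <- total + outer(G[, p], st, "!=")
  }
  sum(apply(total, 2, min))
}
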