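# Independent oracles used by property-style and acceptance tests.

# Brute-force digestion oracle: tests every inter-residue bond
# independently against the stated selectivity rules, then assembles
# products for 0..max_missed missed cleavages.
oracle_digest <- function(seq, enzyme, max_missed = 0L) {
  n <- length(seq$residues)
  parents <- parent_bases(seq)
  modded <- is_modified(seq)
  cut <- logical(max(n - 1L, 0L))
  for (i in seq_len(n - 1L)) {
    ok <- parents[i] %in% enzyme$cleave_after
    if (ok && enzyme$blocked_by_modification && modded[i]) ok <- FALSE
    if (ok && enzyme$no_cleavage_between_identical &&
        parents[i + 1L] == parents[i]) ok <- FALSE
    cut[i] <- ok
  }
  sites <- which(cut)
  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  out <- list()
  for (i in seq_along(starts)) {
    for (k in 0:min(max_missed, length(starts) - i)) {
      j <- i + k
      five <- if (starts[i] == 1L) seq$five else "OH"
      three <- if (ends[j] == n) seq$three else enzyme$product_three
      out[[length(out) + 1L]] <- data.frame(
        start = starts[i], end = ends[j], missed = k,
        product = format_sequence(
          subseq_mod(seq, starts[i], ends[j], five = five, three = three)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$missed, res$start), , drop = FALSE]
}

# Hypergeometric-enumeration oracle for the two-sided Fisher p-value of a
# 2x2 table (a b / c d), conditioning on all margins. Probabilities are
# accumulated from log-binomials; tables as or less probable than the
# observed one are summed with the conventional 1e-7 relative slack.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  xs <- max(0L, c1 - r2):min(c1, r1)
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(N, c1)
  p <- exp(logp)
  pobs <- p[xs == a]
  sum(p[p <= pobs * (1 + 1e-7)])
}

# Two-row stand-in for a codon_usage table carrying only the family counts
# enrichment_test consumes.
fam_table <- function(tyr, ala) {
  data.frame(aa = c("Tyr", "Ala"), count = c(tyr, ala),
             stringsAsFactors = FALSE)
}
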