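#' The standard genetic code grouped into synonymous families
#'
#' @return Data.frame with columns `codon` (DNA alphabet), `aa`
#'   (three-letter code plus `Stp`), `family_size`.
#' @export
codon_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  aa1 <- unname(gc)
  map <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
           Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
           L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
           S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
           `*` = "Stp")
  aa <- unname(map[aa1])
  df <- data.frame(codon = names(gc), aa = aa, stringsAsFactors = FALSE)
  fam <- table(df$aa)
  df$family_size <- as.integer(fam[df$aa])
  df
}

#' Count in-frame codons over a set of coding sequences
#'
#' Counts triplets from position 1 of each CDS using the standard genetic
#' code; T and U are interchangeable (RNA or DNA FASTA dialects). A
#' trailing partial codon is truncated with a warning; codons containing
#' characters outside ACGTU are skipped and tallied.
#'
#' @param cds Character vector (or named vector / `DNAStringSet`) of CDS.
#' @param label Source-set label stored on the table.
#' @return A `codon_usage` data.frame with columns `codon`, `aa`,
#'   `family_size`, `count`, `frequency`; attributes `label` and
#'   `n_skipped` (codons skipped for ambiguity).
#' @export
count_codons <- function(cds, label = "set") {
  cds <- toupper(chartr("Uu", "Tt", as.character(cds)))
  fam <- codon_families()
  counts <- stats::setNames(integer(64), fam$codon)
  skipped <- 0L
  for (s in cds) {
    n <- nchar(s)
    if (n %% 3L != 0L) {
      warning("CDS length not divisible by 3; trailing partial codon dropped")
      n <- n - (n %% 3L)
    }
    if (n < 3L) next
    codons <- substring(s, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
    ok <- codons %in% fam$codon
    skipped <- skipped + sum(!ok)
    tab <- table(codons[ok])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  out <- fam
  out$count <- unname(counts[out$codon])
  total <- sum(out$count)
  out$frequency <- if (total > 0) out$count / total else 0
  attr(out, "label") <- label
  attr(out, "n_skipped") <- skipped
  class(out) <- c("codon_usage", "data.frame")
  out
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its count divided by the mean count of its
#' synonymous family, so the family mean RSCU is 1 whenever the family was
#' observed at all. Stop codons are counted but excluded from RSCU
#' families; single-codon families (Met, Trp) have RSCU 1 whenever
#' observed. Families with zero total get `NA` (flagged undefined), and an
#' RSCU above 1.5 marks a preferred codon, below 0.5 an unpreferred one.
#'
#' @param table Output of [count_codons()].
#' @return The table with added `rscu` and `preference`
#'   (`"preferred"` / `"unpreferred"` / `"neutral"`) columns; stop codons
#'   keep `NA`.
#' @export
rscu <- function(table) {
  stopifnot(inherits(table, "codon_usage") || is.data.frame(table))
  out <- table
  out$rscu <- NA_real_
  for (a in unique(out$aa)) {
    if (a == "Stp") next
    idx <- out$aa == a
    fam_total <- sum(out$count[idx])
    if (fam_total == 0L) next  # undefined, left NA
    out$rscu[idx] <- out$count[idx] / mean(out$count[idx])
  }
  out$preference <- ifelse(is.na(out$rscu), NA_character_,
                    ifelse(out$rscu > 1.5, "preferred",
                    ifelse(out$rscu < 0.5, "unpreferred", "neutral")))
  out
}

#' Codon-family enrichment test between two transcript sets
#'
#' Fisher's exact test on the 2x2 table of target-family versus
#' reference-family codon counts in set A against set B — e.g. tyrosine
#' codons against alanine codons in vitellogenin-class transcripts versus
#' ribosomal-protein transcripts. Raw codon counts are used (the only
#' input for which the exact test is valid).
#'
#' @param tableA,tableB Outputs of [count_codons()].
#' @param target_aa Target amino-acid family (default `"Tyr"`).
#' @param reference_aa Reference family (default `"Ala"`).
#' @return List with the 2x2 `table`, `odds_ratio` (conditional MLE, from
#'   [stats::fisher.test]), `p_value` (two-sided) and the family counts.
#' @export
enrichment_test <- function(tableA, tableB, target_aa = "Tyr",
                            reference_aa = "Ala") {
  fam_count <- function(tab, a) sum(tab$count[tab$aa == a])
  m <- matrix(c(fam_count(tableA, target_aa),
                fam_count(tableA, reference_aa),
                fam_count(tableB, target_aa),
                fam_count(tableB, reference_aa)),
              nrow = 2, byrow = FALSE,
              dimnames = list(c(target_aa, reference_aa), c("A", "B")))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero marginal in the 2x2 enrichment table")
  }
  ft <- stats::fisher.test(m, alternative = "two.sided")
  list(table = m, odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}
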