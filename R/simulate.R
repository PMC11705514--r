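#' Seeded generators for synthetic workflow inputs
#'
#' Each generator takes an integer `seed` and is byte-reproducible under
#' a fixed seed; each emits a machine-readable truth table alongside its
#' data so downstream stages can be tested by parameter recovery.
#'
#' @name simulators
NULL

.isotype_pool <- function() {
  data.frame(
    isotype = c("Ala", "Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu",
                "Gly", "His", "Ile", "Ile", "Leu", "Leu", "Lys", "Met",
                "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val"),
    anticodon = c("AGC", "TGC", "ACG", "GTT", "GTC", "GCA", "TTG", "TTC",
                  "GCC", "GTG", "AAT", "TAT", "CAA", "TAG", "TTT", "CAT",
                  "GAA", "TGG", "AGA", "CGT", "CCA", "GTA", "TAC"),
    stringsAsFactors = FALSE
  )
}

# Isoacceptors that carry an intron in this genome
.INTRON_ISOTYPES <- c("Tyr-GTA", "Ile-TAT", "Leu-CAA")

#' Generate a synthetic tRNA gene set with introns and planted duplicates
#'
#' Gene bodies are random ~72-nt sequences; genes of the three
#' intron-bearing isoacceptors (Tyr-GTA, Ile-TAT, Leu-CAA) receive a
#' 10-20 nt intron after position 37. Exact duplicates are planted by
#' copying previously generated genes under new ids. The defaults (200
#' genes, 42 planted duplicates) match the scale of a high-confidence
#' mosquito tRNA gene set collapsing to ~158 unique precursors.
#'
#' @param n_genes Total genes to emit (including duplicates).
#' @param n_duplicates How many of them are exact copies of earlier genes.
#' @param body_length Intronless gene-body length (nt).
#' @param seed Integer seed.
#' @return List with `genes` (data.frame `gene_id`, `isotype`,
#'   `anticodon`, `sequence`, `intron_start`, `intron_end`) and `truth`
#'   (adds `duplicate_of`, NA for originals).
#' @export
sim_trna_genes <- function(n_genes = 200L, n_duplicates = 42L,
                           body_length = 72L, seed = 1L) {
  stopifnot(n_duplicates < n_genes)
  set.seed(seed)
  pool <- .isotype_pool()
  n_orig <- n_genes - n_duplicates
  pick <- pool[sample.int(nrow(pool), n_orig, replace = TRUE), ]
  genes <- vector("list", n_genes)
  copy_counter <- new.env(parent = emptyenv())
  for (i in seq_len(n_orig)) {
    iso <- pick$isotype[i]; ac <- pick$anticodon[i]
    key <- paste(iso, ac, sep = "-")
    has_intron <- key %in% .INTRON_ISOTYPES
    ilen <- if (has_intron) sample(10:20, 1L) else 0L
    total <- body_length + ilen
    seqchars <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
    sequence <- paste(seqchars, collapse = "")
    istart <- if (has_intron) 38L else NA_integer_
    iend <- if (has_intron) 37L + ilen else NA_integer_
    n <- if (is.null(copy_counter[[key]])) 1L else copy_counter[[key]] + 1L
    copy_counter[[key]] <- n
    genes[[i]] <- data.frame(
      gene_id = sprintf("%s-%s-%d-1", iso, ac, n),
      isotype = iso, anticodon = ac, sequence = sequence,
      intron_start = istart, intron_end = iend,
      duplicate_of = NA_character_, stringsAsFactors = FALSE
    )
  }
  if (n_duplicates > 0L) {
    src <- sample.int(n_orig, n_duplicates, replace = TRUE)
    for (k in seq_len(n_duplicates)) {
      orig <- genes[[src[k]]]
      dup <- orig
      dup$gene_id <- sprintf("%s-%s-%s-copy%d", orig$isotype, orig$anticodon,
                             sub("^.*-(\\d+)-1$", "\\1", orig$gene_id), k)
      dup$duplicate_of <- orig$gene_id
      genes[[n_orig + k]] <- dup
    }
  }
  truth <- do.call(rbind, genes)
  rownames(truth) <- NULL
  list(genes = truth[, setdiff(names(truth), "duplicate_of")], truth = truth)
}

#' Generate a synthetic c/y fragment spectrum for a digestion product
#'
#' Emits the product's c- and y-series ions at the requested negative
#' charge states, optionally jittered in m/z, plus uniform decoy peaks
#' over the acquisition scan range (m/z 600-2000 by default, the oligo
#' full-scan window).
#'
#' @param product A [mod_sequence()] or bracket string; `NULL` gives an
#'   empty peak list.
#' @param charges Fragment charge states (default 1:2).
#' @param jitter_sd Gaussian m/z jitter standard deviation (Da).
#' @param decoy_ratio Decoy:true peak count ratio (0 = none).
#' @param scan_range Decoy m/z range.
#' @param seed Integer seed.
#' @return A [peak_list()]; attribute `"truth"` records the true ion
#'   table and decoy count.
#' @export
sim_spectrum <- function(product, charges = 1:2, jitter_sd = 0,
                         decoy_ratio = 0, scan_range = c(600, 2000),
                         seed = 1L) {
  set.seed(seed)
  if (is.null(product) || length(charges) == 0L) {
    return(peak_list(source = "sim:empty"))
  }
  if (is.character(product)) product <- parse_sequence(product)
  ions <- fragment_series(product, series = "both",
                          max_charge = max(charges), polarity = "negative")
  ions <- ions[ions$charge %in% charges, , drop = FALSE]
  mzv <- ions$mz + if (jitter_sd > 0) stats::rnorm(nrow(ions), 0, jitter_sd)
                   else 0
  n_decoy <- round(decoy_ratio * nrow(ions))
  decoys <- if (n_decoy > 0) stats::runif(n_decoy, scan_range[1], scan_range[2])
            else numeric(0)
  pl <- peak_list(
    c(mzv, decoys),
    intensity = c(stats::runif(nrow(ions), 0.5, 1),
                  stats::runif(n_decoy, 0, 0.5)),
    precursor_mz = mz(neutral_mass(product), 3L),
    precursor_charge = 3L,
    source = paste0("sim:", format_sequence(product))
  )
  attr(pl, "truth") <- list(ions = ions, n_decoy = n_decoy)
  pl
}

# default per-time-point truth fold changes: steady through 24H, reduced at
# 48/72H, the pattern shown by the queuosine-family wobble modifications
.default_mod_truth <- function() {
  times <- c("NBF", "6H", "12H", "24H", "48H", "72H")
  fc_flat <- stats::setNames(rep(1, 6), times)
  list(
    manQ = list(abundance = 0.010,
                fc = stats::setNames(c(1, 1, 1, 1, 0.5, 0.5), times)),
    Q    = list(abundance = 0.015,
                fc = stats::setNames(c(1, 1, 1, 1, 0.5, 0.5), times)),
    m1G  = list(abundance = 0.020,
                fc = stats::setNames(c(1, 1.5, 2, 2, 1.5, 1), times)),
    t6A  = list(abundance = 0.012, fc = fc_flat * c(1, 2, 2, 2, 2, 2)),
    m5C  = list(abundance = 0.030, fc = fc_flat)
  )
}

#' Generate a synthetic nucleoside peak-area table with known truth
#'
#' Canonical nucleoside areas are lognormal around fixed means; each
#' modification's area is its truth normalized abundance times the
#' sample's canonical-area sum times the time point's truth fold change,
#' under mean-preserving lognormal noise of the given coefficient of
#' variation. Three replicates per time point by default, matching the
#' study's replicate structure.
#'
#' @param mods Named list of `list(abundance=, fc=named vector by time)`
#'   truths; default emulates the wobble-modification time course.
#' @param times Time-point labels.
#' @param n_rep Replicates per time point.
#' @param cv Lognormal coefficient of variation (default 0.10).
#' @param tissue Tissue label.
#' @param seed Integer seed.
#' @return List with `table` (long-format sample/time/tissue/nucleoside/
#'   area data.frame) and `truth` (the mods list plus canonical means).
#' @export
sim_peak_areas <- function(mods = .default_mod_truth(),
                           times = c("NBF", "6H", "12H", "24H", "48H", "72H"),
                           n_rep = 3L, cv = 0.10, tissue = "whole body",
                           seed = 1L) {
  set.seed(seed)
  canon_means <- c(A = 5.0e6, G = 4.5e6, C = 4.0e6, U = 3.5e6)
  sigma <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  noise <- function(n) {
    if (sigma == 0) rep(1, n)
    else stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
  }
  rows <- list()
  for (t in times) {
    for (r in seq_len(n_rep)) {
      sample_id <- sprintf("%s_r%d", t, r)
      areas <- canon_means * noise(4L)
      csum <- sum(areas)
      for (nuc in names(areas)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sample_id, time = t, tissue = tissue, nucleoside = nuc,
          area = unname(areas[nuc]), stringsAsFactors = FALSE)
      }
      for (m in names(mods)) {
        fc_t <- mods[[m]]$fc[[t]]
        area <- mods[[m]]$abundance * fc_t * csum * noise(1L)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sample_id, time = t, tissue = tissue, nucleoside = m,
          area = area, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, truth = list(mods = mods, canonical_means = canon_means,
                                 cv = cv, times = times, n_rep = n_rep))
}

#' Generate codon-biased CDS sets (target-like vs reference-like)
#'
#' Codons are drawn i.i.d. from a distribution over the 61 sense codons;
#' the target set multiplies the probability of the tyrosine codons
#' (TAT/TAC) by `tyr_factor` before renormalizing, emulating the doubled
#' tyrosine codon frequency of vitellogenin-class transcripts relative to
#' a ribosomal-protein reference.
#'
#' @param n_target,n_reference Number of CDS per set.
#' @param codons_per_cds Codons per CDS (sequences get a leading ATG and
#'   no stop, so length is exactly `3 * codons_per_cds`).
#' @param tyr_factor Multiplier on tyrosine codon probability in the
#'   target set.
#' @param seed Integer seed.
#' @return List with `target` and `reference` (named character vectors of
#'   CDS) and `truth` (expected tyrosine codon fractions per set).
#' @export
sim_cds_set <- function(n_target = 20L, n_reference = 20L,
                        codons_per_cds = 300L, tyr_factor = 2,
                        seed = 1L) {
  set.seed(seed)
  fam <- codon_families()
  sense <- fam$codon[fam$aa != "Stp"]
  base_p <- stats::setNames(rep(1 / length(sense), length(sense)), sense)
  # mild codon bias so the sets are not perfectly uniform
  base_p["TAC"] <- base_p["TAC"] * 1.5
  base_p <- base_p / sum(base_p)
  tyr <- c("TAT", "TAC")
  target_p <- base_p
  target_p[tyr] <- target_p[tyr] * tyr_factor
  target_p <- target_p / sum(target_p)
  gen_set <- function(n, p, prefix) {
    if (n == 0L) return(stats::setNames(character(0), character(0)))
    out <- vapply(seq_len(n), function(i) {
      paste(sample(names(p), codons_per_cds, replace = TRUE, prob = p),
            collapse = "")
    }, "")
    stats::setNames(out, sprintf("%s_%03d", prefix, seq_len(n)))
  }
  list(
    target = gen_set(n_target, target_p, "vg_like"),
    reference = gen_set(n_reference, base_p, "rp_like"),
    truth = list(tyr_freq_target = sum(target_p[tyr]),
                 tyr_freq_reference = sum(base_p[tyr]),
                 tyr_factor = tyr_factor)
  )
}

#' Generate a random modified RNA sequence
#'
#' Draws canonical residues uniformly and replaces each with a random
#' registry modification of the same parent base with the given
#' probability. Used for property-style testing of the digestion and
#' fragmentation engines.
#'
#' @param length Sequence length.
#' @param mod_rate Per-residue modification probability.
#' @param five,three Terminus chemistry.
#' @param seed Optional integer seed (`NULL` leaves the RNG state alone).
#' @return A [mod_sequence()].
#' @export
sim_modified_sequence <- function(length = 30L, mod_rate = 0.15,
                                  five = "OH", three = "OH", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  reg <- monomer_registry()
  canon <- c("A", "C", "G", "U")
  res <- sample(canon, length, replace = TRUE)
  for (i in seq_len(length)) {
    if (stats::runif(1) < mod_rate) {
      alts <- reg$code[reg$parent == res[i] & !(reg$code %in% canon)]
      if (length(alts)) res[i] <- sample(alts, 1L)
    }
  }
  mod_sequence(res, five = five, three = three)
}
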