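#' Neutral monoisotopic mass of an oligonucleotide
#'
#' Sums residue masses (residue = nucleoside monophosphate - water) and
#' applies the terminal adjustment implied by the terminus chemistry. A
#' chain with one phosphate per residue — (5'-OH, 3'-linear phosphate) or
#' (5'-phosphate, 3'-OH) — gains one water; a 2',3'-cyclic phosphate is a
#' linear phosphate minus water; each missing/extra phosphate subtracts or
#' adds one HPO3.
#'
#' @param seq A [mod_sequence()] or bracket-notation string.
#' @return Neutral monoisotopic mass (Da).
#' @examples
#' neutral_mass("ACU[manQ]UAGp")     # 2571.4233
#' neutral_mass("U[manQ]UAGAUCC>p")  # 3164.4793
#' @export
neutral_mass <- function(seq) {
  if (is.character(seq)) seq <- parse_sequence(seq)
  stopifnot(inherits(seq, "mod_sequence"))
  adj <- MASS_WATER +
    (seq$five == "p") * MASS_HPO3 -
    (seq$three == "OH") * MASS_HPO3 -
    (seq$three == ">p") * MASS_WATER
  sum(residue_mass(seq$residues)) + adj
}

#' m/z of a neutral mass at a given charge
#'
#' Negative mode: `(M - |z| * 1.007276) / |z|` (proton removal). Positive
#' mode by default adds protons the same way; the `"hydrogen"` convention
#' instead adds hydrogen-atom masses (1.007825), the convention under
#' which protonated-nucleoside values such as manQ's 572.2204 are printed.
#'
#' @param M Neutral monoisotopic mass (Da).
#' @param charge Non-zero integer (its sign is ignored; use `polarity`).
#' @param polarity `"negative"` or `"positive"`.
#' @param convention Charge-carrier mass for positive mode: `"proton"`
#'   (1.007276) or `"hydrogen"` (1.007825).
#' @return m/z.
#' @export
mz <- function(M, charge, polarity = c("negative", "positive"),
               convention = c("proton", "hydrogen")) {
  polarity <- match.arg(polarity)
  convention <- match.arg(convention)
  z <- abs(charge)
  if (z == 0) stop("charge must be non-zero")
  carrier <- if (polarity == "positive" && convention == "hydrogen") {
    MASS_HYDROGEN
  } else {
    MASS_PROTON
  }
  out <- if (polarity == "negative") (M - z * carrier) / z
         else (M + z * carrier) / z
  if (out <= 0) stop("non-positive m/z (mass too small for charge ", z, ")")
  out
}

#' c- and y-type fragment ions of an oligonucleotide
#'
#' For a parent of length n, the c series covers the 5' fragments
#' c_1..c_(n-1): `c_i = sum of the first i residue masses` plus HPO3 when
#' the 5' terminus is phosphorylated. The complementary y series is
#' defined by `y_j = M_parent + water - c_(n-j)`, so
#' `c_i + y_(n-i) = M + water` exactly.
#'
#' @param seq A [mod_sequence()] or bracket string, length >= 2.
#' @param series `"c"`, `"y"` or `"both"`.
#' @param max_charge Fragment charge states 1..max_charge are emitted.
#' @param polarity Passed to [mz()] (negative mode is the acquisition mode
#'   for oligonucleotides).
#' @return A data.frame with columns `series`, `index`, `neutral_mass`,
#'   `charge`, `polarity`, `mz`.
#' @export
fragment_series <- function(seq, series = c("both", "c", "y"),
                            max_charge = 1L,
                            polarity = c("negative", "positive")) {
  if (is.character(seq)) seq <- parse_sequence(seq)
  stopifnot(inherits(seq, "mod_sequence"))
  series <- match.arg(series)
  polarity <- match.arg(polarity)
  n <- length(seq$residues)
  if (n < 2L) stop("fragmentation requires length >= 2")
  rm <- residue_mass(seq$residues)
  five_adj <- if (seq$five == "p") MASS_HPO3 else 0
  c_masses <- cumsum(rm)[seq_len(n - 1L)] + five_adj
  M <- neutral_mass(seq)
  y_masses <- M + MASS_WATER - rev(c_masses)  # y_j pairs with c_(n-j)
  tab <- data.frame(
    series = rep(c("c", "y"), each = n - 1L),
    index = rep(seq_len(n - 1L), 2L),
    neutral_mass = c(c_masses, y_masses),
    stringsAsFactors = FALSE
  )
  if (series != "both") tab <- tab[tab$series == series, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(max_charge), function(z) {
    t2 <- tab
    t2$charge <- z
    t2$polarity <- polarity
    t2$mz <- vapply(t2$neutral_mass, mz, 0, charge = z, polarity = polarity)
    t2
  }))
  rownames(out) <- NULL
  out
}

#' Protonated-nucleoside m/z for a registry code
#'
#' Positive-mode m/z of the free nucleoside at charge 1, by default under
#' the hydrogen-atom-addition convention (M + 1.007825).
#'
#' @param code Registry code, e.g. `"manQ"`.
#' @param convention `"hydrogen"` (default) or `"proton"`.
#' @return m/z.
#' @examples
#' nucleoside_mz("manQ")  # 572.2204
#' @export
nucleoside_mz <- function(code, convention = c("hydrogen", "proton")) {
  convention <- match.arg(convention)
  mono <- lookup_monomer(code)
  mz(mono$nucleoside_mass, 1L, polarity = "positive",
     convention = convention)
}

#' Search charge states matching an observed m/z
#'
#' Computes negative-mode m/z of a sequence at charges 1..`max_charge` and
#' reports which charge state reproduces the observed value at the given
#' rounding or tolerance. Used to confirm the charge state behind printed
#' integer m/z values rather than assuming one.
#'
#' @param seq A [mod_sequence()] or bracket string.
#' @param observed Observed m/z (often an integer as printed).
#' @param max_charge Highest charge state searched.
#' @param tol Absolute tolerance; the default 0.5 matches
#'   nearest-integer-printed values.
#' @return Data.frame of charges with their m/z and match flag.
#' @export
match_charge_state <- function(seq, observed, max_charge = 5L, tol = 0.5) {
  if (is.character(seq)) seq <- parse_sequence(seq)
  M <- neutral_mass(seq)
  z <- seq_len(max_charge)
  mzs <- vapply(z, function(zi) mz(M, zi), 0)
  data.frame(charge = z, mz = mzs,
             matches = abs(mzs - observed) <= tol)
}

#' Predicted m/z printed in this workflow's anticodon mapping
#'
#' Internal-standard metadata: the 2-bromo-deoxycytidine spike-in is
#' monitored at the instrument-printed m/z 306.0078; this is recorded as
#' acquisition metadata, not derived from composition.
#' @export
IS_BROMO_DC_MZ <- 306.0078
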