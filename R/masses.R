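#' Monoisotopic atomic masses and derived constants
#'
#' Monoisotopic masses (Da) of the elements occurring in nucleic acids and
#' their modifications, plus the named constants used throughout the mass
#' arithmetic: water, the HPO3 phosphate unit, the proton and the hydrogen
#' atom.
#'
#' @format A named numeric vector (element symbol -> mass in Da).
#' @export
ATOMIC_MASSES <- c(
  H  = 1.0078250319,
  C  = 12.0,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.97376151,
  S  = 31.97207069,
  Se = 79.9165218,
  Br = 78.9183376
)

#' @rdname ATOMIC_MASSES
#' @export
MASS_WATER <- 18.010565

#' @rdname ATOMIC_MASSES
#' @export
MASS_HPO3 <- 79.966331

#' @rdname ATOMIC_MASSES
#' @export
MASS_PROTON <- 1.007276

#' @rdname ATOMIC_MASSES
#' @export
MASS_HYDROGEN <- 1.007825

#' Monoisotopic mass of an elemental formula
#'
#' Sums monoisotopic atomic masses over a Hill-style formula string such as
#' `"C10H13N5O5"`. An empty formula has mass 0.
#'
#' @param formula Formula string. Element symbols are one capital letter
#'   optionally followed by a lowercase letter; counts default to 1 and may
#'   be negative (useful for mass differences, e.g. `"C-1H-2"`).
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")        # 18.010565
#' monoisotopic_mass("C10H13N5O5") # guanosine, 283.09167
#' @export
monoisotopic_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (is.na(formula) || !nzchar(formula)) return(0)
  m <- gregexpr("([A-Z][a-z]?)(-?[0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  tokens <- tokens[nzchar(tokens)]
  consumed <- sum(nchar(tokens))
  if (consumed != nchar(formula)) {
    stop("malformed formula: '", formula, "'")
  }
  total <- 0
  for (tok in tokens) {
    sym <- sub("^([A-Z][a-z]?).*$", "\\1", tok)
    cnt <- sub("^[A-Z][a-z]?", "", tok)
    n <- if (nzchar(cnt)) as.numeric(cnt) else 1
    if (!sym %in% names(ATOMIC_MASSES)) {
      stop("unknown element '", sym, "' in formula '", formula, "'")
    }
    total <- total + n * ATOMIC_MASSES[[sym]]
  }
  total
}

## Canonical residue masses: nucleoside-5'-monophosphate minus water, Da.
.CANONICAL_RESIDUE <- c(
  A = 329.05252, C = 305.04129, G = 345.04744, U = 306.02530
)

## Common mass increments used by the registry.
.INC_METHYL <- 14.015650   # +CH2
.INC_ACETYL <- 42.010565   # +C2H2O

# The built-in monomer registry. Each entry is either a full nucleoside
# formula or a mass increment relative to the parent canonical nucleoside;
# residue masses are derived as parent residue + increment. The inventory
# covers the modifications detectable in mosquito tRNA hydrolysates
# (queuosine family, anticodon-loop and body modifications).
.registry_entries <- function() {
  inc <- function(code, name, parent, increment, formula = NA_character_)
    list(code = code, name = name, parent = parent,
         increment = increment, formula = formula)
  q_inc    <- monoisotopic_mass("C17H23N5O7") - monoisotopic_mass("C10H13N5O5")
  hexose   <- monoisotopic_mass("C6H10O5")
  ch2      <- .INC_METHYL
  ch2s     <- monoisotopic_mass("CH2S")
  t6a_inc  <- monoisotopic_mass("C5H7NO4")
  acp_inc  <- monoisotopic_mass("C4H7NO2")
  mcm_inc  <- monoisotopic_mass("C3H4O2")
  h2       <- monoisotopic_mass("H2")
  s_for_o  <- ATOMIC_MASSES[["S"]] - ATOMIC_MASSES[["O"]]
  deamin   <- ATOMIC_MASSES[["O"]] - monoisotopic_mass("NH")  # A -> I
  list(
    inc("A", "adenosine",  "A", 0, "C10H13N5O4"),
    inc("C", "cytidine",   "C", 0, "C9H13N3O5"),
    inc("G", "guanosine",  "G", 0, "C10H13N5O5"),
    inc("U", "uridine",    "U", 0, "C9H12N2O6"),
    inc("Q",    "queuosine",            "G", q_inc, "C17H23N5O7"),
    inc("manQ", "mannosyl-queuosine",   "G", q_inc + hexose, "C23H33N5O12"),
    inc("galQ", "galactosyl-queuosine", "G", q_inc + hexose, "C23H33N5O12"),
    inc("oQ",   "epoxyqueuosine",       "G", q_inc + ATOMIC_MASSES[["O"]],
        "C17H23N5O8"),
    inc("Ψ",  "pseudouridine",               "U", 0, "C9H12N2O6"),
    inc("Ψm", "2'-O-methylpseudouridine",    "U", ch2),
    inc("D",    "dihydrouridine",                 "U", h2),
    inc("m5U",  "5-methyluridine",                "U", ch2),
    inc("Um",   "2'-O-methyluridine",             "U", ch2),
    inc("acp3U","3-(3-amino-3-carboxypropyl)uridine", "U", acp_inc),
    inc("acp3D","3-(3-amino-3-carboxypropyl)dihydrouridine", "U", acp_inc + h2),
    inc("mcm5U","5-methoxycarbonylmethyluridine", "U", mcm_inc),
    inc("mcm5s2U", "5-methoxycarbonylmethyl-2-thiouridine", "U",
        mcm_inc + s_for_o),
    inc("m1G", "1-methylguanosine",    "G", ch2),
    inc("m2G", "N2-methylguanosine",   "G", ch2),
    inc("Gm",  "2'-O-methylguanosine", "G", ch2),
    inc("m1A", "1-methyladenosine",    "A", ch2),
    inc("Am",  "2'-O-methyladenosine", "A", ch2),
    inc("i6A", "N6-isopentenyladenosine", "A", monoisotopic_mass("C5H8")),
    inc("ms2i6A", "2-methylthio-N6-isopentenyladenosine", "A",
        monoisotopic_mass("C5H8") + ch2s),
    inc("t6A", "N6-threonylcarbamoyladenosine", "A", t6a_inc),
    inc("ms2t6A", "2-methylthio-N6-threonylcarbamoyladenosine", "A",
        t6a_inc + ch2s),
    inc("I",   "inosine",          "A", deamin, "C10H12N4O5"),
    inc("m1I", "1-methylinosine",  "A", deamin + ch2),
    inc("m3C", "3-methylcytidine",    "C", ch2),
    inc("m5C", "5-methylcytidine",    "C", ch2),
    inc("Cm",  "2'-O-methylcytidine", "C", ch2),
    inc("ac4C","N4-acetylcytidine",   "C", .INC_ACETYL)
  )
}

.build_registry <- function() {
  entries <- .registry_entries()
  df <- data.frame(
    code      = vapply(entries, `[[`, "", "code"),
    name      = vapply(entries, `[[`, "", "name"),
    parent    = vapply(entries, `[[`, "", "parent"),
    increment = vapply(entries, `[[`, 0, "increment"),
    formula   = vapply(entries, `[[`, "", "formula"),
    stringsAsFactors = FALSE
  )
  df$residue_mass <- .CANONICAL_RESIDUE[df$parent] + df$increment
  # nucleoside = residue - HPO3 + water
  df$nucleoside_mass <- df$residue_mass - MASS_HPO3 + MASS_WATER
  rownames(df) <- df$code
  df
}

.modomap_env <- new.env(parent = emptyenv())
.modomap_env$registry <- NULL

#' The monomer (nucleoside) registry
#'
#' Returns the registry of canonical and modified residues: code, display
#' name, parent canonical base, mass increment relative to the parent
#' nucleoside, optional elemental formula, and derived residue and
#' nucleoside monoisotopic masses. Residue mass is the
#' nucleoside-5'-monophosphate mass minus water.
#'
#' Isomers (pseudouridine vs uridine, mannosyl- vs galactosyl-queuosine)
#' share a mass but keep distinct codes.
#'
#' @return A data.frame with one row per registered code.
#' @export
monomer_registry <- function() {
  if (is.null(.modomap_env$registry)) {
    .modomap_env$registry <- .build_registry()
  }
  .modomap_env$registry
}

#' Look up a single monomer by code
#'
#' @param code Registry code, e.g. `"A"`, `"manQ"`, `"Ψ"`.
#' @return One-row data.frame (see [monomer_registry()]).
#' @export
lookup_monomer <- function(code) {
  reg <- monomer_registry()
  if (!code %in% reg$code) {
    stop("unknown monomer code '", code, "' (not in registry)")
  }
  reg[code, , drop = FALSE]
}

#' Extend or override the monomer registry from a TSV file
#'
#' The file must have columns `code`, `name`, `parent` and
#' `formula_or_increment`; the last column is either an elemental formula
#' (e.g. `C10H13N5O5`) or a numeric mass increment (Da) relative to the
#' parent canonical nucleoside.
#'
#' @param path Path to the TSV file.
#' @return The updated registry, invisibly.
#' @export
extend_registry <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("code", "name", "parent", "formula_or_increment")
  if (!all(need %in% names(tab))) {
    stop("registry file must have columns: ", paste(need, collapse = ", "))
  }
  reg <- monomer_registry()
  for (i in seq_len(nrow(tab))) {
    parent <- tab$parent[i]
    if (!parent %in% names(.CANONICAL_RESIDUE)) {
      stop("parent base must be one of A/C/G/U, got '", parent, "'")
    }
    foi <- tab$formula_or_increment[i]
    num <- suppressWarnings(as.numeric(foi))
    if (!is.na(num)) {
      increment <- num
      formula <- NA_character_
    } else {
      formula <- foi
      canon_formula <- reg[parent, "formula"]
      increment <- monoisotopic_mass(formula) - monoisotopic_mass(canon_formula)
    }
    row <- data.frame(
      code = tab$code[i], name = tab$name[i], parent = parent,
      increment = increment, formula = formula,
      residue_mass = .CANONICAL_RESIDUE[[parent]] + increment,
      stringsAsFactors = FALSE
    )
    row$nucleoside_mass <- row$residue_mass - MASS_HPO3 + MASS_WATER
    rownames(row) <- row$code
    reg <- reg[setdiff(rownames(reg), row$code), , drop = FALSE]
    reg <- rbind(reg, row)
  }
  .modomap_env$registry <- reg
  invisible(reg)
}

#' Reset the monomer registry to the built-in table
#' @return The built-in registry, invisibly.
#' @export
reset_registry <- function() {
  .modomap_env$registry <- .build_registry()
  invisible(.modomap_env$registry)
}

#' Residue monoisotopic mass for a vector of codes
#' @param codes Character vector of registry codes.
#' @return Numeric vector of residue masses (Da).
#' @export
residue_mass <- function(codes) {
  reg <- monomer_registry()
  bad <- setdiff(unique(codes), reg$code)
  if (length(bad)) {
    stop("unknown monomer code(s): ", paste(bad, collapse = ", "))
  }
  unname(reg[codes, "residue_mass"])
}
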