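#' Construct a modified RNA sequence
#'
#' A `mod_sequence` is an ordered vector of registry residue codes
#' (1-based positions) plus explicit terminus chemistry: the 5' end is
#' hydroxyl (`"OH"`) or monophosphate (`"p"`); the 3' end is hydroxyl,
#' linear phosphate (`"p"`) or 2',3'-cyclic phosphate (`">p"`).
#'
#' @param residues Character vector of registry codes.
#' @param five Five-prime terminus, `"OH"` or `"p"`.
#' @param three Three-prime terminus, `"OH"`, `"p"` or `">p"`.
#' @return An object of class `mod_sequence`.
#' @export
mod_sequence <- function(residues, five = "OH", three = "OH") {
  if (length(residues) < 1L) stop("sequence must have at least one residue")
  five <- match.arg(five, c("OH", "p"))
  three <- match.arg(three, c("OH", "p", ">p"))
  residue_mass(residues)  # validates against the registry
  structure(
    list(residues = as.character(residues), five = five, three = three),
    class = "mod_sequence"
  )
}

#' Parse bracket-notation into a modified sequence
#'
#' Canonical residues are single characters; modifications are enclosed in
#' square brackets (`"ACU[manQ]UAGp"`). A leading `"p"` marks a 5'
#' monophosphate; a trailing `"p"` or `">p"` marks a 3' linear or
#' 2',3'-cyclic phosphate. Unmarked termini default to hydroxyl.
#'
#' @param text Bracket-notation string.
#' @return A [mod_sequence()].
#' @examples
#' parse_sequence("ACU[manQ]UAGp")
#' parse_sequence("U[manQ]UAGAUCC>p")
#' @export
parse_sequence <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) stop("empty sequence string")
  s <- text
  three <- "OH"
  if (endsWith(s, ">p")) {
    three <- ">p"
    s <- substr(s, 1L, nchar(s) - 2L)
  } else if (endsWith(s, "p")) {
    three <- "p"
    s <- substr(s, 1L, nchar(s) - 1L)
  }
  five <- "OH"
  if (startsWith(s, "p")) {
    five <- "p"
    s <- substr(s, 2L, nchar(s))
  }
  if (!nzchar(s)) stop("no residues in sequence string '", text, "'")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  residues <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed '[' in sequence '", text, "'")
      code <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!nzchar(code)) stop("empty modification brackets in '", text, "'")
      residues <- c(residues, code)
      i <- j + 1L
    } else {
      residues <- c(residues, ch)
      i <- i + 1L
    }
  }
  mod_sequence(residues, five = five, three = three)
}

#' Format a modified sequence back to bracket notation
#'
#' Inverse of [parse_sequence()]: multi-character codes are bracketed and
#' terminus chemistry is rendered as the leading/trailing phosphate marks.
#'
#' @param seq A [mod_sequence()].
#' @return Bracket-notation string.
#' @export
format_sequence <- function(seq) {
  stopifnot(inherits(seq, "mod_sequence"))
  body <- vapply(seq$residues, function(r) {
    if (r %in% c("A", "C", "G", "U")) r else paste0("[", r, "]")
  }, "")
  paste0(
    if (seq$five == "p") "p" else "",
    paste(body, collapse = ""),
    switch(seq$three, OH = "", p = "p", `>p` = ">p")
  )
}

#' @export
print.mod_sequence <- function(x, ...) {
  cat("mod_sequence:", format_sequence(x),
      sprintf("(%d nt, 5'-%s, 3'-%s)\n", length(x$residues), x$five, x$three))
  invisible(x)
}

#' @export
length.mod_sequence <- function(x) length(x$residues)

#' Parent canonical bases of a sequence's residues
#' @param seq A [mod_sequence()].
#' @return Character vector of A/C/G/U parent bases.
#' @export
parent_bases <- function(seq) {
  reg <- monomer_registry()
  unname(reg[seq$residues, "parent"])
}

#' Is each residue modified (non-canonical)?
#' @param seq A [mod_sequence()].
#' @return Logical vector.
#' @export
is_modified <- function(seq) {
  !(seq$residues %in% c("A", "C", "G", "U"))
}

#' Take a contiguous slice of a modified sequence
#'
#' @param seq A [mod_sequence()].
#' @param start,end 1-based inclusive bounds.
#' @param five,three Terminus chemistry of the slice.
#' @return A [mod_sequence()].
#' @export
subseq_mod <- function(seq, start, end, five = "OH", three = "OH") {
  stopifnot(start >= 1L, end <= length(seq$residues), start <= end)
  mod_sequence(seq$residues[start:end], five = five, three = three)
}
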