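#' Ribonuclease definitions
#'
#' An `rnase` bundles the cleavage selectivity of an endoribonuclease:
#' which canonical parent bases it cleaves 3' of, whether modification of
#' the cleavage-site residue blocks cleavage, whether it refuses to cleave
#' between two residues of the same (cleavable) parent base — the
#' cusativin CpC rule — and the 3' chemistry of its products (linear
#' phosphate for RNase T1, 2',3'-cyclic phosphate for cusativin).
#' Downstream fragments always receive a 5'-hydroxyl.
#'
#' @param name Enzyme name.
#' @param cleave_after Character vector of parent bases cleaved 3' of.
#' @param blocked_by_modification If `TRUE`, a modified residue at the
#'   cleavage site blocks cleavage.
#' @param no_cleavage_between_identical If `TRUE`, bonds whose flanking
#'   residues share the same cleavable parent base are not cleaved.
#' @param product_three Product 3' chemistry, `"p"` or `">p"`.
#' @return An object of class `rnase`.
#' @export
rnase <- function(name, cleave_after, blocked_by_modification = TRUE,
                  no_cleavage_between_identical = FALSE,
                  product_three = c("p", ">p")) {
  cleave_after <- match.arg(cleave_after, c("A", "C", "G", "U"),
                            several.ok = TRUE)
  if (length(cleave_after) < 1L) stop("cleave_after must be non-empty")
  product_three <- match.arg(product_three)
  structure(
    list(name = name, cleave_after = cleave_after,
         blocked_by_modification = blocked_by_modification,
         no_cleavage_between_identical = no_cleavage_between_identical,
         product_three = product_three, product_five = "OH"),
    class = "rnase"
  )
}

#' @rdname rnase
#' @export
RNASE_T1 <- rnase("RNase T1", "G", product_three = "p")

#' @rdname rnase
#' @export
CUSATIVIN <- rnase("cusativin", "C",
                   no_cleavage_between_identical = TRUE,
                   product_three = ">p")

#' Load enzyme definitions from a TSV config file
#'
#' Columns: `name`, `cleave_after` (comma-separated bases),
#' `blocked_by_modification` (logical), `no_cleavage_between_identical`
#' (logical), `product_three` (`p` or `>p`).
#'
#' @param path Path to the TSV file.
#' @return Named list of [rnase()] objects.
#' @export
read_enzymes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    rnase(tab$name[i],
          strsplit(tab$cleave_after[i], ",")[[1]],
          blocked_by_modification = as.logical(tab$blocked_by_modification[i]),
          no_cleavage_between_identical =
            as.logical(tab$no_cleavage_between_identical[i]),
          product_three = tab$product_three[i])
  })
  names(out) <- tab$name
  out
}

# Logical vector over bonds 1..n-1: is the bond 3' of residue i cleaved?
.cleavage_sites <- function(seq, enzyme) {
  n <- length(seq$residues)
  if (n < 2L) return(logical(0))
  parents <- parent_bases(seq)
  modded <- is_modified(seq)
  i <- seq_len(n - 1L)
  site <- parents[i] %in% enzyme$cleave_after
  if (enzyme$blocked_by_modification) site <- site & !modded[i]
  if (enzyme$no_cleavage_between_identical) {
    site <- site & !(parents[i + 1L] == parents[i] &
                       parents[i] %in% enzyme$cleave_after)
  }
  site
}

#' In-silico ribonuclease digestion
#'
#' Cleaves a modified RNA 3' of every residue matching the enzyme's rules:
#' the residue's parent base is in the cleave-after set, the residue is
#' unmodified (when modification blocks the enzyme), and — for cusativin —
#' the next residue is not also a cytidine-parent residue. Cleavage after
#' the final residue is vacuous. Products are enumerated for 0 up to
#' `max_missed_cleavages` internal missed cleavage sites. The 5'-most
#' product keeps the parent's 5' chemistry and the 3'-terminal product the
#' parent's 3' chemistry; all other termini follow the enzyme
#' (5'-OH downstream, enzyme-specific 3' phosphate).
#'
#' @param parent A [mod_sequence()] or bracket-notation string.
#' @param enzyme An [rnase()], e.g. [RNASE_T1] or [CUSATIVIN].
#' @param max_missed_cleavages Non-negative integer.
#' @param parent_id Identifier recorded in the product table.
#' @return A data.frame with columns `parent_id`, `start`, `end`,
#'   `missed`, `is_3prime_terminal`, `product` (bracket notation) and
#'   `length`, plus a list column `seq` of [mod_sequence()] objects.
#' @examples
#' digest("GGACU[manQ]UAGAUCCUUG", RNASE_T1)
#' digest("ACU[manQ]UAGAUCCAAC", CUSATIVIN)
#' @export
digest <- function(parent, enzyme, max_missed_cleavages = 0L,
                   parent_id = "seq1") {
  if (is.character(parent)) parent <- parse_sequence(parent)
  stopifnot(inherits(parent, "mod_sequence"), inherits(enzyme, "rnase"))
  if (max_missed_cleavages < 0L) stop("max_missed_cleavages must be >= 0")
  n <- length(parent$residues)
  sites <- which(.cleavage_sites(parent, enzyme))
  # segment boundaries: 0-missed products run between consecutive sites
  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  nseg <- length(starts)
  rows <- list()
  for (i in seq_len(nseg)) {
    for (k in 0:min(max_missed_cleavages, nseg - i)) {
      j <- i + k
      s <- starts[i]; e <- ends[j]
      five <- if (s == 1L) parent$five else enzyme$product_five
      is_term <- (e == n)
      three <- if (is_term) parent$three else enzyme$product_three
      frag <- subseq_mod(parent, s, e, five = five, three = three)
      rows[[length(rows) + 1L]] <- list(
        parent_id = parent_id, start = s, end = e, missed = k,
        is_3prime_terminal = is_term, product = format_sequence(frag),
        length = e - s + 1L, seq = list(frag)
      )
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(parent_id = r$parent_id, start = r$start, end = r$end,
               missed = r$missed, is_3prime_terminal = r$is_3prime_terminal,
               product = r$product, length = r$length,
               stringsAsFactors = FALSE)
  }))
  out$seq <- lapply(rows, function(r) r$seq[[1]])
  out[order(out$missed, out$start), , drop = FALSE]
}

#' Count parents yielding a given digestion product
#'
#' Digests every sequence in a database and counts how many parents yield
#' a product whose residue string and terminus chemistry exactly match the
#' query — the uniqueness check behind "the digestion products are unique
#' to Tyr tRNA".
#'
#' @param db Named list of [mod_sequence()] objects or bracket strings.
#' @param enzyme An [rnase()].
#' @param product A [mod_sequence()] or bracket string to look for.
#' @param max_missed_cleavages Passed to [digest()].
#' @return Integer count of parents containing the product, with the
#'   matching parent ids as attribute `"parents"`.
#' @export
product_uniqueness <- function(db, enzyme, product,
                               max_missed_cleavages = 0L) {
  if (length(db) < 1L) stop("database must be non-empty")
  if (is.character(product)) product <- parse_sequence(product)
  key <- format_sequence(product)
  ids <- names(db)
  if (is.null(ids)) ids <- paste0("seq", seq_along(db))
  hit <- vapply(seq_along(db), function(i) {
    prods <- digest(db[[i]], enzyme, max_missed_cleavages,
                    parent_id = ids[i])
    key %in% prods$product
  }, logical(1))
  structure(sum(hit), parents = ids[hit])
}
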