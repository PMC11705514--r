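#' Construct a peak list
#'
#' A minimal MS/MS spectrum container: optional precursor m/z and charge,
#' and a table of fragment peaks.
#'
#' @param mz Numeric vector of fragment m/z values (> 0).
#' @param intensity Numeric vector of intensities (>= 0); defaults to 1.
#' @param precursor_mz Optional precursor m/z.
#' @param precursor_charge Optional precursor charge (magnitude).
#' @param source Source identifier string.
#' @return An object of class `peak_list`.
#' @export
peak_list <- function(mz = numeric(0), intensity = rep(1, length(mz)),
                      precursor_mz = NA_real_, precursor_charge = NA_integer_,
                      source = "unknown") {
  stopifnot(length(mz) == length(intensity))
  if (any(mz <= 0)) stop("fragment m/z values must be > 0")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  structure(
    list(peaks = data.frame(mz = as.numeric(mz),
                            intensity = as.numeric(intensity)),
         precursor_mz = precursor_mz,
         precursor_charge = precursor_charge,
         source = source),
    class = "peak_list"
  )
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("peak_list '%s': %d peaks, precursor m/z %s (z=%s)\n",
              x$source, nrow(x$peaks),
              format(x$precursor_mz), format(x$precursor_charge)))
  invisible(x)
}

#' Read peak lists from an MGF file
#'
#' Supports the BEGIN IONS/END IONS blocks with TITLE, PEPMASS and CHARGE
#' headers and two-column (m/z, intensity) peak lines.
#'
#' @param path Path to the MGF file.
#' @return List of [peak_list()] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      title <- basename(path)
      pmz <- NA_real_; pz <- NA_integer_
      mzv <- numeric(0); intv <- numeric(0)
      i <- i + 1L
      while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (startsWith(ln, "TITLE=")) {
          title <- sub("^TITLE=", "", ln)
        } else if (startsWith(ln, "PEPMASS=")) {
          pmz <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "\\s+")[[1]][1])
        } else if (startsWith(ln, "CHARGE=")) {
          pz <- as.integer(gsub("[^0-9]", "", sub("^CHARGE=", "", ln)))
        } else if (grepl("^[0-9]", ln)) {
          fields <- strsplit(ln, "\\s+")[[1]]
          mzv <- c(mzv, as.numeric(fields[1]))
          intv <- c(intv, if (length(fields) > 1) as.numeric(fields[2]) else 1)
        }
        i <- i + 1L
      }
      out[[length(out) + 1L]] <- peak_list(
        mzv, intv, precursor_mz = pmz, precursor_charge = pz, source = title)
    }
    i <- i + 1L
  }
  out
}

#' Read a two-column TSV peak list
#'
#' @param path Path to a TSV with columns m/z and intensity (header
#'   optional).
#' @param precursor_mz,precursor_charge Optional precursor information.
#' @return A [peak_list()].
#' @export
read_peaks_tsv <- function(path, precursor_mz = NA_real_,
                           precursor_charge = NA_integer_) {
  first <- readLines(path, n = 1L)
  header <- !grepl("^[0-9.]", trimws(first))
  tab <- utils::read.delim(path, header = header)
  peak_list(tab[[1]], tab[[2]], precursor_mz = precursor_mz,
            precursor_charge = precursor_charge, source = basename(path))
}

# theoretical fragment m/z table for scoring: c and y series, 1- and 2-
.theoretical_fragments <- function(candidate, max_charge = 2L) {
  fragment_series(candidate, series = "both", max_charge = max_charge,
                  polarity = "negative")
}

#' Filter candidates by precursor m/z
#'
#' Keeps every candidate whose negative-mode m/z at some charge 1..5 lies
#' within the tolerance of the observed precursor. A peak list without
#' precursor information passes all candidates through, flagged with a
#' warning attribute.
#'
#' @param peaklist A [peak_list()].
#' @param candidates List of [mod_sequence()] objects or bracket strings.
#' @param tol Tolerance (> 0), in ppm (`unit = "ppm"`) or Da.
#' @param unit `"ppm"` or `"da"`.
#' @param max_charge Highest precursor charge searched.
#' @return The retained sublist of `candidates`; attribute
#'   `"matched_charge"` gives the matching charge per candidate, and
#'   attribute `"no_precursor"` flags the pass-through case.
#' @export
match_precursor <- function(peaklist, candidates, tol = 10,
                            unit = c("ppm", "da"), max_charge = 5L) {
  unit <- match.arg(unit)
  if (tol <= 0) stop("tolerance must be > 0")
  candidates <- lapply(candidates, function(x) {
    if (is.character(x)) parse_sequence(x) else x
  })
  if (length(candidates) == 0L) return(candidates)
  if (is.na(peaklist$precursor_mz)) {
    warning("peak list has no precursor m/z; passing all candidates through")
    attr(candidates, "no_precursor") <- TRUE
    return(candidates)
  }
  obs <- peaklist$precursor_mz
  zmatch <- vapply(candidates, function(cand) {
    M <- neutral_mass(cand)
    for (z in seq_len(max_charge)) {
      theo <- mz(M, z)
      delta <- if (unit == "ppm") abs(obs - theo) / theo * 1e6
               else abs(obs - theo)
      if (delta <= tol) return(z)
    }
    NA_integer_
  }, integer(1))
  keep <- !is.na(zmatch)
  out <- candidates[keep]
  attr(out, "matched_charge") <- zmatch[keep]
  out
}

#' Score a candidate against an observed spectrum
#'
#' Greedy presence/absence matching of the candidate's theoretical c/y
#' fragment ions (charges 1- and 2-) to observed peaks: theoretical ions
#' are visited in ascending m/z and each claims the nearest unconsumed
#' observed peak within the tolerance. The score is the matched fraction
#' of theoretical ions; intensity is not used.
#'
#' @param peaklist A [peak_list()].
#' @param candidate A [mod_sequence()] or bracket string (length >= 2).
#' @param tol Fragment tolerance in Da (default 0.5, ion-trap resolution).
#' @param max_charge Fragment charges 1..max_charge are considered.
#' @return A list of class `match_result`: `candidate`, `score`,
#'   `n_matched`, `n_theoretical`, per-series counts, mean absolute
#'   fragment error of the matches, and the fragment assignment table.
#' @export
score_fragments <- function(peaklist, candidate, tol = 0.5, max_charge = 2L) {
  if (is.character(candidate)) candidate <- parse_sequence(candidate)
  stopifnot(inherits(peaklist, "peak_list"))
  if (length(candidate$residues) < 2L) stop("candidate must have length >= 2")
  theo <- .theoretical_fragments(candidate, max_charge = max_charge)
  theo <- theo[order(theo$mz), , drop = FALSE]
  obs <- peaklist$peaks$mz
  available <- rep(TRUE, length(obs))
  matched <- logical(nrow(theo))
  err <- rep(NA_real_, nrow(theo))
  for (i in seq_len(nrow(theo))) {
    if (!length(obs)) break
    d <- abs(obs - theo$mz[i])
    d[!available] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      matched[i] <- TRUE
      err[i] <- d[j]
      available[j] <- FALSE
    }
  }
  theo$matched <- matched
  theo$abs_error <- err
  per_series <- stats::aggregate(matched ~ series, data = theo, FUN = sum)
  structure(
    list(candidate = candidate,
         product = format_sequence(candidate),
         score = if (nrow(theo)) mean(matched) else 0,
         n_matched = sum(matched),
         n_theoretical = nrow(theo),
         per_series = per_series,
         mean_abs_error = if (any(matched)) mean(err[matched]) else NA_real_,
         tol = tol,
         assignments = theo),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: %s  score %.3f (%d/%d ions, tol %.3g Da)\n",
              x$product, x$score, x$n_matched, x$n_theoretical, x$tol))
  invisible(x)
}

#' Localize a modification on a base sequence from fragment evidence
#'
#' Generates one candidate per legal placement of the modification (every
#' position whose parent base matches the modification's parent base,
#' replacing that residue) plus the unmodified candidate, scores each
#' against the spectrum, and ranks by score with ties broken by smaller
#' mean absolute fragment error.
#'
#' @param peaklist A [peak_list()].
#' @param base_sequence Unmodified [mod_sequence()] or bracket string
#'   (terminus chemistry is kept for all candidates).
#' @param modification Registry code to place, e.g. `"manQ"`.
#' @param tol Fragment tolerance in Da.
#' @param max_charge Fragment charges considered.
#' @return A data.frame ranked best-first with columns `position` (NA for
#'   the unmodified candidate), `product`, `score`, `n_matched`,
#'   `n_theoretical`, `mean_abs_error`, `rank`.
#' @export
localize <- function(peaklist, base_sequence, modification, tol = 0.5,
                     max_charge = 2L) {
  if (is.character(base_sequence)) base_sequence <- parse_sequence(base_sequence)
  mono <- lookup_monomer(modification)
  positions <- which(parent_bases(base_sequence) == mono$parent &
                       !is_modified(base_sequence))
  if (length(positions) == 0L) {
    return(data.frame(position = integer(0), product = character(0),
                      score = numeric(0), n_matched = integer(0),
                      n_theoretical = integer(0),
                      mean_abs_error = numeric(0), rank = integer(0)))
  }
  cands <- lapply(positions, function(p) {
    res <- base_sequence$residues
    res[p] <- modification
    mod_sequence(res, five = base_sequence$five, three = base_sequence$three)
  })
  cands <- c(cands, list(base_sequence))
  pos <- c(positions, NA_integer_)
  res <- lapply(cands, function(cand) {
    score_fragments(peaklist, cand, tol = tol, max_charge = max_charge)
  })
  out <- data.frame(
    position = pos,
    product = vapply(res, `[[`, "", "product"),
    score = vapply(res, `[[`, 0, "score"),
    n_matched = vapply(res, `[[`, 0L, "n_matched"),
    n_theoretical = vapply(res, `[[`, 0L, "n_theoretical"),
    mean_abs_error = vapply(res, `[[`, 0, "mean_abs_error"),
    stringsAsFactors = FALSE
  )
  tie_err <- ifelse(is.na(out$mean_abs_error), Inf, out$mean_abs_error)
  ord <- order(-out$score, tie_err)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
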