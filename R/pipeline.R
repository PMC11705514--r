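#' Run the modification-mapping stage end to end
#'
#' Digests every sequence in a database with the chosen enzyme, computes
#' product neutral masses and negative-mode m/z at charges 1-5, matches a
#' set of observed peak lists against the products (precursor filter,
#' fragment scoring) and, when a localization request is given, ranks
#' modification placements.
#'
#' @param db Named list of [mod_sequence()] objects or bracket strings.
#' @param enzyme An [rnase()].
#' @param peaklists Optional list of [peak_list()] objects to match.
#' @param localization Optional list with elements `base_sequence` and
#'   `modification` for placement ranking against each peak list.
#' @param max_missed_cleavages Passed to [digest()].
#' @param tol_precursor_ppm Precursor tolerance (ppm).
#' @param tol_fragment_da Fragment tolerance (Da).
#' @param out_dir Optional directory; product and match tables are written
#'   there as TSV.
#' @return List with `products` (per-parent digestion table with `mass`
#'   and `mz_z1`..`mz_z5` columns), `matches` (per peak list, the scored
#'   candidates) and `localizations`.
#' @export
run_mapping <- function(db, enzyme, peaklists = NULL, localization = NULL,
                        max_missed_cleavages = 0L, tol_precursor_ppm = 10,
                        tol_fragment_da = 0.5, out_dir = NULL) {
  db <- lapply(db, function(x) if (is.character(x)) parse_sequence(x) else x)
  ids <- names(db)
  if (is.null(ids)) ids <- paste0("seq", seq_along(db))
  products <- do.call(rbind, lapply(seq_along(db), function(i) {
    digest(db[[i]], enzyme, max_missed_cleavages, parent_id = ids[i])
  }))
  if (is.null(products)) {
    products <- data.frame(parent_id = character(0), product = character(0))
  }
  if (nrow(products)) {
    products$mass <- vapply(products$seq, neutral_mass, 0)
    for (z in 1:5) {
      products[[paste0("mz_z", z)]] <-
        vapply(products$mass, function(M) mz(M, z), 0)
    }
  }
  matches <- list()
  localizations <- list()
  if (!is.null(peaklists) && nrow(products)) {
    cand_seqs <- products$seq
    names(cand_seqs) <- products$product
    for (k in seq_along(peaklists)) {
      pl <- peaklists[[k]]
      kept <- match_precursor(pl, cand_seqs, tol = tol_precursor_ppm,
                              unit = "ppm")
      scored <- lapply(kept, function(cand) {
        if (length(cand$residues) < 2L) return(NULL)
        score_fragments(pl, cand, tol = tol_fragment_da)
      })
      scored <- Filter(Negate(is.null), scored)
      tab <- if (length(scored)) {
        d <- data.frame(
          peaklist = pl$source,
          product = vapply(scored, `[[`, "", "product"),
          score = vapply(scored, `[[`, 0, "score"),
          n_matched = vapply(scored, `[[`, 0L, "n_matched"),
          n_theoretical = vapply(scored, `[[`, 0L, "n_theoretical"),
          stringsAsFactors = FALSE)
        d <- d[order(-d$score), , drop = FALSE]
        d$rank <- seq_len(nrow(d))
        d
      } else {
        data.frame(peaklist = character(0), product = character(0),
                   score = numeric(0))
      }
      matches[[pl$source]] <- tab
      if (!is.null(localization)) {
        localizations[[pl$source]] <- localize(
          pl, localization$base_sequence, localization$modification,
          tol = tol_fragment_da)
      }
    }
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    ptab <- products[, setdiff(names(products), "seq"), drop = FALSE]
    utils::write.table(ptab, file.path(out_dir, "digestion_products.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (length(matches)) {
      mtab <- do.call(rbind, matches)
      utils::write.table(mtab, file.path(out_dir, "spectrum_matches.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  list(products = products, matches = matches,
       localizations = localizations)
}

#' Run the relative-quantification stage end to end
#'
#' Canonical-sum normalization, per-time fold changes versus the
#' non-blood-fed reference, and the per-nucleoside time-course model.
#'
#' @param table Long-format peak-area table (see
#'   [normalize_abundance()]).
#' @param reference Reference time-point label.
#' @param alpha Significance threshold.
#' @param out_dir Optional directory for the normalized, fold-change and
#'   model CSVs.
#' @return List with `normalized`, `fold_change` and `model` tables.
#' @export
run_quant <- function(table, reference = "NBF", alpha = 0.05,
                      out_dir = NULL) {
  normalized <- normalize_abundance(table)
  fc <- fold_change(normalized, reference = reference)
  model <- per_nucleoside_model(normalized, alpha = alpha)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(normalized, file.path(out_dir, "normalized.csv"),
                     row.names = FALSE)
    utils::write.csv(fc, file.path(out_dir, "fold_change.csv"),
                     row.names = FALSE)
    utils::write.csv(model, file.path(out_dir, "model.csv"),
                     row.names = FALSE)
  }
  list(normalized = normalized, fold_change = fc, model = model)
}
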