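#' Normalize nucleoside peak areas to the canonical-nucleoside sum
#'
#' Each nucleoside's extracted-ion-chromatogram peak area is divided by
#' the summed peak areas of the four canonical nucleosides (A, G, C, U) of
#' the same sample, giving a normalized abundance that is robust to
#' sample-to-sample differences in tRNA input and matrix effects.
#' Modifications absent from a sample keep `NA` areas (censored, never
#' zero-imputed).
#'
#' @param table Long-format data.frame with columns `sample`, `time`,
#'   `nucleoside`, `area` (a `tissue` column is carried through if
#'   present).
#' @return The table with an added `norm_abundance` column.
#' @export
normalize_abundance <- function(table) {
  need <- c("sample", "time", "nucleoside", "area")
  if (!all(need %in% names(table))) {
    stop("table must have columns: ", paste(need, collapse = ", "))
  }
  canon <- c("A", "C", "G", "U")
  out <- table
  out$norm_abundance <- NA_real_
  for (s in unique(out$sample)) {
    idx <- out$sample == s
    ca <- out$area[idx & out$nucleoside %in% canon]
    if (length(ca) < 4L || anyNA(ca)) {
      stop("sample '", s, "' is missing canonical nucleoside areas")
    }
    if (any(ca <= 0) || sum(ca) <= 0) {
      stop("sample '", s, "' has non-positive canonical peak area")
    }
    out$norm_abundance[idx] <- out$area[idx] / sum(ca)
  }
  out
}

#' Fold change of normalized abundance versus a reference time point
#'
#' Per-nucleoside mean normalized abundance at each time point divided by
#' the mean at the reference (non-blood-fed) time point. The reference
#' fold change is 1 by construction.
#'
#' @param table Output of [normalize_abundance()].
#' @param reference Reference time-point label (default `"NBF"`).
#' @return Data.frame with columns `nucleoside`, `time`, `mean_abundance`,
#'   `fold_change`, `flag` (set when the reference mean is zero or
#'   missing).
#' @export
fold_change <- function(table, reference = "NBF") {
  if (!"norm_abundance" %in% names(table)) {
    stop("run normalize_abundance() first")
  }
  if (!reference %in% table$time) {
    stop("reference time point '", reference, "' not present")
  }
  agg <- stats::aggregate(norm_abundance ~ nucleoside + time, data = table,
                          FUN = mean, na.action = stats::na.omit)
  names(agg)[names(agg) == "norm_abundance"] <- "mean_abundance"
  ref <- agg[agg$time == reference, c("nucleoside", "mean_abundance")]
  names(ref)[2] <- "ref_mean"
  out <- merge(agg, ref, by = "nucleoside", all.x = TRUE)
  out$flag <- is.na(out$ref_mean) | out$ref_mean == 0
  out$fold_change <- ifelse(out$flag, NA_real_,
                            out$mean_abundance / out$ref_mean)
  out$ref_mean <- NULL
  out[order(out$nucleoside, out$time), , drop = FALSE]
}

#' Per-nucleoside linear model across time points
#'
#' Ordinary least squares of normalized abundance on the time-point
#' factor, one fit per nucleoside; the overall F-test p-value calls a
#' nucleoside significantly altered across the time course at p < 0.05.
#' Samples with missing abundance for a nucleoside are excluded from that
#' fit.
#'
#' @param table Output of [normalize_abundance()].
#' @param alpha Significance threshold (default 0.05).
#' @return Data.frame with columns `nucleoside`, `f_statistic`, `df1`,
#'   `df2`, `p_value`, `significant`.
#' @export
per_nucleoside_model <- function(table, alpha = 0.05) {
  if (!"norm_abundance" %in% names(table)) {
    stop("run normalize_abundance() first")
  }
  res <- lapply(unique(table$nucleoside), function(nuc) {
    sub <- table[table$nucleoside == nuc & !is.na(table$norm_abundance), ]
    if (length(unique(sub$time)) < 2L) {
      stop("nucleoside '", nuc, "': factor 'time' has fewer than 2 levels")
    }
    fs <- if (stats::var(sub$norm_abundance) == 0) NULL else
      summary(stats::lm(norm_abundance ~ factor(time), data = sub))$fstatistic
    if (is.null(fs)) {
      # constant response: no between-time signal by construction
      f <- 0; df1 <- length(unique(sub$time)) - 1L
      df2 <- nrow(sub) - df1 - 1L; p <- 1
    } else {
      f <- unname(fs[1]); df1 <- unname(fs[2]); df2 <- unname(fs[3])
      p <- stats::pf(f, df1, df2, lower.tail = FALSE)
      if (f == 0) p <- 1
    }
    data.frame(nucleoside = nuc, f_statistic = f, df1 = df1, df2 = df2,
               p_value = p, significant = p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Modification-by-enzyme interaction regressions
#'
#' For every (modification, enzyme) pair, fits two ordinary least squares
#' models of the modification's normalized abundance: one on enzyme
#' expression crossed with blood-feeding treatment, one on expression
#' crossed with the time-point factor (treatment — non-blood-fed versus
#' blood-fed — is determined by time, so the two strata cannot share one
#' model). Sequential-ANOVA F and p are reported per term, yielding one
#' row per (modification, enzyme, term).
#'
#' @param data Data.frame with one row per matched sample and columns
#'   `sample`, `time`, `treatment`, `modification`, `mod_level`, `enzyme`,
#'   `expression`.
#' @param alpha Significance threshold (default 0.05).
#' @return Data.frame with columns `modification`, `enzyme`, `stratum`
#'   (`"treatment"` or `"time"`), `term`, `f_statistic`, `df`, `p_value`,
#'   `significant`.
#' @export
interaction_model <- function(data, alpha = 0.05) {
  need <- c("sample", "time", "treatment", "modification", "mod_level",
            "enzyme", "expression")
  if (!all(need %in% names(data))) {
    stop("data must have columns: ", paste(need, collapse = ", "))
  }
  pairs <- unique(data[, c("modification", "enzyme")])
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    sub <- data[data$modification == pairs$modification[i] &
                  data$enzyme == pairs$enzyme[i] &
                  !is.na(data$mod_level), , drop = FALSE]
    for (stratum in c("treatment", "time")) {
      sub$stratum_f <- factor(sub[[stratum]])
      fit <- stats::lm(mod_level ~ expression * stratum_f, data = sub)
      an <- stats::anova(fit)
      terms <- rownames(an)
      terms <- terms[terms != "Residuals"]
      for (tm in terms) {
        label <- gsub("stratum_f", stratum, tm)
        f <- an[tm, "F value"]
        p <- an[tm, "Pr(>F)"]
        out[[length(out) + 1L]] <- data.frame(
          modification = pairs$modification[i], enzyme = pairs$enzyme[i],
          stratum = stratum, term = label, f_statistic = f,
          df = an[tm, "Df"], p_value = p,
          significant = !is.na(p) && p < alpha,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-gene fold change from a probe-level expression matrix
#'
#' Microarray probes are averaged per gene per sample; fold change is the
#' per-time mean gene value divided by the non-blood-fed mean. A per-gene
#' OLS on the time factor supplies the significance call.
#'
#' @param expr Long-format data.frame with columns `probe`, `gene`,
#'   `sample`, `value`.
#' @param sample_time Data.frame mapping `sample` to `time`.
#' @param reference Reference time label (default `"NBF"`).
#' @param alpha Significance threshold (default 0.05).
#' @return List with `gene_values` (gene x sample averages, long format),
#'   `fold_change` (gene, time, fold_change) and `model` (gene,
#'   f_statistic, p_value, significant).
#' @export
microarray_fold_change <- function(expr, sample_time, reference = "NBF",
                                   alpha = 0.05) {
  need <- c("probe", "gene", "sample", "value")
  if (!all(need %in% names(expr))) {
    stop("expr must have columns: ", paste(need, collapse = ", "))
  }
  counts <- table(unique(expr[, c("probe", "gene")])$gene)
  genes <- unique(expr$gene)
  if (any(!genes %in% names(counts))) stop("gene with no probes")
  gv <- stats::aggregate(value ~ gene + sample, data = expr, FUN = mean)
  gv <- merge(gv, sample_time, by = "sample")
  agg <- stats::aggregate(value ~ gene + time, data = gv, FUN = mean)
  ref <- agg[agg$time == reference, c("gene", "value")]
  names(ref)[2] <- "ref_mean"
  fc <- merge(agg, ref, by = "gene")
  fc$fold_change <- fc$value / fc$ref_mean
  fc <- fc[order(fc$gene, fc$time), c("gene", "time", "fold_change")]
  model <- do.call(rbind, lapply(unique(gv$gene), function(g) {
    sub <- gv[gv$gene == g, ]
    fit <- stats::lm(value ~ factor(time), data = sub)
    fs <- summary(fit)$fstatistic
    if (is.null(fs)) {
      f <- 0; p <- 1
    } else {
      f <- unname(fs[1])
      p <- stats::pf(f, fs[2], fs[3], lower.tail = FALSE)
    }
    data.frame(gene = g, f_statistic = f, p_value = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  }))
  rownames(fc) <- rownames(model) <- NULL
  list(gene_values = gv, fold_change = fc, model = model)
}

#' Heatmap of log2 fold changes with significance stars
#'
#' Convenience display around [pheatmap::pheatmap]: rows are nucleosides
#' (or genes), columns time points, cells log2 fold change, significant
#' rows starred. Display only — log2 scaling is a presentation choice.
#'
#' @param fc Output of [fold_change()] (or a compatible data.frame).
#' @param model Optional output of [per_nucleoside_model()] used to star
#'   significant rows.
#' @param filename Optional path; if given the plot is written there.
#' @return The matrix that was drawn, invisibly.
#' @export
plot_fc_heatmap <- function(fc, model = NULL, filename = NA) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("pheatmap is required for plotting")
  }
  wide <- stats::reshape(
    fc[, c("nucleoside", "time", "fold_change")],
    idvar = "nucleoside", timevar = "time", direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- sub("^fold_change\\.", "", colnames(mat))
  rn <- wide$nucleoside
  if (!is.null(model)) {
    starred <- model$nucleoside[model$significant]
    rn <- ifelse(rn %in% starred, paste0(rn, " *"), rn)
  }
  rownames(mat) <- rn
  lmat <- log2(mat)
  args <- list(lmat, cluster_cols = FALSE,
               main = "log2 fold change vs NBF")
  if (!is.na(filename)) args$filename <- filename
  do.call(pheatmap::pheatmap, args)
  invisible(lmat)
}
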