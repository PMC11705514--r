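mini_table <- function() {
  data.frame(
    sample = rep(c("s1", "s2"), each = 5),
    time = rep(c("NBF", "12H"), each = 5),
    nucleoside = rep(c("A", "C", "G", "U", "manQ"), 2),
    area = c(25, 5, 5, 5, 10,
             50, 10, 10, 10, 40),
    stringsAsFactors = FALSE
  )
}

test_that("normalization divides by the canonical-area sum", {
  norm <- normalize_abundance(mini_table())
  expect_equal(norm$norm_abundance[norm$sample == "s1" &
                                     norm$nucleoside == "manQ"], 0.25)
  # canonical abundances sum to exactly 1 per sample
  for (s in c("s1", "s2")) {
    canon <- norm$norm_abundance[norm$sample == s &
                                   norm$nucleoside %in% c("A", "C", "G", "U")]
    expect_identical(sum(canon), 1)
  }
})

test_that("normalization is invariant to per-sample rescaling", {
  tab <- mini_table()
  scaled <- tab
  scaled$area[scaled$sample == "s1"] <- scaled$area[scaled$sample == "s1"] * 7.3
  expect_equal(normalize_abundance(scaled)$norm_abundance,
               normalize_abundance(tab)$norm_abundance)
})

test_that("normalization fails loudly on bad canonical areas", {
  tab <- mini_table()
  tab$area[tab$sample == "s1" & tab$nucleoside %in% c("A", "C", "G", "U")] <- 0
  expect_error(normalize_abundance(tab), "s1")
  tab2 <- mini_table()[-1, ]  # drop A of s1
  expect_error(normalize_abundance(tab2), "missing canonical")
})

test_that("missing modifications stay NA, not zero", {
  tab <- mini_table()
  tab$area[tab$sample == "s2" & tab$nucleoside == "manQ"] <- NA
  norm <- normalize_abundance(tab)
  expect_true(is.na(norm$norm_abundance[norm$sample == "s2" &
                                          norm$nucleoside == "manQ"]))
})

test_that("fold change is mean ratio versus the reference, identity at NBF", {
  norm <- normalize_abundance(mini_table())
  fc <- fold_change(norm)
  manq <- fc[fc$nucleoside == "manQ", ]
  expect_equal(manq$fold_change[manq$time == "NBF"], 1)
  # 0.5 at 12H vs 0.25 at NBF
  expect_equal(manq$fold_change[manq$time == "12H"], 2)
  expect_error(fold_change(norm, reference = "96H"), "not present")
})

test_that("exact generator round-trip: zero noise recovers truths exactly", {
  sim <- sim_peak_areas(cv = 0, seed = 4)
  norm <- normalize_abundance(sim$table)
  fc <- fold_change(norm)
  for (m in names(sim$truth$mods)) {
    for (t in sim$truth$times) {
      expect_equal(fc$fold_change[fc$nucleoside == m & fc$time == t],
                   unname(sim$truth$mods[[m]]$fc[[t]]), tolerance = 1e-9)
    }
    expect_equal(norm$norm_abundance[norm$nucleoside == m &
                                       norm$time == "NBF"][1],
                 sim$truth$mods[[m]]$abundance, tolerance = 1e-9)
  }
})

test_that("per-nucleoside F equals the one-way ANOVA F on a toy table", {
  tab <- data.frame(
    sample = paste0("s", 1:6),
    time = rep(c("NBF", "12H", "24H"), each = 2),
    nucleoside = "X",
    norm_abundance = c(1.0, 1.2, 2.0, 2.1, 3.3, 2.9),
    stringsAsFactors = FALSE
  )
  res <- per_nucleoside_model(tab)
  ref <- summary(stats::aov(norm_abundance ~ factor(time), data = tab))[[1]]
  expect_equal(res$f_statistic, ref[["F value"]][1], tolerance = 1e-9)
  expect_equal(res$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-9)
})

test_that("identical values across time points give F = 0, p in the 1 region", {
  tab <- data.frame(
    sample = paste0("s", 1:6),
    time = rep(c("NBF", "12H", "24H"), each = 2),
    nucleoside = "X", norm_abundance = rep(0.5, 6),
    stringsAsFactors = FALSE
  )
  res <- per_nucleoside_model(tab)
  expect_equal(res$f_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
})

test_that("a strong planted effect is detected in nearly all seeded runs", {
  hits <- 0L
  for (seed in 1:50) {
    set.seed(seed)
    # delta mean = 10 x SD, n = 3 per group
    tab <- data.frame(
      sample = paste0("s", 1:6),
      time = rep(c("NBF", "12H"), each = 3),
      nucleoside = "X",
      norm_abundance = c(rnorm(3, 1, 0.1), rnorm(3, 2, 0.1)),
      stringsAsFactors = FALSE
    )
    if (per_nucleoside_model(tab)$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 49L)
})

test_that("rank-deficient time design errors with the factor named", {
  tab <- data.frame(sample = c("s1", "s2"), time = "NBF", nucleoside = "X",
                    norm_abundance = c(1, 2), stringsAsFactors = FALSE)
  expect_error(per_nucleoside_model(tab), "time")
})

test_that("interaction model reports Table-1-style per-term rows", {
  set.seed(8)
  times <- rep(c("NBF", "6H", "12H", "24H"), each = 3)
  treatment <- ifelse(times == "NBF", "NBF", "PBF")
  n <- length(times)
  expr_val <- rnorm(n, 10, 1)
  base <- data.frame(
    sample = paste0("s", seq_len(n)), time = times, treatment = treatment,
    stringsAsFactors = FALSE
  )
  # linked pair: modification level follows enzyme expression under treatment
  linked <- base
  linked$modification <- "Q"; linked$enzyme <- "QTRT2"
  linked$expression <- expr_val
  linked$mod_level <- 0.01 +
    ifelse(treatment == "PBF", 0.002 * (expr_val - 10), 0) + rnorm(n, 0, 1e-4)
  # null pair
  null <- base
  null$modification <- "m5C"; null$enzyme <- "NSUN2"
  null$expression <- rnorm(n, 10, 1)
  null$mod_level <- 0.03 + rnorm(n, 0, 1e-3)
  res <- interaction_model(rbind(linked, null))
  expect_true(all(c("modification", "enzyme", "stratum", "term",
                    "f_statistic", "p_value") %in% names(res)))
  # one row per (modification, enzyme, term)
  expect_identical(anyDuplicated(res[, c("modification", "enzyme", "stratum",
                                         "term")]), 0L)
  inter <- res[res$modification == "Q" & res$stratum == "treatment" &
                 res$term == "expression:treatment", ]
  expect_lt(inter$p_value, 0.05)
  null_inter <- res[res$modification == "m5C" & res$stratum == "treatment" &
                      res$term == "expression:treatment", ]
  expect_gt(null_inter$p_value, 0.05)
})

test_that("constant enzyme expression degenerates to the time-course ANOVA", {
  set.seed(9)
  times <- rep(c("NBF", "12H", "24H"), each = 3)
  n <- length(times)
  dat <- data.frame(
    sample = paste0("s", seq_len(n)), time = times,
    treatment = ifelse(times == "NBF", "NBF", "PBF"),
    modification = "X", enzyme = "E",
    expression = 5,  # constant
    mod_level = rnorm(n, rep(c(1, 2, 3), each = 3), 0.2),
    stringsAsFactors = FALSE
  )
  res <- interaction_model(dat)
  time_row <- res[res$stratum == "time" & res$term == "time", ]
  ref <- per_nucleoside_model(data.frame(
    sample = dat$sample, time = dat$time, nucleoside = "X",
    norm_abundance = dat$mod_level, stringsAsFactors = FALSE))
  expect_equal(time_row$f_statistic, ref$f_statistic, tolerance = 1e-9)
  expect_equal(time_row$p_value, ref$p_value, tolerance = 1e-9)
})

test_that("microarray probes average per gene and fold changes track NBF", {
  expr <- data.frame(
    probe = c("p1", "p2", "p1", "p2"),
    gene = "g1",
    sample = c("a", "a", "b", "b"),
    value = c(4, 6, 9, 11),
    stringsAsFactors = FALSE
  )
  st <- data.frame(sample = c("a", "b"), time = c("NBF", "12H"),
                   stringsAsFactors = FALSE)
  res <- microarray_fold_change(expr, st)
  expect_equal(res$gene_values$value, c(5, 10))
  fc <- res$fold_change
  expect_equal(fc$fold_change[fc$time == "NBF"], 1)
  expect_equal(fc$fold_change[fc$time == "12H"], 2)
})

test_that("planted expression effects are recovered with few false positives", {
  run_once <- function(seed) {
    set.seed(seed)
    genes <- sprintf("g%02d", 1:30)
    true_effect <- c(rep(TRUE, 15), rep(FALSE, 15))
    times <- rep(c("NBF", "12H", "24H"), each = 3)
    samples <- paste0("s", seq_along(times))
    rows <- list()
    for (gi in seq_along(genes)) {
      mu <- ifelse(times == "NBF", 10,
                   ifelse(rep(true_effect[gi], length(times)), 14, 10))
      for (p in c("p1", "p2")) {
        rows[[length(rows) + 1L]] <- data.frame(
          probe = paste0(genes[gi], "_", p), gene = genes[gi],
          sample = samples, value = rnorm(length(times), mu, 1),
          stringsAsFactors = FALSE)
      }
    }
    expr <- do.call(rbind, rows)
    st <- data.frame(sample = samples, time = times, stringsAsFactors = FALSE)
    model <- microarray_fold_change(expr, st)$model
    c(tp = sum(model$significant[model$gene %in% genes[true_effect]]),
      fp = sum(model$significant[model$gene %in% genes[!true_effect]]))
  }
  res <- t(vapply(1:20, run_once, c(tp = 0, fp = 0)))
  expect_gte(stats::median(res[, "tp"]), 14)
  expect_lte(stats::median(res[, "fp"]), 2)
})
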