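test_that("in-frame codon counting handles DNA/RNA, partials and ambiguity", {
  tab <- count_codons("ATGTATTACTAA")
  expect_identical(tab$count[tab$codon == "ATG"], 1L)
  expect_identical(tab$count[tab$codon == "TAT"], 1L)
  expect_identical(tab$count[tab$codon == "TAC"], 1L)
  expect_identical(tab$count[tab$codon == "TAA"], 1L)
  expect_identical(sum(tab$count), 4L)
  expect_equal(sum(tab$frequency), 1)

  # U and T are interchangeable
  expect_identical(count_codons("AUGUAUUACUAA")$count, tab$count)

  # empty input -> all-zero table
  empty <- count_codons(character(0))
  expect_true(all(empty$count == 0L))

  # trailing partial codon dropped with a warning
  expect_warning(t2 <- count_codons("ATGTA"), "partial codon")
  expect_identical(sum(t2$count), 1L)

  # ambiguous codons skipped and tallied
  t3 <- count_codons("ATGNNNTAC")
  expect_identical(sum(t3$count), 2L)
  expect_identical(attr(t3, "n_skipped"), 1L)
})

test_that("codon counting is additive over sequence sets", {
  set.seed(31)
  sets <- sim_cds_set(n_target = 3, n_reference = 3, codons_per_cds = 50,
                      seed = 31)
  a <- count_codons(sets$target)
  b <- count_codons(sets$reference)
  ab <- count_codons(c(sets$target, sets$reference))
  expect_identical(ab$count, a$count + b$count)
})

test_that("RSCU follows its definition with families and edge cases", {
  # Tyr family UAC 30 / UAU 10
  cds <- c(paste(rep("TAC", 30), collapse = ""),
           paste(rep("TAT", 10), collapse = ""))
  r <- rscu(count_codons(cds))
  expect_equal(r$rscu[r$codon == "TAC"], 1.5)
  expect_equal(r$rscu[r$codon == "TAT"], 0.5)
  # preference thresholds are strict: exactly 1.5 / 0.5 stay neutral
  expect_identical(r$preference[r$codon == "TAT"], "neutral")
  expect_identical(r$preference[r$codon == "TAC"], "neutral")
  cds2 <- c(paste(rep("TAC", 35), collapse = ""),
            paste(rep("TAT", 5), collapse = ""))
  r3 <- rscu(count_codons(cds2))
  expect_identical(r3$preference[r3$codon == "TAC"], "preferred")
  expect_identical(r3$preference[r3$codon == "TAT"], "unpreferred")
  # unobserved families are flagged undefined
  expect_true(is.na(r$rscu[r$codon == "GCA"]))
  # single-codon family is 1.0 whenever observed
  r2 <- rscu(count_codons("ATGATGATG"))
  expect_equal(r2$rscu[r2$codon == "ATG"], 1)
  # stop codons excluded from RSCU
  expect_true(all(is.na(r2$rscu[r2$aa == "Stp"])))
})

test_that("uniform usage gives RSCU 1 and family means are 1", {
  fam <- codon_families()
  sense <- fam$codon[fam$aa != "Stp"]
  r <- rscu(count_codons(paste(sense, collapse = "")))
  expect_true(all(abs(r$rscu[r$aa != "Stp"] - 1) < 1e-12))
  for (a in unique(fam$aa[fam$aa != "Stp"])) {
    expect_equal(mean(r$rscu[r$aa == a]), 1, tolerance = 1e-12)
  }
})

test_that("generator codon frequencies are recovered at scale", {
  sets <- sim_cds_set(n_target = 10, n_reference = 10,
                      codons_per_cds = 1000, tyr_factor = 2, seed = 17)
  tab <- count_codons(sets$target)
  tyr_freq <- sum(tab$frequency[tab$aa == "Tyr"])
  expect_equal(tyr_freq, sets$truth$tyr_freq_target, tolerance = 0.002)
})

test_that("Fisher enrichment matches the enumeration oracle and edge cases", {
  res <- enrichment_test(fam_table(20, 40), fam_table(10, 80))
  expect_equal(res$p_value, oracle_fisher_p(20, 40, 10, 80),
               tolerance = 1e-10)

  same <- enrichment_test(fam_table(15, 30), fam_table(15, 30))
  expect_equal(same$p_value, 1)
  expect_equal(unname(same$odds_ratio), 1, tolerance = 1e-6)

  expect_error(enrichment_test(fam_table(0, 10), fam_table(0, 20)),
               "zero marginal")
})

test_that("a doubled tyrosine codon frequency is detected as enrichment", {
  sets <- sim_cds_set(n_target = 20, n_reference = 20,
                      codons_per_cds = 300, tyr_factor = 2, seed = 23)
  res <- enrichment_test(count_codons(sets$target, "vg"),
                         count_codons(sets$reference, "rp"))
  expect_lt(res$p_value, 0.01)
  expect_gt(res$odds_ratio, 1)
})

test_that("null sets give well-behaved p-values across seeds", {
  ps <- vapply(1:100, function(seed) {
    sets <- sim_cds_set(n_target = 5, n_reference = 5,
                        codons_per_cds = 200, tyr_factor = 1, seed = seed)
    enrichment_test(count_codons(sets$target),
                    count_codons(sets$reference))$p_value
  }, 0)
  # under the null, small p-values are rare and the distribution is not
  # grossly non-uniform (the exact test's p-values are discrete, so the
  # KS check is a coarse sanity bound)
  expect_lte(sum(ps < 0.05), 12)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.001)
})
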