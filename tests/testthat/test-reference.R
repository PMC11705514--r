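write_trnascan_fixture <- function(path) {
  lines <- c(
    "Sequence\t\ttRNA\tBounds\ttRNA\tAnti\tIntron Bounds\tInf\t",
    "Name    \ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore\tNote",
    "--------\t------\t-----\t----\t----\t-----\t-----\t----\t------\t----",
    "chr1\t1\t11\t30\tPhe\tGAA\t0\t0\t80.2\t",
    "chr1\t2\t41\t70\tTyr\tGTA\t51\t58\t75.0\t",
    "chr1\t3\t120\t101\tAla\tAGC\t0\t0\t66.1\tpseudo"
  )
  writeLines(lines, path)
}

toy_genome <- function() {
  # 130-nt toy chromosome; gene 3 is on the minus strand
  set.seed(123)
  c(chr1 = paste(sample(c("A", "C", "G", "T"), 130, replace = TRUE),
                 collapse = ""))
}

test_that("tRNAscan-SE output parses with strand and intron handling", {
  tf <- tempfile(fileext = ".out")
  on.exit(unlink(tf))
  write_trnascan_fixture(tf)
  genome <- toy_genome()
  genes <- parse_trnascan(tf, genome = genome)
  expect_identical(nrow(genes), 3L)
  expect_identical(sum(!is.na(genes$intron_start)), 1L)

  # intron 0,0 convention: no intron
  expect_true(is.na(genes$intron_start[1]))
  # plus-strand intron converted to sequence-local coordinates
  expect_identical(genes$intron_start[2], 51L - 41L + 1L)
  expect_identical(genes$intron_end[2], 58L - 41L + 1L)

  # minus-strand gene: stored sequence is the reverse complement (oracle)
  expect_identical(genes$strand[3], "-")
  expected <- paste(rev(chartr("ACGT", "TGCA",
                               strsplit(substr(genome[["chr1"]], 101, 120),
                                        "")[[1]])), collapse = "")
  expect_identical(genes$sequence[3], expected)

  # high-confidence filter consumes the pseudo note
  expect_identical(genes$high_confidence, c(TRUE, TRUE, FALSE))
  hc <- parse_trnascan(tf, genome = genome, high_confidence_only = TRUE)
  expect_identical(nrow(hc), 2L)
})

test_that("malformed rows are reported with their line number", {
  tf <- tempfile(fileext = ".out")
  on.exit(unlink(tf))
  writeLines(c("chr1\t1\t11\t30\tPhe", "chr1\t2\t41\tx\ty"), tf)
  expect_error(parse_trnascan(tf), "line 1")
})

test_that("minus-strand intron coordinates map into the sense sequence", {
  tf <- tempfile(fileext = ".out")
  on.exit(unlink(tf))
  writeLines(c(
    "chr1\t1\t40\t11\tTyr\tGTA\t30\t25\t70.0\t"
  ), tf)
  genes <- parse_trnascan(tf)
  # 5' end of the sense strand is genomic position 40
  expect_identical(genes$intron_start[1], 40L - 30L + 1L)
  expect_identical(genes$intron_end[1], 40L - 25L + 1L)
})

test_that("mature sequences drop the intron and gain CCA", {
  gene85 <- paste(rep("A", 85), collapse = "")
  m <- mature_sequence(gene85, 38, 50)  # 13-nt intron
  expect_identical(nchar(m), 85L - 13L + 3L)
  expect_true(endsWith(m, "CCA"))

  gene72 <- paste(rep("G", 72), collapse = "")
  expect_identical(nchar(mature_sequence(gene72)), 75L)

  # generator truth: no mature sequence retains its marked intron
  sim <- sim_trna_genes(n_genes = 40, n_duplicates = 0, seed = 2)
  with_intron <- sim$genes[!is.na(sim$genes$intron_start), ]
  expect_gt(nrow(with_intron), 0)
  for (i in seq_len(nrow(with_intron))) {
    g <- with_intron[i, ]
    intron <- substr(g$sequence, g$intron_start, g$intron_end)
    m <- mature_sequence(g$sequence, g$intron_start, g$intron_end)
    expect_identical(nchar(m),
                     nchar(g$sequence) - nchar(intron) + 3L)
    expect_true(endsWith(m, "CCA"))
  }
})

test_that("dedupe collapses exact copies only and records provenance", {
  genes <- data.frame(
    gene_id = c("a", "b", "c"),
    sequence = c("ACGT", "ACGT", "ACGA"),
    stringsAsFactors = FALSE
  )
  dd <- dedupe_pre(genes)
  expect_identical(dd$unique$gene_id, c("a", "c"))
  expect_identical(dd$duplicates$gene_id, "b")
  expect_identical(dd$duplicates$kept_as, "a")

  sim <- sim_trna_genes(n_genes = 200, n_duplicates = 42, seed = 3)
  dd2 <- dedupe_pre(sim$genes)
  expect_identical(nrow(dd2$unique), 158L)
})

test_that("TPM threshold is strict and exclusivity uses condition means", {
  tpm <- data.frame(
    transcript = rep(c("t1", "t2", "t3"), each = 4),
    sample = rep(c("n1", "n2", "b1", "b2"), 3),
    condition = rep(c("NBF", "NBF", "PBF", "PBF"), 3),
    tpm = c(1.0, 1.0, 1.0, 1.0,    # exactly 1 -> not expressed anywhere
            0.0, 0.2, 5.0, 7.0,    # PBF-exclusive
            2.0, 3.0, 4.0, 5.0),   # expressed in both
    stringsAsFactors = FALSE
  )
  res <- expression_calls(tpm)
  calls <- res$calls
  expect_true(all(calls$status[calls$transcript == "t1"] == "not expressed"))
  expect_identical(res$exclusive$PBF, "t2")
  expect_identical(res$exclusive$NBF, character(0))
  expect_equal(calls$mean_tpm[calls$transcript == "t2" &
                                calls$condition == "PBF"], 6)
  expect_error(expression_calls(transform(tpm, tpm = tpm - 2)), "negative")
})

test_that("reference FASTA files round-trip byte-exactly", {
  sim <- sim_trna_genes(n_genes = 30, n_duplicates = 5, seed = 6)
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  ref <- build_reference(sim$genes, dir)
  mature <- read_fasta(ref$mature)
  pre <- read_fasta(ref$pre)
  expect_identical(unname(mature), ref$mature_table$sequence)
  expect_identical(names(mature), ref$mature_table$gene_id)
  expect_identical(unname(pre), ref$pre_table$sequence)
  # every mature sequence ends in CCA; precursors are untouched gene bodies
  expect_true(all(endsWith(mature, "CCA")))
  expect_identical(unname(pre),
                   sim$genes$sequence[match(names(pre), sim$genes$gene_id)])
})
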