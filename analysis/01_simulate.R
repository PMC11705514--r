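#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emits a tRNA gene set with introns and planted duplicate genes, a
# nucleoside peak-area table over the blood-feeding time course, codon-
# biased CDS sets (vitellogenin-like vs ribosomal-protein-like), and
# noiseless + decoy-laden fragment spectra for the tyrosine anticodon
# digestion products. Everything is seeded, and each generator's truth
# table is written next to its data.

suppressMessages(library(modomap))

SEED <- 101
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genes <- sim_trna_genes(n_genes = 200, n_duplicates = 42, seed = SEED)
write.csv(genes$truth, file.path(out, "trna_genes_truth.csv"),
          row.names = FALSE)
cat(sprintf("tRNA genes: %d total, %d planted duplicates, %d with introns\n",
            nrow(genes$genes), sum(!is.na(genes$truth$duplicate_of)),
            sum(!is.na(genes$genes$intron_start))))

areas <- sim_peak_areas(seed = SEED)
write.csv(areas$table, file.path(out, "peak_areas.csv"), row.names = FALSE)
cat(sprintf("peak areas: %d rows (%d time points x %d replicates), CV %.0f%%\n",
            nrow(areas$table), length(areas$truth$times),
            areas$truth$n_rep, 100 * areas$truth$cv))

cds <- sim_cds_set(n_target = 20, n_reference = 20, codons_per_cds = 300,
                   tyr_factor = 2, seed = SEED)
writeLines(unlist(lapply(names(cds$target), function(n)
  c(paste0(">", n), cds$target[[n]]))), file.path(out, "vg_like.fasta"))
writeLines(unlist(lapply(names(cds$reference), function(n)
  c(paste0(">", n), cds$reference[[n]]))), file.path(out, "rp_like.fasta"))
cat(sprintf("CDS sets: truth Tyr codon fraction %.4f (target) vs %.4f (reference)\n",
            cds$truth$tyr_freq_target, cds$truth$tyr_freq_reference))

for (prod in c("ACU[manQ]UAGp", "U[manQ]UAGAUCC>p")) {
  clean <- sim_spectrum(prod, seed = SEED)
  noisy <- sim_spectrum(prod, decoy_ratio = 10, seed = SEED + 1)
  safe <- gsub("[^A-Za-z0-9]", "_", prod)
  write.table(clean$peaks, file.path(out, paste0(safe, "_clean.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(noisy$peaks, file.path(out, paste0(safe, "_decoy.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
}
cat("spectra written for both anticodon digestion products\n")
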