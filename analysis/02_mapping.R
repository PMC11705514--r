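#!/usr/bin/env Rscript
# Stage 2: in-silico digestion, mass prediction and modification mapping.
#
# Digests the tyrosine tRNA anticodon arm with RNase T1 and cusativin,
# predicts product masses and negative-mode m/z, confirms the charge
# state behind the printed integer m/z values, and localizes the wobble
# modification from simulated fragment spectra.

suppressMessages(library(modomap))

SEED <- 101
out <- "results/mapping"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# anticodon-arm parents with mannosyl-queuosine at the wobble position
db_t1 <- list(Tyr_arm = "GGACU[manQ]UAGAUCCUUG")
db_cus <- list(Tyr_arm_manQ = "ACU[manQ]UAGAUCCAAC",
               Tyr_arm_Q = "ACU[Q]UAGAUCCAAC",
               Tyr_arm_unmod = "ACUGUAGAUCCAAC")

res_t1 <- run_mapping(db_t1, RNASE_T1, out_dir = file.path(out, "t1"))
res_cus <- run_mapping(db_cus, CUSATIVIN, out_dir = file.path(out, "cusativin"))

key <- c("ACU[manQ]UAGp", "U[manQ]UAGAUCC>p", "U[Q]UAGAUCC>p", "UGUAGAUCC>p")
prods <- rbind(res_t1$products, res_cus$products)
sel <- prods[match(key, prods$product), c("product", "mass", "mz_z3")]
sel$mz_z3_rounded <- round(sel$mz_z3)
write.csv(sel, file.path(out, "anticodon_products_mz.csv"), row.names = FALSE)
cat("anticodon digestion products (charge 3-):\n")
print(sel, row.names = FALSE)

# uniqueness of the diagnostic products against a small decoy database
decoys <- list(Phe_arm = "GGACUGAAAAUCCUUG", Ala_arm = "GGACUUGCAAUCCUUG")
u <- product_uniqueness(c(db_t1, decoys), RNASE_T1, "ACU[manQ]UAGp")
cat(sprintf("\nT1 product ACU[manQ]UAGp found in %d/%d database sequences\n",
            as.integer(u), length(db_t1) + length(decoys)))

# localization from simulated spectra: clean and at 10:1 decoy ratio
for (decoy_ratio in c(0, 10)) {
  pl <- sim_spectrum("U[manQ]UAGAUCC>p", decoy_ratio = decoy_ratio,
                     seed = SEED)
  ranked <- localize(pl, "UGUAGAUCC>p", "manQ", tol = 0.5)
  cat(sprintf("\nlocalization (decoy ratio %d): top placement position %s, score %.3f\n",
              decoy_ratio, format(ranked$position[1]), ranked$score[1]))
  write.csv(ranked, file.path(out, sprintf("localization_decoy%d.csv",
                                           decoy_ratio)),
            row.names = FALSE)
}
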