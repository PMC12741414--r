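#!/usr/bin/env Rscript
# Generate the synthetic repertoire: a V2R-like family grown from three
# founders by tandem duplication (p = 0.9) with occasional dispersal,
# plus hit tables, domain table, supports and a TPM matrix.  All later
# stages read the files written here.

library(chemorep)

out <- "results/sim"
sim <- simulate_repertoire(sim_config(seed = 1))
write_sim_truth(sim, out)

tc <- true_clades(sim)
cat(sprintf("simulated %d family genes (+%d decoys) on %d scaffolds\n",
            nrow(sim$genes), length(sim$decoy_ids),
            length(unique(sim$genes$scaffold))))
cat("true clade sizes:\n")
print(table(tc))
cat(sprintf("files written under %s\n", out))
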