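#!/usr/bin/env Rscript
# Simulate the default cross-perturbation tag-count experiment (five
# conditions, duplicated control and primary knockdown, planted response
# classes, artifacts and contaminants) and write the count tables plus
# ground truth under results/simulation/.

suppressPackageStartupMessages(library(dgescreen))

out <- "results/simulation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 20260922L)
sim <- simulate_experiment(cfg)

for (cond in names(sim$tables)) {
  write_count_table(sim$tables[[cond]],
                    file.path(out, paste0("counts_", cond, ".tsv")))
}
write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

tab <- table(sim$truth$label)
cat("Simulated", cfg$n_genes, "genes across",
    length(cfg$library_sizes), "libraries (mean depth",
    round(unname(cfg$library_sizes[1]) / cfg$n_genes), "reads/gene).\n")
cat("Planted labels:\n")
print(tab)
cat("Count tables and truth written to", out, "\n")
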