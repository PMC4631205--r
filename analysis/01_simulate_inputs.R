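#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume and write
# them in the same formats real inputs would arrive in: the enterocyte toy
# model as SBML, merged differential-expression and diet tables as TSV, and
# a two-group metabolite panel. Everything is a pure function of the seed.

suppressMessages(library(gutflux))
seed <- 1
out <- "results/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ep <- make_toy_gem("epithelium")
save_model(ep, file.path(out, "enterocyte_toy.xml"))
save_model(ep, file.path(out, "enterocyte_toy.tsv"), format = "toy_tsv")

de <- make_de_table(ep, fraction_up = 0, fraction_down = 1, seed = seed)
write.table(de$de, file.path(out, "de_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(de$truth, file.path(out, "de_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

pair <- make_crossfeed_pair()
save_model(pair$producer$model, file.path(out, "producer.xml"))
save_model(pair$consumer$model, file.path(out, "consumer.xml"))
write.table(pair$diet$components, file.path(out, "diet.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(pair$diet$aa_profile, file.path(out, "diet_aa_profile.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

mets <- make_metabolomics(n_analytes = 20, n_per_group = 6,
                          effect_sizes = c(rep(2, 4), rep(0, 16)),
                          seed = seed)
write.table(mets$data, file.path(out, "metabolomics.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Enterocyte toy:", nrow(ep$reactions), "reactions,",
    nrow(ep$metabolites), "metabolites,", length(model_genes(ep)),
    "genes; chylomicron optimum", fba(ep)$objective_value, "\n")
cat("Inputs written under", out, "\n")
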