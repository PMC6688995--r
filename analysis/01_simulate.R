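#!/usr/bin/env Rscript
# Stage 1: simulate the annotated genome corpus the downstream stages
# analyze -- 200 multi-contig assemblies with planted marker (FIX-like) and
# toxin (PoNe-like) loci, downstream immunity genes, T6SS clusters,
# contig-end truncations and duplicated contigs, plus the ground truth for
# every planted domain.

suppressMessages(library(toxscan))

cfg <- simulation_config(seed = 7L)  # the study conditions: 200 genomes
corp <- generate_corpus(cfg)

dir.create("results/corpus", recursive = TRUE, showWarnings = FALSE)
write_feature_table(corp$features, "results/corpus/features.tsv")
write_fasta(corp$proteome, "results/corpus/proteome.faa")
write_domain_annotations(corp$annotations, "results/corpus/annotations.tsv")
toxscan:::write_tsv_dialect(corp$truth, "results/corpus/truth.tsv")

tab <- table(corp$truth$planted_domain)
cat("assemblies:           ", length(unique(corp$features$assembly_id)), "\n")
cat("contigs:              ", length(unique(paste(corp$features$assembly_id,
                                                  corp$features$contig_id))),
    "\n")
cat("proteins:             ", length(corp$proteome), "\n")
cat("planted domains:      ",
    paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
tox <- corp$truth[corp$truth$planted_domain == "PoNe", ]
cat("toxin loci:           ", nrow(tox), " (", sum(tox$should_survive),
    "expected to survive curation )\n")
cat("wrote results/corpus/{features.tsv,proteome.faa,annotations.tsv,truth.tsv}\n")
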