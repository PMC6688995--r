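#!/usr/bin/env Rscript
# Stage 5: T6SS classification (>= 9 of 11 core-component COGs per
# assembly) and marker/T6SS co-occurrence, on the corpus and on the
# deterministic preset mirroring the published genome table.

suppressMessages(library(toxscan))

features <- read_feature_table("results/corpus/features.tsv")
annotations <- read_domain_annotations("results/corpus/annotations.tsv")
kept_fix <- toxscan:::read_tsv_dialect("results/kept_fix.tsv")

calls <- detect_components(features, annotations)
out <- calls[c("assembly_id", "n_components", "vgrg_present", "is_t6ss")]
toxscan:::write_tsv_dialect(out, "results/t6ss_calls.tsv")
cooc <- cooccurrence(kept_fix[c("assembly_id", "contig_id", "protein_id")],
                     calls)
cat(sprintf("corpus: %d/%d marker genomes are T6SS-positive (%.2f%%)\n",
            cooc$n_with_t6ss, cooc$n_marker_genomes, cooc$percent))

co <- preset_t6ss_cooccurrence()
pub <- cooccurrence(co$loci, detect_components(co$protein_assembly,
                                               co$annotations))
cat(sprintf("published genome structure: %.2f%% co-occurrence (> 96%%)\n",
            pub$percent))
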