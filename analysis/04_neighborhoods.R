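#!/usr/bin/env Rscript
# Stage 4: strand-aware genomic neighborhoods. Effector/immunity pairing of
# the curated toxin loci and the upstream-domain summary of the curated
# marker loci on the simulated corpus, then the same statistics on the
# deterministic presets mirroring the published locus tables.

suppressMessages(library(toxscan))

features <- read_feature_table("results/corpus/features.tsv")
annotations <- read_domain_annotations("results/corpus/annotations.tsv")
loci_cols <- c("assembly_id", "contig_id", "protein_id")

kept_pone <- toxscan:::read_tsv_dialect("results/kept_pone.tsv")
pairing <- pair_immunity(kept_pone[loci_cols], features, annotations)
toxscan:::write_tsv_dialect(pairing$loci, "results/pairing_loci.tsv")
cat(sprintf("corpus pairing: %d/%d toxin loci with downstream DUF1911 (%.2f%%)\n",
            pairing$summary$n_paired, pairing$summary$n_toxin_loci,
            pairing$summary$percent_paired))

kept_fix <- toxscan:::read_tsv_dialect("results/kept_fix.tsv")
upstream <- summarize_upstream_domains(kept_fix[loci_cols], features,
                                       annotations)
toxscan:::write_tsv_dialect(upstream$table, "results/upstream_domains.tsv")
cat(sprintf("corpus upstream: %d loci with same-strand upstream gene; %.2f%% T6SS components\n",
            upstream$n_upstream_loci, upstream$t6ss_component_percent))

# published locus structure (1546 toxin loci, 1389 paired)
pp <- preset_paper_pairing()
pub <- pair_immunity(pp$loci, pp$features, pp$annotations)
cat(sprintf("published pairing structure: %.2f%% (1389/1546)\n",
            pub$summary$percent_paired))

up <- preset_upstream_domains()
s <- summarize_upstream_domains(up$loci, up$features, up$annotations)
cat(sprintf("published upstream structure: %.2f%% T6SS components; %.2f%% PAAR/DUF4280 markers\n",
            s$t6ss_component_percent,
            marker_paar_share(up$loci, up$annotations)))
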