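#!/usr/bin/env Rscript
# Stage 6: reference-anchored alignment of the curated toxin proteins,
# per-column information content over the motif window (294-354 in
# archetype numbering) and consensus-motif extraction.

suppressMessages(library(toxscan))

proteome <- read_fasta("results/corpus/proteome.faa")
kept <- toxscan:::read_tsv_dialect("results/kept_pone.tsv")
arch <- reference_archetype()

ids <- unique(kept$protein_id)
ids <- ids[nchar(proteome[ids]) >= arch$pone_region[2]]
msa <- anchor_msa(arch$sequence, proteome[ids], reference_id = "archetype")

lt <- logo_table(msa, window = arch$motif_window)
for (col in c("H", "IC", "top_freq", "gap_freq")) {
  lt[[col]] <- sprintf("%.4f", lt[[col]])
}
toxscan:::write_tsv_dialect(lt, "results/logo.tsv")

mot <- consensus_motif(msa, tau = 0.8, window = arch$motif_window)
writeLines(mot$motif, "results/motif.txt")
letters_got <- mot$tokens[mot$tokens$type == "residue", ]
cat("family members aligned:", length(ids), "\n")
cat("consensus motif (tau = 0.8):", mot$motif, "\n")
cat("conserved letters:", paste(letters_got$token, collapse = ""),
    "at positions", paste(letters_got$start, collapse = ","), "\n")
cat("catalytic aspartate at:",
    letters_got$start[letters_got$token == "D"], "\n")
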