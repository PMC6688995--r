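#!/usr/bin/env Rscript
# Stage 3: greedy incremental clustering (40% identity, 50% length ratio)
# of the sequences flanking the anchored domains -- N-terminal flanks for
# toxin-anchored proteins, C-terminal flanks for marker-anchored proteins.

suppressMessages(library(toxscan))

proteome <- read_fasta("results/corpus/proteome.faa")

cluster_arm <- function(kept_path, hits_path, side, tag) {
  kept <- toxscan:::read_tsv_dialect(kept_path)
  hits <- toxscan:::read_tsv_dialect(hits_path)
  ids <- unique(kept$protein_id)
  if (!length(ids)) return(invisible(NULL))
  h <- hits[match(ids, hits$protein_id), ]
  flanks <- data.frame(
    protein_id = ids,
    sequence = vapply(seq_along(ids), function(i) {
      extract_flank(proteome[[ids[i]]],
                    list(start = h$start[i], end = h$end[i]), side)$sequence
    }, character(1)),
    stringsAsFactors = FALSE)
  cl <- greedy_cluster(flanks)
  cl$identity <- sprintf("%.4f", cl$identity)
  toxscan:::write_tsv_dialect(cl, sprintf("results/clusters_%s.tsv", tag))
  sizes <- table(cl$cluster_id)
  cat(sprintf("%s flanks (%s-terminal): %d sequences -> %d clusters; largest %d\n",
              tag, side, nrow(cl), length(sizes), max(sizes)))
}

cluster_arm("results/kept_pone.tsv", "results/hits_pone.tsv", "N", "pone")
cluster_arm("results/kept_fix.tsv", "results/hits_fix.tsv", "C", "fix")
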