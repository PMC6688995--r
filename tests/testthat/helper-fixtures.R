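# Shared fixture builders and independent oracles. Everything is generated
# in code; no fixture files.

# Quick feature-table builder: genes is a data.frame with contig_id, strand,
# protein_id and optionally product / length_aa; coordinates are laid out
# left-to-right with the given intergenic gaps (default 50 bp).
make_features <- function(genes, assembly_id = "ASM", gaps = NULL) {
  genes$product <- genes$product %||% rep("hypothetical protein", nrow(genes))
  genes$length_aa <- genes$length_aa %||% rep(100L, nrow(genes))
  rows <- lapply(split(seq_len(nrow(genes)), genes$contig_id), function(ix) {
    g <- genes[ix, , drop = FALSE]
    gp <- if (is.null(gaps)) rep(50L, nrow(g)) else gaps[ix]
    prev_end <- 0L
    start <- integer(nrow(g)); end <- integer(nrow(g))
    for (i in seq_len(nrow(g))) {
      start[i] <- prev_end + gp[i] + 1L
      end[i] <- start[i] + 3L * g$length_aa[i] + 2L
      prev_end <- end[i]
    }
    data.frame(assembly_id = assembly_id, organism = "org",
               contig_id = g$contig_id, feature_index = seq_len(nrow(g)),
               start = start, end = end, strand = g$strand,
               protein_id = g$protein_id, product = g$product,
               length_aa = g$length_aa, stringsAsFactors = FALSE)
  })
  validate_feature_table(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_annotation <- function(protein_id, domain_name, start = 1L, end = 50L) {
  data.frame(protein_id = protein_id, domain_name = domain_name,
             start = start, end = end, score = 100, expect = 1e-20,
             source = "external-table", stringsAsFactors = FALSE)
}

random_protein <- function(len) {
  paste(sample(toxscan::AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# Brute-force per-residue window score oracle (independent of the compiled
# scan kernel).
oracle_window_scores <- function(protein, pssm) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(chars)
  L <- pssm$L
  if (n < L) return(numeric(0))
  vapply(seq_len(n - L + 1L), function(i) {
    s <- 0
    for (j in seq_len(L)) {
      a <- chars[i + j - 1L]
      if (a %in% colnames(pssm$scores)) s <- s + pssm$scores[j, a]
    }
    s
  }, numeric(1))
}

# Independent enumeration of the greedy clustering procedure: its own
# alignment calls and its own loop, no length prefilter shortcut.
oracle_greedy_cluster <- function(flanks, identity_threshold = 0.40,
                                  length_ratio = 0.50) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  ident <- function(a, b) {
    if (nchar(b) > nchar(a) || (nchar(b) == nchar(a) && b < a)) {
      tmp <- a; a <- b; b <- tmp
    }
    pa <- Biostrings::pairwiseAlignment(
      b, a, substitutionMatrix = BLOSUM62,
      gapOpening = 10, gapExtension = 0.5, type = "overlap")
    Biostrings::nmatch(pa) / min(nchar(a), nchar(b))
  }
  ord <- order(-nchar(flanks$sequence), flanks$protein_id)
  flanks <- flanks[ord, , drop = FALSE]
  reps <- character(0)
  assign_to <- integer(nrow(flanks))
  for (i in seq_len(nrow(flanks))) {
    best <- NA_integer_; best_id <- -1
    for (k in seq_along(reps)) {
      if (nchar(flanks$sequence[i]) / nchar(reps[k]) < length_ratio) next
      idk <- ident(flanks$sequence[i], reps[k])
      if (idk >= identity_threshold && idk > best_id) {
        best_id <- idk; best <- k
      }
    }
    if (is.na(best)) {
      reps <- c(reps, flanks$sequence[i])
      assign_to[i] <- length(reps)
    } else {
      assign_to[i] <- best
    }
  }
  data.frame(protein_id = flanks$protein_id, cluster_id = assign_to,
             stringsAsFactors = FALSE)
}

# Random additive distance matrix from a random tree with positive branch
# lengths; returns list(tree, d).
random_additive_matrix <- function(n_taxa) {
  tree <- ape::rtree(n_taxa, br = function(n) runif(n, 0.1, 1))
  d <- ape::cophenetic.phylo(tree)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tree, d = d)
}

locus_key <- function(df) paste(df$assembly_id, df$contig_id, df$protein_id)
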