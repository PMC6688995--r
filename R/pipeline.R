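#' Pipeline configuration
#'
#' Collects every stage's parameters around one run seed. Defaults echo the
#' published protocol: 5 search iterations with a 500-hit cap, inclusion
#' expect 1e-6, report expect 1e-9, 80-aa toxin minimum, 40\% identity /
#' 50\% length clustering, 9-of-11 T6SS rule, motif window 294-354. The
#' conservation threshold for motif letters defaults to 0.8, the level that
#' separates the planted anchor conservation (1 - 0.1 * divergence) from
#' family background conservation (1 - divergence) at the simulated
#' divergence 0.3; see the methods vignette.
#'
#' @param seed run seed; all stage seeds derive from it via [derive_seed()]
#' @param simulation a [simulation_config()] (its own seed is overridden by
#'   the run seed derivation)
#' @param search a [search_config()]
#' @param curation a [curation_config()]
#' @param identity_threshold,length_ratio clustering thresholds
#' @param tau_cons conservation threshold for motif letters
#' @param motif_window reference window for the logo/motif stage
#' @param min_components T6SS classification threshold
#' @param tree_taxa,tree_sites size of the synthetic marker-gene alignment
#'   for the tree stage
#' @export
pipeline_config <- function(seed = 7L,
                            simulation = simulation_config(),
                            search = search_config(),
                            curation = curation_config(),
                            identity_threshold = 0.40,
                            length_ratio = 0.50,
                            tau_cons = 0.8,
                            motif_window = c(294L, 354L),
                            min_components = 9L,
                            tree_taxa = 24L,
                            tree_sites = 1200L) {
  list(seed = as.integer(seed), simulation = simulation, search = search,
       curation = curation, identity_threshold = identity_threshold,
       length_ratio = length_ratio, tau_cons = tau_cons,
       motif_window = as.integer(motif_window),
       min_components = as.integer(min_components),
       tree_taxa = as.integer(tree_taxa),
       tree_sites = as.integer(tree_sites))
}

format_hits <- function(h) {
  data.frame(protein_id = h$protein_id, profile = h$profile,
             start = h$start, end = h$end,
             bits = sprintf("%.3f", h$bits),
             expect = sprintf("%.6f", h$expect),
             stringsAsFactors = FALSE)
}

# Run one profile search + curation arm; returns empty structures on an
# empty proteome.
search_arm <- function(seed_seq, name, corpus, cfg, apply_length_rule) {
  empty_hits <- data.frame(protein_id = character(0), profile = character(0),
                           start = integer(0), end = integer(0),
                           bits = numeric(0), expect = numeric(0),
                           iteration = integer(0))
  if (length(corpus$proteome) == 0L) {
    return(list(hits = empty_hits,
                report = curation_report(
                  hits_to_loci(empty_hits, corpus$features),
                  data.frame(protein_id = character(0),
                             contig_id = character(0),
                             reason = character(0)))))
  }
  res <- iterate_search(seed_seq, corpus$proteome, cfg, name = name)
  report <- curate_hits(res$hits, corpus$features, apply_length_rule =
                          apply_length_rule)
  list(hits = res$hits, report = report, pssm = res$pssm)
}

#' Run the full pipeline
#'
#' Chains simulate -> scan (marker and toxin profiles) -> curate -> flank
#' clustering -> neighborhood pairing and upstream summary -> T6SS
#' classification and co-occurrence -> logo/motif -> tree, writing every
#' stage table into \code{out_dir} as it completes and finishing with a
#' manifest of md5 content hashes. All randomness derives from the single
#' run seed, so identical config + seed give byte-identical bundles.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory (created if missing)
#' @return the bundle as a list, invisibly; side effect: files under
#'   \code{out_dir}
#' @export
run_all <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  arch <- reference_archetype()

  sim <- config$simulation
  sim$seed <- derive_seed(config$seed, "simulate")
  corpus <- generate_corpus(sim)
  write_feature_table(corpus$features, file.path(out_dir, "features.tsv"))
  write_domain_annotations(corpus$annotations,
                           file.path(out_dir, "annotations.tsv"))
  write_tsv_dialect(corpus$truth, file.path(out_dir, "truth.tsv"))
  if (length(corpus$proteome)) {
    write_fasta(corpus$proteome, file.path(out_dir, "proteome.faa"))
  } else {
    writeLines(character(0), file.path(out_dir, "proteome.faa"))
  }

  scfg <- config$search
  scfg$seed <- derive_seed(config$seed, "search")
  pone_seed <- substr(arch$sequence, arch$pone_region[1], arch$pone_region[2])
  fix_seed <- substr(arch$sequence, 1L, arch$pone_region[1] - 1L)
  pone <- search_arm(pone_seed, "PoNe", corpus, scfg, TRUE)
  fix <- search_arm(fix_seed, "FIX", corpus, scfg, FALSE)
  write_tsv_dialect(format_hits(pone$hits), file.path(out_dir, "hits_pone.tsv"))
  write_tsv_dialect(format_hits(fix$hits), file.path(out_dir, "hits_fix.tsv"))
  for (arm in list(list(r = pone$report, tag = "pone"),
                   list(r = fix$report, tag = "fix"))) {
    kept <- arm$r$kept
    kept$bits <- sprintf("%.3f", kept$bits)
    kept$expect <- sprintf("%.6f", kept$expect)
    write_tsv_dialect(kept, file.path(out_dir,
                                      paste0("kept_", arm$tag, ".tsv")))
    write_tsv_dialect(arm$r$removed,
                      file.path(out_dir, paste0("removed_", arm$tag, ".tsv")))
  }

  # flanks: toxin proteins cluster by the sequence N-terminal to the toxin
  # domain, marker proteins by the sequence C-terminal to the marker
  flank_frame <- function(hits, kept, side) {
    ids <- unique(kept$protein_id)
    h <- hits[match(ids, hits$protein_id), , drop = FALSE]
    seqs <- vapply(seq_along(ids), function(i) {
      extract_flank(corpus$proteome[[ids[i]]],
                    list(start = h$start[i], end = h$end[i]),
                    side)$sequence
    }, character(1))
    data.frame(protein_id = ids, sequence = seqs, stringsAsFactors = FALSE)
  }
  clusters_pone <- if (nrow(pone$report$kept)) {
    greedy_cluster(flank_frame(pone$hits, pone$report$kept, "N"),
                   config$identity_threshold, config$length_ratio)
  } else greedy_cluster(data.frame(protein_id = character(0),
                                   sequence = character(0)))
  clusters_fix <- if (nrow(fix$report$kept)) {
    greedy_cluster(flank_frame(fix$hits, fix$report$kept, "C"),
                   config$identity_threshold, config$length_ratio)
  } else clusters_pone[0, ]
  clusters_pone$profile <- rep("PoNe", nrow(clusters_pone))
  clusters_fix$profile <- rep("FIX", nrow(clusters_fix))
  cl_out <- rbind(clusters_pone, clusters_fix)
  cl_out <- cl_out[c("profile", setdiff(names(cl_out), "profile"))]
  cl_out$identity <- sprintf("%.4f", cl_out$identity)
  write_tsv_dialect(cl_out, file.path(out_dir, "clusters.tsv"))

  loci_cols <- c("assembly_id", "contig_id", "protein_id")
  pairing <- pair_immunity(pone$report$kept[loci_cols], corpus$features,
                           corpus$annotations)
  write_tsv_dialect(pairing$loci, file.path(out_dir, "pairing_loci.tsv"))
  pair_sum <- data.frame(n_toxin_loci = pairing$summary$n_toxin_loci,
                         n_paired = pairing$summary$n_paired,
                         percent_paired =
                           format_percent(pairing$summary$percent_paired))
  write_tsv_dialect(pair_sum, file.path(out_dir, "pairing_summary.tsv"))

  upstream <- summarize_upstream_domains(fix$report$kept[loci_cols],
                                         corpus$features, corpus$annotations)
  write_tsv_dialect(upstream$table, file.path(out_dir, "upstream_domains.tsv"))

  calls <- detect_components(corpus$features, corpus$annotations,
                             min_components = config$min_components)
  cooc <- cooccurrence(fix$report$kept[loci_cols], calls)
  calls_out <- calls[c("assembly_id", "n_components", "vgrg_present",
                       "is_t6ss")]
  write_tsv_dialect(calls_out, file.path(out_dir, "t6ss_calls.tsv"))
  write_tsv_dialect(
    data.frame(n_marker_genomes = cooc$n_marker_genomes,
               n_with_t6ss = cooc$n_with_t6ss,
               percent = format_percent(cooc$percent)),
    file.path(out_dir, "t6ss_cooccurrence.tsv"))

  tox_ids <- unique(pone$report$kept$protein_id)
  tox_ids <- tox_ids[nchar(corpus$proteome[tox_ids]) >= arch$pone_region[2]]
  motif <- NULL
  if (length(tox_ids)) {
    msa <- anchor_msa(arch$sequence, corpus$proteome[tox_ids],
                      reference_id = "archetype")
    lt <- logo_table(msa, window = config$motif_window)
    lt$H <- sprintf("%.4f", lt$H)
    lt$IC <- sprintf("%.4f", lt$IC)
    lt$top_freq <- sprintf("%.4f", lt$top_freq)
    lt$gap_freq <- sprintf("%.4f", lt$gap_freq)
    write_tsv_dialect(lt, file.path(out_dir, "logo.tsv"))
    motif <- consensus_motif(msa, tau = config$tau_cons,
                             window = config$motif_window)
    writeLines(motif$motif, file.path(out_dir, "motif.txt"))
  } else {
    write_tsv_dialect(data.frame(position = integer(0)),
                      file.path(out_dir, "logo.tsv"))
    writeLines(character(0), file.path(out_dir, "motif.txt"))
  }

  aln <- simulate_rpob_alignment(n_taxa = config$tree_taxa,
                                 n_sites = config$tree_sites,
                                 seed = derive_seed(config$seed, "tree"))
  sites <- select_conserved_sites(aln)
  tree <- nj_tree(mismatch_matrix(aln, sites))
  write_newick(tree, file.path(out_dir, "tree.nwk"))

  files <- sort(setdiff(list.files(out_dir), "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  write_tsv_dialect(manifest, file.path(out_dir, "manifest.tsv"))

  invisible(list(corpus = corpus, pone = pone, fix = fix,
                 clusters = list(pone = clusters_pone, fix = clusters_fix),
                 pairing = pairing, upstream = upstream, calls = calls,
                 cooccurrence = cooc, motif = motif, tree = tree,
                 manifest = manifest))
}
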