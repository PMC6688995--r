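# A fixture exercising every curation branch:
#  - contig c1: 3 genes, toxin hit on the middle CDS (survives)
#  - contig c2: toxin hit on the first CDS (contig end)
#  - contig c3: single-gene contig (both first and last)
#  - contigs d1/d1D: duplicated locus, same downstream product at the same
#    distance (dedupable); contigs d2/d2D: distances differ by 1 bp
#  - short79/short80: protein-length boundary; weak: expect boundary
curation_fixture <- function() {
  genes <- data.frame(
    contig_id = c("c1", "c1", "c1",
                  "c2", "c2", "c2",
                  "c3",
                  "d1", "d1", "d1", "d1D", "d1D", "d1D",
                  "d2", "d2", "d2", "d2D", "d2D", "d2D"),
    strand = "+",
    protein_id = c("up1", "mid", "dn1",
                   "first", "x2", "x3",
                   "solo",
                   "du1", "dup", "dd1", "du1", "dup", "dd1",
                   "eu1", "dup2", "ed1", "eu1", "dup2", "ed1"),
    product = c("h", "toxin", "immunity",
                "toxin", "h", "h",
                "toxin",
                "h", "toxin", "immunity", "h", "toxin", "immunity",
                "h", "toxin", "immunity", "h", "toxin", "immunity"),
    length_aa = 200L,
    stringsAsFactors = FALSE)
  gaps <- rep(50L, nrow(genes))
  gaps[genes$contig_id == "d2D"][3] <- 51L  # perturbed downstream distance
  feats <- make_features(genes, gaps = gaps)
  hits <- data.frame(
    protein_id = c("mid", "first", "solo", "dup", "dup2",
                   "short79", "short80", "weak"),
    profile = "PoNe", start = 1L, end = 50L,
    bits = 300, expect = c(0, 0, 0, 0, 0, 1e-12, 1e-9, 1e-8),
    stringsAsFactors = FALSE)
  extra <- make_features(data.frame(
    contig_id = "c9", strand = "+",
    protein_id = c("pad1", "short79", "short80", "weak", "pad2"),
    length_aa = c(100L, 79L, 80L, 200L, 100L),
    stringsAsFactors = FALSE))
  list(features = validate_feature_table(rbind(feats, extra)), hits = hits)
}

test_that("the expect and length thresholds are inclusive boundaries", {
  fx <- curation_fixture()
  loci <- hits_to_loci(fx$hits, fx$features)
  rep <- filter_expect_and_length(loci)
  r <- rep$removed
  expect_equal(r$reason[r$protein_id == "short79"], "length")
  expect_equal(r$reason[r$protein_id == "weak"], "expect")
  expect_true("short80" %in% rep$kept$protein_id)   # exactly 80 aa kept
  # expect exactly 1e-9 kept (boundary inclusive)
  expect_true("short80" %in% rep$kept$protein_id)
  # length rule applies to the toxin search only
  rep_fix <- filter_expect_and_length(loci, apply_length_rule = FALSE)
  expect_true("short79" %in% rep_fix$kept$protein_id)
})

test_that("contig-end hits are removed, including single-gene contigs", {
  fx <- curation_fixture()
  loci <- hits_to_loci(fx$hits, fx$features)
  rep <- drop_contig_end_hits(loci, fx$features)
  expect_true(all(c("first", "solo") %in% rep$removed$protein_id))
  expect_true(all(rep$removed$reason == "contig_end"))
  expect_true("mid" %in% rep$kept$protein_id)  # middle CDS of 3 survives
})

test_that("multi-contig duplicates collapse only at identical distance", {
  fx <- curation_fixture()
  loci <- hits_to_loci(fx$hits, fx$features)
  rep <- dedup_multi_contig(loci, fx$features)
  # dedupable pair: one kept on the lexicographically smallest contig
  dup_rows <- rep$kept[rep$kept$protein_id == "dup", ]
  expect_equal(nrow(dup_rows), 1L)
  expect_equal(dup_rows$contig_id, "d1")
  expect_equal(rep$removed$contig_id[rep$removed$protein_id == "dup"], "d1D")
  expect_true(all(rep$removed$reason == "duplicate"))
  # 50 vs 51 bp downstream distances: both copies kept
  expect_equal(nrow(rep$kept[rep$kept$protein_id == "dup2", ]), 2L)
})

test_that("each curation filter is idempotent", {
  fx <- curation_fixture()
  loci <- hits_to_loci(fx$hits, fx$features)
  for (f in list(function(x) filter_expect_and_length(x),
                 function(x) drop_contig_end_hits(x, fx$features),
                 function(x) dedup_multi_contig(x, fx$features))) {
    once <- f(loci)
    twice <- f(once$kept)
    expect_equal(nrow(twice$removed), 0L)
    expect_equal(twice$kept, once$kept)
  }
})

test_that("the kept set is invariant to filter order", {
  fx <- curation_fixture()
  loci <- hits_to_loci(fx$hits, fx$features)
  filters <- list(
    e = function(x) filter_expect_and_length(x)$kept,
    c = function(x) drop_contig_end_hits(x, fx$features)$kept,
    d = function(x) dedup_multi_contig(x, fx$features)$kept)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  results <- lapply(perms, function(p) {
    out <- loci
    for (i in p) out <- filters[[i]](out)
    sort(paste(out$protein_id, out$contig_id))
  })
  for (r in results[-1]) expect_identical(r, results[[1]])
})

test_that("curation recovers the generator's survival flags exactly", {
  corp <- generate_corpus(simulation_config(seed = 13L, n_genomes = 40L))
  truth <- corp$truth[corp$truth$planted_domain == "PoNe", ]
  # feed the planted loci themselves as hits: rule match must be exact
  hits <- data.frame(protein_id = unique(truth$protein_id),
                     profile = "PoNe", start = 283L, end = 449L,
                     bits = 400, expect = 0, stringsAsFactors = FALSE)
  rep <- curate_hits(hits, corp$features)
  expect_setequal(locus_key(rep$kept),
                  locus_key(truth[truth$should_survive, ]))
  reasons <- rep$removed
  end_truth <- truth[truth$at_contig_end, ]
  expect_setequal(paste(reasons$protein_id[reasons$reason == "contig_end"],
                        reasons$contig_id[reasons$reason == "contig_end"]),
                  paste(end_truth$protein_id, end_truth$contig_id))
  dup_truth <- truth[truth$dup_removed & !truth$at_contig_end, ]
  expect_setequal(paste(reasons$protein_id[reasons$reason == "duplicate"],
                        reasons$contig_id[reasons$reason == "duplicate"]),
                  paste(dup_truth$protein_id, dup_truth$contig_id))
})
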