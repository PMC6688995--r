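adjacency_fixture <- function() {
  make_features(data.frame(
    contig_id = "c1",
    strand = c("+", "+", "-", "+", "+", "+"),
    protein_id = sprintf("p%d", 1:6),
    stringsAsFactors = FALSE))
}

test_that("adjacency is strand-aware and strict by default", {
  ft <- adjacency_fixture()
  focal5 <- ft[ft$protein_id == "p5", ]
  nb <- adjacent_locus(ft, focal5, "down")
  expect_equal(nb$protein_id, "p6")       # + strand: index + 1
  expect_equal(nb$distance, 50L)          # gap-only bp distance
  # opposite-strand adjacent CDS yields none...
  focal2 <- ft[ft$protein_id == "p2", ]
  expect_null(adjacent_locus(ft, focal2, "down"))
  # ...unless opposite-strand genes are skipped
  nb2 <- adjacent_locus(ft, focal2, "down", skip_opposite = TRUE)
  expect_equal(nb2$protein_id, "p4")
  # minus-strand downstream runs towards lower indices
  focal3 <- ft[ft$protein_id == "p3", ]
  expect_null(adjacent_locus(ft, focal3, "down"))  # p2 is + strand
  # contig edges yield none
  expect_null(adjacent_locus(ft, ft[ft$protein_id == "p1", ], "up"))
  expect_null(adjacent_locus(ft, ft[ft$protein_id == "p6", ], "down"))
})

test_that("adjacency is antisymmetric on same-strand pairs", {
  corp <- generate_corpus(simulation_config(seed = 19L, n_genomes = 6L))
  ft <- corp$features
  for (i in seq_len(nrow(ft))) {
    focal <- ft[i, ]
    nb <- adjacent_locus(ft, focal, "down")
    if (is.null(nb)) next
    back <- adjacent_locus(ft, nb, "up")
    expect_equal(back$protein_id, focal$protein_id)
    expect_equal(back$distance, nb$distance)
  }
})

test_that("the pairing preset reproduces the published percentage", {
  pp <- preset_paper_pairing()
  res <- pair_immunity(pp$loci, pp$features, pp$annotations)
  expect_equal(res$summary$n_toxin_loci, 1546L)
  expect_equal(res$summary$n_paired, 1389L)
  expect_equal(res$summary$percent_paired, 89.84)
  # percent recomputes from the counts exactly, half-up at 2 decimals
  expect_equal(res$summary$percent_paired,
               round_half_up(100 * 1389 / 1546, 2))
  # DUF1910 flags only occur on paired loci
  expect_true(all(res$loci$paired[res$loci$duf1910]))
})

test_that("pairing counts match the generator's ground truth", {
  corp <- generate_corpus(simulation_config(seed = 29L, n_genomes = 40L))
  truth <- corp$truth[corp$truth$planted_domain == "PoNe", ]
  res <- pair_immunity(truth[c("assembly_id", "contig_id", "protein_id")],
                       corp$features, corp$annotations)
  expect_equal(res$summary$n_paired, sum(truth$paired_immunity))
  expect_identical(res$loci$paired, truth$paired_immunity)
})

test_that("zero toxin loci give an undefined percentage", {
  corp <- generate_corpus(simulation_config(seed = 3L, n_genomes = 2L))
  empty <- corp$truth[0, c("assembly_id", "contig_id", "protein_id")]
  res <- pair_immunity(empty, corp$features, corp$annotations)
  expect_equal(res$summary$n_toxin_loci, 0L)
  expect_true(is.na(res$summary$percent_paired))
  expect_identical(toxscan:::format_percent(res$summary$percent_paired), ".")
})

test_that("upstream summaries count component domains per locus", {
  # every upstream neighbor VgrG-annotated: share 100
  ft <- make_features(data.frame(
    contig_id = c("c1", "c1", "c2", "c2"), strand = "+",
    protein_id = c("u1", "f1", "u2", "f2"), stringsAsFactors = FALSE))
  loci <- data.frame(assembly_id = "ASM", contig_id = c("c1", "c2"),
                     protein_id = c("f1", "f2"), stringsAsFactors = FALSE)
  ann <- make_annotation(c("u1", "u2"), "VgrG")
  s <- summarize_upstream_domains(loci, ft, ann)
  expect_equal(s$t6ss_component_percent, 100)
  expect_equal(s$table$count[s$table$domain_name == "VgrG"], 2L)
  # no upstream neighbors at all: empty table
  ft2 <- make_features(data.frame(contig_id = c("c1", "c2"), strand = "+",
                                  protein_id = c("f1", "f2"),
                                  stringsAsFactors = FALSE))
  s2 <- summarize_upstream_domains(loci, ft2, ann)
  expect_equal(s2$n_upstream_loci, 0L)
  expect_true(is.na(s2$t6ss_component_percent))
})

test_that("the upstream preset reproduces both published shares", {
  up <- preset_upstream_domains()
  s <- summarize_upstream_domains(up$loci, up$features, up$annotations)
  expect_equal(s$n_upstream_loci, 2100L)
  expect_equal(s$t6ss_component_percent, 70.14)
  expect_equal(marker_paar_share(up$loci, up$annotations), 3.71)
})

test_that("the configured upstream component rate is recovered", {
  cfg <- simulation_config(seed = 37L, n_genomes = 220L)
  corp <- generate_corpus(cfg)
  loci <- corp$truth[corp$truth$planted_domain == "FIX",
                     c("assembly_id", "contig_id", "protein_id")]
  s <- summarize_upstream_domains(loci, corp$features, corp$annotations)
  p <- cfg$upstream_t6ss_rate
  half_ci <- 2.576 * sqrt(p * (1 - p) / s$n_upstream_loci) * 100
  expect_lt(abs(s$t6ss_component_percent - 100 * p), half_ci)
})

test_that("signal peptide calls require both predictors", {
  expect_true(signal_peptide_consensus(TRUE, TRUE))
  expect_false(signal_peptide_consensus(TRUE, FALSE))
  expect_false(signal_peptide_consensus(FALSE, TRUE))
  expect_false(signal_peptide_consensus(FALSE, FALSE))
  expect_false(signal_peptide_consensus(NA, TRUE))  # missing call is FALSE
})

test_that("architecture labels follow precedence and position rules", {
  # LXG N-terminal to the toxin
  ann <- make_annotation("p", "LXG", 1L, 200L)
  expect_equal(classify_architecture(ann, toxin_start = 283L)$label, "LXG")
  # a delivery domain C-terminal to the toxin does not count
  ann2 <- make_annotation("p", "PAAR", 300L, 340L)
  expect_equal(classify_architecture(ann2, toxin_start = 283L)$label, "none")
  # PAAR precedes LXG when both qualify
  ann3 <- rbind(make_annotation("p", "LXG", 1L, 200L),
                make_annotation("p", "PAAR", 10L, 50L))
  expect_equal(classify_architecture(ann3, toxin_start = 283L)$label, "PAAR")
  # SP via the two-predictor consensus, no other domain
  ann4 <- rbind(make_annotation("p", "Phobius", 1L, 25L),
                make_annotation("p", "SignalP", 1L, 22L))
  expect_equal(classify_architecture(ann4, toxin_start = 283L)$label, "SP")
  # one predictor alone is not enough
  ann5 <- make_annotation("p", "Phobius", 1L, 25L)
  expect_equal(classify_architecture(ann5, toxin_start = 283L)$label, "none")
  # classification is order-independent
  expect_equal(classify_architecture(ann3[2:1, ], 283L)$label, "PAAR")
})
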