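uniform_q <- setNames(rep(0.05, 20), sort(toxscan::AA_ALPHABET))

test_that("pseudocounted log-odds match the closed form", {
  p <- build_pssm(rep("G", 10), alpha = 1, q = uniform_q)
  expect_equal(p$L, 1L)
  # f_G = (10 + 0.05) / 11, score = log2(f/q)
  expect_equal(unname(p$scores[1, "G"]), log2(((10 + 0.05) / 11) / 0.05),
               tolerance = 1e-12)
  expect_equal(unname(p$scores[1, "G"]), 4.192, tolerance = 1e-3)
  expect_equal(unname(p$scores[1, "A"]), log2((0.05 / 11) / 0.05),
               tolerance = 1e-12)
  expect_equal(unname(p$scores[1, "A"]), -3.459, tolerance = 1e-3)
  # per-column frequency simplex
  expect_equal(unname(rowSums(p$freqs)), 1)
  expect_true(all(is.finite(p$scores)))
})

test_that("a column with background frequencies scores zero", {
  # an all-gap column has N_j = 0, so f = q and every score is 0
  p <- build_pssm(c("-A", "-C"), alpha = 1)
  expect_equal(unname(p$scores[1, ]), rep(0, 20))
  expect_error(build_pssm(character(0)), "empty alignment")
  expect_error(build_pssm("AC", alpha = 0), "alpha")
})

test_that("the single-row toxin-region seed yields a 167-column profile", {
  arch <- reference_archetype()
  pone <- substr(arch$sequence, arch$pone_region[1], arch$pone_region[2])
  expect_equal(nchar(pone), 167L)
  expect_equal(build_pssm(pone)$L, 167L)
})

test_that("profile rebuilds are deterministic bit-for-bit", {
  rows <- c("ACDEFGHIK", "ACDEFGHIW", "ACDEYGHIK")
  expect_identical(build_pssm(rows), build_pssm(rows))
})

test_that("window scores equal the brute-force per-residue sum", {
  withr::local_seed(21)
  pssm <- build_pssm(vapply(1:4, function(i) random_protein(12L),
                            character(1)))
  prot <- random_protein(40L)
  expected <- oracle_window_scores(prot, pssm)
  hits <- scan_protein(prot, pssm)
  expect_equal(max(hits$bits), max(expected), tolerance = 1e-10)
  one <- random_protein(12L)  # exactly one window
  h1 <- scan_protein(one, pssm)
  expect_equal(h1$bits, oracle_window_scores(one, pssm), tolerance = 1e-10)
  expect_equal(h1$start, 1L)
  expect_equal(h1$end, 12L)
})

test_that("proteins shorter than the profile yield no windows", {
  pssm <- build_pssm("ACDEFGHIKL")
  expect_equal(nrow(scan_protein("ACD", pssm)), 0L)
})

test_that("reported hits are non-overlapping and sorted by score", {
  withr::local_seed(8)
  pssm <- build_pssm(rep("KKKKK", 3))
  prot <- paste0("KKKKK", random_protein(20L), "KKKKK")
  hits <- scan_protein(prot, pssm, min_bits = 0)
  expect_true(all(diff(hits$bits) <= 0))
  if (nrow(hits) > 1) {
    starts <- sort(hits$start)
    expect_true(all(diff(starts) >= pssm$L))
  }
})

test_that("the planted toxin domain is localized exactly", {
  arch <- reference_archetype()
  pone <- substr(arch$sequence, 283, 449)
  pssm <- build_pssm(pone, name = "PoNe")
  top <- scan_protein(arch$sequence, pssm)[1, ]
  expect_equal(top$start, 283L)
  expect_equal(top$end, 449L)
  # marker profile localizes at position 1 of the marker region seed
  fixp <- build_pssm(substr(arch$sequence, 1, 282), name = "FIX")
  topf <- scan_protein(arch$sequence, fixp)[1, ]
  expect_equal(topf$start, 1L)
})

test_that("seeded shuffles score strictly below the planted sequence", {
  arch <- reference_archetype()
  pone <- substr(arch$sequence, 283, 449)
  pssm <- build_pssm(pone)
  planted <- scan_protein(arch$sequence, pssm)$bits[1]
  chars <- strsplit(arch$sequence, "")[[1]]
  withr::local_seed(99)
  for (i in 1:100) {
    shuf <- paste(sample(chars), collapse = "")
    expect_lt(scan_protein(shuf, pssm)$bits[1], planted)
  }
})

test_that("empirical E-values behave as defined on the decoy sample", {
  arch <- reference_archetype()
  pssm <- build_pssm(substr(arch$sequence, 283, 449))
  decoys <- make_decoys(1000L, rep(300L, 10L), seed = 4L)
  cal <- calibrate_expect(pssm, decoys)
  # threshold at empirical E <= 1e-2: at most 10 of 1000 decoys above it
  cut <- toxscan:::score_cutoff(cal, 1e-2)
  expect_lte(sum(cal$scores >= cut), 10L)
  # monotone non-increasing over the sorted decoy score grid
  ev <- expect_value(cal, cal$scores)
  expect_true(all(diff(ev) <= 0))
  # beyond the maximum the tail extrapolation stays below 1/n
  expect_lte(expect_value(cal, cal$max + 1e-6), 1 / cal$n)
  expect_gt(expect_value(cal, cal$max + 1), 0)
  expect_error(calibrate_expect(pssm, decoys[1:50]), "too few")
})

test_that("calibration is valid on fresh decoys", {
  arch <- reference_archetype()
  pssm <- build_pssm(substr(arch$sequence, 283, 449))
  cal <- calibrate_expect(pssm, make_decoys(1000L, rep(300L, 5L), seed = 4L))
  fresh <- best_scores <- vapply(
    make_decoys(1000L, rep(300L, 5L), seed = 5L),
    function(p) max(toxscan:::pssm_window_scores(
      pssm$scores, toxscan:::encode_aa(p))), numeric(1))
  for (x in c(1e-1, 1e-2)) {
    cut <- toxscan:::score_cutoff(cal, x)
    expect_lte(mean(fresh >= cut), 2 * x)
  }
})

test_that("diverged family members clear the E <= 1e-2 threshold", {
  arch <- reference_archetype()
  pssm <- build_pssm(substr(arch$sequence, 283, 449))
  cal <- calibrate_expect(pssm, make_decoys(1000L, rep(300L, 5L), seed = 6L))
  cut <- toxscan:::score_cutoff(cal, 1e-2)
  hits <- vapply(1:200, function(i) {
    m <- emit_family_member(arch, 0.3, seed = i, region = c(283L, 449L))
    scan_protein(m, pssm)$bits[1] >= cut
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("a lone seed database is a fixed point of the iteration", {
  arch <- reference_archetype()
  pone <- substr(arch$sequence, 283, 449)
  db <- c(seedprot = pone)
  res <- iterate_search(pone, db, search_config(seed = 2L,
                                                decoy_count = 100L))
  expect_identical(res$history, rep(1L, 5L))
  expect_identical(res$hits$protein_id, "seedprot")
})

test_that("the per-iteration cap admits min(iteration, family) hits", {
  arch <- reference_archetype()
  pone <- substr(arch$sequence, 283, 449)
  db <- vapply(1:5, function(i) {
    emit_family_member(arch, 0.1, seed = i, region = c(283L, 449L))
  }, character(1))
  names(db) <- sprintf("fam%d", 1:5)
  cfg <- search_config(per_iteration_cap = 1L, seed = 3L,
                       decoy_count = 100L)
  res <- iterate_search(pone, db, cfg)
  expect_identical(res$history, 1:5)
  # ties at the cap are broken by score, then id: admission is deterministic
  res2 <- iterate_search(pone, db, cfg)
  expect_identical(res$hits, res2$hits)
})

test_that("profile refinement does not lose sensitivity", {
  arch <- reference_archetype()
  pone <- substr(arch$sequence, 283, 449)
  members <- vapply(1:100, function(i) {
    emit_family_member(arch, 0.35, seed = 1000L + i)
  }, character(1))
  names(members) <- sprintf("fam%03d", 1:100)
  decoy_db <- make_decoys(1000L, rep(300L, 5L), seed = 31L)
  names(decoy_db) <- sprintf("bg%04d", seq_along(decoy_db))
  db <- c(members, decoy_db)
  res <- iterate_search(pone, db, search_config(seed = 17L))
  fam_hits_by_iter <- vapply(1:5, function(it) {
    sum(grepl("^fam", res$hits$protein_id[res$hits$iteration <= it]))
  }, integer(1))
  expect_gte(fam_hits_by_iter[5], fam_hits_by_iter[1])
  expect_true(all(diff(res$history) >= 0))  # hit set never shrinks
})
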