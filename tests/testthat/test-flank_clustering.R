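test_that("flank extraction follows the anchored-domain sides", {
  arch <- reference_archetype()
  cfl <- extract_flank(arch$sequence, list(start = 43L, end = 121L), "C")
  expect_equal(nchar(cfl$sequence), 328L)  # residues 122..449
  expect_identical(cfl$sequence, substr(arch$sequence, 122, 449))
  nfl <- extract_flank(arch$sequence, list(start = 283L, end = 449L), "N")
  expect_identical(nfl$sequence, substr(arch$sequence, 1, 282))
  # a domain abutting the terminus yields an empty flank
  expect_equal(extract_flank("ACDEF", list(start = 1L, end = 3L),
                             "N")$sequence, "")
  expect_equal(extract_flank("ACDEF", list(start = 3L, end = 5L),
                             "C")$sequence, "")
  expect_error(extract_flank("ACD", list(start = 1L, end = 9L), "C"),
               "outside")
})

test_that("pairwise identity matches hand-checkable cases", {
  expect_equal(pairwise_identity("ACDEFGHIK", "ACDEFGHIK"), 1)
  expect_equal(pairwise_identity("ACDEFGHIK", "ACDEFGHIW"), 8 / 9,
               tolerance = 1e-12)
  expect_equal(pairwise_identity("AAAAAAAA", "GGGGGGGG"), 0)
  expect_error(pairwise_identity("", "ACD"), "empty")
  # symmetric by construction
  withr::local_seed(7)
  for (i in 1:10) {
    a <- random_protein(sample(8:30, 1))
    b <- random_protein(sample(8:30, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("identical inputs collapse to a single cluster", {
  fl <- data.frame(protein_id = c("p1", "p2", "p3"),
                   sequence = rep("MKVLAWDEQ", 3), stringsAsFactors = FALSE)
  cl <- greedy_cluster(fl)
  expect_equal(length(unique(cl$cluster_id)), 1L)
  expect_equal(cl$representative[1], "p1")
})

test_that("the length-ratio rule forces new clusters", {
  # candidate length 4 vs representative length 9: ratio 0.444 < 0.5
  fl <- data.frame(protein_id = c("long", "shrt"),
                   sequence = c("ACDEFGHIK", "ACDE"), stringsAsFactors = FALSE)
  cl <- greedy_cluster(fl)
  expect_equal(length(unique(cl$cluster_id)), 2L)
})

test_that("empty flanks are skipped with a notice", {
  fl <- data.frame(protein_id = c("a", "b"),
                   sequence = c("", "MKVLAWDEQ"), stringsAsFactors = FALSE)
  expect_message(cl <- greedy_cluster(fl), "empty flank")
  expect_equal(nrow(cl), 1L)
})

test_that("greedy clustering equals the brute-force enumeration", {
  withr::local_seed(11)
  for (trial in 1:20) {
    n <- sample(5:15, 1)
    base <- random_protein(30L)
    seqs <- vapply(seq_len(n), function(i) {
      if (runif(1) < 0.5) {
        # mutated/truncated copies of a base: non-trivial cluster structure
        chars <- strsplit(base, "")[[1]]
        k <- sample(0:12, 1)
        if (k > 0) {
          pos <- sample(30L, k)
          chars[pos] <- sample(toxscan::AA_ALPHABET, k, replace = TRUE)
        }
        paste(chars[seq_len(sample(12:30, 1))], collapse = "")
      } else {
        random_protein(sample(10:30, 1))
      }
    }, character(1))
    fl <- data.frame(protein_id = sprintf("p%02d", seq_len(n)),
                     sequence = seqs, stringsAsFactors = FALSE)
    got <- greedy_cluster(fl)
    want <- oracle_greedy_cluster(fl)
    got_map <- got$cluster_id[match(want$protein_id, got$protein_id)]
    expect_identical(unname(got_map), want$cluster_id)
  }
})

test_that("input order does not change the clustering", {
  withr::local_seed(23)
  fl <- data.frame(protein_id = sprintf("p%02d", 1:12),
                   sequence = vapply(1:12, function(i)
                     random_protein(sample(10:25, 1)), character(1)),
                   stringsAsFactors = FALSE)
  c1 <- greedy_cluster(fl)
  c2 <- greedy_cluster(fl[sample(nrow(fl)), , drop = FALSE])
  rownames(c1) <- rownames(c2) <- NULL
  expect_identical(c1, c2)
})

test_that("members verify both thresholds against their representative", {
  withr::local_seed(31)
  base <- random_protein(40L)
  seqs <- vapply(1:15, function(i) {
    chars <- strsplit(base, "")[[1]]
    pos <- sample(40L, sample(0:15, 1))
    chars[pos] <- sample(toxscan::AA_ALPHABET, length(pos), replace = TRUE)
    paste(chars[seq_len(sample(20:40, 1))], collapse = "")
  }, character(1))
  fl <- data.frame(protein_id = sprintf("p%02d", 1:15), sequence = seqs,
                   stringsAsFactors = FALSE)
  cl <- greedy_cluster(fl)
  reps <- cl[cl$is_representative, ]
  seq_of <- setNames(fl$sequence, fl$protein_id)
  for (i in which(!cl$is_representative)) {
    rep_seq <- seq_of[cl$representative[i]]
    mem_seq <- seq_of[cl$protein_id[i]]
    expect_gte(pairwise_identity(mem_seq, rep_seq), 0.40)
    expect_gte(nchar(mem_seq) / nchar(rep_seq), 0.50)
  }
  # representative is the longest member of its cluster
  for (cid in unique(cl$cluster_id)) {
    members <- cl$protein_id[cl$cluster_id == cid]
    rep_id <- unique(cl$representative[cl$cluster_id == cid])
    expect_equal(unname(max(nchar(seq_of[members]))),
                 unname(nchar(seq_of[rep_id])))
  }
})

test_that("cluster count is monotone in the identity threshold", {
  withr::local_seed(41)
  base <- random_protein(30L)
  seqs <- vapply(1:20, function(i) {
    chars <- strsplit(base, "")[[1]]
    pos <- sample(30L, sample(0:18, 1))
    chars[pos] <- sample(toxscan::AA_ALPHABET, length(pos), replace = TRUE)
    paste(chars, collapse = "")
  }, character(1))
  fl <- data.frame(protein_id = sprintf("p%02d", 1:20), sequence = seqs,
                   stringsAsFactors = FALSE)
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8), function(thr) {
    length(unique(greedy_cluster(fl, identity_threshold = thr)$cluster_id))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
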