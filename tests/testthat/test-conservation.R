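test_that("entropy scores hit their normalization endpoints", {
  expect_equal(shannon_score(rep("K", 1012)), 1)
  expect_equal(shannon_score(rep(amino_acids(), 50)), 0)
  expect_equal(shannon_score(rep(c("A", "V"), 50)), 1 - log(2) / log(20))
  expect_equal(stereo_entropy_score(c("V", "L", "I", "M", "V", "L")), 1)
  expect_equal(stereo_entropy_score(rep(c("V", "F"), 50)),
               1 - log(2) / log(9))
  expect_true(is.na(shannon_score(c("-", "X", "B", "Z"))))
})

test_that("grouping residues coarsens the entropy", {
  # pooling residues into the nine groups can only shrink the raw entropy;
  # the normalized scores are not ordered because the two normalizers
  # (log 9 vs log 20) differ, e.g. a 50/50 V/F column scores lower under
  # the grouped score than a 50/50 A/V column under the plain one
  set.seed(21)
  for (i in 1:300) {
    col <- random_column(sample(c(5, 20, 100), 1))
    h_group <- (1 - stereo_entropy_score(col)) * log(9)
    h_aa <- (1 - shannon_score(col)) * log(20)
    expect_lte(h_group, h_aa + 1e-12)
  }
  # and a column varying only within one group is perfectly conserved for
  # the grouped score but not for the plain one
  col <- rep(c("V", "L"), 10)
  expect_equal(stereo_entropy_score(col), 1)
  expect_lt(shannon_score(col), 1)
})

test_that("JSD score is zero at the background and follows the closed form", {
  q <- blosum62_background()
  # column whose empirical distribution equals the background exactly:
  # use counts of 10000 * q rounded -- almost exact; compare to direct formula
  counts <- round(q * 100000)
  col <- rep(names(counts), counts)
  expect_lt(jsd_score(col), 1e-4)

  # single-residue column: closed-form evaluation done independently here
  for (a in c("A", "W", "C")) {
    p <- setNames(numeric(20), amino_acids()); p[a] <- 1
    m <- (p + q) / 2
    ent <- function(v) { v <- v[v > 0]; -sum(v * log(v)) }
    expected <- (ent(m) - (ent(p) + ent(q)) / 2) / log(2)
    expect_equal(jsd_score(rep(a, 50)), expected, tolerance = 1e-12)
  }

  set.seed(22)
  for (i in 1:500) {
    s <- jsd_score(random_column(sample(c(3, 30), 1)))
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("Karlin score matches the hand-computed example and oracle", {
  expect_equal(karlin_score(rep("K", 10)), 1)
  # W/W = 11, C/C = 9, W/C = -2: s = (2*1 + 4*(-2/sqrt(99)))/6
  s <- (2 * 1 + 4 * (-2 / sqrt(99))) / 6
  expect_equal(karlin_score(c("W", "W", "C", "C")), (s + 1) / 2,
               tolerance = 1e-10)
  expect_true(is.na(karlin_score(c("W"))))
  expect_true(is.na(karlin_score(c("W", "-"))))

  # exhaustive equivalence with the brute-force pair sum on all columns of
  # size 2..5 over a 4-letter alphabet
  sub <- blosum62_matrix()
  alpha <- c("A", "C", "D", "E")
  for (n in 2:5) {
    grid <- do.call(expand.grid, rep(list(alpha), n))
    for (r in seq_len(nrow(grid))) {
      col <- as.character(unlist(grid[r, ]))
      expect_equal(karlin_score(col), brute_force_karlin(col, sub),
                   tolerance = 1e-12)
    }
  }
})

test_that("Karlin reranged score stays in [0, 1] on random columns", {
  set.seed(23)
  for (i in 1:1000) {
    s <- karlin_score(random_column(sample(2:30, 1)))
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("phylogeny-weighted score anchors to the reference", {
  tips <- c("REF", paste0("s", 1:4))
  star <- ape::read.tree(text = "(REF:1,s1:1,s2:1,s3:1,s4:1);")
  col <- setNames(c("K", "K", "K", "R", "R"), tips)
  # equal weights reduce to the fraction of comparison strains matching
  expect_equal(phylozoom_score(col, star, "REF"), 0.5)
  expect_equal(phylozoom_score(setNames(rep("K", 5), tips), star, "REF"), 1)

  # a mismatch close to the reference hurts more than one far away
  tr <- ape::read.tree(text = "((REF:0.005,s1:0.005):0.5,(s2:0.5,s3:0.5):0.01);")
  near <- setNames(c("K", "R", "K", "K"), c("REF", "s1", "s2", "s3"))
  far <- setNames(c("K", "K", "R", "K"), c("REF", "s1", "s2", "s3"))
  expect_lt(phylozoom_score(near, tr, "REF"), phylozoom_score(far, tr, "REF"))

  # gapped reference -> undefined
  expect_true(is.na(phylozoom_score(setNames(c("-", "K", "K", "K"),
                                             c("REF", "s1", "s2", "s3")),
                                    tr, "REF")))
})

test_that("gap penalty multiplies by the non-gap fraction", {
  col <- c(rep("A", 6), "-", "X")                 # 25% gaps
  expect_equal(apply_gap_penalty(0.8, col), 0.6)
  expect_equal(apply_gap_penalty(0.7, rep("A", 4)), 0.7)
  expect_equal(apply_gap_penalty(1, rep("-", 4)), 0)
})

test_that("profiles agree with per-column scorers and respect invariants", {
  set.seed(31)
  rows <- replicate(8, paste(random_column(12, 0.15), collapse = ""))
  names(rows) <- c("REF", paste0("s", 1:7))
  aln <- strain_alignment("YX", rows, "REF")
  tree <- simulate_strain_tree(aln$strain_ids, seed = 4)

  per_col <- list(
    shannon = shannon_score, stereo = stereo_entropy_score,
    jsd = function(c) jsd_score(c), karlin = function(c) karlin_score(c)
  )
  for (alg in names(per_col)) {
    p <- score_profile(aln, alg)
    expect_equal(length(p$scores), alignment_length(aln))
    ref <- apply(aln$chars, 2, per_col[[alg]])
    expect_equal(p$scores, unname(ref), tolerance = 1e-12)
  }
  pz <- score_profile(aln, "phylozoom", tree = tree)
  ref <- apply(aln$chars, 2, function(col) {
    phylozoom_score(setNames(col, aln$strain_ids), tree, "REF")
  })
  expect_equal(pz$scores, unname(ref), tolerance = 1e-12)

  # gap penalty applied for shannon, never for karlin
  pg <- score_profile(aln, "shannon", gap_penalty = TRUE)
  p0 <- score_profile(aln, "shannon")
  expect_equal(pg$scores, p0$scores * (1 - gap_fraction(aln)))
  kg <- score_profile(aln, "karlin", gap_penalty = TRUE)
  k0 <- score_profile(aln, "karlin")
  expect_equal(kg$scores, k0$scores)

  # permuting strain order leaves multiset scores unchanged
  perm <- sample(length(rows))
  aln_p <- strain_alignment("YX", rows[perm],
                            reference_strain = "REF")
  for (alg in c("shannon", "stereo", "jsd", "karlin")) {
    expect_equal(score_profile(aln_p, alg)$scores,
                 score_profile(aln, alg)$scores, tolerance = 1e-12)
  }
})

test_that("a monomorphic column maximizes every score", {
  mono <- rep("L", 40)
  tree <- simulate_strain_tree(c("REF", paste0("s", 1:39)), seed = 6)
  expect_equal(shannon_score(mono), 1)
  expect_equal(stereo_entropy_score(mono), 1)
  expect_equal(karlin_score(mono), 1)
  expect_equal(phylozoom_score(setNames(mono, c("REF", paste0("s", 1:39))),
                               tree, "REF"), 1)
  jmax <- jsd_score(mono)
  set.seed(41)
  for (i in 1:500) {
    expect_lte(jsd_score(random_column(40)), jmax + 1e-12)
  }
})

test_that("scores stay in range with and without the gap penalty", {
  set.seed(51)
  for (i in 1:1000) {
    col <- random_column(sample(2:25, 1), gap_prob = 0.2)
    for (f in list(shannon_score, stereo_entropy_score,
                   function(c) jsd_score(c), function(c) karlin_score(c))) {
      s <- f(col)
      if (!is.na(s)) {
        expect_gte(s, -1e-12); expect_lte(s, 1 + 1e-12)
        sg <- apply_gap_penalty(s, col)
        expect_gte(sg, -1e-12); expect_lte(sg, 1 + 1e-12)
      }
    }
  }
})
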