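toy_interactions <- function() {
  data.frame(
    kinase = c("K1", "K2", "K3", "K4", "K1"),
    substrate = c("A", "A", "A", "B", "B"),
    stringsAsFactors = FALSE
  )
}

test_that("single-interaction ratio covers the documented cases", {
  tab <- toy_interactions()
  # K2, K3 single with A; K4 single with B; K1 double -> 3/(3+1)
  expect_equal(single_interaction_ratio("A", "B", tab), 0.75)
  # all single
  only <- data.frame(kinase = c("K1", "K2"), substrate = c("A", "A"),
                     stringsAsFactors = FALSE)
  expect_equal(single_interaction_ratio("A", "B", only), 1)
  # all double
  both <- data.frame(kinase = c("K1", "K1"), substrate = c("A", "B"),
                     stringsAsFactors = FALSE)
  expect_equal(single_interaction_ratio("A", "B", both), 0)
  # no interactions at all -> undefined
  expect_true(is.na(single_interaction_ratio("X", "Y", tab)))

  # converting a double to a single never decreases the ratio
  set.seed(101)
  for (i in 1:20) {
    ks <- sprintf("K%02d", 1:8)
    subs <- sample(c("A", "B", "A+B"), 8, replace = TRUE)
    mk <- function(subs) {
      do.call(rbind, lapply(seq_along(ks), function(j) {
        s <- if (subs[j] == "A+B") c("A", "B") else subs[j]
        data.frame(kinase = ks[j], substrate = s, stringsAsFactors = FALSE)
      }))
    }
    r0 <- single_interaction_ratio("A", "B", mk(subs))
    dbl <- which(subs == "A+B")
    if (length(dbl) > 0) {
      subs[dbl[1]] <- "A"
      r1 <- single_interaction_ratio("A", "B", mk(subs))
      expect_gte(r1, r0)
    }
  }
})

test_that("ratios attach per pair and deduplication works", {
  tab <- rbind(toy_interactions(), toy_interactions())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  dedup <- read_kinase_interactions(tsv)
  expect_equal(nrow(dedup), 5)
  pairs <- data.frame(orf_a = c("A", "X"), orf_b = c("B", "Y"),
                      stringsAsFactors = FALSE)
  out <- single_interaction_ratios(pairs, dedup)
  expect_equal(out$single_interaction_ratio, c(0.75, NA))
})

test_that("PWM scoring sums position weights and breaks ties by id", {
  aas <- amino_acids()
  zero <- matrix(0, 4, 20, dimnames = list(as.character(-2:1), aas))
  # kinase B rewards the observed motif around position 3 of "ARSPG"
  pwm_b <- zero
  pwm_b["-2", "A"] <- 1; pwm_b["-1", "R"] <- 2; pwm_b["1", "P"] <- 3
  pwm_a <- zero
  pwm_a["-1", "K"] <- 5
  pwms <- list(KB = pwm_b, KA = pwm_a, KC = pwm_b)
  expect_equal(score_pwm("ARSPG", 3, pwm_b), 6)
  expect_equal(score_pwm("ARSPG", 3, pwm_a), 0)
  expect_equal(assign_best_kinase("ARSPG", 3, pwms), "KB")  # KB < KC ties
  # terminal window positions are skipped, not padded
  expect_equal(score_pwm("SP", 1, pwm_b), 3)
  expect_error(assign_best_kinase("ARSPG", 3, list()), "input error")

  # adding a constant to the same position of every kinase keeps the argmax
  shift <- lapply(pwms, function(m) { m["-1", ] <- m["-1", ] + 7; m })
  expect_equal(assign_best_kinase("ARSPG", 3, shift),
               assign_best_kinase("ARSPG", 3, pwms))
})

test_that("disjoint kinase pairs are detected symmetrically", {
  aas <- amino_acids()
  mk_pwm <- function(res) {
    m <- matrix(0, 1, 20, dimnames = list("-1", aas))
    m["-1", res] <- 10
    m
  }
  pwms <- list(K1 = mk_pwm("R"), K2 = mk_pwm("E"))
  seqs <- c(A = "ARSAA", B = "AESAA", C = "ARSAA", D = "ARSAA")
  sites <- data.frame(
    orf_a = c("A", "B", "C", "D"), orf_b = c("B", "A", "D", "C"),
    target_orf = c("A", "B", "C", "D"), paralog_orf = c("B", "A", "D", "C"),
    mod_type = "phosphorylation", residue = "S",
    target_position = 3L, paralog_position = 3L, stringsAsFactors = FALSE
  )
  pairs <- data.frame(orf_a = c("A", "C"), orf_b = c("B", "D"),
                      stringsAsFactors = FALSE)
  out <- disjoint_kinase_pairs(pairs, sites, seqs, pwms)
  expect_equal(out$disjoint, c(TRUE, FALSE))   # R-motif vs E-motif; identical
  swapped <- disjoint_kinase_pairs(
    data.frame(orf_a = c("B", "D"), orf_b = c("A", "C"),
               stringsAsFactors = FALSE), sites, seqs, pwms)
  expect_equal(swapped$disjoint, out$disjoint)
})

test_that("abundance filter applies a strict fold threshold", {
  pairs <- data.frame(orf_a = c("A", "C", "E", "G"),
                      orf_b = c("B", "D", "F", "H"),
                      stringsAsFactors = FALSE)
  ab <- data.frame(
    orf_id = c("A", "B", "C", "D", "E", "F"),
    median_abundance = c(100, 150, 100, 250, 100, 200),
    stringsAsFactors = FALSE
  )
  expect_message(out <- filter_pairs_by_abundance(pairs, ab, 2),
                 "dropped 1")
  expect_equal(out$orf_a, "A")       # 1.5-fold kept; 2.5 and exactly 2 dropped
  expect_equal(attr(out, "n_missing"), 1L)
  ab_bad <- data.frame(orf_id = "A", median_abundance = -1)
  expect_error(filter_pairs_by_abundance(pairs, ab_bad), "input error")
})

test_that("multi-study filter keeps well-replicated records", {
  mods <- data.frame(orf_id = c("A", "B"), position = c(1L, 2L),
                     residue = "S", mod_type = "phosphorylation",
                     stringsAsFactors = FALSE)
  mods$study_ids <- I(list(c("s1", "s2"), "s1"))
  mods$n_studies <- c(2L, 1L)
  expect_equal(filter_multi_study(mods, 2)$orf_id, "A")
  expect_equal(nrow(filter_multi_study(mods, 1)), 2)
})

stride_fixture <- function(lines_extra = character(0)) {
  c("REM  --------------- Detailed secondary structure assignment -------",
    "ASG  MET A    1    1    C          Coil    360.00    120.00     180.5",
    "ASG  SER A    2    2    C          Coil    -60.00    140.00     120.0",
    "ASG  LYS A    3    3    H    AlphaHelix    -57.00    -47.00      80.2",
    "ASG  ASP A    4    4    H    AlphaHelix    -60.00    -45.00      60.1",
    "ASG  GLU A    5    5    H    AlphaHelix    -62.00    -41.00      42.3",
    "ASG  ALA A    6    6    T          Turn    -70.00    -20.00      95.0",
    lines_extra)
}

test_that("STRIDE detailed assignments parse into residue records", {
  path <- withr::local_tempfile(fileext = ".stride")
  writeLines(stride_fixture(), path)
  rec <- parse_stride(path, "YTEST")
  expect_equal(nrow(rec), 6)
  expect_equal(rec$position, 1:6)
  expect_equal(rec$residue[3], "K")
  expect_equal(rec$secondary_structure[5], "AlphaHelix")
  expect_equal(rec$solvent_accessible_area[5], 42.3)

  empty <- withr::local_tempfile(fileext = ".stride")
  writeLines("REM nothing here", empty)
  expect_equal(nrow(parse_stride(empty, "X")), 0)

  gap <- withr::local_tempfile(fileext = ".stride")
  writeLines(stride_fixture(
    "ASG  GLY A    9    9    C          Coil    -70.00    -20.00      10.0"),
    gap)
  expect_warning(rec2 <- parse_stride(gap, "X"), "non-contiguous")
  expect_equal(nrow(rec2), 7)

  bad <- withr::local_tempfile(fileext = ".stride")
  writeLines(c(stride_fixture(), "ASG  GLY A"), bad)
  expect_error(parse_stride(bad, "X"), "parse error")
})

test_that("secondary-structure run lengths and pair differences", {
  rec <- data.frame(
    orf_id = "X", position = 1:8, residue = "A",
    secondary_structure = c("Coil", "Coil", "AlphaHelix", "AlphaHelix",
                            "AlphaHelix", "AlphaHelix", "Coil", "Coil"),
    solvent_accessible_area = c(10, 20, 30, 40, 50, 60, 70, 80),
    stringsAsFactors = FALSE
  )
  expect_equal(secondary_structure_length(rec, 4), 4L)
  expect_equal(secondary_structure_length(rec, 1), 2L)
  # identical within one run
  expect_equal(secondary_structure_length(rec, 3),
               secondary_structure_length(rec, 6))
  expect_true(is.na(secondary_structure_length(rec, 99)))

  rec_p <- rec
  rec_p$secondary_structure <- c("Coil", "Coil", "AlphaHelix", "AlphaHelix",
                                 "Coil", "Coil", "Coil", "Coil")
  rec_p$solvent_accessible_area <- rec$solvent_accessible_area - 5
  site <- data.frame(target_orf = "T", paralog_orf = "P",
                     target_position = 4L, paralog_position = 4L,
                     stringsAsFactors = FALSE)
  d <- pair_structure_difference(site, rec, rec_p)
  expect_equal(d$class_pair, "AlphaHelix-AlphaHelix")
  expect_equal(d$d_length, 2L)            # run 4 vs run 2
  expect_equal(d$d_area, 5)
  # antisymmetry under swapping roles
  d_swap <- pair_structure_difference(
    data.frame(target_orf = "P", paralog_orf = "T",
               target_position = 4L, paralog_position = 4L),
    rec_p, rec)
  expect_equal(d_swap$d_length, -d$d_length)
  expect_equal(d_swap$d_area, -d$d_area)
})

test_that("symmetric structure fixtures center differences at zero", {
  # target and paralog structures drawn from the same generator: the
  # difference distribution should not be skewed either way
  set.seed(111)
  classes <- c("Coil", "AlphaHelix", "Turn", "Strand")
  mk_rec <- function(orf) {
    runs <- sample(classes, 12, replace = TRUE)
    lens <- sample(1:6, 12, replace = TRUE)
    ss <- rep(runs, lens)
    data.frame(orf_id = orf, position = seq_along(ss), residue = "A",
               secondary_structure = ss,
               solvent_accessible_area = runif(length(ss), 0, 150),
               stringsAsFactors = FALSE)
  }
  n <- 80
  stride <- list()
  sites <- data.frame(
    orf_a = sprintf("T%03d", 1:n), orf_b = sprintf("P%03d", 1:n),
    target_orf = sprintf("T%03d", 1:n), paralog_orf = sprintf("P%03d", 1:n),
    mod_type = "phosphorylation", residue = "S",
    target_position = 5L, paralog_position = 5L, stringsAsFactors = FALSE
  )
  for (i in 1:n) {
    stride[[sprintf("T%03d", i)]] <- mk_rec(sprintf("T%03d", i))
    stride[[sprintf("P%03d", i)]] <- mk_rec(sprintf("P%03d", i))
  }
  diffs <- pair_structure_differences(sites, stride)
  expect_gt(nrow(diffs), 50)
  sign_test <- binom.test(sum(diffs$d_area > 0), nrow(diffs), 0.5)
  expect_gt(sign_test$p.value, 0.05)
})
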