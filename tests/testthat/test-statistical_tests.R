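make_pairs <- function(tv, pv, mod = "phosphorylation") {
  structure(
    data.frame(mod_type = mod, target_value = tv, paralog_value = pv,
               stringsAsFactors = FALSE),
    class = c("paired_score_set", "data.frame"),
    algorithm = "shannon", statistic = "mean1"
  )
}

test_that("distribution-mean test enumerates the exact one-sided null", {
  # five positive differences: one-sided exact p = 1/2^5
  ps <- make_pairs(c(0.5, 0.6, 0.7, 0.8, 0.9), c(0.4, 0.5, 0.6, 0.7, 0.8) - c(0.01, 0.02, 0.03, 0.04, 0.05))
  r <- paired_wilcoxon_greater(ps)
  expect_equal(r$p_value, 1 / 32)
  expect_equal(r$n, 5)
  # reversing every difference gives the complementary extreme
  ps_rev <- make_pairs(ps$paralog_value, ps$target_value)
  expect_equal(paired_wilcoxon_greater(ps_rev)$p_value, 1)
  # identical members -> degenerate
  expect_error(paired_wilcoxon_greater(make_pairs(1:4 / 10, 1:4 / 10)),
               "degenerate")
})

test_that("pairing test statistic, granularity and extremes behave", {
  set.seed(71)
  tv <- runif(50, 0.6, 0.9)
  pv <- runif(50, 0.1, 0.4)
  ps <- make_pairs(tv, pv)
  r <- paralog_pairing_test(ps, B = 1000, seed = 5)
  expect_equal(r$statistic, 1)            # P_auth is maximal
  # every shuffle also yields P_s = 1 here, so no shuffle is ever beaten
  expect_equal(r$metadata$f, 0)
  expect_equal(r$p_value, 1)
  # granularity: f is an exact multiple of 1/B
  ps2 <- make_pairs(runif(30), runif(30))
  r2 <- paralog_pairing_test(ps2, B = 1000, seed = 6)
  expect_equal(r2$metadata$f * 1000, round(r2$metadata$f * 1000))
  expect_equal(r2$p_value, 1 - r2$metadata$f)
  expect_error(paralog_pairing_test(make_pairs(0.5, 0.4), B = 10),
               "insufficient")
})

test_that("pairing test agrees with exhaustive permutation enumeration", {
  set.seed(73)
  for (n in c(3, 5, 6)) {
    tv <- runif(n); pv <- runif(n)
    ps <- make_pairs(tv, pv)
    ex <- paralog_pairing_exact(ps)
    # independent enumeration oracle
    perms <- all_perms(n)
    p_auth <- mean(tv > pv)
    f_oracle <- mean(vapply(perms, function(pi) p_auth > mean(tv > pv[pi]),
                            logical(1)))
    expect_equal(ex$f, f_oracle)
    expect_equal(ex$p_value, 1 - f_oracle)
    # Monte-Carlo version converges to the exact value
    mc <- paralog_pairing_test(ps, B = 4000, seed = n)
    expect_lt(abs(mc$metadata$f - f_oracle), 0.03)
  }
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.1, 1.2)), "input error")
  # agreement with an independent step-up implementation
  step_up <- function(p) {
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(p[o] * m / (m:1)))[ro]
  }
  set.seed(81)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, step_up(p))
    expect_true(all(adj >= p))
  }
})

test_that("adjust_results fills adjusted p within families", {
  rs <- list(test_result("t", 1, 0.01, 5), test_result("t", 1, 0.04, 5),
             test_result("t", 1, 0.03, 5))
  out <- adjust_results(rs, family = c("a", "a", "b"))
  expect_equal(out[[1]]$adjusted_p, 0.02)
  expect_equal(out[[2]]$adjusted_p, 0.04)
  expect_equal(out[[3]]$adjusted_p, 0.03)
})

test_that("position contingency counts flanking residues", {
  n <- 10
  seqs <- c(setNames(rep("AASPA", n), sprintf("T%02d", 1:n)),
            setNames(rep("AASKA", n), sprintf("P%02d", 1:n)))
  sites <- data.frame(
    orf_a = sprintf("T%02d", 1:n), orf_b = sprintf("P%02d", 1:n),
    target_orf = sprintf("T%02d", 1:n), paralog_orf = sprintf("P%02d", 1:n),
    mod_type = "phosphorylation", residue = "S",
    target_position = 3L, paralog_position = 3L, stringsAsFactors = FALSE
  )
  tab <- build_position_contingency(sites, seqs, "a1")
  expect_equal(unname(tab["target", "P"]), n)
  expect_equal(unname(tab["paralog", "K"]), n)
  expect_equal(unname(rowSums(tab)), c(n, n))
  # out-of-range offsets skip the site
  tab2 <- build_position_contingency(sites, seqs, "b3")
  expect_equal(sum(tab2), 0)
  expect_equal(attr(tab2, "n_skipped"), n)
  expect_equal(attr(tab, "relative_position"), "a1")
})

test_that("chi-square motif test matches hand computation", {
  tab <- matrix(c(10L, 0L, 0L, 10L), 2, 2,
                dimnames = list(c("target", "paralog"), c("R", "K")))
  class(tab) <- c("position_contingency", class(tab))
  r <- chi_square_motif_test(tab, B = 2000, seed = 3)
  expect_equal(r$statistic, 20)           # hand Pearson X2
  # exact enumeration under fixed margins: only two tables reach X2 >= 20
  # out of choose(20, 10) -> true p ~ 1.08e-5; the MC p must be small
  expect_lte(r$p_value, 0.01)

  same <- matrix(c(5L, 5L, 7L, 7L), 2, 2,
                 dimnames = list(c("target", "paralog"), c("R", "K")))
  r2 <- chi_square_motif_test(same, B = 500, seed = 4)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)

  # column permutation leaves the statistic unchanged
  perm <- tab[, c(2, 1)]
  r3 <- chi_square_motif_test(perm, B = 2000, seed = 5)
  expect_equal(r3$statistic, r$statistic)

  bad <- matrix(c(0L, 3L, 0L, 4L), 2, 2,
                dimnames = list(c("target", "paralog"), c("R", "K")))
  expect_error(chi_square_motif_test(bad), "degenerate")
})

test_that("post hoc residuals flag the deviating amino acid", {
  # proportional table -> all residuals zero, adjusted p = 1
  prop <- matrix(c(10L, 10L, 20L, 20L, 30L, 30L), 2, 3,
                 dimnames = list(c("target", "paralog"), c("A", "R", "S")))
  ph <- posthoc_residuals(prop)
  expect_true(all(abs(ph$residual) < 1e-12))
  expect_true(all(ph$adjusted_p == 1))

  # arginine inflated in the target row -> flagged Target > Paralog
  infl <- matrix(c(50L, 10L, 30L, 30L, 40L, 40L), 2, 3,
                 dimnames = list(c("target", "paralog"), c("R", "A", "S")))
  ph2 <- posthoc_residuals(infl)
  row_r <- ph2[ph2$amino_acid == "R", ]
  expect_equal(row_r$direction, "Target > Paralog")
  expect_lt(row_r$adjusted_p, 0.05)
})

test_that("background goodness-of-fit reacts to concentration", {
  q <- blosum62_background()
  counts <- round(q * 10000)
  r <- blosum_background_test(counts, B = 500, seed = 9)
  expect_lt(r$statistic, 1)
  expect_gt(r$p_value, 0.5)

  conc <- setNames(numeric(20), amino_acids())
  conc["W"] <- 100
  r2 <- blosum_background_test(conc, B = 2000, seed = 10)
  expect_lte(r2$p_value, 0.01)

  # doubling all counts doubles the statistic
  set.seed(91)
  obs <- setNames(rpois(20, 20) + 1, amino_acids())
  s1 <- blosum_background_test(obs, B = 100, seed = 1)$statistic
  s2 <- blosum_background_test(obs * 2, B = 100, seed = 1)$statistic
  expect_equal(s2, 2 * s1, tolerance = 1e-9)
})
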