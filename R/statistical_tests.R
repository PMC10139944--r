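# The hypothesis tests: paired one-sided Wilcoxon (distribution-mean
# test), Monte-Carlo paralog-pairing test, positional chi-square with
# Monte-Carlo p and post hoc standardized residuals, goodness of fit
# against the BLOSUM62 background, and Benjamini-Hochberg adjustment.

#' Construct a test-result record
#'
#' @param test_name Short test label.
#' @param statistic Test statistic.
#' @param p_value Raw p-value in `[0, 1]`.
#' @param n Number of observations the test used.
#' @param metadata Named list of provenance (mod_type, algorithm,
#'   statistic, B, seed, ...).
#' @return Object of class `test_result`; `adjusted_p` starts as `NA` and
#'   is filled by [adjust_results()].
#' @export
test_result <- function(test_name, statistic, p_value, n, metadata = list()) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(
    list(test_name = test_name, statistic = statistic, p_value = p_value,
         adjusted_p = NA_real_, n = n, metadata = metadata),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$test_name, ": statistic = ", signif(x$statistic, 4),
      ", p = ", signif(x$p_value, 4),
      if (!is.na(x$adjusted_p)) paste0(", adj. p = ", signif(x$adjusted_p, 4)),
      ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Distribution-mean test: one-sided paired Wilcoxon
#'
#' Wilcoxon signed-rank test on the differences `target - paralog` with
#' alternative "target larger".  Zero differences are dropped (signed-rank
#' convention); the null distribution is enumerated exactly for up to 25
#' nonzero untied pairs and approximated by the tie-corrected normal
#' otherwise.
#'
#' @param pairs A `paired_score_set` (or data frame with `target_value`,
#'   `paralog_value`).
#' @return A [test_result()] with the signed-rank statistic V.
#' @export
paired_wilcoxon_greater <- function(pairs) {
  d <- pairs$target_value - pairs$paralog_value
  d <- d[d != 0]
  if (length(d) == 0) {
    stop("degenerate-data error: all target/paralog differences are zero")
  }
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(d, alternative = "greater", mu = 0,
                       exact = exact, correct = TRUE)
  )
  test_result(
    "distribution_mean", unname(wt$statistic), wt$p.value, length(d),
    metadata = list(mod_type = unique(pairs$mod_type),
                    algorithm = attr(pairs, "algorithm"),
                    statistic = attr(pairs, "statistic"),
                    exact = exact)
  )
}

#' Paralog-pairing Monte-Carlo test
#'
#' Computes `P_auth`, the fraction of authentic pairs whose target value
#' strictly exceeds the paralog value, then reshuffles the paralog
#' assignment `B` times (unrestricted uniform permutations) and computes
#' the same fraction for each shuffle.  The reported frequency
#' `f = mean(P_auth > P_shuffled)` has granularity exactly `1/B`
#' (precision 0.0001 at the default B = 10,000); the p-value is `1 - f`,
#' small when the authentic pairing advantages the targets.
#'
#' @inheritParams paired_wilcoxon_greater
#' @param B Number of shuffles (default 10,000).
#' @param seed Integer seed for the shuffles.
#' @return A [test_result()] with statistic `P_auth`; metadata carries
#'   `f`, `B` and `seed`.
#' @export
paralog_pairing_test <- function(pairs, B = 10000, seed = 1) {
  tv <- pairs$target_value
  pv <- pairs$paralog_value
  n <- length(tv)
  if (n < 2) stop("insufficient-data error: need at least 2 pairs")
  stopifnot(B >= 1)
  p_auth <- mean(tv > pv)
  set.seed(seed)
  wins <- 0L
  for (b in seq_len(B)) {
    p_s <- mean(tv > pv[sample.int(n)])
    if (p_auth > p_s) wins <- wins + 1L
  }
  f <- wins / B
  test_result(
    "paralog_pairing", p_auth, 1 - f, n,
    metadata = list(f = f, B = B, seed = seed,
                    mod_type = unique(pairs$mod_type),
                    algorithm = attr(pairs, "algorithm"),
                    statistic = attr(pairs, "statistic"))
  )
}

#' Exact paralog-pairing test by full permutation enumeration
#'
#' Reference version of [paralog_pairing_test()] that enumerates all `n!`
#' paralog assignments instead of sampling; practical only for small n.
#'
#' @inheritParams paired_wilcoxon_greater
#' @return List with `p_auth`, `f` (exact fraction of permutations with
#'   `P_auth > P_s`) and `p_value = 1 - f`.
#' @export
paralog_pairing_exact <- function(pairs) {
  tv <- pairs$target_value
  pv <- pairs$paralog_value
  n <- length(tv)
  if (n < 2) stop("insufficient-data error: need at least 2 pairs")
  if (n > 8) stop("exact enumeration limited to n <= 8")
  perms <- .permutations(n)
  p_auth <- mean(tv > pv)
  p_s <- apply(perms, 1, function(pi) mean(tv > pv[pi]))
  f <- mean(p_auth > p_s)
  list(p_auth = p_auth, f = f, p_value = 1 - f)
}

# all permutations of 1..n as a matrix (n! rows)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    block <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
    out[r:(r + nrow(sub) - 1L), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, order-preserving and clipped
#' to 1.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, element-wise `>=` the raw values.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("input error: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Fill adjusted p-values within families of test results
#'
#' Applies [bh_adjust()] jointly to each family of results (e.g. all
#' window statistics and modification types of one algorithm under one
#' test).
#'
#' @param results List of [test_result()] objects.
#' @param family Character vector (recycled) or factor assigning each
#'   result to an adjustment family; by default all results form one
#'   family.
#' @return The list with `adjusted_p` filled in.
#' @export
adjust_results <- function(results, family = rep("all", length(results))) {
  stopifnot(length(family) == length(results))
  for (fam in unique(family)) {
    idx <- which(family == fam)
    adj <- bh_adjust(vapply(results[idx], `[[`, numeric(1), "p_value"))
    for (k in seq_along(idx)) results[[idx[k]]]$adjusted_p <- adj[k]
  }
  results
}

#' Tabulate flanking amino acids of targets and paralogs at one offset
#'
#' For each site of interest, counts the amino acid at
#' `target_position + offset` in the target protein and at
#' `paralog_position + offset` in the paralog, building the 2 x 20
#' contingency table of one relative position (b4..b1 = offsets -4..-1,
#' a1..a4 = +1..+4).  Sites whose offset falls outside either sequence, or
#' hits a nonstandard residue, are skipped.
#'
#' @param sites Output of [find_sites_of_interest()] (optionally
#'   filtered, e.g. to one modification type and residue).
#' @param sequences Named character vector of reference protein sequences.
#' @param relative_position Label `"b4".."b1"`, `"a1".."a4"`, or an
#'   integer offset.
#' @return Object of class `position_contingency`: 2 x 20 integer matrix
#'   (rows `target`, `paralog`; columns the amino acids) with attributes
#'   `relative_position` and `n_skipped`.
#' @export
build_position_contingency <- function(sites, sequences, relative_position) {
  offset <- .parse_offset(relative_position)
  aas <- amino_acids()
  counts <- matrix(0L, nrow = 2, ncol = 20,
                   dimnames = list(c("target", "paralog"), aas))
  n_skipped <- 0L
  for (i in seq_len(nrow(sites))) {
    ts <- sequences[[sites$target_orf[i]]]
    ps <- sequences[[sites$paralog_orf[i]]]
    tp <- sites$target_position[i] + offset
    pp <- sites$paralog_position[i] + offset
    if (tp < 1 || tp > nchar(ts) || pp < 1 || pp > nchar(ps)) {
      n_skipped <- n_skipped + 1L
      next
    }
    ta <- substr(ts, tp, tp)
    pa <- substr(ps, pp, pp)
    if (!(ta %in% aas) || !(pa %in% aas)) {
      n_skipped <- n_skipped + 1L
      next
    }
    counts["target", ta] <- counts["target", ta] + 1L
    counts["paralog", pa] <- counts["paralog", pa] + 1L
  }
  structure(counts, class = c("position_contingency", class(counts)),
            relative_position = .offset_label(offset), n_skipped = n_skipped)
}

.parse_offset <- function(relative_position) {
  if (is.numeric(relative_position)) {
    offset <- as.integer(relative_position)
  } else {
    m <- regmatches(relative_position,
                    regexec("^([ba])([1-9])$", relative_position))[[1]]
    if (length(m) == 0) {
      stop("relative_position must be like 'b3', 'a1', or an integer offset")
    }
    offset <- as.integer(m[3]) * if (m[2] == "b") -1L else 1L
  }
  if (offset == 0) stop("offset 0 is the site itself")
  offset
}

.offset_label <- function(offset) {
  paste0(if (offset < 0) "b" else "a", abs(offset))
}

#' Positional chi-square test between target and paralog residue counts
#'
#' Pearson chi-square on the 2 x 20 table of amino-acid counts at one
#' relative position, with Monte-Carlo p-value from `B` resamples under
#' fixed margins: `p = (1 + #(X2_sim >= X2_obs)) / (B + 1)`.  Amino-acid
#' columns with zero total count are dropped from the statistic.
#'
#' @param table A `position_contingency` (or 2 x K count matrix).
#' @param B Number of Monte-Carlo resamples (default 10,000).
#' @param seed Integer seed.
#' @return A [test_result()] with the X-squared statistic.
#' @export
chi_square_motif_test <- function(table, B = 10000, seed = 1) {
  tab <- table[, colSums(table) > 0, drop = FALSE]
  if (any(rowSums(tab) == 0)) {
    stop("degenerate-data error: a row of the table is all zeros")
  }
  set.seed(seed)
  ct <- suppressWarnings(
    stats::chisq.test(tab, simulate.p.value = TRUE, B = B)
  )
  test_result(
    "positional_chi_square", unname(ct$statistic), ct$p.value, sum(tab),
    metadata = list(relative_position = attr(table, "relative_position"),
                    B = B, seed = seed, df_columns = ncol(tab))
  )
}

#' Post hoc standardized residuals of a positional contingency table
#'
#' Per-cell standardized residuals
#' `r = (O - E) / sqrt(E (1 - row/N) (1 - col/N))`, referred to the
#' standard normal for a two-sided p-value, with the direction of each
#' amino acid's deviation recorded as `"Target > Paralog"` or
#' `"Target < Paralog"` (from the sign of the target-row residual; the two
#' rows of a 2 x K table have opposite residuals).  p-values are BH-
#' adjusted across the amino acids of the position.  Amino acids with zero
#' total count, or with a zero expected count, are skipped.
#'
#' @inheritParams chi_square_motif_test
#' @return Data frame with one row per retained amino acid: `amino_acid`,
#'   `residual`, `direction`, `p_value`, `adjusted_p`.
#' @export
posthoc_residuals <- function(table) {
  tab <- table[, colSums(table) > 0, drop = FALSE]
  if (any(rowSums(tab) == 0)) {
    stop("degenerate-data error: a row of the table is all zeros")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  keep <- ct$expected["target", ] > 0
  r <- ct$stdres["target", keep]
  p <- 2 * stats::pnorm(-abs(r))
  out <- data.frame(
    amino_acid = names(r),
    residual = unname(r),
    direction = ifelse(r > 0, "Target > Paralog",
                       ifelse(r < 0, "Target < Paralog", "none")),
    p_value = unname(p),
    adjusted_p = unname(bh_adjust(p)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "relative_position") <- attr(table, "relative_position")
  out
}

#' Goodness of fit of residue counts against the BLOSUM62 background
#'
#' Chi-square of one row of observed amino-acid counts against
#' `N * background`, with Monte-Carlo p-value as in
#' [chi_square_motif_test()].  Background entries are floored at 1e-6 and
#' renormalized before computing expectations.
#'
#' @param observed Named vector of counts over the 20 amino acids (missing
#'   names count 0).
#' @param background Named frequency vector (default
#'   [blosum62_background()]).
#' @param B Number of Monte-Carlo resamples.
#' @param seed Integer seed.
#' @return A [test_result()].
#' @export
blosum_background_test <- function(observed,
                                   background = blosum62_background(),
                                   B = 10000, seed = 1) {
  aas <- amino_acids()
  x <- stats::setNames(numeric(20), aas)
  x[names(observed)] <- observed
  if (sum(x) < 1) stop("input error: need at least one observed count")
  q <- pmax(background[aas], 1e-6)
  q <- q / sum(q)
  set.seed(seed)
  ct <- suppressWarnings(
    stats::chisq.test(x, p = q, simulate.p.value = TRUE, B = B)
  )
  test_result(
    "blosum_background", unname(ct$statistic), ct$p.value, sum(x),
    metadata = list(B = B, seed = seed)
  )
}

#' Collect test results into a long-format data frame
#'
#' @param results List of [test_result()] objects.
#' @return Data frame with one row per result; metadata fields mod_type,
#'   algorithm, statistic become columns when present.
#' @export
results_to_data_frame <- function(results) {
  grab <- function(r, field) {
    v <- r$metadata[[field]]
    if (is.null(v) || length(v) != 1) NA_character_ else as.character(v)
  }
  data.frame(
    test_name = vapply(results, `[[`, character(1), "test_name"),
    mod_type = vapply(results, grab, character(1), "mod_type"),
    algorithm = vapply(results, grab, character(1), "algorithm"),
    statistic = vapply(results, grab, character(1), "statistic"),
    chem_class = vapply(results, grab, character(1), "chem_class"),
    test_statistic = vapply(results, `[[`, numeric(1), "statistic"),
    p_value = vapply(results, `[[`, numeric(1), "p_value"),
    adjusted_p = vapply(results, `[[`, numeric(1), "adjusted_p"),
    n = vapply(results, function(r) as.integer(r$n), integer(1)),
    stringsAsFactors = FALSE
  )
}
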