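# End-to-end orchestration: align pairs -> enumerate sites -> score ->
# window statistics -> distribution-mean / pairing / chemical tests ->
# BH adjustment within families -> long-format results and heatmap-style
# matrices.

#' Unpaired one-sided Wilcoxon test within one chemical class
#'
#' The chemical-similarity analysis cannot keep the pairing structure
#' (target and paralog neighbors may fall into different classes), so the
#' target values whose adjacent residue belongs to the class are compared
#' with the paralog values of that class by an unpaired one-sided
#' Mann-Whitney-Wilcoxon test (alternative: targets larger).
#'
#' @param pairs A `paired_score_set` built with statistic `chem_b1` or
#'   `chem_a1` (has `target_class`/`paralog_class` columns).
#' @param chem_class One of the five chemical classes.
#' @return A [test_result()], or `NULL` if either stratum is empty.
#' @export
chemical_class_test <- function(pairs, chem_class) {
  tv <- pairs$target_value[pairs$target_class %in% chem_class]
  pv <- pairs$paralog_value[pairs$paralog_class %in% chem_class]
  if (length(tv) == 0 || length(pv) == 0) return(NULL)
  wt <- suppressWarnings(
    stats::wilcox.test(tv, pv, alternative = "greater", exact = FALSE)
  )
  test_result(
    "chemical_similarity", unname(wt$statistic), wt$p.value,
    length(tv) + length(pv),
    metadata = list(mod_type = unique(pairs$mod_type),
                    algorithm = attr(pairs, "algorithm"),
                    statistic = attr(pairs, "statistic"),
                    chem_class = chem_class)
  )
}

#' Run the full paralog-modification conservation analysis
#'
#' Executes the whole workflow on in-memory inputs: global alignment of
#' each paralog pair and enumeration of sites of interest; per-ORF
#' conservation profiles for every requested algorithm; window statistics
#' and matched score pairs per modification type; the distribution-mean
#' and paralog-pairing tests per algorithm x statistic x modification;
#' chemical-similarity tests per class; optional positional chi-square
#' with post hoc residuals for phosphoserine sites; and
#' Benjamini-Hochberg adjustment within families (one family per test and
#' algorithm across all window statistics and modification types).
#'
#' @param alignments Named list of [strain_alignment()] objects (one per
#'   ORF).
#' @param pairs Paralog-pair data frame (`orf_a`, `orf_b`).
#' @param mods Modification table.
#' @param algorithms Conservation algorithms to run.
#' @param statistics Window statistics for the two paired tests.
#' @param chem_statistics Chemical statistics (set `character(0)` to
#'   skip).
#' @param positional Logical: run the positional chi-square / post hoc
#'   analysis on phosphoserine sites.
#' @param tree Strain tree (required if `"phylozoom"` is requested).
#' @param gap_penalty Logical gap penalty for the profiles.
#' @param B Monte-Carlo replicates for pairing and chi-square tests.
#' @param seed Integer seed for all Monte-Carlo procedures.
#' @param min_pairs Minimum matched pairs needed to run the paired tests
#'   on a stratum (default 5).
#' @return List with `sites`, `results` (long-format data frame),
#'   `matrices` (one adjusted-p matrix per test x algorithm, rows =
#'   statistics, columns = modification types), `positional` (chi-square
#'   results and post hoc tables) and `counts` (records kept/dropped at
#'   each stage).
#' @export
run_full_analysis <- function(alignments, pairs, mods,
                              algorithms = "shannon",
                              statistics = paste0("mean", 1:4),
                              chem_statistics = c("chem_b1", "chem_a1"),
                              positional = FALSE,
                              tree = NULL, gap_penalty = FALSE,
                              B = 10000, seed = 1, min_pairs = 5) {
  sequences <- vapply(alignments, `[[`, character(1), "ref_sequence")
  names(sequences) <- vapply(alignments, `[[`, character(1), "orf_id")
  sites <- find_sites_of_interest(pairs, mods, sequences)
  counts <- list(n_pairs = nrow(pairs), n_mods = nrow(mods),
                 n_sites = nrow(sites), n_window_dropped = 0L)
  results <- list()
  family <- character(0)
  seed_i <- seed
  for (alg in algorithms) {
    profiles <- lapply(alignments, score_profile, algorithm = alg,
                       gap_penalty = gap_penalty, tree = tree)
    names(profiles) <- names(sequences)
    for (stat in statistics) {
      set_all <- suppressMessages(build_paired_sets(sites, profiles, stat))
      counts$n_window_dropped <- counts$n_window_dropped +
        attr(set_all, "n_dropped")
      for (m in unique(set_all$mod_type)) {
        sub <- set_all[set_all$mod_type == m, , drop = FALSE]
        attr(sub, "algorithm") <- alg
        attr(sub, "statistic") <- stat
        if (nrow(sub) < min_pairs) next
        if (any(sub$target_value != sub$paralog_value)) {
          results <- c(results, list(paired_wilcoxon_greater(sub)))
          family <- c(family, paste("distribution_mean", alg))
        }
        seed_i <- seed_i + 1L
        results <- c(results, list(paralog_pairing_test(sub, B = B,
                                                        seed = seed_i)))
        family <- c(family, paste("paralog_pairing", alg))
      }
    }
    for (stat in chem_statistics) {
      set_all <- suppressMessages(build_paired_sets(sites, profiles, stat))
      for (m in unique(set_all$mod_type)) {
        sub <- set_all[set_all$mod_type == m, , drop = FALSE]
        attr(sub, "algorithm") <- alg
        attr(sub, "statistic") <- stat
        for (cl in names(CHEM_CLASSES)) {
          tr <- chemical_class_test(sub, cl)
          if (is.null(tr) || tr$n < min_pairs) next
          results <- c(results, list(tr))
          family <- c(family, paste("chemical_similarity", alg))
        }
      }
    }
  }
  results <- adjust_results(results, family)
  results_df <- results_to_data_frame(results)
  pos_out <- NULL
  if (positional) {
    ph <- sites[sites$mod_type == "phosphorylation" & sites$residue == "S", ,
                drop = FALSE]
    if (nrow(ph) >= min_pairs) {
      pos_out <- positional_motif_analysis(ph, sequences, B = B, seed = seed)
    }
  }
  list(
    sites = sites,
    results = results_df,
    matrices = results_matrices(results_df),
    positional = pos_out,
    counts = counts
  )
}

#' Positional chi-square and post hoc analysis over all eight offsets
#'
#' Builds the target/paralog contingency table at each relative position
#' b4..a4, runs the Monte-Carlo chi-square test (p-values BH-adjusted
#' across the eight positions) and the post hoc standardized-residual
#' analysis per position.
#'
#' @param sites Sites of interest (typically one modification x residue
#'   stratum).
#' @param sequences Named reference protein sequences.
#' @param B Monte-Carlo replicates.
#' @param seed Integer seed.
#' @return List with `tests` (data frame over positions) and `posthoc`
#'   (named list of per-position residual tables).
#' @export
positional_motif_analysis <- function(sites, sequences, B = 10000, seed = 1) {
  offsets <- c(paste0("b", 4:1), paste0("a", 1:4))
  tests <- list()
  posthoc <- list()
  for (i in seq_along(offsets)) {
    tab <- build_position_contingency(sites, sequences, offsets[i])
    if (any(rowSums(tab) == 0)) next
    tests[[offsets[i]]] <- chi_square_motif_test(tab, B = B, seed = seed + i)
    posthoc[[offsets[i]]] <- posthoc_residuals(tab)
  }
  tests <- adjust_results(tests)
  df <- results_to_data_frame(tests)
  df$relative_position <- vapply(tests, function(r) {
    r$metadata$relative_position
  }, character(1))
  list(tests = df, posthoc = posthoc)
}

#' Adjusted-p matrices in heatmap layout
#'
#' One matrix per (test, algorithm): rows are window statistics (or
#' chemical class x statistic), columns are modification types, cells
#' hold adjusted p-values.
#'
#' @param results_df Long-format results from [results_to_data_frame()].
#' @return Named list of numeric matrices.
#' @export
results_matrices <- function(results_df) {
  out <- list()
  key <- paste(results_df$test_name, results_df$algorithm)
  for (k in unique(key)) {
    sub <- results_df[key == k, , drop = FALSE]
    rows <- if (all(is.na(sub$chem_class))) sub$statistic
            else paste(sub$statistic, sub$chem_class, sep = ":")
    m <- tapply(sub$adjusted_p, list(rows, sub$mod_type), `[`, 1)
    out[[k]] <- m
  }
  out
}

#' Write long-format results and matrices to a directory
#'
#' @param analysis Output of [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis_outputs <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(analysis$results, file.path(dir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_sites_tsv(analysis$sites, file.path(dir, "sites.tsv"))
  for (k in names(analysis$matrices)) {
    fn <- paste0("matrix_", gsub("[^A-Za-z0-9]+", "_", k), ".csv")
    utils::write.csv(analysis$matrices[[k]], file.path(dir, fn))
  }
  if (!is.null(analysis$positional)) {
    utils::write.table(analysis$positional$tests,
                       file.path(dir, "positional_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
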