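# Windowed conservation statistics around sites of interest: symmetric
# means (mean1..mean4), one-sided means (meanb1..meanb4, meana1..meana4)
# and the chemical-similarity average stratified by the adjacent residue's
# chemical class.  Windows live on ungapped reference coordinates of each
# protein; termini clip the window (no padding) and missing per-position
# scores are skipped.

.window_mean <- function(ref_scores, idx) {
  idx <- idx[idx >= 1 & idx <= length(ref_scores)]
  if (length(idx) == 0) return(NA_real_)
  v <- ref_scores[idx]
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' Symmetric window mean around a site
#'
#' Mean conservation score over positions `position - k .. position + k`
#' (2k+1 positions at an interior site: mean1 averages 3 residues, mean2
#' five, mean3 seven, mean4 nine), clipped at the protein termini.
#'
#' @param profile A `conservation_profile`.
#' @param position 1-based ungapped reference position.
#' @param k Half-width, 1..4.
#' @return The window mean, or `NA` if every window score is missing.
#' @export
symmetric_mean <- function(profile, position, k) {
  stopifnot(k >= 1, k <= 4)
  n <- length(profile$ref_scores)
  if (position < 1 || position > n) stop("index error: position outside 1..", n)
  .window_mean(profile$ref_scores, (position - k):(position + k))
}

#' One-sided window mean around a site
#'
#' Mean of the site score and the `k` scores strictly before
#' (`direction = "before"`, the meanb statistics) or strictly after
#' (`"after"`, meana) the site - `k + 1` positions at an interior site,
#' clipped at the termini.
#'
#' @inheritParams symmetric_mean
#' @param direction `"before"` or `"after"`.
#' @return The window mean, or `NA` if every window score is missing.
#' @export
one_sided_mean <- function(profile, position, direction = c("before", "after"),
                           k) {
  direction <- match.arg(direction)
  stopifnot(k >= 1, k <= 4)
  n <- length(profile$ref_scores)
  if (position < 1 || position > n) stop("index error: position outside 1..", n)
  idx <- if (direction == "before") (position - k):position
         else position:(position + k)
  .window_mean(profile$ref_scores, idx)
}

#' Chemical class of a standard amino acid
#'
#' The five classes - aliphatic (G,A,V,L,I,M,P), aromatic (F,Y,W), polar
#' uncharged (S,T,C,N,Q), acidic (E,D) and basic (K,R,H) - partition the
#' 20 standard amino acids.
#'
#' @param residue One-letter amino-acid code.
#' @return One of `"aliphatic"`, `"aromatic"`, `"polar_uncharged"`,
#'   `"acidic"`, `"basic"`.
#' @export
chemical_class_of <- function(residue) {
  cl <- .chem_class_of[toupper(residue)]
  if (anyNA(cl)) {
    stop("classification error: not a standard amino acid: ",
         paste(residue[is.na(cl)], collapse = ", "))
  }
  unname(cl)
}

#' Chemical-similarity average at a site
#'
#' Mean of the site score and the score of the residue immediately before
#' (`"before"`, the chem_b1 statistic) or after (`"after"`, chem_a1),
#' together with the chemical class of that adjacent residue, which is the
#' stratification key of the chemical-similarity analysis.
#'
#' @inheritParams one_sided_mean
#' @param neighbor_residue Optional override of the adjacent residue;
#'   defaults to the profile's reference residue at the adjacent position.
#' @return List with `chem_class` and `value`; both `NA` for a terminal
#'   site with no neighbor.
#' @export
chemical_similarity_mean <- function(profile, position,
                                     direction = c("before", "after"),
                                     neighbor_residue = NULL) {
  direction <- match.arg(direction)
  n <- length(profile$ref_scores)
  if (position < 1 || position > n) stop("index error: position outside 1..", n)
  nb <- if (direction == "before") position - 1 else position + 1
  if (nb < 1 || nb > n) {
    return(list(chem_class = NA_character_, value = NA_real_))
  }
  if (is.null(neighbor_residue)) neighbor_residue <- profile$ref_residues[nb]
  list(
    chem_class = chemical_class_of(neighbor_residue),
    value = .window_mean(profile$ref_scores, c(position, nb))
  )
}

# All statistic labels understood by window_statistic() / build_paired_sets().
.STATISTICS <- c(paste0("mean", 1:4), paste0("meanb", 1:4),
                 paste0("meana", 1:4), "chem_b1", "chem_a1")

#' Evaluate a named window statistic at a site
#'
#' Dispatches `mean1..mean4` to [symmetric_mean()], `meanb1..meanb4` /
#' `meana1..meana4` to [one_sided_mean()] and `chem_b1` / `chem_a1` to
#' [chemical_similarity_mean()].
#'
#' @inheritParams symmetric_mean
#' @param statistic Statistic label.
#' @return For mean statistics a number (or NA); for chemical statistics a
#'   list with `chem_class` and `value`.
#' @export
window_statistic <- function(profile, position, statistic) {
  statistic <- match.arg(statistic, .STATISTICS)
  if (grepl("^mean[1-4]$", statistic)) {
    return(symmetric_mean(profile, position, as.integer(substring(statistic, 5))))
  }
  if (grepl("^mean[ab][1-4]$", statistic)) {
    dir <- if (substring(statistic, 5, 5) == "b") "before" else "after"
    return(one_sided_mean(profile, position, dir,
                          as.integer(substring(statistic, 6))))
  }
  dir <- if (statistic == "chem_b1") "before" else "after"
  chemical_similarity_mean(profile, position, dir)
}

#' Matched target/paralog window scores for the sites of interest
#'
#' Evaluates one window statistic at every site of interest, in the target
#' and in the paralog protein, and assembles the matched value pairs used
#' by the distribution-mean and pairing tests.  Pairs with a missing
#' member are dropped with a message; drop counts are attached as
#' attribute `n_dropped`.
#'
#' @param sites Output of [find_sites_of_interest()].
#' @param profiles Named list of `conservation_profile` objects, one per
#'   ORF (all computed with the same algorithm).
#' @param statistic One of the mean/one-sided/chemical statistic labels
#'   (see [window_statistic()]).
#' @return Data frame of class `paired_score_set` with columns `mod_type`,
#'   `target_orf`, `paralog_orf`, `residue`, `target_position`,
#'   `paralog_position`, `target_value`, `paralog_value` and, for chemical
#'   statistics, `target_class` and `paralog_class`; attributes
#'   `algorithm` and `statistic` record provenance.
#' @export
build_paired_sets <- function(sites, profiles, statistic) {
  statistic <- match.arg(statistic, .STATISTICS)
  needed <- unique(c(sites$target_orf, sites$paralog_orf))
  missing <- setdiff(needed, names(profiles))
  if (length(missing) > 0) {
    stop("missing-profile error: no profile for ",
         paste(missing, collapse = ", "))
  }
  chem <- statistic %in% c("chem_b1", "chem_a1")
  n <- nrow(sites)
  tv <- pv <- rep(NA_real_, n)
  tc <- pc <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    st <- window_statistic(profiles[[sites$target_orf[i]]],
                           sites$target_position[i], statistic)
    sp <- window_statistic(profiles[[sites$paralog_orf[i]]],
                           sites$paralog_position[i], statistic)
    if (chem) {
      tv[i] <- st$value; pv[i] <- sp$value
      tc[i] <- st$chem_class; pc[i] <- sp$chem_class
    } else {
      tv[i] <- st; pv[i] <- sp
    }
  }
  keep <- !is.na(tv) & !is.na(pv)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("dropped ", n_dropped, " site(s) with a missing window score")
  }
  out <- data.frame(
    mod_type = sites$mod_type[keep],
    target_orf = sites$target_orf[keep],
    paralog_orf = sites$paralog_orf[keep],
    residue = sites$residue[keep],
    target_position = sites$target_position[keep],
    paralog_position = sites$paralog_position[keep],
    target_value = tv[keep],
    paralog_value = pv[keep],
    stringsAsFactors = FALSE
  )
  if (chem) {
    out$target_class <- tc[keep]
    out$paralog_class <- pc[keep]
  }
  rownames(out) <- NULL
  structure(out, class = c("paired_score_set", "data.frame"),
            algorithm = profiles[[1]]$algorithm, statistic = statistic,
            n_dropped = n_dropped)
}

#' Export a paired score set as TSV
#'
#' @param pairs A `paired_score_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paired_set_tsv <- function(pairs, path) {
  df <- as.data.frame(pairs)
  df$algorithm <- attr(pairs, "algorithm")
  df$statistic <- attr(pairs, "statistic")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
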