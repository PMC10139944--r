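# Per-column conservation scores.  All five algorithms return values in
# [0, 1], 1 perfectly conserved and 0 random; columns with no usable
# symbols return NA (a missing value that downstream averages skip, not 0).
#
# Gaps are the symbols X, B, Z and '-'.  Entropies use the natural log
# normalized by log(alphabet size), which is base-invariant.

.is_gap <- function(symbols) symbols %in% GAP_SYMBOLS

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Shannon-entropy conservation score of one column
#'
#' `1 - H(p)/log(20)` with `H` the Shannon entropy of the amino-acid
#' frequencies of the column's non-gap symbols.  A monomorphic column
#' scores 1; a column exactly uniform over the 20 standard amino acids
#' scores 0.
#'
#' @param column Character vector of column symbols.
#' @return Score in `[0, 1]`, or `NA` if the column has no non-gap symbol.
#' @export
shannon_score <- function(column) {
  aa <- column[!.is_gap(column)]
  if (length(aa) == 0) return(NA_real_)
  p <- table(aa) / length(aa)
  1 - .entropy(as.numeric(p)) / log(20)
}

#' Stereochemically sensitive entropy score of one column
#'
#' As [shannon_score()], but amino acids are grouped into nine
#' stereochemical groups (VLIM, FWY, ST, NQ, HKR, DE, AG, P, C) whose
#' members are treated as a single entity; normalization is by `log(9)`.
#'
#' @inheritParams shannon_score
#' @return Score in `[0, 1]`, or `NA` for an all-gap column.
#' @export
stereo_entropy_score <- function(column) {
  aa <- column[!.is_gap(column)]
  if (length(aa) == 0) return(NA_real_)
  groups <- .stereo_group_of[aa]
  p <- table(groups) / length(groups)
  1 - .entropy(as.numeric(p)) / log(9)
}

#' Jensen-Shannon divergence conservation score of one column
#'
#' `JSD(p, q) = H((p+q)/2) - H(p)/2 - H(q)/2` between the column's
#' empirical amino-acid distribution `p` and the background `q`
#' (BLOSUM62-derived marginals by default), normalized by its maximum
#' `log(2)`.  Large divergence from the no-selection background reads as
#' conservation.
#'
#' @inheritParams shannon_score
#' @param background Named frequency vector over the 20 amino acids.
#' @return Score in `[0, 1]`, or `NA` for an all-gap column.
#' @export
jsd_score <- function(column, background = blosum62_background()) {
  aa <- column[!.is_gap(column)]
  if (length(aa) == 0) return(NA_real_)
  p <- stats::setNames(numeric(20), amino_acids())
  tab <- table(aa)
  p[names(tab)] <- as.numeric(tab) / length(aa)
  q <- background[amino_acids()]
  m <- (p + q) / 2
  jsd <- .entropy(m) - (.entropy(p) + .entropy(q)) / 2
  max(0, min(1, jsd / log(2)))
}

#' Phylogeny-weighted mismatch conservation score of one column
#'
#' Reference-anchored score `1 - sum(w * mismatch) / sum(w)` over non-gap
#' comparison strains, with weights `w = 1/(d + eps)` where `d` is the
#' patristic distance of the strain to the reference.  A mutation in a
#' strain closely related to the reference is penalized heavily; the same
#' mutation in a distant strain only lightly.  On a star tree with equal
#' branch lengths the score reduces to the fraction of comparison strains
#' matching the reference.
#'
#' This is the package's own distance-weighted formulation of the
#' phylogeny-aware ("zoom"-style) score; it satisfies the reference
#' anchoring and distance-monotonic penalty that define that score family.
#'
#' @param column Named character vector of symbols, names are strain
#'   identifiers.
#' @param tree [ape::phylo] strain tree; every strain in `column` must be
#'   a leaf.
#' @param reference Reference strain identifier.
#' @param epsilon Small positive constant added to distances; defaults to
#'   `1e-6 *` tree diameter (or `1e-6` on a zero-length tree).
#' @param dists Optional precomputed [leaf_distances()] vector (speeds up
#'   whole-profile scoring).
#' @return Score in `[0, 1]`; `NA` if the reference symbol is a gap or no
#'   comparison strain has a non-gap symbol.
#' @export
phylozoom_score <- function(column, tree, reference, epsilon = NULL,
                            dists = NULL) {
  if (is.null(names(column))) stop("column must be named by strain")
  if (!reference %in% names(column)) {
    stop("missing-reference error: ", reference)
  }
  ref_sym <- column[[reference]]
  if (.is_gap(ref_sym)) return(NA_real_)
  if (is.null(dists)) dists <- leaf_distances(tree, reference)
  if (is.null(epsilon)) {
    diam <- max(dists)
    epsilon <- if (diam > 0) 1e-6 * diam else 1e-6
  }
  others <- setdiff(names(column), reference)
  sym <- column[others]
  keep <- !.is_gap(sym)
  if (!any(keep)) return(NA_real_)
  sym <- sym[keep]
  d <- dists[names(sym)]
  if (anyNA(d)) {
    stop("missing-leaf error: ", paste(names(sym)[is.na(d)], collapse = ", "))
  }
  w <- 1 / (d + epsilon)
  1 - sum(w * (sym != ref_sym)) / sum(w)
}

#' Karlin substitution-matrix conservation score of one column
#'
#' Averages the normalized substitution score
#' `M(a, b)/sqrt(M(a, a) * M(b, b))` over all unordered pairs of non-gap
#' symbols in the column; the resulting value in (-1, 1) is reranged to
#' (0, 1) as `(s + 1)/2`.  Gap-containing sequences are excluded from the
#' pair sum and no additional gap penalty is ever applied (the matrix
#' normalization already penalizes rare substitutions).
#'
#' @inheritParams shannon_score
#' @param substitution Substitution matrix (default BLOSUM62) with
#'   positive diagonal.
#' @return Score in `[0, 1]`, or `NA` with fewer than 2 non-gap symbols.
#' @export
karlin_score <- function(column, substitution = blosum62_matrix()) {
  aa <- column[!.is_gap(column)]
  n <- length(aa)
  if (n < 2) return(NA_real_)
  tab <- table(aa)
  syms <- names(tab)
  cnt <- as.numeric(tab)
  diag_m <- diag(substitution[syms, syms, drop = FALSE])
  total <- 0
  for (i in seq_along(syms)) {
    # same-symbol pairs normalize to exactly 1
    total <- total + cnt[i] * (cnt[i] - 1) / 2
    if (i < length(syms)) {
      for (j in (i + 1):length(syms)) {
        v <- substitution[syms[i], syms[j]] / sqrt(diag_m[i] * diag_m[j])
        total <- total + cnt[i] * cnt[j] * v
      }
    }
  }
  s <- 2 * total / (n * (n - 1))
  unname((s + 1) / 2)
}

#' Multiply a score by the column's non-gap fraction
#'
#' The optional gap penalty: `score * (fraction of symbols not in
#' {X, B, Z, '-'})`.  Not applied to the Karlin score, whose gap handling
#' is inherent in the matrix normalization.
#'
#' @param score Score in `[0, 1]` (NA passes through).
#' @param column Character vector of column symbols.
#' @return Penalized score.
#' @export
apply_gap_penalty <- function(score, column) {
  score * mean(!.is_gap(column))
}

#' Fraction of gap symbols per column
#'
#' @param aln A `strain_alignment`.
#' @return Numeric vector of length L with the fraction of symbols in
#'   `{X, B, Z, '-'}` per column.
#' @export
gap_fraction <- function(aln) {
  colMeans(matrix(.is_gap(aln$chars), nrow = nrow(aln$chars)))
}

#' Per-column conservation profile of a multi-strain alignment
#'
#' Applies one of the five per-column scores (plus the optional gap
#' penalty) to every column and indexes the result both by alignment
#' column and by ungapped reference position.
#'
#' @param aln A `strain_alignment`.
#' @param algorithm One of `"shannon"`, `"stereo"`, `"jsd"`,
#'   `"phylozoom"`, `"karlin"`.
#' @param gap_penalty Logical; multiply scores by the non-gap fraction
#'   (ignored for `"karlin"`).
#' @param tree Strain tree, required for `"phylozoom"`.
#' @param background Background frequencies for `"jsd"`.
#' @param substitution Substitution matrix for `"karlin"`.
#' @param epsilon Distance offset for `"phylozoom"`.
#' @return Object of class `conservation_profile`: list with `orf_id`,
#'   `algorithm`, `scores` (length L, NA at undefined columns),
#'   `gap_fraction`, `ref_positions` (alignment column of each ungapped
#'   reference position), `ref_scores` (scores at reference positions) and
#'   `ref_residues` (the reference protein split into residues).
#' @export
score_profile <- function(aln,
                          algorithm = c("shannon", "stereo", "jsd",
                                        "phylozoom", "karlin"),
                          gap_penalty = FALSE, tree = NULL,
                          background = blosum62_background(),
                          substitution = blosum62_matrix(),
                          epsilon = NULL) {
  algorithm <- match.arg(algorithm)
  chars <- aln$chars
  L <- ncol(chars)
  if (algorithm == "phylozoom") {
    if (is.null(tree)) stop("phylozoom requires a strain tree")
    dists <- leaf_distances(tree, aln$reference_strain)
    missing <- setdiff(aln$strain_ids, names(dists))
    if (length(missing) > 0) {
      stop("missing-leaf error: ", paste(missing, collapse = ", "))
    }
    if (is.null(epsilon)) {
      diam <- max(dists, ape::dist.nodes(tree)[seq_along(tree$tip.label),
                                               seq_along(tree$tip.label)])
      epsilon <- if (diam > 0) 1e-6 * diam else 1e-6
    }
    others <- setdiff(aln$strain_ids, aln$reference_strain)
    cmp <- chars[others, , drop = FALSE]
    nongap <- !matrix(.is_gap(cmp), nrow = nrow(cmp))
    ref_row <- chars[aln$reference_strain, ]
    w <- 1 / (dists[others] + epsilon)
    mism <- (cmp != matrix(ref_row, nrow(cmp), L, byrow = TRUE)) & nongap
    denom <- colSums(w * nongap)
    scores <- 1 - colSums(w * mism) / denom
    scores[.is_gap(ref_row) | denom == 0] <- NA_real_
  } else {
    # per-column symbol counts for all columns at once (columns x symbols)
    aas <- amino_acids()
    cnt <- t(table(factor(chars, levels = aas), col(chars)))
    n <- rowSums(cnt)
    ent <- function(p) {
      # rowwise entropy of a proportions matrix, 0 log 0 = 0
      x <- ifelse(p > 0, p * log(p), 0)
      -rowSums(x)
    }
    if (algorithm == "shannon") {
      scores <- 1 - ent(cnt / n) / log(20)
      scores[n == 0] <- NA_real_
    } else if (algorithm == "stereo") {
      grp <- t(rowsum(t(cnt), .stereo_group_of[aas]))
      scores <- 1 - ent(grp / n) / log(9)
      scores[n == 0] <- NA_real_
    } else if (algorithm == "jsd") {
      p <- cnt / n
      q <- matrix(background[aas], nrow(cnt), 20, byrow = TRUE)
      jsd <- ent((p + q) / 2) - (ent(p) + ent(q)) / 2
      scores <- pmax(0, pmin(1, jsd / log(2)))
      scores[n == 0] <- NA_real_
    } else {
      V <- substitution[aas, aas] /
        sqrt(outer(diag(substitution[aas, aas]),
                   diag(substitution[aas, aas])))
      cross <- rowSums((cnt %*% V) * cnt)   # ordered sum incl. same-symbol
      sumsq <- rowSums(cnt^2)
      total <- (cross - sumsq) / 2 + (sumsq - n) / 2
      scores <- (2 * total / (n * (n - 1)) + 1) / 2
      scores[n < 2] <- NA_real_
    }
  }
  scores <- unname(scores)
  gf <- gap_fraction(aln)
  if (gap_penalty && algorithm != "karlin") {
    scores <- scores * (1 - gf)
  }
  ref_res <- strsplit(aln$ref_sequence, "", fixed = TRUE)[[1]]
  structure(
    list(
      orf_id = aln$orf_id,
      algorithm = algorithm,
      gap_penalty = gap_penalty && algorithm != "karlin",
      scores = scores,
      gap_fraction = gf,
      ref_positions = aln$ref_map,
      ref_scores = scores[aln$ref_map],
      ref_residues = ref_res
    ),
    class = "conservation_profile"
  )
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("conservation_profile '", x$orf_id, "' (", x$algorithm,
      if (x$gap_penalty) ", gap penalty" else "", "): ",
      length(x$scores), " columns, ", length(x$ref_scores),
      " reference positions\n", sep = "")
  invisible(x)
}

#' Export a conservation profile as TSV
#'
#' One row per ungapped reference position with its alignment column,
#' residue, score and gap fraction.
#'
#' @param profile A `conservation_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(
    orf = profile$orf_id,
    column = profile$ref_positions,
    ref_position = seq_along(profile$ref_positions),
    ref_residue = profile$ref_residues,
    algorithm = profile$algorithm,
    score = profile$ref_scores,
    gap_fraction = profile$gap_fraction[profile$ref_positions],
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
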