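# Annex analyses: kinase-interaction summaries, PWM kinase assignment,
# abundance and multi-study filters, and secondary-structure comparison
# from STRIDE detailed assignments.

#' Read a kinase-substrate interaction table
#'
#' @param path TSV with header columns `kinase`, `substrate` and
#'   optionally `evidence`.  Duplicate (kinase, substrate) rows are
#'   deduplicated; evidence types are not filtered.
#' @return Data frame with columns `kinase`, `substrate` (and `evidence`
#'   if present), one row per unique kinase-substrate pair.
#' @export
read_kinase_interactions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("kinase", "substrate") %in% names(tab))) {
    stop("interaction table must have columns kinase, substrate")
  }
  tab[!duplicated(tab[, c("kinase", "substrate")]), , drop = FALSE]
}

#' Single-interaction ratio of a paralog pair
#'
#' Number of kinases interacting with exactly one member of the pair,
#' divided by the number interacting with at least one member.  A pair of
#' identically wired proteins scores 0; a pair whose kinases are all
#' exclusive scores 1.  `NA` when no kinase interacts with either member.
#'
#' @param orf_a,orf_b The two ORF identifiers.
#' @param interactions Interaction table from
#'   [read_kinase_interactions()].
#' @return Ratio in `[0, 1]`, or `NA`.
#' @export
single_interaction_ratio <- function(orf_a, orf_b, interactions) {
  ka <- unique(interactions$kinase[interactions$substrate == orf_a])
  kb <- unique(interactions$kinase[interactions$substrate == orf_b])
  n_double <- length(intersect(ka, kb))
  n_single <- length(ka) + length(kb) - 2 * n_double
  if (n_single + n_double == 0) return(NA_real_)
  n_single / (n_single + n_double)
}

#' Single-interaction ratios for a table of paralog pairs
#'
#' @param pairs Data frame with columns `orf_a`, `orf_b`.
#' @param interactions Interaction table.
#' @return The pair table with an added `single_interaction_ratio` column
#'   (`NA` for pairs without any kinase interaction).
#' @export
single_interaction_ratios <- function(pairs, interactions) {
  pairs$single_interaction_ratio <- vapply(
    seq_len(nrow(pairs)),
    function(i) single_interaction_ratio(pairs$orf_a[i], pairs$orf_b[i],
                                         interactions),
    numeric(1)
  )
  pairs
}

#' Read kinase position-weight matrices
#'
#' @param path TSV with columns `kinase`, `position` (offset relative to
#'   the phosphosite, e.g. -5..4) and one weight column per amino acid.
#' @return Named list of matrices (rows = offsets as character, columns =
#'   the 20 amino acids), one per kinase.
#' @export
read_pwms <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  aas <- amino_acids()
  if (!all(c("kinase", "position", aas) %in% names(tab))) {
    stop("PWM table must have columns kinase, position and the 20 amino acids")
  }
  out <- lapply(split(tab, tab$kinase), function(df) {
    m <- as.matrix(df[, aas])
    rownames(m) <- as.character(df$position)
    m
  })
  out[order(names(out))]
}

#' PWM score of a phosphosite window
#'
#' Sums the weight of the observed residue at each PWM offset over the
#' window around the site.  Offsets falling outside the sequence, or on a
#' nonstandard residue, are skipped (their weights are omitted, not
#' padded).
#'
#' @param sequence Protein string.
#' @param position 1-based phosphosite position.
#' @param pwm Matrix from [read_pwms()].
#' @return Numeric score.
#' @export
score_pwm <- function(sequence, position, pwm) {
  total <- 0
  n <- nchar(sequence)
  for (off in as.integer(rownames(pwm))) {
    pos <- position + off
    if (pos < 1 || pos > n) next
    aa <- substr(sequence, pos, pos)
    if (!aa %in% colnames(pwm)) next
    total <- total + pwm[as.character(off), aa]
  }
  total
}

#' Assign the best-scoring kinase to a phosphosite
#'
#' The kinase whose PWM gives the highest summed weight over the window
#' around the site; ties break deterministically by kinase identifier
#' order.
#'
#' @param sequence Protein string.
#' @param position 1-based phosphosite position.
#' @param pwms Named list of PWMs.
#' @return Kinase identifier.
#' @export
assign_best_kinase <- function(sequence, position, pwms) {
  if (length(pwms) == 0) stop("input error: empty PWM list")
  ids <- sort(names(pwms))
  scores <- vapply(ids, function(k) score_pwm(sequence, position, pwms[[k]]),
                   numeric(1))
  ids[which.max(scores)]
}

#' Paralog pairs whose assigned kinase sets are disjoint
#'
#' For each pair, assigns a kinase to every phosphosite of interest of
#' each member (the member's sites as target) and keeps pairs where both
#' members have at least one qualifying site; reports which of those have
#' completely different assigned kinase sets.
#'
#' @param pairs Data frame with columns `orf_a`, `orf_b`.
#' @param sites Output of [find_sites_of_interest()]; only
#'   phosphorylation sites are used.
#' @param sequences Named character vector of protein sequences.
#' @param pwms Named list of PWMs.
#' @return Data frame of qualifying pairs with columns `orf_a`, `orf_b`,
#'   `kinases_a`, `kinases_b` (comma-joined), `disjoint`.
#' @export
disjoint_kinase_pairs <- function(pairs, sites, sequences, pwms) {
  ph <- sites[sites$mod_type == "phosphorylation", , drop = FALSE]
  assign_set <- function(orf) {
    sel <- ph$target_orf == orf
    if (!any(sel)) return(character(0))
    unique(vapply(which(sel), function(i) {
      assign_best_kinase(sequences[[orf]], ph$target_position[i], pwms)
    }, character(1)))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ka <- assign_set(pairs$orf_a[i])
    kb <- assign_set(pairs$orf_b[i])
    if (length(ka) == 0 || length(kb) == 0) return(NULL)
    data.frame(
      orf_a = pairs$orf_a[i], orf_b = pairs$orf_b[i],
      kinases_a = paste(sort(ka), collapse = ","),
      kinases_b = paste(sort(kb), collapse = ","),
      disjoint = length(intersect(ka, kb)) == 0,
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(orf_a = character(0), orf_b = character(0),
                      kinases_a = character(0), kinases_b = character(0),
                      disjoint = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Keep paralog pairs with similar median abundance
#'
#' Retains pairs whose abundance ratio `max/min` is strictly below
#' `max_fold`; pairs with a missing abundance are dropped with a message.
#'
#' @param pairs Data frame with columns `orf_a`, `orf_b`.
#' @param abundances Data frame with columns `orf_id`,
#'   `median_abundance` (positive).
#' @param max_fold Fold-change threshold (> 1; default 2).
#' @return Filtered pair table; dropped-for-missing count attached as
#'   attribute `n_missing`.
#' @export
filter_pairs_by_abundance <- function(pairs, abundances, max_fold = 2) {
  stopifnot(max_fold > 1)
  if (any(abundances$median_abundance <= 0)) {
    stop("input error: abundances must be positive")
  }
  ab <- stats::setNames(abundances$median_abundance, abundances$orf_id)
  a <- ab[pairs$orf_a]
  b <- ab[pairs$orf_b]
  known <- !is.na(a) & !is.na(b)
  n_missing <- sum(!known)
  if (n_missing > 0) {
    message("dropped ", n_missing, " pair(s) with missing abundance")
  }
  keep <- known & pmax(a, b) / pmin(a, b) < max_fold
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_missing") <- n_missing
  out
}

#' Keep modifications reported by multiple studies
#'
#' @param mods Modification table (with `study_ids` list column or
#'   `n_studies`).
#' @param min_studies Minimum number of distinct studies (default 2).
#' @return Filtered modification table.
#' @export
filter_multi_study <- function(mods, min_studies = 2) {
  stopifnot(min_studies >= 1)
  n <- if ("n_studies" %in% names(mods)) mods$n_studies
       else vapply(mods$study_ids, length, integer(1))
  out <- mods[n >= min_studies, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# STRIDE one-letter codes -> full secondary-structure names
.STRIDE_CLASSES <- c(H = "AlphaHelix", G = "310Helix", I = "PiHelix",
                     E = "Strand", B = "Bridge", b = "Bridge",
                     T = "Turn", C = "Coil")

#' Parse STRIDE detailed secondary-structure assignments
#'
#' Reads the `ASG` records of a STRIDE output file: one per residue, with
#' the structure class and the residue solvent accessible area.
#' Non-contiguous residue numbering triggers a warning but records are
#' kept.
#'
#' @param path Path to a STRIDE output file.
#' @param orf_id Identifier to attach to the records.
#' @return Data frame with columns `orf_id`, `position`, `residue`
#'   (one-letter where standard, else the 3-letter code),
#'   `secondary_structure`, `solvent_accessible_area`.  Empty file (no ASG
#'   lines) gives zero rows.
#' @export
parse_stride <- function(path, orf_id = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  asg <- grep("^ASG ", lines, value = TRUE)
  if (length(asg) == 0) {
    return(data.frame(orf_id = character(0), position = integer(0),
                      residue = character(0),
                      secondary_structure = character(0),
                      solvent_accessible_area = numeric(0),
                      stringsAsFactors = FALSE))
  }
  three_to_one <- stats::setNames(
    c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
      "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
  )
  parse_line <- function(i) {
    f <- strsplit(trimws(asg[i]), "[[:space:]]+")[[1]]
    # ASG resname chain pdb_num ordinal code full_name phi psi area ...
    if (length(f) < 10) {
      stop("parse error: malformed ASG record at ASG line ", i)
    }
    pos <- suppressWarnings(as.integer(f[5]))
    area <- suppressWarnings(as.numeric(f[10]))
    ss <- f[7]
    if (!ss %in% .STRIDE_CLASSES) ss <- .STRIDE_CLASSES[f[6]]
    if (is.na(pos) || is.na(area) || is.na(ss)) {
      stop("parse error: malformed ASG record at ASG line ", i)
    }
    res <- three_to_one[f[2]]
    if (is.na(res)) res <- f[2]
    data.frame(orf_id = orf_id, position = pos, residue = unname(res),
               secondary_structure = unname(ss),
               solvent_accessible_area = area, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_along(asg), parse_line))
  if (any(diff(out$position) != 1)) {
    warning("non-contiguous residue numbering in ", path)
  }
  if (any(out$solvent_accessible_area < 0)) {
    stop("parse error: negative solvent accessible area")
  }
  rownames(out) <- NULL
  out
}

#' Length of the uninterrupted secondary-structure stretch at a position
#'
#' @param records STRIDE records for one protein (from [parse_stride()]).
#' @param position 1-based residue position.
#' @return Integer run length of the maximal stretch of identical
#'   structure class containing the position, or `NA` if the position is
#'   not covered.
#' @export
secondary_structure_length <- function(records, position) {
  i <- match(position, records$position)
  if (is.na(i)) return(NA_integer_)
  runs <- rle(records$secondary_structure)
  ends <- cumsum(runs$lengths)
  r <- which(i <= ends)[1]
  runs$lengths[r]
}

#' Structure difference between target and paralog at a site
#'
#' Target-minus-paralog differences of secondary-structure run length and
#' residue solvent accessible area, labelled by the target-first class
#' pair (so `Coil-Turn` and `Turn-Coil` are distinct, preserving
#' antisymmetry under swapping).
#'
#' @param site One row of [find_sites_of_interest()] output.
#' @param target_records,paralog_records STRIDE records for the two
#'   proteins.
#' @return List with `class_pair`, `d_length`, `d_area`, or `NULL` when
#'   either position is not covered.
#' @export
pair_structure_difference <- function(site, target_records, paralog_records) {
  ti <- match(site$target_position, target_records$position)
  pi <- match(site$paralog_position, paralog_records$position)
  if (is.na(ti) || is.na(pi)) return(NULL)
  tl <- secondary_structure_length(target_records, site$target_position)
  pl <- secondary_structure_length(paralog_records, site$paralog_position)
  list(
    class_pair = paste(target_records$secondary_structure[ti],
                       paralog_records$secondary_structure[pi], sep = "-"),
    d_length = tl - pl,
    d_area = target_records$solvent_accessible_area[ti] -
      paralog_records$solvent_accessible_area[pi]
  )
}

#' Structure differences for many sites
#'
#' Applies [pair_structure_difference()] to every site; uncovered sites
#' are skipped with a count.
#'
#' @param sites Output of [find_sites_of_interest()].
#' @param stride_records Named list of STRIDE record data frames, one per
#'   ORF.
#' @return Data frame with columns `class_pair`, `d_length`, `d_area`;
#'   skip count attached as attribute `n_skipped`.
#' @export
pair_structure_differences <- function(sites, stride_records) {
  rows <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(sites))) {
    tr <- stride_records[[sites$target_orf[i]]]
    pr <- stride_records[[sites$paralog_orf[i]]]
    if (is.null(tr) || is.null(pr)) { n_skipped <- n_skipped + 1L; next }
    d <- pair_structure_difference(sites[i, ], tr, pr)
    if (is.null(d)) { n_skipped <- n_skipped + 1L; next }
    rows[[length(rows) + 1L]] <- as.data.frame(d, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) == 0) {
    data.frame(class_pair = character(0), d_length = integer(0),
               d_area = numeric(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}
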