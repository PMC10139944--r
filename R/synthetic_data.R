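# Seed-deterministic generators for every input the pipeline consumes:
# multi-strain alignments with controlled per-column conservation, paralog
# pair datasets with an optional planted flanking-conservation advantage,
# score-level fixtures for the three distribution/pairing regimes, motif
# datasets with a planted positional enrichment, and a random strain tree.

# residue carrying each modification type in simulated data
.MOD_RESIDUE <- c(phosphorylation = "S", ubiquitylation = "K",
                  monoacetylation = "K", "N-glycosylation" = "N",
                  succinylation = "K")

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic generators.  Defaults describe a
#' desk-scale dataset: 64 strains, 60-residue proteins, two modified
#' sites per pair, a mid-range conservation level with spread, and no
#' planted advantage (the exchangeable null).
#'
#' @param n_strains Strains per alignment (including the reference).
#' @param n_pairs Number of paralog pairs.
#' @param sites_per_pair Modified sites per target protein.
#' @param protein_length Ungapped protein length.
#' @param conservation_base Center of the per-pair conservation baseline
#'   in `[0, 1]`.
#' @param conservation_spread Half-width of the uniform spread of the
#'   pair-shared baseline around the base level.  Both members of a pair
#'   share one baseline, reflecting the shared evolutionary history of
#'   paralogs; this between-pair heterogeneity is what gives the pairing
#'   structure meaning.
#' @param pair_spread Half-width of the per-column jitter around the
#'   pair baseline (within-pair, i.i.d. for target and paralog columns).
#' @param flank_advantage Extra conservation added to target columns
#'   within +-4 of each modified site (0 = exchangeable null).
#' @param mod_type Modification type to plant.
#' @param reference_strain Reference strain identifier.
#' @param seed Integer seed; every generator is bit-reproducible given the
#'   same config.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_strains = 64, n_pairs = 50, sites_per_pair = 2,
                       protein_length = 60, conservation_base = 0.7,
                       conservation_spread = 0.2, pair_spread = 0.05,
                       flank_advantage = 0,
                       mod_type = "phosphorylation",
                       reference_strain = "REF", seed = 1) {
  stopifnot(n_strains >= 2, n_pairs >= 1, sites_per_pair >= 1,
            conservation_base >= 0, conservation_base <= 1,
            conservation_spread >= 0, pair_spread >= 0,
            flank_advantage >= 0, mod_type %in% MOD_TYPES)
  structure(
    list(n_strains = n_strains, n_pairs = n_pairs,
         sites_per_pair = sites_per_pair, protein_length = protein_length,
         conservation_base = conservation_base,
         conservation_spread = conservation_spread,
         pair_spread = pair_spread,
         flank_advantage = flank_advantage, mod_type = mod_type,
         reference_strain = reference_strain, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a multi-strain alignment with controlled conservation
#'
#' The reference row carries the consensus sequence; every comparison
#' strain keeps the consensus residue of column j with probability
#' `conservation[j]` and otherwise draws a residue from the background
#' distribution.  Realized conservation scores increase monotonically with
#' the requested level.
#'
#' @param orf_id ORF identifier.
#' @param conservation Vector of per-column conservation levels in
#'   `[0, 1]`; its length is the protein length.
#' @param n_strains Number of strains (including the reference).
#' @param consensus Optional consensus sequence (string); sampled from the
#'   background when omitted.  Must match `length(conservation)`.
#' @param background Residue frequencies for the consensus and for
#'   mutated positions (default [blosum62_background()]).
#' @param reference_strain Reference strain identifier.
#' @param seed Integer seed.
#' @return A [strain_alignment()] (gap-free).
#' @export
simulate_alignment <- function(orf_id, conservation, n_strains = 64,
                               consensus = NULL,
                               background = blosum62_background(),
                               reference_strain = "REF", seed = 1) {
  if (any(conservation < 0 | conservation > 1)) {
    stop("input error: conservation values must lie in [0, 1]")
  }
  L <- length(conservation)
  set.seed(seed)
  aas <- amino_acids()
  if (is.null(consensus)) {
    cons <- sample(aas, L, replace = TRUE, prob = background[aas])
  } else {
    cons <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
    if (length(cons) != L) {
      stop("input error: consensus length differs from conservation length")
    }
  }
  n_cmp <- n_strains - 1L
  mat <- matrix(rep(cons, each = n_cmp), nrow = n_cmp)
  mutate <- matrix(stats::runif(n_cmp * L), nrow = n_cmp) >
    matrix(rep(conservation, each = n_cmp), nrow = n_cmp)
  n_mut <- sum(mutate)
  if (n_mut > 0) {
    mat[mutate] <- sample(aas, n_mut, replace = TRUE, prob = background[aas])
  }
  rows <- c(paste(cons, collapse = ""), apply(mat, 1, paste, collapse = ""))
  names(rows) <- c(reference_strain,
                   sprintf("strain%04d", seq_len(n_cmp)))
  strain_alignment(orf_id, rows, reference_strain)
}

#' Simulate a full paralog-pair dataset
#'
#' Each pair consists of two ORFs sharing an identical consensus protein
#' (so every position is a candidate site) whose strain alignments vary
#' independently.  Each pair draws one shared conservation baseline from
#' `U(base - spread, base + spread)` - paralogs share their evolutionary
#' history, so overall conservation is a pair-level property - and the
#' per-column conservation of each member is drawn i.i.d. around that
#' baseline with half-width `pair_spread`.  With `flank_advantage > 0`
#' the target's columns within +-4 of each modified site get that much
#' extra conservation (the planted signal); otherwise target and paralog
#' flank conservation is exchangeable within each pair (the null).
#' Modified sites are planted in the first ORF of each pair at evenly
#' spaced interior positions, on the residue canonical for the
#' modification type.
#'
#' @param config A [sim_config()].
#' @return List with `alignments` (named list of [strain_alignment()]),
#'   `pairs` (orf_a/orf_b data frame), `mods` (modification table for the
#'   target ORFs) and `site_positions`.
#' @export
simulate_paralog_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$protein_length
  k <- config$sites_per_pair
  margin <- 6L
  if (L < 2 * margin + (k - 1) * 10) {
    stop("protein_length too small for ", k, " spaced sites")
  }
  site_pos <- as.integer(round(seq(margin, L - margin, length.out = k)))
  residue <- .MOD_RESIDUE[[config$mod_type]]
  aas <- amino_acids()
  bg <- blosum62_background()
  lo <- max(0.02, config$conservation_base - config$conservation_spread)
  hi <- min(0.99, config$conservation_base + config$conservation_spread)
  flank_cols <- unique(unlist(lapply(site_pos, function(p) {
    (p - 4):(p + 4)
  })))
  flank_cols <- flank_cols[flank_cols >= 1 & flank_cols <= L]
  alignments <- list()
  mods <- list()
  pairs <- data.frame(orf_a = sprintf("TGT%04d", seq_len(config$n_pairs)),
                      orf_b = sprintf("PAR%04d", seq_len(config$n_pairs)),
                      stringsAsFactors = FALSE)
  sub_seeds <- sample.int(.Machine$integer.max, 2 * config$n_pairs)
  for (i in seq_len(config$n_pairs)) {
    cons <- sample(aas, L, replace = TRUE, prob = bg[aas])
    cons[site_pos] <- residue
    baseline <- stats::runif(1, lo, hi)
    w <- config$pair_spread
    cons_t <- pmin(0.995, pmax(0.01, stats::runif(L, baseline - w, baseline + w)))
    cons_p <- pmin(0.995, pmax(0.01, stats::runif(L, baseline - w, baseline + w)))
    if (config$flank_advantage > 0) {
      cons_t[flank_cols] <- pmin(0.998,
                                 cons_t[flank_cols] + config$flank_advantage)
    }
    a <- pairs$orf_a[i]; b <- pairs$orf_b[i]
    alignments[[a]] <- simulate_alignment(
      a, cons_t, n_strains = config$n_strains,
      consensus = paste(cons, collapse = ""), background = bg,
      reference_strain = config$reference_strain,
      seed = sub_seeds[2 * i - 1]
    )
    alignments[[b]] <- simulate_alignment(
      b, cons_p, n_strains = config$n_strains,
      consensus = paste(cons, collapse = ""), background = bg,
      reference_strain = config$reference_strain,
      seed = sub_seeds[2 * i]
    )
    mods[[i]] <- data.frame(
      orf_id = a, position = site_pos, residue = residue,
      mod_type = config$mod_type, stringsAsFactors = FALSE
    )
  }
  mods <- do.call(rbind, mods)
  mods$study_ids <- I(rep(list("sim"), nrow(mods)))
  mods$n_studies <- 1L
  list(alignments = alignments, pairs = pairs, mods = mods,
       site_positions = site_pos)
}

#' Sites of interest of a simulated paralog dataset, from ground truth
#'
#' The simulated members of a pair share an identical reference protein,
#' so the global alignment of the pair is the identity map and the sites
#' of interest are exactly the planted site positions.  This constructs
#' the sites table directly from the generator's ground truth, bypassing
#' the (identical) alignment step; [find_sites_of_interest()] on the same
#' dataset returns the same table.
#'
#' @param dataset Output of [simulate_paralog_dataset()].
#' @param config The [sim_config()] used to generate it.
#' @return A `sites_of_interest` data frame.
#' @export
sites_from_simulation <- function(dataset, config) {
  pairs <- dataset$pairs
  k <- length(dataset$site_positions)
  out <- data.frame(
    orf_a = rep(pairs$orf_a, each = k),
    orf_b = rep(pairs$orf_b, each = k),
    target_orf = rep(pairs$orf_a, each = k),
    paralog_orf = rep(pairs$orf_b, each = k),
    mod_type = config$mod_type,
    residue = .MOD_RESIDUE[[config$mod_type]],
    target_position = rep(dataset$site_positions, nrow(pairs)),
    paralog_position = rep(dataset$site_positions, nrow(pairs)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("sites_of_interest", "data.frame")
  out
}

#' Score-level fixtures for the three distribution/pairing regimes
#'
#' Generates matched (target, paralog) window-score pairs realizing the
#' three qualitative regimes of the two conservation tests:
#' \describe{
#'   \item{`"separated"`}{Target and paralog score distributions do not
#'     overlap.  The distribution-mean test is significant; the pairing
#'     test is not (every re-pairing leaves all targets on top).}
#'   \item{`"overlap_advantage"`}{Distributions overlap broadly but each
#'     target sits slightly above its own paralog: both tests
#'     significant.}
#'   \item{`"matched_pairing"`}{Target and paralog share the same score
#'     multiset, paired so that most targets win by a small margin and a
#'     few lose by a large one: the pairing test is significant while the
#'     signed-rank distribution-mean test is not.}
#' }
#'
#' @param scenario One of `"separated"`, `"overlap_advantage"`,
#'   `"matched_pairing"`.
#' @param n_pairs Number of pairs (default 100).
#' @param seed Integer seed.
#' @return A `paired_score_set` data frame (mod_type
#'   `"phosphorylation"`, algorithm `"simulated"`).
#' @export
simulate_scenario_sets <- function(scenario = c("separated",
                                                "overlap_advantage",
                                                "matched_pairing"),
                                   n_pairs = 100, seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(n_pairs >= 10)
  set.seed(seed)
  if (scenario == "separated") {
    tv <- stats::runif(n_pairs, 0.70, 0.90)
    pv <- stats::runif(n_pairs, 0.10, 0.30)
  } else if (scenario == "overlap_advantage") {
    pv <- stats::runif(n_pairs, 0.30, 0.70)
    tv <- pmin(0.99, pv + stats::runif(n_pairs, 0.01, 0.12))
  } else {
    # one shared score ladder, paired in blocks: within each block every
    # target takes the value one rung above its paralog, except the lowest
    # value, which is paired with the block's top rung
    v <- seq(0.2, 0.8, length.out = n_pairs) +
      stats::rnorm(n_pairs, sd = 1e-4)
    v <- sort(v)
    block_sizes <- rep(c(3L, 4L), length.out = ceiling(n_pairs / 3))
    block_sizes <- block_sizes[cumsum(block_sizes) <= n_pairs]
    if (sum(block_sizes) < n_pairs) {
      block_sizes <- c(block_sizes, n_pairs - sum(block_sizes))
    }
    tv <- pv <- numeric(0)
    at <- 1L
    for (bs in block_sizes) {
      vals <- v[at:(at + bs - 1L)]
      tv <- c(tv, vals[c(2:bs, 1L)])
      pv <- c(pv, vals[c(1:(bs - 1L), bs)])
      at <- at + bs
    }
  }
  out <- data.frame(
    mod_type = "phosphorylation",
    target_orf = sprintf("TGT%04d", seq_along(tv)),
    paralog_orf = sprintf("PAR%04d", seq_along(tv)),
    residue = "S",
    target_position = 1L, paralog_position = 1L,
    target_value = tv, paralog_value = pv,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("paired_score_set", "data.frame"),
            algorithm = "simulated", statistic = "mean1", n_dropped = 0L)
}

#' Simulate a motif dataset with a planted positional enrichment
#'
#' Creates one (target, paralog) protein pair per site, each nine residues
#' long with the modified residue at position 5.  Flanking residues are
#' drawn from the background distribution; at the planted relative
#' position the target's residue is drawn with the planted residue's
#' probability multiplied by the enrichment factor (then renormalized).
#' Enrichment 1 gives the exchangeable null at every offset.
#'
#' @param n_sites Number of sites (default 500).
#' @param motif_plant List with `relative_position` (e.g. `"b3"`),
#'   `residue` and `enrichment` (>= 1).
#' @param mod_type Modification type of the sites.
#' @param background Residue frequencies (default
#'   [blosum62_background()]).
#' @param seed Integer seed.
#' @return List with `sites` (a `sites_of_interest` data frame) and
#'   `sequences` (named character vector).
#' @export
simulate_motif_dataset <- function(n_sites = 500,
                                   motif_plant = list(
                                     relative_position = "b3",
                                     residue = "R", enrichment = 1),
                                   mod_type = "phosphorylation",
                                   background = blosum62_background(),
                                   seed = 1) {
  stopifnot(motif_plant$enrichment >= 1)
  offset <- .parse_offset(motif_plant$relative_position)
  set.seed(seed)
  aas <- amino_acids()
  bg <- background[aas]
  boosted <- bg
  boosted[motif_plant$residue] <- boosted[motif_plant$residue] *
    motif_plant$enrichment
  boosted <- boosted / sum(boosted)
  site_pos <- 5L
  width <- 9L
  residue <- .MOD_RESIDUE[[mod_type]]
  seqs <- character(2 * n_sites)
  names(seqs) <- c(sprintf("MT%04d", seq_len(n_sites)),
                   sprintf("MP%04d", seq_len(n_sites)))
  for (i in seq_len(n_sites)) {
    tseq <- sample(aas, width, replace = TRUE, prob = bg)
    pseq <- sample(aas, width, replace = TRUE, prob = bg)
    tseq[site_pos] <- residue
    pseq[site_pos] <- residue
    tseq[site_pos + offset] <- sample(aas, 1, prob = boosted)
    seqs[i] <- paste(tseq, collapse = "")
    seqs[n_sites + i] <- paste(pseq, collapse = "")
  }
  sites <- data.frame(
    orf_a = names(seqs)[seq_len(n_sites)],
    orf_b = names(seqs)[n_sites + seq_len(n_sites)],
    target_orf = names(seqs)[seq_len(n_sites)],
    paralog_orf = names(seqs)[n_sites + seq_len(n_sites)],
    mod_type = mod_type, residue = residue,
    target_position = site_pos, paralog_position = site_pos,
    stringsAsFactors = FALSE
  )
  class(sites) <- c("sites_of_interest", "data.frame")
  list(sites = sites, sequences = seqs)
}

#' Simulate a random strain tree
#'
#' Coalescent-style random binary tree over the strain labels, with
#' branch lengths from [ape::rcoal()]; seed-controlled.
#'
#' @param strain_ids Leaf labels.
#' @param seed Integer seed.
#' @return An [ape::phylo] tree.
#' @export
simulate_strain_tree <- function(strain_ids, seed = 1) {
  set.seed(seed)
  ape::rcoal(length(strain_ids), tip.label = strain_ids)
}
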