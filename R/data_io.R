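# Readers, writers and column-level views for the standard-format inputs:
# aligned FASTA per ORF, modification/paralog/abundance TSV tables and the
# Newick strain tree.

#' Construct a multi-strain alignment object
#'
#' @param orf_id ORF identifier.
#' @param rows Named character vector of aligned residue strings, one per
#'   strain (names are strain identifiers).  All rows must have identical
#'   length; residues are uppercased.
#' @param reference_strain Identifier of the reference strain; must be one
#'   of `names(rows)`.
#' @return An object of class `strain_alignment` with fields `orf_id`,
#'   `strain_ids`, `rows`, `reference_strain`, the residue matrix `chars`
#'   (strains x columns), the ungapped reference sequence `ref_sequence`
#'   and `ref_map`, the alignment column of each ungapped reference
#'   position.
#' @export
strain_alignment <- function(orf_id, rows, reference_strain) {
  if (length(rows) == 0) stop("empty alignment: no sequences")
  if (is.null(names(rows)) || any(names(rows) == "")) {
    stop("alignment rows must be named by strain identifier")
  }
  if (anyDuplicated(names(rows))) {
    stop("duplicate strain identifiers in alignment")
  }
  if (length(rows) < 2) stop("alignment must contain at least 2 strains")
  rows <- toupper(rows)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1) {
    stop("alignment-format error: rows have unequal lengths (",
         paste(unique(widths), collapse = ", "), ")")
  }
  if (!reference_strain %in% names(rows)) {
    stop("missing-reference error: reference strain '", reference_strain,
         "' not present in alignment")
  }
  chars <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(chars) <- names(rows)
  ref_chars <- chars[reference_strain, ]
  ref_map <- which(!ref_chars %in% GAP_SYMBOLS)
  structure(
    list(
      orf_id = orf_id,
      strain_ids = names(rows),
      rows = rows,
      reference_strain = reference_strain,
      chars = chars,
      ref_sequence = paste(ref_chars[ref_map], collapse = ""),
      ref_map = ref_map
    ),
    class = "strain_alignment"
  )
}

#' @export
print.strain_alignment <- function(x, ...) {
  cat("strain_alignment '", x$orf_id, "': ", length(x$strain_ids),
      " strains x ", ncol(x$chars), " columns (reference ",
      x$reference_strain, ", ", nchar(x$ref_sequence),
      " ungapped residues)\n", sep = "")
  invisible(x)
}

#' Number of alignment columns
#' @param aln A `strain_alignment`.
#' @return Integer alignment length L.
#' @export
alignment_length <- function(aln) ncol(aln$chars)

#' Read a multi-strain protein alignment from aligned FASTA
#'
#' Headers are strain identifiers.  Rows are validated for equal length,
#' uppercased, and checked for the presence of the reference strain and for
#' duplicate identifiers (rejected).
#'
#' @param path Path to an aligned FASTA file.
#' @param reference_strain Strain identifier used as coordinate reference.
#' @param orf_id ORF identifier; defaults to the file name without
#'   extension.
#' @return A [strain_alignment()].
#' @export
read_alignment_fasta <- function(path, reference_strain,
                                 orf_id = sub("\\.[^.]*$", "", basename(path))) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("empty-input error: no sequences in ", path)
  rows <- stats::setNames(as.character(seqs), names(seqs))
  strain_alignment(orf_id, rows, reference_strain)
}

#' Write a multi-strain alignment to aligned FASTA
#'
#' Inverse of [read_alignment_fasta()]; round-tripping preserves rows and
#' their order.
#'
#' @param aln A `strain_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  set <- Biostrings::BStringSet(aln$rows)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a modification-site table
#'
#' Expects a tab-separated file with header columns `orf`, `position`,
#' `residue`, `mod_type`, `study`.  Rows sharing (orf, position, mod_type)
#' are merged and their study identifiers pooled.  Rows whose `mod_type` is
#' not one of the five canonical types (phosphorylation, ubiquitylation,
#' monoacetylation, N-glycosylation, succinylation) are dropped with a
#' message.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `orf_id`, `position`, `residue`,
#'   `mod_type`, `study_ids` (list column) and `n_studies`; the number of
#'   dropped noncanonical rows is attached as attribute `n_dropped`.
#' @export
read_modification_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- c("orf", "position", "residue", "mod_type", "study")
  if (!all(needed %in% names(raw))) {
    stop("modification table must have columns: ",
         paste(needed, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(raw$position))
  bad <- is.na(pos) | as.character(pos) != trimws(raw$position)
  if (any(bad)) {
    stop("parse error: non-integer position(s): ",
         paste(unique(raw$position[bad]), collapse = ", "))
  }
  if (any(pos < 1)) stop("parse error: positions must be >= 1")
  keep <- raw$mod_type %in% MOD_TYPES
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("dropped ", n_dropped, " row(s) with noncanonical mod_type")
  }
  raw <- raw[keep, , drop = FALSE]
  pos <- pos[keep]
  key <- paste(raw$orf, pos, raw$mod_type, sep = "\r")
  res_by_key <- tapply(toupper(raw$residue), key,
                       function(r) unique(r), simplify = FALSE)
  conflict <- vapply(res_by_key, length, integer(1)) > 1
  if (any(conflict)) {
    stop("inconsistency error: conflicting residues for site(s): ",
         paste(gsub("\r", ":", names(res_by_key)[conflict]), collapse = "; "))
  }
  idx <- !duplicated(key)
  out <- data.frame(
    orf_id = raw$orf[idx],
    position = pos[idx],
    residue = toupper(raw$residue[idx]),
    mod_type = raw$mod_type[idx],
    stringsAsFactors = FALSE
  )
  studies <- split(raw$study, key)[key[idx]]
  out$study_ids <- I(lapply(studies, function(s) sort(unique(s))))
  out$n_studies <- vapply(out$study_ids, length, integer(1))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Check modification records against reference sequences
#'
#' Verifies that each record's residue matches the reference protein at the
#' stated ungapped position.  Mismatches (including out-of-range positions)
#' are an error by default, or dropped with a message.
#'
#' @param mods Modification table as from [read_modification_table()].
#' @param sequences Named character vector of ungapped reference protein
#'   sequences.
#' @param on_mismatch `"error"` (default) or `"skip"`.
#' @return The (possibly filtered) modification table.
#' @export
validate_modifications <- function(mods, sequences,
                                   on_mismatch = c("error", "skip")) {
  on_mismatch <- match.arg(on_mismatch)
  obs <- vapply(seq_len(nrow(mods)), function(i) {
    s <- sequences[[mods$orf_id[i]]]
    if (is.null(s) || is.na(s) || mods$position[i] > nchar(s)) return(NA_character_)
    substr(s, mods$position[i], mods$position[i])
  }, character(1))
  ok <- !is.na(obs) & obs == mods$residue
  if (all(ok)) return(mods)
  if (on_mismatch == "error") {
    stop("residue mismatch for ", sum(!ok), " modification record(s), e.g. ",
         mods$orf_id[!ok][1], ":", mods$position[!ok][1])
  }
  message("skipped ", sum(!ok), " modification record(s) with residue mismatch")
  mods[ok, , drop = FALSE]
}

#' Read a paralog-pair table
#'
#' @param path TSV with header columns `orf_a`, `orf_b`.
#' @return Data frame with columns `orf_a`, `orf_b`.
#' @export
read_paralog_pairs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("orf_a", "orf_b") %in% names(tab))) {
    stop("paralog-pair table must have columns orf_a, orf_b")
  }
  if (any(tab$orf_a == tab$orf_b)) {
    stop("paralog pair with identical members")
  }
  tab[, c("orf_a", "orf_b")]
}

#' Read a protein-abundance table
#'
#' @param path TSV with header columns `orf`, `median_abundance`.
#' @return Data frame with columns `orf_id`, `median_abundance`.
#' @export
read_abundance_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("orf", "median_abundance") %in% names(tab))) {
    stop("abundance table must have columns orf, median_abundance")
  }
  ab <- as.numeric(tab$median_abundance)
  if (any(is.na(ab) | ab <= 0)) {
    stop("input error: median_abundance must be positive")
  }
  data.frame(orf_id = tab$orf, median_abundance = ab,
             stringsAsFactors = FALSE)
}

#' Symbol counts and proportions for one alignment column
#'
#' @param aln A `strain_alignment`.
#' @param column 1-based alignment column index.
#' @return Data frame with columns `symbol`, `count`, `proportion` (summing
#'   to 1 over observed symbols).
#' @export
column_frequencies <- function(aln, column) {
  L <- alignment_length(aln)
  if (length(column) != 1 || is.na(column) || column < 1 || column > L) {
    stop("index error: column must be in 1..", L)
  }
  tab <- table(aln$chars[, column])
  data.frame(
    symbol = names(tab),
    count = as.integer(tab),
    proportion = as.numeric(tab) / sum(tab),
    stringsAsFactors = FALSE
  )
}

#' Map an ungapped reference position to its alignment column
#'
#' @param aln A `strain_alignment`.
#' @param position 1-based ungapped position in the reference protein.
#' @return 1-based alignment column index.
#' @export
reference_to_column <- function(aln, position) {
  n <- length(aln$ref_map)
  if (any(position < 1 | position > n)) {
    stop("index error: reference position must be in 1..", n)
  }
  aln$ref_map[position]
}

#' Patristic distance between a strain and the reference strain
#'
#' Sum of branch lengths on the tree path between the two leaves.
#'
#' @param tree An [ape::phylo] strain tree with branch lengths.
#' @param strain,reference Leaf labels.
#' @return Nonnegative numeric distance (0 when `strain == reference`).
#' @export
strain_distance_to_reference <- function(tree, strain, reference) {
  labs <- tree$tip.label
  if (!strain %in% labs) stop("missing-leaf error: ", strain)
  if (!reference %in% labs) stop("missing-leaf error: ", reference)
  if (strain == reference) return(0)
  d <- leaf_distances(tree, reference)
  unname(d[strain])
}

#' Patristic distances from one leaf to all leaves
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param reference Leaf label to measure from.
#' @return Named numeric vector over all leaves (0 at the reference).
#' @export
leaf_distances <- function(tree, reference) {
  labs <- tree$tip.label
  if (!reference %in% labs) stop("missing-leaf error: ", reference)
  dn <- ape::dist.nodes(tree)
  ref_i <- match(reference, labs)
  stats::setNames(dn[ref_i, seq_along(labs)], labs)
}
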