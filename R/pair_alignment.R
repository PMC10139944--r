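# Needleman-Wunsch global alignment of the two reference proteins of a
# paralog pair, coordinate mapping between them, and enumeration of sites of
# interest (identical residue, exactly one member modified).

#' Global (Needleman-Wunsch) alignment of two protein sequences
#'
#' True global alignment under affine gap cost, where a gap of length k
#' costs `gap_open + k * gap_extend` (a length-1 gap costs 10.5 with the
#' defaults) subtracted from the summed substitution scores.  End gaps are
#' penalized like internal gaps.  Backed by
#' [Biostrings::pairwiseAlignment()] with `type = "global"`.
#'
#' @param seq_a,seq_b Non-empty protein strings.
#' @param substitution 20x20 (or larger) substitution matrix; default
#'   BLOSUM62 including ambiguity rows.
#' @param gap_open,gap_extend Affine gap parameters (default 10 and 0.5).
#' @return An object of class `site_map`: list with `aligned_a`,
#'   `aligned_b` (gapped strings of equal length), `score`, and
#'   `correspondence`, a data frame with one row per alignment column and
#'   columns `column`, `pos_a`, `pos_b` (ungapped 1-based positions, NA at
#'   gaps), `res_a`, `res_b`.
#' @export
needleman_wunsch_align <- function(seq_a, seq_b,
                                   substitution = get_blosum62_full(),
                                   gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    stop("empty-input error: sequences must be non-empty")
  }
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  pa <- Biostrings::pairwiseAlignment(
    pattern = seq_a, subject = seq_b, type = "global",
    substitutionMatrix = substitution,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  aligned_a <- as.character(Biostrings::alignedPattern(pa))
  aligned_b <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  pos_a <- ifelse(ca == "-", NA_integer_, cumsum(ca != "-"))
  pos_b <- ifelse(cb == "-", NA_integer_, cumsum(cb != "-"))
  structure(
    list(
      aligned_a = aligned_a,
      aligned_b = aligned_b,
      score = Biostrings::score(pa),
      correspondence = data.frame(
        column = seq_along(ca),
        pos_a = pos_a, pos_b = pos_b,
        res_a = ca, res_b = cb,
        stringsAsFactors = FALSE
      )
    ),
    class = "site_map"
  )
}

#' @export
print.site_map <- function(x, ...) {
  cat("site_map: ", nchar(x$aligned_a), " columns, score ", x$score, "\n",
      sep = "")
  invisible(x)
}

#' Map an ungapped position from one paralog to the other
#'
#' @param map A `site_map` from [needleman_wunsch_align()].
#' @param position 1-based ungapped position in the `from` sequence.
#' @param from `"a"` or `"b"`.
#' @return The corresponding ungapped position in the other sequence, or
#'   `NA` if it is aligned to a gap.
#' @export
map_position <- function(map, position, from = c("a", "b")) {
  from <- match.arg(from)
  corr <- map$correspondence
  src <- if (from == "a") corr$pos_a else corr$pos_b
  dst <- if (from == "a") corr$pos_b else corr$pos_a
  i <- match(position, src)
  if (any(is.na(i))) stop("index error: position not present in sequence ", from)
  dst[i]
}

#' Enumerate differentially modified, residue-identical sites
#'
#' For each paralog pair and modification type independently, finds every
#' globally aligned position where both paralogs carry the identical
#' residue and exactly one of the two is modified for that type.  The
#' modified member is the target.  Residue substitutions of any kind are
#' rejected, and positions modified in both paralogs are excluded.
#'
#' @param pairs Data frame with columns `orf_a`, `orf_b`.
#' @param mods Modification table as from [read_modification_table()].
#' @param sequences Named character vector of ungapped reference protein
#'   sequences (one per ORF).
#' @param gap_open,gap_extend Alignment gap parameters (default 10, 0.5).
#' @return Data frame of class `sites_of_interest` with columns `orf_a`,
#'   `orf_b`, `target_orf`, `paralog_orf`, `mod_type`, `residue`,
#'   `target_position`, `paralog_position`.
#' @export
find_sites_of_interest <- function(pairs, mods, sequences,
                                   gap_open = 10, gap_extend = 0.5) {
  missing_orfs <- setdiff(unique(c(pairs$orf_a, pairs$orf_b)), names(sequences))
  if (length(missing_orfs) > 0) {
    stop("missing-sequence error: no sequence for ",
         paste(missing_orfs, collapse = ", "))
  }
  mod_key <- paste(mods$orf_id, mods$position, mods$mod_type, sep = "\r")
  out <- vector("list", nrow(pairs) * length(MOD_TYPES))
  k <- 0L
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$orf_a[i]; b <- pairs$orf_b[i]
    map <- needleman_wunsch_align(sequences[[a]], sequences[[b]],
                                  gap_open = gap_open,
                                  gap_extend = gap_extend)
    corr <- map$correspondence
    ident <- !is.na(corr$pos_a) & !is.na(corr$pos_b) & corr$res_a == corr$res_b
    corr <- corr[ident, , drop = FALSE]
    if (nrow(corr) == 0) next
    for (m in intersect(MOD_TYPES, unique(mods$mod_type))) {
      a_mod <- paste(a, corr$pos_a, m, sep = "\r") %in% mod_key
      b_mod <- paste(b, corr$pos_b, m, sep = "\r") %in% mod_key
      sel <- xor(a_mod, b_mod)
      if (!any(sel)) next
      k <- k + 1L
      out[[k]] <- data.frame(
        orf_a = a, orf_b = b,
        target_orf = ifelse(a_mod[sel], a, b),
        paralog_orf = ifelse(a_mod[sel], b, a),
        mod_type = m,
        residue = corr$res_a[sel],
        target_position = ifelse(a_mod[sel], corr$pos_a[sel], corr$pos_b[sel]),
        paralog_position = ifelse(a_mod[sel], corr$pos_b[sel], corr$pos_a[sel]),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (k == 0) {
    data.frame(orf_a = character(0), orf_b = character(0),
               target_orf = character(0), paralog_orf = character(0),
               mod_type = character(0), residue = character(0),
               target_position = integer(0), paralog_position = integer(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out[seq_len(k)])
  }
  rownames(res) <- NULL
  class(res) <- c("sites_of_interest", "data.frame")
  res
}

#' Write sites of interest as TSV
#'
#' @param sites Output of [find_sites_of_interest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  utils::write.table(as.data.frame(sites), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Search the reference sequence of an alignment for a motif or positions
#'
#' A character motif is matched against the ungapped reference protein;
#' `'X'` in the motif matches any residue.  A numeric query is validated
#' against the protein length and returned as is.
#'
#' @param aln A `strain_alignment`.
#' @param query Motif string over amino acids and the wildcard `'X'`, or a
#'   vector of 1-based ungapped reference positions.
#' @return Integer vector of matching (or validated) 1-based ungapped
#'   reference start positions.
#' @export
motif_search <- function(aln, query) {
  n <- nchar(aln$ref_sequence)
  if (is.numeric(query)) {
    if (any(query < 1 | query > n)) {
      stop("index error: position outside 1..", n)
    }
    return(as.integer(query))
  }
  query <- toupper(query)
  if (nchar(query) < 1) stop("query error: empty motif")
  chars <- strsplit(query, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c(amino_acids(), "X"))) {
    stop("query error: motif may contain amino acids and 'X' only")
  }
  pattern <- paste(ifelse(chars == "X", ".", chars), collapse = "")
  hits <- gregexpr(paste0("(?=", pattern, ")"), aln$ref_sequence,
                   perl = TRUE)[[1]]
  if (length(hits) == 1 && hits == -1) return(integer(0))
  as.integer(hits)
}
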