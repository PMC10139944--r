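# Alphabets, residue groupings and the background distribution shared by the
# scoring and simulation code.

#' The 20 standard amino acids (one-letter, BLOSUM order)
#'
#' @return Character vector of the 20 standard one-letter amino-acid codes.
#' @export
amino_acids <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# Symbols treated as gaps throughout: the alignment gap character and the
# noncanonical/ambiguous codes X, B, Z.
GAP_SYMBOLS <- c("-", "X", "B", "Z")

# The five modification types retained for analysis.
MOD_TYPES <- c("phosphorylation", "ubiquitylation", "monoacetylation",
               "N-glycosylation", "succinylation")

# Stereochemical groups: members of one group count as a single entity for
# the grouped-entropy score.
STEREO_GROUPS <- list(
  c("V", "L", "I", "M"),
  c("F", "W", "Y"),
  c("S", "T"),
  c("N", "Q"),
  c("H", "K", "R"),
  c("D", "E"),
  c("A", "G"),
  "P",
  "C"
)

# residue -> group index lookup
.stereo_group_of <- local({
  map <- character(0)
  for (g in seq_along(STEREO_GROUPS)) {
    map[STEREO_GROUPS[[g]]] <- as.character(g)
  }
  map
})

# Chemical classes of the 20 amino acids (a partition).
CHEM_CLASSES <- list(
  aliphatic       = c("G", "A", "V", "L", "I", "M", "P"),
  aromatic        = c("F", "Y", "W"),
  polar_uncharged = c("S", "T", "C", "N", "Q"),
  acidic          = c("E", "D"),
  basic           = c("K", "R", "H")
)

.chem_class_of <- local({
  map <- character(0)
  for (cl in names(CHEM_CLASSES)) map[CHEM_CLASSES[[cl]]] <- cl
  map
})

# Amino-acid frequencies derived from the BLOSUM62 target-frequency
# marginals; the standard "no selection pressure" background used for the
# Jensen-Shannon divergence score and as the simulation background.
.BLOSUM62_BACKGROUND <- c(
  A = 0.078, R = 0.051, N = 0.041, D = 0.052, C = 0.024,
  Q = 0.034, E = 0.059, G = 0.083, H = 0.025, I = 0.062,
  L = 0.092, K = 0.056, M = 0.024, F = 0.044, P = 0.043,
  S = 0.059, T = 0.055, W = 0.014, Y = 0.034, V = 0.072
)

#' BLOSUM62-derived background amino-acid frequencies
#'
#' The marginal amino-acid frequency vector of the BLOSUM62 substitution
#' matrix, used as the no-selection background distribution for the
#' Jensen-Shannon divergence score, the background goodness-of-fit test and
#' the synthetic-data generators.  Frequencies are renormalized to sum
#' exactly to 1.
#'
#' @param path Optional path to a two-column tab-separated file
#'   (residue, frequency) overriding the packaged vector.
#' @return Named numeric vector over the 20 standard amino acids, summing
#'   to 1.
#' @export
blosum62_background <- function(path = NULL) {
  if (is.null(path)) {
    q <- .BLOSUM62_BACKGROUND
  } else {
    tab <- utils::read.delim(path, header = FALSE,
                             col.names = c("residue", "frequency"),
                             stringsAsFactors = FALSE)
    q <- stats::setNames(as.numeric(tab$frequency), tab$residue)
    missing <- setdiff(amino_acids(), names(q))
    if (length(missing) > 0) {
      stop("background file lacks frequencies for: ",
           paste(missing, collapse = ", "))
    }
    q <- q[amino_acids()]
  }
  q / sum(q)
}

#' BLOSUM62 substitution matrix restricted to the 20 standard amino acids
#'
#' @return 20 x 20 integer matrix of BLOSUM62 scores.
#' @export
blosum62_matrix <- function() {
  mat <- get_blosum62_full()
  mat[amino_acids(), amino_acids()]
}

# Full BLOSUM62 (with ambiguity codes) as shipped by Biostrings; used for
# pairwise alignment where X/B/Z rows are needed.  Loaded once per session.
get_blosum62_full <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      cached <<- env$BLOSUM62
    }
    cached
  }
})
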