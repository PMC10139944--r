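# Shared fixtures and independent oracles used across the test files.

# small alignment: 4 strains x 8 columns, reference S288C
toy_alignment <- function() {
  strain_alignment(
    "YTOY001",
    c(S288C = "MSKDEACW", st1 = "MSKDEACW", st2 = "MSRDEACW",
      st3 = "MSKDE-CW"),
    "S288C"
  )
}

# brute-force global affine alignment score: enumerates every monotone
# alignment path and applies cost gap_open + k*gap_extend per gap run.
# Independent of any dynamic-programming shortcut.
brute_force_global_score <- function(a, b, sub, gap_open = 10,
                                     gap_extend = 0.5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1, j + 1, score + sub[ca[i], cb[j]], "m")
    }
    if (i <= length(ca)) {
      pen <- gap_extend + if (state == "d") 0 else gap_open
      rec(i + 1, j, score - pen, "d")
    }
    if (j <= length(cb)) {
      pen <- gap_extend + if (state == "i") 0 else gap_open
      rec(i, j + 1, score - pen, "i")
    }
  }
  rec(1, 1, 0, "m")
  best
}

# brute-force patristic distance: breadth-first search on the edge list,
# summing branch lengths along the unique path between two tips.
brute_force_patristic <- function(tree, tip_a, tip_b) {
  n_tip <- length(tree$tip.label)
  a <- match(tip_a, tree$tip.label)
  b <- match(tip_b, tree$tip.label)
  adj <- list()
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[as.character(u)]] <- rbind(adj[[as.character(u)]], c(v, w))
    adj[[as.character(v)]] <- rbind(adj[[as.character(v)]], c(u, w))
  }
  # BFS with distances (tree: unique paths)
  dist <- rep(NA_real_, n_tip + tree$Nnode)
  dist[a] <- 0
  queue <- a
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    nb <- adj[[as.character(u)]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1]
      if (is.na(dist[v])) {
        dist[v] <- dist[u] + nb[r, 2]
        queue <- c(queue, v)
      }
    }
  }
  dist[b]
}

# brute-force Karlin column score: explicit double loop over all unordered
# symbol pairs (no counts shortcut).
brute_force_karlin <- function(column, sub) {
  aa <- column[!column %in% c("-", "X", "B", "Z")]
  n <- length(aa)
  if (n < 2) return(NA_real_)
  total <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + sub[aa[i], aa[j]] / sqrt(sub[aa[i], aa[i]] *
                                                  sub[aa[j], aa[j]])
    }
  }
  (2 * total / (n * (n - 1)) + 1) / 2
}

# all permutations of 1..n (recursive, independent of the package's)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

# random column of symbols (possibly with gaps)
random_column <- function(n, gap_prob = 0) {
  syms <- amino_acids()
  col <- sample(syms, n, replace = TRUE)
  if (gap_prob > 0) {
    g <- runif(n) < gap_prob
    col[g] <- sample(c("-", "X", "B", "Z"), sum(g), replace = TRUE)
  }
  col
}

# conservation profile object with given reference scores (for window tests)
fake_profile <- function(scores, residues = NULL) {
  n <- length(scores)
  if (is.null(residues)) residues <- rep("A", n)
  structure(
    list(orf_id = "FAKE", algorithm = "shannon", gap_penalty = FALSE,
         scores = scores, gap_fraction = rep(0, n),
         ref_positions = seq_len(n), ref_scores = scores,
         ref_residues = residues),
    class = "conservation_profile"
  )
}
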