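# Independent oracles and fixture builders used across the suite.

random_aa_str <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A","R","N","D","C","Q","E","G","H",
                                        "I","L","K","M","F","P","S","T","W",
                                        "Y","V"), n, replace = TRUE),
                               collapse = ""))
}

random_dna_str <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A","C","G","T"), n, replace = TRUE),
                               collapse = ""))
}

# Quadratic-time global (Gotoh) alignment oracle: returns the optimal score
# under BLOSUM62 with affine gaps (open 11, extend 1), end gaps penalized.
# Plain dynamic programming, independent of Biostrings.
nw_score_oracle <- function(a, b, gap_open = 11, gap_extend = 1) {
  S <- blosum62()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - (i - 2) * gap_extend
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - (j - 2) * gap_extend
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      M[i, j] <- max(M[i-1, j-1], X[i-1, j-1], Y[i-1, j-1]) +
        S[av[i-1], bv[j-1]]
      X[i, j] <- max(M[i-1, j] - gap_open, Y[i-1, j] - gap_open,
                     X[i-1, j] - gap_extend)
      Y[i, j] <- max(M[i, j-1] - gap_open, X[i, j-1] - gap_open,
                     Y[i, j-1] - gap_extend)
    }
  }
  max(M[n+1, m+1], X[n+1, m+1], Y[n+1, m+1])
}

# Quadratic-time local (Smith-Waterman) oracle: best local score.
sw_score_oracle <- function(a, b, gap_open = 11, gap_extend = 1) {
  S <- blosum62()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      M[i, j] <- max(0, max(M[i-1, j-1], X[i-1, j-1], Y[i-1, j-1]) +
                       S[av[i-1], bv[j-1]])
      X[i, j] <- max(M[i-1, j] - gap_open, X[i-1, j] - gap_extend)
      Y[i, j] <- max(M[i, j-1] - gap_open, Y[i, j-1] - gap_extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Random additive distance matrix: pairwise path lengths on a random
# unrooted binary tree with positive branch lengths.
random_additive_matrix <- function(ntaxa, seed) {
  tr <- withr::with_seed(seed, ape::rtree(ntaxa, rooted = FALSE,
                                          br = function(k) runif(k, 0.2, 2)))
  D <- ape::cophenetic.phylo(tr)
  D[order(rownames(D)), order(colnames(D))]
}

# Build a tiny genome string holding one element with known flanks and TSD.
plant_one_element <- function(el_seq, tsd = "AACAC", left = 3000, right = 3000,
                              seed = 1) {
  lft <- random_dna_str(left, seed)
  rgt <- random_dna_str(right, seed + 1)
  g <- paste0(lft, tsd, el_seq, tsd, rgt)
  list(genome = g, start = nchar(lft) + nchar(tsd),
       end = nchar(lft) + nchar(tsd) + nchar(el_seq))
}

# Shared demonstration scene for the heavier acceptance blocks (built once).
.scene_cache <- new.env(parent = emptyenv())
get_demo_scene <- function() {
  if (is.null(.scene_cache$scene)) {
    scene <- plant_elements(2e6, 0.5, demo_family_specs(), rng_seed = 42L)
    scene$loci <- mine_genome(scene$genome)
    .scene_cache$scene <- scene
  }
  .scene_cache$scene
}
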