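## phylogeny: progressive multiple alignment, p/Poisson distance matrices,
## neighbor-joining with deterministic tie-breaking, column bootstrap,
## outgroup rooting and clade assignment at the >= 50% support convention.

aln_char_matrix <- function(x) {
  nm <- names(x)                   # as.character/toupper drop names
  seqs <- toupper(as.character(x))
  names(seqs) <- nm
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences are not aligned (unequal widths)")
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  m
}

is_nucleotide_set <- function(seqs) {
  all(grepl("^[ACGTMRWSYKVHDBNU-]+$", toupper(as.character(seqs))))
}

#' Pairwise distance matrix from an alignment
#'
#' `p` is the proportion of differing sites over columns where both
#' sequences are ungapped; the Poisson model applies the multiple-hit
#' correction `d = -ln(1 - p)`.
#'
#' @param alignment Aligned sequences (equal width; `XStringSet` or named
#'   character).
#' @param model `"p"` or `"poisson"`.
#' @return Symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(alignment, model = c("poisson", "p")) {
  model <- match.arg(model)
  m <- aln_char_matrix(alignment)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2L) return(D)
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) stop("no shared ungapped columns for pair ",
                         rownames(m)[i], "/", rownames(m)[j])
      p <- mean(m[i, ok] != m[j, ok])
      D[i, j] <- D[j, i] <- if (model == "p") p else poisson_distance(p)
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei Q-criterion agglomeration.  Ties are broken by the
#' lexicographically smallest taxon pair (each cluster represented by its
#' smallest leaf label), so the result is deterministic.  Negative branch
#' lengths are clamped to zero with the deficit transferred to the sister
#' branch, preserving path lengths.
#'
#' @param D Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An unrooted [ape::phylo] tree (trifurcation at the final join).
#' @export
nj_tree <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  taxa <- rownames(D)
  if (is.null(taxa)) stop("distance matrix needs taxon dimnames")
  r <- nrow(D)
  if (r < 3L) stop("neighbor-joining needs >= 3 taxa")

  fmt <- function(x) sprintf("%.10g", max(x, 0))
  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  nwk <- setNames(taxa, taxa)       # subtree strings
  lab <- setNames(taxa, taxa)       # representative (smallest leaf) labels
  act <- taxa                       # active cluster keys
  Dm <- D

  while (length(act) > 3L) {
    r <- length(act)
    Rs <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(Rs, Rs, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-9 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keypair <- apply(cand, 1, function(ij) {
      p <- sort(c(lab[act[ij[1]]], lab[act[ij[2]]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keypair)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- Dm[i, j]
    li <- dij / 2 + (Rs[i] - Rs[j]) / (2 * (r - 2))
    lj <- dij - li
    ll <- clamp_pair(li, lj)
    new_key <- paste0("(", act[i], ",", act[j], ")")
    new_nwk <- paste0("(", nwk[act[i]], ":", fmt(ll[1]), ",",
                      nwk[act[j]], ":", fmt(ll[2]), ")")
    new_lab <- min(lab[act[i]], lab[act[j]])
    others <- act[-c(i, j)]
    dnew <- pmax((Dm[i, match(others, act)] + Dm[j, match(others, act)] - dij) / 2, 0)
    keep <- match(others, act)
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], dnew),
                c(dnew, 0))
    act <- c(others, new_key)
    dimnames(Dm) <- list(act, act)
    nwk[new_key] <- new_nwk
    lab[new_key] <- new_lab
  }

  a <- act[order(lab[act])]
  dab <- Dm[a[1], a[2]]; dac <- Dm[a[1], a[3]]; dbc <- Dm[a[2], a[3]]
  la <- (dab + dac - dbc) / 2
  lb <- (dab + dbc - dac) / 2
  lc <- (dac + dbc - dab) / 2
  tree_str <- paste0("(", nwk[a[1]], ":", fmt(la), ",",
                     nwk[a[2]], ":", fmt(lb), ",",
                     nwk[a[3]], ":", fmt(lc), ");")
  ape::read.tree(text = tree_str)
}

#' Progressive multiple sequence alignment
#'
#' Pairwise global-alignment distances give a neighbor-joining guide tree;
#' profiles are then merged progressively (postorder) by global
#' profile-profile alignment with affine gaps.  Deterministic for a given
#' input set.
#'
#' @param sequences `>= 2` sequences, one alphabet ([Biostrings::AAStringSet],
#'   [Biostrings::DNAStringSet] or named character).
#' @return Aligned sequences of equal width, same names, as an
#'   `AAStringSet`/`DNAStringSet` matching the input alphabet.
#' @export
progressive_msa <- function(sequences) {
  nm <- names(sequences)
  seqs <- as.character(sequences)
  names(seqs) <- nm
  if (length(seqs) < 2L) stop("need >= 2 sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("s", seq_along(seqs))
  nuc <- vapply(seqs, function(s) is_nucleotide_set(s), TRUE)
  if (!all(nuc) && any(nuc)) stop("mixed alphabets in progressive_msa")
  is_nuc <- all(nuc)

  if (is_nuc) {
    alpha <- c("A", "C", "G", "T")
    submat <- matrix(-1, 4, 4, dimnames = list(alpha, alpha))
    diag(submat) <- 2
    go <- 5; ge <- 2
    xset <- Biostrings::DNAStringSet
  } else {
    alpha <- .AA20
    B <- blosum62()
    submat <- B[alpha, alpha]
    go <- 10; ge <- 0.5
    xset <- Biostrings::AAStringSet
  }

  to_profile <- function(mat) {
    pr <- matrix(0, length(alpha), ncol(mat))
    for (c0 in seq_len(ncol(mat))) {
      col <- mat[, c0]
      col <- col[col %in% alpha]
      if (length(col) > 0L) {
        tb <- table(factor(col, levels = alpha))
        pr[, c0] <- as.numeric(tb) / nrow(mat)
      }
    }
    pr
  }
  merge_blocks <- function(A, B2) {
    path <- .align_profiles_cpp(to_profile(A), to_profile(B2),
                                submat, go, ge)
    splice <- function(mat, idx) {
      out <- matrix("-", nrow(mat), length(idx))
      nz <- idx > 0
      out[, nz] <- mat[, idx[nz], drop = FALSE]
      rownames(out) <- rownames(mat)
      out
    }
    rbind(splice(A, path$a), splice(B2, path$b))
  }
  as_block <- function(id) {
    m <- matrix(strsplit(seqs[[id]], "")[[1]], nrow = 1)
    rownames(m) <- id
    m
  }

  if (length(seqs) == 2L) {
    res <- merge_blocks(as_block(names(seqs)[1]), as_block(names(seqs)[2]))
  } else {
    ## guide distances from pairwise identity (global alignment)
    n <- length(seqs)
    D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        two <- merge_blocks(as_block(names(seqs)[i]), as_block(names(seqs)[j]))
        ok <- two[1, ] != "-" & two[2, ] != "-"
        D[i, j] <- D[j, i] <- 1 - (if (any(ok)) mean(two[1, ok] == two[2, ok])
                                   else 0)
      }
    }
    guide <- nj_tree(D)
    guide <- ape::reorder.phylo(guide, "postorder")
    ntip <- length(guide$tip.label)
    blocks <- vector("list", ntip + guide$Nnode)
    for (t in seq_len(ntip)) blocks[[t]] <- as_block(guide$tip.label[t])
    nodes <- unique(guide$edge[, 1])
    for (nd in nodes) {
      kids <- guide$edge[guide$edge[, 1] == nd, 2]
      acc <- blocks[[kids[1]]]
      for (kd in kids[-1]) acc <- merge_blocks(acc, blocks[[kd]])
      blocks[[nd]] <- acc
    }
    res <- blocks[[ntip + 1L]]
    res <- res[names(seqs), , drop = FALSE]   # restore input order
  }
  out <- xset(apply(res, 1, paste, collapse = ""))
  names(out) <- rownames(res)
  out
}

#' Bootstrap a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement `n` times; the support
#' of each internal bipartition of the point-estimate tree is the
#' percentage of replicate trees containing it.  Supports are stored in
#' `node.label`.  With identical input sequences every replicate yields the
#' same (lexicographic) topology, so supports degenerate to 100.
#'
#' @param alignment Aligned sequences.
#' @param n Number of replicates (`0` returns the point tree, no supports).
#' @param seed Integer seed (fixed seed, identical supports).
#' @param model Distance model for [distance_matrix()].
#' @return [ape::phylo] with numeric `node.label` supports (point tree).
#' @export
bootstrap_tree <- function(alignment, n = 1000L, seed = 1L,
                           model = "poisson") {
  m <- aln_char_matrix(alignment)
  point <- nj_tree(distance_matrix(alignment, model))
  if (n == 0L) return(point)
  to_set <- function(mm) {
    x <- apply(mm, 1, paste, collapse = "")
    names(x) <- rownames(mm)
    x
  }
  boots <- with_cm_seed(seed, {
    lapply(seq_len(n), function(b) {
      cols <- sample.int(ncol(m), replace = TRUE)
      nj_tree(distance_matrix(to_set(m[, cols, drop = FALSE]), model))
    })
  })
  ## bipartition keys: the side containing the alphabetically first taxon
  taxa <- sort(point$tip.label)
  split_keys <- function(tr) {
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    vapply(pp, function(ix) {
      side <- labs[ix]
      if (!(taxa[1] %in% side)) side <- setdiff(taxa, side)
      paste(sort(side), collapse = "\r")
    }, "")
  }
  point_keys <- split_keys(point)
  boot_keys <- unlist(lapply(boots, function(b) unique(split_keys(b))))
  counts <- vapply(point_keys, function(k) sum(boot_keys == k), 0)
  point$node.label <- as.character(round(100 * counts / n))
  point
}

node_support <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Tip labels descending from each internal node
#' @param tree [ape::phylo].
#' @return List of character vectors, one per internal node (in node
#'   numbering order).
#' @export
clade_members <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  lapply(pp, function(ix) labs[ix])
}

#' Assign query leaves to reference clades
#'
#' For each query leaf, the smallest ancestral clade whose reference leaves
#' all carry one label (and none another) and whose bootstrap support
#' reaches `support_min` supplies the clade; otherwise the query is
#' `"unclassified"`.
#'
#' @param tree [ape::phylo] with bootstrap `node.label` (see
#'   [bootstrap_tree()]).
#' @param reference_labels Named character vector: reference leaf ->
#'   clade name.
#' @param support_min Minimum bootstrap support (percent).
#' @return data.frame: `query`, `clade`, `support`.
#' @export
assign_clades <- function(tree, reference_labels, support_min = 50) {
  ntip <- length(tree$tip.label)
  members <- clade_members(tree)
  supports <- node_support(tree)
  parent_of <- function(node) {
    p <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(p) == 0L) NA_integer_ else p
  }
  queries <- setdiff(tree$tip.label, names(reference_labels))
  rows <- lapply(queries, function(q) {
    node <- parent_of(which(tree$tip.label == q))
    clade <- "unclassified"; supp <- NA_real_
    while (!is.na(node)) {
      tips <- members[[node - ntip]]
      refs <- intersect(tips, names(reference_labels))
      if (length(refs) > 0L) {
        labs <- unique(reference_labels[refs])
        if (length(labs) > 1L) break      # mixed: no larger clade can be pure
        s <- supports[node - ntip]
        if (!is.na(s) && s >= support_min) {
          clade <- labs; supp <- s
          break
        }
      }
      node <- parent_of(node)
    }
    data.frame(query = q, clade = clade, support = supp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(query = character(),
                                      clade = character(),
                                      support = numeric(),
                                      stringsAsFactors = FALSE)
  out
}

#' Root a tree on the branch separating an outgroup
#'
#' @param tree Unrooted [ape::phylo].
#' @param outgroup_ids Tip labels of the outgroup; must be monophyletic in
#'   the unrooted tree and a proper subset of the leaves.
#' @return Rooted [ape::phylo].
#' @export
root_with_outgroup <- function(tree, outgroup_ids) {
  if (!all(outgroup_ids %in% tree$tip.label))
    stop("outgroup tips not in tree: ",
         paste(setdiff(outgroup_ids, tree$tip.label), collapse = ", "))
  if (length(outgroup_ids) >= length(tree$tip.label))
    stop("outgroup cannot contain all leaves")
  if (length(outgroup_ids) > 1L &&
      !ape::is.monophyletic(tree, outgroup_ids))
    stop("outgroup is not monophyletic in the unrooted tree")
  ape::root(tree, outgroup = outgroup_ids, resolve.root = TRUE)
}
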