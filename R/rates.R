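## rate_ht_analysis: Poisson-corrected amino-acid distances, calibrated
## substitution rates, and the three-criterion assessment of candidate
## horizontal-transfer events (phylogenetic incongruence, rate slowdown,
## patchy distribution).

#' Poisson-corrected amino-acid distance
#'
#' `d = -ln(1 - p)` for a proportion `p` of differing amino acids.
#'
#' @param p Proportion of differing sites, `0 <= p < 1`.
#' @return Distance `d` (substitutions per site).
#' @export
poisson_distance <- function(p) {
  if (any(p < 0)) stop("p must be >= 0")
  if (any(p >= 1 - 1e-9)) stop("Poisson correction undefined for p >= 1")
  -log(1 - p)
}

#' Substitution rate from distance and divergence time
#'
#' `r = d / (2 T)` with `T` in Myr (converted to years), giving
#' substitutions per site per year.
#'
#' @param d Poisson-corrected distance.
#' @param T_myr Divergence time of the last common ancestor, Myr (> 0).
#' @return Rate per site per year.
#' @export
substitution_rate <- function(d, T_myr) {
  if (any(T_myr <= 0)) stop("T_myr must be > 0")
  if (any(d < 0)) stop("d must be >= 0")
  d / (2 * T_myr * 1e6)
}

#' Rate (in 1e-9/site/year units) from a percent identity and a time
#'
#' Convenience composition of [poisson_distance()] and
#' [substitution_rate()] on the scale divergence tables are printed in.
#'
#' @param identity_pct Percent amino-acid identity (0-100).
#' @param T_myr Divergence time, Myr.
#' @return Rate in units of 1e-9 substitutions/site/year.
#' @export
rate_from_identity <- function(identity_pct, T_myr) {
  p <- 1 - identity_pct / 100
  substitution_rate(poisson_distance(p), T_myr) * 1e9
}

#' Pairwise divergence and rate table
#'
#' For each pair: global alignment, identity (per `gap_mode`), proportion
#' of differing residues `p`, Poisson distance `d`, divergence time lookup
#' and rate `r` (reported in 1e-9/site/year).
#'
#' @param pairs data.frame with columns `id1`, `id2`, `group1`, `group2`
#'   (host taxon groups for the time lookup).
#' @param sequences Named amino-acid sequences (`AAStringSet` or character).
#' @param time_table Divergence-time table (default [divergence_times()]).
#' @param gap_mode Identity convention, see [pairwise_identity()].
#' @return data.frame: `id1`, `id2`, `aligned_aa`, `identity_pct`, `p`,
#'   `d`, `T_myr`, `rate_e9`.
#' @export
rate_table <- function(pairs, sequences, time_table = divergence_times(),
                       gap_mode = "exclude") {
  nm <- names(sequences)
  seqs <- as.character(sequences)
  names(seqs) <- nm
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    id1 <- pairs$id1[i]; id2 <- pairs$id2[i]
    if (!all(c(id1, id2) %in% names(seqs)))
      stop("sequence missing for pair ", id1, "/", id2)
    T_myr <- lookup_divergence_time(time_table, pairs$group1[i],
                                    pairs$group2[i])
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seqs[[id1]]), Biostrings::AAString(seqs[[id2]]),
      substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
      type = "global")
    av <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
    bv <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
    ok <- av != "-" & bv != "-"
    ident <- if (gap_mode == "exclude") mean(av[ok] == bv[ok])
             else mean(av == bv & av != "-")
    naligned <- if (gap_mode == "exclude") sum(ok) else length(av)
    p <- 1 - ident
    d <- poisson_distance(p)
    data.frame(id1 = id1, id2 = id2, aligned_aa = naligned,
               identity_pct = 100 * ident, p = p, d = d, T_myr = T_myr,
               rate_e9 = substitution_rate(d, T_myr) * 1e9,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Recompute rates for the bundled published divergence table
#'
#' Feeds each printed identity and its applicable calibration time through
#' the Poisson correction and rate equation.  Rows without an applicable
#' published calibration time keep `NA` (not computable rather than
#' guessed).
#'
#' @param table Table from [published_divergence_table()].
#' @return The table with a `rate_recomputed_e9` column appended.
#' @export
recompute_published_rates <- function(table = published_divergence_table()) {
  table$rate_recomputed_e9 <- ifelse(
    is.na(table$T_myr), NA_real_,
    vapply(seq_len(nrow(table)), function(i) {
      if (is.na(table$T_myr[i])) return(NA_real_)
      rate_from_identity(table$identity_pct[i], table$T_myr[i])
    }, 0))
  table
}

#' Estimate a substitution rate from an ungapped protein pair
#'
#' Site-wise proportion of differences, Poisson correction, and the rate
#' equation; the standard error of the rate follows from the binomial
#' variance of `p` by the delta method
#' (`SE_d = SE_p / (1 - p)`, `SE_r = SE_d / (2 T)`).
#'
#' @param seq1,seq2 Equal-length amino-acid strings.
#' @param T_myr Divergence time, Myr.
#' @return `list(p, d, rate, se_rate)` with rate in subs/site/year.
#' @export
estimate_rate_from_pair <- function(seq1, seq2, T_myr) {
  a <- strsplit(seq1, "")[[1]]
  b <- strsplit(seq2, "")[[1]]
  if (length(a) != length(b)) stop("sequences differ in length")
  p <- mean(a != b)
  d <- poisson_distance(p)
  se_p <- sqrt(p * (1 - p) / length(a))
  se_d <- se_p / (1 - p)
  list(p = p, d = d, rate = substitution_rate(d, T_myr),
       se_rate = se_d / (2 * T_myr * 1e6))
}

#' Test for the rate-slowdown signature of horizontal transfer
#'
#' TRUE iff the largest transposable-element rate is strictly below the
#' smallest host-gene rate over a comparable taxon-pair set; the margin is
#' `min(gene) - max(te)`.
#'
#' @param te_rates,gene_rates Non-empty numeric vectors (same units).
#' @return `list(slowdown, margin)`.
#' @export
slowdown_test <- function(te_rates, gene_rates) {
  if (length(te_rates) == 0L || length(gene_rates) == 0L)
    stop("both rate sets must be non-empty")
  margin <- min(gene_rates) - max(te_rates)
  list(slowdown = max(te_rates) < min(gene_rates), margin = margin)
}

#' Test for patchy distribution of an element on the host tree
#'
#' Under single-origin vertical descent (presence at the host-tree root,
#' no regain), the minimum number of independent losses equals the number
#' of maximal all-absent clades.  The distribution is patchy iff at least
#' one loss is required and the element is not universal.
#'
#' @param presence Named logical vector over the host tips.
#' @param host_tree [ape::phylo] host phylogeny.
#' @return `list(patchy, losses_required)`.
#' @export
patchy_distribution_test <- function(presence, host_tree) {
  tips <- host_tree$tip.label
  if (!all(tips %in% names(presence)))
    stop("presence vector missing tips: ",
         paste(setdiff(tips, names(presence)), collapse = ", "))
  pres <- presence[tips]
  ntip <- length(tips)
  ## all-absent status per node (tips then internal, postorder fill)
  absent <- logical(ntip + host_tree$Nnode)
  absent[seq_len(ntip)] <- !pres
  edges <- ape::reorder.phylo(host_tree, "postorder")$edge
  kids <- split(edges[, 2], edges[, 1])
  for (nd in unique(edges[, 1])) absent[nd] <- NA
  for (nd in unique(edges[, 1]))  # postorder: children resolved first
    absent[nd] <- all(absent[kids[[as.character(nd)]]])
  ## a loss for every maximal all-absent subtree
  root <- ntip + 1L
  losses <- sum(vapply(seq_along(absent), function(nd) {
    if (!isTRUE(absent[nd])) return(FALSE)
    p <- edges[edges[, 2] == nd, 1]
    if (length(p) == 0L) return(nd == root)   # fully absent tree
    !isTRUE(absent[p])
  }, TRUE))
  list(patchy = losses >= 1L && any(pres), losses_required = losses)
}

tree_splits <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  sets <- lapply(pp, function(ix) labs[ix])
  sets[-1]   # drop the trivial all-taxa clade
}

splits_compatible <- function(a1, a2, universe) {
  b1 <- setdiff(universe, a1)
  b2 <- setdiff(universe, a2)
  length(intersect(a1, a2)) == 0L || length(intersect(a1, b2)) == 0L ||
    length(intersect(b1, a2)) == 0L || length(intersect(b1, b2)) == 0L
}

#' Test for phylogenetic incongruence between element and host trees
#'
#' TRUE iff some element-tree bipartition with support at or above
#' `support_min`, after mapping element leaves to their hosts, is
#' incompatible with the host tree (and hence with every resolution of
#' it).  Bipartitions whose two sides share a host after mapping are
#' skipped (paralogy, not clean conflict).
#'
#' @param element_tree [ape::phylo] with bootstrap `node.label`.
#' @param host_tree [ape::phylo] over the host taxa.
#' @param leaf_map Named character: element leaf -> host taxon.
#' @param support_min Minimum support for a conflict to count.
#' @return `list(incongruent, offending)`: flag plus the first offending
#'   host-mapped bipartition (character vector) or `NULL`.
#' @export
incongruence_test <- function(element_tree, host_tree, leaf_map,
                              support_min = 50) {
  if (!all(element_tree$tip.label %in% names(leaf_map)))
    stop("leaf_map missing element leaves")
  esplits <- tree_splits(element_tree)
  esupp <- node_support(element_tree)[-1]
  hosts_all <- unique(leaf_map[element_tree$tip.label])
  hsplits <- tree_splits(host_tree)
  hsplits <- lapply(hsplits, intersect, hosts_all)     # restrict to shared taxa
  for (k in seq_along(esplits)) {
    s <- esupp[k]
    if (is.na(s) || s < support_min) next
    side1 <- unique(leaf_map[esplits[[k]]])
    side2 <- unique(leaf_map[setdiff(element_tree$tip.label, esplits[[k]])])
    if (length(intersect(side1, side2)) > 0L) next     # paralogy: skip
    if (length(side1) < 2L || length(side2) < 2L) next # trivial split
    for (h in hsplits) {
      h <- intersect(h, union(side1, side2))
      if (length(h) < 2L || length(setdiff(union(side1, side2), h)) < 2L) next
      if (!splits_compatible(side1, h, union(side1, side2)))
        return(list(incongruent = TRUE, offending = side1))
    }
  }
  list(incongruent = FALSE, offending = NULL)
}

#' Combined three-criterion horizontal-transfer report
#'
#' The verdict is `"HT-supported"` iff the rate slowdown holds (the
#' strongest criterion) and at least one of incongruence or patchy
#' distribution also holds; otherwise `"vertical-plausible"`.
#'
#' @param candidate Name of the candidate element/pair.
#' @param incongruence Result of [incongruence_test()].
#' @param slowdown Result of [slowdown_test()].
#' @param patchy Result of [patchy_distribution_test()].
#' @return A `cm_ht_report` list: `candidate`, the three criterion flags
#'   with their evidence, and `verdict`.
#' @export
ht_report <- function(candidate, incongruence, slowdown, patchy) {
  verdict <- if (isTRUE(slowdown$slowdown) &&
                 (isTRUE(incongruence$incongruent) || isTRUE(patchy$patchy)))
    "HT-supported" else "vertical-plausible"
  structure(list(candidate = candidate,
                 criterion_incongruence = isTRUE(incongruence$incongruent),
                 offending_bipartition = incongruence$offending,
                 criterion_slowdown = isTRUE(slowdown$slowdown),
                 slowdown_margin = slowdown$margin,
                 criterion_patchy = isTRUE(patchy$patchy),
                 losses_required = patchy$losses_required,
                 verdict = verdict),
            class = "cm_ht_report")
}

#' @export
print.cm_ht_report <- function(x, ...) {
  cat("Horizontal-transfer report:", x$candidate, "\n")
  cat(sprintf("  phylogenetic incongruence : %s\n", x$criterion_incongruence))
  cat(sprintf("  rate slowdown             : %s (margin %.3f)\n",
              x$criterion_slowdown, x$slowdown_margin))
  cat(sprintf("  patchy distribution       : %s (min losses %d)\n",
              x$criterion_patchy, x$losses_required))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Constructed cross-kingdom scenario for the Tcn1-like case
#'
#' A host tree over fungi and plant lineages with the element present in
#' mosses, *Selaginella*-like lycophytes and basidiomycetes only; an
#' element tree grouping the fungal and non-seed-plant elements with high
#' support; and TE/gene rate sets recomputed from the bundled published
#' identities for the cross-kingdom (Plants/Fungi) taxon pairs.
#'
#' @return list(host_tree, element_tree, leaf_map, presence, te_rates,
#'   gene_rates).
#' @export
tcn1_scenario <- function() {
  host_tree <- ape::read.tree(text = paste0(
    "((basidiomycete_A:1,basidiomycete_B:1):3,",
    "(green_algae:3,(moss:1.5,(lycophyte:1.4,",
    "(fern:1,seed_plant:1):0.5):0.4):0.8):1);"))
  element_tree <- ape::read.tree(text = paste0(
    "((elem_moss:0.2,elem_basidioA:0.2)92:0.1,",
    "(elem_lycophyte:0.25,elem_basidioB:0.25)85:0.1,",
    "(elem_fern_other:0.8,elem_seed_other:0.8)88:0.3);"))
  leaf_map <- c(elem_moss = "moss", elem_lycophyte = "lycophyte",
                elem_basidioA = "basidiomycete_A",
                elem_basidioB = "basidiomycete_B",
                elem_fern_other = "fern", elem_seed_other = "seed_plant")
  presence <- c(basidiomycete_A = TRUE, basidiomycete_B = TRUE,
                green_algae = FALSE, moss = TRUE, lycophyte = TRUE,
                fern = FALSE, seed_plant = FALSE)
  tab <- recompute_published_rates()
  cross <- tab[!is.na(tab$T_myr) & tab$T_myr == 1500, ]
  te_rates <- cross$rate_recomputed_e9[cross$set == "Tcn1"]
  gene_rates <- cross$rate_recomputed_e9[cross$set %in% c("Pho88", "uapA")]
  list(host_tree = host_tree, element_tree = element_tree,
       leaf_map = leaf_map, presence = presence,
       te_rates = te_rates, gene_rates = gene_rates)
}
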