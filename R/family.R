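## family_clustering: group annotated elements into families by amino-acid
## identity of their RT--Int regions; estimate copy number and genome
## fraction per family.

#' Pairwise amino-acid identity after global alignment
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps 11/1);
#' identity is matches over aligned columns.  With
#' `gap_mode = "exclude"` (default) columns where either sequence gaps are
#' dropped from the denominator; `"mismatch"` counts them as differences.
#'
#' @param protein_a,protein_b Amino-acid strings.
#' @param gap_mode `"exclude"` or `"mismatch"`.
#' @return Identity fraction in `[0, 1]`; symmetric in its arguments.
#' @export
pairwise_identity <- function(protein_a, protein_b,
                              gap_mode = c("exclude", "mismatch")) {
  gap_mode <- match.arg(gap_mode)
  if (nchar(protein_a) == 0L || nchar(protein_b) == 0L)
    stop("empty sequence in pairwise_identity")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein_a), Biostrings::AAString(protein_b),
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
    type = "global")
  av <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
  bv <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
  if (gap_mode == "exclude") {
    ok <- av != "-" & bv != "-"
    if (!any(ok)) return(0)
    mean(av[ok] == bv[ok])
  } else {
    mean(av == bv & av != "-")
  }
}

#' Cluster elements into families by RT--Int identity
#'
#' Single-linkage clustering: elements are in one family iff connected by a
#' chain of pairwise identities at or above the threshold.  Output is
#' sorted by size (then name) and is invariant to input order.
#'
#' @param elements Named character vector (or list) of RT--Int amino-acid
#'   translations, one per element.
#' @param threshold Identity threshold (family definition: members share
#'   90-100% amino-acid identity).
#' @param gap_mode Passed to [pairwise_identity()].
#' @return List of `cm_family` lists: `name`, `members`, `representative`,
#'   `mean_identity`, `size`.
#' @export
cluster_families <- function(elements, threshold = 0.90,
                             gap_mode = "exclude") {
  seqs <- unlist(as.list(elements))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("elements must be named")
  ids <- sort(names(seqs))        # order-invariant processing
  seqs <- seqs[ids]
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  idm <- matrix(1, n, n)
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        idm[i, j] <- idm[j, i] <-
          pairwise_identity(seqs[[i]], seqs[[j]], gap_mode)
        if (idm[i, j] >= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  fams <- lapply(unique(roots), function(r) {
    m <- ids[roots == r]
    sub <- idm[roots == r, roots == r, drop = FALSE]
    mean_id <- if (length(m) > 1L) mean(sub[upper.tri(sub)]) else 1
    rep_id <- m[which.max(nchar(seqs[m]))]
    list(name = NA_character_, members = m, representative = rep_id,
         mean_identity = mean_id, size = length(m))
  })
  ord <- order(-vapply(fams, `[[`, 0L, "size"),
               vapply(fams, function(f) f$members[1], ""))
  fams <- fams[ord]
  for (i in seq_along(fams)) {
    fams[[i]]$name <- sprintf("F%02d", i)
    class(fams[[i]]) <- "cm_family"
  }
  fams
}

#' Count genomic copies of a representative element
#'
#' Seed-and-extend search of the representative's nucleotide sequence
#' against the genome on both strands: exact `k`-mer seeds are grouped
#' into candidate loci, each verified by alignment identity; loci covering
#' at least `min_len` nt of the representative at `min_identity` are
#' counted (truncated copies above `min_len` still count).
#'
#' @param representative Nucleotide string (full element).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param min_identity Identity floor for a counted hit.
#' @param min_len Minimum hit length (nt).
#' @param k Seed length.
#' @param stride Sample every `stride`-th representative k-mer as a seed.
#' @return `list(count, loci)`: count and the hit table (genome
#'   coordinates, strand, identity, matched length).
#' @export
estimate_copy_number <- function(representative, genome, min_identity = 0.80,
                                 min_len = 100L, k = 16L, stride = 8L) {
  rep_len <- nchar(representative)
  starts <- seq(1L, rep_len - k + 1L, by = stride)
  ## keep duplicated k-mers (the two LTRs share sequence): every offset
  ## must seed its own diagonal or one LTR of each hit drops off the locus
  pats <- substring(representative, starts, starts + k - 1L)
  pd <- Biostrings::PDict(pats)
  rows <- list()
  for (gi in seq_along(genome)) {
    sid <- names(genome)[gi]
    n <- length(genome[[gi]])
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") genome[[gi]]
                 else Biostrings::reverseComplement(genome[[gi]])
      mm <- Biostrings::matchPDict(pd, subject)
      hit_pos <- integer(0); hit_off <- integer(0)
      for (pi in seq_along(mm)) {
        st <- BiocGenerics::start(mm[[pi]])
        if (length(st) > 0L) {
          hit_pos <- c(hit_pos, st - 1L)                    # 0-based genome
          hit_off <- c(hit_off, rep(starts[pi] - 1L, length(st)))
        }
      }
      if (length(hit_pos) == 0L) next
      ## group seeds into loci by implied element start (diagonal)
      diag <- hit_pos - hit_off
      ord <- order(diag, hit_pos)
      diag <- diag[ord]; hit_pos <- hit_pos[ord]; hit_off <- hit_off[ord]
      grp <- cumsum(c(TRUE, diff(diag) > 400L))
      for (g in unique(grp)) {
        sel <- grp == g
        off_min <- min(hit_off[sel]); off_max <- max(hit_off[sel]) + k
        span <- off_max - off_min
        if (span < min_len) next
        g_start <- min(hit_pos[sel]); g_end <- max(hit_pos[sel]) + k
        hseq <- substr(as.character(subject), g_start + 1L, g_end)
        rseq <- substr(representative, off_min + 1L, off_max)
        ident <- mean(strsplit(hseq, "")[[1]][seq_len(min(nchar(hseq), nchar(rseq)))] ==
                      strsplit(rseq, "")[[1]][seq_len(min(nchar(hseq), nchar(rseq)))])
        if (ident < min_identity) next
        st <- g_start; en <- g_end
        if (strand == "-") { st <- n - g_end; en <- n - g_start }
        rows[[length(rows) + 1L]] <- data.frame(
          seqid = sid, start = st, end = en, strand = strand,
          identity = ident, matched = span, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(list(count = 0L,
                loci = data.frame(seqid = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  identity = numeric(), matched = integer(),
                                  stringsAsFactors = FALSE)))
  loci <- do.call(rbind, rows)
  ## collapse overlapping loci, longest matched span first (guards against
  ## LTR cross-matches and both-strand double counting)
  loci <- loci[order(loci$seqid, -loci$matched, loci$start), , drop = FALSE]
  kept <- loci[0, ]
  for (i in seq_len(nrow(loci))) {
    cand <- loci[i, ]
    same <- kept[kept$seqid == cand$seqid, , drop = FALSE]
    if (nrow(same) == 0L ||
        all(cand$end <= same$start | same$end <= cand$start))
      kept <- rbind(kept, cand)
  }
  kept <- kept[order(kept$seqid, kept$start), , drop = FALSE]
  rownames(kept) <- NULL
  list(count = nrow(kept), loci = kept)
}

#' Genome fraction occupied per family and in total
#'
#' Overlapping hit intervals are counted once.
#'
#' @param family_hits Named list of hit tables (`start`/`end` columns,
#'   0-based half-open), one per family — e.g. the `loci` component of
#'   [estimate_copy_number()].
#' @param genome_length Genome length (bp).
#' @return `list(per_family, total)`: named fractions and the overall
#'   fraction (union across families).
#' @export
genome_fraction <- function(family_hits, genome_length) {
  merged_len <- function(df) {
    if (nrow(df) == 0L) return(0L)
    df <- df[order(df$start), , drop = FALSE]
    tot <- 0L; cs <- df$start[1]; ce <- df$end[1]
    for (i in seq_len(nrow(df))[-1]) {
      if (df$start[i] <= ce) ce <- max(ce, df$end[i])
      else { tot <- tot + (ce - cs); cs <- df$start[i]; ce <- df$end[i] }
    }
    tot + (ce - cs)
  }
  per <- vapply(family_hits, function(df) merged_len(df) / genome_length, 0)
  all_hits <- do.call(rbind, lapply(family_hits, function(df)
    df[, c("start", "end"), drop = FALSE]))
  total <- if (is.null(all_hits) || nrow(all_hits) == 0L) 0
           else merged_len(all_hits) / genome_length
  list(per_family = per, total = total)
}

#' Family summary table for a set of annotations
#'
#' Clusters element RT--Int translations into families, then estimates copy
#' number and genome fraction from each family representative.
#'
#' @param loci Locus table from [mine_genome()] (provides translations).
#' @param annotations Annotations from [annotate_loci()] (same order).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param threshold Family identity threshold.
#' @return `list(families, table)`: `cm_family` objects (augmented with
#'   `copy_number` and `genome_fraction`) and a summary data.frame.
#' @export
summarize_families <- function(loci, annotations, genome, threshold = 0.90) {
  trans <- setNames(loci$translation,
                    sprintf("elem%03d", seq_len(nrow(loci))))
  fams <- cluster_families(trans, threshold)
  glen <- sum(vapply(seq_along(genome), function(i) length(genome[[i]]), 0L))
  gseq <- as.character(genome[[1]])
  hit_tables <- list()
  for (i in seq_along(fams)) {
    f <- fams[[i]]
    idx <- match(f$members, names(trans))
    anns <- annotations[idx]
    full <- Filter(function(a) !a$partial, anns)
    rep_ann <- if (length(full) > 0L)
      full[[which.max(vapply(full, function(a) diff(a$element), 0))]]
    else anns[[which.max(vapply(anns, function(a) diff(a$element), 0))]]
    rep_seq <- substr(gseq, rep_ann$element[1] + 1L, rep_ann$element[2])
    if (identical(rep_ann$strand, "-")) rep_seq <- revcomp(rep_seq)
    cn <- estimate_copy_number(rep_seq, genome)
    fams[[i]]$copy_number <- cn$count
    hit_tables[[f$name]] <- cn$loci
  }
  gf <- genome_fraction(hit_tables, glen)
  for (i in seq_along(fams))
    fams[[i]]$genome_fraction <- unname(gf$per_family[fams[[i]]$name])
  tab <- data.frame(
    family = vapply(fams, `[[`, "", "name"),
    size = vapply(fams, `[[`, 0L, "size"),
    representative = vapply(fams, `[[`, "", "representative"),
    mean_identity = vapply(fams, `[[`, 0, "mean_identity"),
    copy_number = vapply(fams, `[[`, 0L, "copy_number"),
    genome_fraction = vapply(fams, `[[`, 0, "genome_fraction"),
    members = vapply(fams, function(f) paste(f$members, collapse = ","), ""),
    stringsAsFactors = FALSE)
  list(families = fams, table = tab, total_fraction = gf$total)
}
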