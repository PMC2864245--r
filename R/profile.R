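## domain_search: six-frame translation, position-specific profile search,
## reference-panel verification and locus merging.  The profile model is a
## PSSM with affine gap penalties scanned glocally (profile-global,
## sequence-local); scores are log-odds in bits against a uniform 1/20
## background.

.PROFILE_ALPHABET <- c(.AA20, "other")  # 21st slot absorbs X and *

aa_to_index <- function(aa_string) {
  code <- match(strsplit(aa_string, "")[[1]], .AA20)
  code[is.na(code)] <- 21L
  code - 1L  # 0-based for C++
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' Uses the standard genetic code; stop codons are emitted as `*` and
#' ambiguity-containing codons translate to `X` unless every expansion
#' agrees.
#'
#' @param record A [Biostrings::DNAString], single-sequence `DNAStringSet`,
#'   or nucleotide character scalar.
#' @param source_id Identifier recorded on each frame.
#' @return List of six frame objects (`cm_frame`): fields `source_id`,
#'   `frame` (+1,+2,+3,-1,-2,-3), `aa` (translation) and `source_length`.
#' @export
six_frame_translate <- function(record, source_id = "seq") {
  if (is(record, "DNAStringSet")) {
    stopifnot(length(record) == 1L)
    if (!is.null(names(record))) source_id <- names(record)[1]
    record <- record[[1]]
  }
  if (is.character(record)) {
    if (grepl("[EFILPQZ*]", record))
      stop("six_frame_translate expects nucleotide input")
    record <- Biostrings::DNAString(record)
  }
  if (!is(record, "DNAString")) stop("six_frame_translate expects nucleotide input")
  n <- length(record)
  if (n < 3L) stop("sequence shorter than one codon")
  rc <- Biostrings::reverseComplement(record)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  lapply(frames, function(f) {
    src <- if (f > 0) record else rc
    off <- abs(f) - 1L
    sub <- Biostrings::subseq(src, off + 1L, off + 3L * ((n - off) %/% 3L))
    aa <- if (length(sub) >= 3L)
      as.character(Biostrings::translate(sub, if.fuzzy.codon = "solve", no.init.codon = TRUE))
    else ""
    structure(list(source_id = source_id, frame = f, aa = aa,
                   source_length = n), class = "cm_frame")
  })
}

#' Map an amino-acid interval on a frame to source nucleotide coordinates
#'
#' @param frame A `cm_frame` object.
#' @param aa_start,aa_end 0-based half-open interval on the translation.
#' @return `list(start, end, strand)` on the forward source sequence.
#' @export
frame_to_nt <- function(frame, aa_start, aa_end) {
  off <- abs(frame$frame) - 1L
  n <- frame$source_length
  s <- off + 3L * aa_start
  e <- off + 3L * aa_end
  if (frame$frame > 0) list(start = s, end = e, strand = "+")
  else list(start = n - e, end = n - s, strand = "-")
}

#' Build a position-specific scoring model from a seed alignment
#'
#' Match columns are those with fewer than 50% gaps.  Emission
#' probabilities are `(count + pseudocount) / (total + 20 * pseudocount)`
#' per column, converted to log-odds (bits) against the uniform 1/20
#' background.
#'
#' @param seed_aln Aligned sequences: a [Biostrings::AAStringSet] or named
#'   character vector, all of equal width, `>= 2` sequences.
#' @param pseudocount Additive smoothing count.
#' @param gap_open,gap_extend Affine gap penalties (bits).
#' @param threshold Default score threshold (bits) for [scan_profile()].
#' @return A `cm_profile` object.
#' @export
build_profile <- function(seed_aln, pseudocount = 0.5, gap_open = 12,
                          gap_extend = 2, threshold = 25) {
  seqs <- toupper(as.character(seed_aln))
  if (length(seqs) < 2L) stop("seed alignment needs >= 2 sequences")
  if (length(unique(nchar(seqs))) != 1L)
    stop("ragged alignment: sequences differ in width")
  mat <- do.call(rbind, strsplit(seqs, ""))
  gap_frac <- colMeans(mat == "-" | mat == ".")
  match_cols <- which(gap_frac < 0.5)
  if (length(match_cols) == 0L) stop("no match columns (alignment all gaps)")
  emis <- matrix(0, nrow = length(match_cols), ncol = 21L,
                 dimnames = list(NULL, .PROFILE_ALPHABET))
  consensus <- character(length(match_cols))
  for (k in seq_along(match_cols)) {
    col <- mat[, match_cols[k]]
    col <- col[col %in% .AA20]
    counts <- table(factor(col, levels = .AA20))
    probs <- (as.numeric(counts) + pseudocount) /
      (length(col) + 20 * pseudocount)
    emis[k, 1:20] <- log2(probs / (1 / 20))
    consensus[k] <- .AA20[which.max(counts)]
  }
  emis[, 21] <- 0  # X / * are uninformative
  structure(list(ncolumns = length(match_cols), emissions = emis,
                 match_columns = match_cols,
                 consensus = paste(consensus, collapse = ""),
                 pseudocount = pseudocount, gap_open = gap_open,
                 gap_extend = gap_extend, threshold = threshold),
            class = "cm_profile")
}

#' Emission probabilities of one profile column
#' @param profile A `cm_profile`.
#' @param column Column index (1-based).
#' @return Named numeric vector over the 20 residues (sums to 1).
#' @export
profile_emissions <- function(profile, column) {
  lo <- profile$emissions[column, 1:20]
  setNames(2^lo / 20, .AA20)
}

#' Scan a translated frame with a profile
#'
#' Glocal dynamic programming: the profile is matched end-to-end, the
#' sequence locally.  All non-overlapping segments scoring at or above the
#' threshold are returned best-first, with source-strand nucleotide
#' coordinates derived through the frame map.
#'
#' @param frame A `cm_frame` (or an amino-acid character scalar, in which
#'   case no nucleotide mapping is attached).
#' @param profile A `cm_profile`.
#' @param threshold Score threshold in bits (defaults to the profile's).
#' @return data.frame of hits: `source_id`, `frame`, `aa_start`, `aa_end`,
#'   `nt_start`, `nt_end`, `strand`, `score`, `coverage`.
#' @export
scan_profile <- function(frame, profile, threshold = NULL) {
  if (is.null(threshold)) threshold <- profile$threshold
  plain <- is.character(frame)
  aa <- if (plain) frame else frame$aa
  empty <- data.frame(source_id = character(), frame = integer(),
                      aa_start = integer(), aa_end = integer(),
                      nt_start = integer(), nt_end = integer(),
                      strand = character(), score = numeric(),
                      coverage = numeric(), stringsAsFactors = FALSE)
  if (is.na(aa) || nchar(aa) == 0L) return(empty)
  hits <- .scan_pssm_cpp(aa_to_index(aa), profile$emissions,
                         profile$gap_open, profile$gap_extend, threshold)
  if (nrow(hits) == 0L) return(empty)
  cov <- hits$matched / profile$ncolumns
  if (plain) {
    return(data.frame(source_id = "protein", frame = NA_integer_,
                      aa_start = hits$aa_start, aa_end = hits$aa_end,
                      nt_start = NA_integer_, nt_end = NA_integer_,
                      strand = "+", score = hits$score, coverage = cov,
                      stringsAsFactors = FALSE))
  }
  nt <- Map(function(s, e) frame_to_nt(frame, s, e), hits$aa_start, hits$aa_end)
  data.frame(source_id = frame$source_id, frame = frame$frame,
             aa_start = hits$aa_start, aa_end = hits$aa_end,
             nt_start = vapply(nt, `[[`, 0, "start"),
             nt_end = vapply(nt, `[[`, 0, "end"),
             strand = vapply(nt, `[[`, "", "strand"),
             score = hits$score, coverage = cov, stringsAsFactors = FALSE)
}

## extract the translated hit region from its frame
hit_translation <- function(frames, hit) {
  fr <- Filter(function(f) f$frame == hit$frame, frames)[[1]]
  substr(fr$aa, hit$aa_start + 1L, hit$aa_end)
}

#' Verify profile hits against a labelled reference panel
#'
#' Each hit's translation is locally aligned (BLOSUM62, affine gaps 11/1)
#' to every panel member; the hit is kept iff the best identity reaches
#' `min_identity` over at least `min_aligned` aligned positions, and is
#' labelled with the best panel member.
#'
#' @param hits Hit table from [scan_profile()] with a `translation` column,
#'   or hits plus `frames` to extract translations from.
#' @param reference_panel Named `AAStringSet` (or named character vector)
#'   of labelled RT--Int amino-acid sequences.
#' @param min_identity Identity floor.
#' @param min_aligned Minimum aligned (non-gap) positions.
#' @param frames Optional list of `cm_frame` objects to pull translations.
#' @return Filtered hit table with `label` and `label_identity` columns.
#' @export
verify_hits <- function(hits, reference_panel, min_identity = 0.25,
                        min_aligned = 100L, frames = NULL) {
  panel <- as.character(reference_panel)
  names(panel) <- names(reference_panel)
  if (length(panel) == 0L) stop("empty reference panel")
  if (is.null(names(panel)) || any(!nzchar(names(panel))))
    stop("reference panel must be named")
  if (nrow(hits) == 0L) {
    hits$label <- character(0)
    hits$label_identity <- numeric(0)
    return(hits)
  }
  if (is.null(hits$translation)) {
    if (is.null(frames)) stop("need frames to extract hit translations")
    hits$translation <- vapply(seq_len(nrow(hits)), function(i)
      hit_translation(frames, hits[i, ]), "")
  }
  B62 <- blosum62()
  lab <- character(nrow(hits))
  ident <- numeric(nrow(hits))
  keep <- logical(nrow(hits))
  trimmed <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    best_id <- -1
    best_lab <- NA_character_
    best_rng <- c(1L, nchar(hits$translation[i]))
    for (p in names(panel)) {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(hits$translation[i]),
        Biostrings::AAString(panel[[p]]),
        substitutionMatrix = B62, gapOpening = 11, gapExtension = 1,
        type = "local")
      st <- alignment_identity(as.character(Biostrings::pattern(al)),
                               as.character(Biostrings::subject(al)))
      if (st$aligned >= min_aligned && st$identity > best_id) {
        best_id <- st$identity
        best_lab <- p
        best_rng <- c(BiocGenerics::start(Biostrings::pattern(al)),
                      BiocGenerics::end(Biostrings::pattern(al)))
      }
    }
    keep[i] <- best_id >= min_identity
    lab[i] <- best_lab
    ident[i] <- best_id
    ## restrict the reported translation to the panel-supported region:
    ## truncated copies otherwise drag flanking residues into downstream
    ## identity computations
    trimmed[i] <- substr(hits$translation[i], best_rng[1], best_rng[2])
  }
  out <- hits[keep, , drop = FALSE]
  out$label <- lab[keep]
  out$label_identity <- ident[keep]
  out$translation <- trimmed[keep]
  rownames(out) <- NULL
  out
}

## identity over aligned columns, excluding columns where either side gaps
alignment_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  ok <- av != "-" & bv != "-"
  list(identity = if (any(ok)) mean(av[ok] == bv[ok]) else 0,
       aligned = sum(ok))
}

#' Merge nearby same-strand hits into loci
#'
#' Frame-split and frameshift-fragmented hits on the same strand, separated
#' by at most `max_gap_nt`, are merged into one locus spanning their union.
#'
#' @param hits Verified hit table (one source sequence).
#' @param max_gap_nt Maximum merge gap in nucleotides.
#' @return data.frame of loci: `source_id`, `nt_start`, `nt_end`, `strand`,
#'   `score` (best hit), `n_hits`, `label`, `translation` (best hit's).
#' @export
merge_hits <- function(hits, max_gap_nt = 1000L) {
  if (nrow(hits) == 0L) {
    return(data.frame(source_id = character(), nt_start = integer(),
                      nt_end = integer(), strand = character(),
                      score = numeric(), n_hits = integer(),
                      label = character(), translation = character(),
                      stringsAsFactors = FALSE))
  }
  loci <- list()
  for (sid in unique(hits$source_id)) {
    for (str in unique(hits$strand[hits$source_id == sid])) {
      h <- hits[hits$source_id == sid & hits$strand == str, , drop = FALSE]
      h <- h[order(h$nt_start, h$nt_end), , drop = FALSE]
      grp <- cumsum(c(TRUE, h$nt_start[-1] > cummax(h$nt_end)[-nrow(h)] +
                        max_gap_nt))
      for (g in unique(grp)) {
        hh <- h[grp == g, , drop = FALSE]
        bi <- which.max(hh$score)
        loci[[length(loci) + 1L]] <- data.frame(
          source_id = sid, nt_start = min(hh$nt_start),
          nt_end = max(hh$nt_end), strand = str,
          score = hh$score[bi], n_hits = nrow(hh),
          label = if (!is.null(hh$label)) hh$label[bi] else NA_character_,
          translation = if (!is.null(hh$translation)) hh$translation[bi]
                        else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, loci)
  out[order(out$source_id, out$nt_start), , drop = FALSE]
}

#' Mine a genome for RT--partial-Int coding regions
#'
#' Six-frame translation, glocal profile scan, reference-panel
#' verification, and merging of fragmented hits into candidate loci — the
#' discovery stage of the pipeline.
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param profile Search profile (default: built from [seed_alignment()]).
#' @param reference_panel Labelled panel (default [ref_clade_panel()]).
#' @param threshold Bit-score threshold.
#' @param min_identity,min_aligned Verification parameters.
#' @param max_gap_nt Locus merge distance.
#' @return Locus table (see [merge_hits()]).
#' @export
mine_genome <- function(genome, profile = NULL, reference_panel = NULL,
                        threshold = NULL, min_identity = 0.25,
                        min_aligned = 100L, max_gap_nt = 1000L) {
  if (is.null(profile)) profile <- build_profile(seed_alignment())
  if (is.null(reference_panel)) reference_panel <- ref_clade_panel()
  all_hits <- list()
  for (i in seq_along(genome)) {
    frames <- six_frame_translate(genome[i])
    hits <- do.call(rbind, lapply(frames, scan_profile, profile = profile,
                                  threshold = threshold))
    if (nrow(hits) > 0L) {
      hits$translation <- vapply(seq_len(nrow(hits)), function(k)
        hit_translation(frames, hits[k, ]), "")
      hits <- verify_hits(hits, reference_panel, min_identity, min_aligned)
    }
    all_hits[[i]] <- hits
  }
  hits <- do.call(rbind, all_hits)
  if (is.null(hits) || nrow(hits) == 0L) return(merge_hits(hits[0, ]))
  merge_hits(hits, max_gap_nt)
}

#' Per-domain search profiles
#'
#' One profile per Pol domain (PR, RT, RH, INT, CHD, dUTPase), each built
#' from the clade-diverged variants of the synthetic domain reference.
#' Thresholds scale with domain length (0.25 bits/column, floor 10).
#'
#' @return Named list of `cm_profile` objects.
#' @export
domain_profiles <- function() {
  pols <- c(list(base = make_pol_protein(domain_order = names(.DOMAIN_LEN),
                                         pol_aa = 1238L)$protein),
            lapply(ref_clade_names(), function(cl)
              mutate_protein(make_pol_protein(domain_order = names(.DOMAIN_LEN),
                                              pol_aa = 1238L)$protein,
                             .CLADE_DIVERGENCE,
                             derive_seed(.CM_BASE_SEED, paste0("clade_", cl)))))
  lay <- pol_layout(names(.DOMAIN_LEN), 1238L)
  out <- lapply(seq_len(nrow(lay)), function(i) {
    aln <- Biostrings::AAStringSet(vapply(pols, substr,
                                          "", lay$aa_start[i] + 1L,
                                          lay$aa_end[i]))
    names(aln) <- paste0("v", seq_along(aln))
    p <- build_profile(aln)
    p$threshold <- max(10, 0.25 * p$ncolumns)
    p
  })
  names(out) <- lay$name
  out
}
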