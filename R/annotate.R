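## element_annotation: reconstruct full elements around verified loci —
## window expansion, LTR direct-repeat search, TSD, ORFs, domain
## architecture, CCHC / PPT / PBS, promoter boxes, and the in-silico
## degenerate-primer PCR.

#' Default LTR search parameters
#'
#' `min_len`/`min_identity` gate candidate direct repeats; `k` is the exact
#' seed length; `max_span` bounds the distance from 5' LTR start to 3' LTR
#' end (covers elements up to 15 kb).
#' @return Named list.
#' @export
ltr_params <- function() {
  list(min_len = 100L, min_identity = 0.80, k = 12L, max_span = 15000L,
       canonical_bonus = 50)
}

#' Expand a locus window around a domain hit
#'
#' @param nt_start,nt_end Hit span (0-based half-open, genome coordinates).
#' @param seq_length Length of the source sequence.
#' @param flank Expansion on each side (bp), at most 15000.
#' @return `list(start, end)` clipped to the sequence bounds.
#' @export
expand_locus <- function(nt_start, nt_end, seq_length, flank = 15000L) {
  stopifnot(flank <= 15000L, nt_start >= 0L, nt_end <= seq_length)
  list(start = max(0L, as.integer(nt_start - flank)),
       end = min(as.integer(seq_length), as.integer(nt_end + flank)))
}

## x-drop ungapped extension; returns how far the repeat extends (0-based
## offsets relative to the two starting positions), tolerant of scattered
## mismatches but trimmed back to the last matching position
extend_repeat <- function(a, b, i0, j0, dir, lim_i, lim_j,
                          match = 1, mismatch = -2, xdrop = 6) {
  best <- 0; score <- 0; ext <- 0L; best_ext <- 0L
  repeat {
    i <- i0 + dir * (ext + 1L)
    j <- j0 + dir * (ext + 1L)
    if (dir > 0 && (i > lim_i || j > lim_j)) break
    if (dir < 0 && (i < lim_i || j < lim_j)) break
    score <- score + if (a[i] == b[j]) match else mismatch
    ext <- ext + 1L
    if (a[i] == b[j] && score > best) { best <- score; best_ext <- ext }
    if (best - score >= xdrop) break
  }
  best_ext
}

#' Find the best LTR direct-repeat pair flanking an anchor
#'
#' Seeds exact `k`-mers shared between the regions upstream and downstream
#' of the anchor (the RT--Int hit), chains them on common diagonals,
#' extends un-gapped with an x-drop, then snaps boundaries to the canonical
#' TG...CA LTR termini when these are found near the repeat ends.
#' Candidates are scored by length x identity with a bonus for canonical
#' ends.
#'
#' @param window_seq Window nucleotide string.
#' @param anchor `c(start, end)` of the hit inside the window (0-based
#'   half-open).
#' @param params See [ltr_params()].
#' @return `list(five_prime, three_prime, identity, ends_canonical)` with
#'   0-based half-open intervals, or `NULL` when no acceptable repeat.
#' @export
find_ltr_pair <- function(window_seq, anchor, params = ltr_params()) {
  n <- nchar(window_seq)
  k <- params$k
  a_s <- anchor[1]; a_e <- anchor[2]
  if (a_s < k || n - a_e < k) return(NULL)
  chars <- strsplit(window_seq, "")[[1]]

  up_starts <- seq_len(a_s - k + 1L)                 # 1-based starts in window
  down_starts <- seq(a_e + 1L, n - k + 1L)
  up_k <- substring(window_seq, up_starts, up_starts + k - 1L)
  down_k <- substring(window_seq, down_starts, down_starts + k - 1L)
  common <- intersect(unique(up_k), unique(down_k))
  if (length(common) == 0L) return(NULL)
  ui <- which(up_k %in% common)
  di <- which(down_k %in% common)
  up_map <- split(up_starts[ui], up_k[ui])
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (t in di) {
    us <- up_map[[down_k[t]]]
    pairs_i <- c(pairs_i, us)
    pairs_j <- c(pairs_j, rep(down_starts[t], length(us)))
  }
  if (length(pairs_i) == 0L) return(NULL)
  diag <- pairs_j - pairs_i

  best <- NULL
  for (d in unique(diag)) {
    sel <- diag == d
    i_min <- min(pairs_i[sel]); i_max <- max(pairs_i[sel]) + k - 1L
    j_min <- i_min + d; j_max <- i_max + d
    ## extend outward (stay out of the anchor and off the other copy)
    left <- extend_repeat(chars, chars, i_min, j_min, -1L, 1L, a_e + 1L)
    right <- extend_repeat(chars, chars, i_max, j_max, +1L, a_s, n)
    s1 <- i_min - left; e1 <- i_max + right          # 1-based inclusive
    s2 <- s1 + d; e2 <- e1 + d
    e1 <- min(e1, a_s); e2 <- min(e2, n)             # keep 5' copy upstream
    s2 <- max(s2, a_e + 1L)
    len <- min(e1 - s1, e2 - s2) + 1L
    e1 <- s1 + len - 1L; e2 <- s2 + len - 1L
    if (len < params$min_len) next
    if (e2 - s1 + 1L > params$max_span) next

    ## canonical snapping: common offset where both copies start TG / end CA
    snap <- function(p1, p2, pat, range) {
      for (dd in order(abs(range))) {
        o <- range[dd]
        q1 <- p1 + o; q2 <- p2 + o
        if (q1 < 1L || q2 + 1L > n) next
        if (identical(chars[q1], substr(pat, 1, 1)) &&
            identical(chars[q1 + 1L], substr(pat, 2, 2)) &&
            identical(chars[q2], substr(pat, 1, 1)) &&
            identical(chars[q2 + 1L], substr(pat, 2, 2))) return(o)
      }
      NA_integer_
    }
    off_s <- snap(s1, s2, "TG", -8:8)
    off_e <- snap(e1 - 1L, e2 - 1L, "CA", -8:8)
    canonical <- !is.na(off_s) && !is.na(off_e)
    if (canonical) {
      s1 <- s1 + off_s; s2 <- s2 + off_s
      e1 <- e1 + off_e; e2 <- e2 + off_e
    }
    if (s1 < 1L || e2 > n || e1 >= s2) next
    len <- e1 - s1 + 1L
    if (len < params$min_len) next
    ident <- mean(chars[s1:e1] == chars[s2:e2])
    if (ident < params$min_identity) next
    score <- len * ident + if (canonical) params$canonical_bonus else 0
    if (is.null(best) || score > best$score) {
      best <- list(five_prime = c(s1 - 1L, e1), three_prime = c(s2 - 1L, e2),
                   identity = ident, ends_canonical = canonical,
                   score = score)
    }
  }
  if (is.null(best)) return(NULL)
  best$score <- NULL
  best
}

#' Find the target-site duplication flanking an element
#'
#' Returns the longest `k` in `[min_len, max_len]` for which the `k`-mers
#' immediately left of the element start and right of the element end are
#' identical.
#'
#' @param genome_seq Genome nucleotide string (or single `DNAStringSet`).
#' @param element_bounds `c(start, end)`, 0-based half-open.
#' @param min_len,max_len TSD length range.
#' @return The duplicated string, or `NULL`.
#' @export
find_tsd <- function(genome_seq, element_bounds, min_len = 4L, max_len = 6L) {
  if (is(genome_seq, "DNAStringSet")) genome_seq <- as.character(genome_seq[[1]])
  s <- element_bounds[1]; e <- element_bounds[2]
  n <- nchar(genome_seq)
  for (k in seq(max_len, min_len)) {
    if (s - k < 0L || e + k > n) next
    left <- substr(genome_seq, s - k + 1L, s)
    right <- substr(genome_seq, e + 1L, e + k)
    if (left == right) return(left)
  }
  NULL
}

#' Find complete open reading frames
#'
#' Reports maximal start-to-stop ORFs on both strands with at least
#' `min_aa` codons; the reported interval runs from the start codon through
#' the last sense codon (the stop codon is excluded).  ORFs running off the
#' sequence end without a stop are not reported.
#'
#' @param seq Nucleotide string.
#' @param min_aa Minimum protein length (codons).
#' @return data.frame: `start`, `end` (0-based half-open on the input),
#'   `strand`, `aa_len`, `protein`, sorted by `start`.
#' @export
find_orfs <- function(seq, min_aa = 200L) {
  n <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (off in 0:2) {
      ncod <- (n - off) %/% 3L
      if (ncod < 1L) next
      aa <- as.character(Biostrings::translate(
        Biostrings::subseq(Biostrings::DNAString(s), off + 1L, off + 3L * ncod),
        if.fuzzy.codon = "solve", no.init.codon = TRUE))
      stops <- c(0L, which(strsplit(aa, "")[[1]] == "*"), nchar(aa) + 1L)
      stop_pos <- which(strsplit(aa, "")[[1]] == "*")
      seg_start <- c(1L, stop_pos + 1L)
      seg_stop <- c(stop_pos, NA_integer_)  # NA: runs off the end
      for (g in seq_along(seg_start)) {
        if (is.na(seg_stop[g])) next       # incomplete: no stop codon
        a <- seg_start[g]; b <- seg_stop[g] - 1L
        if (b < a) next
        seg <- substr(aa, a, b)
        m <- regexpr("M", seg, fixed = TRUE)
        if (m < 0) next
        orf_a <- a + as.integer(m) - 1L    # codon index of the start codon
        len <- b - orf_a + 1L
        if (len < min_aa) next
        nt_s <- off + (orf_a - 1L) * 3L    # 0-based on strand s
        nt_e <- off + (b) * 3L
        if (strand == "-") { tmp <- nt_s; nt_s <- n - nt_e; nt_e <- n - tmp }
        rows[[length(rows) + 1L]] <- data.frame(
          start = nt_s, end = nt_e, strand = strand, aa_len = len,
          protein = substr(seg, as.integer(m), b - a + 1L),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), aa_len = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Detect Pol enzymatic domains in a protein
#'
#' Scans the protein with each per-domain profile; overlapping calls are
#' resolved best-score-first and the result is ordered by position.
#'
#' @param protein Amino-acid string.
#' @param profiles Named list of `cm_profile` objects
#'   (default [domain_profiles()]).
#' @return data.frame: `name`, `aa_start`, `aa_end`, `score`, ordered by
#'   `aa_start`.
#' @export
detect_domains <- function(protein, profiles = domain_profiles()) {
  hits <- list()
  for (d in names(profiles)) {
    h <- scan_profile(protein, profiles[[d]])
    if (nrow(h) > 0L)
      hits[[length(hits) + 1L]] <- data.frame(
        name = d, aa_start = h$aa_start, aa_end = h$aa_end, score = h$score,
        stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L)
    return(data.frame(name = character(), aa_start = integer(),
                      aa_end = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  all <- do.call(rbind, hits)
  all <- all[order(-all$score), , drop = FALSE]
  kept <- all[0, ]
  for (i in seq_len(nrow(all))) {
    cand <- all[i, ]
    if (nrow(kept) == 0L ||
        all(cand$aa_end <= kept$aa_start | kept$aa_end <= cand$aa_start))
      kept <- rbind(kept, cand)
  }
  kept <- kept[order(kept$aa_start), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

## domain detection across the three forward frames of a nucleotide
## region; hits are projected to nucleotide intervals and overlaps
## resolved best-score-first, so architectures survive in-frame stops
detect_domains_frames <- function(nt_seq, profiles = domain_profiles()) {
  empty <- data.frame(name = character(), nt_start = integer(),
                      nt_end = integer(), score = numeric(),
                      frame = integer(), stringsAsFactors = FALSE)
  n <- nchar(nt_seq)
  if (n < 60L) return(empty)
  hits <- list()
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 10L) next
    aa <- as.character(Biostrings::translate(Biostrings::subseq(
      Biostrings::DNAString(nt_seq), f + 1L, f + 3L * ncod),
      if.fuzzy.codon = "solve", no.init.codon = TRUE))
    for (d in names(profiles)) {
      h <- scan_profile(aa, profiles[[d]])
      if (nrow(h) > 0L)
        hits[[length(hits) + 1L]] <- data.frame(
          name = d, nt_start = f + 3L * h$aa_start, nt_end = f + 3L * h$aa_end,
          score = h$score, frame = f + 1L, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(empty)
  all <- do.call(rbind, hits)
  all <- all[order(-all$score), , drop = FALSE]
  kept <- all[0, ]
  for (i in seq_len(nrow(all))) {
    cand <- all[i, ]
    if (nrow(kept) == 0L ||
        all(cand$nt_end <= kept$nt_start | kept$nt_end <= cand$nt_start))
      kept <- rbind(kept, cand)
  }
  kept <- kept[order(kept$nt_start), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Find CCHC zinc-knuckle motifs (C-X2-C-X4-H-X4-C)
#'
#' @param protein Amino-acid string.
#' @return Integer vector of 0-based match offsets (overlaps reported).
#' @export
find_cchc <- function(protein) {
  m <- gregexpr("(?=C.{2}C.{4}H.{4}C)", protein, perl = TRUE)[[1]]
  if (m[1] < 0) integer(0) else as.integer(m) - 1L
}

#' Find the polypurine tract upstream of the 3' LTR
#'
#' The longest window of at least `min_len` nt with at least `min_purine`
#' purines whose end lies within `max_gap` nt of the 3' LTR start.
#'
#' @param seq Nucleotide string (element or window, any frame of reference
#'   as long as `three_prime_ltr_start` matches it).
#' @param three_prime_ltr_start 0-based start of the 3' LTR on `seq`.
#' @param min_len Minimum tract length.
#' @param min_purine Minimum purine fraction.
#' @param max_gap Maximum distance from tract end to LTR start.
#' @return `c(start, end)` 0-based half-open, or `NULL`.
#' @export
find_ppt <- function(seq, three_prime_ltr_start, min_len = 10L,
                     min_purine = 0.9, max_gap = 20L) {
  L <- three_prime_ltr_start
  lo <- max(0L, L - max_gap - 60L)
  chars <- strsplit(substr(seq, lo + 1L, L), "")[[1]]
  pur <- as.integer(chars %in% c("A", "G"))
  m <- length(pur)
  best <- NULL
  for (e in seq_len(m)) {                       # e: end (inclusive) in window
    if ((m - e) > max_gap) next                 # must end within max_gap of LTR
    for (s in seq_len(e)) {
      len <- e - s + 1L
      if (len < min_len) next
      if (mean(pur[s:e]) >= min_purine &&
          (is.null(best) || len > best[2] - best[1]))
        best <- c(lo + s - 1L, lo + e)
    }
  }
  best
}

#' Find the primer-binding site downstream of the 5' LTR
#'
#' Looks within `window` nt downstream of the 5' LTR for (a) a match of at
#' least `min_match` nt to the reverse complement of a panel tRNA 3'
#' terminus (tRNA priming) or (b) a match to the LTR 3' terminus or its
#' reverse complement (self-priming).
#'
#' @param seq Nucleotide string.
#' @param five_prime_ltr_end 0-based end (exclusive) of the 5' LTR on `seq`.
#' @param trna 3'-terminal tRNA sequences (named character,
#'   default [trna_panel()]).
#' @param ltr_seq The LTR sequence (for self-priming detection); `NULL`
#'   skips that check.
#' @param min_match Minimum match length.
#' @param window Search window downstream of the LTR.
#' @return `list(start, end, mechanism, trna)` (0-based half-open) or `NULL`.
#' @export
find_pbs <- function(seq, five_prime_ltr_end, trna = trna_panel(),
                     ltr_seq = NULL, min_match = 12L, window = 30L) {
  region <- substr(seq, five_prime_ltr_end + 1L,
                   min(nchar(seq), five_prime_ltr_end + window + 20L))
  find_frag <- function(pattern_full, anchor = c("prefix", "suffix")) {
    ## longest end-anchored fragment of pattern_full found in the region
    anchor <- match.arg(anchor)
    for (L in seq(nchar(pattern_full), min_match)) {
      pat <- if (anchor == "prefix") substr(pattern_full, 1L, L)
             else substr(pattern_full, nchar(pattern_full) - L + 1L,
                         nchar(pattern_full))
      p <- regexpr(pat, region, fixed = TRUE)
      if (p > 0 && (p - 1L) <= window)
        return(c(five_prime_ltr_end + p - 1L, five_prime_ltr_end + p - 1L + L))
    }
    NULL
  }
  for (tn in names(trna)) {
    ## PBS complementary to the tRNA 3' terminus: after reverse
    ## complementing, the terminus-proximal end is the pattern PREFIX
    hit <- find_frag(revcomp(trna[[tn]]), "prefix")
    if (!is.null(hit))
      return(list(start = hit[1], end = hit[2], mechanism = "trna",
                  trna = tn))
  }
  if (!is.null(ltr_seq)) {
    term <- substr(ltr_seq, max(1L, nchar(ltr_seq) - 17L), nchar(ltr_seq))
    for (spec_pat in list(c(term, "suffix"), c(revcomp(term), "prefix"))) {
      hit <- find_frag(spec_pat[1], spec_pat[2])
      if (!is.null(hit))
        return(list(start = hit[1], end = hit[2],
                    mechanism = "self-priming", trna = NA_character_))
    }
  }
  NULL
}

.IUPAC_OK <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K", "V", "H",
               "D", "B", "N")

#' In-silico PCR with degenerate primers
#'
#' The forward primer is matched on either strand with full IUPAC
#' degeneracy; the reverse primer's reverse complement is matched
#' downstream on the same strand.  Products within the length window are
#' reported (nearest reverse site per forward site, as in a real reaction).
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param primer_pair `list(forward, reverse_core, product_min,
#'   product_max)` — see [rt_primer_pair()].
#' @return Feature table of `PCR_product` features with the product
#'   sequence in the attributes.
#' @export
in_silico_pcr <- function(genome, primer_pair = rt_primer_pair()) {
  fwd <- toupper(primer_pair$forward)
  rev_core <- toupper(primer_pair$reverse_core)
  for (p in c(fwd, rev_core)) {
    bad <- setdiff(strsplit(p, "")[[1]], .IUPAC_OK)
    if (length(bad) > 0L)
      stop("primer contains undefined IUPAC code(s): ",
           paste(unique(bad), collapse = ", "))
  }
  pmin <- primer_pair$product_min
  pmax <- primer_pair$product_max
  rows <- list()
  for (i in seq_along(genome)) {
    sid <- names(genome)[i]
    n <- length(genome[[i]])
    for (strand in c("+", "-")) {
      s <- if (strand == "+") genome[[i]]
           else Biostrings::reverseComplement(genome[[i]])
      f <- Biostrings::matchPattern(fwd, s, fixed = FALSE)
      if (length(f) == 0L) next
      r <- Biostrings::matchPattern(
        Biostrings::reverseComplement(Biostrings::DNAString(rev_core)),
        s, fixed = FALSE)
      if (length(r) == 0L) next
      fs <- BiocGenerics::start(f) - 1L          # 0-based product start
      re <- BiocGenerics::end(r)                 # 0-based exclusive end
      for (a in fs) {
        lens <- re - a
        ok <- which(lens >= pmin & lens <= pmax)
        if (length(ok) == 0L) next
        b <- re[ok[which.min(lens[ok])]]
        st <- a; en <- b
        if (strand == "-") { st <- n - b; en <- n - a }
        prod <- substr(as.character(s), a + 1L, b)
        rows[[length(rows) + 1L]] <- features(
          sid, st, en, strand, "PCR_product",
          sprintf("length=%d;seq=%s", b - a, prod))
      }
    }
  }
  if (length(rows) == 0L) return(features())
  out <- do.call(bind_features, rows)
  out[order(out$seqid, out$start), , drop = FALSE]
}

## map an interval on the (possibly flipped) window back to genome coords
window_to_genome <- function(iv, w_start, w_len, flipped) {
  if (is.null(iv)) return(NULL)
  if (flipped) c(w_start + (w_len - iv[2]), w_start + (w_len - iv[1]))
  else c(w_start + iv[1], w_start + iv[2])
}

#' Annotate a full element around a verified locus
#'
#' Expands the locus, finds the LTR pair, TSD, ORFs, Pol domain
#' architecture, Gag CCHC motif, PPT, PBS and TATA/CAAT promoter boxes, and
#' classifies the element as chromovirus (CHD downstream of the integrase)
#' or non-chromovirus Gypsy.  Loci with no acceptable LTR pair are flagged
#' partial.
#'
#' @param locus One row of a locus table from [mine_genome()].
#' @param genome Named [Biostrings::DNAStringSet].
#' @param profiles Per-domain profiles (default [domain_profiles()]).
#' @param trna tRNA panel for PBS detection.
#' @param flank Window expansion (bp).
#' @param params LTR search parameters.
#' @param min_orf_aa Minimum ORF length.
#' @return A `cm_annotation` list.
#' @export
annotate_element <- function(locus, genome, profiles = domain_profiles(),
                             trna = trna_panel(), flank = 15000L,
                             params = ltr_params(), min_orf_aa = 200L) {
  sid <- locus$source_id
  gseq <- as.character(genome[[sid]])
  n <- nchar(gseq)
  win <- expand_locus(locus$nt_start, locus$nt_end, n, flank)
  wseq <- substr(gseq, win$start + 1L, win$end)
  wlen <- nchar(wseq)
  anchor <- c(locus$nt_start - win$start, locus$nt_end - win$start)
  flipped <- identical(locus$strand, "-")
  if (flipped) {
    wseq <- revcomp(wseq)
    anchor <- c(wlen - anchor[2], wlen - anchor[1])
  }

  ltr <- find_ltr_pair(wseq, anchor, params)
  ann <- list(source_id = sid, strand = locus$strand,
              label = locus$label, partial = is.null(ltr),
              window = c(win$start, win$end))
  if (is.null(ltr)) {
    ann$element <- c(locus$nt_start, locus$nt_end)
    ann$classification <- NA_character_
    class(ann) <- "cm_annotation"
    return(ann)
  }

  el_rel <- c(ltr$five_prime[1], ltr$three_prime[2])
  ann$element <- window_to_genome(el_rel, win$start, wlen, flipped)
  ann$ltr5 <- window_to_genome(ltr$five_prime, win$start, wlen, flipped)
  ann$ltr3 <- window_to_genome(ltr$three_prime, win$start, wlen, flipped)
  if (flipped) { tmp <- ann$ltr5; ann$ltr5 <- ann$ltr3; ann$ltr3 <- tmp }
  ann$ltr_identity <- ltr$identity
  ann$ends_canonical <- ltr$ends_canonical
  ann$tsd <- find_tsd(gseq, ann$element)

  eseq <- substr(wseq, el_rel[1] + 1L, el_rel[2])
  ltr_len <- ltr$five_prime[2] - ltr$five_prime[1]
  ltr_seq <- substr(eseq, 1L, ltr_len)
  orfs <- find_orfs(eseq, min_orf_aa)
  orfs <- orfs[orfs$strand == "+", , drop = FALSE]   # element orientation
  ann$orfs <- orfs
  gag_prot <- if (nrow(orfs) > 0L) orfs$protein[1] else NULL
  ## domain architecture from the forward-frame translations of the
  ## internal region: robust to the in-frame stops accumulated by aged
  ## copies, which fragment the start-to-stop ORFs
  internal <- substr(eseq, ltr_len + 1L, nchar(eseq) - ltr_len)
  ann$domains <- detect_domains_frames(internal, profiles)
  ann$cchc_present <- (!is.null(gag_prot) && length(find_cchc(gag_prot)) > 0L) ||
    any(vapply(0:2, function(f) {
      ncod <- (nchar(internal) - f) %/% 3L
      if (ncod < 6L) return(FALSE)
      aa <- as.character(Biostrings::translate(Biostrings::subseq(
        Biostrings::DNAString(internal), f + 1L, f + 3L * ncod),
        if.fuzzy.codon = "solve", no.init.codon = TRUE))
      length(find_cchc(aa)) > 0L
    }, TRUE))
  ann$cchc_positions <- if (is.null(gag_prot)) integer(0) else find_cchc(gag_prot)
  three_ltr_rel <- ltr$three_prime[1] - el_rel[1]
  ann$ppt <- find_ppt(eseq, three_ltr_rel)
  pbs <- find_pbs(eseq, ltr_len, trna, ltr_seq)
  ann$pbs <- pbs
  ann$promoter_boxes <- promoter_boxes(ltr_seq)

  dn <- ann$domains$name
  ann$classification <-
    if ("CHD" %in% dn && "INT" %in% dn &&
        which(dn == "CHD")[1] > which(dn == "INT")[1]) "chromovirus"
    else "non-chromovirus Gypsy"
  class(ann) <- "cm_annotation"
  ann
}

## literal TATAWA / CAAT promoter motifs inside an LTR
promoter_boxes <- function(ltr_seq) {
  out <- list()
  for (box in c(TATA = "TATAWA", CAAT = "CAAT")) {
    m <- Biostrings::matchPattern(box, Biostrings::DNAString(ltr_seq),
                                  fixed = FALSE)
    if (length(m) > 0L)
      out[[length(out) + 1L]] <- data.frame(
        box = names(which(c(TATA = "TATAWA", CAAT = "CAAT") == box)),
        start = BiocGenerics::start(m) - 1L, end = BiocGenerics::end(m),
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(box = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Annotate all loci of a mining run
#' @param loci Locus table from [mine_genome()].
#' @param genome Named [Biostrings::DNAStringSet].
#' @param ... Passed to [annotate_element()].
#' @return List of `cm_annotation` objects.
#' @export
annotate_loci <- function(loci, genome, ...) {
  profiles <- domain_profiles()
  trna <- trna_panel()
  lapply(seq_len(nrow(loci)), function(i)
    annotate_element(loci[i, ], genome, profiles = profiles, trna = trna, ...))
}

#' Convert annotations to a feature table
#' @param annotations List of `cm_annotation` objects.
#' @return A feature table (genome coordinates) for [write_gff3()].
#' @export
annotations_to_features <- function(annotations) {
  rows <- lapply(seq_along(annotations), function(i) {
    a <- annotations[[i]]
    id <- sprintf("elem%03d", i)
    base <- sprintf("ID=%s;label=%s;partial=%s;classification=%s", id,
                    a$label, tolower(a$partial),
                    ifelse(is.na(a$classification), ".", a$classification))
    out <- features(a$source_id, a$element[1], a$element[2], a$strand,
                    "LTR_retrotransposon",
                    paste0(base, if (!is.null(a$tsd)) paste0(";tsd=", a$tsd)))
    if (!a$partial) {
      out <- bind_features(out,
        features(a$source_id, c(a$ltr5[1], a$ltr3[1]),
                 c(a$ltr5[2], a$ltr3[2]), a$strand, "long_terminal_repeat",
                 paste0("Parent=", id)))
      if (!is.null(a$tsd)) {
        tl <- nchar(a$tsd)
        out <- bind_features(out,
          features(a$source_id, c(a$element[1] - tl, a$element[2]),
                   c(a$element[1], a$element[2] + tl), ".",
                   "target_site_duplication",
                   paste0("Parent=", id, ";seq=", a$tsd)))
      }
    }
    out
  })
  do.call(bind_features, rows)
}

#' Greedily merge overlapping partial sequences
#'
#' Reconstruction helper for families with no intact copy: sequences whose
#' suffix/prefix overlap is at least `min_overlap` nt at `min_identity`
#' identity are merged, longest first.
#'
#' @param seqs Character vector of nucleotide sequences.
#' @param min_overlap Minimum overlap (nt).
#' @param min_identity Minimum overlap identity.
#' @return Character vector of merged sequences.
#' @export
merge_partial_sequences <- function(seqs, min_overlap = 200L,
                                    min_identity = 0.95) {
  seqs <- seqs[order(-nchar(seqs))]
  merged <- TRUE
  while (merged && length(seqs) > 1L) {
    merged <- FALSE
    for (i in seq_along(seqs)) {
      for (j in seq_along(seqs)) {
        if (i == j) next
        ov <- best_overlap(seqs[i], seqs[j], min_overlap, min_identity)
        if (!is.null(ov)) {
          seqs[i] <- ov
          seqs <- seqs[-j]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
  }
  seqs
}

## longest suffix(a)/prefix(b) overlap meeting the identity floor
best_overlap <- function(a, b, min_overlap, min_identity) {
  na <- nchar(a); nb <- nchar(b)
  for (L in seq(min(na, nb), min_overlap)) {
    sa <- strsplit(substr(a, na - L + 1L, na), "")[[1]]
    sb <- strsplit(substr(b, 1L, L), "")[[1]]
    if (mean(sa == sb) >= min_identity)
      return(paste0(a, substr(b, L + 1L, nb)))
  }
  NULL
}
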