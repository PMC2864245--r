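## synthetic_genome: generate genomes with planted LTR retroelements and
## protein pairs of known divergence.  Every generator is deterministic
## under an explicit seed and emits exact ground truth, so downstream
## stages can be scored by plant-and-recover.

.CODON_BY_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
})

#' Describe the structure of a synthetic LTR retroelement
#'
#' Defaults reproduce a 5704-bp chromovirus with 440-bp LTRs, a 323-aa Gag
#' (969-bp ORF) and a 1238-aa Pol (3714-bp ORF) carrying PR-RT-RH-Int-CHD.
#'
#' @param ltr_length LTR length in bp (>= 100).
#' @param tsd_length Target-site duplication length (4-6 bp).
#' @param orf_layout `"two"` (separate gag and pol) or `"single"` (fused).
#' @param domain_order Pol domain names, N-to-C, from
#'   PR, RT, RH, INT, CHD, dUTPase.
#' @param has_cchc Plant the C-X2-C-X4-H-X4-C zinc knuckle in Gag.
#' @param has_pbs `"none"`, `"trna"` (PBS complementary to a panel tRNA
#'   3' terminus) or `"self"` (LTR-derived self-priming sequence).
#' @param has_ppt Plant a polypurine tract just upstream of the 3' LTR.
#' @param primer_cassette Embed degenerate-primer-compatible sites in RT
#'   (forward site plus, ~283 nt downstream, the reverse complement of the
#'   reverse-primer core; amplicon 320 bp).
#' @param gag_aa,pol_aa Protein lengths (aa).
#' @param leader_len,spacer_len,tail_len Untranslated segment lengths (nt).
#' @return A list with class `cm_element_template`.
#' @export
element_template <- function(ltr_length = 440L, tsd_length = 5L,
                             orf_layout = c("two", "single"),
                             domain_order = c("PR", "RT", "RH", "INT", "CHD"),
                             has_cchc = TRUE, has_pbs = "none",
                             has_ppt = TRUE, primer_cassette = TRUE,
                             gag_aa = 323L, pol_aa = 1238L,
                             leader_len = 60L, spacer_len = 30L,
                             tail_len = 45L) {
  orf_layout <- match.arg(orf_layout)
  if (isTRUE(has_pbs)) has_pbs <- "trna"
  if (identical(has_pbs, FALSE)) has_pbs <- "none"
  has_pbs <- match.arg(has_pbs, c("none", "trna", "self"))
  tpl <- structure(list(ltr_length = as.integer(ltr_length),
                        tsd_length = as.integer(tsd_length),
                        orf_layout = orf_layout,
                        domain_order = domain_order,
                        has_cchc = isTRUE(has_cchc), has_pbs = has_pbs,
                        has_ppt = isTRUE(has_ppt),
                        primer_cassette = isTRUE(primer_cassette),
                        gag_aa = as.integer(gag_aa),
                        pol_aa = as.integer(pol_aa),
                        leader_len = as.integer(leader_len),
                        spacer_len = as.integer(spacer_len),
                        tail_len = as.integer(tail_len)),
                   class = "cm_element_template")
  validate_template(tpl)
  tpl
}

#' Total length (bp) of an element built from a template
#' @param tpl An element template.
#' @return Integer length.
#' @export
template_length <- function(tpl) {
  coding <- if (tpl$orf_layout == "two") {
    (tpl$gag_aa * 3L + 3L) + tpl$spacer_len + (tpl$pol_aa * 3L + 3L)
  } else {
    (tpl$gag_aa + tpl$pol_aa) * 3L + 3L
  }
  2L * tpl$ltr_length + tpl$leader_len + coding + tpl$tail_len
}

validate_template <- function(tpl) {
  if (tpl$ltr_length < 100L) stop("ltr_length must be >= 100")
  if (!(tpl$tsd_length %in% 4:6)) stop("tsd_length must be 4-6")
  if (!all(tpl$domain_order %in% names(.DOMAIN_LEN)))
    stop("unknown domain(s): ",
         paste(setdiff(tpl$domain_order, names(.DOMAIN_LEN)), collapse = ", "))
  if ("CHD" %in% tpl$domain_order) {
    if (!("INT" %in% tpl$domain_order) ||
        which(tpl$domain_order == "CHD") <= which(tpl$domain_order == "INT"))
      stop("chromovirus templates must carry CHD after INT")
  }
  len <- template_length(tpl)
  if (len < 4400L || len > 13500L)
    stop("total element length ", len, " outside 4400-13500 bp")
  if (tpl$has_ppt && tpl$tail_len < 45L)
    stop("tail_len must be >= 45 to host the polypurine tract")
  if (tpl$has_pbs != "none" && tpl$leader_len < 20L)
    stop("leader_len must be >= 20 to host a PBS")
  invisible(tpl)
}

random_dna <- function(n, seed, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_cm_seed(seed,
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = ""))
}

#' Substitute nucleotide sites at a given per-site probability
#' @param dna Character scalar.
#' @param p_sub Per-site substitution probability.
#' @param seed Integer seed.
#' @return Character scalar.
#' @export
mutate_dna <- function(dna, p_sub, seed) {
  if (p_sub <= 0) return(dna)
  nt <- strsplit(dna, "")[[1]]
  bases <- c("A", "C", "G", "T")
  with_cm_seed(seed, {
    hit <- which(runif(length(nt)) < p_sub)
    for (i in hit) {
      alt <- setdiff(bases, nt[i])
      nt[i] <- alt[sample.int(3L, 1L)]
    }
  })
  paste(nt, collapse = "")
}

## encode a protein as nucleotides, sampling synonymous codons uniformly
encode_protein <- function(protein, seed) {
  aa <- strsplit(protein, "")[[1]]
  with_cm_seed(seed, {
    codons <- vapply(aa, function(a) {
      cs <- .CODON_BY_AA[[a]]
      cs[sample.int(length(cs), 1L)]
    }, "", USE.NAMES = FALSE)
  })
  paste(codons, collapse = "")
}

#' Build one synthetic LTR retroelement
#'
#' The element begins and ends with identical LTRs whose termini are the
#' canonical TG...CA dinucleotides; the internal region encodes the Gag and
#' Pol ORFs with the planted domain blocks in template order.
#'
#' @param template An [element_template()].
#' @param rng_seed Integer seed (same seed, same sequence).
#' @param proteins Optional `list(gag =, pol =)` amino-acid sequences to
#'   encode (family founders); defaults to the base synthetic proteins.
#' @return `list(seq, truth, proteins, template)`: `seq` is the element
#'   nucleotide string; `truth` a feature table in element-relative 0-based
#'   half-open coordinates (seqid `"element"`); `proteins` the realised
#'   gag/pol translations.
#' @export
build_element <- function(template = element_template(), rng_seed = 1L,
                          proteins = NULL) {
  validate_template(template)
  tpl <- template
  lay <- pol_layout(tpl$domain_order, tpl$pol_aa)
  if (is.null(proteins)) {
    proteins <- list(
      gag = make_gag_protein(tpl$gag_aa, tpl$has_cchc, derive_seed(rng_seed, "g")),
      pol = make_pol_protein(tpl$domain_order, tpl$pol_aa)$protein)
  }
  stopifnot(nchar(proteins$gag) == tpl$gag_aa, nchar(proteins$pol) == tpl$pol_aa)

  ltr <- paste0("TG", random_dna(tpl$ltr_length - 4L, derive_seed(rng_seed, "ltr")),
                "CA")

  ## leader: thymine-rich, optionally hosting a PBS right after the 5' LTR
  leader_nt <- with_cm_seed(derive_seed(rng_seed, "leader"),
    paste(sample(c("A", "C", "G", "T"), tpl$leader_len, replace = TRUE,
                 prob = c(0.15, 0.1, 0.1, 0.65)), collapse = ""))
  pbs_rel <- NULL
  if (tpl$has_pbs == "trna") {
    trna <- trna_panel()[[1]]
    pbs <- revcomp(substr(trna, nchar(trna) - 14L, nchar(trna)))  # 15-mer
    leader_nt <- paste0(pbs, substr(leader_nt, 16L, tpl$leader_len))
    pbs_rel <- c(0L, 15L)
  } else if (tpl$has_pbs == "self") {
    pbs <- substr(ltr, tpl$ltr_length - 13L, tpl$ltr_length)  # LTR 3' 14-mer
    leader_nt <- paste0(pbs, substr(leader_nt, 15L, tpl$leader_len))
    pbs_rel <- c(0L, 14L)
  }

  gag_nt <- encode_protein(proteins$gag, derive_seed(rng_seed, "gagnt"))
  pol_nt <- encode_protein(proteins$pol, derive_seed(rng_seed, "polnt"))

  ## degenerate-primer cassette: overwrite in-frame segments inside RT
  cass_rel <- NULL
  if (tpl$primer_cassette) {
    rt <- lay[lay$name == "RT", ]
    fwd_off <- rt$aa_start * 3L + 60L        # codon-aligned inside RT
    rev_off <- fwd_off + nchar(.CASSETTE_FWD) + .CASSETTE_GAP
    stopifnot(rev_off + nchar(.CASSETTE_REV_RC) <= rt$aa_end * 3L)
    substr(pol_nt, fwd_off + 1L, fwd_off + nchar(.CASSETTE_FWD)) <- .CASSETTE_FWD
    substr(pol_nt, rev_off + 1L, rev_off + nchar(.CASSETTE_REV_RC)) <- .CASSETTE_REV_RC
    cass_rel <- c(fwd_off, rev_off + nchar(.CASSETTE_REV_RC))  # within pol ORF
  }

  ## tail: [pad 25][PPT 12 purines][8 nt] before the 3' LTR
  ppt_rel <- NULL
  tail_nt <- with_cm_seed(derive_seed(rng_seed, "tail"),
    paste(sample(c("A", "C", "G", "T"), tpl$tail_len, replace = TRUE,
                 prob = c(0.15, 0.35, 0.15, 0.35)), collapse = ""))
  if (tpl$has_ppt) {
    ppt <- with_cm_seed(derive_seed(rng_seed, "ppt"),
      paste(sample(c("A", "G"), 12L, replace = TRUE), collapse = ""))
    p0 <- tpl$tail_len - 20L - 12L
    substr(tail_nt, p0 + 1L, p0 + 12L) <- ppt
    ppt_rel <- c(p0, p0 + 12L)
  }

  stop_codon <- "TAA"
  ## close the frame upstream of each ORF so planted ORFs are maximal:
  ## the 3 nt preceding a start codon read as a stop in that ORF's frame
  substr(leader_nt, tpl$leader_len - 2L, tpl$leader_len) <- stop_codon
  if (tpl$orf_layout == "two") {
    spacer_nt <- random_dna(tpl$spacer_len, derive_seed(rng_seed, "sp"))
    substr(spacer_nt, tpl$spacer_len - 2L, tpl$spacer_len) <- stop_codon
    internal <- paste0(leader_nt, gag_nt, stop_codon, spacer_nt,
                       pol_nt, stop_codon, tail_nt)
    gag_s <- tpl$ltr_length + tpl$leader_len
    pol_s <- gag_s + tpl$gag_aa * 3L + 3L + tpl$spacer_len
    orf_rows <- features(seqid = "element",
                         start = c(gag_s, pol_s),
                         end = c(gag_s + tpl$gag_aa * 3L, pol_s + tpl$pol_aa * 3L),
                         strand = "+", type = "ORF",
                         attributes = c("ID=gag", "ID=pol"))
  } else {
    internal <- paste0(leader_nt, gag_nt, pol_nt, stop_codon, tail_nt)
    gag_s <- tpl$ltr_length + tpl$leader_len
    pol_s <- gag_s + tpl$gag_aa * 3L
    orf_rows <- features(seqid = "element",
                         start = gag_s,
                         end = gag_s + (tpl$gag_aa + tpl$pol_aa) * 3L,
                         strand = "+", type = "ORF", attributes = "ID=gag-pol")
  }
  seq <- paste0(ltr, internal, ltr)
  total <- nchar(seq)

  dom_rows <- features(seqid = "element",
                       start = pol_s + lay$aa_start * 3L,
                       end = pol_s + lay$aa_end * 3L,
                       strand = "+", type = "protein_domain",
                       attributes = paste0("Name=", lay$name))
  truth <- bind_features(
    features("element", c(0L, total - tpl$ltr_length),
             c(tpl$ltr_length, total), "+", "long_terminal_repeat",
             c("ID=ltr5", "ID=ltr3")),
    orf_rows, dom_rows)
  if (!is.null(cass_rel))
    truth <- bind_features(truth,
      features("element", pol_s + cass_rel[1], pol_s + cass_rel[2], "+",
               "PCR_product", "ID=primer_cassette"))
  if (!is.null(ppt_rel)) {
    tail_s <- total - tpl$ltr_length - tpl$tail_len
    truth <- bind_features(truth,
      features("element", tail_s + ppt_rel[1], tail_s + ppt_rel[2], "+",
               "RR_tract", "ID=ppt"))
  }
  if (!is.null(pbs_rel))
    truth <- bind_features(truth,
      features("element", tpl$ltr_length + pbs_rel[1],
               tpl$ltr_length + pbs_rel[2], "+", "primer_binding_site",
               paste0("ID=pbs;mechanism=", tpl$has_pbs)))

  ## realised translations (cassette overwrite shifts a few residues)
  pol_prot <- as.character(Biostrings::translate(Biostrings::DNAString(pol_nt), no.init.codon = TRUE))
  list(seq = seq, truth = truth,
       proteins = list(gag = proteins$gag, pol = pol_prot),
       template = tpl)
}

#' Describe a synthetic retroelement family
#'
#' @param name Family name.
#' @param template An [element_template()].
#' @param copy_number Number of copies to plant.
#' @param within_divergence Expected pairwise proportion of substituted
#'   nucleotide sites among copies (<= 0.10); each copy is mutated at half
#'   this rate from the family founder.
#' @param decay_fraction Fraction of copies rendered partial by truncation
#'   at one end.
#' @param clade Reference clade the founder derives from (see
#'   [ref_clade_names()]).
#' @param founder_divergence Amino-acid divergence of the family founder
#'   from its clade reference.
#' @return A list with class `cm_family_spec`.
#' @export
family_spec <- function(name, template = element_template(), copy_number = 6L,
                        within_divergence = 0.03, decay_fraction = 0,
                        clade = "Tcn1", founder_divergence = 0.15) {
  if (within_divergence > 0.10)
    stop("within_divergence must be <= 0.10 (family definition: >= 90% identity)")
  stopifnot(copy_number >= 1L, clade %in% ref_clade_names())
  structure(list(name = name, template = template,
                 copy_number = as.integer(copy_number),
                 within_divergence = within_divergence,
                 decay_fraction = decay_fraction, clade = clade,
                 founder_divergence = founder_divergence),
            class = "cm_family_spec")
}

## founder proteins: base -> clade divergence -> family divergence;
## motif/start residues are re-planted so structural truth holds
family_founder_proteins <- function(spec) {
  tpl <- spec$template
  clade_seed <- derive_seed(.CM_BASE_SEED, paste0("clade_", spec$clade))
  fam_seed <- derive_seed(.CM_BASE_SEED, paste0("fam_", spec$name))
  base_pol <- make_pol_protein(tpl$domain_order, tpl$pol_aa)$protein
  pol <- mutate_protein(base_pol, .CLADE_DIVERGENCE, clade_seed)
  pol <- mutate_protein(pol, spec$founder_divergence, fam_seed)
  pol <- paste0("M", substr(pol, 2L, nchar(pol)))
  gag <- make_gag_protein(tpl$gag_aa, tpl$has_cchc, derive_seed(fam_seed, "gag0"))
  gag <- mutate_protein(gag, spec$founder_divergence, derive_seed(fam_seed, "gagm"))
  aa <- strsplit(gag, "")[[1]]
  aa[1] <- "M"
  if (tpl$has_cchc) aa <- plant_cchc(aa, .GAG_CCHC_OFFSET)
  list(gag = paste(aa, collapse = ""), pol = pol)
}

shift_features <- function(df, by, seqid = NULL) {
  df$start <- df$start + as.integer(by)
  df$end <- df$end + as.integer(by)
  if (!is.null(seqid)) df$seqid <- seqid
  df
}

flip_features <- function(df, len) {
  new_start <- len - df$end
  df$end <- len - df$start
  df$start <- new_start
  df$strand <- ifelse(df$strand == "+", "-", ifelse(df$strand == "-", "+", "."))
  df
}

## truncate an element at one end, keeping features that survive intact
truncate_element <- function(seq, truth, side, keep_frac) {
  len <- nchar(seq)
  keep <- max(500L, as.integer(round(len * keep_frac)))
  if (side == "5") {
    cut <- len - keep
    seq <- substr(seq, cut + 1L, len)
    truth <- truth[truth$start >= cut, , drop = FALSE]
    truth <- shift_features(truth, -cut)
  } else {
    seq <- substr(seq, 1L, keep)
    truth <- truth[truth$end <= keep, , drop = FALSE]
  }
  list(seq = seq, truth = truth)
}

#' Plant retroelement families into a random background genome
#'
#' Each insertion is flanked by an identical target-site duplication taken
#' from the insertion site.  Per-copy substitutions are applied inside the
#' element only, so TSD flanks stay exactly equal.  Decayed copies are
#' truncated at a random end.
#'
#' @param background_length Background genome length (bp).
#' @param gc Background GC content.
#' @param family_specs List of [family_spec()] objects (may be empty).
#' @param rng_seed Integer seed.
#' @param min_separation Minimum distance between insertion sites (bp).
#' @return `list(genome, truth, founders)`: `genome` is a named
#'   [Biostrings::DNAStringSet] of one sequence (`chr1`); `truth` a feature
#'   table in genome coordinates; `founders` per-family founder sequences
#'   and proteins.
#' @export
plant_elements <- function(background_length, gc = 0.5, family_specs = list(),
                           rng_seed = 1L, min_separation = 3000L) {
  background_length <- as.integer(background_length)
  bg <- random_dna(background_length, derive_seed(rng_seed, "bg"), gc)

  copies <- list()
  founders <- list()
  for (spec in family_specs) {
    stopifnot(inherits(spec, "cm_family_spec"))
    prot <- family_founder_proteins(spec)
    founder <- build_element(spec$template,
                             derive_seed(rng_seed, paste0("b_", spec$name)),
                             proteins = prot)
    founders[[spec$name]] <- founder
    n <- spec$copy_number
    n_trunc <- as.integer(round(spec$decay_fraction * n))
    trunc_idx <- if (n_trunc > 0)
      with_cm_seed(derive_seed(rng_seed, paste0("t_", spec$name)),
                   sample.int(n, n_trunc)) else integer()
    for (i in seq_len(n)) {
      cseed <- derive_seed(rng_seed, paste0("c_", spec$name, "_", i))
      seq <- mutate_dna(founder$seq, spec$within_divergence / 2, cseed)
      truth <- founder$truth
      truncated <- i %in% trunc_idx
      if (truncated) {
        side <- with_cm_seed(derive_seed(cseed, "side"),
                             sample(c("5", "3"), 1L))
        keep <- with_cm_seed(derive_seed(cseed, "keep"), runif(1, 0.35, 0.65))
        tr <- truncate_element(seq, truth, side, keep)
        seq <- tr$seq
        truth <- tr$truth
      }
      strand <- with_cm_seed(derive_seed(cseed, "str"),
                             sample(c("+", "-"), 1L))
      if (strand == "-") {
        truth <- flip_features(truth, nchar(seq))
        seq <- revcomp(seq)
      }
      copies[[length(copies) + 1L]] <-
        list(id = paste0(spec$name, "_c", i), family = spec$name,
             clade = spec$clade, seq = seq, truth = truth,
             truncated = truncated, strand = strand,
             tsd_length = spec$template$tsd_length,
             within_divergence = spec$within_divergence)
    }
  }

  k <- length(copies)
  if (k == 0L) {
    genome <- Biostrings::DNAStringSet(setNames(bg, "chr1"))
    return(list(genome = genome, truth = features(), founders = founders))
  }

  total_elem <- sum(vapply(copies, function(co) nchar(co$seq), 0))
  if (background_length < total_elem + (k + 1L) * min_separation)
    stop("genome too small for requested copies")

  ## insertion sites: separated, away from ends, non-homopolymer TSD site
  positions <- with_cm_seed(derive_seed(rng_seed, "pos"), {
    ok <- FALSE
    for (try in 1:2000) {
      p <- sort(sample.int(background_length - 2L * min_separation, k) +
                  min_separation)
      if (k > 1L && any(diff(p) < min_separation)) next
      tsds <- substring(bg, p + 1L, p + vapply(copies, `[[`, 0L, "tsd_length"))
      if (any(vapply(strsplit(tsds, ""),
                     function(x) length(unique(x)) == 1L, TRUE))) next
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place copies with the requested separation")
    p
  })

  ## order copies randomly over positions
  ord <- with_cm_seed(derive_seed(rng_seed, "ord"), sample.int(k))
  pieces <- character(0)
  truth_all <- list()
  prev_cut <- 0L
  out_len <- 0L
  for (j in seq_len(k)) {
    co <- copies[[ord[j]]]
    p <- positions[j]
    t <- co$tsd_length
    tsd_seq <- substr(bg, p + 1L, p + t)
    left <- substr(bg, prev_cut + 1L, p + t)
    pieces <- c(pieces, left, co$seq)
    out_len <- out_len + nchar(left)
    elem_start <- out_len
    elem_len <- nchar(co$seq)
    out_len <- out_len + elem_len
    prev_cut <- p  # re-emits bg[p, p+t) as the right TSD copy

    ft <- shift_features(co$truth, elem_start, seqid = "chr1")
    attrs <- sprintf("ID=%s;family=%s;clade=%s;truncated=%s;strand=%s",
                     co$id, co$family, co$clade,
                     tolower(co$truncated), co$strand)
    ft$attributes <- paste0("Parent=", co$id,
                            ifelse(nzchar(ft$attributes), ";", ""),
                            ft$attributes)
    elem_row <- features("chr1", elem_start, elem_start + elem_len,
                         co$strand, "LTR_retrotransposon",
                         paste0(attrs, ";tsd=", tsd_seq))
    tsd_rows <- features("chr1",
                         c(elem_start - t, elem_start + elem_len),
                         c(elem_start, elem_start + elem_len + t),
                         ".", "target_site_duplication",
                         paste0("Parent=", co$id, ";seq=", tsd_seq))
    truth_all[[j]] <- bind_features(elem_row, tsd_rows, ft)
  }
  pieces <- c(pieces, substr(bg, prev_cut + 1L, background_length))
  genome_seq <- paste(pieces, collapse = "")
  genome <- Biostrings::DNAStringSet(setNames(genome_seq, "chr1"))
  truth <- do.call(bind_features, truth_all)
  validate_features(truth, setNames(nchar(genome_seq), "chr1"))
  list(genome = genome, truth = truth, founders = founders)
}

#' Evolve an amino-acid sequence pair under the Poisson model
#'
#' Site `i` of the second sequence differs from the first independently
#' with probability `1 - exp(-d)` where `d = 2 * rate_r * T` (T converted
#' to years); replacements are uniform over the 19 alternative residues.
#'
#' @param length_aa Sequence length (>= 50).
#' @param rate_r Substitution rate per site per year (e.g. `0.45e-9`).
#' @param time_T_myr Divergence time in Myr.
#' @param rng_seed Integer seed.
#' @return `list(seq1, seq2, true_d, p_expected)`.
#' @export
evolve_protein_pair <- function(length_aa, rate_r, time_T_myr, rng_seed = 1L) {
  stopifnot(length_aa >= 50L, rate_r >= 0, time_T_myr > 0)
  d <- 2 * rate_r * time_T_myr * 1e6
  p <- 1 - exp(-d)
  seq1 <- random_protein(length_aa, derive_seed(rng_seed, "s1"))
  seq2 <- mutate_protein(seq1, p, derive_seed(rng_seed, "s2"))
  list(seq1 = seq1, seq2 = seq2, true_d = d, p_expected = p)
}

#' Family specifications for the bundled demonstration scene
#'
#' Five chromovirus families (one per reference clade), six copies each,
#' 3% within-family nucleotide divergence, 20% of copies truncated —
#' a scaled-down, fully ground-truthed analogue of a repeat-bearing genome.
#'
#' @param copy_number Copies per family.
#' @param within_divergence Pairwise within-family divergence.
#' @param decay_fraction Fraction of truncated copies.
#' @return List of [family_spec()] objects.
#' @export
demo_family_specs <- function(copy_number = 6L, within_divergence = 0.03,
                              decay_fraction = 0.2) {
  clades <- ref_clade_names()[1:5]
  lapply(seq_along(clades), function(i) {
    family_spec(name = paste0("fam", i, "_", clades[i]),
                copy_number = copy_number,
                within_divergence = within_divergence,
                decay_fraction = decay_fraction,
                clade = clades[i])
  })
}
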