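## Bundled reference material.  The protein references here are SYNTHETIC:
## deterministic stand-ins with the domain architecture of chromoviral
## Gag/Pol polyproteins, generated from a fixed internal seed.  They anchor
## the simulator and the search profiles to the same coordinate system, so
## plant-and-recover experiments have exact ground truth.  Published
## divergence times and the degenerate-primer sequences are field data.

.CM_BASE_SEED <- 104729L

#' Run code with a fixed, isolated RNG state
#' @keywords internal
with_cm_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed %% .Machine$integer.max), code)
}

## derive a reproducible child seed from a parent seed and a string tag
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.double(seed) * 7919 + h) %% 2147483647)
}

random_protein <- function(n, seed) {
  with_cm_seed(seed, paste(sample(.AA20, n, replace = TRUE), collapse = ""))
}

#' Substitute amino-acid sites at a given per-site probability
#'
#' Each site is replaced independently with probability `p_sub`; the
#' replacement is drawn uniformly from the 19 alternative residues (the
#' Poisson model with uniform exchangeability, no rate heterogeneity).
#'
#' @param protein Character scalar (amino acids).
#' @param p_sub Per-site substitution probability.
#' @param seed Integer seed.
#' @return Character scalar.
#' @export
mutate_protein <- function(protein, p_sub, seed) {
  aa <- strsplit(protein, "")[[1]]
  with_cm_seed(seed, {
    hit <- which(runif(length(aa)) < p_sub)
    for (i in hit) {
      alt <- setdiff(.AA20, aa[i])
      aa[i] <- alt[sample.int(length(alt), 1L)]
    }
  })
  paste(aa, collapse = "")
}

## Domain lengths (aa) used by every synthetic polyprotein.
.DOMAIN_LEN <- c(PR = 100L, RT = 180L, RH = 80L, INT = 160L, CHD = 55L,
                 dUTPase = 130L)
.POL_NTERM <- 30L
.POL_LINKER <- 10L

#' Synthetic reference domain proteins
#'
#' Deterministic amino-acid sequences standing in for the conserved cores of
#' the chromoviral Pol domains (PR, RT, RH, INT, CHD) and the accessory
#' dUTPase.  Synthetic: generated once from a fixed internal seed.
#'
#' @return Named list of character scalars.
#' @export
ref_domain_proteins <- function() {
  out <- lapply(names(.DOMAIN_LEN), function(d) {
    random_protein(.DOMAIN_LEN[[d]], derive_seed(.CM_BASE_SEED, paste0("dom_", d)))
  })
  names(out) <- names(.DOMAIN_LEN)
  out
}

#' Layout of a synthetic Pol polyprotein
#'
#' @param domain_order Character vector of domain names in N-to-C order.
#' @param pol_aa Total polyprotein length (aa); the tail is padded.
#' @return data.frame with columns name, aa_start, aa_end (0-based half-open).
#' @export
pol_layout <- function(domain_order = c("PR", "RT", "RH", "INT", "CHD"),
                       pol_aa = 1238L) {
  stopifnot(all(domain_order %in% names(.DOMAIN_LEN)))
  pos <- .POL_NTERM
  rows <- lapply(domain_order, function(d) {
    r <- data.frame(name = d, aa_start = pos, aa_end = pos + .DOMAIN_LEN[[d]])
    pos <<- pos + .DOMAIN_LEN[[d]] + .POL_LINKER
    r
  })
  out <- do.call(rbind, rows)
  if (max(out$aa_end) > pol_aa)
    stop("pol_aa too short for the requested domain order")
  out
}

#' Build a synthetic Pol polyprotein with the given domain order
#' @param domain_order Domain names N-to-C.
#' @param pol_aa Total length.
#' @param seed Seed for linkers/padding.
#' @return list(protein =, layout =)
#' @export
make_pol_protein <- function(domain_order = c("PR", "RT", "RH", "INT", "CHD"),
                             pol_aa = 1238L, seed = .CM_BASE_SEED) {
  doms <- ref_domain_proteins()
  lay <- pol_layout(domain_order, pol_aa)
  filler <- strsplit(random_protein(pol_aa, derive_seed(seed, "pol_fill")),
                     "")[[1]]
  aa <- filler
  for (i in seq_len(nrow(lay))) {
    idx <- (lay$aa_start[i] + 1L):lay$aa_end[i]
    aa[idx] <- strsplit(doms[[lay$name[i]]], "")[[1]]
  }
  aa[1] <- "M"
  list(protein = paste(aa, collapse = ""), layout = lay)
}

#' Build a synthetic Gag protein (optionally with the CCHC zinc knuckle)
#' @param gag_aa Length in aa.
#' @param has_cchc Plant a C-X2-C-X4-H-X4-C motif.
#' @param seed Seed.
#' @return Character scalar.
#' @export
make_gag_protein <- function(gag_aa = 323L, has_cchc = TRUE,
                             seed = .CM_BASE_SEED) {
  aa <- strsplit(random_protein(gag_aa, derive_seed(seed, "gag")), "")[[1]]
  aa[1] <- "M"
  ## avoid an accidental motif when has_cchc is FALSE: strip cysteines
  if (!has_cchc) aa[aa == "C"] <- "S"
  if (has_cchc) aa <- plant_cchc(aa, offset = .GAG_CCHC_OFFSET)
  paste(aa, collapse = "")
}

.GAG_CCHC_OFFSET <- 200L  # 0-based position of the motif in synthetic Gag

plant_cchc <- function(aa, offset) {
  motif_pos <- offset + c(0L, 3L, 8L, 13L)  # C, C, H, C (0-based)
  aa[offset + seq_len(14L)][aa[offset + seq_len(14L)] == "C"] <- "S"
  aa[motif_pos + 1L] <- c("C", "C", "H", "C")
  ## clear stray C/H inside the spacer positions so the motif is unambiguous
  spacers <- setdiff(offset + 0:13, motif_pos)
  aa[spacers + 1L][aa[spacers + 1L] %in% c("C", "H")] <- "A"
  aa
}

#' Names of the synthetic reference clades
#' @export
ref_clade_names <- function() c("Tcn1", "Tcn2", "Pyggy", "Pyret", "Maggy", "Galahad")

## amino-acid divergence of each clade from the base polyprotein
.CLADE_DIVERGENCE <- 0.45

#' Clade-diverged synthetic Pol polyproteins
#' @return Named list of character scalars (one per clade).
#' @export
ref_clade_pols <- function() {
  base <- make_pol_protein()$protein
  out <- lapply(ref_clade_names(), function(cl) {
    mutate_protein(base, .CLADE_DIVERGENCE,
                   derive_seed(.CM_BASE_SEED, paste0("clade_", cl)))
  })
  names(out) <- ref_clade_names()
  out
}

#' Interval of the RT--RH--partial-Int seed region within the Pol layout
#' @return list(aa_start, aa_end), 0-based half-open; the region spans RT
#'   through the first 60 aa of the integrase.
#' @export
seed_region_bounds <- function() {
  lay <- pol_layout()
  rt <- lay[lay$name == "RT", ]
  int <- lay[lay$name == "INT", ]
  list(aa_start = rt$aa_start, aa_end = int$aa_start + 60L)
}

extract_seed_region <- function(pol_protein) {
  b <- seed_region_bounds()
  substr(pol_protein, b$aa_start + 1L, b$aa_end)
}

#' Reference panel of clade-labelled RT--Int amino-acid sequences
#'
#' Synthetic stand-ins for the clade exemplars used to verify and label
#' profile hits.
#'
#' @return A named [Biostrings::AAStringSet] (names are clade names).
#' @export
ref_clade_panel <- function() {
  pols <- ref_clade_pols()
  out <- Biostrings::AAStringSet(vapply(pols, extract_seed_region, ""))
  names(out) <- names(pols)
  out
}

#' Seed alignment for the RT--partial-Int search profile
#'
#' Gap-free alignment of the base seed region plus its six clade-diverged
#' variants (substitution-only divergence keeps the columns in register).
#'
#' @return A named [Biostrings::AAStringSet], all of equal width.
#' @export
seed_alignment <- function() {
  base <- extract_seed_region(make_pol_protein()$protein)
  panel <- as.character(ref_clade_panel())
  out <- Biostrings::AAStringSet(c(consensus_base = base, panel))
  out
}

#' Degenerate PCR primers targeting the conserved RT core
#'
#' `forward` is the GyRT1 primer; `reverse` is the ty3-A primer whose 5'
#' 14-nt tail is a cloning adapter — only the 3' 17-nt degenerate core
#' anneals genomically, so matching uses the core.
#'
#' @return list(forward, reverse_full, reverse_core, product_min, product_max)
#' @export
rt_primer_pair <- function() {
  list(forward = "MRNATGTGYGTNGAYTAYMG",
       reverse_full = "AATTCGCTGCCGCTAAGATNARNADRTCRTC",
       reverse_core = "AAGATNARNADRTCRTC",
       product_min = 250L, product_max = 400L)
}

## Concrete in-frame expansions planted by the simulator.  The first matches
## the forward primer; the second is the reverse complement of an expansion
## of the reverse-primer core (so the core anneals on the minus strand).
.CASSETTE_FWD <- "AGAATGTGCGTAGATTACAG"
.CASSETTE_REV_RC <- "GATGACCTGCTGATCTT"
.CASSETTE_GAP <- 283L   # nt between forward site end and reverse site start

#' Divergence-time calibration table
#'
#' Published divergence times (Myr) between the host taxon groups used for
#' substitution-rate calibration.
#'
#' @return data.frame with columns group1, group2, T_myr.
#' @export
divergence_times <- function() {
  path <- system.file("extdata", "divergence_times.tsv",
                      package = "chromomine", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Look up a divergence time (symmetric)
#' @param table Table from [divergence_times()].
#' @param group1,group2 Taxon-group names.
#' @return Time in Myr.
#' @export
lookup_divergence_time <- function(table, group1, group2) {
  hit <- (table$group1 == group1 & table$group2 == group2) |
         (table$group1 == group2 & table$group2 == group1)
  if (!any(hit))
    stop("no divergence time for taxon pair: ", group1, "/", group2)
  table$T_myr[which(hit)[1]]
}

#' Published pairwise-divergence table for rate calibration
#'
#' Pairwise amino-acid identities, host taxon groups and published
#' substitution rates for retroelement RT--Int fragments (Tcn1, Pyggy and
#' Pyret clades) and two host genes (Pho88, uapA).  `T_myr` is the
#' calibration time applicable to each pair (NA where none of the published
#' calibrations applies, e.g. the moss/lycophyte split).
#'
#' @return data.frame.
#' @export
published_divergence_table <- function() {
  path <- system.file("extdata", "published_divergence_table.tsv",
                      package = "chromomine", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "ND"))
}

#' The BLOSUM62 substitution matrix (from Biostrings)
#' @return Integer matrix.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

#' Panel of tRNA 3'-terminal sequences for PBS detection
#'
#' Synthetic stand-ins: short 3'-terminal fragments (ending in the canonical
#' CCA) for a few primer tRNAs.
#'
#' @return Named character vector (3'-terminal 18-mers, 5'->3').
#' @export
trna_panel <- function() {
  path <- system.file("extdata", "trna_panel.fasta",
                      package = "chromomine", mustWork = TRUE)
  x <- read_fasta(path, "nucleotide")
  setNames(as.character(x), names(x))
}
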