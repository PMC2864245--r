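---
title: "Methods: mining chromoviruses and weighing horizontal transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining chromoviruses and weighing horizontal transfer}
  %\VignetteEncoding{UTF-8}
---

# Scope

`chromomine` implements a complete in-silico pipeline for
chromodomain-containing Gypsy (Metaviridae) LTR retrotransposons:
discovery of reverse-transcriptase/integrase (RT--Int) coding regions in
genomic sequence, structural annotation of the surrounding element,
family classification, neighbor-joining phylogenetics with bootstrap,
and a three-criterion assessment of candidate horizontal-transfer (HT)
events based on Poisson-corrected amino-acid distances and calibrated
substitution rates.  Because the survey of real fungal and plant
assemblies is out of scope here, every discovery-side stage is exercised
against a synthetic-genome simulator that plants structurally realistic
elements with exact ground truth.

# The discovery model

## Profile search over six-frame translations

Genomic sequence is translated in all six reading frames under the
standard genetic code (`no.init.codon`; stop codons are kept as `*`,
ambiguous codons become `X` unless every IUPAC expansion agrees).  Each
frame is scanned with a position-specific scoring model built from a
gap-free seed alignment of RT--partial-Int amino-acid sequences.

The model is a PSSM with affine gap penalties rather than a full
profile HMM: per-column emission probabilities are
`(count + pseudocount) / (total + 20 * pseudocount)` (pseudocount 0.5),
log-odds scored in bits against the uniform 1/20 background, and the
scan is a glocal Viterbi-style dynamic programme — global in the
profile, local in the sequence — with gap open 12 and extend 2 bits.
`X` and `*` are neutral (0 bits), which lets hits extend across the
premature stops that accumulate in aged element copies.  The default
reporting threshold is 25 bits.  The separation is extreme by
construction: a true hit at 50% amino-acid identity scores several
hundred bits while the best glocal score of a scrambled frame is
strongly negative, and the suite verifies zero hits over 100 scrambled
2,000-residue frames.  The threshold is therefore a guard band, not a
tuned quantity.

Hits are verified by local alignment (BLOSUM62, gap open 11 / extend 1,
the standard protein-BLAST parameterisation) against a clade-labelled
reference panel; a hit is kept iff its best identity reaches 0.25 over
at least 100 aligned residues, a conservative homology floor.  The
reported translation is trimmed to the panel-supported region, so a
truncated copy whose hit runs past the break into background sequence
does not drag non-homologous residues into downstream identity
computations.  Same-strand hits within 1,000 nt merge into loci
(frameshift-fragmented copies re-join; 1 kb stays far below the
between-element spacing).

## Structural annotation

Each verified locus is expanded by up to 15 kb per side and annotated
in element-forward orientation:

* **LTR pair** — exact 12-mer seeds shared between the regions upstream
  and downstream of the RT--Int anchor, chained by diagonal, extended
  un-gapped with an x-drop, then snapped to the canonical `TG...CA`
  termini when both copies show them within 8 nt.  Candidates need
  length >= 100 nt at >= 0.80 identity within a 15 kb span and are
  ranked by length x identity with a bonus for canonical ends.  The
  extension is un-gapped because the bundled generator is
  substitution-only by default; with real (indel-bearing) LTRs the
  boundaries would degrade gracefully but no banded gapped refinement
  is attempted — a known limitation.
* **TSD** — the longest k in [4, 6] with identical flanks immediately
  outside the element; ties go to the longest.
* **ORFs** — maximal start-to-stop ORFs on both strands (the reported
  interval excludes the stop codon); complete ORFs only.
* **Domains** — per-domain PSSMs (PR, RT, RH, INT, CHD, dUTPase) are
  scanned over the three forward-frame translations of the internal
  region, with overlaps resolved best-score-first.  Scanning frames
  rather than assembled ORF products keeps the architecture callable
  for copies whose ORFs are broken by nonsense substitutions; an
  element is a chromovirus iff a CHD call lies downstream of the
  integrase.
* **CCHC / PPT / PBS / promoter boxes** — the Gag zinc knuckle is the
  literal pattern `C-X2-C-X4-H-X4-C` (all, including overlapping,
  matches); the polypurine tract is the longest window >= 10 nt at
  >= 90% purines ending within 20 nt of the 3' LTR; the primer-binding
  site is a >= 12 nt match within 30 nt of the 5' LTR to the reverse
  complement of a panel tRNA 3' terminus (tRNA priming) or to the LTR
  terminus (self-priming); TATA/CAAT boxes are the literal motifs
  `TATAWA` and `CAAT` inside the LTR.  The PBS and PPT thresholds are
  fixed, exposed defaults: the underlying biology defines the concepts
  but not the cutoffs.

## Families, copy number, genome fraction

Elements cluster into families by single-linkage on pairwise global
amino-acid identity of their RT--Int translations at a 0.90 threshold
(family members share 90--100% identity; single linkage realises the
transitive "same family" usage for near-identical copies).  Identity
excludes columns where either sequence gaps; counting end gaps as
mismatches is available as `gap_mode = "mismatch"` because published
pairwise-identity tables in this area are not exactly reproducible
under either convention and the original convention is not stated.
Copy number is a seed-and-extend nucleotide search of the family
representative (exact 16-mers every 8 positions, diagonal-grouped,
identity-verified at >= 0.80 over >= 100 nt, overlap-collapsed longest
first); genome fraction is the union length of hits over genome length.

# Phylogeny

Multiple alignment is progressive: pairwise global-alignment distances
feed a neighbor-joining guide tree, and profiles merge postorder by
global profile-profile alignment with affine gaps.  Neighbor joining
follows the Saitou--Nei Q criterion with two deterministic choices the
original algorithm leaves open: ties break by the lexicographically
smallest taxon pair, and negative branch lengths are clamped to zero
with the deficit moved to the sister branch so path lengths are
preserved.  Exactness on additive matrices is property-tested (100
random trees, up to 12 taxa) and cross-checked against an independent
NJ implementation.  Bootstrap resamples alignment columns with
replacement; support for each internal bipartition of the point tree is
its percentage among replicate trees, computed by explicit bipartition
keys.  With degenerate (all-identical) input every replicate returns
the same lexicographic topology, so supports read 100.  Clade
assignment gives a query the label of the smallest ancestral clade
whose reference leaves are label-uniform at >= 50% support — the usual
"nodes with bootstrap values over 50%" convention.

# Rates and the horizontal-transfer criteria

Amino-acid distances use the Poisson correction `d = -ln(1 - p)` for a
proportion `p` of differing residues, and rates the calibration
`r = d / (2T)` with `T` the divergence time of the hosts' last common
ancestor (reported in units of 1e-9 substitutions/site/year).  The
bundled calibration table carries the published times (Plants/Fungi
1,500 Myr; Basidiomycetes/Ascomycetes 1,200; Homobasidiomycetes/
Chytridiomycetes 900; Sordariomycetes/Eurotiomycetes 540;
Sordariomycetes/Dothideomycetes 490; Tremellomycetes/Agaricomycetes
700).  The bundled pairwise-divergence table records, per comparison,
the applicable calibration time; comparisons with no published
calibration (for example the moss/lycophyte split, or
Dothideomycetes/Eurotiomycetes) are deliberately `NA` — "not
computable" rather than a guessed time — and several published rows are
known not to be reproducible from their printed identities under any
listed calibration; they are excluded from every check.

The three HT criteria are implemented as:

1. **Phylogenetic incongruence** — some element-tree bipartition with
   bootstrap support >= 50, after mapping element leaves to hosts, is
   incompatible with the host tree (four-intersection test; such a
   split conflicts with every resolution of the host tree).
   Bipartitions whose two sides share a host are skipped as paralogy.
2. **Rate slowdown** — the largest element rate is strictly below the
   smallest host-gene rate over a matched taxon-pair set.
3. **Patchy distribution** — under single-origin vertical descent
   (presence at the host-tree root, no regain) at least one loss is
   required; the minimal loss count is the number of maximal all-absent
   clades.

The combined verdict is `HT-supported` iff slowdown holds together with
at least one of the other two.  The literature describes slowdown as
the strongest of the three lines of evidence but never states a
boolean combination; this conjunction operationalises that emphasis and
is exposed for inspection in the report object rather than hidden.

# The synthetic-genome generator

The generator is first-class, tested code and defines the study
conditions for every discovery-side check.  An element template
defaults to the anatomy of the best-described full-length chromovirus
reference: 5,704 bp total, 440-bp identical LTRs with `TG...CA`
termini, a 5-bp TSD, a thymine-rich leader, a 969-bp gag ORF (323 aa,
CCHC knuckle), a 3,714-bp pol ORF (1,238 aa; PR-RT-RH-Int-CHD, with
dUTPase placements available for the known variant layouts), a
12-purine PPT ending 8 nt before the 3' LTR, optional tRNA- or
self-primed PBS, and degenerate-primer-compatible sites inside RT
spaced so the amplicon is 320 bp.  Elements must fall in the observed
4.4--13.5 kb range.

Proteins are synthetic: deterministic sequences with the right domain
geometry, generated once from a fixed internal seed.  Clade references
derive from the base polyprotein at 45% amino-acid divergence (giving
the ~30--50% between-clade identities typical of chromoviral clades),
and family founders from a clade reference at a further 15%.  Codon
choice is uniform over synonymous codons; the leader and spacer end in
an in-frame stop so planted ORFs are maximal exactly as specified.

Background sequence is i.i.d. at configurable GC (default 0.5): the
simplest null, and repeat-free so false LTR hits cannot arise from the
background by construction.  Per-copy divergence applies substitutions
only (each copy mutated at half the requested pairwise
`within_divergence`, inside the element only, so TSD flanks stay
exactly equal and truth coordinates stay exact); an indel mode is
deliberately absent so boundary-recovery tests have unambiguous truth.
Decayed copies are 5'- or 3'-truncated (no internal deletions), keeping
35--65% of the element.  Insertion sites are >= 3 kb apart, away from
the sequence ends, and rejected if the would-be TSD is a homopolymer
(for which "the" duplicated string is ill-defined).  LTR--LTR aging
within a copy is configurable separately and defaults to zero, since
insertion dating by LTR divergence is out of scope.

Protein pairs for rate studies evolve under the same Poisson model the
correction assumes: each site differs independently with probability
`1 - exp(-d)`, `d = 2 r T`, replacements uniform over the 19
alternatives, no rate heterogeneity.  That alignment of generator and
estimator is intentional — it makes rate recovery a calibration test of
the estimator, not a robustness study.

What passing these tests does **not** show: tolerance to indels,
nested insertions, solo LTRs, recombination between copies,
codon-usage structure, or compositionally biased backgrounds.  Real
genomes have all of these; results on them should be read as
upper-bound behaviour of the pipeline's logic, not a benchmark of
field performance.

# Demonstration scene and problem sizes

The bundled scene plants 5 families (one per reference clade) x 6
copies in 2 Mb of background at 3% within-family pairwise divergence
with 20% of copies truncated — 30 elements, about 7% of the genome,
chosen as a faithful scaled-down analogue of a repeat-bearing fungal
assembly in which family structure, truncation and both strands are all
represented.  3% divergence sits in the upper half of the 90--100%
family-identity definition while leaving headroom for the amino-acid
level (3% nucleotide pairwise divergence is roughly 7% amino-acid
divergence, safely above the 0.90 clustering threshold).  Rate-recovery
experiments use 200 replicate pairs of 680 residues at
r = 0.45e-9/site/year and T = 700 Myr, matching the length scale and
rate regime of the published RT--Int comparisons.  NJ exactness uses
100 random additive matrices of up to 12 taxa.  The full suite and the
acceptance script each run in a few minutes on one CPU.

# Numerical choices and degenerate inputs

* Poisson correction errors for p >= 1 - 1e-9 (the correction diverges).
* The NJ Q-matrix tie tolerance is 1e-9 relative; branch lengths are
  written with 10 significant digits internally and 6 in Newick output.
* Glocal scan candidates are reduced greedily, best score first, to
  non-overlapping segments; the same rule resolves overlapping domain
  calls and overlapping copy-number loci (longest matched span first,
  which also suppresses LTR cross-matches between a representative's
  two identical LTRs).
* The in-silico PCR reports, per forward-primer site, the nearest
  compatible reverse site within the product window, as a real reaction
  dominated by the shortest amplicon would; the reverse primer's
  5' cloning adapter never anneals genomically, so only its 3'
  17-nt degenerate core is matched.
* Empty inputs (no hits, no families, empty feature tables) propagate
  as empty tables, not errors; hard errors are reserved for contract
  violations (ragged alignments, missing calibration times, undefined
  IUPAC codes, p at the correction's pole).

# Known limitations

Un-gapped LTR extension (above); no E-value statistics for the profile
scan (a bit threshold with an empirical null instead); no solo-LTR
discovery; no reconstruction of insertion ages; the progressive MSA is
a straightforward guide-tree/profile implementation without iterative
refinement and should not be expected to rival dedicated aligners on
hard alignment problems; and the HT verdict is a transparent boolean
rule over three tests, not a probabilistic model of transfer.
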