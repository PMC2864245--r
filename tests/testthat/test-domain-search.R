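test_that("six-frame translation follows the standard code with * stops", {
  fr <- six_frame_translate("ATGAAATAG")
  expect_equal(fr[[1]]$aa, "MK*")
  expect_error(six_frame_translate("MKLLPQ*"), "nucleotide")
})

test_that("reverse complementing the input swaps plus and minus frames", {
  s <- random_dna_str(90, 6)
  fr <- six_frame_translate(s)
  fr_rc <- six_frame_translate(revcomp(s))
  for (i in 1:3)
    expect_identical(fr_rc[[i]]$aa, fr[[i + 3]]$aa)
})

test_that("ambiguity codons translate to X unless all expansions agree", {
  expect_equal(six_frame_translate("ATGNGG")[[1]]$aa, "MX")
  # GGN is glycine under every expansion
  expect_equal(six_frame_translate("ATGGGN")[[1]]$aa, "MG")
})

test_that("the frame map converts aa intervals to strand-aware nt intervals", {
  s <- random_dna_str(100, 9)
  fr <- six_frame_translate(s)
  for (f in fr) {
    nt <- frame_to_nt(f, 2L, 7L)
    expect_equal(nt$end - nt$start, 15L)   # 3 nt per residue
    sub <- substr(s, nt$start + 1L, nt$end)
    if (nt$strand == "-") sub <- revcomp(sub)
    expect_equal(as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                                    no.init.codon = TRUE)),
                 substr(f$aa, 3L, 7L))
  }
})

test_that("profile emissions follow the stated pseudocount formula", {
  twin <- Biostrings::AAStringSet(c(a = "AC", b = "AC"))
  p0 <- build_profile(twin, pseudocount = 0)
  expect_equal(unname(profile_emissions(p0, 1)["A"]), 1.0)
  expect_equal(unname(profile_emissions(p0, 2)["C"]), 1.0)

  four <- Biostrings::AAStringSet(c(s1 = "A", s2 = "A", s3 = "A", s4 = "C"))
  p1 <- build_profile(four, pseudocount = 0)
  expect_equal(unname(profile_emissions(p1, 1)[c("A", "C")]), c(0.75, 0.25))

  two <- Biostrings::AAStringSet(c(s1 = "A", s2 = "A"))
  p2 <- build_profile(two, pseudocount = 1)
  expect_equal(unname(profile_emissions(p2, 1)["A"]), 3 / 22)
  expect_equal(unname(profile_emissions(p2, 1)["C"]), 1 / 22)

  expect_error(build_profile(c(a = "ACD", b = "AC")), "ragged")
})

test_that("match columns are those with under 50% gaps", {
  aln <- Biostrings::AAStringSet(c(a = "A-CD", b = "A-C-", c = "AAC-",
                                   d = "A-CD"))
  p <- build_profile(aln)
  # column 2 has 75% gaps, column 4 exactly 50%: both excluded
  expect_equal(p$match_columns, c(1L, 3L))
})

test_that("the profile consensus attains the maximum scan score", {
  prof <- build_profile(seed_alignment())
  hit <- scan_profile(prof$consensus, prof)
  expect_equal(nrow(hit), 1L)
  max_score <- sum(apply(prof$emissions[, 1:20], 1, max))
  expect_equal(hit$score, max_score, tolerance = 1e-9)
  rnd <- scan_profile(random_aa_str(nchar(prof$consensus), 4), prof,
                      threshold = -1e6)
  expect_lte(rnd$score[1], max_score)
})

test_that("a frame containing the seed consensus is recovered with high coverage", {
  prof <- build_profile(seed_alignment())
  frame_aa <- paste0(random_aa_str(200, 11), prof$consensus,
                     random_aa_str(150, 12))
  hits <- scan_profile(frame_aa, prof)
  expect_equal(nrow(hits), 1L)
  expect_gte(hits$coverage, 0.95)
  expect_lte(hits$aa_start, 200)
  expect_gte(hits$aa_end, 200 + prof$ncolumns)
})

test_that("scrambled sequences yield zero hits at the default threshold", {
  prof <- build_profile(seed_alignment())
  n_hits <- vapply(1:100, function(b)
    nrow(scan_profile(random_aa_str(2000, 1e4 + b), prof)), 0L)
  expect_identical(sum(n_hits), 0L)
})

test_that("an empty frame yields an empty hit table", {
  prof <- build_profile(seed_alignment())
  expect_equal(nrow(scan_profile("", prof)), 0L)
})

test_that("verification keeps homologous hits and labels them", {
  panel <- ref_clade_panel()
  hits <- data.frame(source_id = "x", frame = 1L, aa_start = 0L,
                     aa_end = 340L, nt_start = 0L, nt_end = 1020L,
                     strand = "+", score = 100, coverage = 1,
                     translation = as.character(panel[["Tcn1"]]),
                     stringsAsFactors = FALSE)
  v <- verify_hits(hits, panel)
  expect_equal(nrow(v), 1L)
  expect_equal(v$label, "Tcn1")
  expect_equal(v$label_identity, 1.0)

  hits$translation <- random_aa_str(340, 77)
  expect_equal(nrow(verify_hits(hits, panel)), 0L)
  expect_error(verify_hits(hits, Biostrings::AAStringSet()), "empty")
})

test_that("a diverged hit above the identity floor keeps its best label", {
  panel <- ref_clade_panel()
  q <- mutate_protein(as.character(panel[["Pyggy"]]), 0.5, 123)
  hits <- data.frame(source_id = "x", frame = 1L, aa_start = 0L,
                     aa_end = 340L, nt_start = 0L, nt_end = 1020L,
                     strand = "+", score = 100, coverage = 1,
                     translation = q, stringsAsFactors = FALSE)
  v <- verify_hits(hits, panel, min_identity = 0.25)
  expect_equal(nrow(v), 1L)
  expect_equal(v$label, "Pyggy")
  expect_gte(v$label_identity, 0.25)
})

test_that("hit merging joins nearby same-strand hits and never crosses strands", {
  h <- data.frame(source_id = "chr1", frame = c(1L, 2L),
                  nt_start = c(1000L, 2050L), nt_end = c(2000L, 2950L),
                  strand = "+", score = c(50, 60),
                  label = "Tcn1", translation = "M",
                  stringsAsFactors = FALSE)
  m <- merge_hits(h, max_gap_nt = 500L)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$nt_start, m$nt_end), c(1000L, 2950L))
  expect_equal(m$score, 60)

  h$strand <- c("+", "-")
  expect_equal(nrow(merge_hits(h, max_gap_nt = 500L)), 2L)

  h3 <- data.frame(source_id = "chr1", frame = 1L,
                   nt_start = c(0L, 400L, 800L), nt_end = c(300L, 700L, 1100L),
                   strand = "+", score = 1:3, label = "x", translation = "M",
                   stringsAsFactors = FALSE)
  m3 <- merge_hits(h3, max_gap_nt = 200L)
  expect_equal(nrow(m3), 1L)
  expect_equal(c(m3$nt_start, m3$nt_end), c(0L, 1100L))
})

test_that("mining is strand-symmetric in mirrored coordinates", {
  spec <- demo_family_specs(copy_number = 2, decay_fraction = 0)[1]
  sc <- plant_elements(1e5, 0.5, spec, rng_seed = 19L)
  loci_fwd <- mine_genome(sc$genome)
  n <- length(sc$genome[[1]])
  rc <- Biostrings::DNAStringSet(setNames(
    as.character(Biostrings::reverseComplement(sc$genome[[1]])), "chr1"))
  loci_rc <- mine_genome(rc)
  expect_equal(nrow(loci_fwd), nrow(loci_rc))
  mirrored <- data.frame(nt_start = n - rev(loci_rc$nt_end),
                         nt_end = n - rev(loci_rc$nt_start))
  expect_equal(loci_fwd$nt_start, mirrored$nt_start)
  expect_equal(loci_fwd$nt_end, mirrored$nt_end)
})
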