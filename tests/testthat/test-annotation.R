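test_that("locus expansion clips to sequence bounds", {
  expect_equal(expand_locus(20000L, 21000L, 100000L),
               list(start = 5000L, end = 36000L))
  expect_equal(expand_locus(500L, 1500L, 100000L)$start, 0L)
  expect_equal(expand_locus(20000L, 21000L, 100000L, flank = 0L),
               list(start = 20000L, end = 21000L))
})

test_that("an undiverged planted element yields an exact canonical LTR pair", {
  el <- build_element(rng_seed = 41L)
  pl <- plant_one_element(el$seq, left = 2000, right = 2000, seed = 5)
  anchor <- c(pl$start + 2000L, pl$start + 3000L)  # inside the internal region
  lp <- find_ltr_pair(pl$genome, anchor)
  expect_false(is.null(lp))
  expect_equal(lp$five_prime, c(pl$start, pl$start + 440L))
  expect_equal(lp$three_prime, c(pl$end - 440L, pl$end))
  expect_equal(lp$identity, 1.0)
  expect_true(lp$ends_canonical)
})

test_that("windows without an acceptable repeat give no LTR pair", {
  g <- random_dna_str(8000, 33)
  expect_null(find_ltr_pair(g, c(3500L, 4500L)))
})

test_that("diverged LTR pairs are recovered with accurate identity", {
  el <- build_element(rng_seed = 43L)
  seq <- el$seq
  # mutate the 3' LTR only, at ~5%
  ltr3 <- substr(seq, nchar(seq) - 439L, nchar(seq))
  ltr3_mut <- mutate_dna(ltr3, 0.05, 99L)
  substr(seq, nchar(seq) - 439L, nchar(seq)) <- ltr3_mut
  true_id <- mean(strsplit(ltr3, "")[[1]] == strsplit(ltr3_mut, "")[[1]])
  pl <- plant_one_element(seq, left = 1500, right = 1500, seed = 6)
  lp <- find_ltr_pair(pl$genome, c(pl$start + 2000L, pl$start + 3000L))
  expect_false(is.null(lp))
  expect_lt(abs(lp$identity - true_id), 0.02)
})

test_that("the TSD is the longest equal flank pair, ties to the longest", {
  el <- paste0("TG", random_dna_str(100, 1), "CA")
  g <- plant_one_element(el, tsd = "AACAC", left = 300, right = 300, seed = 2)
  expect_equal(find_tsd(g$genome, c(g$start, g$end)), "AACAC")

  # no equality at any width
  g2 <- paste0(strrep("C", 50), el, strrep("G", 50))
  expect_null(find_tsd(g2, c(50L, 50L + nchar(el))))

  # equality at k = 5 wins over k = 4
  g3 <- paste0(strrep("C", 45), "GATCA", el, "GATCA", strrep("G", 45))
  expect_equal(find_tsd(g3, c(50L, 50L + nchar(el))), "GATCA")
})

test_that("ORF finding reports complete start-to-stop frames only", {
  el <- build_element(rng_seed = 7L)
  orfs <- find_orfs(el$seq, 200)
  gag <- orfs[orfs$aa_len == 323L & orfs$strand == "+", ]
  expect_equal(nrow(gag), 1L)
  expect_equal(gag$end - gag$start, 969L)

  expect_equal(nrow(find_orfs(strrep("TAA", 300), 5)), 0L)

  no_stop <- paste0("ATG", strrep("GCT", 300))  # runs off the end
  orf_ns <- find_orfs(no_stop, 100)
  expect_equal(nrow(orf_ns[orf_ns$strand == "+", ]), 0L)
})

test_that("domain architecture is recovered in template order", {
  pol <- make_pol_protein()$protein
  dd <- detect_domains(pol)
  expect_equal(dd$name, c("PR", "RT", "RH", "INT", "CHD"))

  pol5 <- make_pol_protein(c("PR", "dUTPase", "RT", "RH", "INT", "CHD"),
                           pol_aa = 1380L)$protein
  dd5 <- detect_domains(pol5)
  i_pr <- which(dd5$name == "PR")
  i_du <- which(dd5$name == "dUTPase")
  i_rt <- which(dd5$name == "RT")
  expect_true(i_pr < i_du && i_du < i_rt)

  expect_equal(nrow(detect_domains(random_aa_str(800, 55))), 0L)
})

test_that("CCHC motif search reports all (and overlapping) matches", {
  expect_equal(find_cchc("ACKTCGKEGHYANRCPA"), 1L)
  expect_equal(find_cchc("ACKTCGKEGAYANRCPA"), integer(0))  # no H
  # the two matches share the cysteine at offset 13: overlapping reported
  two <- "CAACAAAAHAAAACAACAAAAHAAAAC"
  expect_equal(find_cchc(two), c(0L, 13L))
})

test_that("PPT detection honours length, purity and distance rules", {
  ltr_at <- 100L
  base <- strsplit(paste0(strrep("C", 60), strrep("T", 40)), "")[[1]]
  s <- base
  s[81:92] <- strsplit("AGGGGAAAGGGA", "")[[1]]  # ends 8 nt before the LTR
  ppt <- find_ppt(paste(s, collapse = ""), ltr_at)
  expect_false(is.null(ppt))
  expect_true(ppt[1] <= 80L && ppt[2] >= 92L)

  expect_null(find_ppt(paste(base, collapse = ""), ltr_at))  # pyrimidine-rich

  far <- base
  far[61:72] <- strsplit("AGGGGAAAGGGA", "")[[1]]  # ends 28 nt before the LTR
  expect_null(find_ppt(paste(far, collapse = ""), ltr_at))
})

test_that("PBS detection distinguishes tRNA priming, self-priming and absence", {
  el_trna <- build_element(element_template(has_pbs = "trna"), rng_seed = 61L)
  pbs <- find_pbs(el_trna$seq, 440L)
  expect_false(is.null(pbs))
  expect_equal(pbs$mechanism, "trna")
  expect_gte(pbs$end - pbs$start, 12L)

  el_none <- build_element(rng_seed = 62L)
  ltr <- substr(el_none$seq, 1, 440)
  expect_null(find_pbs(el_none$seq, 440L, ltr_seq = ltr))

  el_self <- build_element(element_template(has_pbs = "self"), rng_seed = 63L)
  ltr <- substr(el_self$seq, 1, 440)
  pbs_s <- find_pbs(el_self$seq, 440L, ltr_seq = ltr)
  expect_false(is.null(pbs_s))
  expect_equal(pbs_s$mechanism, "self-priming")
})

test_that("degenerate forward-primer sites are matched code by code", {
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(
    "TTTT", "AGAATGTGCGTAGATTACAG", random_dna_str(300, 3),
    "GATGACCTGCTGATCTT", "TTTT")))
  prod <- in_silico_pcr(g)
  expect_equal(nrow(prod), 1L)
  expect_equal(prod$end - prod$start, 4L + 20L + 300L + 17L - 4L)

  polyA <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 2000)))
  expect_equal(nrow(in_silico_pcr(polyA)), 0L)

  bad <- rt_primer_pair()
  bad$forward <- "ACGTQ"
  expect_error(in_silico_pcr(g, bad), "undefined IUPAC")
})

test_that("in-silico PCR is strand-symmetric in mirrored coordinates", {
  el <- build_element(rng_seed = 71L)
  pl <- plant_one_element(el$seq, left = 1000, right = 1000, seed = 9)
  g <- Biostrings::DNAStringSet(c(chr1 = pl$genome))
  fwd <- in_silico_pcr(g)
  n <- nchar(pl$genome)
  rc <- Biostrings::DNAStringSet(c(chr1 = revcomp(pl$genome)))
  bwd <- in_silico_pcr(rc)
  expect_equal(nrow(fwd), nrow(bwd))
  expect_equal(sort(n - bwd$end), sort(fwd$start))
  expect_setequal(paste(fwd$end - fwd$start), paste(bwd$end - bwd$start))
})

test_that("a clean planted element is annotated end-to-end", {
  el <- build_element(rng_seed = 81L)
  pl <- plant_one_element(el$seq, left = 4000, right = 4000, seed = 10)
  g <- Biostrings::DNAStringSet(c(chr1 = pl$genome))
  loci <- mine_genome(g)
  expect_equal(nrow(loci), 1L)
  ann <- annotate_element(loci[1, ], g)
  expect_false(ann$partial)
  expect_equal(ann$element[2] - ann$element[1], 5704)
  expect_equal(ann$ltr5[2] - ann$ltr5[1], 440)
  expect_equal(ann$ltr3[2] - ann$ltr3[1], 440)
  expect_equal(ann$tsd, "AACAC")
  expect_equal(ann$classification, "chromovirus")
  expect_true(ann$cchc_present)
  expect_false(is.null(ann$ppt))
  expect_null(ann$pbs)
  orfs <- ann$orfs
  expect_equal(sort(orfs$aa_len[orfs$aa_len %in% c(323L, 1238L)]),
               c(323L, 1238L))
  expect_gte(nrow(ann$promoter_boxes), 0L)
})

test_that("a locus with no LTR pair is flagged partial", {
  # internal fragment only: no repeats in the window
  el <- build_element(rng_seed = 82L)
  frag <- substr(el$seq, 1200, 4200)  # RT region without LTRs
  pl <- plant_one_element(frag, tsd = "", left = 3000, right = 3000, seed = 11)
  g <- Biostrings::DNAStringSet(c(chr1 = pl$genome))
  loci <- mine_genome(g)
  expect_equal(nrow(loci), 1L)
  ann <- annotate_element(loci[1, ], g)
  expect_true(ann$partial)
})

test_that("non-chromovirus templates classify as non-chromovirus Gypsy", {
  tpl <- element_template(domain_order = c("PR", "RT", "RH", "INT"),
                          gag_aa = 360L)
  el <- build_element(tpl, rng_seed = 83L)
  pl <- plant_one_element(el$seq, left = 4000, right = 4000, seed = 12)
  g <- Biostrings::DNAStringSet(c(chr1 = pl$genome))
  loci <- mine_genome(g)
  ann <- annotate_element(loci[1, ], g)
  expect_false(ann$partial)
  expect_equal(ann$classification, "non-chromovirus Gypsy")
})

test_that("partial sequences merge through high-identity overlaps", {
  whole <- random_dna_str(3000, 21)
  a <- substr(whole, 1, 1800)
  b <- substr(whole, 1500, 3000)
  merged <- merge_partial_sequences(c(a, b))
  expect_equal(length(merged), 1L)
  expect_equal(merged, whole)

  unrelated <- c(random_dna_str(500, 22), random_dna_str(500, 23))
  expect_equal(length(merge_partial_sequences(unrelated)), 2L)
})
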