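test_that("built elements have identical LTRs with canonical TG...CA ends", {
  el <- build_element(rng_seed = 3L)
  L <- 440L
  n <- nchar(el$seq)
  expect_equal(n, 5704L)
  ltr5 <- substr(el$seq, 1, L)
  ltr3 <- substr(el$seq, n - L + 1L, n)
  expect_identical(ltr5, ltr3)
  expect_equal(substr(ltr5, 1, 2), "TG")
  expect_equal(substr(ltr5, L - 1L, L), "CA")
})

test_that("the Gag zinc knuckle matches C-X2-C-X4-H-X4-C when requested", {
  el <- build_element(rng_seed = 5L)
  expect_match(el$proteins$gag, "C.{2}C.{4}H.{4}C")
  tpl <- element_template(has_cchc = FALSE)
  el2 <- build_element(tpl, rng_seed = 5L)
  expect_false(grepl("C.{2}C.{4}H.{4}C", el2$proteins$gag))
})

test_that("element construction is bit-reproducible under a fixed seed", {
  expect_identical(build_element(rng_seed = 9L)$seq,
                   build_element(rng_seed = 9L)$seq)
  expect_false(identical(build_element(rng_seed = 9L)$seq,
                         build_element(rng_seed = 10L)$seq))
})

test_that("template invariants are enforced", {
  expect_error(element_template(ltr_length = 80), "ltr_length")
  expect_error(element_template(tsd_length = 7), "tsd_length")
  expect_error(element_template(domain_order = c("PR", "CHD", "RT", "INT")),
               "CHD after INT")
  expect_error(element_template(gag_aa = 50L, pol_aa = 400L),
               "outside 4400-13500")
})

test_that("planted polypurine tract sits inside the detection window", {
  el <- build_element(rng_seed = 21L)
  ppt <- el$truth[el$truth$type == "RR_tract", ]
  ltr3_start <- 5704L - 440L
  expect_true(ppt$end <= ltr3_start)
  expect_true(ltr3_start - ppt$end <= 20L)
  run <- substr(el$seq, ppt$start + 1L, ppt$end)
  expect_gte(mean(strsplit(run, "")[[1]] %in% c("A", "G")), 0.9)
  expect_gte(nchar(run), 10L)
})

test_that("the primer cassette plants compatible sites ~283 nt apart in RT", {
  el <- build_element(rng_seed = 2L)
  fwd_pos <- regexpr("AGAATGTGCGTAGATTACAG", el$seq, fixed = TRUE)
  rev_pos <- regexpr("GATGACCTGCTGATCTT", el$seq, fixed = TRUE)
  expect_gt(fwd_pos, 0)
  expect_gt(rev_pos, 0)
  expect_equal(as.integer(rev_pos) - (as.integer(fwd_pos) + 20L), 283L)
  cass <- el$truth[el$truth$type == "PCR_product", ]
  expect_equal(cass$end - cass$start, 320L)
})

test_that("planted copies share >= 94% identity at 3% within-family divergence", {
  spec <- family_spec("famA", copy_number = 3, within_divergence = 0.03,
                      clade = "Tcn1")
  sc <- plant_elements(2e5, 0.5, list(spec), rng_seed = 31L)
  tr <- sc$truth[sc$truth$type == "LTR_retrotransposon", ]
  expect_equal(nrow(tr), 3L)
  g <- as.character(sc$genome[[1]])
  seqs <- vapply(seq_len(3), function(i) {
    s <- substr(g, tr$start[i] + 1L, tr$end[i])
    if (tr$strand[i] == "-") s <- revcomp(s)
    s
  }, "")
  for (i in 1:2) for (j in (i + 1):3) {
    a <- strsplit(seqs[i], "")[[1]]
    b <- strsplit(seqs[j], "")[[1]]
    expect_gte(mean(a == b), 0.94)
  }
})

test_that("every planted TSD flank pair is exactly equal (incl. truncated copies)", {
  specs <- demo_family_specs(copy_number = 3, decay_fraction = 0.34)[1:2]
  sc <- plant_elements(3e5, 0.5, specs, rng_seed = 8L)
  g <- as.character(sc$genome[[1]])
  tr <- sc$truth[sc$truth$type == "LTR_retrotransposon", ]
  for (i in seq_len(nrow(tr))) {
    tsd <- feature_attr(tr[i, ], "tsd")
    k <- nchar(tsd)
    expect_identical(substr(g, tr$start[i] - k + 1L, tr$start[i]), tsd)
    expect_identical(substr(g, tr$end[i] + 1L, tr$end[i] + k), tsd)
  }
})

test_that("truth LTR pairs keep identity >= 1 - 2 * within_divergence", {
  spec <- family_spec("famB", copy_number = 4, within_divergence = 0.06,
                      clade = "Pyggy")
  sc <- plant_elements(2.5e5, 0.5, list(spec), rng_seed = 13L)
  g <- as.character(sc$genome[[1]])
  ltrs <- sc$truth[sc$truth$type == "long_terminal_repeat", ]
  elems <- sc$truth[sc$truth$type == "LTR_retrotransposon", ]
  for (i in seq_len(nrow(elems))) {
    mine <- ltrs[ltrs$start >= elems$start[i] & ltrs$end <= elems$end[i], ]
    if (nrow(mine) < 2L) next  # truncated copy lost one LTR
    a <- strsplit(substr(g, mine$start[1] + 1L, mine$end[1]), "")[[1]]
    b <- strsplit(substr(g, mine$start[2] + 1L, mine$end[2]), "")[[1]]
    expect_gte(mean(a == b), 1 - 2 * 0.06)
  }
})

test_that("zero families gives background only with empty truth", {
  sc <- plant_elements(5e4, 0.4, list(), rng_seed = 4L)
  expect_equal(length(sc$genome[[1]]), 5e4)
  expect_equal(nrow(sc$truth), 0L)
})

test_that("an overfull genome request errors", {
  spec <- family_spec("famC", copy_number = 10)
  expect_error(plant_elements(3e4, 0.5, list(spec), rng_seed = 1L),
               "too small")
})

test_that("genomes are bit-reproducible under a fixed seed", {
  specs <- demo_family_specs(copy_number = 2, decay_fraction = 0)[1]
  a <- plant_elements(1e5, 0.5, specs, rng_seed = 77L)
  b <- plant_elements(1e5, 0.5, specs, rng_seed = 77L)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
})

test_that("evolved pairs match the Poisson closed-form expectation", {
  z <- evolve_protein_pair(100, 0, 700, rng_seed = 1L)
  expect_identical(z$seq1, z$seq2)
  expect_equal(z$true_d, 0)

  pp <- evolve_protein_pair(680, 0.45e-9, 700, rng_seed = 2L)
  p_exp <- 1 - exp(-2 * 0.45e-9 * 700e6)
  expect_equal(p_exp, pp$p_expected)
  a <- strsplit(pp$seq1, "")[[1]]
  b <- strsplit(pp$seq2, "")[[1]]
  p_hat <- mean(a != b)
  se <- sqrt(p_exp * (1 - p_exp) / 680)
  expect_lt(abs(p_hat - p_exp), 3 * se)

  pp2 <- evolve_protein_pair(680, 0.45e-9, 700, rng_seed = 3L)
  expect_false(identical(pp$seq2, pp2$seq2))
})

test_that("the evolved-pair difference proportion is asymptotically unbiased", {
  d <- 2 * 0.45e-9 * 700e6
  p_exp <- 1 - exp(-d)
  devs <- vapply(1:200, function(b) {
    z <- evolve_protein_pair(680, 0.45e-9, 700, rng_seed = 500 + b)
    a <- strsplit(z$seq1, "")[[1]]
    bb <- strsplit(z$seq2, "")[[1]]
    abs(mean(a != bb) - p_exp)
  }, 0)
  expect_lt(mean(devs), 0.02)
})
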