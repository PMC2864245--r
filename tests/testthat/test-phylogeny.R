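test_that("identical sequences align without gaps", {
  m <- progressive_msa(c(a = "MKLVST", b = "MKLVST"))
  expect_equal(as.character(m), c(a = "MKLVST", b = "MKLVST"))
})

test_that("a 3-vs-4 nucleotide pair aligns into 4 columns with one gap", {
  m <- progressive_msa(c(a = "ACGT", b = "ACT"))
  chars <- as.character(m)
  expect_equal(unique(nchar(chars)), 4L)
  expect_equal(sum(strsplit(chars[["b"]], "")[[1]] == "-"), 1L)
  expect_equal(gsub("-", "", chars[["b"]]), "ACT")
})

test_that("mixed alphabets are rejected", {
  expect_error(progressive_msa(c(a = "ACGT", b = "MKLW*")), "mixed alphabets")
})

test_that("alignment width is invariant under input order", {
  seqs <- c(f1 = random_aa_str(120, 1),
            f2 = mutate_protein(random_aa_str(120, 1), 0.2, 2),
            f3 = random_aa_str(110, 3),
            f4 = mutate_protein(random_aa_str(110, 3), 0.2, 4),
            f5 = random_aa_str(130, 5),
            f6 = mutate_protein(random_aa_str(130, 5), 0.2, 6))
  w0 <- unique(nchar(as.character(progressive_msa(seqs))))
  for (s in 1:3) {
    perm <- withr::with_seed(s, sample(seqs))
    expect_equal(unique(nchar(as.character(progressive_msa(perm)))), w0)
  }
})

test_that("distance models agree with closed forms and reject p near 1", {
  pair <- c(a = "MKLV", b = "MKLV")
  expect_true(all(distance_matrix(pair, "p") == 0))
  expect_true(all(distance_matrix(pair, "poisson") == 0))

  a <- strrep("A", 100)
  b <- paste0(strrep("C", 48), strrep("A", 52))
  D <- distance_matrix(c(x = a, y = b), "poisson")
  expect_equal(D["x", "y"], 0.6539, tolerance = 1e-4)
  Dp <- distance_matrix(c(x = a, y = b), "p")
  expect_equal(Dp["x", "y"], 0.48)

  allneq <- c(x = strrep("A", 50), y = strrep("C", 50))
  expect_error(distance_matrix(allneq, "poisson"), "undefined")
})

test_that("Poisson distance dominates p-distance except at zero", {
  p <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(poisson_distance(p) > p))
  expect_equal(poisson_distance(0), 0)
})

test_that("neighbor joining is exact on the worked additive example", {
  taxa <- c("A", "B", "C", "D")
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(taxa, taxa))
  tr <- nj_tree(D)
  expect_true(ape::is.monophyletic(tr, c("A", "B")))
  pd <- ape::cophenetic.phylo(tr)[taxa, taxa]
  expect_equal(pd, D, tolerance = 1e-8)
})

test_that("three taxa resolve by the closed-form star formulas", {
  D <- matrix(c(0, 2, 3,
                2, 0, 4,
                3, 4, 0), 3, 3, dimnames = list(c("A","B","C"), c("A","B","C")))
  tr <- nj_tree(D)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(len[c("A", "B", "C")]), c(0.5, 1.5, 2.5))
})

test_that("neighbor joining recovers 100 random additive matrices exactly", {
  for (s in 1:100) {
    n <- withr::with_seed(s, sample(4:12, 1))
    D <- random_additive_matrix(n, 1000 + s)
    tr <- nj_tree(D)
    pd <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
    expect_equal(pd, D, tolerance = 1e-6)
  }
})

test_that("our NJ topology agrees with the reference implementation", {
  for (s in 1:10) {
    D <- random_additive_matrix(8, 2000 + s)
    ours <- nj_tree(D)
    ref <- ape::nj(as.dist(D))
    expect_equal(phangorn::RF.dist(ours, ref), 0)
  }
})

test_that("negative branch lengths are clamped with the deficit transferred", {
  taxa <- c("A", "B", "C", "D")
  D <- matrix(c(0, 0.1, 4, 4,
                0.1, 0, 4.8, 4.8,
                4, 4.8, 0, 0.1,
                4, 4.8, 0.1, 0), 4, 4, dimnames = list(taxa, taxa))
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
  # path lengths are preserved through clamp-and-transfer within each pair
  pd <- ape::cophenetic.phylo(tr)
  expect_equal(pd["A", "B"], 0.1, tolerance = 1e-8)
})

test_that("bootstrap supports are reproducible, bounded, and optional", {
  aln <- seed_alignment()
  t1 <- bootstrap_tree(aln, n = 50, seed = 9)
  t2 <- bootstrap_tree(aln, n = 50, seed = 9)
  expect_identical(t1$node.label, t2$node.label)
  s <- as.numeric(t1$node.label)
  expect_true(all(s >= 0 & s <= 100))
  t0 <- bootstrap_tree(aln, n = 0)
  expect_null(t0$node.label)
})

test_that("identical sequences give degenerate full supports", {
  aln <- c(a = "MKLVSTAG", b = "MKLVSTAG", c = "MKLVSTAG", d = "MKLVSTAG")
  tr <- bootstrap_tree(aln, n = 20, seed = 1)
  expect_true(all(as.numeric(tr$node.label) == 100))
})

test_that("clade assignment honours purity and the 50% support rule", {
  tr <- ape::read.tree(
    text = "((q1:1,(t1:1,t2:1)100:1)100:1,(g1:1,g2:1)100:1,out:3);")
  refs <- c(t1 = "Tcn1", t2 = "Tcn1", g1 = "Galahad", g2 = "Galahad")
  asg <- assign_clades(tr, refs)
  expect_equal(asg$clade[asg$query == "q1"], "Tcn1")
  expect_equal(asg$support[asg$query == "q1"], 100)
  expect_equal(asg$clade[asg$query == "out"], "unclassified")

  mixed <- ape::read.tree(
    text = "((q1:1,(t1:1,g1:1)100:1)100:1,(t2:1,g2:1)100:1);")
  asg2 <- assign_clades(mixed, refs)
  expect_equal(asg2$clade[asg2$query == "q1"], "unclassified")

  weak <- ape::read.tree(
    text = "((q1:1,(t1:1,t2:1)49:1)49:1,(g1:1,g2:1)100:1);")
  asg3 <- assign_clades(weak, refs)
  expect_equal(asg3$clade[asg3$query == "q1"], "unclassified")
})

test_that("outgroup rooting validates and round-trips the bipartition set", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:1,D:1);")
  rooted <- root_with_outgroup(tr, "A")
  expect_true(ape::is.rooted(rooted))
  expect_error(root_with_outgroup(tr, c("A", "B", "C", "D")), "all leaves")
  expect_error(root_with_outgroup(tr, "Z"), "not in tree")

  back <- ape::unroot(rooted)
  key <- function(t) {
    pp <- ape::prop.part(t)
    labs <- attr(pp, "labels")
    sort(vapply(pp, function(ix) {
      side <- labs[ix]
      if (!("A" %in% side)) side <- setdiff(labs, side)
      paste(sort(side), collapse = "|")
    }, ""))
  }
  expect_identical(unique(key(back)), unique(key(tr)))
})

test_that("a non-monophyletic outgroup is rejected", {
  tr <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  expect_error(root_with_outgroup(tr, c("A", "B")), "monophyletic")
})
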