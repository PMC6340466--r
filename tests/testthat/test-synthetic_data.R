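test_that("simulation limiting cases: zero branches and determinism", {
  tr <- tree4()
  tr0 <- tr
  tr0$edge.length[] <- 0
  sim0 <- simulate_codon_alignment(tr0, 30, seed = 1)
  root <- sim0$node_seqs[["node5"]]
  for (tx in tr$tip.label)
    expect_identical(sim0$alignment$seqs[[tx]], root)
  s1 <- simulate_codon_alignment(tr, 50, seed = 99)
  s2 <- simulate_codon_alignment(tr, 50, seed = 99)
  expect_identical(s1$alignment$seqs, s2$alignment$seqs)
  expect_identical(s1$history, s2$history)
  s3 <- simulate_codon_alignment(tr, 50, seed = 100)
  expect_false(identical(s1$alignment$seqs, s3$alignment$seqs))
})

test_that("functional lineages never carry internal stop codons", {
  sim <- simulate_codon_alignment(balanced_tree(8, 0.15), 120, kappa = 2,
                                  omega = 0.3, seed = 3)
  gc <- genetic_code()
  for (s in sim$node_seqs) {
    aa <- translate_cds(s, gc)
    expect_false(grepl("*", aa, fixed = TRUE))
  }
})

test_that("counting dN/dS converges to the simulating omega on long pairs", {
  tr <- read_newick(text = "(A:0.3,B:0.3);")
  sim <- simulate_codon_alignment(tr, 2000, kappa = 2, omega = 0.3, seed = 11)
  cd <- count_dnds(sim$alignment$seqs[["A"]], sim$alignment$seqs[["B"]])
  expect_lt(abs(cd$omega - 0.3), 0.1)
})

test_that("lesion injection: identity, polarity, and overlap handling", {
  sim <- simulate_codon_alignment(tree4(), 40, seed = 5)
  aln <- sim$alignment
  expect_identical(inject_lesions(aln, NULL)$alignment$seqs, aln$seqs)

  inj <- inject_lesions(aln, data.frame(taxon = "A", kind = "deletion",
                                        position = 5, length_nt = 3))
  sc <- scan_orf(inj$alignment, reference_taxon = "B")
  expect_equal(sc$calls$status[sc$calls$taxon == "A"], "functional")
  expect_equal(sc$lesions$causes_frameshift[sc$lesions$taxon == "A"], FALSE)

  inj1 <- inject_lesions(aln, data.frame(taxon = "A", kind = "deletion",
                                         position = 5, length_nt = 1))
  sc1 <- scan_orf(inj1$alignment, reference_taxon = "B")
  expect_equal(sc1$calls$status[sc1$calls$taxon == "A"], "pseudogene")
  expect_true(any(sc1$lesions$taxon == "A" & sc1$lesions$causes_frameshift))

  expect_error(inject_lesions(aln, data.frame(
    taxon = c("A", "A"), kind = c("deletion", "deletion"),
    position = c(5, 5), length_nt = c(4, 2))), "overlap")
})

test_that("injected lesion ground truth is recovered exactly by scan_orf", {
  sim <- simulate_codon_alignment(balanced_tree(8, 0.05), 60, seed = 21)
  les <- data.frame(
    taxon = c("t1", "t2", "t3", "t5"),
    kind = c("deletion", "insertion", "stop_substitution", "deletion"),
    position = c(10, 25, 40, 50),
    length_nt = c(2, 4, 3, 6))
  inj <- inject_lesions(sim$alignment, les)
  sc <- scan_orf(inj$alignment, reference_taxon = "t8", leniency = 0)
  # every truth row must be present with exact kind/column/length
  for (i in seq_len(nrow(inj$lesions))) {
    tr <- inj$lesions[i, ]
    hit <- sc$lesions$taxon == tr$taxon & sc$lesions$kind == tr$kind &
      sc$lesions$codon_column == tr$codon_column &
      sc$lesions$length_nt == tr$length_nt
    expect_true(any(hit), info = paste("lesion row", i))
  }
})

test_that("pseudogenisation limiting cases and validation", {
  tr <- read_newick(text = "((A:20,B:20):10,(C:15,(D:7,E:7):8):15);")
  # loss at the branch origin: the whole terminal branch is neutral
  s1 <- simulate_pseudogenization(tr, data.frame(lineage = "A", age = 20),
                                  n_codons = 30, seed = 2)
  expect_equal(s1$truth$T_p, 20)
  expect_equal(s1$truth$T, 20)
  # loss at the tip: no neutral era
  s2 <- simulate_pseudogenization(tr, data.frame(lineage = "A", age = 0),
                                  n_codons = 30, seed = 2)
  expect_equal(s2$truth$T_p, 0)
  # out-of-span loss age is rejected
  expect_error(simulate_pseudogenization(
    tr, data.frame(lineage = "A", age = 25), n_codons = 10), "span")
})

test_that("dead lineages end up scannable as pseudogenes", {
  tr <- read_newick(text = "((A:20,B:20):10,(C:15,(D:7,E:7):8):15);")
  sim <- simulate_pseudogenization(tr, data.frame(lineage = "A", age = 15),
                                   n_codons = 200, omega = 0.1, seed = 8)
  sc <- scan_orf(sim$alignment)
  expect_equal(sc$calls$status[sc$calls$taxon == "A"], "pseudogene")
  expect_true(all(sc$calls$status[sc$calls$taxon != "A"] == "functional"))
})

test_that("presets provide a labelled 12-taxon study design", {
  for (nm in c("pteropodid_like", "mormoopid_like")) {
    p <- opsin_preset(nm)
    expect_equal(length(p$tree$tip.label), 12L)
    expect_true(ape::is.ultrametric(p$tree, tol = 1e-6))
    expect_equal(sum(p$tags$hdc), 4L)
    expect_true(all(p$loss$lineage %in% p$tree$tip.label))
  }
})

test_that("simulate() on a fitted model draws from the fitted parameters", {
  sim <- simulate_codon_alignment(tree4(), 40, seed = 61)
  fit <- fit_codon_model(sim$alignment, sim$tree, "M0", n_starts = 1,
                         max_rounds = 2, tol = 1e-3)
  reps <- simulate(fit, nsim = 2, seed = 9, n_codons = 25)
  expect_length(reps, 2L)
  for (r in reps) {
    expect_s3_class(r, "codon_sim")
    expect_equal(r$alignment$n_codon, 25L)
    expect_setequal(names(r$alignment$seqs), tree4()$tip.label)
  }
  # site-mixture simulation draws a class per site
  fitm <- fit_codon_model(sim$alignment, sim$tree, "M1a", n_starts = 1,
                          fix_branch_lengths = TRUE)
  rm1 <- simulate(fitm, seed = 10, n_codons = 30)[[1]]
  expect_equal(rm1$alignment$n_codon, 30L)
  expect_length(rm1$site_class, 30L)
})
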