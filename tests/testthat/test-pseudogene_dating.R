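test_that("branch categorisation around lesion origins", {
  tr <- tree4()
  a <- match("A", tr$tip.label)
  # lesion on a terminal branch: that branch mixed, everything else functional
  c1 <- categorize_branches(tr, a)
  expect_equal(c1$category[c1$child == a], "mixed")
  expect_true(all(c1$category[c1$child != a] == "functional"))
  # lesion on a 2-taxon clade stem: stem mixed, both terminals nonfunctional
  stem <- ape::getMRCA(tr, c("A", "B"))
  c2 <- categorize_branches(tr, stem)
  expect_equal(c2$category[c2$child == stem], "mixed")
  b <- match("B", tr$tip.label)
  expect_equal(sort(c2$child[c2$category == "nonfunctional"]), sort(c(a, b)))
  expect_true(all(c2$category[c2$child %in% c(match("C", tr$tip.label),
                                              match("D", tr$tip.label))] ==
                    "functional"))
  # two independent origins in disjoint clades
  c_ <- match("C", tr$tip.label)
  c3 <- categorize_branches(tr, c(a, c_))
  expect_equal(sort(c3$child[c3$category == "mixed"]), sort(c(a, c_)))
  expect_false(any(c3$category == "nonfunctional"))
  # sister origins: their common stem is premutation (all tips below lost)
  c4 <- categorize_branches(tr, c(a, b))
  expect_equal(c4$category[c4$child == stem], "premutation")
  # no lesions: everything functional
  c5 <- categorize_branches(tr, integer())
  expect_true(all(c5$category == "functional"))
})

test_that("the relaxation equation has the stated limits and shape", {
  # no omega increase: no neutral era
  expect_equal(as.numeric(date_relaxation(0.1, 0.1, 30)), 0)
  # fully neutral branch: the entire branch postdates the loss
  expect_equal(as.numeric(date_relaxation(1, 0.1, 30)), 30)
  # worked mixture: omega_f = 0.111, omega_m = 0.5116, T = 30
  expect_equal(as.numeric(date_relaxation(0.5116, 0.111, 30)),
               30 * (0.5116 - 0.111) / (1 - 0.111), tolerance = 1e-12)
  expect_equal(as.numeric(date_relaxation(0.5116, 0.111, 30)), 13.52,
               tolerance = 1e-2)
  # monotone increasing in omega_m, decreasing in omega_f
  wm <- seq(0.1, 1, by = 0.05)
  tp <- as.numeric(date_relaxation(wm, 0.1, 20))
  expect_true(all(diff(tp) > 0))
  wf <- seq(0, 0.49, by = 0.05)
  tp2 <- as.numeric(date_relaxation(0.5, wf, 20))
  expect_true(all(diff(tp2) < 0))
  # clamping flags out-of-range inputs
  low <- date_relaxation(0.05, 0.1, 20)
  expect_equal(as.numeric(low), 0)
  expect_true(attr(low, "clamped"))
  # error contracts
  expect_error(date_relaxation(0.5, 1, 20), "omega_f")
  expect_error(date_relaxation(0.5, 0.1, 0), "T")
})

test_that("mixed branches resolve into era components on the time tree", {
  tr <- read_newick(text = "((A:20,B:20):10,(C:15,(D:7,E:7):8):15);")
  a <- match("A", tr$tip.label)
  cats <- categorize_branches(tr, a)
  res <- resolve_mixed(tr, cats, omega_f = 0.1, omega_m = 0.55)
  expect_equal(nrow(res), 1L)
  expect_equal(res$T, 20)
  expect_equal(res$T_f + res$T_p, res$T, tolerance = 1e-12)
  expect_equal(res$T_p, 20 * (0.55 - 0.1) / 0.9, tolerance = 1e-12)
  # A is a tip of an ultrametric tree, so loss age = T_p
  expect_equal(res$loss_age_Ma, res$T_p)
  # whole branch neutral: loss at the branch start
  res2 <- resolve_mixed(tr, cats, omega_f = 0.1, omega_m = 1)
  expect_equal(res2$T_p, 20)
  expect_equal(res2$loss_age_Ma, 20)
  # omega_m below the functional level clamps to zero and flags it
  res3 <- resolve_mixed(tr, cats, omega_f = 0.2, omega_m = 0.1)
  expect_equal(res3$T_p, 0)
  expect_true(res3$clamped)
  # missing omega_m for a mixed branch: skipped with a warning
  expect_warning(r4 <- resolve_mixed(tr, cats, 0.1,
                                     stats::setNames(0.5, "999")), "skipped")
  expect_equal(nrow(r4), 0L)
})

test_that("clade subsetting recovers columns lost to out-of-clade indels", {
  sim <- simulate_codon_alignment(balanced_tree(8, 0.05), 30, seed = 51)
  inj <- inject_lesions(sim$alignment,
                        data.frame(taxon = "t1", kind = "deletion",
                                   position = 4, length_nt = 6))
  full <- strip_indel_codons(inj$alignment)
  expect_equal(full$n_codon, 28L)
  sub <- clade_subset(inj$alignment, sim$tree, c("t5", "t6", "t7", "t8"))
  expect_equal(sub$alignment$n_codon, 30L)    # clade rows are gap-free
  expect_setequal(sub$tree$tip.label, c("t5", "t6", "t7", "t8"))
  expect_error(clade_subset(inj$alignment, sim$tree, "t5"), "2 tips")
})
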