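test_that("indel-containing codon columns are stripped with a log", {
  aln <- codon_alignment(c(a = "ATGAAACCC", b = "ATGAAACCC"))
  expect_identical(strip_indel_codons(aln)$seqs, aln$seqs)
  aln2 <- codon_alignment(c(a = "ATG---CCC", b = "ATGAAACCC"))
  s2 <- strip_indel_codons(aln2)
  expect_equal(s2$n_codon, 2L)
  expect_equal(attr(s2, "removed")$codon_column, 2L)
  # 10 codon columns, gaps in columns 2 and 7 -> 8 remain
  row <- strrep("ATGAAACCCGGGTTTACTGATCACCTTGAA", 1)
  r2 <- paste0(substr(row, 1, 3), "---", substr(row, 7, 18), "---",
               substr(row, 22, 30))
  aln3 <- codon_alignment(c(a = row, b = r2))
  s3 <- strip_indel_codons(aln3)
  expect_equal(s3$n_codon, 8L)
  expect_equal(attr(s3, "removed")$codon_column, c(2L, 7L))
  # stop-containing columns are removed like indel columns
  aln4 <- codon_alignment(c(a = "ATGTAACCC", b = "ATGAAACCC"))
  expect_equal(strip_indel_codons(aln4)$n_codon, 2L)
  expect_error(strip_indel_codons(codon_alignment(c(a = "---", b = "AAA"),
                                                  frame_strict = FALSE)),
               "all codon columns")
})

test_that("NG86 counting matches the single-change synonymy oracle", {
  cd <- count_dnds("TTT", "TTA")        # Phe -> Leu
  expect_false(oracle_synonymous("TTT", "TTA"))
  expect_equal(cd$Nd, 1); expect_equal(cd$Sd, 0)
  cd2 <- count_dnds("GGT", "GGC")       # Gly -> Gly
  expect_true(oracle_synonymous("GGT", "GGC"))
  expect_equal(cd2$Nd, 0); expect_equal(cd2$Sd, 1)
  # identical sequences: all-zero distances
  cd3 <- count_dnds("ATGAAA", "ATGAAA")
  expect_equal(cd3$Nd + cd3$Sd, 0)
  expect_equal(cd3$dN, 0); expect_equal(cd3$dS, 0)
  # site counts always satisfy N + S = 3 x codons
  set.seed(5)
  sim <- simulate_codon_alignment(read_newick(text = "(A:0.1,B:0.1);"), 50,
                                  seed = 5)
  cd4 <- count_dnds(sim$alignment$seqs[["A"]], sim$alignment$seqs[["B"]])
  expect_equal(cd4$N + cd4$S, 3 * cd4$n_codons)
  # every single-nt difference is classified like the oracle says
  expect_error(count_dnds("ATGTAAAAA", "ATGTAAAAA"), "stop")
})

test_that("the codon generator has the Goldman-Yang structure", {
  pi <- codon_freqs(codon_alignment(c(a = "ATGAAACCCGGGTTTCAT")), "F1x4")
  Q <- codon_rate_matrix(3.1, 0.47, freqs = pi)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  # detailed balance pi_i q_ij = pi_j q_ji, i.e. diag(pi) %*% Q is symmetric
  p <- attr(Q, "pi")
  D <- p * Q
  expect_lt(max(abs(D - t(D))), 1e-15)
  # expected rate is 1 under the "expected" scaling
  expect_equal(-sum(p * diag(Q)), 1, tolerance = 1e-12)
  # multi-nucleotide changes are forbidden
  expect_equal(Q["TTT", "AAT"], 0)
  # omega = 0 kills nonsynonymous rates but not synonymous ones
  Q0 <- codon_rate_matrix(2, 0, freqs = pi)
  expect_equal(Q0["TTT", "TTA"], 0)          # Phe -> Leu
  expect_gt(Q0["GGT", "GGC"], 0)             # Gly -> Gly
})

test_that("pruning likelihood equals exhaustive summation (3 taxa x 5 codons)", {
  sim <- simulate_codon_alignment(tree3(), 5, kappa = 2, omega = 0.3, seed = 7)
  for (pars in list(c(2, 0.3), c(1.5, 1.2))) {
    expect_equal(codon_loglik(sim$alignment, tree3(), pars[1], pars[2])$loglik,
                 bf_loglik(sim$alignment, tree3(), pars[1], pars[2]),
                 tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to taxon order and codon-column permutation", {
  sim <- simulate_codon_alignment(tree4(), 40, seed = 9)
  aln <- sim$alignment
  base <- codon_loglik(aln, tree4(), 2, 0.3)$loglik
  perm_tax <- codon_alignment(aln$seqs[c("D", "B", "A", "C")])
  expect_equal(codon_loglik(perm_tax, tree4(), 2, 0.3)$loglik, base)
  set.seed(1)
  cols <- sample(aln$n_codon)
  cm <- codon_matrix(aln)[, cols]
  perm_cols <- codon_alignment(apply(cm, 1, paste, collapse = ""))
  # column permutation changes F1x4 estimates not at all (same nt pool)
  expect_equal(codon_loglik(perm_cols, tree4(), 2, 0.3)$loglik, base)
})

test_that("two-ratio likelihood collapses to M0 at equal omegas", {
  sim <- simulate_codon_alignment(tree4(), 60, seed = 15)
  fit0 <- fit_codon_model(sim$alignment, sim$tree, "M0", n_starts = 1,
                          max_rounds = 6, tol = 1e-8)
  # evaluating a per-branch omega vector with every entry omega-hat(M0)
  # on the fitted tree reproduces the M0 likelihood exactly
  wv <- stats::setNames(rep(fit0$omega, nrow(fit0$tree$edge)),
                        fit0$tree$edge[, 2])
  expect_equal(codon_loglik(sim$alignment, fit0$tree, fit0$kappa, wv)$loglik,
               fit0$lnL, tolerance = 1e-6)
  # and the optimised two-ratio fit can only improve the likelihood
  fit2 <- fit_codon_model(sim$alignment, sim$tree, "two_ratio",
                          foreground = c("A", "B"), n_starts = 1,
                          max_rounds = 6, tol = 1e-8)
  expect_gte(fit2$lnL, fit0$lnL - 1e-4)
  expect_equal(fit2$np, fit0$np + 1L)
})

test_that("likelihood-ratio tests follow the chi-square contract", {
  fake <- function(lnL, np, model = "x")
    structure(list(lnL = lnL, np = np, model = model), class = "codon_fit")
  t0 <- lrt(fake(-100, 5), fake(-100, 4))
  expect_equal(t0$twice_delta, 0)
  expect_equal(t0$p_value, 1)
  t1 <- lrt(fake(-100, 6), fake(-111.55, 4))
  expect_equal(t1$twice_delta, 23.1)
  expect_equal(t1$df, 2)
  expect_equal(t1$p_value, 9.7e-6, tolerance = 1e-2)
  expect_warning(lrt(fake(-105, 6), fake(-100, 4)), "exceeds")
})

test_that("branch labelling follows the all-descendants rule", {
  tr <- balanced_tree(8)
  ann <- data.frame(taxon = tr$tip.label,
                    all = TRUE,
                    one = tr$tip.label == "t3",
                    para = tr$tip.label %in% c("t1", "t2", "t3"))
  trl <- label_branches(tr, ann)
  expect_equal(sort(tagged_branches(trl, "all")), sort(tr$edge[, 2]))
  expect_equal(tagged_branches(trl, "one"), match("t3", tr$tip.label))
  # paraphyletic set on the balanced 8-tip tree: hand enumeration
  # t1,t2 form a cherry (their stem qualifies); t3 is isolated from them
  para <- tagged_branches(trl, "para")
  cherry_stem <- ape::getMRCA(tr, c("t1", "t2"))
  expect_setequal(para, c(match(c("t1", "t2", "t3"), tr$tip.label), cherry_stem))
  expect_error(tagged_branches(trl, "absent"), "no branch tags|not present")
})

test_that("site-model fits respect nesting on a small fixture", {
  sim <- simulate_codon_alignment(balanced_tree(6, 0.15), 60, kappa = 2,
                                  omega = 0.3, seed = 19)
  common <- list(fix_branch_lengths = TRUE, n_starts = 1, ncat = 5)
  f1a <- do.call(fit_codon_model, c(list(sim$alignment, sim$tree, "M1a"), common))
  f2a <- do.call(fit_codon_model, c(list(sim$alignment, sim$tree, "M2a"), common))
  expect_gte(f2a$lnL, f1a$lnL - 1e-3)
  tst <- lrt(f2a, f1a)
  expect_equal(tst$df, 2)
  expect_gte(tst$twice_delta, -1e-3)
})
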