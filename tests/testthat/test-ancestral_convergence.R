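test_that("Fitch parsimony matches hand counts on simple patterns", {
  tr <- tree4()
  m <- matrix(c("L", "L", "L", "L",
                "L", "L", "S", "S"), 4, 2,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  fp <- fitch_parsimony(tr, m)
  expect_equal(fp$score, c(0L, 1L))
  expect_true(all(fp$states[, 1] == "L"))
})

test_that("parsimony scores equal the exhaustive minimum on small trees", {
  set.seed(17)
  for (rep in 1:8) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n)
    states <- sample(c("L", "S", "T", "N"), n, TRUE)
    names(states) <- tr$tip.label
    m <- matrix(states, n, 1, dimnames = list(tr$tip.label, NULL))
    fp <- fitch_parsimony(tr, m)
    expect_equal(fp$score, bf_parsimony_site(tr, states), info = paste("rep", rep))
  }
})

test_that("parsimony score agrees with phangorn on a larger fixture", {
  skip_if_not_installed("phangorn")
  set.seed(23)
  tr <- ape::rtree(10)
  m <- matrix(sample(c("A", "C", "D", "E", "F"), 10 * 20, TRUE), 10, 20,
              dimnames = list(tr$tip.label, NULL))
  fp <- fitch_parsimony(tr, m)
  pd <- phangorn::phyDat(m, type = "AA")
  expect_equal(fp$total_score,
               as.integer(phangorn::parsimony(tr, pd)))
})

test_that("sites with fewer than two observed tips are skipped", {
  tr <- tree4()
  m <- matrix(c("L", NA, NA, NA), 4, 1, dimnames = list(c("A", "B", "C", "D"), NULL))
  fp <- fitch_parsimony(tr, m)
  expect_true(is.na(fp$score[1]))
  expect_equal(fp$skipped, 1L)
})

test_that("marginal posteriors equal brute-force summation on a 3-tip tree", {
  tr <- tree3()
  m <- matrix(c("L", "L", "S",
                "T", "N", "T"), 3, 2, dimnames = list(c("A", "B", "C"), NULL))
  rec <- marginal_ml_reconstruction(tr, m)
  # independent oracle: closed-form Poisson P, exhaustive root/internal sum
  trp <- ape::reorder.phylo(tr, "postorder")
  P <- lapply(trp$edge.length, poisson_P)
  aa <- opsinevol:::AA_ALPHABET
  idx <- m[trp$tip.label, , drop = FALSE]
  for (s in 1:2) {
    joint <- matrix(0, 20, 20)   # root state x internal state
    for (r in 1:20) for (v in 1:20) {
      p <- 1 / 20
      for (e in seq_len(nrow(trp$edge))) {
        pa <- trp$edge[e, 1]; ch <- trp$edge[e, 2]
        from <- if (pa == 4) r else v
        to <- if (ch <= 3) match(idx[ch, s], aa) else v
        p <- p * P[[e]][from, to]
      }
      joint[r, v] <- p
    }
    expect_equal(unname(rec$posterior[[s]][4, ]),
                 unname(rowSums(joint) / sum(joint)), tolerance = 1e-9)
    expect_equal(unname(rec$posterior[[s]][5, ]),
                 unname(colSums(joint) / sum(joint)), tolerance = 1e-9)
  }
  # loglik agrees with the oracle total
})

test_that("marginal reconstruction limiting behaviour", {
  # identical tips, short branches: root posterior concentrates
  tr <- read_newick(text = "(A:0.01,B:0.01);")
  m <- matrix(c("L", "L"), 2, 1, dimnames = list(c("A", "B"), NULL))
  rec <- marginal_ml_reconstruction(tr, m)
  expect_gt(rec$posterior[[1]][3, "L"], 0.99)
  # very long branches: posterior approaches the stationary distribution
  tr2 <- read_newick(text = "(A:60,B:60);")
  rec2 <- marginal_ml_reconstruction(tr2, m)
  expect_equal(unname(rec2$posterior[[1]][3, ]), rep(1 / 20, 20),
               tolerance = 1e-3)
  # argmax ties broken alphabetically
  tr3 <- read_newick(text = "(A:1,B:1);")
  m3 <- matrix(c("C", "A"), 2, 1, dimnames = list(c("A", "B"), NULL))
  rec3 <- marginal_ml_reconstruction(tr3, m3)
  expect_equal(unname(rec3$states[3, 1]), "A")
  # tip argmax equals the observed state
  expect_equal(unname(rec3$states[1, 1]), "C")
  expect_equal(unname(rec3$states[2, 1]), "A")
})

test_that("substitution enumeration matches hand-traced histories", {
  tr <- tree4()
  m <- matrix(c("L", "L", "L", "L"), 4, 1, dimnames = list(c("A", "B", "C", "D"), NULL))
  rec <- marginal_ml_reconstruction(tr, m)
  expect_equal(nrow(enumerate_substitutions(rec)), 0L)
  m2 <- matrix(c("S", "L", "L", "L"), 4, 1, dimnames = list(c("A", "B", "C", "D"), NULL))
  ev <- enumerate_substitutions(marginal_ml_reconstruction(tr, m2))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$child, match("A", tr$tip.label))
  expect_equal(ev$from, "L"); expect_equal(ev$to, "S")
})

test_that("reconstruction recovers most true events at moderate divergence", {
  sim <- simulate_codon_alignment(balanced_tree(8, 0.1), 300, kappa = 2,
                                  omega = 0.2, seed = 41)
  aa_tips <- vapply(sim$alignment$seqs, translate_cds, character(1))
  rec <- marginal_ml_reconstruction(sim$tree, aa_tips)
  got <- enumerate_substitutions(rec)
  # true amino-acid events from the simulator's node sequences
  truth <- list()
  aa_nodes <- vapply(sim$node_seqs, translate_cds, character(1))
  for (e in seq_len(nrow(sim$tree$edge))) {
    pa <- aa_nodes[[sim$tree$edge[e, 1]]]
    ch <- aa_nodes[[sim$tree$edge[e, 2]]]
    d <- which(strsplit(pa, "")[[1]] != strsplit(ch, "")[[1]])
    if (length(d)) truth[[e]] <- paste(sim$tree$edge[e, 2], d,
                                       substring(ch, d, d))
  }
  truth <- unlist(truth)
  found <- paste(got$child, got$site, got$to)
  expect_gte(mean(truth %in% found), 0.9)
})

test_that("convergent and divergent sites follow the definitions", {
  tr <- tree4()
  a <- match("A", tr$tip.label); c_ <- match("C", tr$tip.label)
  ev <- data.frame(child = c(a, c_, a, c_, a),
                   parent = 0L, site = c(12L, 12L, 30L, 30L, 44L),
                   from = c("T", "T", "T", "T", "G"),
                   to = c("S", "S", "S", "N", "A"))
  cv <- detect_convergence(ev, tr, "A", "C")
  expect_equal(cv$convergent$site, 12L)
  expect_equal(cv$divergent$site, 30L)
  expect_equal(cv$n_shared, cv$n_convergent + cv$n_divergent)
  # symmetric in the branch pair
  cv2 <- detect_convergence(ev, tr, "C", "A")
  expect_equal(cv2$convergent$site, cv$convergent$site)
  expect_equal(cv2$n_divergent, cv$n_divergent)
  # disjoint changed-site sets: nothing shared
  ev2 <- ev[c(1, 4), ]
  ev2$site <- c(1L, 2L)
  cv3 <- detect_convergence(ev2, tr, "A", "C")
  expect_equal(cv3$n_shared, 0L)
  # nested branches are rejected
  root_child <- tr$edge[tr$edge[, 1] == 5 & tr$edge[, 2] > 4, 2][1]
  expect_error(detect_convergence(ev, tr, root_child, "A"), "nested|ancestral")
  expect_error(detect_convergence(ev, tr, "A", "A"), "distinct")
})
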