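# Maximum-likelihood fitting of Goldman-Yang codon models on a fixed tree:
# one-ratio (M0), two-ratio (foreground/background), free-ratio branch models
# and the M1a/M2a/M7/M8 site-mixture models, with likelihood-ratio tests.
#
# The likelihood is computed by Felsenstein pruning over compressed codon
# site patterns (see pruning.R). Site-mixture models sum the per-site
# likelihood over omega classes with class weights. Optimisation alternates
# bounded quasi-Newton updates of the substitution parameters with Brent
# line-searches on each branch length, using cached inside/outside partials
# so a one-branch profile costs a single matrix product.

MODEL_IDS <- c("M0", "two_ratio", "free_ratio", "M1a", "M2a", "M7", "M8")

normalize_model_id <- function(model) {
  m <- gsub("-", "_", model[1], fixed = TRUE)
  m <- switch(tolower(m),
              "m0" = , "one_ratio" = "M0",
              "two_ratio" = "two_ratio",
              "free_ratio" = "free_ratio",
              "m1a" = "M1a", "m2a" = "M2a", "m7" = "M7", "m8" = "M8",
              stop("unknown model: ", model))
  m
}

# --- data preparation ------------------------------------------------------

codon_fit_data <- function(aln, tree, freq = "F1x4", freqs = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  validate_tree(tree)
  code <- aln$code
  cm <- codon_matrix(aln)
  st <- code$sense_codons
  idx <- matrix(match(cm, st), nrow = nrow(cm), dimnames = dimnames(cm))
  pat <- compress_patterns(idx)
  if (is.null(freqs)) freqs <- codon_freqs(aln, method = freq, code = code)
  eng <- lik_engine(tree, pat$idx, nstate = length(st), weights = pat$weights)
  list(eng = eng, pi = unname(freqs[st]), freqs = freqs, code = code,
       pattern_of_site = pat$pattern_of_site, n_sites = ncol(idx),
       freq_method = freq)
}

resolve_foreground <- function(tree_po, foreground) {
  # -> integer child-node ids on the postorder tree
  if (is.null(foreground)) stop("two-ratio model needs a foreground")
  if (is.character(foreground) && length(foreground) == 1L &&
      !foreground %in% tree_po$tip.label) {
    return(tagged_branches(tree_po, foreground))
  }
  if (is.character(foreground)) return(edges_for_tips(tree_po, foreground))
  if (is.logical(foreground)) {
    stopifnot(length(foreground) == nrow(tree_po$edge))
    return(tree_po$edge[foreground, 2])
  }
  as.integer(foreground)  # child node ids
}

# --- model parameterisation ------------------------------------------------

# Each model is described by a transformed parameter vector theta with box
# bounds, and a builder mapping (theta, branch structure) -> mixture classes.
# A "class" is list(weight, eigs = list of rev_eigen, edge_eig = int per edge).

theta_spec <- function(model, nedge, egroup, ncat, init = list()) {
  gi <- function(nm, def) if (!is.null(init[[nm]])) init[[nm]] else def
  lk <- log(gi("kappa", 2))
  lw <- function(w) log(w)
  sp <- switch(model,
    M0 = list(names = c("lkappa", "lomega"),
              init = c(lk, lw(gi("omega", 0.4))),
              lower = c(log(0.05), log(1e-4)),
              upper = c(log(50), log(50))),
    two_ratio = list(names = c("lkappa", "lomega_bg", "lomega_fg"),
              init = c(lk, lw(gi("omega", 0.2)), lw(gi("omega_fg", 0.4))),
              lower = c(log(0.05), log(1e-4), log(1e-4)),
              upper = c(log(50), log(50), log(50))),
    free_ratio = list(names = c("lkappa", paste0("lomega_e", seq_len(nedge))),
              init = c(lk, rep(lw(gi("omega", 0.3)), nedge)),
              lower = c(log(0.05), rep(log(1e-4), nedge)),
              upper = c(log(50), rep(log(50), nedge))),
    M1a = list(names = c("lkappa", "a_p0", "a_w0"),
              init = c(lk, stats::qlogis(gi("p0", 0.8)), stats::qlogis(gi("omega0", 0.2))),
              lower = c(log(0.05), -15, -15),
              upper = c(log(50), 15, 15)),
    M2a = list(names = c("lkappa", "a_p0", "a_p1", "a_w0", "x_w2"),
              init = c(lk, stats::qlogis(gi("p0", 0.7)), stats::qlogis(gi("p1c", 0.6)),
                       stats::qlogis(gi("omega0", 0.2)), log(gi("omega2", 1.5) - 1)),
              lower = c(log(0.05), -15, -15, -15, -20),
              upper = c(log(50), 15, 15, 15, log(49))),
    M7 = list(names = c("lkappa", "l_p", "l_q"),
              init = c(lk, log(gi("p", 0.5)), log(gi("q", 1.5))),
              lower = c(log(0.05), log(0.005), log(0.005)),
              upper = c(log(50), log(99), log(99))),
    M8 = list(names = c("lkappa", "a_p0", "l_p", "l_q", "a_ws"),
              init = c(lk, stats::qlogis(gi("p0", 0.9)), log(gi("p", 0.5)),
                       log(gi("q", 1.5)), stats::qlogis((gi("omega_s", 2) - 1) / 49)),
              lower = c(log(0.05), -15, log(0.005), log(0.005), -15),
              upper = c(log(50), 15, log(99), log(99), 15)),
    stop("unknown model ", model))
  sp$model <- model
  sp$egroup <- egroup
  sp$ncat <- ncat
  sp
}

theta_estimates <- function(sp, theta, edge_names = NULL) {
  p <- stats::setNames(theta, sp$names)
  out <- list(kappa = exp(p[["lkappa"]]))
  switch(sp$model,
    M0 = { out$omega <- exp(p[["lomega"]]) },
    two_ratio = {
      out$omega <- c(background = exp(p[["lomega_bg"]]),
                     foreground = exp(p[["lomega_fg"]]))
    },
    free_ratio = {
      w <- exp(p[grep("^lomega_e", sp$names)])
      names(w) <- edge_names
      out$omega <- w
    },
    M1a = {
      p0 <- stats::plogis(p[["a_p0"]])
      out$proportions <- c(p0 = p0, p1 = 1 - p0)
      out$omega <- c(omega0 = stats::plogis(p[["a_w0"]]), omega1 = 1)
    },
    M2a = {
      p0 <- stats::plogis(p[["a_p0"]])
      p1 <- (1 - p0) * stats::plogis(p[["a_p1"]])
      out$proportions <- c(p0 = p0, p1 = p1, p2 = 1 - p0 - p1)
      out$omega <- c(omega0 = stats::plogis(p[["a_w0"]]), omega1 = 1,
                     omega2 = 1 + exp(p[["x_w2"]]))
    },
    M7 = { out$beta <- c(p = exp(p[["l_p"]]), q = exp(p[["l_q"]])) },
    M8 = {
      out$proportions <- c(p0 = stats::plogis(p[["a_p0"]]))
      out$beta <- c(p = exp(p[["l_p"]]), q = exp(p[["l_q"]]))
      out$omega <- c(omega_s = 1 + 49 * stats::plogis(p[["a_ws"]]))
    })
  out
}

beta_categories <- function(p, q, ncat) {
  # extreme shapes near the optimiser bounds trigger harmless qbeta accuracy
  # warnings; the discretised categories remain a valid mixture
  suppressWarnings(stats::qbeta((seq_len(ncat) - 0.5) / ncat, p, q))
}

build_classes <- function(sp, theta, pi, code, nedge) {
  est <- theta_estimates(sp, theta)
  kappa <- est$kappa
  ones <- rep(1L, nedge)
  if (sp$model %in% c("M0", "two_ratio", "free_ratio")) {
    omegas <- switch(sp$model,
      M0 = est$omega,
      two_ratio = unname(est$omega),
      free_ratio = unname(est$omega))
    ngr <- length(omegas)
    eigs <- lapply(omegas, function(w)
      rev_eigen(codon_rate_matrix(kappa, w, freqs = pi, code = code,
                                  scale = "expected"), pi))
    edge_eig <- if (sp$model == "M0") ones else
      if (sp$model == "two_ratio") sp$egroup else seq_len(nedge)
    return(list(list(weight = 1, eigs = eigs, edge_eig = edge_eig)))
  }
  # site-mixture models: one omega per class, shared across branches,
  # generator scaled by the mixture-average substitution rate
  if (sp$model == "M1a") {
    w <- unname(est$omega); pr <- unname(est$proportions)
  } else if (sp$model == "M2a") {
    w <- unname(est$omega); pr <- unname(est$proportions)
  } else if (sp$model == "M7") {
    w <- beta_categories(est$beta[["p"]], est$beta[["q"]], sp$ncat)
    pr <- rep(1 / sp$ncat, sp$ncat)
  } else { # M8
    w <- c(beta_categories(est$beta[["p"]], est$beta[["q"]], sp$ncat),
           est$omega[["omega_s"]])
    p0 <- est$proportions[["p0"]]
    pr <- c(rep(p0 / sp$ncat, sp$ncat), 1 - p0)
  }
  Qs <- lapply(w, function(wk)
    codon_rate_matrix(kappa, wk, freqs = pi, code = code, scale = "none"))
  rates <- vapply(Qs, function(Q) attr(Q, "rate"), numeric(1))
  R <- sum(pr * rates)
  lapply(seq_along(w), function(k) {
    list(weight = pr[k], eigs = list(rev_eigen(Qs[[k]] / R, pi)),
         edge_eig = rep(1L, nedge))
  })
}

# --- likelihood evaluation --------------------------------------------------

build_P <- function(cl, bl) {
  lapply(seq_along(bl), function(e) trans_prob(cl$eigs[[cl$edge_eig[e]]], bl[e]))
}

classes_site_loglik <- function(eng, classes, bl, pi) {
  C <- length(classes)
  llmat <- matrix(0, C, eng$npat)
  for (k in seq_len(C)) {
    ins <- inside_pass(eng, build_P(classes[[k]], bl))
    llmat[k, ] <- root_site_loglik(eng, ins, pi)
  }
  if (C == 1L) return(llmat[1, ])
  wts <- vapply(classes, `[[`, numeric(1), "weight")
  logsumexp_rows(llmat + log(wts))
}

classes_loglik <- function(eng, classes, bl, pi) {
  sum(eng$weights * classes_site_loglik(eng, classes, bl, pi))
}

sweep_branches <- function(eng, classes, bl, pi, lower = 1e-8, upper = 15) {
  C <- length(classes)
  lw <- log(vapply(classes, `[[`, numeric(1), "weight"))
  for (e in seq_len(eng$nedge)) {
    pres <- lapply(classes, function(cl) {
      P <- build_P(cl, bl)
      ins <- inside_pass(eng, P)
      outs <- outside_pass(eng, P, ins, pi)
      list(cl = cl, ins = ins, outs = outs)
    })
    ch <- eng$edge[e, 2]
    prof <- function(t) {
      llmat <- matrix(0, C, eng$npat)
      for (k in seq_len(C)) {
        pr <- pres[[k]]
        Pe <- trans_prob(pr$cl$eigs[[pr$cl$edge_eig[e]]], t)
        v <- colSums(pr$outs$above[[e]] * (Pe %*% pr$ins$part[[ch]]))
        llmat[k, ] <- log(pmax(v, 1e-300)) +
          pr$outs$aslog[[e]] + pr$ins$slog[[ch]]
      }
      llv <- if (C == 1L) llmat[1, ] else logsumexp_rows(llmat + lw)
      sum(eng$weights * llv)
    }
    cur <- prof(bl[e])
    opt <- stats::optimize(prof, c(lower, upper), maximum = TRUE, tol = 1e-7)
    if (opt$objective > cur) bl[e] <- opt$maximum
  }
  bl
}

#' Fit a codon substitution model by maximum likelihood
#'
#' Fits a Goldman-Yang codon model on a fixed tree topology. Supported
#' parameterisations: `"M0"` (one dN/dS ratio for the whole tree),
#' `"two_ratio"` (a foreground/background ratio pair), `"free_ratio"` (an
#' independent ratio per branch; practical on small trees only), and the
#' site-mixture models `"M1a"` (nearly neutral), `"M2a"` (positive
#' selection), `"M7"` (beta) and `"M8"` (beta & omega). Nested pairs are
#' compared with [lrt()].
#'
#' Branch lengths (expected substitutions per codon site) are re-optimised by
#' default, starting from the input tree's lengths; with
#' `fix_branch_lengths = TRUE` they are held at the input values, the common
#' practice when the tree was estimated under M0 first.
#'
#' @param aln A [codon_alignment()], indel-stripped (see
#'   [strip_indel_codons()]); stray ambiguous codons are treated as missing
#'   data.
#' @param tree An [ape::phylo] tree whose tips match the alignment. For
#'   `foreground = "<tag>"` the tree must carry branch tags from
#'   [label_branches()].
#' @param model Model identifier (see above; `"one_ratio"` is an alias for
#'   `"M0"`, hyphens are tolerated).
#' @param foreground For `"two_ratio"`: a branch-tag name, a character vector
#'   of tip labels (the implied branches via [edges_for_tips()]), or integer
#'   child-node ids.
#' @param freq Codon frequency model: `"F1x4"` (default), `"F3x4"`, or
#'   `"uniform"`; alternatively supply `freqs` directly.
#' @param freqs Optional named codon frequency vector over the sense codons.
#' @param fix_branch_lengths Hold branch lengths at the input values.
#' @param init Optional named list of starting values (`kappa`, `omega`, ...).
#' @param n_starts Number of optimisation starts (default 3; deterministic
#'   spread around the initial values, all starts recorded in the result).
#' @param ncat Number of discrete beta categories for M7/M8 (default 10).
#' @param max_rounds Maximum alternation rounds between substitution-parameter
#'   and branch-length optimisation.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param site_loglik Also return per-site log-likelihoods (for external
#'   topology tests).
#' @return Object of class `"codon_fit"` with elements `model`, `lnL`, `np`,
#'   `kappa`, `omega`, `proportions`, `beta`, `tree` (with fitted branch
#'   lengths), `freqs`, `convergence`, `starts`, and optionally
#'   `site_loglik`.
#' @seealso [lrt()], [codon_loglik()], [simulate.codon_fit()]
#' @export
fit_codon_model <- function(aln, tree, model = "M0", foreground = NULL,
                            freq = c("F1x4", "F3x4", "uniform"), freqs = NULL,
                            fix_branch_lengths = FALSE, init = list(),
                            n_starts = 3, ncat = 10, max_rounds = 30,
                            tol = 1e-8, site_loglik = FALSE) {
  model <- normalize_model_id(model)
  freq <- match.arg(freq)
  dat <- codon_fit_data(aln, tree, freq = freq, freqs = freqs)
  eng <- dat$eng
  nedge <- eng$nedge

  egroup <- rep(1L, nedge)
  if (model == "two_ratio") {
    fg_children <- resolve_foreground(eng$tree, foreground)
    bad <- setdiff(fg_children, eng$edge[, 2])
    if (length(bad)) stop("foreground child node(s) not in tree: ",
                          paste(bad, collapse = ", "))
    egroup[eng$edge[, 2] %in% fg_children] <- 2L
    if (all(egroup == 2L)) warning("every branch is foreground")
  }
  sp <- theta_spec(model, nedge, egroup, ncat, init)

  bl0 <- eng$tree$edge.length
  if (is.null(bl0)) bl0 <- rep(0.1, nedge)
  bl0 <- pmax(bl0, 1e-8)

  run_one <- function(theta0, bl) {
    ll_old <- -Inf
    theta <- theta0
    rounds <- 0L
    converged <- FALSE
    repeat {
      rounds <- rounds + 1L
      opt <- stats::optim(theta, function(p) {
        cls <- build_classes(sp, p, dat$pi, dat$code, nedge)
        -classes_loglik(eng, cls, bl, dat$pi)
      }, method = "L-BFGS-B", lower = sp$lower, upper = sp$upper,
      control = list(maxit = 300))
      theta <- opt$par
      ll <- -opt$value
      if (!fix_branch_lengths) {
        cls <- build_classes(sp, theta, dat$pi, dat$code, nedge)
        bl <- sweep_branches(eng, cls, bl, dat$pi)
        ll <- classes_loglik(eng, cls, bl, dat$pi)
      }
      if (ll - ll_old <= max(tol, 1e-8)) { converged <- TRUE; break }
      ll_old <- ll
      if (rounds >= max_rounds) break
      if (fix_branch_lengths) { converged <- TRUE; break }
    }
    list(theta = theta, bl = bl, lnL = ll, rounds = rounds,
         converged = converged)
  }

  offsets <- c(0, 0.7, -0.7, 1.4, -1.4)
  starts <- lapply(seq_len(max(1L, n_starts)), function(s) {
    th <- pmin(pmax(sp$init + offsets[((s - 1L) %% length(offsets)) + 1L],
                    sp$lower), sp$upper)
    th
  })
  runs <- lapply(starts, run_one, bl = bl0)
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "lnL"))]]
  if (!best$converged)
    warning("optimisation did not reach tolerance after ", best$rounds,
            " rounds; result flagged as non-converged")

  edge_names <- {
    ch <- eng$edge[, 2]
    ifelse(ch <= eng$ntip, eng$tree$tip.label[ch], paste0("node", ch))
  }
  est <- theta_estimates(sp, best$theta, edge_names = edge_names)
  np <- length(sp$init) + if (fix_branch_lengths) 0L else nedge

  fit_tree <- eng$tree
  fit_tree$edge.length <- best$bl

  out <- structure(list(
    model = model, lnL = best$lnL, np = np,
    kappa = unname(est$kappa), omega = est$omega,
    proportions = est$proportions, beta = est$beta,
    tree = fit_tree, foreground = if (model == "two_ratio")
      eng$edge[egroup == 2L, 2] else NULL,
    freqs = dat$freqs, freq_method = dat$freq_method,
    n_codons = dat$n_sites, n_patterns = eng$npat,
    fix_branch_lengths = fix_branch_lengths,
    convergence = best$converged, rounds = best$rounds,
    starts = starts, theta = best$theta, ncat = ncat,
    code_id = dat$code$id
  ), class = "codon_fit")

  if (site_loglik) {
    cls <- build_classes(sp, best$theta, dat$pi, dat$code, nedge)
    sl <- classes_site_loglik(eng, cls, best$bl, dat$pi)
    out$site_loglik <- sl[dat$pattern_of_site]
  }
  out
}

#' Evaluate the codon-model log-likelihood at given parameters
#'
#' Direct likelihood evaluation (no optimisation) of a one-class
#' Goldman-Yang model: scalar `omega` for the whole tree, or a named vector
#' of per-branch omegas indexed by child node id. Useful for model-nesting
#' checks and per-site log-likelihood export at externally chosen parameters.
#'
#' @inheritParams fit_codon_model
#' @param kappa Transition/transversion ratio.
#' @param omega Scalar, or named numeric vector (names = child node ids).
#' @param per_site Return per-site log-likelihoods as well.
#' @return List with `loglik` and optionally `site_loglik`.
#' @export
codon_loglik <- function(aln, tree, kappa, omega,
                         freq = c("F1x4", "F3x4", "uniform"), freqs = NULL,
                         per_site = FALSE) {
  freq <- match.arg(freq)
  dat <- codon_fit_data(aln, tree, freq = freq, freqs = freqs)
  eng <- dat$eng
  nedge <- eng$nedge
  if (length(omega) == 1L && is.null(names(omega))) {
    omegas <- unname(omega); edge_eig <- rep(1L, nedge)
  } else {
    if (is.null(names(omega))) stop("per-branch omega must be named by child node id")
    ids <- as.integer(names(omega))
    edge_eig <- match(eng$edge[, 2], ids)
    if (anyNA(edge_eig)) stop("omega missing for child node(s): ",
                              paste(eng$edge[is.na(edge_eig), 2], collapse = ", "))
    omegas <- unname(omega)
  }
  eigs <- lapply(omegas, function(w)
    rev_eigen(codon_rate_matrix(kappa, w, freqs = dat$pi, code = dat$code,
                                scale = "expected"), dat$pi))
  cls <- list(list(weight = 1, eigs = eigs, edge_eig = edge_eig))
  bl <- eng$tree$edge.length
  sl <- classes_site_loglik(eng, cls, bl, dat$pi)
  out <- list(loglik = sum(eng$weights * sl))
  if (per_site) out$site_loglik <- sl[dat$pattern_of_site]
  out
}

#' Likelihood-ratio test between nested codon-model fits
#'
#' Computes `2 * (lnL_general - lnL_restricted)` and the chi-square
#' upper-tail p-value. Degrees of freedom default to the difference in
#' parameter counts (standard pairings: M0 vs two-ratio, 1; M1a vs M2a, 2;
#' M7 vs M8, 2; M0 vs free-ratio, branches - 1).
#'
#' @param general,restricted `"codon_fit"` objects, `general` nesting
#'   `restricted`.
#' @param df Degrees of freedom (default `general$np - restricted$np`).
#' @param tol Tolerance on a negative `2*delta` before a convergence warning
#'   is raised.
#' @return Object of class `"codon_lrt"`: list with `twice_delta`, `df`,
#'   `p_value` and the two model ids.
#' @export
lrt <- function(general, restricted, df = NULL, tol = 1e-4) {
  stopifnot(inherits(general, "codon_fit"), inherits(restricted, "codon_fit"))
  if (is.null(df)) df <- general$np - restricted$np
  if (df < 0) stop("general model has fewer parameters than restricted; swap arguments?")
  td <- 2 * (general$lnL - restricted$lnL)
  if (td < -tol)
    warning("restricted lnL exceeds general lnL by more than the tolerance; ",
            "likely non-convergence of the general fit")
  p <- stats::pchisq(max(td, 0), df = max(df, 1L), lower.tail = FALSE)
  if (df == 0) p <- NA_real_
  structure(list(twice_delta = td, df = df, p_value = p,
                 general = general$model, restricted = restricted$model),
            class = "codon_lrt")
}

#' @export
print.codon_lrt <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: 2*delta = %.4f, df = %d, p = %.3g\n",
              x$restricted, x$general, x$twice_delta, x$df, x$p_value))
  invisible(x)
}

# --- codon_fit methods ------------------------------------------------------

#' @export
print.codon_fit <- function(x, ...) {
  cat("Codon model fit:", x$model, "\n")
  cat(sprintf("  lnL = %.4f  np = %d  (%d codons, %d patterns)\n",
              x$lnL, x$np, x$n_codons, x$n_patterns))
  cat(sprintf("  kappa = %.4f\n", x$kappa))
  if (!is.null(x$omega)) {
    if (length(x$omega) <= 6)
      cat("  omega:", paste(sprintf("%s=%.4f", names2(x$omega), x$omega),
                            collapse = "  "), "\n")
    else
      cat("  omega: per-branch (", length(x$omega), "values, range",
          sprintf("%.3f-%.3f", min(x$omega), max(x$omega)), ")\n")
  }
  if (!is.null(x$proportions))
    cat("  proportions:", paste(sprintf("%s=%.4f", names(x$proportions),
                                        x$proportions), collapse = "  "), "\n")
  if (!is.null(x$beta))
    cat(sprintf("  beta(p = %.4f, q = %.4f)\n", x$beta[["p"]], x$beta[["q"]]))
  if (!x$convergence) cat("  WARNING: non-converged fit\n")
  invisible(x)
}

names2 <- function(x) {
  nm <- names(x)
  if (is.null(nm)) rep("omega", length(x)) else nm
}

#' @export
summary.codon_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  codon frequencies: %s;  branch lengths %s;  %d rounds\n",
              object$freq_method,
              if (object$fix_branch_lengths) "fixed" else "optimised",
              object$rounds))
  cat(sprintf("  tree length = %.4f expected substitutions/codon\n",
              sum(object$tree$edge.length)))
  invisible(object)
}

#' @export
coef.codon_fit <- function(object, ...) {
  out <- c(kappa = object$kappa)
  if (!is.null(object$omega)) {
    w <- object$omega
    names(w) <- paste0("omega.", names2(w))
    out <- c(out, w)
  }
  if (!is.null(object$proportions)) {
    p <- object$proportions
    names(p) <- paste0("prop.", names(p))
    out <- c(out, p)
  }
  if (!is.null(object$beta)) {
    b <- object$beta
    names(b) <- paste0("beta.", names(b))
    out <- c(out, b)
  }
  out
}

#' @export
logLik.codon_fit <- function(object, ...) {
  structure(object$lnL, df = object$np, nobs = object$n_codons,
            class = "logLik")
}
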