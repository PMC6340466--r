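# End-to-end orchestration: simulate/load -> scan -> tune -> reconstruct ->
# dN/dS -> date -> converge, with per-stage status, seeded determinism and a
# checksummed output manifest.

default_config <- function() {
  list(
    seed = 1L,
    outdir = tempfile("opsinevol_run_"),
    simulate = list(preset = "pteropodid_like", n_codons = 150,
                    rate = 0.005, kappa = 2),
    input = NULL,   # list(alignment=, tree=, annotation=) to skip simulation
    stages = list(scan = TRUE, tune = TRUE, ancestral = TRUE, dnds = TRUE,
                  dating = TRUE, converge = TRUE),
    tune = list(gene = "LWS", reference = "first"),
    dnds = list(models = c("M0", "two_ratio"), foreground = "auto_mixed",
                freq = "F1x4", n_starts = 1, max_rounds = 4, tol = 1e-4),
    converge = list(branch_a = NULL, branch_b = NULL)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' @param config A named list of overrides, or the path of a YAML file.
#' @return The merged configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_config(), config)
  if (!is.null(cfg$input)) {
    for (f in unlist(cfg$input))
      if (!file.exists(f)) stop("input file not found: ", f)
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the opsin molecular-evolution pipeline
#'
#' Executes the analysis stages in dependency order on either a simulated
#' preset fixture (default) or user-supplied alignment/tree/annotation files:
#' lesion scan and placement, spectral-tuning profiles, ancestral
#' reconstruction, codon-model fits with LRTs, sudden-relaxation loss dating
#' and convergence detection. A stage failure halts its dependents but not
#' independent stages. All outputs are TSV files in `outdir`; the run is a
#' pure function of (inputs, config, seed).
#'
#' @param config See [pipeline_config()].
#' @return Object of class `"run_report"`: per-stage status and warnings,
#'   the output manifest with md5 checksums, seed, package version and
#'   config hash.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  stages <- list()
  outputs <- character()
  note <- function(stage, status, warnings = character(), detail = "") {
    stages[[stage]] <<- list(status = status, warnings = warnings,
                             detail = detail)
  }
  run_stage <- function(stage, enabled, deps_ok, fun) {
    if (!isTRUE(enabled)) { note(stage, "skipped"); return(NULL) }
    if (!deps_ok) { note(stage, "skipped-dependency"); return(NULL) }
    warns <- character()
    res <- tryCatch(
      withCallingHandlers(fun(), warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        note(stage, "failed", warns, conditionMessage(e))
        NULL
      })
    if (is.null(stages[[stage]])) note(stage, "done", warns)
    res
  }
  emit <- function(df, name) {
    path <- file.path(cfg$outdir, name)
    write_tsv_det(df, path, header_lines = paste0("seed=", cfg$seed))
    outputs <<- c(outputs, path)
    path
  }

  # --- inputs -------------------------------------------------------------
  preset <- NULL
  inputs <- run_stage("input", TRUE, TRUE, function() {
    if (!is.null(cfg$input)) {
      aln <- codon_alignment(read_fasta(cfg$input$alignment, to_upper = TRUE))
      tree <- read_newick(cfg$input$tree)
      tags <- if (!is.null(cfg$input$annotation))
        read_annotation(cfg$input$annotation) else NULL
      list(aln = aln, tree = tree, tags = tags, truth = NULL)
    } else {
      preset <<- opsin_preset(cfg$simulate$preset)
      sim <- simulate_pseudogenization(
        preset$tree, preset$loss, n_codons = cfg$simulate$n_codons,
        kappa = cfg$simulate$kappa, omega = preset$background_omega,
        rate = cfg$simulate$rate, seed = cfg$seed)
      write_fasta(sim$alignment$seqs, file.path(cfg$outdir, "alignment.fasta"))
      write_newick(sim$tree, file.path(cfg$outdir, "tree.nwk"))
      outputs <<- c(outputs, file.path(cfg$outdir, c("alignment.fasta", "tree.nwk")))
      emit(sim$truth, "simulation_truth.tsv")
      list(aln = sim$alignment, tree = sim$tree, tags = preset$tags,
           truth = sim$truth)
    }
  })
  if (is.null(inputs))
    return(finish_report(cfg, stages, outputs))

  # --- lesion scan ----------------------------------------------------------
  scan <- run_stage("scan", cfg$stages$scan, TRUE, function() {
    sc <- scan_orf(inputs$aln)
    emit(sc$lesions, "lesions.tsv")
    emit(sc$calls, "functionality_calls.tsv")
    placed <- place_lesions(sc, inputs$tree)
    emit(placed, "lesion_origins.tsv")
    list(scan = sc, placed = placed)
  })

  # --- spectral tuning -------------------------------------------------------
  run_stage("tune", cfg$stages$tune, TRUE, function() {
    prof <- tuning_profile(inputs$aln, gene = cfg$tune$gene,
                           reference = cfg$tune$reference)
    emit(prof, "tuning_profiles.tsv")
    prof
  })

  # --- ancestral reconstruction ---------------------------------------------
  anc <- run_stage("ancestral", cfg$stages$ancestral, TRUE, function() {
    stripped <- strip_indel_codons(inputs$aln)
    sub_tree <- inputs$tree
    sub_tree$edge.length <- pmax(sub_tree$edge.length /
                                   max(sum(sub_tree$edge.length), 1), 1e-6)
    rec <- marginal_ml_reconstruction(sub_tree, stripped)
    ev <- enumerate_substitutions(rec)
    emit(ev, "substitution_events.tsv")
    anc_seqs <- apply(rec$states, 1, function(x)
      paste(ifelse(is.na(x), "X", x), collapse = ""))
    write_fasta(anc_seqs, file.path(cfg$outdir, "ancestral_sequences.fasta"))
    outputs <<- c(outputs, file.path(cfg$outdir, "ancestral_sequences.fasta"))
    list(rec = rec, events = ev)
  })

  # --- codon-model fits ------------------------------------------------------
  dnds <- run_stage("dnds", cfg$stages$dnds, TRUE, function() {
    stripped <- strip_indel_codons(inputs$aln)
    tree <- inputs$tree
    fg <- cfg$dnds$foreground
    if (identical(fg, "auto_mixed")) {
      if (is.null(scan) || !any(!is.na(scan$placed$origin_child)))
        fg <- NULL
      else fg <- unique(scan$placed$origin_child[!is.na(scan$placed$origin_child)])
    } else if (is.character(fg) && !is.null(inputs$tags)) {
      tree <- label_branches(tree, inputs$tags)
    }
    fits <- list()
    for (m in cfg$dnds$models) {
      mid <- normalize_model_id(m)
      if (mid == "two_ratio" && is.null(fg)) next
      fits[[mid]] <- fit_codon_model(
        stripped, tree, model = mid,
        foreground = if (mid == "two_ratio") fg else NULL,
        freq = cfg$dnds$freq, n_starts = cfg$dnds$n_starts,
        max_rounds = cfg$dnds$max_rounds, tol = cfg$dnds$tol)
    }
    comparisons <- NULL
    if (all(c("M0", "two_ratio") %in% names(fits)))
      comparisons <- data.frame(general = "two_ratio", restricted = "M0")
    tab <- render_model_table(fits, comparisons)
    emit(tab, "model_fits.tsv")
    list(fits = fits, table = tab, foreground = fg)
  })

  # --- loss dating -----------------------------------------------------------
  run_stage("dating", cfg$stages$dating,
            !is.null(dnds) && !is.null(scan), function() {
    origins <- scan$placed
    cats <- categorize_branches(inputs$tree, origins)
    emit(cats, "branch_categories.tsv")
    fits <- dnds$fits
    if (!"two_ratio" %in% names(fits))
      stop("dating needs a two-ratio fit with the mixed branches foreground")
    wf <- fits$two_ratio$omega[["background"]]
    wm <- fits$two_ratio$omega[["foreground"]]
    res <- resolve_mixed(inputs$tree, cats, omega_f = wf, omega_m = wm)
    emit(res, "loss_dating.tsv")
    res
  })

  # --- convergence -----------------------------------------------------------
  run_stage("converge", cfg$stages$converge, !is.null(anc), function() {
    ba <- cfg$converge$branch_a
    bb <- cfg$converge$branch_b
    if (is.null(ba) || is.null(bb)) {
      if (is.null(preset)) stop("branch pair must be configured for non-preset runs")
      hdc <- preset$tags$taxon[preset$tags$hdc]
      cave <- preset$tags$taxon[preset$tags$cave]
      ba <- hdc; bb <- cave
    }
    cv <- detect_convergence(anc$events, anc$rec$tree, ba, bb)
    df <- data.frame(
      site = c(cv$convergent$site, cv$divergent$site),
      type = c(rep("convergent", cv$n_convergent),
               rep("divergent", cv$n_divergent)))
    emit(df, "convergence_report.tsv")
    cv
  })

  finish_report(cfg, stages, outputs)
}

finish_report <- function(cfg, stages, outputs) {
  manifest <- data.frame(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs)))
  cfg_txt <- yaml::as.yaml(cfg[setdiff(names(cfg), "outdir")])
  tmp <- tempfile()
  writeLines(cfg_txt, tmp)
  structure(list(stages = stages, manifest = manifest, seed = cfg$seed,
                 outdir = cfg$outdir,
                 version = as.character(utils::packageVersion("opsinevol")),
                 config_hash = unname(tools::md5sum(tmp)),
                 config = cfg),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("opsinevol pipeline run (seed ", x$seed, ", v", x$version, ")\n", sep = "")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-10s %s", nm, st$status))
    if (length(st$warnings)) cat("  [", length(st$warnings), "warning(s) ]")
    if (nzchar(st$detail)) cat("  -", st$detail)
    cat("\n")
  }
  cat("  outputs:", nrow(x$manifest), "file(s) in", x$outdir, "\n")
  invisible(x)
}

#' Render a model-fit comparison table
#'
#' Formats a battery of codon-model fits into the conventional
#' selective-pressure table: one row per model with its omega estimates,
#' log-likelihood and parameter count, plus the likelihood-ratio comparisons
#' (`"i vs j"`, 2*delta, p-value).
#'
#' @param fits Named list of `"codon_fit"` objects.
#' @param comparisons Optional data.frame with columns `general`,
#'   `restricted` (names into `fits`).
#' @return Data.frame: model, omega, lnL, np, models_compared, twice_delta,
#'   p_value.
#' @export
render_model_table <- function(fits, comparisons = NULL) {
  stopifnot(length(fits) >= 1L, !is.null(names(fits)))
  fmt_omega <- function(fit) {
    if (!is.null(fit$omega) && length(fit$omega) <= 6) {
      nm <- names(fit$omega)
      if (is.null(nm)) return(sprintf("omega = %.4f", fit$omega))
      paste(sprintf("%s = %.4f", nm, fit$omega), collapse = "; ")
    } else if (!is.null(fit$omega)) {
      "variable by branch"
    } else if (!is.null(fit$beta)) {
      sprintf("beta(p = %.4f, q = %.4f)", fit$beta[["p"]], fit$beta[["q"]])
    } else ""
  }
  rows <- data.frame(
    model = names(fits),
    omega = vapply(fits, fmt_omega, character(1)),
    lnL = vapply(fits, `[[`, numeric(1), "lnL"),
    np = vapply(fits, `[[`, numeric(1), "np"),
    models_compared = "", twice_delta = NA_real_, p_value = NA_real_,
    stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  if (!is.null(comparisons)) {
    for (i in seq_len(nrow(comparisons))) {
      g <- comparisons$general[i]; r <- comparisons$restricted[i]
      tst <- lrt(fits[[g]], fits[[r]])
      j <- match(g, rows$model)
      rows$models_compared[j] <- sprintf("%d vs %d", match(r, rows$model), j)
      rows$twice_delta[j] <- tst$twice_delta
      rows$p_value[j] <- tst$p_value
    }
  }
  rows
}
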