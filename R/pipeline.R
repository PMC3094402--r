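#' Pipeline configuration
#'
#' Collects everything one analysis run needs.  Inputs can be in-memory
#' objects (a `"phylo"`, a `"trait_table"`, a climate matrix) or file paths
#' (Newick, trait CSV); paths are read on construction.
#'
#' @param tree a `"phylo"` or path to a Newick file.
#' @param traits a `"trait_table"` data frame or path to a trait CSV with
#'   columns `species,SVL,clutch` and optionally `CC1,CC2`.
#' @param climate optional locality-by-variable climate matrix (rownames =
#'   species); when given, CC scores are computed by [reduce_climate()] and
#'   override any CC columns in `traits`.
#' @param schemes branch-length schemes to screen.
#' @param models regression models to fit (`"OLS"` always uses no tree).
#' @param n_perm permutations for the signal test.
#' @param seed integer seed (mandatory).
#' @param alpha significance level for diagnostics and partial-F reporting.
#' @param out_dir optional directory for TSV output and the run log.
#' @return a `"run_config"` list.
#' @export
pipeline_config <- function(tree, traits, climate = NULL,
                            schemes = c("constant", "grafen", "pagel", "nee"),
                            models = c("OLS", "PGLS", "RegOU"),
                            n_perm = 999L, seed, alpha = 0.05,
                            out_dir = NULL) {
  if (missing(seed)) stop("a seed is required")
  if (is.character(tree)) tree <- read_phylogeny(tree)
  if (is.character(traits)) traits <- read_trait_csv(traits)
  validate_phylogeny(tree)
  models <- match.arg(models, c("OLS", "PGLS", "RegOU"), several.ok = TRUE)
  schemes <- match.arg(schemes,
                       c("constant", "grafen", "pagel", "nee", "as_given"),
                       several.ok = TRUE)
  structure(list(tree = tree, traits = traits, climate = climate,
                 schemes = schemes, models = models,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 alpha = alpha, out_dir = out_dir),
            class = "run_config")
}

#' Run the full comparative pipeline
#'
#' Reproduces the analysis shape of the study design: (1) screen every
#' candidate branch-length scheme with the contrast diagnostic on each
#' analyzed trait, retaining passers (with a warning, not a stop, when a
#' scheme fails -- and a fallback to all schemes if none pass); (2)
#' phylogenetic-signal reports per trait under each passing scheme; (3) the
#' regression continuum (OLS once, plus PGLS and RegOU under each passing
#' scheme) for the two models `clutch ~ SVL + CC1 + CC2` and
#' `SVL ~ CC1 + CC2`; (4) AIC model comparison per response; (5)
#' squared-change parsimony reconstructions of both traits plus the Fitch
#' step count for single- versus multi-egg clutches.  Species dropped from
#' any stage (missing values) are named in the log, never silent.
#'
#' @param config a [pipeline_config()].
#' @return a `"pipeline_result"` list with elements `diagnostics`,
#'   `passing_schemes`, `signal`, `fits`, `comparisons`, `ancestral`,
#'   `clutch_origins`, `exclusions`, `log`, `config`.  When
#'   `config$out_dir` is set, TSVs and `run.log` are written there via
#'   [render_tables()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  # log lines carry no wall-clock stamps so that identical (config, seed)
  # runs produce byte-identical output bundles
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  note("pipeline start, seed = ", config$seed)
  traits <- config$traits
  tree <- config$tree

  # -- climate reduction ----------------------------------------------------
  if (!is.null(config$climate)) {
    pca <- reduce_climate(config$climate)
    note("climate PCA: ", pca$retained, " component(s) retained")
    sc <- pca$scores
    idx <- match(traits$species, rownames(sc))
    if (anyNA(idx))
      stop("pipeline stage climate: no climate row for species ",
           paste(traits$species[is.na(idx)], collapse = ", "))
    for (j in seq_len(min(ncol(sc), 2L)))
      traits[[paste0("CC", j)]] <- sc[idx, j]
  } else {
    pca <- NULL
  }
  for (v in c("SVL", "clutch", "CC1", "CC2"))
    if (!v %in% names(traits))
      stop("pipeline stage input: trait table lacks column ", v)

  # complete cases, logged
  used <- stats::complete.cases(traits[, c("SVL", "clutch", "CC1", "CC2")])
  excl <- traits$species[!used]
  if (length(excl))
    note("excluded species (incomplete data): ", paste(excl, collapse = ", "))
  else note("no species excluded")
  traits <- traits[used, , drop = FALSE]
  tree <- ape::keep.tip(tree, traits$species)

  svl <- trait_vector(traits, "SVL")
  clutch <- trait_vector(traits, "clutch")
  if (sd(svl) == 0 || sd(clutch) == 0)
    stop("pipeline stage signal: degenerate (constant) trait; SVL sd = ",
         sd(svl), ", clutch sd = ", sd(clutch))

  # -- branch-length screening ---------------------------------------------
  diag_tab <- NULL
  trees <- Vs <- list()
  for (s in config$schemes) {
    tr_s <- assign_branch_lengths(tree, s)
    trees[[s]] <- tr_s
    Vs[[s]] <- phylo_covariance(tr_s)
    for (tn in c("SVL", "clutch")) {
      dg <- diagnose_branch_lengths(
        independent_contrasts(tr_s, if (tn == "SVL") svl else clutch),
        alpha = config$alpha)
      diag_tab <- rbind(diag_tab,
                        data.frame(scheme = s, trait = tn, r = dg$r, p = dg$p,
                                   pass = dg$pass))
    }
  }
  pass_by_scheme <- tapply(diag_tab$pass, diag_tab$scheme, all)
  passing <- config$schemes[config$schemes %in% names(pass_by_scheme)[pass_by_scheme]]
  for (s in setdiff(config$schemes, passing)) {
    warning("branch-length scheme '", s, "' failed the contrast diagnostic",
            call. = FALSE)
    note("scheme ", s, " FAILED diagnostics")
  }
  if (!length(passing)) {
    warning("no scheme passed the diagnostics; proceeding with all of them",
            call. = FALSE)
    note("no passing scheme; falling back to all schemes")
    passing <- config$schemes
  }
  note("passing schemes: ", paste(passing, collapse = ", "))

  # -- phylogenetic signal --------------------------------------------------
  signal <- list()
  for (tn in c("SVL", "clutch")) {
    x <- if (tn == "SVL") svl else clutch
    for (s in passing) {
      signal[[paste(tn, s, sep = "|")]] <-
        signal_permutation_test(x, Vs[[s]], n_perm = config$n_perm,
                                seed = config$seed + match(s, config$schemes))
    }
  }
  note("signal reports: ", length(signal))

  # -- regressions ----------------------------------------------------------
  model_specs <- list(
    clutch = list(y = clutch, X = as.matrix(traits[, c("SVL", "CC1", "CC2")])),
    SVL = list(y = svl, X = as.matrix(traits[, c("CC1", "CC2")]))
  )
  fits <- list(clutch = list(), SVL = list())
  for (resp in names(model_specs)) {
    y <- model_specs[[resp]]$y
    X <- model_specs[[resp]]$X
    rownames(X) <- traits$species
    if ("OLS" %in% config$models)
      fits[[resp]][["OLS|none"]] <- fit_ols(y, X)
    for (s in passing) {
      if ("PGLS" %in% config$models)
        fits[[resp]][[paste0("PGLS|", s)]] <- fit_pgls(y, X, Vs[[s]])
      if ("RegOU" %in% config$models)
        fits[[resp]][[paste0("RegOU|", s)]] <- fit_regou(y, X, Vs[[s]])
    }
  }
  comparisons <- lapply(fits, compare_models)
  note("fits: ", sum(lengths(fits)), "; best clutch model: ",
       comparisons$clutch$model[1L], " (", comparisons$clutch$scheme[1L], ")")

  # -- ancestral reconstruction --------------------------------------------
  anc_tree <- resolve_polytomies(trees[[passing[1L]]])
  ancestral <- list(
    SVL = squared_change_parsimony(anc_tree, svl, weighted = TRUE),
    clutch = squared_change_parsimony(anc_tree, clutch, weighted = TRUE)
  )
  clutch_origins <- count_state_origins(anc_tree, discretize_clutch(clutch))
  note("clutch single-egg origins (Fitch steps): ", clutch_origins)
  note("pipeline done")

  out <- structure(list(
    diagnostics = diag_tab, passing_schemes = passing, pca = pca,
    signal = signal, fits = fits, comparisons = comparisons,
    ancestral = ancestral, clutch_origins = clutch_origins,
    exclusions = excl, trees = trees, log = log_lines, config = config
  ), class = "pipeline_result")
  if (!is.null(config$out_dir)) render_tables(out, config$out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("comparative pipeline result\n")
  cat("  passing schemes:", paste(x$passing_schemes, collapse = ", "), "\n")
  cat("  signal reports:", length(x$signal), "\n")
  for (resp in names(x$comparisons)) {
    cmp <- x$comparisons[[resp]]
    cat(sprintf("  %s: best model %s (%s), AIC = %.2f\n",
                resp, cmp$model[1L], cmp$scheme[1L], cmp$AIC[1L]))
  }
  cat("  single-egg clutch origins (Fitch steps):", x$clutch_origins, "\n")
  invisible(x)
}

#' Write the result bundle as publication-shaped TSV tables
#'
#' Emits `table_pca.tsv` (loadings and eigenvalue rows, when climate input
#' was reduced), `table_signal.tsv` (trait, branches, MSEtree, MSEstar, K,
#' P, lnL tree/star), one `table_regression_<response>.tsv` per response
#' (branch length, model, slopes, per-term F, AIC, AICc, LnL, d, with the
#' within-2-AIC support flag), `ancestral_<trait>.tsv` node values, and
#' `run.log`.  Every table carries a provenance header line (seed, package
#' version, schemes).
#'
#' @param result a `"pipeline_result"`.
#' @param out_dir output directory (created if absent).
#' @return invisible vector of files written.
#' @export
render_tables <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  prov <- sprintf("# tropilife %s | seed %d | schemes: %s",
                  as.character(utils::packageVersion("tropilife")),
                  result$config$seed,
                  paste(result$passing_schemes, collapse = ","))
  emit <- function(tab, file) {
    path <- file.path(out_dir, file)
    con <- file(path, "w")
    writeLines(prov, con)
    write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    written <<- c(written, path)
  }

  if (!is.null(result$pca)) {
    pca <- result$pca
    keep <- seq_len(max(pca$retained, 1L))
    tab <- as.data.frame(round(pca$loadings[, keep, drop = FALSE], 3))
    tab <- cbind(variable = rownames(pca$loadings), tab)
    tab <- rbind(tab, c("Eigenvalue(%var)",
                        sprintf("%.3f (%.2f%%)", pca$eigenvalues[keep],
                                pca$pct_var[keep])))
    emit(tab, "table_pca.tsv")
  }

  nm <- strsplit(names(result$signal), "|", fixed = TRUE)
  sig <- cbind(
    data.frame(trait = vapply(nm, `[[`, "", 1L),
               branches = vapply(nm, `[[`, "", 2L)),
    do.call(rbind, lapply(result$signal, function(r)
      data.frame(MSEtree = r$MSE_tree, MSEstar = r$MSE_star, K = r$K,
                 P = r$P, lnL_tree = r$lnL_tree, lnL_star = r$lnL_star))))
  emit(sig, "table_signal.tsv")

  for (resp in names(result$fits)) {
    emit(regression_table(result$fits[[resp]]),
         paste0("table_regression_", resp, ".tsv"))
  }
  for (tn in names(result$ancestral)) {
    anc <- result$ancestral[[tn]]
    emit(data.frame(node = names(anc$states), value = unname(anc$states)),
         paste0("ancestral_", tn, ".tsv"))
  }
  writeLines(c(prov, result$log), file.path(out_dir, "run.log"))
  written <- c(written, file.path(out_dir, "run.log"))
  invisible(written)
}

#' Flatten regression fits into a publication-shaped table
#'
#' One row per fit: branch length, model, one slope and one F column per
#' coefficient, AIC, AICc, LnL, d, and the substantial-support flag
#' (AIC within 2 units of the best).
#'
#' @param fits list of `"phylo_fit"` objects on the same response.
#' @return a data frame.
#' @export
regression_table <- function(fits) {
  if (inherits(fits, "phylo_fit")) fits <- list(fits)
  cmp <- compare_models(fits)
  fits <- attr(cmp, "fits")
  coef_names <- names(fits[[1L]]$coefficients)
  rows <- lapply(fits, function(f) {
    est <- setNames(as.list(round(f$coefficients, 4)), paste0("slope_", coef_names))
    est[["slope_(Intercept)"]] <- round(f$coefficients[["(Intercept)"]], 4)
    Fv <- setNames(as.list(round(f$F, 4)), paste0("F_", coef_names))
    cbind(data.frame(branch_length = f$scheme, model = f$model_kind),
          as.data.frame(est, check.names = FALSE),
          as.data.frame(Fv, check.names = FALSE),
          data.frame(AIC = round(f$AIC, 3), AICc = round(f$AICc, 3),
                     LnL = round(f$lnL, 4),
                     d = ifelse(is.na(f$d), "", format(f$d, digits = 4))))
  })
  tab <- do.call(rbind, rows)
  tab$substantial <- cmp$substantial
  rownames(tab) <- NULL
  tab
}
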