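#' Build a run configuration for the full pipeline
#'
#' All knobs in one serializable list.  A run's config plus its seed
#' reproduces its outputs byte-identically.
#'
#' @param fasta,ss_source,labels Input paths, see [assemble_dataset()];
#'   all `NULL` when `simulate` is set.
#' @param simulate `NULL`, or a list `list(n_per_class=, length_range=)`
#'   to generate the inputs instead of reading them.
#' @param families Feature families to extract.
#' @param ss_preset `"full"` or `"eleven"`.
#' @param forest `list(s=, t=)` RI-forest shape (`s = NULL` means
#'   `ceiling(d/30)`).
#' @param size_grid Candidate subset sizes; `NULL` for a default sweep
#'   (10, 20, 30, 40, 50, 75, 100, 150, 200, 300, and all features),
#'   capped at the matrix dimension.
#' @param exponents Dyadic grid exponents for the SVM search.
#' @param standardize Standardize features inside every fold.
#' @param nested Re-tune (C, gamma) on every candidate subset instead of
#'   reusing the full-matrix tuning (slower, leak-free).
#' @param seed Master seed for every stochastic stage.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(fasta = NULL, ss_source = NULL, labels = NULL,
                       simulate = NULL,
                       families = c("PSF", "PPF", "RCF", "PSSF"),
                       ss_preset = "full", forest = list(s = NULL, t = 50L),
                       size_grid = NULL, exponents = -10:10,
                       standardize = TRUE, nested = FALSE, seed = 1L,
                       out_dir = tempfile("strucclass_run_")) {
  cfg <- list(fasta = fasta, ss_source = ss_source, labels = labels,
              simulate = simulate, families = families,
              ss_preset = ss_preset, forest = forest, size_grid = size_grid,
              exponents = exponents, standardize = standardize,
              nested = nested, seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from JSON
#' @param path JSON file with any subset of [run_config()]'s fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, obj)
}

default_size_grid <- function(d) {
  unique(pmin(c(10L, 20L, 30L, 40L, 50L, 75L, 100L, 150L, 200L, 300L, d), d))
}

#' Run the full extract -> select -> evaluate pipeline
#'
#' Stages: (1) load or simulate the dataset; (2) build the combined
#' feature matrix; (3) RI forest scores; (4) dyadic grid search for
#' (C, gamma) on the full matrix; (5) nested-subset sweep, scoring each
#' candidate size by jackknife overall accuracy; (6) jackknife evaluation
#' of the chosen subset.  Writes the feature matrix (CSV), RI table (TSV),
#' selection report and evaluation report (JSON), and a plain-text log of
#' all seeds and choices under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return Invisibly, a list: `dataset`, `features`, `ri`, `params`,
#'   `selection`, `report_full`, `report_chosen`, `paths`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  t0 <- Sys.time()
  ds <- if (!is.null(config$simulate)) {
    say("stage simulate: ", config$simulate$n_per_class, " records/class")
    simulate_protein_dataset(config$simulate$n_per_class,
                             config$simulate$length_range %||% c(100L, 300L),
                             seed = config$seed)
  } else {
    if (is.null(config$fasta) || is.null(config$labels)) {
      stop("stage load: config needs either simulate= or fasta=/labels=")
    }
    assemble_dataset(config$fasta, config$ss_source, config$labels)
  }

  say("stage extract: families ", paste(config$families, collapse = "+"))
  fm <- tryCatch(
    build_feature_matrix(ds, config$families, config$ss_preset),
    error = function(e) stop("stage extract: ", conditionMessage(e),
                             call. = FALSE))
  d <- ncol(fm$X)

  say("stage select: RI forest over ", d, " features")
  ri <- ri_scores(fm$X, ds$label, s = config$forest$s,
                  t = config$forest$t %||% 50L, seed = config$seed)

  say("stage tune: dyadic grid search")
  params <- svm_grid_search(fm$X, ds$label, seed = config$seed,
                            exponents = config$exponents,
                            standardize = config$standardize)
  say(sprintf("  chosen C = 2^%g, gamma = 2^%g (CV accuracy %.4f)",
              log2(params$C), log2(params$gamma), params$cv_accuracy))

  grid <- config$size_grid %||% default_size_grid(d)
  grid <- unique(pmin(as.integer(grid), d))
  # each candidate subset is re-tuned by CV before its jackknife: gamma's
  # useful scale depends on the subset dimension, so one tuning cannot
  # serve all sizes
  eval_fn <- make_jackknife_eval(NULL, seed = config$seed,
                                 standardize = config$standardize,
                                 nested = config$nested)
  say("stage sweep: sizes ", paste(grid, collapse = ", "))
  sel <- select_feature_subset(fm$X, ds$label, ri, grid, eval_fn,
                               verbose = verbose)

  say("stage evaluate: jackknife on chosen subset (", sel$chosen_size,
      " features) and on all ", d, " features")
  params_chosen <- svm_grid_search(fm$X[, sel$chosen, drop = FALSE],
                                   ds$label, seed = config$seed,
                                   exponents = config$exponents,
                                   standardize = config$standardize)
  report_chosen <- jackknife_evaluate(fm$X[, sel$chosen, drop = FALSE],
                                      ds$label, params_chosen,
                                      standardize = config$standardize,
                                      nested = config$nested,
                                      seed = config$seed)
  report_full <- jackknife_evaluate(fm$X, ds$label, params,
                                    standardize = config$standardize,
                                    nested = config$nested,
                                    seed = config$seed)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    features = file.path(config$out_dir, "features.csv"),
    ri = file.path(config$out_dir, "ri_scores.tsv"),
    selection = file.path(config$out_dir, "selection.json"),
    report = file.path(config$out_dir, "eval_report.json"),
    confusion = file.path(config$out_dir, "confusion.csv"),
    log = file.path(config$out_dir, "run.log"))
  write_feature_csv(fm, paths$features)
  write_ri_tsv(ri, paths$ri)
  jsonlite::write_json(
    list(size_grid = grid, scores = as.list(sel$scores),
         chosen_size = sel$chosen_size, chosen = sel$chosen,
         full_accuracy = report_full$overall_accuracy),
    paths$selection, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_eval_report(report_chosen, paths$report)
  utils::write.csv(as.data.frame.matrix(report_chosen$confusion),
                   paths$confusion)
  writeLines(c(
    paste0("seed: ", config$seed),
    paste0("families: ", paste(config$families, collapse = "+")),
    paste0("n_features: ", d),
    paste0("forest: s=", ri$s, " t=", ri$t, " m=", ri$m),
    paste0("svm_full: C=2^", log2(params$C), " gamma=2^", log2(params$gamma),
           " cv_accuracy=", format(params$cv_accuracy, digits = 17)),
    paste0("svm_chosen: C=2^", log2(params_chosen$C), " gamma=2^",
           log2(params_chosen$gamma), " cv_accuracy=",
           format(params_chosen$cv_accuracy, digits = 17)),
    paste0("size_grid: ", paste(grid, collapse = ",")),
    paste0("scores: ", paste(format(sel$scores, digits = 17),
                             collapse = ",")),
    paste0("chosen_size: ", sel$chosen_size),
    paste0("accuracy_chosen: ",
           format(report_chosen$overall_accuracy, digits = 17)),
    paste0("accuracy_full: ",
           format(report_full$overall_accuracy, digits = 17))),
    paths$log)
  say(sprintf("done in %.1f s: chosen %d/%d features, accuracy %.4f (full %.4f)",
              as.numeric(difftime(Sys.time(), t0, units = "secs")),
              sel$chosen_size, d, report_chosen$overall_accuracy,
              report_full$overall_accuracy))
  invisible(list(dataset = ds, features = fm, ri = ri, params = params,
                 params_chosen = params_chosen, selection = sel,
                 report_full = report_full, report_chosen = report_chosen,
                 paths = paths))
}
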