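# End-to-end wrappers tying the stages together: simulate -> train ->
# predict -> evaluate.  These functions back the command-line interface in
# inst/cli/comtop; all outputs are plain text and deterministic given the
# config seed.

#' Read a run configuration
#'
#' YAML configuration with command-line-style overrides; unknown keys are
#' an error so typos fail fast.  All randomness in a run flows from the
#' single `seed`.
#'
#' @param path YAML file, or `NULL` for defaults only.
#' @param overrides named list overriding config values.
#' @return a named list with the full configuration.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    scores_dir = NULL, truth_dir = NULL, weights_file = NULL,
    out_dir = ".",
    specs = c("5L", "3L", "2L", "L", "L/2", "L/5"),
    margin_mode = "soft_margin", delta = 1e-4, impute_mode = "literal",
    time_limit = 600, threshold = 8, min_separation = 6L,
    seed = 1L, synth = NULL
  )
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), c(names(defaults), "synth"))
    if (length(unknown)) stop("unknown config keys: ",
                              paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) stop("unknown config overrides: ",
                            paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  cfg$specs <- as.character(unlist(cfg$specs))
  cfg
}

synth_config_from_list <- function(x, seed) {
  if (is.null(x)) return(synth_config(seed = seed))
  methods <- if (!is.null(x$methods)) {
    do.call(rbind, lapply(x$methods, function(m) {
      data.frame(method_id = m$method_id, reliability = m$reliability,
                 shared_error_weight = m$shared_error_weight %||% 0,
                 noise_scale = m$noise_scale %||% 0)
    }))
  } else {
    eval(formals(synth_config)$methods)
  }
  synth_config(
    n_proteins = x$n_proteins %||% 10L,
    L_range = unlist(x$L_range %||% c(40L, 80L)),
    contact_density = x$contact_density %||% 1.0,
    methods = methods,
    min_separation = x$min_separation %||% 6L,
    output_spec = x$output_spec %||% "5L",
    seed = seed
  )
}

#' Simulate a corpus to disk
#'
#' @param config run configuration (see [read_run_config()]); uses its
#'   `synth` block and `seed`, writing RR and truth files under `out_dir`.
#' @return invisibly, the generated [contact_corpus()].
#' @export
run_simulate <- function(config) {
  sc <- synth_config_from_list(config$synth, config$seed)
  corpus <- generate_corpus(sc)
  write_corpus(corpus, file.path(config$out_dir, "scores"),
               file.path(config$out_dir, "truth"))
  message(sprintf("simulated %d proteins x %d methods -> %s",
                  length(corpus$scores), length(corpus$methods),
                  config$out_dir))
  invisible(corpus)
}

#' Train weights from score and truth directories
#'
#' Runs preprocessing and the MILP per sub-model, writes the weights JSON
#' and a plain-text training report.
#'
#' @param config run configuration with `scores_dir`, `truth_dir`,
#'   `out_dir`.
#' @param corpus optionally, an in-memory corpus (skips directory reads).
#' @return invisibly, the fitted [comtop()] object.
#' @export
run_train <- function(config, corpus = NULL) {
  corpus <- corpus %||% read_corpus(config$scores_dir, config$truth_dir,
                                    config$min_separation)
  fit <- comtop(corpus, specs = config$specs,
                margin_mode = config$margin_mode, delta = config$delta,
                impute_mode = config$impute_mode,
                time_limit = config$time_limit)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wf <- config$weights_file %||% file.path(config$out_dir, "weights.json")
  write_weights(fit, wf)
  report <- utils::capture.output(print(summary(fit)))
  writeLines(report, file.path(config$out_dir, "training_report.txt"))
  message("weights written to ", wf)
  invisible(fit)
}

#' Predict consensus contacts from trained weights
#'
#' Writes one RR file per protein and requested cutoff
#' (`<protein>__consensus__<spec>.rr`; cutoff slashes become dashes) plus a
#' tab-separated ranking report.  No optimization runs at prediction time.
#'
#' @param config run configuration with `scores_dir`, `weights_file`,
#'   `out_dir` (and `truth_dir` or per-protein lengths available from the
#'   corpus).
#' @param corpus optional in-memory corpus.
#' @param fit optional in-memory fit (skips reading `weights_file`).
#' @return invisibly, the nested prediction list from [predict.comtop()].
#' @export
run_predict <- function(config, corpus = NULL, fit = NULL) {
  corpus <- corpus %||% read_corpus(config$scores_dir, config$truth_dir,
                                    config$min_separation)
  fit <- fit %||% read_weights(config$weights_file)
  preds <- stats::predict(fit, corpus, specs = config$specs)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (spec in names(preds)) {
    tag <- gsub("/", "-", spec, fixed = TRUE)
    for (pid in names(preds[[spec]])) {
      pr <- preds[[spec]][[pid]]
      write_rr(as_prediction_set(pr),
               file.path(config$out_dir,
                         sprintf("%s__consensus__%s.rr", pid, tag)))
      rows[[length(rows) + 1]] <- cbind(spec = spec, protein = pid,
                                        pr$entries)
    }
  }
  report <- do.call(rbind, rows)
  utils::write.table(report, file.path(config$out_dir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message("predictions written to ", config$out_dir)
  invisible(preds)
}

#' Evaluate predictions against truths
#'
#' Writes the cutoffs-by-metrics table (macro-averaged over proteins) as
#' TSV, and per-method baselines alongside the consensus for a
#' methods-by-cutoffs accuracy table.
#'
#' @param config run configuration.
#' @param corpus optional in-memory corpus (with truths).
#' @param predictions optional in-memory predictions from [run_predict()].
#' @return invisibly, a list with `consensus` (the [evaluate_suite()]
#'   table) and `by_method` (accuracy per method and cutoff).
#' @export
run_evaluate <- function(config, corpus = NULL, predictions = NULL) {
  corpus <- corpus %||% read_corpus(config$scores_dir, config$truth_dir,
                                    config$min_separation)
  if (is.null(corpus$truths)) stop("evaluation requires truths")
  if (is.null(predictions)) {
    fit <- read_weights(config$weights_file)
    predictions <- stats::predict(fit, corpus, specs = config$specs)
  }
  consensus <- evaluate_suite(predictions, corpus$truths)
  by_method <- lapply(corpus$methods, function(mid) {
    base <- method_baseline(corpus, mid, specs = config$specs)
    tab <- evaluate_suite(base, corpus$truths)
    stats::setNames(tab$accuracy, tab$spec)
  })
  names(by_method) <- corpus$methods
  acc_table <- rbind(do.call(rbind, by_method),
                     consensus = stats::setNames(consensus$accuracy,
                                                 consensus$spec))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(consensus, file.path(config$out_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(method = rownames(acc_table),
                           as.data.frame(round(acc_table, 6))),
                     file.path(config$out_dir, "accuracy_by_method.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message("evaluation written to ", config$out_dir)
  invisible(list(consensus = consensus, by_method = by_method))
}

#' Run the full pipeline: simulate, train, predict, evaluate
#'
#' Deterministic end to end for a fixed config and seed: repeated runs
#' produce byte-identical weights, predictions and reports.
#'
#' @param config run configuration; the `synth` block controls simulation.
#' @return invisibly, list(fit, predictions, evaluation).
#' @export
run_pipeline <- function(config) {
  base_out <- config$out_dir
  cfg <- config
  cfg$out_dir <- file.path(base_out, "data")
  corpus <- run_simulate(cfg)
  cfg$out_dir <- file.path(base_out, "model")
  cfg$weights_file <- file.path(cfg$out_dir, "weights.json")
  fit <- run_train(cfg, corpus = corpus)
  cfg$out_dir <- file.path(base_out, "predictions")
  preds <- run_predict(cfg, corpus = corpus, fit = fit)
  cfg$out_dir <- file.path(base_out, "evaluation")
  ev <- run_evaluate(cfg, corpus = corpus, predictions = preds)
  invisible(list(fit = fit, predictions = preds, evaluation = ev))
}
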