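# Model fitting: per-cutoff consensus weights learned from a training
# corpus, wrapped in a classed fit object.

#' Bundle prediction sets and truths into a training corpus
#'
#' @param scores named list: protein id -> named list: method id ->
#'   [prediction_set()].
#' @param truths named list: protein id -> [contact_map()] (may be omitted
#'   for a prediction-only corpus).
#' @return object of class `contact_corpus`.
#' @export
contact_corpus <- function(scores, truths = NULL) {
  stopifnot(is.list(scores), length(scores) >= 1)
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    stop("scores must be a named list keyed by protein id")
  }
  methods <- sort(unique(unlist(lapply(scores, names))))
  for (pid in names(scores)) {
    if (!setequal(names(scores[[pid]]), methods)) {
      stop("protein '", pid, "' does not supply all methods (",
           paste(methods, collapse = ", "), ")")
    }
  }
  if (!is.null(truths)) {
    missing_truth <- setdiff(names(scores), names(truths))
    if (length(missing_truth)) {
      stop("proteins with scores but no truth: ",
           paste(missing_truth, collapse = ", "))
    }
    truths <- truths[names(scores)]
  }
  structure(list(scores = scores, truths = truths, methods = methods),
            class = "contact_corpus")
}

#' @export
print.contact_corpus <- function(x, ...) {
  cat(sprintf("Contact corpus: %d proteins x %d methods (%s)%s\n",
              length(x$scores), length(x$methods),
              paste(x$methods, collapse = ", "),
              if (is.null(x$truths)) ", no truths" else ""))
  invisible(x)
}

#' Read a corpus from score and truth directories
#'
#' Score files are flat `"<protein>__<method>.rr"` CASP RR files; truth
#' files are `"<protein>.pairs"` pair lists ([read_pair_list()]).
#'
#' @param scores_dir directory of RR files.
#' @param truth_dir directory of pair-list files, or `NULL`.
#' @param min_separation separation floor recorded on the truth maps.
#' @return a [contact_corpus()].
#' @export
read_corpus <- function(scores_dir, truth_dir = NULL, min_separation = 6L) {
  files <- sort(list.files(scores_dir, pattern = "\\.rr$", full.names = TRUE))
  if (length(files) == 0) stop("no .rr files in ", scores_dir)
  stem <- sub("\\.rr$", "", basename(files))
  parts <- strsplit(stem, "__", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    stop("score files must be named <protein>__<method>.rr; offending: ",
         basename(files[bad][1]))
  }
  prot <- vapply(parts, `[`, "", 1L)
  meth <- vapply(parts, `[`, "", 2L)
  scores <- list()
  for (k in seq_along(files)) {
    scores[[prot[k]]][[meth[k]]] <- read_rr(files[k], prot[k], meth[k])
  }
  truths <- NULL
  if (!is.null(truth_dir)) {
    truths <- lapply(names(scores), function(pid) {
      f <- file.path(truth_dir, paste0(pid, ".pairs"))
      if (!file.exists(f)) stop("missing truth file for protein ", pid)
      read_pair_list(f, pid, min_separation)
    })
    names(truths) <- names(scores)
  }
  contact_corpus(scores, truths)
}

#' Write a corpus to score and truth directories
#'
#' @param corpus a [contact_corpus()].
#' @param scores_dir,truth_dir output directories (created if needed).
#' @return invisibly, the corpus.
#' @export
write_corpus <- function(corpus, scores_dir, truth_dir = NULL) {
  dir.create(scores_dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in names(corpus$scores)) {
    for (mid in names(corpus$scores[[pid]])) {
      write_rr(corpus$scores[[pid]][[mid]],
               file.path(scores_dir, paste0(pid, "__", mid, ".rr")))
    }
  }
  if (!is.null(truth_dir) && !is.null(corpus$truths)) {
    dir.create(truth_dir, recursive = TRUE, showWarnings = FALSE)
    for (pid in names(corpus$truths)) {
      write_pair_list(corpus$truths[[pid]],
                      file.path(truth_dir, paste0(pid, ".pairs")))
    }
  }
  invisible(corpus)
}

#' Train the per-cutoff weight sub-models
#'
#' For each top-k cutoff, builds the training tensors at that cutoff's
#' candidate count, assembles the MILP instance and solves it for the
#' method weights.  One weight vector (on the probability simplex) is
#' learned per cutoff.
#'
#' @param corpus a [contact_corpus()] with truths.
#' @param specs character vector of top-k specifiers; the default six
#'   cutoffs give the six standard sub-models.
#' @param margin_mode,delta see [milp_instance()].
#' @param impute_mode see [impute_scores()].
#' @param time_limit solver budget per sub-model, seconds.
#' @param max_proteins guardrail on corpus size (override by raising it).
#' @param ... passed to [solve_milp()].
#' @return named list: spec -> list(lambdas, objective, status, gap,
#'   n_pairs, n_proteins).
#' @export
train_submodels <- function(corpus, specs = c("5L", "3L", "2L", "L", "L/2", "L/5"),
                            margin_mode = "soft_margin", delta = 1e-4,
                            impute_mode = "literal", time_limit = 600,
                            max_proteins = 200L, ...) {
  stopifnot(inherits(corpus, "contact_corpus"))
  if (is.null(corpus$truths)) stop("training requires truths")
  if (length(corpus$scores) > max_proteins) {
    stop("corpus exceeds the ", max_proteins,
         "-protein training guardrail; raise max_proteins to override")
  }
  out <- list()
  for (spec in specs) {
    tensors <- lapply(names(corpus$scores), function(pid) {
      prepare_protein(corpus$scores[[pid]], corpus$truths[[pid]],
                      spec = spec, impute_mode = impute_mode)
    })
    inst <- milp_instance(tensors, margin_mode = margin_mode, delta = delta)
    sol <- solve_milp(inst, time_limit = time_limit, ...)
    if (sol$status == "infeasible") {
      stop("sub-model '", spec, "' reported infeasible (", sol$n_pairs,
           " pairs); this should not happen for valid score tensors")
    }
    out[[spec]] <- list(
      lambdas = sol$lambdas, objective = sol$objective, status = sol$status,
      gap = sol$gap, n_pairs = sol$n_pairs,
      n_proteins = length(corpus$scores)
    )
  }
  out
}

#' Fit a consensus contact predictor
#'
#' Learns, for each top-k reporting cutoff, the per-method weights that
#' maximize the number of residue pairs whose correct score mass outweighs
#' their incorrect score mass over the training corpus, by mixed integer
#' linear optimization.  The fitted object scores new proteins with the
#' weighted-sum consensus score and reports the top-kL pairs per cutoff.
#'
#' @param corpus a [contact_corpus()] with truths (or `scores` plus
#'   `truths` lists accepted by [contact_corpus()]).
#' @param truths optional named list of [contact_map()]s when `corpus` is a
#'   bare scores list.
#' @param specs top-k cutoffs to fit, one sub-model each.
#' @param margin_mode `"soft_margin"` (default) or `"hard_count"`.
#' @param delta strict-inequality tolerance of the discrimination
#'   constraint.
#' @param impute_mode missing-score rule, `"literal"` or `"floor"`.
#' @param time_limit solver budget per sub-model (seconds).
#' @param ... passed to [solve_milp()].
#' @return object of class `comtop` with components `weights` (cutoffs x
#'   methods matrix), `submodels` (solver metadata per cutoff), `methods`,
#'   `specs`, `delta`, `margin_mode`, `impute_mode`, `call`.
#' @seealso [predict.comtop()], [coef.comtop()], [write_weights()]
#' @examples
#' corpus <- generate_corpus(synth_config(n_proteins = 4, L_range = c(30, 40),
#'                                        seed = 1))
#' fit <- comtop(corpus, specs = c("L", "L/5"))
#' coef(fit)
#' @export
comtop <- function(corpus, truths = NULL,
                   specs = c("5L", "3L", "2L", "L", "L/2", "L/5"),
                   margin_mode = c("soft_margin", "hard_count"),
                   delta = 1e-4, impute_mode = c("literal", "floor"),
                   time_limit = 600, ...) {
  margin_mode <- match.arg(margin_mode)
  impute_mode <- match.arg(impute_mode)
  if (!inherits(corpus, "contact_corpus")) {
    corpus <- contact_corpus(corpus, truths)
  }
  sub <- train_submodels(corpus, specs = specs, margin_mode = margin_mode,
                         delta = delta, impute_mode = impute_mode,
                         time_limit = time_limit, ...)
  weights <- do.call(rbind, lapply(sub, function(s) s$lambdas))
  rownames(weights) <- names(sub)
  structure(
    list(weights = weights, submodels = sub, methods = corpus$methods,
         specs = names(sub), delta = delta, margin_mode = margin_mode,
         impute_mode = impute_mode, call = match.call()),
    class = "comtop"
  )
}

#' @export
print.comtop <- function(x, digits = 4, ...) {
  cat("Consensus contact predictor (MILP-weighted)\n")
  cat(sprintf("  methods: %s\n", paste(x$methods, collapse = ", ")))
  cat(sprintf("  margin mode: %s, delta = %g, impute = %s\n",
              x$margin_mode, x$delta, x$impute_mode))
  cat("  weights per sub-model:\n")
  print(round(x$weights, digits))
  invisible(x)
}

#' @export
coef.comtop <- function(object, spec = NULL, ...) {
  if (is.null(spec)) return(object$weights)
  if (!spec %in% rownames(object$weights)) {
    stop("no sub-model for spec '", spec, "'")
  }
  object$weights[spec, ]
}

#' @export
summary.comtop <- function(object, ...) {
  meta <- do.call(rbind, lapply(object$submodels, function(s) {
    data.frame(objective = s$objective, status = s$status, gap = s$gap,
               n_pairs = s$n_pairs, n_proteins = s$n_proteins)
  }))
  meta <- cbind(spec = names(object$submodels), meta)
  rownames(meta) <- NULL
  out <- list(weights = object$weights, training = meta,
              margin_mode = object$margin_mode, delta = object$delta)
  class(out) <- "summary.comtop"
  out
}

#' @export
print.summary.comtop <- function(x, digits = 4, ...) {
  cat("Consensus contact predictor — training summary\n\n")
  cat("Weights (rows: sub-models, columns: methods):\n")
  print(round(x$weights, digits))
  cat("\nSolver metadata:\n")
  print(x$training, row.names = FALSE)
  invisible(x)
}

#' Plot learned weights per sub-model
#'
#' Grouped barplot of the weight each method receives in each top-k
#' sub-model.
#'
#' @param x a fitted [comtop()] object.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.comtop <- function(x, ...) {
  graphics::barplot(t(x$weights), beside = TRUE, legend.text = x$methods,
                    xlab = "sub-model (top-k cutoff)", ylab = "weight",
                    args.legend = list(x = "topright", bty = "n"), ...)
  invisible(x)
}

# ---- weight serialization ----------------------------------------------

#' Write fitted weights to a versioned JSON document
#'
#' @param fit a [comtop()] fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(fit, path) {
  stopifnot(inherits(fit, "comtop"))
  doc <- list(
    format = "comtop-weights",
    version = 1L,
    methods = fit$methods,
    margin_mode = fit$margin_mode,
    delta = fit$delta,
    impute_mode = fit$impute_mode,
    submodels = lapply(fit$submodels, function(s) {
      list(lambdas = as.list(s$lambdas), objective = s$objective,
           status = s$status, gap = s$gap, n_pairs = s$n_pairs,
           n_proteins = s$n_proteins)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read fitted weights from JSON
#'
#' @param path path written by [write_weights()].
#' @return a `comtop` object usable by [predict.comtop()].
#' @export
read_weights <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "comtop-weights")) {
    stop("not a consensus-weights document: ", path)
  }
  methods <- unlist(doc$methods)
  sub <- lapply(doc$submodels, function(s) {
    lam <- unlist(s$lambdas)
    if (!setequal(names(lam), methods)) stop("weights/method mismatch in ", path)
    list(lambdas = lam[methods], objective = s$objective, status = s$status,
         gap = s$gap, n_pairs = s$n_pairs, n_proteins = s$n_proteins)
  })
  weights <- do.call(rbind, lapply(sub, function(s) s$lambdas))
  rownames(weights) <- names(doc$submodels)
  structure(
    list(weights = weights, submodels = sub, methods = methods,
         specs = names(doc$submodels), delta = doc$delta,
         margin_mode = doc$margin_mode, impute_mode = doc$impute_mode,
         call = NULL),
    class = "comtop"
  )
}
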