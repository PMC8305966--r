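# Score normalization, top-kL candidate selection, tensor assembly and the
# missing-value rules applied before training.

#' Min-max normalize a score vector
#'
#' Maps scores affinely so that the minimum becomes 0 and the maximum 1,
#' per protein per method: `z = (x - min) / (max - min)`.  When all scores
#' are equal the mapping is undefined and all outputs are 0 (a constant
#' score carries no ranking signal).
#'
#' @param raw_scores numeric vector, at least one value, no NaN/NA.
#' @return numeric vector in `[0, 1]`.
#' @examples
#' minmax_normalize(c(2, 4, 6))
#' @export
minmax_normalize <- function(raw_scores) {
  if (length(raw_scores) == 0) stop("at least one score required")
  if (anyNA(raw_scores) || any(is.nan(raw_scores))) {
    stop("NaN/NA in raw scores")
  }
  rng <- range(raw_scores)
  if (rng[1] == rng[2]) return(rep(0, length(raw_scores)))
  (raw_scores - rng[1]) / (rng[2] - rng[1])
}

#' Resolve a top-k specifier to a pair count
#'
#' The standard contact evaluation cutoffs are multiples or fractions of the
#' protein length L.  Returns `floor(k * L)` with a minimum of 1.
#'
#' @param L protein length (residues).
#' @param spec one of `"5L"`, `"4.5L"`, `"3L"`, `"2L"`, `"L"`, `"L/2"`,
#'   `"L/5"` (any `"<num>L"` or `"L/<num>"` form is accepted).
#' @return integer count.
#' @examples
#' resolve_topk_count(47, "L/5")
#' @export
resolve_topk_count <- function(L, spec) {
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("L must be a positive integer")
  max(1L, as.integer(floor(topk_multiplier(spec) * L)))
}

topk_multiplier <- function(spec) {
  spec <- as.character(spec)
  if (length(spec) != 1L) stop("one specifier at a time")
  if (spec == "L") return(1)
  m <- regmatches(spec, regexec("^([0-9]*\\.?[0-9]+)L$", spec))[[1]]
  if (length(m) == 2) return(as.numeric(m[2]))
  m <- regmatches(spec, regexec("^L/([0-9]*\\.?[0-9]+)$", spec))[[1]]
  if (length(m) == 2) return(1 / as.numeric(m[2]))
  stop("unknown top-k specifier: '", spec, "'")
}

#' Keep the highest-confidence entries of a prediction set
#'
#' Returns the `count` highest-confidence entries, ties broken by smaller
#' `i` then smaller `j` (stable and platform independent).  A count at or
#' above the number of entries returns them all.
#'
#' @param predictions a [prediction_set()].
#' @param count number of entries to keep (non-negative).
#' @return a [prediction_set()] with at most `count` entries.
#' @export
select_top_k <- function(predictions, count) {
  stopifnot(inherits(predictions, "prediction_set"))
  if (count < 0) stop("count must be non-negative")
  e <- predictions$entries
  ord <- order(-e$confidence, e$i, e$j)
  keep <- ord[seq_len(min(count, nrow(e)))]
  prediction_set(predictions$protein_id, predictions$method_id,
                 cbind(e$i[keep], e$j[keep]), e$confidence[keep])
}

# Normalize a method's scores and truncate to the training candidate count:
# top-floor(min(k, 4.5) * L) (the 5L sub-model uses the 4.5L trim of the
# top-5L list; smaller cutoffs use their own kL).
prepare_method <- function(predictions, L, spec) {
  e <- predictions$entries
  norm <- prediction_set(predictions$protein_id, predictions$method_id,
                         cbind(e$i, e$j),
                         if (nrow(e)) minmax_normalize(e$confidence) else numeric(0))
  count <- max(1L, as.integer(floor(min(topk_multiplier(spec), 4.5) * L)))
  select_top_k(norm, count)
}

#' Assemble per-protein score and label tensors
#'
#' Builds the pairs-by-methods confidence matrix `confS` and label matrix
#' `predSS` over the union of all methods' retained candidate pairs.  A
#' (pair, method) cell is missing when that method did not retain the pair;
#' missing cells are NA until [impute_scores()] / [impute_labels()] run.
#' For non-missing cells the label is 1 exactly when the pair is a native
#' contact (a returned prediction is "true" iff the pair is in contact).
#'
#' @param per_method list of [prediction_set()]s for one protein, already
#'   normalized and truncated to the candidate count.
#' @param truth the protein's [contact_map()], or `NULL` at prediction time
#'   (labels then stay NA).
#' @param protein_id protein identifier; defaults to the sets' common id.
#' @return object of class `contact_tensor`: list with `protein_id`, `L`,
#'   `pairs` (matrix), `methods`, `conf`, `labels`, `missing` (logical
#'   matrix), `truth` (logical vector per pair or NULL), `imputed` flag.
#' @export
assemble_tensors <- function(per_method, truth = NULL, protein_id = NULL) {
  stopifnot(length(per_method) >= 1)
  ids <- vapply(per_method, function(s) s$protein_id, "")
  if (length(unique(ids)) != 1L) {
    stop("prediction sets refer to different proteins: ",
         paste(unique(ids), collapse = ", "))
  }
  if (!is.null(truth) && truth$protein_id != ids[1]) {
    stop("truth protein id '", truth$protein_id,
         "' does not match prediction sets ('", ids[1], "')")
  }
  methods <- vapply(per_method, function(s) s$method_id, "")
  if (anyDuplicated(methods)) stop("duplicate method ids")
  ord_m <- order(methods)
  per_method <- per_method[ord_m]
  methods <- methods[ord_m]

  keys <- sort(unique(unlist(lapply(per_method, function(s) {
    pair_keys(pred_pairs(s))
  }))))
  pairs <- keys_to_pairs(keys)
  keys <- pair_keys(pairs)  # canonical row order
  n <- nrow(pairs); m <- length(methods)
  conf <- matrix(NA_real_, n, m, dimnames = list(keys, methods))
  for (k in seq_len(m)) {
    e <- per_method[[k]]$entries
    if (nrow(e)) conf[paste(e$i, e$j, sep = ":"), k] <- e$confidence
  }
  missing <- is.na(conf)
  truth_vec <- if (!is.null(truth)) is_contact(truth, pairs) else NULL
  labels <- matrix(NA_real_, n, m, dimnames = dimnames(conf))
  if (!is.null(truth_vec)) {
    labels[!missing] <- as.numeric(matrix(truth_vec, n, m)[!missing])
  }
  L <- if (!is.null(truth)) truth$L else if (n) max(pairs[, 2]) else 1L
  structure(
    list(protein_id = ids[1], L = L, pairs = pairs, methods = methods,
         conf = conf, labels = labels, missing = missing, truth = truth_vec,
         imputed = FALSE),
    class = "contact_tensor"
  )
}

#' @export
print.contact_tensor <- function(x, ...) {
  cat(sprintf("Contact tensor '%s': %d pairs x %d methods, %d missing cells%s\n",
              x$protein_id, nrow(x$pairs), length(x$methods),
              sum(x$missing), if (x$imputed) " (imputed)" else ""))
  invisible(x)
}

#' Impute missing confidence scores
#'
#' Applies the training-time missing-value rule to the score matrix.  With
#' `x_p`, `y_p`, `z_p` the minimum, maximum and mean of the protein's
#' non-missing scores: in `"literal"` mode a missing cell of a native
#' contact pair receives `(x_p - x_p) / y_p * 1000`, which is identically 0,
#' and a missing cell of a non-contact pair receives `z_p`.  `"floor"` mode
#' replaces the self-cancelling contact branch with `x_p`.  When no truth is
#' available (prediction time) every missing cell receives 0: a method that
#' did not return a pair lends it no support.
#'
#' @param tensor a `contact_tensor` from [assemble_tensors()].
#' @param mode `"literal"` (default) or `"floor"`.
#' @return the tensor with `conf` fully populated; the missing mask is kept
#'   for diagnostics.
#' @export
impute_scores <- function(tensor, mode = c("literal", "floor")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tensor, "contact_tensor"))
  conf <- tensor$conf
  miss <- tensor$missing
  if (!any(miss)) {
    tensor$imputed <- TRUE
    return(tensor)
  }
  obs <- conf[!miss]
  if (length(obs) == 0) {
    stop("all cells missing for protein '", tensor$protein_id,
         "': per-protein statistics undefined")
  }
  if (is.null(tensor$truth)) {
    conf[miss] <- 0
  } else {
    x_p <- min(obs); y_p <- max(obs); z_p <- mean(obs)
    contact_cell <- matrix(tensor$truth, nrow(conf), ncol(conf))
    conf[miss & contact_cell] <- switch(mode,
      literal = (x_p - x_p) / y_p * 1000,  # self-cancelling: identically 0
      floor = x_p
    )
    conf[miss & !contact_cell] <- z_p
  }
  tensor$conf <- conf
  tensor$imputed <- TRUE
  tensor
}

#' Impute missing prediction labels
#'
#' A method's silence on a pair counts as a correct negative when the pair
#' is not a native contact (label 1) and as a miss when it is (label 0).
#' Non-missing labels are untouched.
#'
#' @param tensor a `contact_tensor` with truth attached.
#' @return the tensor with `labels` fully populated.
#' @export
impute_labels <- function(tensor) {
  stopifnot(inherits(tensor, "contact_tensor"))
  if (is.null(tensor$truth)) stop("label imputation requires truth")
  labels <- tensor$labels
  miss <- tensor$missing
  if (!identical(dim(labels), dim(tensor$conf))) {
    stop("label matrix shape mismatch")
  }
  contact_cell <- matrix(tensor$truth, nrow(labels), ncol(labels))
  labels[miss & !contact_cell] <- 1
  labels[miss & contact_cell] <- 0
  tensor$labels <- labels
  tensor
}

#' Prepare one protein's training tensor
#'
#' Convenience wrapper: normalizes each method's scores, truncates to the
#' sub-model's candidate count, assembles the tensors over the union pair
#' universe and applies both imputation rules.
#'
#' @param per_method list of raw [prediction_set()]s for one protein.
#' @param truth the protein's [contact_map()], or NULL at prediction time.
#' @param spec top-k specifier of the sub-model (candidate count
#'   `floor(min(k, 4.5) * L)`).
#' @param L protein length; taken from `truth` when omitted.
#' @param impute_mode passed to [impute_scores()].
#' @return an imputed `contact_tensor`.
#' @export
prepare_protein <- function(per_method, truth = NULL, spec = "4.5L",
                            L = NULL, impute_mode = "literal") {
  L <- L %||% (if (!is.null(truth)) truth$L else
    stop("L required when no truth is supplied"))
  trimmed <- lapply(per_method, prepare_method, L = L, spec = spec)
  tensor <- assemble_tensors(trimmed, truth)
  tensor <- impute_scores(tensor, mode = impute_mode)
  if (!is.null(truth)) tensor <- impute_labels(tensor)
  tensor
}

#' Export a tensor as a long-format table
#'
#' @param tensor a `contact_tensor`.
#' @return data.frame with columns protein, i, j, method, conf, label,
#'   missing — one row per (pair, method) cell.
#' @export
tensor_as_table <- function(tensor) {
  n <- nrow(tensor$pairs); m <- length(tensor$methods)
  data.frame(
    protein = tensor$protein_id,
    i = rep(tensor$pairs[, 1], m),
    j = rep(tensor$pairs[, 2], m),
    method = rep(tensor$methods, each = n),
    conf = as.vector(tensor$conf),
    label = as.vector(tensor$labels),
    missing = as.vector(tensor$missing)
  )
}
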