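# Consensus scoring, ranking and top-kL reporting from trained weights.

#' Weighted consensus score per pair
#'
#' `S(p,(i,j)) = sum_m lambda_m * confS(p,(i,j),m)`; with weights on the
#' probability simplex and confidences in `[0,1]`, `S` lies in `[0,1]`.
#'
#' @param tensor an imputed `contact_tensor`.
#' @param lambdas weight vector on the simplex, named by method or in the
#'   tensor's method order.
#' @return numeric vector of consensus scores, one per tensor pair.
#' @export
consensus_score <- function(tensor, lambdas) {
  stopifnot(inherits(tensor, "contact_tensor"))
  if (!tensor$imputed) stop("tensor must be imputed before scoring")
  if (!is.null(names(lambdas))) {
    if (!setequal(names(lambdas), tensor$methods)) {
      stop("weight names do not match the tensor's methods")
    }
    lambdas <- lambdas[tensor$methods]
  }
  if (length(lambdas) != length(tensor$methods)) {
    stop("method count mismatch between weights and tensor")
  }
  check_simplex(unname(lambdas), length(tensor$methods))
  as.vector(tensor$conf %*% unname(lambdas))
}

#' Top-kL consensus contact prediction for one protein
#'
#' Scores the tensor's candidate universe with the given sub-model's
#' weights and returns the `floor(k * L)` best pairs, ties broken by
#' smaller i then smaller j.  When the universe is smaller than the cutoff
#' the whole universe is returned with a warning.
#'
#' @param tensor an imputed `contact_tensor` for the protein.
#' @param weights a fitted [comtop()] object, or a bare named weight vector.
#' @param spec top-k specifier selecting both the cutoff and (for a fit
#'   object) the sub-model's weights.
#' @param L protein length; defaults to the tensor's.
#' @return object of class `consensus_prediction`: `protein_id`, `entries`
#'   (data.frame rank, i, j, score), `submodel`, `L`.
#' @export
predict_contacts <- function(tensor, weights, spec = "L", L = NULL) {
  L <- L %||% tensor$L
  lam <- if (inherits(weights, "comtop")) {
    if (!spec %in% rownames(weights$weights)) {
      stop("no sub-model trained for spec '", spec, "'")
    }
    weights$weights[spec, ]
  } else {
    weights
  }
  s <- consensus_score(tensor, lam)
  count <- resolve_topk_count(L, spec)
  if (count > nrow(tensor$pairs)) {
    warning(sprintf("candidate universe of '%s' (%d pairs) smaller than top-%s cutoff (%d)",
                    tensor$protein_id, nrow(tensor$pairs), spec, count))
    count <- nrow(tensor$pairs)
  }
  ord <- order(-s, tensor$pairs[, 1], tensor$pairs[, 2])
  keep <- ord[seq_len(count)]
  structure(
    list(protein_id = tensor$protein_id,
         entries = data.frame(rank = seq_along(keep),
                              i = tensor$pairs[keep, 1],
                              j = tensor$pairs[keep, 2],
                              score = s[keep]),
         submodel = spec, L = L),
    class = "consensus_prediction"
  )
}

#' @export
print.consensus_prediction <- function(x, ...) {
  cat(sprintf("Consensus prediction '%s' (top-%s of L=%d): %d pairs\n",
              x$protein_id, x$submodel, x$L, nrow(x$entries)))
  print(utils::head(x$entries, 5), row.names = FALSE)
  if (nrow(x$entries) > 5) cat("...\n")
  invisible(x)
}

#' Consensus label vector over a pair universe
#'
#' 1 for pairs returned by the prediction, 0 for universe pairs that were
#' not returned.
#'
#' @param prediction a `consensus_prediction`.
#' @param universe 2-column matrix of pairs containing all predicted pairs.
#' @return integer vector aligned with the universe rows.
#' @export
consensus_label_matrix <- function(prediction, universe) {
  universe <- canonical_pairs(universe)
  pk <- paste(prediction$entries$i, prediction$entries$j, sep = ":")
  uk <- pair_keys(universe)
  if (!all(pk %in% uk)) stop("prediction contains pairs outside the universe")
  as.integer(uk %in% pk)
}

#' Predict consensus contacts for new proteins
#'
#' Assembles each protein's candidate universe (union of the methods'
#' normalized top-4.5L lists), scores it with the sub-model weights for
#' each requested cutoff and returns the top-kL pairs.  No optimization is
#' solved at prediction time; missing method scores are imputed as 0
#' (truth-free rule).
#'
#' @param object a fitted [comtop()] object (or [read_weights()] result).
#' @param newdata a [contact_corpus()], or a named list protein ->
#'   named list method -> [prediction_set()].
#' @param specs top-k cutoffs to report; default all trained sub-models.
#' @param L named integer vector of protein lengths; required when
#'   `newdata` carries no truths (lengths are otherwise taken from them).
#' @param ... unused.
#' @return named list: spec -> named list: protein -> `consensus_prediction`.
#' @export
predict.comtop <- function(object, newdata, specs = NULL, L = NULL, ...) {
  specs <- specs %||% rownames(object$weights)
  if (!inherits(newdata, "contact_corpus")) {
    newdata <- contact_corpus(newdata)
  }
  if (!setequal(newdata$methods, object$methods)) {
    stop("method set mismatch: weights trained on {",
         paste(object$methods, collapse = ", "), "}, scores supply {",
         paste(newdata$methods, collapse = ", "), "}")
  }
  lengths <- L
  out <- list()
  for (spec in specs) {
    if (!spec %in% rownames(object$weights)) {
      stop("no sub-model trained for spec '", spec, "'")
    }
    per_prot <- list()
    for (pid in names(newdata$scores)) {
      Lp <- if (!is.null(lengths)) lengths[[pid]]
            else if (!is.null(newdata$truths)) newdata$truths[[pid]]$L
            else stop("protein lengths required: supply L or truths")
      tensor <- prepare_protein(newdata$scores[[pid]], truth = NULL,
                                spec = "4.5L", L = Lp)
      per_prot[[pid]] <- predict_contacts(tensor, object, spec = spec, L = Lp)
    }
    out[[spec]] <- per_prot
  }
  out
}

#' Convert a consensus prediction to a prediction set
#'
#' Useful for writing consensus output in RR format via [write_rr()].
#'
#' @param prediction a `consensus_prediction`.
#' @param method_id method id to attach (default `"consensus"`).
#' @return a [prediction_set()].
#' @export
as_prediction_set <- function(prediction, method_id = "consensus") {
  prediction_set(prediction$protein_id, method_id,
                 cbind(prediction$entries$i, prediction$entries$j),
                 prediction$entries$score)
}
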