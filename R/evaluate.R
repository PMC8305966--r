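# Top-kL evaluation metrics, method-overlap Jaccard matrices and
# Bland-Altman agreement analysis.

#' Confusion counts of a contact prediction
#'
#' Counts TP/FP/FN/TN of a predicted pair set against a native contact map
#' over an evaluation universe.  The default universe is every pair with
#' `j - i >= min_separation` and `j <= L` — the negative universe needed by
#' specificity and NPV.
#'
#' @param predicted 2-column pair matrix (or `consensus_prediction` /
#'   [prediction_set()]).
#' @param truth a [contact_map()].
#' @param universe optional restricted universe (2-column pair matrix);
#'   must contain all predicted pairs.
#' @return object of class `confusion_counts`: list TP, FP, TN, FN,
#'   n_universe.
#' @export
confusion_counts <- function(predicted, truth, universe = NULL) {
  if (inherits(predicted, "consensus_prediction")) {
    predicted <- cbind(predicted$entries$i, predicted$entries$j)
  } else if (inherits(predicted, "prediction_set")) {
    predicted <- pred_pairs(predicted)
  }
  predicted <- canonical_pairs(predicted)
  if (is.null(universe)) {
    universe <- eligible_pairs(truth$L, truth$min_separation)
  } else {
    universe <- canonical_pairs(universe)
  }
  uk <- pair_keys(universe)
  pk <- pair_keys(predicted)
  if (!all(pk %in% uk)) stop("predicted pairs outside the evaluation universe")
  ck <- pair_keys(truth$contacts)
  ck <- ck[ck %in% uk]  # contacts restricted to the universe
  tp <- sum(pk %in% ck)
  fp <- length(pk) - tp
  fn <- length(ck) - tp
  tn <- length(uk) - tp - fp - fn
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 n_universe = length(uk)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d  (universe %d pairs)\n",
              x$TP, x$FP, x$TN, x$FN, x$n_universe))
  invisible(x)
}

#' Prediction accuracy (positive predictive value)
#'
#' `TP / (TP + FP)`: the fraction of predicted contacts that are native.
#' NaN (with a warning) when nothing was predicted.
#'
#' @param c a [confusion_counts()].
#' @return numeric in `[0, 1]` or NaN.
#' @export
accuracy <- function(c) {
  if (c$TP + c$FP == 0) {
    warning("accuracy undefined: no predicted contacts")
    return(NaN)
  }
  c$TP / (c$TP + c$FP)
}

#' Coverage (true positive rate / sensitivity)
#'
#' `TP / (TP + FN)`: the fraction of native contacts recovered.
#'
#' @inheritParams accuracy
#' @return numeric in `[0, 1]` or NaN when there are no native contacts.
#' @export
coverage <- function(c) {
  if (c$TP + c$FN == 0) {
    warning("coverage undefined: no native contacts in universe")
    return(NaN)
  }
  c$TP / (c$TP + c$FN)
}

#' Specificity (true negative rate)
#'
#' `TN / (TN + FP)`.
#'
#' @inheritParams accuracy
#' @return numeric in `[0, 1]` or NaN when there are no negatives.
#' @export
specificity <- function(c) {
  if (c$TN + c$FP == 0) {
    warning("specificity undefined: no negative pairs in universe")
    return(NaN)
  }
  c$TN / (c$TN + c$FP)
}

#' Negative predictive value
#'
#' `TN / (TN + FN)`.
#'
#' @inheritParams accuracy
#' @return numeric in `[0, 1]` or NaN when nothing was called negative.
#' @export
npv <- function(c) {
  if (c$TN + c$FN == 0) {
    warning("NPV undefined: no negative calls")
    return(NaN)
  }
  c$TN / (c$TN + c$FN)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the balanced
#' two-class quality score in `[-1, 1]`.  When any denominator factor is 0
#' the conventional value 0 is returned.
#'
#' @inheritParams accuracy
#' @return numeric in `[-1, 1]`.
#' @export
mcc <- function(c) {
  den <- prod(sqrt(c(c$TP + c$FP, c$TP + c$FN, c$TN + c$FP, c$TN + c$FN)))
  if (den == 0) return(0)
  (c$TP * c$TN - c$FP * c$FN) / den
}

all_metrics <- function(c) {
  c(accuracy = suppressWarnings(accuracy(c)),
    coverage = suppressWarnings(coverage(c)),
    specificity = suppressWarnings(specificity(c)),
    npv = suppressWarnings(npv(c)),
    mcc = mcc(c))
}

#' Jaccard similarity of two pair sets
#'
#' `|A intersect B| / |A union B|`; measures how redundant two predictors'
#' returned pair sets are.
#'
#' @param a,b 2-column pair matrices (or [prediction_set()]s, whose pairs
#'   are used).
#' @return numeric in `[0, 1]`; NaN with a warning when both sets are
#'   empty.
#' @export
jaccard_similarity <- function(a, b) {
  if (inherits(a, "prediction_set")) a <- pred_pairs(a)
  if (inherits(b, "prediction_set")) b <- pred_pairs(b)
  ka <- pair_keys(canonical_pairs(a))
  kb <- pair_keys(canonical_pairs(b))
  u <- union(ka, kb)
  if (length(u) == 0) {
    warning("Jaccard undefined: both sets empty")
    return(NaN)
  }
  length(intersect(ka, kb)) / length(u)
}

#' Pairwise Jaccard matrix of several methods' pair sets
#'
#' @param sets named list of pair matrices or [prediction_set()]s.
#' @return symmetric matrix with unit diagonal.
#' @export
jaccard_matrix <- function(sets) {
  m <- length(sets)
  out <- matrix(1, m, m, dimnames = list(names(sets), names(sets)))
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      if (a < b) {
        out[a, b] <- out[b, a] <- jaccard_similarity(sets[[a]], sets[[b]])
      }
    }
  }
  out
}

#' Bland-Altman agreement analysis
#'
#' Paired-difference comparison of two methods' per-protein accuracies (or
#' any paired measurements): mean bias, sample SD of the differences,
#' limits of agreement at bias +/- 2*SD, and the percentage of differences
#' inside the closed limits.
#'
#' @param paired_a,paired_b numeric vectors of equal length >= 2.
#' @return object of class `bland_altman`: `bias`, `sd`, `limits`
#'   (lower, upper), `pct_within`, plus the differences and pair means for
#'   plotting.
#' @export
bland_altman <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b)) {
    stop("paired vectors must have equal length")
  }
  if (length(paired_a) < 2) stop("at least two pairs required")
  d <- paired_a - paired_b
  bias <- mean(d)
  s <- stats::sd(d)
  limits <- c(lower = bias - 2 * s, upper = bias + 2 * s)
  within <- d >= limits[1] & d <= limits[2]
  structure(
    list(bias = bias, sd = s, limits = limits,
         pct_within = 100 * mean(within),
         differences = d, means = (paired_a + paired_b) / 2),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4f, SD %.4f, limits [%.4f, %.4f], %.1f%% within\n",
              x$bias, x$sd, x$limits[1], x$limits[2], x$pct_within))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences, xlab = "mean of pair",
                 ylab = "difference", ...)
  graphics::abline(h = c(x$bias, x$limits), lty = c(1, 3, 3))
  invisible(x)
}

#' Evaluate predictions across a corpus
#'
#' Computes the five standard metrics per protein and macro-averages them
#' over proteins, per top-k cutoff; pooled confusion counts are reported
#' alongside for reference.
#'
#' @param predictions named list: spec -> named list: protein ->
#'   prediction (`consensus_prediction`, [prediction_set()] or pair
#'   matrix), as returned by [predict.comtop()].
#' @param truths named list: protein -> [contact_map()].
#' @return data.frame with one row per spec: macro-averaged accuracy,
#'   coverage, specificity, npv, mcc, pooled TP/FP/TN/FN, n_proteins.
#' @export
evaluate_suite <- function(predictions, truths) {
  stopifnot(length(predictions) >= 1)
  rows <- lapply(names(predictions), function(spec) {
    per_prot <- predictions[[spec]]
    missing_truth <- setdiff(names(per_prot), names(truths))
    if (length(missing_truth)) {
      stop("missing truth for protein(s): ",
           paste(missing_truth, collapse = ", "))
    }
    counts <- lapply(names(per_prot), function(pid) {
      confusion_counts(per_prot[[pid]], truths[[pid]])
    })
    per_metrics <- do.call(rbind, lapply(counts, all_metrics))
    pooled <- Reduce(function(a, b) {
      list(TP = a$TP + b$TP, FP = a$FP + b$FP, TN = a$TN + b$TN,
           FN = a$FN + b$FN, n_universe = a$n_universe + b$n_universe)
    }, counts)
    data.frame(
      spec = spec,
      accuracy = mean(per_metrics[, "accuracy"], na.rm = TRUE),
      coverage = mean(per_metrics[, "coverage"], na.rm = TRUE),
      specificity = mean(per_metrics[, "specificity"], na.rm = TRUE),
      npv = mean(per_metrics[, "npv"], na.rm = TRUE),
      mcc = mean(per_metrics[, "mcc"], na.rm = TRUE),
      TP = pooled$TP, FP = pooled$FP, TN = pooled$TN, FN = pooled$FN,
      n_proteins = length(per_prot)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-method top-kL baseline predictions
#'
#' Ranks each individual method's own normalized scores and reports its
#' top-kL pairs, for side-by-side evaluation against the consensus.
#'
#' @param corpus a [contact_corpus()].
#' @param method_id which method to extract.
#' @param specs top-k cutoffs.
#' @return named list: spec -> named list: protein -> [prediction_set()].
#' @export
method_baseline <- function(corpus, method_id, specs = "L") {
  stopifnot(inherits(corpus, "contact_corpus"))
  if (!method_id %in% corpus$methods) stop("unknown method: ", method_id)
  out <- list()
  for (spec in specs) {
    per_prot <- list()
    for (pid in names(corpus$scores)) {
      Lp <- if (!is.null(corpus$truths)) corpus$truths[[pid]]$L else
        max(corpus$scores[[pid]][[method_id]]$entries$j)
      per_prot[[pid]] <- select_top_k(corpus$scores[[pid]][[method_id]],
                                      resolve_topk_count(Lp, spec))
    }
    out[[spec]] <- per_prot
  }
  out
}
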