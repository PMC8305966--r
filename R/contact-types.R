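#' comtop: consensus residue-residue contact prediction by mixed integer
#' linear optimization
#'
#' Combines the confidence scores of several residue-residue contact
#' predictors into a consensus predictor.  Per-method weights are learned by
#' solving a mixed integer linear program that maximizes, over a training
#' corpus, the number of residue pairs for which the weighted score mass of
#' correct predictions exceeds that of incorrect ones.  The consensus score
#' of a pair is then the weight-averaged method confidence, and the top-kL
#' highest-scoring pairs of a protein of length L are reported as contacts.
#'
#' The fitting entry point is [comtop()]; synthetic corpora for development
#' and benchmarking come from [generate_corpus()]; evaluation helpers follow
#' the standard top-kL contact metrics ([evaluate_suite()], [mcc()],
#' [bland_altman()], [jaccard_similarity()]).
#'
#' @keywords internal
"_PACKAGE"

# ---- residue-pair primitives -------------------------------------------

# Pairs are stored as 2-column integer matrices (columns i, j) in canonical
# order i < j.  A string key "i:j" is used for set operations.

#' Canonicalize a set of residue pairs
#'
#' Reorders each pair so that `i < j`, drops duplicates and sorts rows by
#' `(i, j)`.  Pairs with `i == j` are an error: a residue cannot contact
#' itself in a contact map.
#'
#' @param i,j integer vectors of residue indices (1-based), or `i` may be a
#'   2-column matrix in which case `j` is ignored.
#' @return integer matrix with columns `i`, `j`, `i < j`, no duplicates,
#'   sorted by `(i, j)`.
#' @examples
#' canonical_pairs(c(9, 2), c(1, 8))
#' @export
canonical_pairs <- function(i, j = NULL) {
  if (is.matrix(i)) {
    stopifnot(ncol(i) == 2)
    j <- i[, 2]
    i <- i[, 1]
  }
  if (length(i) != length(j)) stop("i and j must have equal length")
  if (length(i) == 0) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  i <- as.integer(i)
  j <- as.integer(j)
  if (anyNA(i) || anyNA(j)) stop("residue indices must be non-missing integers")
  if (any(i < 1L) || any(j < 1L)) stop("residue indices must be >= 1")
  if (any(i == j)) stop("self-pairs (i == j) are not valid residue contacts")
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  m <- unique(cbind(i = lo, j = hi))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

pair_keys <- function(pairs) {
  if (nrow(pairs) == 0) return(character(0))
  paste(pairs[, 1], pairs[, 2], sep = ":")
}

keys_to_pairs <- function(keys) {
  if (length(keys) == 0) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  parts <- strsplit(keys, ":", fixed = TRUE)
  canonical_pairs(
    as.integer(vapply(parts, `[`, "", 1L)),
    as.integer(vapply(parts, `[`, "", 2L))
  )
}

# ---- true contact map ---------------------------------------------------

#' Construct a native contact map
#'
#' A contact map is the ground truth for training and evaluation: the set of
#' residue pairs of a protein of length `L` that are in contact in the
#' native structure, subject to a minimum sequence separation.
#'
#' @param protein_id protein identifier.
#' @param L sequence length in residues.
#' @param contacts residue pairs (2-column matrix or data.frame with i, j).
#' @param min_separation minimum sequence separation `j - i` of a valid
#'   contact (residues).
#' @param distance_threshold distance threshold in Angstrom, recorded only
#'   when the map was derived from structure coordinates.
#' @return object of class `contact_map` with fields `protein_id`, `L`,
#'   `contacts`, `min_separation`, `distance_threshold`.
#' @examples
#' contact_map("toy", L = 50, contacts = cbind(c(2, 3), c(10, 30)))
#' @export
contact_map <- function(protein_id, L, contacts,
                        min_separation = 6L, distance_threshold = NA_real_) {
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("L must be a positive integer")
  if (is.data.frame(contacts)) contacts <- as.matrix(contacts[, 1:2])
  contacts <- canonical_pairs(contacts)
  if (nrow(contacts) > 0) {
    if (any(contacts[, 2] > L)) {
      stop("contact with residue index j > L in protein ", protein_id)
    }
    sep <- contacts[, 2] - contacts[, 1]
    if (any(sep < min_separation)) {
      stop("contact with separation below min_separation in protein ",
           protein_id)
    }
  }
  structure(
    list(protein_id = as.character(protein_id), L = L, contacts = contacts,
         min_separation = as.integer(min_separation),
         distance_threshold = distance_threshold),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("Native contact map '%s': L = %d, %d contacts (separation >= %d%s)\n",
              x$protein_id, x$L, nrow(x$contacts), x$min_separation,
              if (is.na(x$distance_threshold)) ""
              else sprintf(", threshold %.1f A", x$distance_threshold)))
  invisible(x)
}

is_contact <- function(map, pairs) {
  pair_keys(pairs) %in% pair_keys(map$contacts)
}

# All pairs eligible for evaluation: j - i >= min_separation, j <= L.
eligible_pairs <- function(L, min_separation = 6L) {
  if (L <= min_separation) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  idx <- which(outer(seq_len(L), seq_len(L), function(a, b) b - a >= min_separation),
               arr.ind = TRUE)
  canonical_pairs(idx[, 1], idx[, 2])
}

# ---- per-method prediction set -----------------------------------------

#' Construct one predictor's scored pair list for one protein
#'
#' @param protein_id protein identifier.
#' @param method_id predictor identifier.
#' @param pairs residue pairs (2-column matrix); canonicalized to `i < j`.
#' @param confidence numeric confidence score per pair.
#' @param dedupe how to resolve duplicate pairs after canonicalization:
#'   `"max"` keeps the highest confidence (deterministic and order
#'   independent), `"error"` refuses.
#' @return object of class `prediction_set`: list with `protein_id`,
#'   `method_id` and an `entries` data.frame (i, j, confidence) ordered by
#'   decreasing confidence, ties by (i, j).
#' @examples
#' prediction_set("toy", "mA", cbind(c(1, 2), c(9, 8)), c(0.7, 0.9))
#' @export
prediction_set <- function(protein_id, method_id, pairs, confidence,
                           dedupe = c("max", "error")) {
  dedupe <- match.arg(dedupe)
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs[, 1:2])
  if (nrow(pairs) != length(confidence)) {
    stop("confidence must have one value per pair")
  }
  if (anyNA(confidence) || any(is.nan(confidence))) {
    stop("confidence scores must be non-missing")
  }
  if (nrow(pairs) > 0) {
    i <- pmin(pairs[, 1], pairs[, 2])
    j <- pmax(pairs[, 1], pairs[, 2])
    if (any(i == j)) stop("self-pairs (i == j) are not valid predictions")
    key <- paste(i, j, sep = ":")
    if (anyDuplicated(key)) {
      if (dedupe == "error") stop("duplicate pairs in prediction set")
      ord <- order(key, -confidence)
      keep <- !duplicated(key[ord])
      sel <- ord[keep]
      i <- i[sel]; j <- j[sel]; confidence <- confidence[sel]
    }
    ord <- order(-confidence, i, j)
    entries <- data.frame(i = as.integer(i[ord]), j = as.integer(j[ord]),
                          confidence = as.numeric(confidence[ord]))
  } else {
    entries <- data.frame(i = integer(0), j = integer(0),
                          confidence = numeric(0))
  }
  structure(
    list(protein_id = as.character(protein_id),
         method_id = as.character(method_id), entries = entries),
    class = "prediction_set"
  )
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("Prediction set: protein '%s', method '%s', %d pairs\n",
              x$protein_id, x$method_id, nrow(x$entries)))
  if (nrow(x$entries) > 0) {
    print(utils::head(x$entries, 5))
    if (nrow(x$entries) > 5) cat("...\n")
  }
  invisible(x)
}

pred_pairs <- function(ps) {
  cbind(i = ps$entries$i, j = ps$entries$j)
}

# ---- seeded RNG helper --------------------------------------------------

# Evaluate `expr` under a local RNG stream; the caller's RNG state is
# untouched.  All stochastic generators in the package route through this.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Derive a reproducible 32-bit sub-seed from a base seed and an index.
sub_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483629)
}
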