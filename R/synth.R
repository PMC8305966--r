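# Synthetic proteins, contact maps and correlated imperfect predictor
# ensembles: makes every stage testable without running any upstream
# predictor.

#' Configuration for a synthetic corpus
#'
#' The generator emulates a training corpus of proteins with known contact
#' maps and an ensemble of imperfect predictors.  Each method's latent
#' pair score is `rho * contact_indicator + (1 - rho) * noise`, where the
#' noise linearly mixes a method-private uniform component with a shared
#' per-pair uniform component: `shared_error_weight` therefore tunes the
#' Jaccard overlap between methods' returned pair lists, the redundancy
#' structure that drives correlated weights.
#'
#' @param n_proteins number of proteins.
#' @param L_range length range (min >= 20 residues); lengths are drawn
#'   uniformly.
#' @param contact_density expected native contacts per residue; each map
#'   gets `round(density * L)` contacts.
#' @param methods data.frame with columns `method_id`, `reliability`
#'   (rho in `[0,1]`), `shared_error_weight` (in `[0,1]`), and optionally
#'   `noise_scale` (SD of extra Gaussian jitter on the latent score,
#'   default 0).  The default ensemble is three predictors of strongly
#'   graded reliability with independent errors.
#' @param min_separation sequence-separation floor for contacts.
#' @param output_spec how much each method returns (top-kL specifier;
#'   `"5L"` mirrors the candidate lists consumed in training).
#' @param seed integer seed; every output is a pure function of
#'   (config, seed).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 10L, L_range = c(40L, 80L),
                         contact_density = 1.0,
                         methods = data.frame(
                           method_id = c("mA", "mB", "mC"),
                           reliability = c(0.85, 0.55, 0.30),
                           shared_error_weight = c(0, 0, 0)
                         ),
                         min_separation = 6L, output_spec = "5L",
                         seed = 1L) {
  stopifnot(n_proteins >= 1, length(L_range) == 2, L_range[1] >= 20,
            L_range[1] <= L_range[2], contact_density > 0)
  if (!all(c("method_id", "reliability", "shared_error_weight") %in%
           names(methods))) {
    stop("methods needs columns method_id, reliability, shared_error_weight")
  }
  if (any(methods$reliability < 0 | methods$reliability > 1)) {
    stop("reliabilities must lie in [0, 1]")
  }
  if (any(methods$shared_error_weight < 0 | methods$shared_error_weight > 1)) {
    stop("shared_error_weight must lie in [0, 1]")
  }
  if (is.null(methods$noise_scale)) methods$noise_scale <- 0
  structure(
    list(n_proteins = as.integer(n_proteins), L_range = as.integer(L_range),
         contact_density = contact_density, methods = methods,
         min_separation = as.integer(min_separation),
         output_spec = output_spec, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a synthetic native contact map
#'
#' Samples `round(density * L)` distinct pairs with separation at least
#' `min_separation`, biased toward short separations (sampling weight
#' proportional to `1 / (j - i)`) so that the map shows the near-diagonal
#' banding of real contact maps.  Deterministic per seed.
#'
#' @param L protein length.
#' @param density expected contacts per residue.
#' @param min_separation separation floor.
#' @param seed integer seed.
#' @param protein_id identifier for the map.
#' @return a [contact_map()].
#' @export
generate_contact_map <- function(L, density = 1.0, min_separation = 6L,
                                 seed = 1L, protein_id = "synthetic") {
  elig <- eligible_pairs(L, min_separation)
  n_contacts <- round(density * L)
  if (n_contacts > nrow(elig)) {
    stop("density * L exceeds the number of eligible pairs")
  }
  sep <- elig[, 2] - elig[, 1]
  idx <- with_seed(seed, sample.int(nrow(elig), n_contacts, prob = 1 / sep))
  contact_map(protein_id, L = L, contacts = elig[idx, , drop = FALSE],
              min_separation = min_separation)
}

#' Generate one imperfect predictor's scores for a protein
#'
#' Latent score per eligible pair:
#' `rho * is_contact + (1 - w) * private + w * shared`
#' with `private ~ U(0,1)` per method and `shared` a per-pair latent
#' common to all methods (inducing inter-method overlap), plus optional
#' Gaussian jitter of SD `noise_scale`.  The noise term keeps full
#' amplitude at every reliability, so the signal and noise ranges overlap
#' and ranking accuracy grades smoothly with `rho` (rho = 0 is an
#' uninformative predictor, rho = 1 an essentially perfect one).
#' Scores are min-max normalized and
#' only the method's top pairs (per `output_spec`) are returned, emulating
#' the truncated candidate lists real predictors emit.
#'
#' @param truth the protein's [contact_map()].
#' @param method_id predictor identifier.
#' @param reliability rho in `[0,1]`; 1 ranks exactly the native contacts
#'   first, 0 is uninformative.
#' @param shared_error_weight mixing weight of the shared noise component.
#' @param shared_noise numeric vector of per-pair shared latents aligned
#'   with `eligible_pairs(truth$L, truth$min_separation)`; generated from
#'   the seed when NULL.
#' @param noise_scale SD of additional Gaussian jitter (default 0).
#' @param output_spec top-k specifier for the returned list size.
#' @param seed integer seed.
#' @return a [prediction_set()].
#' @export
generate_method_scores <- function(truth, method_id, reliability,
                                   shared_error_weight = 0,
                                   shared_noise = NULL, noise_scale = 0,
                                   output_spec = "5L", seed = 1L) {
  elig <- eligible_pairs(truth$L, truth$min_separation)
  n <- nrow(elig)
  if (is.null(shared_noise)) {
    shared_noise <- with_seed(sub_seed(seed, 104729L), stats::runif(n))
  }
  if (length(shared_noise) != n) {
    stop("shared_noise must have one value per eligible pair")
  }
  ind <- as.numeric(is_contact(truth, elig))
  latent <- with_seed(seed, {
    private <- stats::runif(n)
    noise <- (1 - shared_error_weight) * private +
      shared_error_weight * shared_noise
    # Full-amplitude noise: the signal and noise score ranges overlap for
    # every rho < 1, so top-L accuracy grades smoothly with reliability
    # instead of snapping to perfect once rho exceeds the noise ceiling.
    x <- reliability * ind + noise
    if (noise_scale > 0) x <- x + stats::rnorm(n, sd = noise_scale)
    x
  })
  # quantize to the RR printed precision so that writing the corpus to
  # disk and reading it back is lossless (end-to-end determinism)
  ps <- prediction_set(truth$protein_id, method_id, elig,
                       round(minmax_normalize(latent), 6))
  select_top_k(ps, resolve_topk_count(truth$L, output_spec))
}

#' Generate a full synthetic corpus
#'
#' Draws protein lengths, contact maps and per-method truncated score lists
#' per the configuration.  Byte-identical for identical (config, seed).
#'
#' @param config a [synth_config()].
#' @return a [contact_corpus()] with truths; the config is attached as
#'   attribute `"config"`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_proteins
  Ls <- with_seed(config$seed, {
    sample(config$L_range[1]:config$L_range[2], n, replace = TRUE)
  })
  truths <- list()
  scores <- list()
  for (k in seq_len(n)) {
    pid <- sprintf("synth%03d", k)
    truths[[pid]] <- generate_contact_map(
      Ls[k], config$contact_density, config$min_separation,
      seed = sub_seed(config$seed, k), protein_id = pid
    )
    shared <- with_seed(sub_seed(config$seed, 100000L + k), {
      stats::runif(nrow(eligible_pairs(Ls[k], config$min_separation)))
    })
    scores[[pid]] <- list()
    for (q in seq_len(nrow(config$methods))) {
      mrow <- config$methods[q, ]
      scores[[pid]][[mrow$method_id]] <- generate_method_scores(
        truths[[pid]], mrow$method_id, mrow$reliability,
        shared_error_weight = mrow$shared_error_weight,
        shared_noise = shared, noise_scale = mrow$noise_scale,
        output_spec = config$output_spec,
        seed = sub_seed(config$seed, 200000L + 1000L * k + q)
      )
    }
  }
  corpus <- contact_corpus(scores, truths)
  attr(corpus, "config") <- config
  corpus
}
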