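# Shared fixtures: hand-built tensors, random MILP instances and a tiny
# PDB writer.  Everything is generated in code; no binary fixtures.

# Build a contact_tensor directly from explicit matrices (bypassing file
# I/O) — used to pin down solver behaviour on hand-checkable instances.
mk_tensor <- function(conf, labels, protein_id = "toy", L = 50L,
                      missing = NULL, truth = NULL) {
  n <- nrow(conf)
  pairs <- cbind(i = seq_len(n), j = seq_len(n) + 10L)
  structure(
    list(protein_id = protein_id, L = L, pairs = pairs,
         methods = colnames(conf), conf = conf, labels = labels,
         missing = missing %||% matrix(FALSE, n, ncol(conf)),
         truth = truth %||% (labels[, 1] == 1), imputed = TRUE),
    class = "contact_tensor"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The worked two-pair, two-method instance: pair A is called correctly by
# m1 (conf 0.9) and wrongly by m2 (conf 0.8); pair B wrongly by m1 (0.2)
# and correctly by m2 (0.9).
micro_instance <- function(margin_mode = "hard_count") {
  conf <- matrix(c(0.9, 0.8,
                   0.2, 0.9), 2, 2, byrow = TRUE,
                 dimnames = list(NULL, c("m1", "m2")))
  labs <- matrix(c(1, 0,
                   0, 1), 2, 2, byrow = TRUE, dimnames = dimnames(conf))
  milp_instance(list(mk_tensor(conf, labs)), margin_mode = margin_mode)
}

# Random small training instance with uniform confidences and Bernoulli
# labels; sizes per the oracle-comparison protocol.
random_instance <- function(seed, n_range = 5:30, m_range = 2:3,
                            margin_mode = "hard_count") {
  set.seed(seed)
  n <- sample(n_range, 1)
  m <- sample(m_range, 1)
  conf <- matrix(runif(n * m), n, m, dimnames = list(NULL, paste0("m", 1:m)))
  labs <- matrix(rbinom(n * m, 1, 0.5), n, m, dimnames = dimnames(conf))
  milp_instance(list(mk_tensor(conf, labs, L = 100L)),
                margin_mode = margin_mode)
}

# Minimal PDB text for structure-derived contact tests: one CA (and
# optionally CB) per residue at given coordinates.
write_mini_pdb <- function(path, resno, xyz_cb, resname = NULL,
                           chain = "A", xyz_ca = NULL) {
  stopifnot(length(resno) == nrow(xyz_cb))
  resname <- resname %||% rep("ALA", length(resno))
  xyz_ca <- xyz_ca %||% (xyz_cb + matrix(c(0.5, 0, 0), nrow(xyz_cb), 3,
                                         byrow = TRUE))
  fmt <- function(serial, name, resn, resno, x, y, z) {
    sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            serial, name, resn, chain, resno, x, y, z, 1, 0)
  }
  lines <- character(0)
  serial <- 0L
  for (k in seq_along(resno)) {
    serial <- serial + 1L
    lines <- c(lines, fmt(serial, "CA", resname[k], resno[k],
                          xyz_ca[k, 1], xyz_ca[k, 2], xyz_ca[k, 3]))
    if (resname[k] != "GLY") {
      serial <- serial + 1L
      lines <- c(lines, fmt(serial, "CB", resname[k], resno[k],
                            xyz_cb[k, 1], xyz_cb[k, 2], xyz_cb[k, 3]))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

pair_keys_test <- function(pairs) paste(pairs[, 1], pairs[, 2], sep = ":")

pred_pairs_test <- function(ps) cbind(ps$entries$i, ps$entries$j)

# tiny corpus for fast end-to-end tests
small_config <- function(seed = 1L, n_proteins = 4L, L_range = c(30L, 40L),
                         reliabilities = c(0.85, 0.55, 0.30),
                         shared = 0) {
  synth_config(
    n_proteins = n_proteins, L_range = L_range,
    methods = data.frame(
      method_id = paste0("m", LETTERS[seq_along(reliabilities)]),
      reliability = reliabilities,
      shared_error_weight = shared
    ),
    seed = seed
  )
}
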