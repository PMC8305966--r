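# The weight-training mixed integer linear program.
#
# Variables: per-method weights lambda (simplex), one binary y per
# (protein, pair), one non-negative slack eps per (protein, pair).
# Objective: maximize sum(y) - sum(eps).  One constraint per pair:
#
#   wrong(p) - correct(p) + s * eps_p <= 1 - y_p - delta
#
# with correct(p) = sum_m lambda_m * confS * predSS and wrong(p) the
# complement, s = +1 in the hard-count formulation (the slack only
# tightens, so optimal eps = 0 and the objective is a pure count of
# correctly discriminated pairs) and s = -1 in the soft-margin formulation
# (eps buys constraint slack at objective cost).  delta converts the strict
# inequality of the discrimination rule into a solvable "<=".

#' Build a weight-training MILP instance
#'
#' Stacks the per-protein tensors into the coefficient structure of the
#' training program.  Row p of the coefficient matrix `C` holds, per method,
#' `confS * (1 - 2 * predSS)`, so that `C %*% lambda` is the margin
#' `wrong - correct` of that pair.
#'
#' @param tensors list of imputed `contact_tensor`s (see
#'   [prepare_protein()]); all must share the same method set.
#' @param margin_mode `"soft_margin"` (default; eps relaxes the constraint
#'   and is penalized) or `"hard_count"` (eps tightens and is inert).
#' @param delta strictness tolerance replacing the strict inequality;
#'   must be positive and small relative to score margins.
#' @return object of class `milp_instance`.
#' @export
milp_instance <- function(tensors, margin_mode = c("soft_margin", "hard_count"),
                          delta = 1e-4) {
  margin_mode <- match.arg(margin_mode)
  if (delta <= 0) stop("delta must be positive")
  stopifnot(length(tensors) >= 1)
  methods <- tensors[[1]]$methods
  for (tn in tensors) {
    stopifnot(inherits(tn, "contact_tensor"))
    if (!identical(tn$methods, methods)) {
      stop("all tensors must share the same ordered method set")
    }
    if (!tn$imputed || anyNA(tn$conf) || anyNA(tn$labels)) {
      stop("tensors must be imputed (scores and labels) before training")
    }
  }
  C <- do.call(rbind, lapply(tensors, function(tn) tn$conf * (1 - 2 * tn$labels)))
  protein <- unlist(lapply(tensors, function(tn) {
    rep(tn$protein_id, nrow(tn$pairs))
  }))
  pair_id <- unlist(lapply(tensors, function(tn) pair_keys(tn$pairs)))
  if (nrow(C) == 0) stop("empty pair set: nothing to train on")
  structure(
    list(C = unname(C), methods = methods, protein = protein,
         pair = pair_id, margin_mode = margin_mode, delta = delta),
    class = "milp_instance"
  )
}

#' @export
print.milp_instance <- function(x, ...) {
  cat(sprintf("MILP instance: %d pairs x %d methods (%d proteins), mode %s, delta %g\n",
              nrow(x$C), length(x$methods), length(unique(x$protein)),
              x$margin_mode, x$delta))
  invisible(x)
}

#' Describe the MILP model of an instance
#'
#' Expands an instance into an explicit model description: variable counts
#' and one linear constraint row per pair plus the weight-simplex equality.
#' Mostly useful for inspection and verification; [solve_milp()] consumes
#' the instance directly.
#'
#' @param instance a [milp_instance()].
#' @return list with `n_binary` (one y per pair), `n_continuous` (lambdas
#'   plus one eps per pair), `n_constraints`, `lambda_coef` (the matrix C),
#'   `y_coef`, `eps_coef`, `rhs`, `delta`, `margin_mode`.
#' @export
build_milp <- function(instance) {
  stopifnot(inherits(instance, "milp_instance"))
  n <- nrow(instance$C)
  m <- length(instance$methods)
  list(
    n_binary = n,
    n_continuous = m + n,
    n_constraints = n + 1L,  # one per pair + the simplex equality
    lambda_coef = instance$C,
    y_coef = rep(1, n),
    eps_coef = rep(if (instance$margin_mode == "hard_count") 1 else -1, n),
    rhs = rep(1 - instance$delta, n),
    delta = instance$delta,
    margin_mode = instance$margin_mode
  )
}

# margin a_p = wrong - correct for each pair at the given weights
pair_margins <- function(instance, lambdas) {
  as.vector(instance$C %*% lambdas)
}

# Count of pairs the MILP may discriminate at fixed weights: the model
# constraint allows y = 1 iff a_p <= -delta (closed), so the count uses the
# closed rule with a small numerical slack for LP vertices that sit exactly
# on the boundary.  The spec-level oracle objective_at() keeps the strict
# "margin > delta" reading; the two differ only on boundary ties.
milp_count <- function(instance, lambdas, num_tol = 1e-9) {
  a <- pair_margins(instance, lambdas)
  sum(a <= -instance$delta + num_tol)
}

check_simplex <- function(lambdas, m, tol = 1e-6) {
  if (length(lambdas) != m) stop("lambda length does not match method count")
  if (any(lambdas < -tol) || abs(sum(lambdas) - 1) > tol) {
    stop("lambda is off the probability simplex beyond tolerance ", tol)
  }
}

#' Evaluate the training objective at fixed weights
#'
#' With the weights fixed the program separates by pair.  In `"count"` form
#' (the discrimination count that the training objective maximizes in the
#' hard-count formulation, and the quantity the brute-force oracle searches
#' over) a pair scores 1 exactly when the correct score mass exceeds the
#' incorrect mass by more than `delta`, with `eps = 0`.  In `"soft"` form
#' the per-pair optimum of `y - eps` under the soft-margin constraint is
#' `min(1, 1 - delta - (wrong - correct))`, and the objective is its sum.
#'
#' @param lambdas weight vector on the probability simplex (checked to
#'   1e-6).
#' @param instance a [milp_instance()].
#' @param form `"count"` (default) or `"soft"`.
#' @return list with `objective` and the binary `y` assignment.
#' @export
objective_at <- function(lambdas, instance, form = c("count", "soft")) {
  form <- match.arg(form)
  stopifnot(inherits(instance, "milp_instance"))
  check_simplex(lambdas, length(instance$methods))
  a <- pair_margins(instance, lambdas)
  if (form == "count") {
    y <- (-a) > instance$delta  # correct - wrong > delta
    list(objective = sum(y), y = as.integer(y))
  } else {
    contrib <- pmin(1, 1 - instance$delta - a)
    y <- as.integer(a <= 1 - instance$delta)
    list(objective = sum(contrib), y = y)
  }
}

# objective in the instance's own training mode
mode_objective_at <- function(lambdas, instance) {
  objective_at(lambdas, instance,
               form = if (instance$margin_mode == "hard_count") "count" else "soft")
}

# ---- soft-margin solve: exact cutting planes ---------------------------

# g(lambda) = sum_p min(1, 1 - delta - C_p lambda) is concave piecewise
# linear; Kelley's method with exact supporting cuts and evaluated
# incumbents converges to the global optimum.  Unit vectors and the uniform
# point are seeded, so the returned objective dominates every single-method
# weighting by construction.
solve_soft_margin <- function(instance, time_limit = 600, tol = 1e-8,
                              max_iter = 400L) {
  C <- instance$C
  m <- ncol(C)
  delta <- instance$delta
  g_eval <- function(lam) {
    a <- as.vector(C %*% lam)
    on_linear <- a >= -delta
    list(value = sum(pmin(1, 1 - delta - a)),
         subgrad = -colSums(C[on_linear, , drop = FALSE]))
  }
  seeds <- c(lapply(seq_len(m), function(k) replace(rep(0, m), k, 1)),
             list(rep(1 / m, m)))
  if (m == 1L) {
    ev <- g_eval(1)
    return(list(lambdas = 1, objective = ev$value, status = "optimal",
                gap = 0, iterations = 0L))
  }
  cuts <- list()
  best_val <- -Inf
  best_lam <- NULL
  add_cut <- function(lam) {
    ev <- g_eval(lam)
    cuts[[length(cuts) + 1]] <<- list(lam = lam, val = ev$value, sg = ev$subgrad)
    if (ev$value > best_val + 1e-12) {
      best_val <<- ev$value
      best_lam <<- lam
    }
    ev$value
  }
  for (s in seeds) add_cut(s)
  t0 <- proc.time()[["elapsed"]]
  ub <- Inf
  status <- "feasible"
  for (iter in seq_len(max_iter)) {
    # master: maximize v over lambda in simplex, v <= cut supports;
    # v is split into vp - vn to keep all variables non-negative.
    nc <- length(cuts)
    A <- matrix(0, nc + 1, m + 2)
    rhs <- numeric(nc + 1)
    dir <- character(nc + 1)
    for (k in seq_len(nc)) {
      ck <- cuts[[k]]
      A[k, seq_len(m)] <- -ck$sg
      A[k, m + 1] <- 1; A[k, m + 2] <- -1
      rhs[k] <- ck$val - sum(ck$sg * ck$lam)
      dir[k] <- "<="
    }
    A[nc + 1, seq_len(m)] <- 1
    rhs[nc + 1] <- 1
    dir[nc + 1] <- "="
    obj <- c(rep(0, m), 1, -1)
    sol <- simplex_lp(obj, A, dir, rhs)
    if (sol$status != "optimal") {
      stop("cutting-plane master LP returned status ", sol$status)
    }
    lam <- sol$x[seq_len(m)]
    lam[lam < 0] <- 0
    lam <- lam / sum(lam)
    ub <- sol$objective
    val <- add_cut(lam)
    if (ub - best_val <= tol * max(1, abs(best_val))) {
      status <- "optimal"
      break
    }
    if (proc.time()[["elapsed"]] - t0 > time_limit) {
      status <- "time_limit"
      break
    }
  }
  if (status == "feasible") status <- "time_limit"
  list(lambdas = best_lam, objective = best_val, status = status,
       gap = max(0, ub - best_val), iterations = length(cuts))
}

# ---- hard-count solve: branch and bound on y ---------------------------

# Node relaxation: maximize |F1| + sum(y_free) over lambda in the simplex,
# y_free in [0, 1], subject to C_p lambda + y_p <= 1 - delta (free pairs),
# C_q lambda <= -delta (pairs fixed to 1) and C_q lambda <= 1 - delta
# (pairs fixed to 0).
solve_hard_count <- function(instance, time_limit = 600, mip_gap = 0,
                          max_pairs = 400L) {
  C <- instance$C
  n <- nrow(C); m <- ncol(C)
  delta <- instance$delta
  if (n > max_pairs) {
    stop("hard-count branch and bound is capped at ", max_pairs,
         " pairs (", n, " supplied); use soft_margin for large instances ",
         "or raise the cap")
  }

  node_lp <- function(f1, f0) {
    free <- setdiff(seq_len(n), c(f1, f0))
    nf <- length(free)
    nv <- m + nf
    rows <- nf + nf + length(f1) + length(f0) + 1L
    A <- matrix(0, rows, nv)
    rhs <- numeric(rows); dir <- character(rows)
    r <- 0L
    for (k in seq_along(free)) {          # C_p lambda + y_p <= 1 - delta
      r <- r + 1L
      A[r, seq_len(m)] <- C[free[k], ]
      A[r, m + k] <- 1
      rhs[r] <- 1 - delta; dir[r] <- "<="
    }
    for (k in seq_along(free)) {          # y_p <= 1
      r <- r + 1L
      A[r, m + k] <- 1
      rhs[r] <- 1; dir[r] <- "<="
    }
    for (q in f1) {
      r <- r + 1L
      A[r, seq_len(m)] <- C[q, ]
      rhs[r] <- -delta; dir[r] <- "<="
    }
    for (q in f0) {
      r <- r + 1L
      A[r, seq_len(m)] <- C[q, ]
      rhs[r] <- 1 - delta; dir[r] <- "<="
    }
    r <- r + 1L
    A[r, seq_len(m)] <- 1
    rhs[r] <- 1; dir[r] <- "="
    obj <- c(rep(0, m), rep(1, nf))
    sol <- simplex_lp(obj, A, dir, rhs)
    if (sol$status != "optimal") return(list(status = sol$status))
    list(status = "optimal",
         value = sol$objective + length(f1),
         lambda = sol$x[seq_len(m)],
         y_free = if (nf) sol$x[m + seq_len(nf)] else numeric(0),
         free = free)
  }

  best_val <- -1
  best_lam <- NULL
  consider <- function(lam) {
    lam[lam < 0] <- 0
    s <- sum(lam)
    if (s <= 0) return(invisible(NULL))
    lam <- lam / s
    v <- milp_count(instance, lam)
    if (v > best_val) {
      best_val <<- v
      best_lam <<- lam
    }
    invisible(NULL)
  }
  for (k in seq_len(m)) consider(replace(rep(0, m), k, 1))
  consider(rep(1 / m, m))

  t0 <- proc.time()[["elapsed"]]
  status <- "optimal"
  nodes <- list(list(f1 = integer(0), f0 = integer(0), bound = Inf))
  explored <- 0L
  while (length(nodes) > 0) {
    if (proc.time()[["elapsed"]] - t0 > time_limit) {
      status <- "time_limit"
      break
    }
    # best-bound first
    bounds <- vapply(nodes, function(nd) nd$bound, 0)
    k <- which.max(bounds)
    node <- nodes[[k]]
    nodes[[k]] <- NULL
    if (floor(node$bound + 1e-6) <= best_val) next
    lp <- node_lp(node$f1, node$f0)
    explored <- explored + 1L
    if (lp$status != "optimal") next  # infeasible branch
    if (floor(lp$value + 1e-6) <= best_val) next
    consider(lp$lambda)
    frac <- abs(lp$y_free - round(lp$y_free))
    if (length(frac) == 0 || max(frac) < 1e-6) {
      # integral relaxation: the candidate was already absorbed by
      # consider(lp$lambda) above; nothing left to branch on
      next
    }
    p <- lp$free[which.max(frac)]
    for (child_f1 in c(TRUE, FALSE)) {
      nodes[[length(nodes) + 1]] <- list(
        f1 = if (child_f1) c(node$f1, p) else node$f1,
        f0 = if (child_f1) node$f0 else c(node$f0, p),
        bound = lp$value
      )
    }
  }
  remaining_ub <- if (length(nodes)) max(vapply(nodes, function(nd) nd$bound, 0)) else best_val
  gap <- max(0, floor(remaining_ub + 1e-6) - best_val)
  if (status == "optimal" && gap > mip_gap * max(1, best_val)) status <- "feasible"
  list(lambdas = best_lam, objective = best_val, status = status,
       gap = gap, iterations = explored)
}

#' Solve the weight-training MILP
#'
#' Dispatches on the instance's margin mode.  The soft-margin formulation
#' reduces exactly to maximizing a concave piecewise-linear function of the
#' weights and is solved by cutting planes; the hard-count formulation is a
#' genuine combinatorial count maximization and is solved by branch and
#' bound over the binary discrimination indicators with LP node
#' relaxations.  Every returned solution is re-verified against the model
#' constraints by direct arithmetic before return.
#'
#' @param instance a [milp_instance()].
#' @param time_limit wall-clock budget in seconds.
#' @param mip_gap acceptable relative gap (hard-count mode).
#' @param ... passed to the mode-specific solver (e.g. `max_pairs` for the
#'   hard-count branch-and-bound cap).
#' @return object of class `milp_solution`: `lambdas`, `y`, `epsilons`,
#'   `objective`, `status` (`optimal`/`feasible`/`time_limit`), `gap`,
#'   `margin_mode`, `delta`.
#' @examples
#' conf <- matrix(c(0.9, 0.8, 0.2, 0.9), 2, byrow = TRUE,
#'                dimnames = list(c("1:9", "2:8"), c("m1", "m2")))
#' labs <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE, dimnames = dimnames(conf))
#' tn <- structure(list(protein_id = "toy", L = 10,
#'                      pairs = cbind(i = c(1, 2), j = c(9, 8)),
#'                      methods = c("m1", "m2"), conf = conf, labels = labs,
#'                      missing = conf * 0 > 1, truth = c(TRUE, TRUE),
#'                      imputed = TRUE), class = "contact_tensor")
#' solve_milp(milp_instance(list(tn)))$objective
#' @export
solve_milp <- function(instance, time_limit = 600, mip_gap = 0, ...) {
  stopifnot(inherits(instance, "milp_instance"))
  res <- if (instance$margin_mode == "hard_count") {
    solve_hard_count(instance, time_limit = time_limit, mip_gap = mip_gap, ...)
  } else {
    solve_soft_margin(instance, time_limit = time_limit, ...)
  }
  sol <- finish_solution(res, instance)
  verify_milp_solution(sol, instance)
  sol
}

finish_solution <- function(res, instance) {
  lam <- res$lambdas
  a <- pair_margins(instance, lam)
  delta <- instance$delta
  if (instance$margin_mode == "hard_count") {
    y <- as.integer(a <= -delta + 1e-9)
    eps <- rep(0, length(a))
    objective <- sum(y)
  } else {
    # per-pair optimal (y, eps) of y - eps under the relaxed constraint
    y <- as.integer(a <= 1 - delta)
    eps <- ifelse(y == 1, pmax(0, a + delta), pmax(0, a - 1 + delta))
    objective <- sum(y - eps)
  }
  structure(
    list(lambdas = stats::setNames(lam, instance$methods), y = y,
         epsilons = eps, objective = objective, status = res$status,
         gap = res$gap, iterations = res$iterations,
         margin_mode = instance$margin_mode, delta = delta,
         n_pairs = length(a)),
    class = "milp_solution"
  )
}

#' @export
print.milp_solution <- function(x, ...) {
  cat(sprintf("MILP solution (%s): objective %.6g over %d pairs, status %s, gap %.3g\n",
              x$margin_mode, x$objective, x$n_pairs, x$status, x$gap))
  cat("weights:\n")
  print(round(x$lambdas, 4))
  invisible(x)
}

#' Verify a MILP solution against the model by direct arithmetic
#'
#' Independently of the solver, checks the weight simplex, variable bounds,
#' every per-pair constraint and the objective identity.  Errors on
#' violation.
#'
#' @param solution a `milp_solution`.
#' @param instance the [milp_instance()] it solves.
#' @param tol numeric tolerance.
#' @return `TRUE`, invisibly.
#' @export
verify_milp_solution <- function(solution, instance, tol = 1e-6) {
  lam <- unname(solution$lambdas)
  check_simplex(lam, length(instance$methods), tol)
  if (any(solution$epsilons < -tol)) stop("negative eps in solution")
  if (!all(solution$y %in% c(0L, 1L))) stop("non-binary y in solution")
  a <- pair_margins(instance, lam)
  s <- if (instance$margin_mode == "hard_count") 1 else -1
  lhs <- a + s * solution$epsilons
  rhs <- 1 - solution$y - instance$delta
  if (any(lhs > rhs + tol)) {
    stop("constraint violation in MILP solution (max excess ",
         format(max(lhs - rhs)), ")")
  }
  obj <- sum(solution$y) - sum(solution$epsilons)
  if (abs(obj - solution$objective) > tol * max(1, abs(obj))) {
    stop("objective does not match sum(y) - sum(eps)")
  }
  invisible(TRUE)
}

# ---- brute-force oracle -------------------------------------------------

# all compositions of k into m non-negative parts, lexicographic order
simplex_grid <- function(m, k) {
  if (m == 1) return(matrix(k, 1, 1))
  out <- vector("list", k + 1)
  for (first in 0:k) {
    rest <- simplex_grid(m - 1, k - first)
    out[[first + 1]] <- cbind(first, rest)
  }
  unname(do.call(rbind, out))
}

#' Brute-force weight search on a simplex grid
#'
#' Verification oracle: enumerates every weight vector on the simplex grid
#' of resolution `grid_step`, evaluates the discrimination count at each and
#' returns the best (ties broken lexicographically).  Guard-railed to small
#' instances; independent of the MILP solve path.
#'
#' @param instance a [milp_instance()].
#' @param grid_step grid resolution (>= 0.01).
#' @return list with `lambdas`, `objective` and the grid size searched.
#' @export
brute_force_train <- function(instance, grid_step = 0.01) {
  stopifnot(inherits(instance, "milp_instance"))
  m <- length(instance$methods)
  n <- nrow(instance$C)
  if (m > 4) stop("brute force capped at 4 methods")
  if (n > 200) stop("brute force capped at 200 pairs")
  if (grid_step < 0.01) stop("grid_step must be >= 0.01")
  k <- round(1 / grid_step)
  grid <- simplex_grid(m, k) / k
  A <- instance$C %*% t(grid)                   # margins, pairs x grid points
  counts <- colSums(A < -instance$delta)
  best <- which.max(counts)                     # first max = lexicographic tie-break
  list(lambdas = stats::setNames(grid[best, ], instance$methods),
       objective = as.integer(counts[best]), grid_points = nrow(grid))
}
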