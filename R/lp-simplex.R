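# Dense two-phase primal simplex solver for the small linear programs that
# arise in weight training (cutting-plane masters, branch-and-bound node
# relaxations).  Standard form: maximize c'x subject to A x (<=|>=|=) b,
# x >= 0.  Bland's anti-cycling rule; dense tableau; intended for problems
# with at most a few hundred rows/columns.

# Returns list(status = "optimal"|"infeasible"|"unbounded",
#              x = primal solution, objective = c'x).
simplex_lp <- function(cvec, A, dir, rhs, tol = 1e-9, max_iter = 20000L) {
  if (is.null(dim(A))) A <- matrix(A, nrow = length(rhs))
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(cvec) == n, length(dir) == m, length(rhs) == m)
  dir <- as.character(dir)

  # normalize rhs >= 0
  neg <- rhs < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    rhs[neg] <- -rhs[neg]
    dir[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[neg]]
  }

  # columns: n structural, slacks for <=, surplus for >=, artificials
  slack_rows <- which(dir == "<=")
  surp_rows <- which(dir == ">=")
  art_rows <- which(dir %in% c(">=", "="))
  n_slack <- length(slack_rows); n_surp <- length(surp_rows)
  n_art <- length(art_rows)
  ntot <- n + n_slack + n_surp + n_art

  Tb <- matrix(0, m, ntot)
  Tb[, seq_len(n)] <- A
  if (n_slack) for (k in seq_along(slack_rows)) Tb[slack_rows[k], n + k] <- 1
  if (n_surp) for (k in seq_along(surp_rows)) Tb[surp_rows[k], n + n_slack + k] <- -1
  if (n_art) for (k in seq_along(art_rows)) Tb[art_rows[k], n + n_slack + n_surp + k] <- 1
  b <- rhs

  # initial basis: slack for <= rows, artificial for others
  basis <- integer(m)
  basis[slack_rows] <- n + seq_len(n_slack)
  basis[art_rows] <- n + n_slack + n_surp + seq_len(n_art)

  art_cols <- if (n_art) n + n_slack + n_surp + seq_len(n_art) else integer(0)

  run_phase <- function(Tb, b, basis, obj, allowed, max_iter) {
    # maximize obj over allowed columns; returns updated state
    for (iter in seq_len(max_iter)) {
      # reduced costs: obj - obj_B' B^{-1} A, computed on the updated tableau
      cb <- obj[basis]
      red <- obj - as.vector(crossprod(Tb, cb))
      red[-allowed] <- -Inf
      cand <- which(red > tol)
      if (length(cand) == 0) {
        return(list(Tb = Tb, b = b, basis = basis, status = "optimal"))
      }
      enter <- min(cand)  # Bland's rule
      col <- Tb[, enter]
      pos <- which(col > tol)
      if (length(pos) == 0) {
        return(list(Tb = Tb, b = b, basis = basis, status = "unbounded"))
      }
      ratio <- b[pos] / col[pos]
      rmin <- min(ratio)
      ties <- pos[ratio <= rmin + tol]
      leave <- ties[which.min(basis[ties])]  # Bland tie-break
      # pivot
      piv <- Tb[leave, enter]
      Tb[leave, ] <- Tb[leave, ] / piv
      b[leave] <- b[leave] / piv
      other <- setdiff(seq_len(nrow(Tb)), leave)
      f <- Tb[other, enter]
      Tb[other, ] <- Tb[other, , drop = FALSE] - outer(f, Tb[leave, ])
      b[other] <- b[other] - f * b[leave]
      basis[leave] <- enter
    }
    list(Tb = Tb, b = b, basis = basis, status = "iteration_limit")
  }

  # phase 1: drive artificials to zero
  if (n_art) {
    obj1 <- rep(0, ntot)
    obj1[art_cols] <- -1
    # make the initial tableau canonical for phase 1 (reduced costs handled
    # by run_phase via crossprod, so nothing to do)
    st <- run_phase(Tb, b, basis, obj1, allowed = seq_len(ntot), max_iter)
    if (st$status != "optimal") return(list(status = "infeasible", x = NULL,
                                            objective = NA_real_))
    phase1_val <- sum(st$b[st$basis %in% art_cols])
    if (phase1_val > 1e-7) {
      return(list(status = "infeasible", x = NULL, objective = NA_real_))
    }
    Tb <- st$Tb; b <- st$b; basis <- st$basis
    # pivot any artificial still in the basis out (degenerate at zero)
    for (r in which(basis %in% art_cols)) {
      row <- Tb[r, ]
      row[art_cols] <- 0
      enter <- which(abs(row) > tol)[1]
      if (is.na(enter)) next  # all-zero row: redundant constraint
      piv <- Tb[r, enter]
      Tb[r, ] <- Tb[r, ] / piv
      b[r] <- b[r] / piv
      other <- setdiff(seq_len(m), r)
      f <- Tb[other, enter]
      Tb[other, ] <- Tb[other, , drop = FALSE] - outer(f, Tb[r, ])
      b[other] <- b[other] - f * b[r]
      basis[r] <- enter
    }
  }

  # phase 2
  obj2 <- rep(0, ntot)
  obj2[seq_len(n)] <- cvec
  allowed <- setdiff(seq_len(ntot), art_cols)
  st <- run_phase(Tb, b, basis, obj2, allowed, max_iter)
  if (st$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, objective = NA_real_))
  }
  if (st$status == "iteration_limit") {
    stop("simplex iteration limit reached")
  }
  x <- numeric(ntot)
  x[st$basis] <- st$b
  xs <- x[seq_len(n)]
  list(status = "optimal", x = xs, objective = sum(cvec * xs))
}
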