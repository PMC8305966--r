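test_that("build_milp counts variables and constraints from the instance", {
  inst <- milp_instance(list(mk_tensor(
    matrix(c(0.5, 0.6), 1, 2, dimnames = list(NULL, c("m1", "m2"))),
    matrix(c(1, 0), 1, 2)
  )), delta = 1e-4)
  mdl <- build_milp(inst)
  expect_equal(mdl$n_binary, 1)
  expect_equal(mdl$n_continuous, 3)     # two lambdas + one eps
  expect_equal(mdl$n_constraints, 2)    # one pair row + the simplex row
  expect_equal(mdl$rhs, 1 - 1e-4)
  expect_equal(mdl$eps_coef, -1)        # soft margin relaxes

  conf <- matrix(runif(6 * 2), 6, 2, dimnames = list(NULL, c("m1", "m2")))
  labs <- matrix(rbinom(12, 1, 0.5), 6, 2)
  big <- build_milp(milp_instance(
    list(mk_tensor(conf[1:3, ], labs[1:3, ], "p1"),
         mk_tensor(conf[4:6, ], labs[4:6, ], "p2")),
    margin_mode = "hard_count"))
  expect_equal(big$n_binary, 6)
  expect_equal(big$n_continuous, 8)
  expect_equal(big$eps_coef, rep(1, 6))  # literal: eps tightens
})

test_that("the worked two-pair instance solves to objective 2 in both modes", {
  for (mode in c("hard_count", "soft_margin")) {
    inst <- micro_instance(mode)
    sol <- solve_milp(inst)
    expect_equal(sol$objective, 2, tolerance = 1e-6)
    expect_equal(sol$status, "optimal")
    expect_true(all(sol$y == 1))
    expect_equal(sum(sol$lambdas), 1, tolerance = 1e-9)
  }
  inst <- micro_instance()
  expect_equal(objective_at(c(1, 0), inst)$objective, 1)
  expect_equal(objective_at(c(0, 1), inst)$objective, 1)
  expect_equal(objective_at(c(0.5, 0.5), inst)$objective, 2)
  # the equal split discriminates both pairs: 0.45 > 0.40 and 0.45 > 0.10
  expect_error(objective_at(c(0.7, 0.7), inst), "simplex")
})

test_that("single-method and all-wrong instances behave as the constraint dictates", {
  conf <- matrix(c(0.9, 0.3, 0.50004), 3, 1, dimnames = list(NULL, "m1"))
  labs <- matrix(c(1, 0, 1), 3, 1)
  inst <- milp_instance(list(mk_tensor(conf, labs)),
                        margin_mode = "hard_count", delta = 1e-4)
  sol <- solve_milp(inst)
  expect_equal(unname(sol$lambdas), 1)
  # y = 1 exactly where conf*label > conf*(1-label) + delta
  expect_equal(sol$y, c(1L, 0L, 1L))
  expect_equal(sol$objective, 2)

  all_wrong <- milp_instance(list(mk_tensor(
    matrix(runif(8), 4, 2, dimnames = list(NULL, c("m1", "m2"))),
    matrix(0, 4, 2)
  )), margin_mode = "hard_count")
  sw <- solve_milp(all_wrong)
  expect_equal(sw$objective, 0)
  expect_true(all(sw$y == 0))
})

test_that("solver matches the brute-force grid oracle on random instances", {
  for (seed in 1:8) {
    inst <- random_instance(seed)
    sol <- solve_milp(inst)
    bf <- brute_force_train(inst, grid_step = 0.01)
    expect_gte(sol$objective, bf$objective)
    # the solver's weights really achieve its claimed count
    expect_equal(comtop:::milp_count(inst, unname(sol$lambdas)),
                 sol$objective)
  }
})

test_that("solutions verify and corrupted solutions are caught", {
  inst <- random_instance(101)
  sol <- solve_milp(inst)
  expect_true(verify_milp_solution(sol, inst))
  bad <- sol
  bad$lambdas <- bad$lambdas * 2
  expect_error(verify_milp_solution(bad, inst), "simplex")
  bad2 <- sol
  bad2$objective <- bad2$objective + 5
  expect_error(verify_milp_solution(bad2, inst), "objective")
  bad3 <- sol
  bad3$y <- rep(1L, length(bad3$y))
  expect_error(verify_milp_solution(bad3, inst), "violation")
})

test_that("a simplex point with y = 0 is always feasible (solver never infeasible)", {
  for (seed in 21:30) {
    for (mode in c("hard_count", "soft_margin")) {
      inst <- random_instance(seed, margin_mode = mode)
      m <- length(inst$methods)
      lam <- rep(1 / m, m)
      a <- comtop:::pair_margins(inst, lam)
      # y = 0, eps = 0: constraint requires wrong - correct <= 1 - delta
      expect_true(all(a <= 1 - inst$delta))
      sol <- solve_milp(inst)
      expect_true(sol$status %in% c("optimal", "feasible"))
    }
  }
})

test_that("the consensus objective dominates every single method", {
  for (seed in 41:46) {
    inst <- random_instance(seed, margin_mode = "hard_count")
    sol <- solve_milp(inst)
    m <- length(inst$methods)
    for (k in seq_len(m)) {
      e_k <- replace(rep(0, m), k, 1)
      expect_gte(sol$objective, objective_at(e_k, inst)$objective)
    }
  }
  # soft margin: dominance in the mode's own objective
  inst <- random_instance(47, margin_mode = "soft_margin")
  sol <- solve_milp(inst)
  m <- length(inst$methods)
  for (k in seq_len(m)) {
    e_k <- replace(rep(0, m), k, 1)
    expect_gte(sol$objective,
               objective_at(e_k, inst, form = "soft")$objective - 1e-9)
  }
})

test_that("duplicating a method leaves the solved objective unchanged", {
  set.seed(77)
  conf <- matrix(runif(24), 12, 2, dimnames = list(NULL, c("mA", "mB")))
  labs <- matrix(rbinom(24, 1, 0.5), 12, 2, dimnames = dimnames(conf))
  base <- solve_milp(milp_instance(list(mk_tensor(conf, labs)),
                                   margin_mode = "hard_count"))
  conf3 <- cbind(conf, mA2 = conf[, "mA"])
  labs3 <- cbind(labs, mA2 = labs[, "mA"])
  dup <- solve_milp(milp_instance(list(mk_tensor(conf3, labs3)),
                                  margin_mode = "hard_count"))
  expect_equal(dup$objective, base$objective)
})

test_that("imputed and explicit identical cells give the same model", {
  # flipping a cell from missing-imputed to the same explicit value must
  # leave the instance's coefficients unchanged
  truth <- contact_map("p", 40, cbind(1L, 11L))
  a <- prediction_set("p", "A", cbind(c(1, 2), c(11, 12)), c(0.9, 0.4))
  b <- prediction_set("p", "B", cbind(2L, 12L), 0.8)
  tn <- impute_labels(impute_scores(assemble_tensors(list(a, b), truth)))
  tn_explicit <- tn
  tn_explicit$missing[] <- FALSE
  i1 <- milp_instance(list(tn))
  i2 <- milp_instance(list(tn_explicit))
  expect_equal(i1$C, i2$C)
})

test_that("brute force enforces its guardrails", {
  inst <- random_instance(5)
  expect_error(brute_force_train(inst, grid_step = 0.001), ">= 0.01")
  big_conf <- matrix(runif(300 * 2), 300, 2,
                     dimnames = list(NULL, c("m1", "m2")))
  big <- milp_instance(list(mk_tensor(big_conf,
                                      matrix(rbinom(600, 1, 0.5), 300, 2),
                                      L = 400L)))
  expect_error(brute_force_train(big), "200 pairs")
})
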