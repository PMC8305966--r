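test_that("consensus score is the weighted sum of method confidences", {
  tn <- mk_tensor(matrix(c(0.5, 0.25), 1, 2,
                         dimnames = list(NULL, c("m1", "m2"))),
                  matrix(c(1, 1), 1, 2))
  expect_equal(consensus_score(tn, c(0.6, 0.4)), 0.4)

  conf <- matrix(runif(10), 5, 2, dimnames = list(NULL, c("m1", "m2")))
  tn2 <- mk_tensor(conf, matrix(1, 5, 2))
  expect_equal(consensus_score(tn2, c(1, 0)), unname(conf[, 1]))

  conf7 <- matrix(1, 3, 7, dimnames = list(NULL, paste0("m", 1:7)))
  tn7 <- mk_tensor(conf7, conf7)
  expect_equal(consensus_score(tn7, rep(1 / 7, 7)), rep(1, 3))

  expect_error(consensus_score(tn, c(0.5, 0.3, 0.2)), "mismatch")
  # named weights are aligned by method id
  expect_equal(consensus_score(tn, c(m2 = 0.4, m1 = 0.6)), 0.4)
})

test_that("predict_contacts selects top-kL with clamping and determinism", {
  set.seed(8)
  conf <- matrix(runif(16), 8, 2, dimnames = list(NULL, c("m1", "m2")))
  tn <- mk_tensor(conf, matrix(1, 8, 2), L = 10L)
  pr <- predict_contacts(tn, c(0.5, 0.5), spec = "L/5", L = 10)
  expect_equal(nrow(pr$entries), 2)
  s <- consensus_score(tn, c(0.5, 0.5))
  expect_equal(pr$entries$score, sort(s, decreasing = TRUE)[1:2])

  expect_warning(predict_contacts(tn, c(0.5, 0.5), spec = "5L", L = 10),
                 "smaller than")

  # a universally dominant pair ranks first at every cutoff
  conf2 <- conf
  conf2[3, ] <- 1
  tn2 <- mk_tensor(conf2, matrix(1, 8, 2), L = 10L)
  for (spec in c("L/5", "L/2", "L")) {
    p <- suppressWarnings(predict_contacts(tn2, c(0.3, 0.7), spec = spec, L = 10))
    expect_equal(p$entries$i[1], 3)
  }
})

test_that("selections are nested across cutoffs for one weight vector", {
  set.seed(21)
  conf <- matrix(runif(120), 60, 2, dimnames = list(NULL, c("m1", "m2")))
  tn <- mk_tensor(conf, matrix(1, 60, 2), L = 40L)
  lam <- c(0.7, 0.3)
  keys <- lapply(c("L/5", "L/2", "L"), function(spec) {
    e <- predict_contacts(tn, lam, spec = spec, L = 40)$entries
    paste(e$i, e$j)
  })
  expect_true(all(keys[[1]] %in% keys[[2]]))
  expect_true(all(keys[[2]] %in% keys[[3]]))
})

test_that("consensus score is invariant to method permutation and monotone", {
  set.seed(5)
  conf <- matrix(runif(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  tn <- mk_tensor(conf, matrix(1, 10, 3))
  lam <- c(a = 0.5, b = 0.3, c = 0.2)
  perm <- c(3, 1, 2)
  tn_p <- tn
  tn_p$conf <- conf[, perm]
  tn_p$methods <- colnames(conf)[perm]
  expect_equal(consensus_score(tn, lam), consensus_score(tn_p, lam))

  # raising one method's confidence never lowers the consensus score
  tn_up <- tn
  tn_up$conf[4, 2] <- tn_up$conf[4, 2] + 0.1
  expect_gte(consensus_score(tn_up, lam)[4], consensus_score(tn, lam)[4])
})

test_that("consensus label vector marks returned pairs over the universe", {
  tn <- mk_tensor(matrix(c(0.9, 0.1), 2, 1, dimnames = list(NULL, "m")),
                  matrix(1, 2, 1), L = 20L)
  pr <- predict_contacts(tn, c(m = 1), spec = "L/5", L = 10)  # top 2 of 2
  universe <- tn$pairs
  expect_equal(consensus_label_matrix(pr, universe), c(1L, 1L))

  pr1 <- predict_contacts(tn, c(m = 1), spec = "L/5", L = 5)  # top 1
  expect_equal(consensus_label_matrix(pr1, universe), c(1L, 0L))

  empty <- pr1
  empty$entries <- empty$entries[0, ]
  expect_equal(consensus_label_matrix(empty, universe), c(0L, 0L))
  outside <- pr1
  outside$entries$i <- 19L; outside$entries$j <- 39L
  expect_error(consensus_label_matrix(outside, universe), "outside")
})

test_that("predict.comtop enforces the trained method set", {
  corpus <- generate_corpus(small_config(seed = 2))
  fit <- comtop(corpus, specs = "L")
  smaller <- contact_corpus(
    lapply(corpus$scores, function(s) s[c("mA", "mB")]),
    corpus$truths
  )
  expect_error(predict(fit, smaller), "mismatch")

  preds <- predict(fit, corpus, specs = "L")
  expect_named(preds, "L")
  expect_equal(length(preds$L), length(corpus$scores))
  p1 <- preds$L[[1]]
  expect_equal(nrow(p1$entries),
               resolve_topk_count(corpus$truths[[p1$protein_id]]$L, "L"))
  expect_error(predict(fit, corpus, specs = "3L"), "no sub-model")
})

test_that("a unit-vector weighting reproduces that method's ranking", {
  corpus <- generate_corpus(small_config(seed = 3))
  fit <- comtop(corpus, specs = "L/2")
  fit$weights["L/2", ] <- c(1, 0, 0)  # force weight onto mA
  preds <- predict(fit, corpus, specs = "L/2")
  pid <- names(corpus$scores)[1]
  Lp <- corpus$truths[[pid]]$L
  own <- select_top_k(corpus$scores[[pid]]$mA,
                      resolve_topk_count(Lp, "L/2"))$entries
  got <- preds$`L/2`[[pid]]$entries
  expect_equal(paste(got$i, got$j), paste(own$i, own$j))
})
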