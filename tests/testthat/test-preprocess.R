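test_that("min-max normalization maps endpoints and handles degeneracy", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(-1, 0, 3)), c(0, 0.25, 1))
  expect_equal(minmax_normalize(c(5, 5, 5)), c(0, 0, 0))
  expect_error(minmax_normalize(c(1, NaN)), "NaN")
  expect_error(minmax_normalize(numeric(0)), "at least one")
})

test_that("normalization is idempotent on non-degenerate input", {
  set.seed(11)
  for (k in 1:10) {
    x <- runif(sample(3:50, 1), -5, 5)
    z <- minmax_normalize(x)
    expect_equal(minmax_normalize(z), z)
    expect_true(all(z >= 0 & z <= 1))
  }
})

test_that("top-k counts floor with a minimum of one", {
  expect_equal(resolve_topk_count(100, "L/2"), 50L)
  expect_equal(resolve_topk_count(47, "L/5"), 9L)
  expect_equal(resolve_topk_count(10, "4.5L"), 45L)
  expect_equal(resolve_topk_count(100, "5L"), 500L)
  expect_equal(resolve_topk_count(3, "L/5"), 1L)  # floor(0.6) -> min 1
  expect_error(resolve_topk_count(100, "2M"), "unknown")
})

test_that("select_top_k is deterministic with (i, j) tie-breaks and clamps", {
  ps <- prediction_set("p", "m", cbind(c(1, 2, 3), c(9, 8, 7)),
                       c(0.9, 0.5, 0.1))
  top2 <- select_top_k(ps, 2)
  expect_equal(top2$entries$confidence, c(0.9, 0.5))

  tie <- prediction_set("p", "m", cbind(c(2, 1), c(8, 9)), c(0.5, 0.5))
  top1 <- select_top_k(tie, 1)
  expect_equal(c(top1$entries$i, top1$entries$j), c(1, 9))

  expect_equal(nrow(select_top_k(ps, 10)$entries), 3)
  expect_error(select_top_k(ps, -1), "non-negative")
  set.seed(3)
  for (k in 1:5) {
    n <- sample(5:40, 1)
    i <- seq_len(n); j <- i + 6L
    p <- prediction_set("p", "m", cbind(i, j), runif(n))
    count <- sample(0:(n + 5), 1)
    out <- select_top_k(p, count)$entries$confidence
    expect_length(out, min(count, n))
    expect_true(all(diff(out) <= 0))
  }
})

test_that("tensor assembly takes the union universe and marks missing cells", {
  mk <- function(mid, i, conf) {
    prediction_set("p", mid, cbind(i, i + 10L), conf)
  }
  truth <- contact_map("p", 40, cbind(c(1L, 6L), c(11L, 16L)))
  a <- mk("A", 1:5, seq(0.9, 0.5, length.out = 5))
  b <- mk("B", 6:10, seq(0.9, 0.5, length.out = 5))
  c3 <- mk("C", 11:15, seq(0.9, 0.5, length.out = 5))

  tn <- assemble_tensors(list(a, b, c3), truth)
  expect_equal(nrow(tn$pairs), 15)
  expect_equal(sum(tn$missing), 30)

  same <- assemble_tensors(list(mk("A", 1:5, 1:5 / 10), mk("B", 1:5, 5:1 / 10)),
                           truth)
  expect_false(any(same$missing))

  # invariant to method supply order (columns sorted by id)
  tn2 <- assemble_tensors(list(c3, a, b), truth)
  expect_equal(tn2$conf, tn$conf)
  expect_equal(tn2$methods, tn$methods)

  bad <- prediction_set("other", "B", cbind(1L, 11L), 0.5)
  expect_error(assemble_tensors(list(a, bad), truth), "different proteins")
})

test_that("score imputation follows the literal rule and its floor variant", {
  truth <- contact_map("p", 40, cbind(1L, 11L))  # (1,11) is the only contact
  a <- prediction_set("p", "A", cbind(c(1, 2, 3), c(11, 12, 13)),
                      c(0.9, 0.4, 0.1))
  b <- prediction_set("p", "B", cbind(c(2, 3), c(12, 13)), c(0.8, 0.2))
  tn <- assemble_tensors(list(a, b), truth)
  # B is silent on (1,11): missing & contact.  Observed scores:
  # 0.9 0.4 0.1 0.8 0.2 -> x_p = 0.1, y_p = 0.9, z_p = 0.48
  lit <- impute_scores(tn, mode = "literal")
  expect_equal(lit$conf["1:11", "B"], 0)
  expect_true(lit$imputed)
  expect_false(anyNA(lit$conf))
  expect_true(all(lit$conf >= 0 & lit$conf <= 1))

  flo <- impute_scores(tn, mode = "floor")
  expect_equal(flo$conf["1:11", "B"], 0.1)

  # a missing non-contact cell receives the protein mean
  b2 <- prediction_set("p", "B", cbind(c(1, 3), c(11, 13)), c(0.8, 0.2))
  tn2 <- assemble_tensors(list(a, b2), truth)
  obs_mean <- mean(c(0.9, 0.4, 0.1, 0.8, 0.2))
  expect_equal(impute_scores(tn2)$conf["2:12", "B"], obs_mean)

  # no missing cells: identity
  full <- assemble_tensors(list(a, prediction_set("p", "B",
    cbind(c(1, 2, 3), c(11, 12, 13)), c(0.7, 0.6, 0.5))), truth)
  expect_equal(impute_scores(full)$conf, full$conf)
})

test_that("label imputation credits silence on non-contacts only", {
  truth <- contact_map("p", 40, cbind(1L, 11L))
  a <- prediction_set("p", "A", cbind(c(1, 2), c(11, 12)), c(0.9, 0.4))
  b <- prediction_set("p", "B", cbind(3L, 13L), 0.8)
  tn <- impute_labels(assemble_tensors(list(a, b), truth))
  expect_equal(tn$labels["1:11", "B"], 0)  # silent on a contact: a miss
  expect_equal(tn$labels["2:12", "B"], 1)  # silent on a non-contact: correct
  expect_equal(tn$labels["1:11", "A"], 1)  # returned true prediction
  expect_equal(tn$labels["2:12", "A"], 0)  # returned false prediction
  expect_equal(tn$labels["3:13", "A"], 1)  # A silent on non-contact (3,13)
})

test_that("prediction-time imputation (no truth) fills zeros", {
  a <- prediction_set("p", "A", cbind(c(1, 2), c(11, 12)), c(0.9, 0.4))
  b <- prediction_set("p", "B", cbind(2L, 12L), 0.8)
  tn <- impute_scores(assemble_tensors(list(a, b), truth = NULL))
  expect_equal(tn$conf["1:11", "B"], 0)
})

test_that("tensor long-table export is faithful", {
  truth <- contact_map("p", 40, cbind(1L, 11L))
  a <- prediction_set("p", "A", cbind(c(1, 2), c(11, 12)), c(0.9, 0.4))
  b <- prediction_set("p", "B", cbind(2L, 12L), 0.8)
  tn <- impute_labels(impute_scores(assemble_tensors(list(a, b), truth)))
  tab <- tensor_as_table(tn)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$conf[tab$method == "A" & tab$i == 1], 0.9)
  expect_equal(sum(tab$missing), 1)
})
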