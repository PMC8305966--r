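cc <- function(TP, FP, TN, FN) {
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 n_universe = TP + FP + TN + FN),
            class = "confusion_counts")
}

test_that("confusion counts partition the evaluation universe", {
  truth <- contact_map("p", 30, cbind(c(1L, 3L), c(11L, 13L)))
  universe <- cbind(c(1L, 2L, 3L, 4L), c(11L, 12L, 13L, 14L))
  counts <- confusion_counts(cbind(c(1L, 2L), c(11L, 12L)), truth, universe)
  expect_equal(unlist(counts[c("TP", "FP", "FN", "TN")]),
               c(TP = 1, FP = 1, FN = 1, TN = 1))

  perfect <- confusion_counts(truth$contacts, truth, truth$contacts)
  expect_equal(unlist(perfect[c("FP", "FN", "TN")]),
               c(FP = 0, FN = 0, TN = 0))

  none <- confusion_counts(matrix(integer(0), ncol = 2), truth, universe)
  expect_equal(none$TP + none$FP, 0)

  expect_error(confusion_counts(cbind(5L, 25L), truth, universe), "outside")

  # counts conservation over the default universe
  set.seed(13)
  for (k in 1:5) {
    L <- sample(30:60, 1)
    tm <- generate_contact_map(L, 1, seed = k, protein_id = "x")
    elig <- comtop:::eligible_pairs(L, 6)
    pred <- elig[sample(nrow(elig), 2 * L), ]
    ct <- confusion_counts(pred, tm)
    expect_equal(ct$TP + ct$FP + ct$TN + ct$FN, nrow(elig))
  }
})

test_that("the five metrics match hand-computed values on constructed tables", {
  cases <- list(
    # TP FP TN FN, accuracy, coverage, specificity, npv, mcc
    list(cc(9, 1, 0, 0),    0.9,  1.0,  0.0,  NaN,  0),
    list(cc(0, 5, 5, 0),    0.0,  NaN,  0.5,  1.0,  0),
    list(cc(59, 41, 0, 0),  0.59, 1.0,  0.0,  NaN,  0),
    list(cc(8, 0, 10, 2),   1.0,  0.8,  1.0,  10 / 12, NA),
    list(cc(7, 3, 20, 13),  0.7,  0.35, 20 / 23, 20 / 33, NA),
    list(cc(90, 10, 90, 10), 0.9, 0.9,  0.9,  0.9,  0.8),
    list(cc(0, 9, 3, 0),    0.0,  NaN,  0.25, 1.0,  0),
    list(cc(1, 0, 1, 3),    1.0,  0.25, 1.0,  0.25, NA),
    list(cc(5, 0, 5, 0),    1.0,  1.0,  1.0,  1.0,  1.0),
    list(cc(0, 5, 0, 5),    0.0,  0.0,  0.0,  0.0, -1.0),
    list(cc(3, 1, 4, 2),    0.75, 0.6,  0.8,  4 / 6, 10 / sqrt(600))
  )
  for (cs in cases) {
    ct <- cs[[1]]
    expect_equal(suppressWarnings(accuracy(ct)), cs[[2]])
    expect_equal(suppressWarnings(coverage(ct)), cs[[3]])
    expect_equal(suppressWarnings(specificity(ct)), cs[[4]])
    expect_equal(suppressWarnings(npv(ct)), cs[[5]])
    if (!is.na(cs[[6]])) expect_equal(mcc(ct), cs[[6]], tolerance = 1e-12)
    expect_true(mcc(ct) >= -1 && mcc(ct) <= 1)
  }
  expect_warning(accuracy(cc(0, 0, 5, 5)), "no predicted")
  expect_equal(mcc(cc(0, 0, 5, 5)), 0)  # zero-denominator convention
})

test_that("mcc is invariant under simultaneous TP/TN and FP/FN swap", {
  set.seed(31)
  for (k in 1:10) {
    v <- sample(0:30, 4, replace = TRUE)
    a <- cc(v[1], v[2], v[3], v[4])
    b <- cc(v[3], v[4], v[1], v[2])
    expect_equal(mcc(a), mcc(b))
  }
})

test_that("jaccard similarity follows set arithmetic and the matrix is symmetric", {
  a <- cbind(c(1L, 2L, 3L), c(11L, 12L, 13L))
  b <- cbind(c(2L, 3L, 4L), c(12L, 13L, 14L))
  expect_equal(jaccard_similarity(a, a), 1)
  expect_equal(jaccard_similarity(a, b), 0.5)
  expect_equal(jaccard_similarity(a, cbind(9L, 19L)), 0)
  expect_warning(
    expect_true(is.nan(jaccard_similarity(matrix(integer(0), ncol = 2),
                                          matrix(integer(0), ncol = 2)))),
    "both sets empty")

  corpus <- generate_corpus(small_config(seed = 4, shared = 0.5))
  pid <- names(corpus$scores)[1]
  jm <- jaccard_matrix(corpus$scores[[pid]])
  expect_equal(jm, t(jm))
  expect_equal(unname(diag(jm)), rep(1, 3))
  expect_true(all(jm >= 0 & jm <= 1))
})

test_that("bland_altman reports bias, 2SD limits and coverage of the limits", {
  ba <- bland_altman(c(2, 3, 4), c(1, 2, 3))  # d = (1,1,1)
  expect_equal(ba$bias, 1)
  expect_equal(ba$sd, 0)
  expect_equal(unname(ba$limits), c(1, 1))
  expect_equal(ba$pct_within, 100)

  ba2 <- bland_altman(c(0, 2), c(0, 0))  # d = (0,2), sample sd = sqrt(2)
  expect_equal(ba2$bias, 1)
  expect_equal(ba2$sd, sqrt(2))
  expect_equal(unname(ba2$limits), c(1 - 2 * sqrt(2), 1 + 2 * sqrt(2)))
  expect_equal(ba2$pct_within, 100)

  x <- runif(10)
  ba3 <- bland_altman(x, x)
  expect_equal(ba3$bias, 0)
  expect_equal(ba3$pct_within, 100)

  expect_error(bland_altman(1:3, 1:2), "equal length")
})

test_that("evaluate_suite macro-averages per-protein metrics", {
  # two proteins engineered to accuracies 0.8 and 0.6 at 5 predictions each
  t1 <- contact_map("p1", 40, cbind(c(1L, 2L, 3L, 4L), c(11L, 12L, 13L, 14L)))
  t2 <- contact_map("p2", 40, cbind(c(1L, 2L, 3L), c(11L, 12L, 13L)))
  pred1 <- cbind(c(1L, 2L, 3L, 4L, 5L), c(11L, 12L, 13L, 14L, 15L))  # 4/5
  pred2 <- cbind(c(1L, 2L, 3L, 5L, 6L), c(11L, 12L, 13L, 15L, 16L))  # 3/5
  ev <- evaluate_suite(list(L = list(p1 = pred1, p2 = pred2)),
                       list(p1 = t1, p2 = t2))
  expect_equal(ev$accuracy, 0.7)
  expect_equal(ev$TP, 7)
  expect_equal(ev$n_proteins, 2)

  one <- evaluate_suite(list(L = list(p1 = pred1)), list(p1 = t1))
  expect_equal(one$accuracy, 0.8)

  perfect <- evaluate_suite(list(L = list(p1 = t1$contacts)), list(p1 = t1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$coverage, 1)

  expect_error(evaluate_suite(list(L = list(p9 = pred1)), list(p1 = t1)),
               "missing truth")
})

test_that("top-k accuracy is non-increasing for a perfectly ordered score list", {
  # all true contacts outrank all non-contacts: accuracy is 1 until the
  # contacts are exhausted, then decays monotonically
  L <- 50L
  tm <- generate_contact_map(L, 1, seed = 9, protein_id = "p")
  elig <- comtop:::eligible_pairs(L, 6L)
  truth_flag <- comtop:::is_contact(tm, elig)
  ord <- order(-truth_flag)
  accs <- vapply(c(10, 25, 50, 100, 150), function(k) {
    accuracy(confusion_counts(elig[ord[seq_len(k)], ], tm))
  }, 0)
  expect_true(all(diff(accs) <= 1e-12))
})
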