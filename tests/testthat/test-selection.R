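mk_fm <- function(pos, neg, names = NULL) {
  # pos/neg: matrices (samples x features) per class
  x <- rbind(pos, neg)
  colnames(x) <- if (is.null(names)) paste0("f", seq_len(ncol(x))) else names
  rownames(x) <- paste0("s", seq_len(nrow(x)))
  feature_matrix(x, rep(c("positive", "negative"),
                        c(nrow(pos), nrow(neg))))
}

test_that("F-score analytic cases", {
  # identical values in both classes -> 0/0 convention -> 0
  fm <- mk_fm(matrix(7, 3, 1), matrix(7, 4, 1))
  expect_equal(fscore_rank(fm)$score, 0)

  # {0,0} vs {1,1}: positive numerator, zero denominator -> Inf, ranked first
  fm2 <- mk_fm(cbind(c(0, 0), rnorm(2)), cbind(c(1, 1), rnorm(2)))
  rk <- fscore_rank(fm2)
  expect_identical(rk$feature[1], "f1")
  expect_equal(rk$score[1], Inf)

  expect_error(fscore_rank(mk_fm(matrix(1, 1, 1), matrix(0, 4, 1))),
               ">= 2 samples")
})

test_that("F-score matches the brute-force oracle on random data", {
  set.seed(17)
  for (i in 1:15) {
    np <- sample(3:12, 1); nn <- sample(3:12, 1)
    pos <- matrix(rnorm(np * 10), np)
    neg <- matrix(rnorm(nn * 10, mean = 0.5), nn)
    fm <- mk_fm(pos, neg)
    rk <- fscore_rank(fm)
    want <- vapply(1:10, function(j) oracle_fscore(pos[, j], neg[, j]),
                   numeric(1))
    got <- rk$score[match(paste0("f", 1:10), rk$feature)]
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(diff(rk$score) <= 0))        # non-increasing
    expect_true(all(rk$score >= 0))
  }
})

test_that("printed (asymmetric) F-score variant drops the positive Bessel factor", {
  set.seed(18)
  pos <- matrix(rnorm(8 * 3), 8); neg <- matrix(rnorm(5 * 3), 5)
  fm <- mk_fm(pos, neg)
  rk <- fscore_rank(fm, variant = "printed")
  want <- vapply(1:3, function(j) {
    bp <- mean(pos[, j]); bn <- mean(neg[, j]); bb <- mean(c(pos[, j], neg[, j]))
    ((bp - bb)^2 + (bn - bb)^2) /
      (sum((pos[, j] - bp)^2) + sum((neg[, j] - bn)^2) / (nrow(neg) - 1))
  }, numeric(1))
  got <- rk$score[match(paste0("f", 1:3), rk$feature)]
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("F-score invariances: affine rescaling and sample order", {
  set.seed(19)
  pos <- matrix(rnorm(6 * 5), 6); neg <- matrix(rnorm(7 * 5, 1), 7)
  fm <- mk_fm(pos, neg)
  base <- fscore_rank(fm)
  # joint affine map on feature 2 in both classes
  fm2 <- fm
  fm2$x[, 2] <- -3.7 * fm2$x[, 2] + 11
  expect_equal(fscore_rank(fm2)$score, base$score, tolerance = 1e-9)
  # shuffling sample order
  perm <- sample(nrow(fm$x))
  fm3 <- feature_matrix(fm$x[perm, ], fm$label[perm])
  expect_equal(fscore_rank(fm3), base, tolerance = 1e-12)
})

test_that("IFS walks nested subsets and picks the smallest best d", {
  set.seed(20)
  # feature 1 perfectly separating, ranked first
  pos <- cbind(rnorm(6, 10), matrix(rnorm(6 * 2), 6))
  neg <- cbind(rnorm(6, -10), matrix(rnorm(6 * 2), 6))
  fm <- mk_fm(pos, neg)
  rk <- fscore_rank(fm)
  expect_identical(rk$feature[1], "f1")

  calls <- 0L
  evaluator <- function(sub) {
    calls <<- calls + 1L
    r <- kfold(sub, make_svm_trainer(svm_config(c = 10, gamma = 1)),
               folds = 3, smote_mode = "none", seed = 1)
    r$acc
  }
  curve <- ifs_select(fm, rk, evaluator, step = 1)
  expect_equal(calls, 3L)                       # one call per d
  expect_equal(attr(curve, "selected_d"), 1L)   # peak already at d = 1
  expect_equal(curve$acc[1], 100)

  # evaluation count = ceil(p / step); ties broken toward smaller d
  fake_eval <- function(sub) 42
  for (p in c(3, 7, 10)) {
    fmp <- mk_fm(matrix(rnorm(4 * p), 4), matrix(rnorm(4 * p), 4))
    rkp <- fscore_rank(fmp)
    for (step in c(1, 2, 4)) {
      cv <- ifs_select(fmp, rkp, fake_eval, step = step)
      expect_equal(nrow(cv), ceiling(p / step))
      expect_equal(attr(cv, "selected_d"), 1L)  # all tied -> smallest d
    }
  }

  expect_error(ifs_select(fm, structure(data.frame(feature = character(0),
                                                   score = numeric(0)),
                                        class = c("feature_ranking",
                                                  "data.frame")),
                          fake_eval), "empty|match")
})
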