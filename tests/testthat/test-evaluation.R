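test_that("metric formulas: analytic confusion tables", {
  r <- compute_metrics(confusion_counts(68, 307, 0, 0))
  expect_equal(c(r$sn, r$sp, r$acc, r$mcc), c(100, 100, 100, 1))

  r2 <- compute_metrics(confusion_counts(0, 0, 307, 68))
  expect_equal(c(r2$sn, r2$sp, r2$acc, r2$mcc), c(0, 0, 0, -1))

  r3 <- compute_metrics(confusion_counts(45, 40, 10, 5))
  expect_equal(r3$sn, 90)
  expect_equal(r3$sp, 80)
  expect_equal(r3$acc, 85)
  expect_equal(r3$mcc, (45 * 40 - 10 * 5) / sqrt(55 * 45 * 50 * 50))
  expect_equal(r3$mcc, 0.7035, tolerance = 1e-4)

  # printed specificity variant: TN/(TN+FN)
  r4 <- compute_metrics(confusion_counts(45, 40, 10, 5),
                        sp_variant = "printed")
  expect_equal(r4$sp, 100 * 40 / 45)

  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)), "empty")
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("metrics agree with an independent oracle on random tables", {
  set.seed(23)
  for (i in 1:1000) {
    v <- rpois(4, sample(c(0.5, 3, 20), 1))
    if (sum(v) == 0) next
    got <- compute_metrics(confusion_counts(v[1], v[2], v[3], v[4]))
    want <- oracle_metrics(v[1], v[2], v[3], v[4])
    expect_equal(got$sn, want$sn, tolerance = 1e-12)
    expect_equal(got$sp, want$sp, tolerance = 1e-12)
    expect_equal(got$acc, want$acc, tolerance = 1e-12)
    expect_equal(got$mcc, want$mcc, tolerance = 1e-12)
    expect_true(is.na(got$mcc) || (got$mcc >= -1 && got$mcc <= 1))
  }
})

test_that("MCC attains +/-1 exactly at the perfect and inverted corners", {
  set.seed(24)
  for (i in 1:50) {
    tp <- sample(0:5, 1); tn <- sample(0:5, 1)
    fp <- sample(0:5, 1); fn <- sample(0:5, 1)
    if (tp + tn + fp + fn == 0) next
    m <- compute_metrics(confusion_counts(tp, tn, fp, fn))$mcc
    expect_equal(isTRUE(all.equal(m, 1)),
                 fp == 0 && fn == 0 && tp > 0 && tn > 0)
    expect_equal(isTRUE(all.equal(m, -1)),
                 tp == 0 && tn == 0 && fp > 0 && fn > 0)
  }
})

test_that("jackknife: separable toy is perfect; one round per sample", {
  fm <- toy_separable(n_per = 6)
  seen <- 0L
  counting_trainer <- function(train_fm) {
    seen <<- seen + 1L
    svm_train(train_fm, svm_config(c = 10, gamma = 1))
  }
  rep <- jackknife(fm, counting_trainer, smote_mode = "none")
  expect_equal(rep$acc, 100)
  expect_equal(seen, nrow(fm$x))
  expect_equal(rep$protocol$protocol, "jackknife")
  expect_error(jackknife(fm, smote_mode = "sideways"), "arg")
})

test_that("kfold with k = n equals the jackknife; seeded determinism", {
  fm <- toy_separable(n_per = 4)
  tr <- make_svm_trainer(svm_config(c = 10, gamma = 1))
  jk <- jackknife(fm, tr, smote_mode = "none")
  kf <- kfold(fm, tr, folds = 8, smote_mode = "none", seed = 8)  # k = n
  expect_identical(unclass(kf$counts), unclass(jk$counts))

  a <- kfold(fm, tr, folds = 2, smote_mode = "none", seed = 5)
  b <- kfold(fm, tr, folds = 2, smote_mode = "none", seed = 5)
  expect_identical(unclass(a$counts), unclass(b$counts))

  expect_error(kfold(fm, tr, folds = 5, smote_mode = "none"),
               "smaller class")
})

test_that("inside mode never synthesizes from the held-out sample", {
  fm <- gen_feature_matrix(synth_spec(5, 12, separation = 1, seed = 9))
  ids <- rownames(fm$x)
  round <- 0L
  spy_trainer <- function(train_fm) {
    round <<- round + 1L
    held_out <- ids[round]          # jackknife holds out sample `round`
    expect_false(held_out %in% rownames(train_fm$x))
    syn <- rownames(train_fm$x)[train_fm$provenance == "synthetic"]
    # synthetic ids embed their base sample id: none may reference held-out
    expect_false(any(grepl(paste0("\\.", held_out, "$"), syn)))
    # fold is balanced after inside-SMOTE
    expect_equal(sum(train_fm$label == "positive"),
                 sum(train_fm$label == "negative"))
    svm_train(train_fm, svm_config(c = 1, gamma = 0.5))
  }
  rep <- jackknife(fm, spy_trainer, smote_mode = "inside", seed = 2)
  expect_equal(round, nrow(fm$x))
  expect_equal(rep$counts$tp + rep$counts$tn + rep$counts$fp +
                 rep$counts$fn, nrow(fm$x))
})

test_that("outside mode tests only originals unless asked otherwise", {
  fm <- gen_feature_matrix(synth_spec(4, 10, separation = 2, seed = 10))
  tr <- make_svm_trainer(svm_config(c = 1, gamma = 1))
  rep <- jackknife(fm, tr, smote_mode = "outside", seed = 3, k = 3)
  n_counted <- rep$counts$tp + rep$counts$tn + rep$counts$fp + rep$counts$fn
  expect_equal(n_counted, nrow(fm$x))       # 14 originals only
  rep2 <- jackknife(fm, tr, smote_mode = "outside", seed = 3, k = 3,
                    include_synthetic = TRUE)
  n2 <- rep2$counts$tp + rep2$counts$tn + rep2$counts$fp + rep2$counts$fn
  expect_equal(n2, 20L)                     # 14 originals + 6 synthetic
})

test_that("report serialization: JSON and Table-style TSV line", {
  rep <- compute_metrics(confusion_counts(45, 40, 10, 5))
  fj <- withr::local_tempfile(fileext = ".json")
  write_report(rep, fj, "json")
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(back$acc, 85)
  expect_equal(back$counts$tp, 45)
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep, ft, "tsv")
  lines <- readLines(ft)
  expect_identical(lines[1], "Sn\tSp\tMCC\tAcc")
  expect_identical(lines[2], "90.00\t80.00\t0.7035\t85.00")
})
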