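test_that("scoring matches at the requested granularity", {
  ext <- data.frame(report_id = c("r1", "r2", "r3"),
                    field = "local_invasion",
                    value = c("pT4a", "pT4a", "pT4a"),
                    confidence = c(90, 80, 70))
  truth <- data.frame(report_id = c("r1", "r2", "r3"),
                      field = "local_invasion",
                      value = c("pT4a", "pT4b", "pT3"))
  spec <- score_extractions(ext, truth, granularity = "specific")
  expect_identical(spec$label, c(1L, 0L, 0L))
  broad <- score_extractions(ext, truth, granularity = "broad")
  expect_identical(broad$label, c(1L, 1L, 0L))
  # truth surface forms are normalised before comparison
  truth$value <- c("T4A", "t4b", "T3")
  expect_identical(score_extractions(ext, truth)$label, c(1L, 0L, 0L))
})

test_that("missing truth entries are skipped with a message, NA matching is a switch", {
  ext <- data.frame(report_id = c("r1", "r2"), field = "histologic_grade",
                    value = c("High", "NA"), confidence = c(90, 50))
  truth <- data.frame(report_id = "r2", field = "histologic_grade", value = "NA")
  expect_message(recs <- score_extractions(ext, truth), "skipped")
  expect_identical(nrow(recs), 1L)
  expect_identical(recs$label, 1L)
  expect_message(recs2 <- score_extractions(ext, truth, na_matches = FALSE))
  expect_identical(recs2$label, 0L)
  bad <- data.frame(report_id = "r1", field = "nope", value = "x")
  expect_error(score_extractions(bad, truth), "absent from schema")
})

test_that("accuracy is the label mean and demands input", {
  expect_equal(accuracy(c(1, 1, 1, 1)), 1)
  expect_equal(accuracy(c(1, 0, 1, 0)), 0.5)
  expect_equal(accuracy(c(0)), 0)
  expect_error(accuracy(integer(0)), "no records")
})

test_that("Cohen's kappa corrects agreement for chance", {
  # perfect agreement
  d <- data.frame(extracted = c("High", "Low", "High"),
                  truth = c("High", "Low", "High"))
  expect_equal(cohen_kappa(d), 1)
  # hand-computed 2x2 table: a=45, b=5, c=5, d=45 -> p_o=0.9, p_e=0.5
  d <- data.frame(
    extracted = c(rep("A", 45), rep("B", 5), rep("A", 5), rep("B", 45)),
    truth = c(rep("A", 45), rep("A", 5), rep("B", 5), rep("B", 45)))
  expect_equal(cohen_kappa(d), 0.8, tolerance = 1e-12)
  # constant extractor against balanced truth is chance-level
  d <- data.frame(extracted = rep("Low", 100),
                  truth = rep(c("Low", "High"), 50))
  expect_equal(cohen_kappa(d), 0)
  # both raters constant and equal: kappa 1 by convention
  d <- data.frame(extracted = rep("R0", 5), truth = rep("R0", 5))
  expect_equal(cohen_kappa(d), 1)
  expect_error(cohen_kappa(data.frame(extracted = "A", truth = "A")), "at least 2")
})

test_that("kappa agrees with an independent implementation on random tables", {
  skip_if_not_installed("e1071")
  withr::with_seed(111, {
    for (i in 1:20) {
      a <- sample(c("A", "B", "C"), 60, replace = TRUE)
      b <- sample(c("A", "B", "C"), 60, replace = TRUE)
      tab <- table(factor(a, c("A", "B", "C")), factor(b, c("A", "B", "C")))
      expect_equal(cohen_kappa(data.frame(extracted = a, truth = b)),
                   e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
    }
  })
})

test_that("AUROC equals the pairwise Mann-Whitney statistic", {
  expect_equal(auroc(c(10, 9, 2, 1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(5, 5, 5, 5), c(1, 0, 1, 0)), 0.5)
  expect_equal(auroc(c(0.9, 0.8, 0.4), c(1, 0, 1)), 0.5)
  withr::with_seed(222, {
    for (i in 1:200) {
      n <- sample(4:200, 1)
      conf <- round(stats::runif(n, 0, 100) / sample(c(1, 5, 25), 1))
      lab <- stats::rbinom(n, 1, 0.4)
      if (length(unique(lab)) < 2) next
      expect_equal(auroc(conf, lab), oracle_auroc(conf, lab), tolerance = 1e-12)
    }
  })
  expect_error(auroc(c(1, 2), c(1, 1)), "single class")
})

test_that("AUROC is invariant under strictly increasing transforms", {
  withr::with_seed(333, {
    conf <- stats::runif(300, 0, 100)
    lab <- stats::rbinom(300, 1, conf / 100)
  })
  base <- auroc(conf, lab)
  expect_equal(auroc(exp(conf / 20), lab), base, tolerance = 1e-12)
  m <- structure(list(field = "x", a_coef = -0.07, b_coef = 3, n_fit = 1L),
                 class = "platt_model")
  expect_equal(auroc(apply_platt(m, conf), lab), base, tolerance = 1e-12)
})

test_that("AUROC agrees with pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(444, {
    conf <- round(stats::runif(150, 0, 100))
    lab <- stats::rbinom(150, 1, conf / 100)
  })
  expect_equal(auroc(conf, lab),
               as.numeric(pROC::auc(pROC::roc(lab, conf, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("the abstention curve rejects strictly below threshold", {
  recs <- data.frame(confidence = c(90, 40), label = c(1, 0))
  curve <- abstention_curve(recs, thresholds = c(0, 50, 95))
  expect_equal(curve$rejected_fraction, c(0, 0.5, 1))
  expect_equal(curve$accepted_accuracy[1], 0.5)  # full coverage accuracy
  expect_equal(curve$accepted_accuracy[2], 1)
  expect_true(is.na(curve$accepted_accuracy[3]))
  # default thresholds: non-decreasing rejection starting at 0
  withr::with_seed(555, {
    recs <- data.frame(confidence = sample(seq(0, 100, 5), 40, replace = TRUE),
                       label = stats::rbinom(40, 1, 0.7))
  })
  curve <- abstention_curve(recs)
  expect_equal(curve$threshold[1], 0)
  expect_equal(curve$rejected_fraction[1], 0)
  expect_true(all(diff(curve$rejected_fraction) >= 0))
})

test_that("the per-field summary reports accuracy, kappa and AUROC together", {
  withr::with_seed(666, {
    recs <- data.frame(
      report_id = rep(sprintf("r%d", 1:30), 2),
      field = rep(c("histologic_grade", "resection"), each = 30),
      extracted = sample(c("High", "Low"), 60, replace = TRUE),
      truth = sample(c("High", "Low"), 60, replace = TRUE),
      confidence = stats::runif(60, 0, 100))
    recs$label <- as.integer(recs$extracted == recs$truth)
  })
  s <- evaluation_summary(recs)
  expect_setequal(s$field, c("histologic_grade", "resection"))
  for (f in s$field) {
    sub <- recs[recs$field == f, ]
    expect_equal(s$accuracy[s$field == f], mean(sub$label))
    expect_equal(s$auroc[s$field == f], oracle_auroc(sub$confidence, sub$label))
  }
})
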