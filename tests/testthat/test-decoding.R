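# Feature construction and the undersampled SVM protocol.

dff_from <- function(v, fps = 30, condition = NA_character_) {
  tibble::new_tibble(
    tibble::tibble(time_s = (seq_along(v) - 1) / fps, dff = v),
    nrow = length(v), class = "dff_trace", fps = fps,
    condition_label = condition
  )
}

pem_with_snippets <- function(snippets, condition) {
  n <- length(snippets)
  v <- rep(0, (n + 10) * 90)
  pem <- extract_perievent(
    dff_from(v, condition = condition),
    tibble::tibble(
      time_s = seq(5, length.out = n, by = 2),
      event_type = "nose_poke_active", rewarded = TRUE
    )
  )
  pem$snippet <- snippets
  pem
}

gauss_features <- function(n, mu_rr, mu_ri, sd = 1) {
  tibble::tibble(
    label = factor(rep(c("RR", "RI"), each = n), levels = c("RR", "RI")),
    x = c(rnorm(n, mu_rr, sd), rnorm(n, mu_ri, sd))
  )
}

test_that("features are pre/post means over the requested input range", {
  const <- lapply(1:6, function(i) rep(0.3, 120))
  ramp <- lapply(1:6, function(i) c(rep(0, 60), seq(0, 0.1, length.out = 60)))
  ft <- build_features(
    pem_with_snippets(const, "RR"),
    pem_with_snippets(ramp, "RI"), "NP R+"
  )
  expect_equal(nrow(ft), 12)
  rr <- ft[ft$label == "RR", ]
  ri <- ft[ft$label == "RI", ]
  expect_true(all(rr$pre_mean == 0.3) && all(rr$post_mean == 0.3))
  expect_equal(unique(ri$pre_mean), 0)
  expect_equal(unique(ri$post_mean), 0.05, tolerance = 1e-2) # ramp mean to grid precision
  # narrower input range uses 30 + 30 frames
  ft1 <- build_features(
    pem_with_snippets(const, "RR"),
    pem_with_snippets(ramp, "RI"), "NP R+",
    input_range = c(-1, 1)
  )
  ri1 <- ft1[ft1$label == "RI", ]
  expect_equal(unique(ri1$post_mean), mean(seq(0, 0.1, length.out = 60)[1:30]))
  expect_error(
    build_features(
      pem_with_snippets(const, "RR"),
      pem_with_snippets(ramp, "RI"), "M_exit R-"
    ),
    "no events"
  )
})

test_that("perfectly separable classes give mean AUC and accuracy of 1", {
  set.seed(1)
  ft <- gauss_features(60, 0, 10, sd = 0.01)
  res <- run_svm_protocol(ft, n_resamples = 25, seed = 2)
  expect_equal(res$summary$mean[res$summary$metric == "auc"], 1.0)
  expect_equal(res$summary$mean[res$summary$metric == "accuracy"], 1.0)
})

test_that("label permutation pins every metric to chance", {
  set.seed(3)
  ft <- gauss_features(100, 0, 3) # real effect, destroyed by permutation
  res <- run_svm_protocol(ft, n_resamples = 150, seed = 4, permute_labels = TRUE)
  s <- res$summary
  for (m in c("auc", "accuracy", "sensitivity", "specificity")) {
    expect_lt(abs(s$mean[s$metric == m] - 0.5), 0.02)
  }
})

test_that("Gaussian class separation recovers the binormal AUC", {
  set.seed(5)
  ft <- gauss_features(200, 0, 1)
  res <- run_svm_protocol(ft, n_resamples = 60, seed = 6)
  expect_lt(abs(res$summary$mean[1] - pnorm(1 / sqrt(2))), 0.03)
})

test_that("mean AUC is non-decreasing in class separation", {
  set.seed(7)
  aucs <- vapply(c(0.3, 1, 2.5), function(sep) {
    ft <- gauss_features(80, 0, sep)
    run_svm_protocol(ft, n_resamples = 50, seed = 8)$summary$mean[1]
  }, 0)
  expect_true(all(diff(aucs) > 0))
})

test_that("pooled-score AUC matches an independent ROC implementation", {
  set.seed(9)
  scores <- rnorm(100)
  truth <- rep(c(TRUE, FALSE), 50)
  scores[truth] <- scores[truth] + 1
  expect_equal(
    habitometry:::auc_rank(scores, truth),
    as.numeric(pROC::auc(pROC::roc(truth, scores,
      direction = "<", quiet = TRUE
    )))
  )
})

test_that("balanced evaluation makes accuracy the mean of sensitivity and specificity", {
  set.seed(10)
  ft <- gauss_features(48, 0, 1.2)
  res <- run_svm_protocol(ft, n_resamples = 40, seed = 11)
  m <- res$metrics
  expect_equal(m$accuracy, (m$sensitivity + m$specificity) / 2, tolerance = 1e-12)
})

test_that("identical seeds reproduce the full decoding result", {
  set.seed(12)
  ft <- gauss_features(30, 0, 1)
  a <- run_svm_protocol(ft, n_resamples = 10, seed = 13)
  b <- run_svm_protocol(ft, n_resamples = 10, seed = 13)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$roc, b$roc)
})

test_that("confusion metrics follow the printed formulas exactly", {
  m <- metrics_from_confusion(tp = 3, tn = 4, fp = 1, fn = 2)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  perfect <- metrics_from_confusion(tp = 5, tn = 7, fp = 0, fn = 0)
  expect_true(all(unlist(perfect) == 1))
  expect_warning(deg <- metrics_from_confusion(tp = 0, tn = 4, fp = 1, fn = 0),
    "sensitivity"
  )
  expect_true(is.nan(deg$sensitivity))
  expect_equal(deg$accuracy, 0.8)
  expect_error(metrics_from_confusion(-1, 0, 0, 0), "non-negative")
})

test_that("chance comparison is a two-tailed one-sample t test", {
  r <- compare_to_chance(c(0.6, 0.7, 0.8), chance = 0.5)
  expect_equal(r$t, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-6) # 3.464
  expect_equal(r$estimate, 0.7)
  sym <- compare_to_chance(c(0.4, 0.5, 0.6), chance = 0.5)
  expect_equal(sym$t, 0)
  expect_equal(sym$p_value, 1)
  expect_error(compare_to_chance(0.7), "at least 2")
  expect_error(compare_to_chance(c(0.5, 0.5)), "variance")
})

test_that("too few trials per class is an error", {
  ft <- tibble::tibble(label = factor(rep(c("RR", "RI"), c(3, 20))), x = rnorm(23))
  expect_error(run_svm_protocol(ft, k = 4), "insufficient trials")
})
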