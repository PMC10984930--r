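test_that("a query identical to a training record takes its class outright", {
  tab <- simulate_hybrid_table(n = 40, separation = 8, cat_fidelity = 1,
                               label_noise = 0, seed = 41)
  fit <- anrs(tab)
  pr <- predict(fit, tab$data[5, ], type = "full")[[1]]
  expect_identical(pr$label, tab$data$class[5])
  expect_false(pr$tie_broken)
})

test_that("vote ties fall back to mean member distance, then the lexical label", {
  # one numeric attribute, values 0.2/0.6 labeled a and 1.0/1.4 labeled b;
  # r = 1 sweeps all four in: 2-2 vote, class a is nearer on average
  tab <- as_hybrid_table(data.frame(v = c(0.2, 0.6, 1.0, 1.4),
                                    y = c("a", "a", "b", "b"),
                                    stringsAsFactors = FALSE), decision = "y")
  fit <- anrs(tab, r = 1)
  pr <- predict(fit, data.frame(v = 0), type = "full")[[1]]
  expect_identical(length(pr$members), 4L)
  expect_identical(pr$label, "a")
  expect_true(pr$tie_broken)

  # perfectly symmetric tie: lexicographically smallest label wins
  tab2 <- as_hybrid_table(data.frame(v = c(-1, 1), y = c("b", "a"),
                                     stringsAsFactors = FALSE), decision = "y")
  fit2 <- anrs(tab2, r = 0)
  pr2 <- predict(fit2, data.frame(v = 0), type = "full")[[1]]
  expect_identical(pr2$label, "a")
  expect_true(pr2$tie_broken)
})

test_that("r = 0 predictions equal the brute-force nearest-neighbor oracle", {
  set.seed(42)
  for (i in 1:20) {
    tab <- random_table(25, n_classes = sample(2:3, 1))
    fit <- anrs(tab, r = 0)
    for (j in 1:3) {
      q <- random_table(1)$data[, setdiff(names(tab$data), "class"), drop = FALSE]
      expect_identical(predict(fit, q), nn_oracle(tab, q))
    }
  }
})

test_that("prediction never inspects the query's true label", {
  tab <- simulate_hybrid_table(n = 50, seed = 43)
  fit <- anrs(tab)
  with_label <- tab$data
  with_label$class <- rev(with_label$class)     # scrambled labels present
  without_label <- tab$data[, setdiff(names(tab$data), "class")]
  expect_identical(predict(fit, with_label), predict(fit, without_label))
})

test_that("votes sum to the neighborhood size and empty queries return empty output", {
  tab <- simulate_hybrid_table(n = 30, seed = 44)
  fit <- anrs(tab)
  full <- predict(fit, tab$data[1:4, ], type = "full")
  for (pr in full) expect_identical(sum(pr$votes), length(pr$members))
  v <- predict(fit, tab$data[1:4, ], type = "votes")
  expect_identical(dim(v), c(4L, 2L))
  expect_identical(predict(fit, tab$data[0, ]), character(0))
})

test_that("query frames must carry every condition attribute", {
  tab <- simulate_hybrid_table(n = 20, seed = 45)
  fit <- anrs(tab)
  q <- tab$data[1:2, setdiff(names(tab$data), c("class", "num1"))]
  expect_error(predict(fit, q), "num1", class = "anrs_config_error")
})

test_that("the formula and data-frame interfaces agree with the table interface", {
  tab <- simulate_hybrid_table(n = 40, seed = 46)
  df <- tab$data
  f1 <- anrs(class ~ ., data = df)
  f2 <- anrs(df, decision = "class")
  f3 <- anrs(tab)
  q <- df[1:5, ]
  expect_identical(predict(f1, q), predict(f3, q))
  expect_identical(predict(f2, q), predict(f3, q))
})

test_that("k-fold CV is stratified, sized, averaged and reproducible", {
  tab <- simulate_hybrid_table(n = 100, separation = 3, seed = 47)
  cv <- cv_anrs(tab, k = 10, seed = 5)
  expect_identical(cv$fold_sizes, rep(10L, 10))
  expect_length(cv$fold_accuracies, 10)
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracies))
  expect_true(all(cv$fold_accuracies >= 0 & cv$fold_accuracies <= 1))
  cv2 <- cv_anrs(tab, k = 10, seed = 5)
  expect_identical(cv, cv2)
  expect_error(cv_anrs(tab, k = 101, seed = 1), class = "anrs_config_error")
  expect_error(cv_anrs(tab, k = 1, seed = 1), class = "anrs_config_error")
})

test_that("a wide-margin synthetic table cross-validates near perfectly", {
  tab <- simulate_hybrid_table(n = 80, separation = 8, cat_fidelity = 1,
                               label_noise = 0, seed = 48)
  cv <- cv_anrs(tab, k = 5, seed = 2)
  expect_gte(cv$mean_accuracy, 0.95)
})

test_that("label-shuffled data scores near the majority-class rate", {
  tab <- simulate_hybrid_table(n = 400, separation = 3, seed = 49)
  shuf <- tab
  shuf$data$class <- with_seed_helper(99, sample(shuf$data$class))
  cv <- cv_anrs(shuf, k = 10, seed = 3)
  base_rate <- max(table(shuf$data$class)) / 400
  expect_lt(abs(cv$mean_accuracy - base_rate), 0.1)
})

test_that("holdout trains on the first split and is exact on duplicated data", {
  tab <- simulate_hybrid_table(n = 60, seed = 50)
  # duplicate every record: with r = 0 each test query finds its twin
  dup <- tab
  dup$data <- rbind(tab$data, tab$data)
  acc <- holdout_anrs(dup, n_train = 60, n_test = 60, r = 0, seed = 7)
  expect_gte(acc, 0.95)
  expect_error(holdout_anrs(tab, n_train = 50, n_test = 20),
               class = "anrs_config_error")
})

test_that("radius sweep reuses identical folds and rejects duplicates", {
  tab <- simulate_hybrid_table(n = 60, separation = 2, label_noise = 0.1, seed = 51)
  sw <- radius_sweep(tab, c(0, 0.002, 0.5), k = 5, seed = 9)
  expect_identical(nrow(sw), 3L)
  expect_error(radius_sweep(tab, c(0.002, 0.002), k = 5, seed = 9),
               class = "anrs_config_error")
  # the r = 0 entry matches an independent CV run at r = 0 on the same seed
  cv0 <- cv_anrs(tab, k = 5, r = 0, seed = 9)
  expect_equal(sw$mean_accuracy[sw$r == 0], cv0$mean_accuracy)
  # sweeps are reproducible
  expect_identical(sw, radius_sweep(tab, c(0, 0.002, 0.5), k = 5, seed = 9))
})

test_that("accuracy degrades as synthetic class overlap rises", {
  # separation high -> medium -> low at a fixed seed
  seps <- c(6, 2, 0.5)
  accs <- vapply(seps, function(s) {
    tab <- simulate_hybrid_table(n = 120, separation = s, cat_fidelity = 0.8,
                                 seed = 52)
    cv_anrs(tab, k = 5, seed = 4)$mean_accuracy
  }, numeric(1))
  expect_true(all(diff(accs) <= 0.03))
})
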