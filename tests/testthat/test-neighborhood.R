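test_that("adaptive threshold blends minimum and range", {
  th <- adaptive_threshold(c(0.2, 0.7, 1.2), r = 0.002)
  expect_equal(th$delta, 0.202)
  expect_equal(th$min_d, 0.2)
  expect_equal(th$range_d, 1.0)

  expect_equal(adaptive_threshold(c(0.4, 0.9), r = 0)$delta, 0.4)
  th0 <- adaptive_threshold(rep(0.3, 5), r = 7)
  expect_equal(th0$range_d, 0)
  expect_equal(th0$delta, 0.3)

  expect_error(adaptive_threshold(numeric(0), 0.1), class = "anrs_contract_error")
  expect_error(adaptive_threshold(c(0.1, 0.2), r = -1), class = "anrs_config_error")
})

test_that("the threshold law holds exactly on random distance lists", {
  set.seed(31)
  for (i in 1:200) {
    d <- runif(sample.int(30, 1), 0, 5)
    r <- runif(1, 0, 2)
    th <- adaptive_threshold(d, r)
    expect_identical(th$delta, min(d) + r * (max(d) - min(d)))
  }
})

test_that("neighborhoods contain the argmin and grow monotonically in r", {
  # one numeric attribute: training values 1, 5, 9, query 0 -> at tiny r
  # only the nearest record qualifies
  tab <- as_hybrid_table(data.frame(v = c(1, 5, 9), y = c("a", "b", "a"),
                                    stringsAsFactors = FALSE), decision = "y")
  p <- fit_distance_params(tab)
  nb <- build_neighborhood(list(v = 0), tab, p, r = 0.002)
  expect_identical(nb$members, 1L)
  expect_equal(nb$delta, nb$min_d + 0.002 * nb$range_d)

  # r >= 1 sweeps in every record
  nb_all <- build_neighborhood(list(v = 0), tab, p, r = 1)
  expect_identical(nb_all$members, 1:3)

  # single-record table
  tab1 <- subset_rec <- as_hybrid_table(data.frame(v = 2, y = "a",
                                                   stringsAsFactors = FALSE),
                                        decision = "y")
  p1 <- suppressMessages(fit_distance_params(tab1))
  expect_identical(build_neighborhood(list(v = 99), tab1, p1, r = 0.002)$members, 1L)

  # monotone membership in r, never empty, on random tables
  set.seed(32)
  for (i in 1:20) {
    rt <- random_table(15)
    pp <- fit_distance_params(rt)
    q <- rt$data[sample.int(15, 1), ]
    prev <- integer(0)
    for (r in c(0, 0.01, 0.1, 0.5, 1)) {
      m <- build_neighborhood(q, rt, pp, r = r)$members
      expect_gt(length(m), 0)
      expect_true(all(prev %in% m))
      prev <- m
    }
  }
})

test_that("the attribute subset must be known condition attributes", {
  tab <- random_table(8)
  p <- fit_distance_params(tab)
  expect_error(build_neighborhood(tab$data[1, ], tab, p, attributes = "class"),
               class = "anrs_config_error")
  expect_error(build_neighborhood(tab$data[1, ], tab, p, attributes = "nope"),
               class = "anrs_config_error")
  nb <- build_neighborhood(tab$data[1, ], tab, p, attributes = "num1")
  expect_gt(length(nb$members), 0)
})

test_that("discrete granulation gives exact approximations and empty boundary", {
  # two tight, far-apart clusters; r small -> every neighborhood is pure
  df <- data.frame(v = c(0, 0.1, 0.2, 100, 100.1, 100.2),
                   y = rep(c("a", "b"), each = 3), stringsAsFactors = FALSE)
  tab <- as_hybrid_table(df, decision = "y")
  ap <- class_approximations(tab, r = 0.0001)
  expect_identical(ap$lower$a, 1:3)
  expect_identical(ap$upper$a, 1:3)
  expect_identical(ap$lower$b, 4:6)
  expect_identical(ap$boundary, integer(0))
  expect_identical(boundary_region(ap), integer(0))
  expect_equal(ap$quality, 1)
})

test_that("a straddling record lands in both uppers, no lower, and the boundary", {
  # 6-record toy: record 6 labeled b sits between the clusters; with a
  # generous radius its neighborhood spans both classes
  df <- data.frame(v = c(0, 1, 2, 20, 21, 10),
                   y = c("a", "a", "a", "b", "b", "b"), stringsAsFactors = FALSE)
  tab <- as_hybrid_table(df, decision = "y")
  r <- 0.75
  ap <- class_approximations(tab, r = r)
  want <- approx_oracle(tab, r)
  expect_same_approx(ap, want)
  expect_true(6L %in% ap$upper$a && 6L %in% ap$upper$b)
  expect_false(6L %in% c(ap$lower$a, ap$lower$b))
  expect_true(6L %in% ap$boundary)
  expect_identical(boundary_region(ap), ap$boundary)
})

test_that("a single-class table is its own lower and upper approximation", {
  df <- data.frame(v = rnorm(5), y = rep("only", 5), stringsAsFactors = FALSE)
  tab <- as_hybrid_table(df, decision = "y")
  ap <- class_approximations(tab, r = 2)
  expect_identical(ap$lower$only, 1:5)
  expect_identical(ap$upper$only, 1:5)
  expect_identical(ap$boundary, integer(0))
})

test_that("approximations equal brute-force enumeration on random tables", {
  set.seed(33)
  for (i in 1:30) {
    tab <- random_table(sample(5:25, 1), n_num = sample(1:2, 1),
                        n_cat = sample(1:2, 1), n_classes = sample(2:3, 1))
    r <- sample(c(0, 0.002, 0.05, 0.3, 0.8), 1)
    ap <- class_approximations(tab, r = r)
    want <- approx_oracle(tab, r)
    expect_same_approx(ap, want)
    # containment invariants
    lows <- ap$lower
    for (cl in ap$classes) {
      expect_true(all(ap$lower[[cl]] %in% ap$upper[[cl]]))
      lab <- table_cls <- tab$data$class[ap$lower[[cl]]]
      expect_true(all(lab == cl))
    }
    expect_identical(anyDuplicated(unlist(lows)), 0L)
    expect_identical(sort(unique(unlist(ap$upper))), seq_len(ap$n))
  }
})

test_that("at large r every neighborhood is the universe and mixed tables are all boundary", {
  set.seed(34)
  for (i in 1:5) {
    tab <- random_table(15, n_classes = 2)
    if (length(unique(tab$data$class)) < 2) next
    ap <- class_approximations(tab, r = 50)
    expect_identical(ap$boundary, seq_len(15L))
    expect_identical(unique(lengths(ap$lower)), 0L)
  }
})

test_that("unlabeled records break the approximation contract", {
  tab <- random_table(6)
  tab$data$class[2] <- NA
  expect_error(class_approximations(tab), class = "anrs_contract_error")
})
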