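# Independent oracles, kept deliberately naive: a dynamic-programming edit
# distance, a from-scratch hybrid distance built on it, brute-force
# neighborhood/approximation enumeration, and a nearest-neighbor voter.
# None of them call the package's distance or neighborhood code paths.

lev_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  if (na == 0) return(nb)
  if (nb == 0) return(na)
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- numeric(nb + 1)
    cur[1] <- i
    for (j in seq_len(nb)) {
      cur[j + 1] <- min(prev[j + 1] + 1,
                        cur[j] + 1,
                        prev[j] + (ca[i] != cb[j]))
    }
    prev <- cur
  }
  prev[nb + 1]
}

# Population sd, divisor n.
pop_sd_oracle <- function(v) sqrt(mean((v - mean(v))^2))

# Hybrid distance between two rows of a data frame, from first principles.
dist_oracle <- function(x, y, kinds, sigmas, weights, normalize) {
  acc <- 0
  for (a in names(kinds)) {
    w <- weights[[a]]
    if (kinds[[a]] == "numeric") {
      s <- sigmas[[a]]
      if (s > 0) acc <- acc + w * (abs(x[[a]] - y[[a]]) / (4 * s))^2
    } else {
      L <- lev_oracle(as.character(x[[a]]), as.character(y[[a]]))
      if (normalize) {
        m <- max(nchar(as.character(x[[a]])), nchar(as.character(y[[a]])))
        L <- if (m > 0) L / m else 0
      }
      acc <- acc + w * L^2
    }
  }
  sqrt(acc)
}

oracle_setup <- function(tab, normalize = TRUE) {
  kinds <- tab$schema$kinds
  num <- names(kinds)[kinds == "numeric"]
  sigmas <- vapply(num, function(a) pop_sd_oracle(tab$data[[a]]), numeric(1))
  list(kinds = kinds, sigmas = sigmas, weights = tab$schema$weights,
       normalize = normalize)
}

oracle_pairwise <- function(tab, normalize = TRUE) {
  st <- oracle_setup(tab, normalize)
  n <- nrow(tab$data)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) {
        D[i, j] <- dist_oracle(tab$data[i, ], tab$data[j, ], st$kinds,
                               st$sigmas, st$weights, st$normalize)
      }
    }
  }
  D + t(D)
}

# Brute-force lower/upper/boundary enumeration over all records.
approx_oracle <- function(tab, r, normalize = TRUE) {
  D <- oracle_pairwise(tab, normalize)
  lab <- tab$data[[tab$schema$decision]]
  n <- nrow(D)
  classes <- sort(unique(lab))
  lower <- setNames(lapply(classes, function(cl) integer(0)), classes)
  upper <- lower
  for (i in seq_len(n)) {
    delta <- min(D[i, ]) + r * (max(D[i, ]) - min(D[i, ]))
    hood <- lab[D[i, ] <= delta]
    for (cl in classes) {
      if (all(hood == cl)) lower[[cl]] <- c(lower[[cl]], i)
      if (any(hood == cl)) upper[[cl]] <- c(upper[[cl]], i)
    }
  }
  boundary <- sort(setdiff(unique(unlist(upper)), unique(unlist(lower))))
  list(lower = lower, upper = upper, boundary = boundary)
}

# Nearest-neighbor vote with the package's stated tie-break cascade
# (plurality over the argmin set; then smaller mean distance; then
# lexicographically smallest label) -- at r = 0 the neighborhood is the
# argmin set, so this is the reference for r = 0 predictions.
nn_oracle <- function(train_tab, query_row, r = 0, normalize = TRUE) {
  st <- oracle_setup(train_tab, normalize)
  d <- vapply(seq_len(nrow(train_tab$data)), function(j)
    dist_oracle(query_row, train_tab$data[j, ], st$kinds, st$sigmas,
                st$weights, st$normalize), numeric(1))
  delta <- min(d) + r * (max(d) - min(d))
  members <- which(d <= delta)
  lab <- train_tab$data[[train_tab$schema$decision]][members]
  counts <- table(lab)
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1) {
    md <- vapply(top, function(cl) mean(d[members][lab == cl]), numeric(1))
    top <- sort(top[md == min(md)])[1]
  }
  top[1]
}

with_seed_helper <- function(seed, code) {
  set.seed(seed)
  force(code)
}

random_token <- function(len, alphabet = letters[1:5]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Small random hybrid table straight from data-frame primitives (does not
# go through the package generator).
random_table <- function(n, n_num = 2, n_cat = 2, n_classes = 2,
                         spread = 1.5, max_len = 4) {
  df <- list()
  for (j in seq_len(n_num)) df[[paste0("num", j)]] <- rnorm(n, sd = spread)
  for (j in seq_len(n_cat)) {
    df[[paste0("cat", j)]] <- vapply(seq_len(n), function(i)
      random_token(sample.int(max_len, 1)), character(1))
  }
  df[["class"]] <- paste0("c", sample.int(n_classes, n, replace = TRUE))
  as_hybrid_table(as.data.frame(df, stringsAsFactors = FALSE), decision = "class")
}

expect_same_approx <- function(got, want) {
  for (cl in names(want$lower)) {
    expect_identical(as.integer(got$lower[[cl]]), as.integer(want$lower[[cl]]))
    expect_identical(as.integer(got$upper[[cl]]), as.integer(want$upper[[cl]]))
  }
  expect_identical(as.integer(got$boundary), as.integer(want$boundary))
}
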