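test_that("symmetric uncertainty matches closed forms and brute force", {
  x <- c(1, 1, 2, 2, 3, 3)
  expect_equal(symmetric_uncertainty(x, x), 1)
  ## independent balanced binary variables on a complete 2x2 table
  a <- c(0, 0, 1, 1); b <- c(0, 1, 0, 1)
  expect_equal(symmetric_uncertainty(a, b), 0)

  ## 8-sample toy table against direct entropy computation
  x8 <- c(1, 1, 1, 2, 2, 3, 3, 3)
  y8 <- c(1, 1, 2, 2, 2, 1, 3, 3)
  H2 <- function(v) {
    p <- as.numeric(table(v)) / length(v)
    -sum(p * log2(p))
  }
  Hxy <- {
    p <- as.numeric(table(paste(x8, y8))) / 8
    -sum(p * log2(p))
  }
  expect_equal(symmetric_uncertainty(x8, y8),
               2 * (H2(x8) + H2(y8) - Hxy) / (H2(x8) + H2(y8)),
               tolerance = 1e-12)
  ## symmetry and relabeling invariance
  expect_equal(symmetric_uncertainty(x8, y8), symmetric_uncertainty(y8, x8))
  expect_equal(symmetric_uncertainty(x8, y8),
               symmetric_uncertainty(c("a", "b", "c")[x8], y8))
})

test_that("MDL discretization splits informative features only", {
  set.seed(5)
  y <- rep(c(TRUE, FALSE), each = 100)
  x_signal <- ifelse(y, rnorm(200, 2), rnorm(200, -2))
  x_noise <- rnorm(200)
  b_signal <- discretize_mdl(x_signal, y)
  b_noise <- discretize_mdl(x_noise, y)
  expect_gte(length(attr(b_signal, "cuts")), 1L)
  expect_equal(length(attr(b_noise, "cuts")), 0L)
  expect_equal(length(unique(b_noise)), 1L)
})

test_that("merit of a singleton equals its class correlation", {
  set.seed(9)
  y <- rep(c(1, 2), 30)
  X <- cbind(f1 = y + sample(0:1, 60, TRUE), f2 = sample(1:3, 60, TRUE))
  expect_equal(cfs_merit(X, y, 1), symmetric_uncertainty(X[, 1], y))
  expect_equal(cfs_merit(X, y, integer(0)), 0)
})

test_that("redundancy is penalized, complementary signal rewarded", {
  set.seed(10)
  y <- rep(c(1, 2), 40)
  f <- y + sample(0:1, 80, TRUE)
  ## a perfect duplicate brings no merit gain (full redundancy penalty) ...
  X <- cbind(f, f)
  expect_equal(cfs_merit(X, y, c(1, 2)), cfs_merit(X, y, 1))
  ## ... while an equally informative independent feature raises the merit
  g <- y + sample(0:1, 80, TRUE)
  X2 <- cbind(f, g)
  expect_gt(cfs_merit(X2, y, c(1, 2)),
            max(cfs_merit(X2, y, 1), cfs_merit(X2, y, 2)) - 1e-10)
})

test_that("features uncorrelated with the class have zero merit", {
  y <- rep(c(1, 2), each = 4)
  X <- cbind(rep(c(1, 2), 4), rep(c(1, 1, 2, 2), 2))
  expect_equal(cfs_merit(X, y, 1:2), 0)
})

test_that("best-first search finds a planted predictive feature", {
  set.seed(21)
  n <- 120
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- cbind(matrix(rnorm(n * 8), n), ifelse(y, 1, 0) + rnorm(n, sd = 0.05))
  colnames(X) <- paste0("f", 1:9)
  sel <- best_first_search(X, y)
  expect_true(9 %in% sel)
  ## deterministic
  sel2 <- best_first_search(X, y)
  expect_identical(sel, sel2)
})

test_that("all-noise search cannot beat its best singleton", {
  set.seed(33)
  n <- 60
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- matrix(sample(1:3, n * 6, TRUE), n)
  best_single <- max(vapply(1:6, function(f)
    symmetric_uncertainty(X[, f], y), numeric(1)))
  sel <- best_first_search(X, y, discretize = FALSE)
  expect_gte(attr(sel, "merit") + 1e-12, 0)
  expect_gte(attr(sel, "merit"),
             cfs_merit(X, y, sel) - 1e-10)  # reported merit is the set's merit
  ## the search result never falls below the best singleton it evaluated
  expect_gte(attr(sel, "merit") + 1e-10, best_single)
})

test_that("balanced-subset selection recovers planted signal features", {
  set.seed(44)
  n <- 300
  y <- c(rep(TRUE, 60), rep(FALSE, 240))
  M <- 40
  X <- matrix(rnorm(n * M), n, M)
  colnames(X) <- c("rel_dist", "coev_MIc_c0", paste0("noise", 1:(M - 2)))
  ## partially informative, complementary signals: neither alone separates
  ## the classes, together they do much better
  X[, 1] <- ifelse(y, 0.2, 0.7) + rnorm(n, sd = 0.25)
  X[, 2] <- ifelse(y, 0.8, 0.3) + rnorm(n, sd = 0.25)
  pairs <- tibble::tibble(features = X, label_DEF1 = y)
  res <- select_features(pairs, label = "DEF1", n_subsets = 10, seed = 7)
  expect_true(all(c(1, 2) %in% res$union))
  noise_frac <- length(setdiff(res$union, 1:2)) / (M - 2)
  expect_lte(noise_frac, 0.10)
  ## union is the union of the per-subsample sets; reproducible with seed
  expect_setequal(res$union, sort(unique(unlist(res$subsets))))
  res2 <- select_features(pairs, label = "DEF1", n_subsets = 10, seed = 7)
  expect_identical(res$union, res2$union)
})
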