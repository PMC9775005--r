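test_that("singleton Gaussian case matches the closed form", {
  fam <- unit_gaussian_family()
  v <- mk_mmd2(matrix(0), matrix(1), fam)
  expect_equal(v, 2 - 2 * exp(-0.5), tolerance = 1e-12)
})

test_that("identical empirical distributions give zero (biased)", {
  set.seed(1)
  A <- matrix(rnorm(60), 15)
  fam <- make_kernel_family(A)
  expect_lt(abs(mk_mmd2(A, A, fam)), 1e-12)
})

test_that("degenerate convex weights reduce to single-kernel MMD", {
  set.seed(2)
  A <- matrix(rnorm(40), 10)
  B <- matrix(rnorm(40, 0.5), 10)
  fam <- make_kernel_family(rbind(A, B), m = 4)
  fam1 <- set_kernel_weights(fam, c(1, 0, 0, 0))
  single <- structure(list(bandwidths = fam$bandwidths[1], beta = 1,
                           kernel = "gaussian"), class = "kernel_family")
  expect_equal(mk_mmd2(A, B, fam1), mk_mmd2(A, B, single), tolerance = 1e-12)
})

test_that("production estimator equals the naive double-sum oracle", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(2:64, 1)
    np <- sample(2:64, 1)
    d <- sample(1:5, 1)
    m <- sample(1:5, 1)
    S <- matrix(rnorm(n * d), n)
    T_ <- matrix(rnorm(np * d, mean = runif(1, -1, 1)), np)
    fam <- suppressWarnings(make_kernel_family(rbind(S, T_), m))
    for (est in c("biased", "unbiased")) {
      prod <- mk_mmd2(S, T_, fam, est)
      orac <- naive_mk_mmd2(S, T_, fam, est)
      expect_equal(prod, orac, tolerance = 1e-8)
    }
  }
})

test_that("biased estimate is nonnegative; unbiased is centred under the null", {
  set.seed(5)
  fam <- NULL
  vals <- replicate(200, {
    S <- matrix(rnorm(16), 8)
    T_ <- matrix(rnorm(16), 8)
    if (is.null(fam)) fam <<- make_kernel_family(rbind(S, T_))
    c(mk_mmd2(S, T_, fam, "biased"), mk_mmd2(S, T_, fam, "unbiased"))
  })
  expect_true(all(vals[1, ] >= 0))
  se <- sd(vals[2, ]) / sqrt(ncol(vals))
  expect_lt(abs(mean(vals[2, ])), 2 * se + 1e-8)
})

test_that("MK-MMD grows with the mean separation of two Gaussians", {
  set.seed(8)
  mus <- c(0, 0.5, 1, 2)
  means <- sapply(mus, function(mu) {
    mean(replicate(20, {
      S <- matrix(rnorm(256), ncol = 1)
      T_ <- matrix(rnorm(256, mean = mu), ncol = 1)
      fam <- make_kernel_family(rbind(S, T_))
      mk_mmd2(S, T_, fam)
    }))
  })
  expect_true(all(diff(means) > 0))
})

test_that("kernel family obeys the convex-combination constraints", {
  set.seed(3)
  X <- matrix(rnorm(30), 10)
  for (m in c(1, 3, 5)) {
    fam <- make_kernel_family(X, m)
    expect_length(fam$beta, m)
    expect_equal(sum(fam$beta), 1)
    expect_true(all(fam$beta >= 0))
  }
  # median heuristic on a hand-enumerable set: distances {2}, median 2
  fam1 <- make_kernel_family(matrix(c(0, 2), ncol = 1), m = 1)
  expect_equal(fam1$bandwidths, 2)
  # geometric ladder around the median for m = 5, spacing 2
  fam5 <- make_kernel_family(matrix(c(0, 2), ncol = 1), m = 5, spacing = 2)
  expect_equal(fam5$bandwidths, 2 * c(0.25, 0.5, 1, 2, 4))
  # all-identical features fall back to bandwidth 1 with a warning
  expect_warning(fam0 <- make_kernel_family(matrix(1, 4, 2)), "bandwidth")
  expect_equal(fam0$bandwidths[3], 1)
  # weight updates keep the simplex constraint
  fam5b <- set_kernel_weights(fam5, c(2, 1, 1, 0, 0))
  expect_equal(sum(fam5b$beta), 1)
  expect_error(set_kernel_weights(fam5, c(-1, 1, 1, 1, 1)),
               class = "eegdan_invalid_argument")
})

test_that("sampled multi-kernel Gram matrices are positive semi-definite", {
  set.seed(9)
  X <- matrix(rnorm(60), 20)
  fam <- make_kernel_family(X)
  K <- eegdan:::.multi_gram(eegdan:::.sqdist(X, X), fam)
  expect_true(isSymmetric(K, tol = 1e-12))
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("estimator rejects mismatched or empty inputs", {
  fam <- unit_gaussian_family()
  expect_error(mk_mmd2(matrix(1, 2, 2), matrix(1, 2, 3), fam),
               class = "eegdan_invalid_argument")
  expect_error(mk_mmd2(matrix(numeric(0), 0, 1), matrix(1), fam),
               class = "eegdan_invalid_argument")
  expect_error(mk_mmd2(matrix(1), matrix(1), fam, "unbiased"),
               class = "eegdan_invalid_argument")
})

test_that("analytic MMD gradient matches finite differences", {
  set.seed(12)
  S <- matrix(rnorm(15), 5)
  T_ <- matrix(rnorm(12, 0.5), 4)
  fam <- make_kernel_family(rbind(S, T_), m = 3)
  g <- eegdan:::mk_mmd2_grad(S, T_, fam)
  expect_equal(g$value, mk_mmd2(S, T_, fam), tolerance = 1e-12)
  eps <- 1e-6
  for (k in 1:5) {
    i <- sample(nrow(S), 1); j <- sample(ncol(S), 1)
    Sp <- S; Sp[i, j] <- Sp[i, j] + eps
    Sm <- S; Sm[i, j] <- Sm[i, j] - eps
    num <- (mk_mmd2(Sp, T_, fam) - mk_mmd2(Sm, T_, fam)) / (2 * eps)
    expect_equal(g$grad_source[i, j], num, tolerance = 1e-5)
    i <- sample(nrow(T_), 1)
    Tp <- T_; Tp[i, j] <- Tp[i, j] + eps
    Tm <- T_; Tm[i, j] <- Tm[i, j] - eps
    num <- (mk_mmd2(S, Tp, fam) - mk_mmd2(S, Tm, fam)) / (2 * eps)
    expect_equal(g$grad_target[i, j], num, tolerance = 1e-5)
  }
})
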