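test_that("classic silhouette reproduces the 1-D hand computation", {
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  cl <- c(1, 1, 2, 2)
  s <- classic_silhouette(pts, cl)
  # point 0: a = 1, b = 10.5
  expect_equal(s[1], 9.5 / 10.5, tolerance = 1e-12)
  expect_equal(s[1], 0.904762, tolerance = 1e-6)
  expect_true(all(s >= -1 & s <= 1))
})

test_that("classic silhouette agrees with cluster::silhouette", {
  set.seed(11)
  for (K in 2:3) {
    n <- 30
    pts <- matrix(rnorm(n * 2), n, 2)
    cl <- sample(seq_len(K), n, replace = TRUE)
    while (length(unique(cl)) < K) cl <- sample(seq_len(K), n, replace = TRUE)
    mine <- classic_silhouette(pts, cl)
    ref <- cluster::silhouette(cl, dist(pts))[, "sil_width"]
    expect_equal(mine, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("a point equidistant to both clusters gets silhouette zero", {
  pts <- matrix(c(0, 2, -2), ncol = 1)
  cl <- c(1, 1, 2)
  s <- classic_silhouette(pts, cl)
  expect_equal(s[1], 0)  # a = b = 2 for the point at the origin
})

test_that("fuzzy silhouette reproduces the weighted hand computations", {
  # unweighted: equals the classic value
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  st <- fuzzy_silhouette(X, theta = rep(1, 4), omega1 = 1:2, omega_neg = 3:4)
  expect_equal(st$beta_pos[1], 1)
  expect_equal(st$beta_neg[1], 10.5)
  expect_equal(st$s[1], 9.5 / 10.5, tolerance = 1e-12)

  # weighted: omega1 = {0, 1, 2} with theta (1, 0.5, 1)
  X2 <- matrix(c(0, 1, 2, 10, 11), ncol = 1)
  st2 <- fuzzy_silhouette(X2, theta = c(1, 0.5, 1, 1, 1),
                          omega1 = 1:3, omega_neg = 4:5)
  expect_equal(st2$beta_pos[1], 5 / 3, tolerance = 1e-12)
})

test_that("equal beta values give silhouette zero", {
  X <- matrix(c(0, -2, 2), ncol = 1)  # point 1 equidistant to both sets
  st <- suppressWarnings(
    fuzzy_silhouette(X, theta = rep(1, 3), omega1 = 2, omega_neg = 3))
  expect_equal(st$s[1], 0)
})

test_that("with unit weights the fuzzy silhouette reduces to the classic one", {
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(6:50, 1)
    q <- sample(1:3, 1)
    X <- matrix(rnorm(n * q), n, q)
    n1 <- sample(2:(n - 2), 1)
    omega1 <- seq_len(n1); omega_neg <- (n1 + 1):n
    st <- fuzzy_silhouette(X, rep(1, n), omega1, omega_neg)
    cl <- c(rep(1, n1), rep(2, n - n1))
    ref <- classic_silhouette(X, cl, orient_toward = 1)
    expect_equal(st$s, ref, tolerance = 1e-12)
    # own-cluster magnitudes agree; only the decoy orientation differs
    plain <- classic_silhouette(X, cl)
    expect_equal(abs(st$s), abs(plain), tolerance = 1e-12)
    expect_equal(st$s[omega1], plain[omega1], tolerance = 1e-12)
  }
})

test_that("swapping the two sets negates every silhouette value", {
  set.seed(13)
  X <- matrix(rnorm(40), 20, 2)
  theta <- runif(20, 0.2, 1)
  a <- fuzzy_silhouette(X, theta, 1:8, 9:20)
  b <- fuzzy_silhouette(X, theta, 9:20, 1:8)
  expect_equal(a$s, -b$s, tolerance = 1e-12)
})

test_that("silhouettes are invariant under rigid transforms", {
  set.seed(14)
  X <- matrix(rnorm(60), 30, 2)
  theta <- runif(30, 0.1, 1)
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  Xr <- sweep(X %*% R, 2, c(5, -3), `+`)
  a <- fuzzy_silhouette(X, theta, 1:10, 11:30)
  b <- fuzzy_silhouette(Xr, theta, 1:10, 11:30)
  expect_equal(a$s, b$s, tolerance = 1e-9)
})

test_that("subsampled silhouettes are seeded, deterministic, and consistent", {
  set.seed(15)
  X <- rbind(matrix(rnorm(500, 0), 250, 2), matrix(rnorm(500, 3), 250, 2))
  theta <- rep(1, 500)
  omega1 <- 1:250; omega_neg <- 251:500
  full <- fuzzy_silhouette(X, theta, omega1, omega_neg)
  cors <- vapply(1:5, function(sd) {
    sub <- fuzzy_silhouette(X, theta, omega1, omega_neg,
                            silhouette_config(rho = 0.5, seed = sd))
    sub2 <- fuzzy_silhouette(X, theta, omega1, omega_neg,
                             silhouette_config(rho = 0.5, seed = sd))
    expect_identical(sub$s, sub2$s)
    cor(sub$s, full$s)
  }, numeric(1))
  expect_gte(mean(cors), 0.9)
})

test_that("degenerate reference sets are handled per convention", {
  X <- matrix(c(0, 1, 5), ncol = 1)
  # singleton own set: neutral value with a warning
  expect_warning(st <- fuzzy_silhouette(X, rep(1, 3), omega1 = 1,
                                        omega_neg = 2:3),
                 "singleton")
  expect_equal(st$s[1], 0)
  # zero weight mass in the opposite set: hard error naming the class
  expect_error(fuzzy_silhouette(X, c(0, 0, 1), omega1 = 1:2, omega_neg = 3),
               "omega1")
  expect_error(fuzzy_silhouette(X, rep(1, 3), omega1 = 1:2,
                                omega_neg = integer(0)),
               "nonempty")
})

test_that("separation averages the classes and halves the gap", {
  st <- list(s = c(0.8, 0.8, -0.8, -0.8, 0.1))
  out <- separation(st, omega1 = 1:2, omega_neg = 3:4, omega0 = 5)
  expect_equal(out$s_bar_pos, 0.8)
  expect_equal(out$s_bar_neg, -0.8)
  expect_equal(out$s_bar_zero, 0.1)
  expect_equal(out$sep, 0.8)
  same <- separation(list(s = rep(0.3, 4)), 1:2, 3:4)
  expect_equal(same$sep, 0)
  expect_true(is.na(same$s_bar_zero))
  expect_error(separation(st, integer(0), 3:4), "degenerated")
})
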