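test_that("class covariances are trace-normalized within-class averages", {
  # identical trials across classes -> identical covariances
  set.seed(1)
  X <- matrix(rnorm(2 * 30), 2)
  data <- array(0, dim = c(4, 2, 30))
  for (i in 1:4) data[i, , ] <- X
  cc <- class_covariances(epoch_set(data, c("left", "left", "right", "right"),
                                    0, 0.3, 100))
  expect_equal(cc$C1, cc$C2)
  expect_equal(sum(diag(cc$C1)), 1)

  # single-channel epochs -> normalization forces both covariances to 1
  d1 <- array(rnorm(4 * 1 * 30), dim = c(4, 1, 30))
  cc1 <- class_covariances(epoch_set(d1, c("left", "left", "right", "right"),
                                     0, 0.3, 100))
  expect_equal(as.numeric(cc1$C1), 1)
  expect_equal(as.numeric(cc1$C2), 1)
})

test_that("class covariances match a brute-force oracle on a toy set", {
  set.seed(2)
  data <- array(rnorm(3 * 2 * 4), dim = c(3, 2, 4))  # 3 trials, 2 ch, 4 samp
  labels <- c("left", "left", "right")
  # oracle: per-trial cov() over time, trace-normalized, averaged in class
  oracle <- function(idx) {
    Cs <- lapply(idx, function(i) {
      C <- stats::cov(t(data[i, , ]))
      C / sum(diag(C))
    })
    Reduce(`+`, Cs) / length(idx)
  }
  expect_error(class_covariances(epoch_set(data, rep("left", 3), 0, 4, 1)),
               "two classes")
  data2 <- array(rnorm(4 * 2 * 4), dim = c(4, 2, 4))
  cc <- class_covariances(epoch_set(data2, c("left", "left", "right", "right"),
                                    0, 4, 1))
  oracle2 <- function(idx) {
    Cs <- lapply(idx, function(i) {
      C <- stats::cov(t(data2[i, , ]))
      C / sum(diag(C))
    })
    Reduce(`+`, Cs) / length(idx)
  }
  expect_equal(unname(cc$C1), unname(oracle2(1:2)), tolerance = 1e-12)
  expect_equal(unname(cc$C2), unname(oracle2(3:4)), tolerance = 1e-12)
})

test_that("fit_csp solves the generalized eigenproblem", {
  # identical classes -> all eigenvalues 1/2
  m <- fit_csp(diag(2) / 2, diag(2) / 2, 2)
  expect_equal(m$eigenvalues, c(0.5, 0.5))

  # known diagonal pair -> lambda {2/3, 1/3}, axis-aligned filters
  m2 <- fit_csp(diag(c(2, 1)) / 3, diag(c(1, 2)) / 3, 2)
  expect_equal(sort(m2$eigenvalues), c(1 / 3, 2 / 3), tolerance = 1e-12)
  for (j in 1:2) {
    w <- m2$filters[j, ]
    expect_lt(min(abs(w)) / max(abs(w)), 1e-10)  # one coordinate only
  }

  # random SPD pairs: each filter satisfies the defining identities
  for (seed in 1:5) {
    set.seed(seed)
    d <- sample(4:10, 1)
    C1 <- random_spd(d); C2 <- random_spd(d)
    nf <- 4
    m3 <- fit_csp(C1, C2, nf)
    Cc <- C1 + C2
    for (j in seq_len(nf)) {
      w <- m3$filters[j, ]
      expect_lt(abs(drop(w %*% Cc %*% w) - 1), 1e-8)        # normalization
      expect_lt(abs(drop(w %*% C1 %*% w) / drop(w %*% Cc %*% w) -
                      m3$eigenvalues[j]), 1e-8)              # Rayleigh = lambda
      resid <- C1 %*% w - m3$eigenvalues[j] * (Cc %*% w)
      expect_lt(max(abs(resid)), 1e-8)                       # eigen equation
    }
    expect_true(all(diff(pmax(m3$eigenvalues, 1 - m3$eigenvalues)) <= 1e-12))
  }
})

test_that("fit_csp validates its inputs", {
  expect_error(fit_csp(diag(3), diag(3), 3), "even")
  expect_error(fit_csp(diag(2), diag(2), 4), "exceed")
  expect_error(fit_csp(matrix(0, 2, 2), matrix(0, 2, 2), 2), "singular")
  A <- matrix(c(1, 0.5, 0.1, 1), 2)
  expect_error(fit_csp(A, diag(2), 2), "symmetric")
})

test_that("CSP is invariant to a common invertible linear transform", {
  set.seed(4)
  d <- 6
  C1 <- random_spd(d); C2 <- random_spd(d)
  A <- matrix(rnorm(d * d), d)
  while (abs(det(A)) < 0.1) A <- matrix(rnorm(d * d), d)
  m <- fit_csp(C1, C2, 4)
  mt <- fit_csp(A %*% C1 %*% t(A), A %*% C2 %*% t(A), 4)
  expect_equal(m$eigenvalues, mt$eigenvalues, tolerance = 1e-8)
  # filters correspond up to sign: w_t A ~ +/- w
  for (j in 1:4) {
    w <- m$filters[j, ]
    wt <- mt$filters[j, ] %*% A
    expect_lt(min(max(abs(wt - w)), max(abs(wt + w))), 1e-6)
  }
})

test_that("swapping class labels maps lambda to 1 - lambda", {
  set.seed(5)
  C1 <- random_spd(5); C2 <- random_spd(5)
  m12 <- fit_csp(C1, C2, 4)
  m21 <- fit_csp(C2, C1, 4)
  expect_equal(sort(m12$eigenvalues), sort(1 - m21$eigenvalues),
               tolerance = 1e-8)
})

test_that("csp_features are per-trial variances of projected signals", {
  ep <- separable_epochs(n_per_class = 3, n_ch = 2, n_samp = 40)
  cc <- class_covariances(ep)
  m <- fit_csp(cc$C1, cc$C2, 2)
  F <- csp_features(m, ep)
  expect_equal(dim(F), c(6, 2))
  # brute force: variance of the filtered time course
  for (i in 1:6) for (j in 1:2)
    expect_equal(F[i, j],
                 stats::var(drop(m$filters[j, ] %*% ep$data[i, , ])),
                 tolerance = 1e-10)

  # zero trial -> zero features; doubling amplitude quadruples features
  ep$data[1, , ] <- 0
  F2 <- csp_features(m, ep)
  expect_true(all(F2[1, ] == 0))
  ep$data[2, , ] <- 2 * ep$data[2, , ]
  F3 <- csp_features(m, ep)
  expect_equal(F3[2, ], 4 * F2[2, ], tolerance = 1e-10)

  # identity filter on 1-channel data returns plain signal variance
  d1 <- array(rnorm(3 * 1 * 20), dim = c(3, 1, 20))
  ep1 <- epoch_set(d1, c("left", "right", "left"), 0, 0.2, 100)
  ident <- structure(list(filters = matrix(1, 1, 1), eigenvalues = 0.5),
                     class = "csp_model")
  expect_equal(drop(csp_features(ident, ep1)),
               apply(d1[, 1, ], 1, stats::var), tolerance = 1e-12)

  expect_error(csp_features(m, ep1), "channels")
})

test_that("FLDA weights and threshold match the closed form", {
  # symmetric 1-D problem -> threshold at 0
  f <- matrix(c(-1.2, -0.8, -1, 1.2, 0.8, 1), ncol = 1)
  m <- fit_flda(f, c("a", "a", "a", "b", "b", "b"))
  expect_equal(m$bias, 0, tolerance = 1e-12)

  # 2-D toy set: weights equal Sw^-1 (m1 - m2) computed by brute force
  set.seed(6)
  X <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 2), 10, 2))
  y <- rep(c("a", "b"), each = 10)
  m2 <- fit_flda(X, y)
  m1v <- colMeans(X[1:10, ]); m2v <- colMeans(X[11:20, ])
  Sw <- crossprod(sweep(X[1:10, ], 2, m1v)) +
    crossprod(sweep(X[11:20, ], 2, m2v))
  expect_equal(m2$weights, drop(solve(Sw, m1v - m2v)), tolerance = 1e-10)

  # identical class means -> near-chance training accuracy
  set.seed(7)
  Xn <- matrix(rnorm(200), 100, 2)
  mn <- fit_flda(Xn, rep(c("a", "b"), 50))
  acc <- mean(predict(mn, Xn) == rep(c("a", "b"), 50))
  expect_lt(abs(acc - 0.5), 0.2)
})

test_that("FLDA predictions are correct, tie-broken, and scale-invariant", {
  X <- rbind(matrix(rnorm(40, -3), 20, 2), matrix(rnorm(40, 3), 20, 2))
  y <- rep(c("a", "b"), each = 20)
  m <- fit_flda(X, y)
  expect_true(all(predict(m, X) == y))

  # a point exactly on the boundary goes to the positive class
  w <- m$weights
  boundary <- matrix(m$bias * w / sum(w^2), 1)
  expect_equal(as.character(predict(m, boundary)),
               unname(m$class_map["positive"]))

  # decisions invariant to affine rescaling of one feature dimension
  X2 <- X; X2[, 2] <- 10 * X2[, 2] + 5
  m2 <- fit_flda(X2, y)
  Xt <- matrix(rnorm(60, 0, 4), 30, 2)
  Xt2 <- Xt; Xt2[, 2] <- 10 * Xt2[, 2] + 5
  expect_equal(as.character(predict(m, Xt)), as.character(predict(m2, Xt2)))

  expect_error(predict(m, Xt[, 1, drop = FALSE]), "width")
  expect_error(fit_flda(X, rep("a", 40)), "two classes")
})
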