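test_that("substructure counting matches a per-cell loop oracle", {
  X <- matrix(c(1, 1, 0, 0, 1, 1), 3, 2)
  ds <- fp_dataset(c("a", "b", "c"), X, c("positive", "positive", "negative"))
  cnt <- count_substructures(ds)
  expect_equal(unname(cnt$c_SP), c(2, 1))
  expect_equal(unname(cnt$c_SN), c(0, 1))
  expect_equal(cnt$N_P, 2)
  expect_equal(cnt$N_N, 1)

  set.seed(9)
  ds2 <- tiny_dataset(50, n_bits = 20, seed = 9)
  ds2$labels[1:5] <- "unlabeled"  # ignored by counting
  cnt2 <- count_substructures(ds2)
  orc <- oracle_counts(ds2$X, ds2$labels)
  expect_equal(unname(cnt2$c_SP), orc$c_SP)
  expect_equal(unname(cnt2$c_SN), orc$c_SN)
  expect_equal(cnt2$N_P, orc$N_P)

  ds2$labels[ds2$labels == "negative"] <- "unlabeled"
  expect_error(count_substructures(ds2), "positive and one negative")
})

test_that("the 180/132 worked case reproduces the hand-derived posterior and L", {
  st <- smoothed_stats(list(c_SP = 90, c_SN = 11, N_P = 180, N_N = 132), k = 1)
  expect_equal(st$p_S_given_P, 91 / 182)
  expect_equal(st$p_S_given_N, 12 / 134)
  orc <- oracle_bayes(90, 11, 180, 132, k = 1)
  expect_equal(st$post_P, orc$post_P, tolerance = 1e-12)
  expect_equal(st$L, orc$L, tolerance = 1e-12)
  expect_equal(st$post_P, 0.8839, tolerance = 1e-4)
  expect_equal(st$L, 2.929, tolerance = 1e-3)
})

test_that("posteriors and L match the pseudo-observation oracle on random configs", {
  set.seed(21)
  for (r in 1:200) {
    N_P <- sample(2:60, 1); N_N <- sample(2:60, 1)
    k <- sample(1:3, 1)
    c_SP <- sample(0:N_P, 5, replace = TRUE)
    c_SN <- sample(0:N_N, 5, replace = TRUE)
    st <- smoothed_stats(list(c_SP = c_SP, c_SN = c_SN, N_P = N_P, N_N = N_N), k = k)
    orc <- oracle_bayes(c_SP, c_SN, N_P, N_N, k)
    expect_equal(st$post_P, orc$post_P, tolerance = 1e-12)
    expect_equal(st$L, orc$L, tolerance = 1e-12)
    expect_equal(st$post_P + st$post_N, rep(1, 5), tolerance = 1e-12)
    expect_equal(st$L, log2(st$post_P / st$post_N), tolerance = 1e-12)
  }
})

test_that("symmetric classes with equal counts give post_P = 0.5 and L = 0", {
  for (k in c(0.5, 1, 5)) {
    st <- smoothed_stats(list(c_SP = c(3, 7), c_SN = c(3, 7), N_P = 10, N_N = 10), k = k)
    expect_equal(st$post_P, rep(0.5, 2))
    expect_equal(st$L, rep(0, 2))
  }
})

test_that("L is monotone in the class counts", {
  base <- list(c_SN = 5, N_P = 40, N_N = 30)
  L_up <- vapply(0:40, function(c_SP)
    smoothed_stats(c(base, list(c_SP = c_SP)), k = 1)$L, 0)
  expect_true(all(diff(L_up) >= 0))
  L_dn <- vapply(0:30, function(c_SN)
    smoothed_stats(list(c_SP = 20, c_SN = c_SN, N_P = 40, N_N = 30), k = 1)$L, 0)
  expect_true(all(diff(L_dn) <= 0))
})

test_that("as k grows the posterior shrinks to the class prior", {
  cnt <- list(c_SP = 35, c_SN = 2, N_P = 40, N_N = 30)
  prior <- 40 / 70
  post <- vapply(c(1, 10, 1e3, 1e6), function(k) smoothed_stats(cnt, k)$post_P, 0)
  expect_true(all(diff(abs(post - prior)) < 0))
  expect_equal(post[4], prior, tolerance = 1e-4)
})

test_that("k = 0 with a class-degenerate bit is rejected, pointing to smoothing", {
  cnt <- list(c_SP = 0, c_SN = 3, N_P = 10, N_N = 10)
  expect_error(smoothed_stats(cnt, k = 0), "k > 0")
  expect_silent(smoothed_stats(cnt, k = 1))
  ok <- smoothed_stats(list(c_SP = 4, c_SN = 3, N_P = 10, N_N = 10), k = 0)
  expect_equal(ok$p_S_given_P, 0.4)
})

test_that("weight vector amplifies selected log-odds and leaves the rest at one", {
  st <- smoothed_stats(list(c_SP = c(10, 4, 0), c_SN = c(0, 3, 9),
                            N_P = 10, N_N = 10), k = 1)
  st$L <- c(3.0, 0.4, -1.0)  # direct rule check on stated scores
  wv <- build_weight_vector(st, theta = 2.5, n_mult = 15)
  expect_equal(unname(wv$w), c(45, 1, 1))
  expect_equal(wv$selected, 1L)

  expect_equal(unname(build_weight_vector(st, theta = Inf, n_mult = 15)$w),
               rep(1, 3))
  expect_error(build_weight_vector(st, theta = 0, n_mult = 15), "theta must be > 0")
  expect_error(build_weight_vector(st, theta = -1, n_mult = 15), "theta must be > 0")
  expect_error(build_weight_vector(st, theta = 2.5, n_mult = 0), "positive")
  # ties at theta are selected
  wv_tie <- build_weight_vector(st, theta = 3.0, n_mult = 2)
  expect_equal(wv_tie$selected, 1L)
  expect_equal(unname(wv_tie$w[1]), 6)
})

test_that("apply_weights is the element-wise product (loop oracle, identity case)", {
  expect_equal(unname(apply_weights(matrix(c(1, 0, 1), 1), c(45, 1, 9))[1, ]),
               c(45, 0, 9))
  set.seed(14)
  X <- matrix(rbinom(300, 1, 0.5), 30, 10)
  w <- runif(10, 0.5, 20)
  got <- apply_weights(X, w)
  want <- matrix(0, 30, 10)
  for (i in 1:30) for (j in 1:10) want[i, j] <- X[i, j] * w[j]
  expect_equal(unname(got), want, tolerance = 1e-12)
  expect_equal(unname(apply_weights(X, rep(1, 10))), X)
  expect_error(apply_weights(X, rep(1, 9)), "does not match")
})

test_that("weight tables round-trip through CSV + JSON export", {
  ds <- tiny_dataset(30, n_bits = 12, seed = 3)
  wv <- build_weight_vector(smoothed_stats(count_substructures(ds), k = 1),
                            theta = 0.5, n_mult = 10)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_weight_table(wv, csv)
  back <- read_weight_table(csv)
  expect_equal(back$w, unname(wv$w))
  expect_equal(back$selected, wv$selected)
  expect_equal(back$theta, wv$theta)
  expect_equal(back$n_mult, wv$n_mult)
})
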