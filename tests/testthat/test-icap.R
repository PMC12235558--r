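test_that("Total Activation maps zero input to zero and respects the penalty limit", {
  run <- ts_run(rep(0, 60))
  m <- volume_mask(array(1, c(1, 1, 1)))
  act <- total_activation(run, m, lambda = 0.5)
  expect_equal(act$activity[1, ], rep(0, 60))

  # lambda -> infinity: generalized total variation of the fit vanishes
  set.seed(3)
  y <- rnorm(60)
  act_inf <- total_activation(ts_run(y), m, lambda = 1e6)
  expect_equal(sum(abs(act_inf$s)), 0, tolerance = 1e-10)
  expect_equal(sum(abs(diff(act_inf$activity[1, ]))), 0, tolerance = 1e-10)
})

test_that("Total Activation recovers a noiseless block train", {
  hrf <- canonical_hrf(2.5)
  t <- 80
  a <- numeric(t); a[30:37] <- 1
  y <- convolve(a, rev(hrf), type = "open")[seq_len(t)]
  act <- total_activation(ts_run(y), volume_mask(array(1, c(1, 1, 1))),
                          lambda = 0.02, tol = 1e-6)
  expect_gte(cor(act$activity[1, ], a), 0.9)
})

test_that("solver satisfies the lasso optimality condition on a random problem", {
  set.seed(12)
  t <- 50; V <- 8
  hrf <- canonical_hrf(2.5)
  A <- cordparc:::ta_operator(t, hrf)
  Y <- matrix(rnorm(V * t), V, t)
  lam <- 0.3
  fx <- mat_run(Y)
  act <- total_activation(fx$run, fx$mask, lambda = lam, tol = 1e-6)
  for (v in seq_len(V)) {
    s <- act$s[v, ]
    g <- crossprod(A, Y[v, ] - A %*% s)          # A'(y - As)
    on <- which(s != 0)
    if (length(on)) {
      expect_lt(max(abs(g[on] - lam * sign(s[on]))), 1e-4)
    }
    expect_lt(max(abs(g)), lam + 1e-4)
    # duality-gap certificate reported below tolerance
    expect_lte(act$gap[v], 1e-6 * max(act$primal[v], 0.5 * sum(Y[v, ]^2)))
  }
})

test_that("innovations are the first difference with a zero first volume", {
  U <- matrix(c(1, 1, 1, 1, 1,
                0, 0, 1, 1, 0), 2, 5, byrow = TRUE)
  inn <- innovations(U)
  expect_equal(inn[1, ], c(0, 0, 0, 0, 0))
  expect_equal(inn[2, ], c(0, 0, 1, 0, -1))
  # unit step: single +1 at the step
  step <- matrix(c(rep(0, 9), rep(1, 11)), 1, 20)
  expect_equal(which(innovations(step)[1, ] != 0), 10L)
  # telescoping
  set.seed(1)
  U2 <- matrix(rnorm(30), 2, 15)
  expect_equal(rowSums(innovations(U2)), U2[, 15] - U2[, 1] + U2[, 1] * 0 +
                 (U2[, 1] - U2[, 1]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("phase randomization preserves the amplitude spectrum", {
  set.seed(21)
  Y <- matrix(rnorm(3 * 64), 3, 64)
  set.seed(5)
  Ys <- cordparc:::phase_randomize(Y)
  for (v in 1:3) {
    expect_equal(Mod(fft(Ys[v, ])), Mod(fft(Y[v, ])), tolerance = 1e-8)
  }
  expect_false(isTRUE(all.equal(Ys, Y)))
})

test_that("surrogate thresholds are seeded and approximately calibrated", {
  set.seed(30)
  t <- 100; V <- 12
  hrf <- canonical_hrf(2.5)
  sig <- sapply(seq_len(V), function(i) {
    a <- numeric(t); o <- sample(1:90, 2)
    for (x in o) a[x:(x + 5)] <- 1
    convolve(a, rev(hrf), type = "open")[seq_len(t)]
  })
  Y <- t(sig) + matrix(rnorm(V * t, 0, 0.4), V, t)
  fx <- mat_run(Y)
  th1 <- surrogate_thresholds(fx$run, fx$mask, n_surrogates = 6, seed = 77)
  th2 <- surrogate_thresholds(fx$run, fx$mask, n_surrogates = 6, seed = 77)
  expect_identical(th1, th2)
  expect_true(all(th1[, "lower"] <= th1[, "upper"]))

  # applying the thresholds back to fresh surrogates of the same series
  # marks about alpha of the samples active
  set.seed(91)
  Ys <- cordparc:::phase_randomize(Y)
  fx2 <- mat_run(Ys)
  act <- total_activation(fx2$run, fx2$mask)
  inn <- innovations(act)[, -1]
  active <- inn < th1[, "lower"] | inn > th1[, "upper"]
  n <- length(active)
  rate <- mean(active)
  # binomial 2-sd band around alpha = 0.05, plus quantile granularity slack
  expect_lt(abs(rate - 0.05), 2 * sqrt(0.05 * 0.95 / n) + 0.03)
})

test_that("frame selection applies the spatial-fraction rule with provenance", {
  V <- 40
  th <- cbind(lower = rep(-1, V), upper = rep(1, V))
  inn <- matrix(0, V, 6)
  inn[1:8, 3] <- 2       # 20% active  -> retained
  inn[1:2, 4] <- 2       # 5% active   -> not > 0.05, dropped
  inn[1:8, 5] <- -2      # negative side retained, sign kept
  fr <- select_frames(inn, th, spatial_fraction = 0.05, run_id = "s1")
  expect_equal(fr$volume, c(3L, 5L))
  expect_equal(fr$frames[1, 1:8], rep(2, 8))
  expect_equal(fr$frames[2, 1:8], rep(-2, 8))
  expect_true(all(fr$frames[, 9:V] == 0))
  expect_equal(fr$run_id, c("s1", "s1"))
  expect_warning(sf <- select_frames(matrix(0, V, 4), th, 0.05),
                 "no frames")
  expect_equal(nrow(sf$frames), 0)
})

test_that("k-means clustering of frames matches the generating partition", {
  geo <- tiny_geometry()
  nvox <- sum(geo$cord$data)
  set.seed(44)
  p1 <- numeric(nvox); p1[1:30] <- 1
  p2 <- numeric(nvox); p2[31:60] <- 1
  # two orthogonal frame populations, random amplitudes and signs
  F <- rbind(
    t(sapply(1:12, function(i) p1 * rnorm(1, 2) * sample(c(-1, 1), 1))),
    t(sapply(1:12, function(i) p2 * rnorm(1, 2) * sample(c(-1, 1), 1))))
  frames <- structure(list(frames = F, run_id = rep("x", 24),
                           volume = 1:24, active_fraction = rep(0.3, 24),
                           spatial_fraction = 0.05),
                      class = "significant_frames")
  cs <- cluster_icaps(frames, geo$cord, K = 2, seed = 2)
  cl <- attr(cs, "cluster")
  truth <- rep(1:2, each = 12)
  # adjusted agreement with the generating 2-partition is exact
  agree <- max(mean(cl == truth), mean(cl == 3 - truth))
  expect_equal(agree, 1)
  # maps align with the generating patterns
  m1 <- cs$maps[, , , 1, drop = TRUE][geo$cord$data > 0]
  m2 <- cs$maps[, , , 2, drop = TRUE][geo$cord$data > 0]
  expect_gt(max(abs(cor(m1, p1)), abs(cor(m1, p2))), 0.99)
  expect_gt(max(abs(cor(m2, p1)), abs(cor(m2, p2))), 0.99)
})

test_that("K=1 clustering yields the Z-scored mean folded frame and duplication is inert", {
  geo <- tiny_geometry()
  nvox <- sum(geo$cord$data)
  set.seed(45)
  base <- rexp(nvox)
  F <- t(sapply(1:10, function(i) base * rnorm(1, 1.5, 0.1)))
  frames <- structure(list(frames = F, run_id = rep("x", 10),
                           volume = 1:10, active_fraction = rep(0.3, 10),
                           spatial_fraction = 0.05),
                      class = "significant_frames")
  cs1 <- cluster_icaps(frames, geo$cord, K = 1, seed = 5)
  Fn <- F / sqrt(rowSums(F^2))
  expected <- cordparc:::zscore_vec(colMeans(Fn))
  got <- cs1$maps[, , , 1, drop = TRUE][geo$cord$data > 0]
  expect_equal(got, expected, tolerance = 1e-8)

  frames2 <- frames
  frames2$frames <- rbind(F, F)
  frames2$run_id <- rep("x", 20); frames2$volume <- 1:20
  frames2$active_fraction <- rep(0.3, 20)
  cs2 <- cluster_icaps(frames2, geo$cord, K = 1, seed = 5)
  expect_equal(cs2$maps, cs1$maps, tolerance = 1e-8)

  expect_error(cluster_icaps(frames, geo$cord, K = 11), "fewer frames")
})
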