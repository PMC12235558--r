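test_that("DVARS is zero for constant runs and closed-form for a single spike", {
  geo <- tiny_geometry()
  dims <- dim(geo$cord$data)
  arr <- array(1, c(dims, 10))
  run <- bold_run(arr, tr = 2.5)
  dv <- compute_dvars(run, geo$cord)
  expect_equal(dv$dvars, rep(0, 9))
  expect_length(dv$outliers, 0)

  # one volume shifted by +c at all in-mask voxels: entering and leaving
  # the spike each contribute a DVARS entry equal to c
  cshift <- 3.7
  arr2 <- arr
  idx <- which(geo$cord$data > 0)
  flat <- matrix(arr2, prod(dims), 10)
  flat[idx, 5] <- flat[idx, 5] + cshift
  run2 <- bold_run(array(flat, c(dims, 10)), tr = 2.5)
  dv2 <- compute_dvars(run2, geo$cord)
  expect_equal(dv2$dvars[4], cshift, tolerance = 1e-12)
  expect_equal(dv2$dvars[5], cshift, tolerance = 1e-12)
  expect_equal(dv2$dvars[-c(4, 5)], rep(0, 7))
  expect_true(all(c(5, 6) %in% dv2$outliers))
})

test_that("DVARS matches a naive per-pair RMS loop on random data", {
  geo <- tiny_geometry()
  dims <- dim(geo$cord$data)
  set.seed(4)
  arr <- array(rnorm(prod(dims) * 8), c(dims, 8))
  run <- bold_run(arr, tr = 2.5)
  dv <- compute_dvars(run, geo$cord)
  idx <- which(geo$cord$data > 0)
  oracle <- numeric(7)
  for (n in 1:7) {
    acc <- 0
    for (v in idx) {
      ijk <- arrayInd(v, dims)
      acc <- acc + (arr[ijk[1], ijk[2], ijk[3], n + 1] -
                      arr[ijk[1], ijk[2], ijk[3], n])^2
    }
    oracle[n] <- sqrt(acc / length(idx))
  }
  expect_equal(dv$dvars, oracle, tolerance = 1e-8)
})

test_that("CompCor recovers a planted rank-1 CSF process and returns orthonormal columns", {
  geo <- tiny_geometry()
  dims <- dim(geo$cord$data)
  ncsf <- sum(geo$csf$data)
  t <- 60
  set.seed(8)
  s <- sin(2 * pi * (1:t) / 7)
  w <- rnorm(ncsf)
  flat <- matrix(0, prod(dims), t)
  flat[geo$csf$data > 0, ] <- outer(w, s) + matrix(rnorm(ncsf * t, 0, 1e-3),
                                                   ncsf, t)
  run <- bold_run(array(flat, c(dims, t)), tr = 2.5)
  cc <- compcor_regressors(run, geo$csf, n = 5)
  expect_equal(ncol(cc), 5)
  expect_gte(abs(cor(cc[, 1], s)), 0.99)
  gram <- crossprod(cc)
  expect_equal(gram, diag(5), tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(compcor_regressors(run, geo$csf, n = t + 1), "exceeds")
})

test_that("RETROICOR expansion yields the configured column counts and phase values", {
  t <- 50
  set.seed(2)
  pc <- runif(t, 0, 2 * pi); pr <- runif(t, 0, 2 * pi)
  r <- retroicor_regressors(pc, pr)
  expect_equal(ncol(r), 18)  # 2*3 cardiac + 2*4 respiratory + 4 interaction

  pc0 <- pc; pc0[1] <- 0
  r11 <- retroicor_regressors(pc0, pr, c(cardiac = 1, respiratory = 1,
                                         interaction = 0))
  expect_equal(ncol(r11), 4)
  expect_equal(unname(r11[1, "retroicor_c1_cos"]), 1)
  expect_equal(unname(r11[1, "retroicor_c1_sin"]), 0)

  r0 <- retroicor_regressors(pc, pr, c(cardiac = 0, respiratory = 0,
                                       interaction = 0))
  expect_equal(ncol(r0), 0)
  expect_error(retroicor_regressors(pc, pr, c(cardiac = -1, respiratory = 0,
                                              interaction = 0)), "non-negative")
})

test_that("DCT basis is orthonormal with the expected low-frequency structure", {
  for (t in c(40, 91)) {
    B <- dct_basis(t, tr = 2, n = 5)
    # brute-force Gram matrix by direct summation
    gram <- matrix(0, 5, 5)
    for (i in 1:5) for (j in 1:5) gram[i, j] <- sum(B[, i] * B[, j])
    expect_equal(gram, diag(5), tolerance = 1e-10)
    # lowest cosine changes sign exactly once
    expect_equal(sum(diff(sign(B[, 1])) != 0), 1)
  }
  expect_error(dct_basis(5, 1, n = 5), "smaller than t")
})

test_that("cleaning residualizes against the full design and is idempotent", {
  geo <- tiny_geometry()
  sim <- small_cohort()$sim
  run <- sim$runs[[1]]
  cfg <- small_cohort()$cfg
  des <- default_design(run, geo$cord, geo$csf, sim$confounds[[1]], cfg)
  cleaned <- suppressWarnings(clean(run, geo$cord, des, 0.01))
  X <- cordparc:::mask_matrix(cleaned, geo$cord)
  # residuals orthogonal to every design column
  for (j in seq_len(ncol(des$matrix))) {
    cors <- abs(as.vector(X %*% des$matrix[, j])) /
      (sqrt(rowSums(X^2)) * sqrt(sum(des$matrix[, j]^2)))
    expect_lt(max(cors), 1e-8)
  }
  twice <- suppressWarnings(clean(cleaned, geo$cord, des, 0.01))
  expect_equal(twice$data, cleaned$data, tolerance = 1e-10)
  # energy never increases
  X0 <- cordparc:::mask_matrix(run, geo$cord)
  X0 <- X0 - rowMeans(X0)
  expect_true(all(rowSums(X^2) <= rowSums(X0^2) + 1e-8))
})

test_that("signals in the design null space survive cleaning", {
  geo <- tiny_geometry()
  dims <- dim(geo$cord$data)
  t <- 80
  set.seed(14)
  cc <- matrix(rnorm(t * 3), t, 3)
  des <- nuisance_design(compcor = cc, dct = dct_basis(t, 2.5, 3), t = t)
  sb <- cordparc:::highpass_stopband(t, 2.5, 0.01)
  aug <- cbind(sb, des$matrix)
  # construct a signal in the orthogonal complement of the augmented design
  s <- rnorm(t)
  s <- s - qr.fitted(qr(aug), s)   # qr handles the rank-deficient design
  s <- as.vector(s)
  nvox <- sum(geo$cord$data)
  flat <- matrix(0, prod(dims), t)
  flat[geo$cord$data > 0, ] <- outer(rnorm(nvox, 1, 0.1), s)
  run <- bold_run(array(flat, c(dims, t)), tr = 2.5)
  cleaned <- clean(run, geo$cord, des, 0.01)
  Xc <- cordparc:::mask_matrix(cleaned, geo$cord)
  cors <- apply(Xc, 1, cor, y = s)
  expect_true(all(cors >= 0.999))
})

test_that("cleaning is invariant to the order of nuisance families", {
  geo <- tiny_geometry()
  sim <- small_cohort()$sim
  run <- sim$runs[[2]]
  cfg <- small_cohort()$cfg
  t <- dim(run$data)[4]
  cc <- compcor_regressors(run, geo$csf, 3)
  ret <- retroicor_regressors(sim$confounds[[2]]$cardiac_phase,
                              sim$confounds[[2]]$resp_phase)
  d1 <- nuisance_design(compcor = cc, retroicor = ret, t = t)
  # same columns, families assembled in the opposite order
  d2 <- nuisance_design(retroicor = ret, compcor = cc, t = t)
  c1 <- suppressWarnings(clean(run, geo$cord, d1, 0.01))
  c2 <- suppressWarnings(clean(run, geo$cord, d2, 0.01))
  expect_equal(c1$data, c2$data, tolerance = 1e-10)
})

test_that("denoising improves recovery of the planted level signal", {
  # default run length and event rate: with sparser/shorter runs the
  # block trains carry substantial sub-0.01 Hz energy and the high-pass
  # itself costs more truth correlation than the confounds do
  geo <- tiny_geometry()
  sim <- simulate_cohort(n_subjects = 1, geometry = geo, t = 200,
                         event_rate = 8, seed = 33)
  run <- sim$runs[[1]]
  cfg <- pipeline_config(K = 3)
  des <- default_design(run, geo$cord, geo$csf, sim$confounds[[1]], cfg)
  cleaned <- suppressWarnings(clean(run, geo$cord, des, 0.01))
  hrf <- sim$truth$hrf
  lab <- sim$truth$subject_labels[[1]]
  tt <- dim(run$data)[4]
  cor_before <- cor_after <- numeric(0)
  for (l in 1:3) {
    expected <- convolve(sim$truth$activity[[1]][l, ], rev(hrf),
                         type = "open")[seq_len(tt)]
    vox <- which(lab == l)
    flat0 <- matrix(run$data, prod(dim(lab)), tt)
    flat1 <- matrix(cleaned$data, prod(dim(lab)), tt)
    cor_before <- c(cor_before, apply(flat0[vox, ], 1, cor, y = expected))
    cor_after <- c(cor_after, apply(flat1[vox, ], 1, cor, y = expected))
  }
  expect_gt(mean(cor_after), mean(cor_before))
})
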