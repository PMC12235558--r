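test_that("Z>1.6 thresholding retains the upper tail of a Gaussian map", {
  set.seed(10)
  dims <- c(50, 50, 40)
  mask <- volume_mask(array(1, dims))
  m <- array(rnorm(prod(dims)), dims)
  m <- array(cordparc:::zscore_vec(as.vector(m)), dims)
  b <- threshold_binarize(m, mask, z = 1.6)
  frac <- sum(b$data) / prod(dims)
  expect_gt(frac, 0.04); expect_lt(frac, 0.07)
  # z = +inf empties the map; alternative thresholds accepted
  expect_equal(sum(threshold_binarize(m, mask, z = Inf)$data), 0)
  for (z in c(2, 2.3)) {
    bz <- threshold_binarize(m, mask, z = z)
    expect_lt(sum(bz$data), sum(b$data))
    expect_equal(bz$z_threshold, z)
  }
  expect_error(threshold_binarize(array(0, dims), mask), "zero-variance")
})

test_that("Dice follows its set formula and marks double-empty as undefined", {
  dims <- c(4, 4, 4)
  mk <- function(idx) {
    a <- array(0L, dims); a[idx] <- 1L
    structure(list(data = a, z_threshold = 1.6, source = NULL),
              class = "binary_map")
  }
  a <- mk(1:4); b <- mk(3:6)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(mk(1:4), mk(5:8)), 0)
  expect_equal(dice(a, b), 0.5)            # |A|=4, |B|=4, |A^B|=2
  expect_equal(dice(a, b), dice(b, a))
  expect_warning(dna <- dice(mk(NULL), mk(NULL)), "undefined")
  expect_true(is.na(dna))
})

test_that("cosine similarity equals the brute-force inner-product oracle", {
  dims <- c(5, 5, 6)
  mask <- volume_mask(array(rbinom(prod(dims), 1, 0.6), dims))
  set.seed(11)
  a <- array(rnorm(prod(dims)), dims); a[mask$data == 0] <- 0
  b <- array(rnorm(prod(dims)), dims); b[mask$data == 0] <- 0
  got <- cosine_similarity(a, b, mask)
  num <- 0; na <- 0; nb <- 0
  for (i in which(mask$data > 0)) {
    num <- num + a[i] * b[i]; na <- na + a[i]^2; nb <- nb + b[i]^2
  }
  expect_equal(got, num / sqrt(na * nb), tolerance = 1e-10)
  expect_equal(cosine_similarity(a, a, mask), 1, tolerance = 1e-10)
  expect_equal(cosine_similarity(a, -a, mask), -1, tolerance = 1e-10)
})

test_that("maximum-weight matching agrees with exhaustive search", {
  w <- matrix(1, 3, 3); diag(w) <- 5
  m <- match_components(w)
  expect_equal(m$pairs$b, 1:3)
  set.seed(12)
  for (i in 1:5) {
    w4 <- matrix(runif(16), 4, 4)
    expect_equal(match_components(w4)$total_weight, brute_force_match(w4),
                 tolerance = 1e-8)
  }
  w7 <- matrix(runif(49), 7, 7)
  m7 <- match_components(w7)
  expect_equal(m7$total_weight, brute_force_match(w7), tolerance = 1e-8)
  # matching beats the identity assignment
  expect_gte(m7$total_weight, sum(diag(w7)))

  # rectangular: 5 components against 9 levels -> 5 pairs
  w59 <- matrix(runif(45), 5, 9)
  m59 <- match_components(w59)
  expect_equal(nrow(m59$pairs), 5)
  expect_equal(m59$total_weight, brute_force_match(w59), tolerance = 1e-8)
  expect_length(m59$unmatched_b, 4)
})

test_that("level overlap percentages partition the component's voxels", {
  geo <- tiny_geometry()
  atlas <- geo$atlas
  in3 <- which(atlas$labels == 3)
  mk <- function(idx) {
    a <- array(0L, dim(atlas$labels)); a[idx] <- 1L
    structure(list(data = a, z_threshold = 1.6, source = NULL),
              class = "binary_map")
  }
  ov <- level_overlap(mk(in3[1:10]), atlas)
  expect_equal(unname(ov["level_3"]), 100)
  expect_equal(sum(ov), 100)
  ov2 <- level_overlap(mk(c(which(atlas$labels == 2)[1:5],
                            which(atlas$labels == 3)[1:5])), atlas)
  expect_equal(unname(ov2[c("level_2", "level_3")]), c(50, 50))
  expect_error(level_overlap(mk(integer(0)), atlas), "empty map")
})

test_that("z center of mass uses 0-based slices scaled by voxel size", {
  dims <- c(3, 3, 10)
  mk <- function(idx) {
    a <- array(0L, dims); a[idx] <- 1L
    structure(list(data = a, z_threshold = 1.6, source = NULL),
              class = "binary_map")
  }
  one <- array(0L, dims); one[2, 2, 8] <- 1L   # slice 7, 0-based
  expect_equal(center_of_mass_z(one, voxel_size_z = 3), 21)
  two <- array(0L, dims); two[2, 2, 5] <- 1L; two[2, 2, 7] <- 1L
  expect_equal(center_of_mass_z(two, voxel_size_z = 3), 15)
  # largest-cluster restriction
  big <- array(0L, dims)
  big[1:2, 1:2, 1:3] <- 1L              # 12-voxel cluster near z=0..2
  big[3, 3, 9:10] <- 1L                 # 2-voxel cluster near the top
  com_all <- center_of_mass_z(big, 1)
  com_big <- center_of_mass_z(big, 1, largest_cluster_only = TRUE)
  expect_lt(com_big, com_all)
  expect_equal(com_big, 1)
  expect_equal(com_distance(one, two, voxel_size_z = 3), 6)
  expect_error(center_of_mass_z(array(0, dims)), "empty map")
})

test_that("26-connectivity clustering separates diagonal-touching from distant blobs", {
  dims <- c(4, 4, 4)
  b <- array(FALSE, dims)
  b[1, 1, 1] <- TRUE; b[2, 2, 2] <- TRUE   # touch diagonally: one cluster
  b[4, 4, 4] <- TRUE                       # separate
  lab <- cordparc:::label_clusters_26(b)
  expect_equal(lab[1, 1, 1], lab[2, 2, 2])
  expect_false(lab[4, 4, 4] == lab[1, 1, 1])
  expect_equal(max(lab), 2)
})

test_that("individual heatmaps sum sorted binarized maps across subjects", {
  prep <- small_prepared()
  sets <- extract_components(prep, "icap", K = 3, scope = "subject", seed = 4)
  h1 <- individual_heatmap(sets[1], z = 1.6)
  b1 <- cordparc:::binarize_components(sets[[1]], 1.6)
  expect_equal(sum(h1), sum(sapply(b1, function(b) sum(b$data))))
  hn <- individual_heatmap(sets, z = 1.6)
  expect_true(all(hn <= length(sets)))
  # identical subjects: heatmap max equals the subject count
  hd <- individual_heatmap(list(sets[[1]], sets[[1]], sets[[1]]), z = 1.6)
  expect_equal(max(hd), 3)
})

test_that("FDR adjustment reproduces the Benjamini-Hochberg step-up rule", {
  # hand-derived: p_(i) * n / i, monotonized from the largest rank down
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(fdr_adjust(0.03), 0.03)
  p <- c(0.005, 0.049, 0.05, 0.2)
  expect_equal(fdr_adjust(p), c(0.02, 0.0666666666666667, 0.0666666666666667, 0.2),
               tolerance = 1e-10)
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})
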