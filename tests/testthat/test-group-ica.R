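# Sparse, heavy-tailed spatial sources for unmixing checks.
make_sources <- function(C, V, seed) {
  set.seed(seed)
  S <- matrix(0, C, V)
  for (i in seq_len(C)) {
    idx <- ((i - 1) * floor(V / C) + 1):(i * floor(V / C))
    S[i, idx] <- rexp(length(idx)) * sample(c(-1, 1), length(idx), TRUE)
  }
  S + matrix(rnorm(C * V, sd = 0.01), C, V)
}

test_that("subject reduction is lossless at full rank", {
  set.seed(201)
  A <- matrix(rnorm(40 * 5), 40, 5)
  S <- matrix(rnorm(5 * 120), 5, 120)
  x <- A %*% S                       # exact rank 5
  red <- subject_reduce(x, 5)
  recon <- red$operator %*% red$reduced
  expect_lt(norm(recon - x, "F") / norm(x, "F"), 1e-8)
  expect_equal(red$explained_variance, 1, tolerance = 1e-12)
})

test_that("explained variance matches the eigenvalue oracle", {
  set.seed(202)
  x <- matrix(rnorm(60 * 200), 60, 200)
  red <- subject_reduce(x, 20)
  ev <- eigen(tcrossprod(x), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(red$explained_variance, sum(ev[1:20]) / sum(ev),
               tolerance = 1e-10)
  # two perfectly correlated voxels: one component explains everything
  v <- rnorm(50)
  red1 <- subject_reduce(cbind(v, 2 * v), 1)
  expect_equal(red1$explained_variance, 1, tolerance = 1e-12)
  expect_error(subject_reduce(x %*% t(x) %*% x, 61), "n_pc")
})

test_that("rank-deficient input below n_pc is reported", {
  A <- matrix(rnorm(30 * 3), 30, 3)
  x <- A %*% matrix(rnorm(3 * 90), 3, 90)   # rank 3
  expect_error(subject_reduce(x, 5), "rank")
})

test_that("fixed-point ICA recovers planted sparse sources", {
  V <- 600
  S <- make_sources(3, V, seed = 203)
  set.seed(204)
  mixes <- lapply(1:2, function(i) matrix(rnorm(20 * 3), 20, 3) %*% S)
  reduced <- lapply(mixes, subject_reduce, n_pc = 3)
  fit <- group_ica_estimate(reduced, 3, seed = 1)
  R <- abs(cor(t(fit$maps), t(S)))
  # each true source matched by exactly one estimate with |r| > 0.95
  expect_true(all(apply(R, 2, max) > 0.95))
  expect_equal(sort(apply(R, 2, which.max)), 1:3)
  # sign convention: max-abs voxel positive
  for (i in 1:3) {
    m <- fit$maps[i, ]
    expect_gt(m[which.max(abs(m))], 0)
  }
})

test_that("single-source estimation is near-exact and seed-stable", {
  V <- 400
  S <- make_sources(1, V, seed = 205)
  set.seed(206)
  x <- matrix(rnorm(15), 15, 1) %*% S
  red <- subject_reduce(x, 1)
  fit <- group_ica_estimate(list(red), 1, seed = 3)
  expect_gt(abs(cor(fit$maps[1, ], S[1, ])), 0.99)
  fit2 <- group_ica_estimate(list(red), 1, seed = 3)
  expect_identical(fit$maps, fit2$maps)
})

test_that("back-reconstruction returns the mixing time courses for one subject", {
  V <- 500
  S <- make_sources(3, V, seed = 207)
  S <- S - rowMeans(S)
  set.seed(208)
  A <- matrix(rnorm(40 * 3), 40, 3)
  x <- A %*% S
  red <- subject_reduce(x, 3)
  fit <- group_ica_estimate(list(red), 3, seed = 2)
  bk <- back_reconstruct(list(red), fit)[[1]]
  expect_equal(dim(bk$timecourses), c(40, 3))
  # the reconstructed time courses span the planted mixing: each planted
  # column is reproduced by its matched estimated column up to scale
  R <- abs(cor(bk$timecourses, A))
  expect_true(all(apply(R, 2, max) > 0.99))
})

test_that("planted subject gains are recovered within 5 percent", {
  V <- 500
  S <- make_sources(3, V, seed = 209)
  S <- S - rowMeans(S)
  set.seed(210)
  A <- matrix(rnorm(30 * 3), 30, 3)
  gains <- c(1, 2.4)
  mixes <- lapply(gains, function(g) g * (A %*% S))
  reduced <- lapply(mixes, subject_reduce, n_pc = 3)
  fit <- group_ica_estimate(reduced, 3, seed = 4)
  bks <- back_reconstruct(reduced, fit)
  ratio <- norm(bks[[2]]$timecourses, "F") / norm(bks[[1]]$timecourses, "F")
  expect_equal(ratio, 2.4, tolerance = 0.05 * 2.4)
})

test_that("near-constant reconstructed components are flagged", {
  V <- 300
  S <- make_sources(2, V, seed = 211)
  set.seed(212)
  x <- cbind(rnorm(20), rnorm(20) * 1e-6) %*% S   # second source ~absent
  red <- subject_reduce(x, 2)
  fit <- group_ica_estimate(list(red), 2, seed = 5)
  bk <- back_reconstruct(list(red), fit)[[1]]
  sds <- apply(bk$timecourses, 2, sd)
  expect_true(any(sds < 1e-6 * max(sds)) == (length(bk$flagged_components) > 0))
})

test_that("template labeling assigns by absolute correlation with floor", {
  V <- 200
  set.seed(213)
  templates <- make_sources(3, V, seed = 214)
  rownames(templates) <- c("DMN", "SMN", "VN")
  maps <- rbind(templates["DMN", ],            # identical -> r = 1
                -templates["SMN", ],           # sign-flipped
                rnorm(V))                      # unrelated -> unassigned
  rownames(maps) <- c("IC01", "IC02", "IC03")
  lab <- label_components(maps, templates, floor_r = 0.2)
  expect_equal(lab$network[1], "DMN")
  expect_equal(lab$correlation[1], 1, tolerance = 1e-12)
  expect_equal(lab$network[2], "SMN")
  expect_lt(lab$correlation[2], 0)             # sign recorded
  expect_equal(lab$network[3], "unassigned")
  expect_error(label_components(maps, templates[, 1:100]), "voxel grid")
})

test_that("synthetic maps built on the study grouping give 2/2/2/3/1 counts", {
  V <- 500
  nets <- c("SMN", "DAN", "VN", "DMN", "VAN")
  templates <- make_sources(5, V, seed = 215)
  rownames(templates) <- nets
  assignment <- default_networks()
  maps <- templates[unname(assignment), ] +
    matrix(rnorm(10 * V, sd = 0.1), 10, V)
  rownames(maps) <- names(assignment)
  lab <- label_components(maps, templates)
  counts <- table(factor(lab$network, levels = nets))
  expect_equal(unname(c(counts)), c(2, 2, 2, 3, 1))
  # deterministic given maps and templates
  expect_identical(lab, label_components(maps, templates))
})

test_that("NIfTI volumes load as time-by-voxel matrices", {
  skip_if_not_installed("RNifti")
  dims <- c(4, 4, 3, 6)
  set.seed(216)
  arr <- array(rnorm(prod(dims)), dims)
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  got <- read_nifti_timeseries(path)
  expect_equal(got$dim, dims[1:3])
  expect_equal(dim(got$data), c(6, 48))
  expect_equal(got$data[3, ], as.vector(arr[, , , 3]), tolerance = 1e-6)
  unlink(path)
})
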