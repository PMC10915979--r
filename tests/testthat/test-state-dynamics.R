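test_that("k = 1 clustering returns the grand mean as centroid", {
  arrays <- lapply(1:3, function(i) toy_windows(5, 4, seed = i))
  stack <- toy_stack(arrays)
  model <- cluster_states(stack, k = 1, n_replicates = 5, seed = 1)
  expect_true(all(model$labels$state == 1))
  sm <- dynfnc:::.stack_to_matrix(stack)
  grand <- colMeans(sm$X)
  expect_equal(model$centroids[1, , ][upper.tri(diag(4))], unname(grand),
               tolerance = 1e-8)
})

test_that("clustering is deterministic given a seed and relabels by occurrence", {
  arrays <- lapply(1:4, function(i) toy_windows(12, 5, seed = 10 + i))
  stack <- toy_stack(arrays)
  m1 <- cluster_states(stack, k = 3, n_replicates = 20, seed = 7)
  m2 <- cluster_states(stack, k = 3, n_replicates = 20, seed = 7)
  expect_identical(m1$labels, m2$labels)
  expect_identical(m1$inertia, m2$inertia)
  occ <- tabulate(m1$labels$state, 3)
  expect_true(all(diff(occ) <= 0))        # states sorted by occurrence
  # centroids equal the mean of their members
  sm <- dynfnc:::.stack_to_matrix(stack)
  for (s in 1:3) {
    mem <- colMeans(sm$X[m1$labels$state == s, , drop = FALSE])
    expect_equal(m1$centroids[s, , ][upper.tri(diag(5))], unname(mem),
                 tolerance = 1e-8)
  }
})

test_that("best-of-replicates inertia is no worse than single restarts", {
  arrays <- lapply(1:3, function(i) toy_windows(15, 5, seed = 20 + i))
  stack <- toy_stack(arrays)
  multi <- cluster_states(stack, k = 4, n_replicates = 25, seed = 3)
  singles <- vapply(1:5, function(s) {
    cluster_states(stack, k = 4, n_replicates = 1, seed = 100 + s)$inertia
  }, numeric(1))
  expect_true(all(multi$inertia <= singles + 1e-8))
})

test_that("k exceeding the number of windows is rejected", {
  stack <- toy_stack(list(toy_windows(3, 4, seed = 1)))
  expect_error(cluster_states(stack, k = 10, n_replicates = 2, seed = 1),
               "exceeds")
})

test_that("fraction time counts windows per state", {
  expect_equal(fraction_time(c(4, 4, 4, 4), 4), c(0, 0, 0, 1))
  expect_equal(fraction_time(c(1, 1, 2, 2, 2, 1), 2), c(0.5, 0.5))
  set.seed(5)
  for (i in 1:20) {
    lab <- sample.int(4, sample(5:50, 1), replace = TRUE)
    expect_equal(sum(fraction_time(lab, 4)), 1)
  }
  expect_error(fraction_time(c(1, 5), 4), "out of range")
})

test_that("mean dwell time averages maximal runs", {
  d <- mean_dwell_time(c(4, 4, 4, 1, 4, 4), 4)
  expect_equal(d[4], 2.5)     # runs of 3 and 2
  expect_equal(d[1], 1)
  expect_equal(d[2], 0)       # unvisited
  expect_equal(mean_dwell_time(rep(2, 9), 3), c(0, 9, 0))
  # run-length conservation: sum over states of dwell * runs = n
  set.seed(6)
  for (i in 1:20) {
    lab <- sample.int(3, sample(5:60, 1), replace = TRUE)
    r <- rle(lab)
    runs <- tabulate(r$values, 3)
    expect_equal(sum(mean_dwell_time(lab, 3) * runs), length(lab))
  }
})

test_that("transition count equals runs minus one", {
  expect_equal(n_transitions(rep(3, 12)), 0)
  expect_equal(n_transitions(c(4, 4, 4, 1, 4, 4)), 2)
  set.seed(7)
  for (i in 1:20) {
    lab <- sample.int(4, sample(2:80, 1), replace = TRUE)
    expect_equal(n_transitions(lab), length(rle(lab)$lengths) - 1)
  }
  expect_error(n_transitions(integer(0)), "empty")
})

test_that("state_metrics ties per-subject labels to tidy metrics", {
  arrays <- list(toy_windows(6, 4, seed = 1), toy_windows(6, 4, seed = 2))
  stack <- toy_stack(arrays)
  model <- cluster_states(stack, k = 2, n_replicates = 10, seed = 2)
  met <- state_metrics(model)
  expect_equal(nrow(met), 2 * 2)
  for (sid in unique(met$subject_id)) {
    sub <- met[met$subject_id == sid, ]
    expect_equal(sum(sub$fraction_time), 1, tolerance = 1e-12)
    lab <- model$labels$state[model$labels$subject_id == sid]
    expect_equal(unique(sub$n_transitions), n_transitions(lab))
    expect_equal(sub$fraction_time, fraction_time(lab, 2))
    expect_equal(sub$mean_dwell_time, mean_dwell_time(lab, 2))
    # windows-per-state counts are integers
    expect_equal(sub$fraction_time * length(lab),
                 round(sub$fraction_time * length(lab)))
  }
})

test_that("group centroids are hand-verifiable means with occurrence counts", {
  a1 <- toy_windows(4, 3, seed = 1)
  a2 <- toy_windows(4, 3, seed = 2)
  stack <- toy_stack(list(a1, a2), groups = c("patient", "control"))
  model <- cluster_states(stack, k = 2, n_replicates = 10, seed = 4)
  gsc <- group_state_centroids(stack, model)
  expect_equal(nrow(gsc), 4)
  expect_true(all(gsc$n_subjects <= 1))
  lab <- model$labels
  for (i in seq_len(nrow(gsc))) {
    g <- gsc$group[i]; s <- gsc$state[i]
    sid <- stack$subject_id[stack$group == g]
    rows <- lab$subject_id == sid & lab$state == s
    if (!any(rows)) {
      expect_equal(gsc$n_subjects[i], 0L)
      expect_true(all(is.na(gsc$centroid[[i]])))
    } else {
      a <- if (g == "patient") a1 else a2
      manual <- apply(a[lab$window[rows], , , drop = FALSE], c(2, 3), mean)
      got <- gsc$centroid[[i]]
      expect_equal(got[upper.tri(got)], manual[upper.tri(manual)],
                   tolerance = 1e-10)
    }
  }
})

test_that("elbow selection warns on flat curves and needs 3 candidates", {
  # single-state data: all windows from one regime, no cluster structure
  arrays <- lapply(1:3, function(i) toy_windows(30, 4, seed = 40 + i))
  stack <- toy_stack(arrays)
  expect_error(select_k_elbow(stack, k_candidates = c(2, 3)), "3 candidate")
  expect_warning(
    sel <- select_k_elbow(stack, 2:6, n_replicates = 5, seed = 1, tol = 0.9),
    "flat"
  )
  expect_equal(sel$k, 2L)
  expect_named(sel$curve, c("k", "index", "curvature", "chord_distance"))
})

test_that("validity index decreases in k on structured data", {
  design <- cohort_design(n_patients = 3, n_controls = 3,
                          n_timepoints = 120, seed = 15)
  cohort <- simulate_cohort(design)
  stack <- dfnc(cohort$subjects, lambda = 0.01, seed = 15)
  sel <- select_k_elbow(stack, 2:6, n_replicates = 20, seed = 15)
  expect_true(all(diff(sel$curve$index) < 0))
})

test_that("model tidiers expose labels and fit summaries", {
  arrays <- lapply(1:2, function(i) toy_windows(5, 4, seed = 50 + i))
  stack <- toy_stack(arrays)
  model <- cluster_states(stack, k = 2, n_replicates = 5, seed = 6)
  lab <- tidy(model)
  expect_named(lab, c("subject_id", "window", "state"))
  gl <- glance(model)
  expect_equal(gl$k, 2)
  expect_equal(gl$n_windows, 10)
  expect_output(print(model), "state_model")
})
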