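# Validation experiments on the synthetic generator: these re-run the full
# estimation pipeline against planted ground truth and are the package's own
# evidence that states, their dwell structure and the model order are
# recoverable.

#' Taper-weighted dominant true state per window
#'
#' Windows mix time points from several hidden states; the window's dominant
#' state is the one carrying the most taper weight (ties break to the lower
#' state id).
#'
#' @param true_states Length-T integer state sequence.
#' @param starts 0-based window starts.
#' @param taper A [build_taper()] object.
#' @param k Number of states.
#' @return Integer vector, one dominant state per window.
#' @export
window_dominant_states <- function(true_states, starts, taper, k) {
  w <- taper$weights
  W <- taper$window_length
  vapply(starts, function(s) {
    seg <- true_states[(s + 1):(s + W)]
    mass <- vapply(seq_len(k), function(st) sum(w[seg == st]), numeric(1))
    which.max(mass)
  }, integer(1))
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Equal-length integer label vectors.
#' @return The adjusted Rand index.
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) abort("label vectors must be equal length")
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (nij - expected) / (maxi - expected)
}

# Match estimated centroids to the planted states by enumerating all
# assignments of planted states onto estimated ones (k small), maximising
# the summed correlation of upper-triangle vectors.
.match_states <- function(centroids, planted_z) {
  k <- dim(centroids)[1]
  C <- dim(centroids)[2]
  ut <- upper.tri(matrix(0, C, C))
  est <- t(vapply(seq_len(k), function(s) centroids[s, , ][ut],
                  numeric(sum(ut))))
  pla <- t(vapply(seq_along(planted_z), function(s) planted_z[[s]][ut],
                  numeric(sum(ut))))
  R <- cor(t(est), t(pla))                      # est x planted
  perms <- .permutations(k)
  scores <- apply(perms, 1, function(p) sum(R[cbind(p, seq_len(k))]))
  best <- perms[which.max(scores), ]
  # best[j] = estimated state matched to planted state j
  setNames(best, seq_len(k))
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- .permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Shared simulate -> dFNC -> residualise path for the experiments.
.simulated_stack <- function(n_patients, n_controls, seed, lambda,
                             design_fun = cohort_design) {
  design <- design_fun(n_patients = n_patients, n_controls = n_controls,
                       seed = seed)
  cohort <- simulate_cohort(design)
  stack <- dfnc(cohort$subjects, lambda = lambda, seed = seed)
  stack <- residualize_stack(stack, c("age", "gender"))
  list(design = design, cohort = cohort, stack = stack)
}

#' Elbow model-order recovery experiment
#'
#' Repeatedly simulates a cohort with four planted connectivity states,
#' runs the windowed connectivity pipeline and the elbow criterion over a
#' candidate range, and records the chosen k per seed.
#'
#' @param n_seeds Number of simulation seeds.
#' @param n_patients,n_controls Cohort sizes per seed.
#' @param k_candidates Candidate model orders.
#' @param n_replicates k-means restarts per candidate.
#' @param lambda Graphical-lasso penalty for the windowed fits.
#' @param seed Base seed; seed `i` of the experiment uses `seed + i`.
#' @return Tibble: seed, chosen_k, n_windows; the per-seed index curves as
#'   attribute `"curves"`.
#' @export
run_elbow_recovery <- function(n_seeds = 20, n_patients = 10, n_controls = 10,
                               k_candidates = 2:8, n_replicates = 100,
                               lambda = 0.01, seed = 1) {
  rows <- vector("list", n_seeds)
  curves <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    sim <- .simulated_stack(n_patients, n_controls, seed + i, lambda)
    sel <- select_k_elbow(sim$stack, k_candidates,
                          n_replicates = n_replicates, seed = seed + i)
    n_windows <- sum(vapply(sim$stack$z, function(a) dim(a)[1], numeric(1)))
    rows[[i]] <- tibble(seed = seed + i, chosen_k = sel$k,
                        n_windows = n_windows)
    curves[[i]] <- sel$curve %>% mutate(seed = seed + i)
  }
  out <- bind_rows(rows)
  attr(out, "curves") <- bind_rows(curves)
  out
}

#' Planted-state and dwell-bias recovery experiment
#'
#' Per seed: simulate a cohort whose patients dwell longer in the designated
#' abnormality state, estimate windowed connectivity, cluster at the true k,
#' match estimated states to the planted ones by centroid correlation, and
#' record (a) the adjusted Rand index between window labels and the
#' taper-dominant true states and (b) whether the patient-minus-control
#' difference in mean dwell time of the biased state has the planted
#' (positive) sign.
#'
#' @param n_seeds Number of seeds.
#' @param n_patients,n_controls Cohort sizes.
#' @param k True/assumed number of states.
#' @param n_replicates k-means restarts.
#' @param lambda Graphical-lasso penalty.
#' @param seed Base seed.
#' @return Tibble: seed, ari, dwell_diff (patient - control, windows),
#'   sign_correct.
#' @export
run_dwell_recovery <- function(n_seeds = 50, n_patients = 33, n_controls = 23,
                               k = 4, n_replicates = 10, lambda = 0.01,
                               seed = 1) {
  rows <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    sim <- .simulated_stack(n_patients, n_controls, seed + i, lambda)
    model <- cluster_states(sim$stack, k = k, n_replicates = n_replicates,
                            seed = seed + i)
    taper <- build_taper(attr(sim$stack, "window_length"),
                         attr(sim$stack, "sigma"))
    truth <- unlist(lapply(seq_len(nrow(sim$cohort$subjects)), function(j) {
      window_dominant_states(sim$cohort$subjects$true_states[[j]],
                             sim$stack$window_starts[[j]], taper, k)
    }))
    ari <- adjusted_rand(model$labels$state, truth)
    planted_z <- lapply(sim$design$states, function(s) {
      z <- fisher_z(s$covariance * (1 - diag(nrow(s$covariance))))
      z
    })
    match <- .match_states(model$centroids, planted_z)
    biased <- length(sim$design$states)      # abnormality state = last
    est_biased <- match[[biased]]
    metrics <- state_metrics(model) %>% filter(.data$state == est_biased)
    diff <- mean(metrics$mean_dwell_time[metrics$group == "patient"]) -
      mean(metrics$mean_dwell_time[metrics$group == "control"])
    rows[[i]] <- tibble(seed = seed + i, ari = ari, dwell_diff = diff,
                        sign_correct = diff > 0)
  }
  bind_rows(rows)
}

#' Type-I error calibration of the two-sample t-test
#'
#' Simulates `n_features` null features (both groups from the same normal)
#' and reports the rejection rate at `alpha`.
#'
#' @param n_features Number of simulated features.
#' @param n_per_group Observations per group.
#' @param alpha Nominal level.
#' @param seed Integer seed.
#' @return Tibble: n_features, alpha, rejection_rate.
#' @export
calibrate_type1 <- function(n_features = 5000, n_per_group = 30,
                            alpha = 0.05, seed = 1) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  p <- vapply(seq_len(n_features), function(i) {
    two_sample_t(rnorm(n_per_group), rnorm(n_per_group))$p_value
  }, numeric(1))
  tibble(n_features = n_features, alpha = alpha,
         rejection_rate = mean(p < alpha))
}

#' Empirical FDR of the BH procedure on a known mixture
#'
#' Simulates features of which a fraction carry a true group difference,
#' applies [two_sample_t()] + [bh_fdr()], and reports the realised false
#' discovery proportion at `q_threshold`, averaged over replicates.
#'
#' @param n_features Features per replicate.
#' @param frac_nonnull Fraction of features with a true effect.
#' @param effect_size Mean shift of non-null features (SD units).
#' @param n_per_group Observations per group.
#' @param n_replicates Number of replicates.
#' @param q_threshold Discovery threshold on q-values.
#' @param seed Integer seed.
#' @return Tibble: replicate, n_discoveries, n_false, fdp; mean FDR as
#'   attribute `"mean_fdr"`.
#' @export
calibrate_fdr <- function(n_features = 500, frac_nonnull = 0.2,
                          effect_size = 1.5, n_per_group = 30,
                          n_replicates = 20, q_threshold = 0.05, seed = 1) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    nonnull <- seq_len(n_features) <= round(frac_nonnull * n_features)
    p <- vapply(seq_len(n_features), function(i) {
      shift <- if (nonnull[i]) effect_size else 0
      two_sample_t(rnorm(n_per_group, shift), rnorm(n_per_group))$p_value
    }, numeric(1))
    q <- bh_fdr(p)
    disc <- q < q_threshold
    rows[[r]] <- tibble(replicate = r, n_discoveries = sum(disc),
                        n_false = sum(disc & !nonnull),
                        fdp = if (sum(disc) == 0) 0
                              else sum(disc & !nonnull) / sum(disc))
  }
  out <- bind_rows(rows)
  attr(out, "mean_fdr") <- mean(out$fdp)
  out
}
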