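#' Default component-to-network assignment
#'
#' Ten independent components grouped into the five canonical large-scale
#' networks populated in this analysis: somatomotor (SMN, 2 ICs), dorsal
#' attention (DAN, 2), visual (VN, 2), default mode (DMN, 3) and ventral
#' attention (VAN, 1).
#'
#' @return Named character vector mapping component id (`IC01`..`IC10`) to
#'   network name.
#' @export
default_networks <- function() {
  setNames(
    c("SMN", "SMN", "DAN", "DAN", "VN", "VN", "DMN", "DMN", "DMN", "VAN"),
    sprintf("IC%02d", 1:10)
  )
}

#' Construct planted connectivity-state covariances
#'
#' Builds `k` distinct symmetric positive-definite correlation matrices over
#' `n_components` components, structured in within-network blocks. The first
#' state is deliberately sparse/weak (off-diagonals near zero); later states
#' carry increasingly strong within-network coupling, a globally integrated
#' pattern, and a distinct "abnormality" pattern with anti-correlated
#' DMN/DAN blocks. A small seeded jitter makes matrices differ across seeds
#' while remaining reproducible.
#'
#' @param n_components Number of components C (>= 2).
#' @param k Number of states (>= 1).
#' @param block_structure Named character vector mapping component id to
#'   network, as [default_networks()]. Length must equal `n_components`.
#' @param seed Integer seed for the jitter.
#' @param jitter_sd Half-width of the uniform off-diagonal jitter.
#' @return List of `k` state specifications, each with `state_id`,
#'   `covariance` (C x C correlation-form SPD matrix) and `label`.
#' @export
make_state_covariances <- function(n_components = 10, k = 4,
                                   block_structure = default_networks(),
                                   seed = 1, jitter_sd = 0.03) {
  if (n_components < 2) abort("n_components must be >= 2")
  if (k < 1) abort("k must be >= 1")
  if (length(block_structure) != n_components) {
    abort("block_structure must name every component")
  }
  networks <- unname(block_structure)
  same_net <- outer(networks, networks, "==")
  block <- function(a, b) {
    m <- outer(networks == a, networks == b, "&")
    m | t(m)
  }

  # Four qualitatively different regimes, each differing from the others in
  # a large share of the component pairs: (1) sparse/weak, (2) segregated
  # (within-network coupling, mild between-network anticorrelation),
  # (3) globally integrated positive, (4) "abnormality" mixed pattern with
  # anti-correlated DMN/attention-motor blocks.
  base_pattern <- function(state_id) {
    within <- c(0.05, 0.70, 0.55, 0.70)[min(state_id, 4)]
    between <- c(0.00, -0.20, 0.30, 0.05)[min(state_id, 4)]
    m <- matrix(between, n_components, n_components)
    m[same_net] <- within
    if (state_id == 4) {
      m[block("DMN", "DMN") & same_net] <- 0.30
      m[block("DMN", "DAN")] <- -0.42
      m[block("DMN", "SMN")] <- -0.35
      m[block("VN", "DAN")] <- 0.45
    }
    diag(m) <- 1
    m
  }

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  states <- vector("list", k)
  labels <- c("sparse", "within-network", "integration", "abnormality")
  for (s in seq_len(k)) {
    m <- base_pattern(s)
    jit <- matrix(runif(n_components^2, -jitter_sd, jitter_sd),
                  n_components, n_components)
    jit <- (jit + t(jit)) / 2
    diag(jit) <- 0
    m <- m + jit
    m <- .force_spd_correlation(m)
    states[[s]] <- list(
      state_id = s,
      covariance = m,
      label = if (s <= length(labels)) labels[s] else sprintf("state-%d", s)
    )
  }
  dists <- outer(seq_len(k), seq_len(k), Vectorize(function(a, b) {
    norm(states[[a]]$covariance - states[[b]]$covariance, "F")
  }))
  if (k > 1 && min(dists[upper.tri(dists)]) <= 0) {
    abort("planted states collapsed onto each other")
  }
  states
}

# Shrink toward the identity until SPD, then rescale to unit diagonal.
.force_spd_correlation <- function(m, min_eig = 0.05, max_rounds = 50) {
  for (i in seq_len(max_rounds)) {
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) >= min_eig) {
      d <- sqrt(diag(m))
      m <- m / outer(d, d)
      diag(m) <- 1
      ev2 <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev2) > 0) return(m)
    }
    m <- (m + 0.1 * diag(nrow(m))) / 1.1
  }
  abort("could not construct a positive-definite correlation matrix")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) return(invisible())
  assign(".Random.seed", old, envir = globalenv())
  invisible()
}

#' Build group transition matrices with a dwell bias in one state
#'
#' Controls follow a symmetric first-order Markov chain with self-transition
#' probability `self_prob` in every state. Patients receive an additional
#' `dwell_bias` on the self-transition of `biased_state` (lengthening its
#' expected dwell time) and shift a third of `dwell_bias` of each other
#' row's mass toward it (a propensity to enter the state).
#'
#' The dwell scale balances two requirements. A hidden state is only
#' expressible in windowed connectivity if it persists over a few window
#' lengths (a run of `d` TRs contains `d - W + 1` fully within-state
#' windows), which argues for long dwells; but a run must also fit well
#' inside the scan (`T = 199` TRs by default) for its length — and hence the
#' group dwell contrast — to be observable rather than truncated at the scan
#' ends. The default baseline expected dwell is two window lengths (60 TRs,
#' self-transition 1 - 1/60) and the patients' biased state four window
#' lengths (120 TRs, self-transition 1 - 1/120), a two-fold contrast whose
#' runs fit comfortably within the scan.
#'
#' @param k Number of states.
#' @param self_prob Baseline self-transition probability.
#' @param dwell_bias Extra self-transition probability for the biased state
#'   in the patient group; 0 gives identical dynamics in the two groups.
#' @param biased_state State index receiving the bias (default `k`).
#' @return List with row-stochastic `control` and `patient` k x k matrices.
#' @export
group_transition_matrices <- function(k = 4, self_prob = 1 - 1 / 60,
                                      dwell_bias = 1 / 60 - 1 / 120,
                                      biased_state = k) {
  if (self_prob <= 0 || self_prob >= 1) abort("self_prob must be in (0,1)")
  if (dwell_bias < 0 || self_prob + dwell_bias >= 1) {
    abort("dwell_bias must be >= 0 and keep probabilities below 1")
  }
  off <- (1 - self_prob) / (k - 1)
  ctrl <- matrix(off, k, k)
  diag(ctrl) <- self_prob
  pat <- ctrl
  b <- biased_state
  pat[b, ] <- (1 - (self_prob + dwell_bias)) / (k - 1)
  pat[b, b] <- self_prob + dwell_bias
  shift <- dwell_bias / 3
  for (s in seq_len(k)[-b]) {
    pat[s, b] <- pat[s, b] + shift
    pat[s, s] <- pat[s, s] - shift
  }
  stopifnot(all(abs(rowSums(ctrl) - 1) < 1e-12),
            all(abs(rowSums(pat) - 1) < 1e-12))
  list(control = ctrl, patient = pat)
}

#' Default clinical score linkage
#'
#' Linear links from (group, planted dwell time in the target state, planted
#' switching rate) to each clinical score, with Gaussian noise. Intercepts
#' and group effects emulate the typical contrast between a hydrocephalus
#' cohort and elderly controls (low MMSE, slow timed-up-and-go, grading-scale
#' subscores near 2); dwell coefficients tie symptom severity to time spent
#' in the abnormality state.
#'
#' @param target_state State whose dwell time drives symptom scores.
#' @return Named list of per-score coefficient sets.
#' @export
default_clinical_link <- function(target_state = 4) {
  list(
    target_state = target_state,
    MMSE  = list(intercept = 29, b_group = -12, b_dwell = -0.15,
                 b_switch = 0, noise_sd = 4),
    TUG   = list(intercept = 10, b_group = 14, b_dwell = 0.35,
                 b_switch = 0, noise_sd = 5),
    iNPHGS_c = list(intercept = 0.3, b_group = 1.7, b_dwell = 0.03,
                    b_switch = 0, noise_sd = 0.5),
    iNPHGS_m = list(intercept = 0.3, b_group = 1.7, b_dwell = 0.03,
                    b_switch = 0, noise_sd = 0.5),
    iNPHGS_u = list(intercept = 0.2, b_group = 1.5, b_dwell = 0.02,
                    b_switch = 0, noise_sd = 0.5)
  )
}

#' Cohort design for the synthetic generator
#'
#' Bundles every parameter of the synthetic cohort: sizes, scan length,
#' planted connectivity states, group-dependent Markov transition matrices
#' and the clinical-score linkage. Defaults emulate the study conditions:
#' 33 patients vs 23 controls, 199 time points (so a 30-TR unit-step window
#' scheme yields 170 windows), 10 ICs in 5 networks, 4 recurring states with
#' a patient dwell bias in state 4, and a male-skewed patient group.
#'
#' @param n_patients,n_controls Group sizes.
#' @param n_timepoints Scan length in TRs.
#' @param tr_seconds Repetition time in seconds.
#' @param n_components Number of ICs.
#' @param network_labels Component-to-network map.
#' @param states List of planted states from [make_state_covariances()];
#'   built from `seed` when `NULL`.
#' @param transition_matrices List with `control` and `patient` row-stochastic
#'   matrices, as [group_transition_matrices()].
#' @param clinical_link Score linkage, as [default_clinical_link()].
#' @param noise_sd SD of white measurement noise added to state draws.
#' @param ar_phi Optional AR(1) smoothing coefficient (0 disables).
#' @param male_prob Probability of male gender per group
#'   (patient, control).
#' @param seed Integer seed governing all randomness.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_patients = 33, n_controls = 23,
                          n_timepoints = 199, tr_seconds = 2,
                          n_components = 10,
                          network_labels = default_networks(),
                          states = NULL,
                          transition_matrices = group_transition_matrices(),
                          clinical_link = default_clinical_link(),
                          noise_sd = 0, ar_phi = 0,
                          male_prob = c(patient = 26 / 33, control = 9 / 23),
                          seed = 1) {
  if (n_patients < 1 || n_controls < 1) abort("need >= 1 subject per group")
  if (is.null(states)) {
    states <- make_state_covariances(n_components, k = 4,
                                     block_structure = network_labels,
                                     seed = seed)
  }
  k <- length(states)
  for (s in states) {
    if (!all(dim(s$covariance) == n_components)) {
      abort("state covariance dimension must equal n_components")
    }
  }
  for (nm in c("control", "patient")) {
    P <- transition_matrices[[nm]]
    if (is.null(P) || nrow(P) != k || ncol(P) != k) {
      abort("transition matrices must be k x k for both groups")
    }
    if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12)) {
      abort("transition matrices must be row-stochastic")
    }
  }
  ts <- clinical_link$target_state
  if (!is.null(ts) && (ts < 1 || ts > k)) {
    abort("clinical_link target_state refers to an unknown state")
  }
  structure(list(
    n_patients = n_patients, n_controls = n_controls,
    n_timepoints = n_timepoints, tr_seconds = tr_seconds,
    n_components = n_components, network_labels = network_labels,
    states = states, transition_matrices = transition_matrices,
    clinical_link = clinical_link, noise_sd = noise_sd, ar_phi = ar_phi,
    male_prob = male_prob, seed = seed
  ), class = "cohort_design")
}
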