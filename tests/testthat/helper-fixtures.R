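# Small shared fixtures, built in code.

# A dfnc_stack-shaped tibble built directly from a list of n x C x C arrays,
# bypassing the estimation path; enough structure for the downstream stages.
toy_stack <- function(arrays, groups = NULL, ages = NULL, genders = NULL) {
  n_sub <- length(arrays)
  out <- tibble::tibble(
    subject_id = sprintf("sub%03d", seq_len(n_sub)),
    group = groups %||% rep(c("patient", "control"), length.out = n_sub),
    age = ages %||% seq(70, 80, length.out = n_sub),
    gender = genders %||% rep(c("male", "female"), length.out = n_sub),
    lambda_used = 0,
    z = arrays,
    window_starts = lapply(arrays, function(a) seq_len(dim(a)[1]) - 1L)
  )
  attr(out, "window_length") <- 30
  attr(out, "sigma") <- 3
  attr(out, "step") <- 1
  attr(out, "residualized") <- FALSE
  class(out) <- c("dfnc_stack", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# n x C x C array with symmetric slices, NA diagonal, seeded noise around an
# optional base matrix.
toy_windows <- function(n, C, seed = 1, base = NULL, noise = 0.2) {
  set.seed(seed)
  a <- array(NA_real_, c(n, C, C))
  for (w in seq_len(n)) {
    m <- matrix(rnorm(C * C, sd = noise), C, C)
    m <- (m + t(m)) / 2
    if (!is.null(base)) m <- m + base
    diag(m) <- NA_real_
    a[w, , ] <- m
  }
  a
}

# Tiny cohort for pipeline-level tests: short scans, few subjects.
tiny_design <- function(seed = 1, n_patients = 4, n_controls = 4,
                        n_timepoints = 80) {
  cohort_design(n_patients = n_patients, n_controls = n_controls,
                n_timepoints = n_timepoints, seed = seed)
}
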