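#' Sample a first-order Markov state sequence
#'
#' @param n_timepoints Sequence length.
#' @param transition_matrix k x k row-stochastic matrix.
#' @param initial_distribution Length-k probability vector (default uniform).
#' @param seed Integer seed.
#' @return Integer vector of state ids in `1..k`.
#' @export
simulate_state_sequence <- function(n_timepoints, transition_matrix,
                                    initial_distribution = NULL, seed = 1) {
  if (n_timepoints < 1) abort("n_timepoints must be >= 1")
  P <- as.matrix(transition_matrix)
  k <- nrow(P)
  if (ncol(P) != k) abort("transition matrix must be square")
  if (any(P < 0)) abort("transition probabilities must be non-negative")
  if (any(abs(rowSums(P) - 1) > 1e-8)) abort("transition rows must sum to 1")
  if (is.null(initial_distribution)) initial_distribution <- rep(1 / k, k)
  if (any(initial_distribution < 0)) abort("initial probabilities must be non-negative")
  initial_distribution <- initial_distribution / sum(initial_distribution)

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  out <- integer(n_timepoints)
  out[1] <- sample.int(k, 1, prob = initial_distribution)
  if (n_timepoints > 1) {
    u <- runif(n_timepoints - 1)
    cum <- t(apply(P, 1, cumsum))
    for (t in 2:n_timepoints) {
      out[t] <- findInterval(u[t - 1], cum[out[t - 1], ]) + 1L
    }
  }
  out
}

#' Simulate one subject's IC time courses
#'
#' At each time point the observation is a zero-mean multivariate Gaussian
#' draw with the covariance of the active hidden state, optionally plus white
#' measurement noise and AR(1) smoothing. Columns are mean-centred after
#' generation. The true state sequence is kept as ground truth.
#'
#' @param design A [cohort_design()].
#' @param group `"patient"` or `"control"`.
#' @param subject_id Subject identifier.
#' @param age,gender Covariate draw for the subject.
#' @param seed Integer seed.
#' @param force_state Optional single state id: disables switching and holds
#'   the chain in that state (used for distributional checks).
#' @return One-row tibble with metadata, `timecourses` (T x C matrix
#'   list-column) and `true_states` (length-T integer list-column).
#' @export
simulate_subject <- function(design, group = c("patient", "control"),
                             subject_id = "sub001", age = 75,
                             gender = "male", seed = 1,
                             force_state = NULL) {
  group <- match.arg(group)
  Tn <- design$n_timepoints
  C <- design$n_components
  k <- length(design$states)
  chols <- lapply(design$states, function(s) {
    ch <- tryCatch(chol(s$covariance), error = function(e) NULL)
    if (is.null(ch)) abort(sprintf("state %d covariance is not SPD", s$state_id))
    ch
  })
  if (is.null(force_state)) {
    P <- design$transition_matrices[[group]]
    states <- simulate_state_sequence(Tn, P, seed = seed)
  } else {
    if (force_state < 1 || force_state > k) abort("force_state out of range")
    states <- rep(as.integer(force_state), Tn)
  }

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed + 500000L)
  z <- matrix(rnorm(Tn * C), Tn, C)
  x <- matrix(0, Tn, C)
  for (s in unique(states)) {
    rows <- which(states == s)
    x[rows, ] <- z[rows, , drop = FALSE] %*% chols[[s]]
  }
  if (design$ar_phi > 0) {
    phi <- design$ar_phi
    for (t in 2:Tn) x[t, ] <- phi * x[t - 1, ] + sqrt(1 - phi^2) * x[t, ]
  }
  if (design$noise_sd > 0) {
    x <- x + matrix(rnorm(Tn * C, sd = design$noise_sd), Tn, C)
  }
  x <- scale(x, center = TRUE, scale = FALSE)
  attr(x, "scaled:center") <- NULL
  colnames(x) <- names(design$network_labels)
  tibble(
    subject_id = subject_id, group = group, age = age, gender = gender,
    tr_seconds = design$tr_seconds,
    timecourses = list(x), true_states = list(states)
  )
}

#' Simulate a full synthetic cohort
#'
#' Generates patients and controls under group-specific Markov switching
#' between planted connectivity states, with group-imbalanced gender, ages
#' drawn near the target cohort's, and clinical scores tied to the planted
#' dynamics through the design's linear linkage. Patients receive a
#' preoperative and a (improved) postoperative clinical record; controls one
#' record.
#'
#' @param design A [cohort_design()].
#' @return List with `subjects` (one row per subject; `timecourses` and
#'   `true_states` list-columns) and `clinical` (long tibble, one row per
#'   subject x timepoint).
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  n <- design$n_patients + design$n_controls
  groups <- rep(c("patient", "control"), c(design$n_patients, design$n_controls))

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(design$seed)
  age <- ifelse(groups == "patient",
                rnorm(n, 74.4, 8.8), rnorm(n, 75.6, 6.7))
  age <- pmin(pmax(round(age, 1), 60), 92)
  male_p <- unname(design$male_prob[ifelse(groups == "patient",
                                           "patient", "control")])
  gender <- ifelse(runif(n) < male_p, "male", "female")
  subject_seeds <- design$seed + 7919L * seq_len(n)

  subjects <- bind_rows(lapply(seq_len(n), function(i) {
    simulate_subject(design, groups[i],
                     subject_id = sprintf("sub%03d", i),
                     age = age[i], gender = gender[i],
                     seed = subject_seeds[i])
  }))
  clinical <- .simulate_clinical(design, subjects)
  list(subjects = subjects, clinical = clinical)
}

# Clinical scores from the linear linkage on (group, planted dwell time in
# the target state, planted switching rate), Gaussian noise, then clipping /
# rounding / ordinal thresholding into valid ranges.
.simulate_clinical <- function(design, subjects) {
  link <- design$clinical_link
  k <- length(design$states)
  ts <- link$target_state
  if (is.null(ts) || ts < 1 || ts > k) {
    abort("clinical_link target_state refers to an unknown state")
  }
  dwell <- map_dbl(subjects$true_states, function(s) {
    r <- rle(s)
    runs <- r$lengths[r$values == ts]
    if (length(runs) == 0) 0 else mean(runs)
  })
  switch_rate <- map_dbl(subjects$true_states, function(s) {
    sum(diff(s) != 0) / (length(s) - 1)
  })
  dwell_c <- dwell - mean(dwell)
  switch_c <- switch_rate - mean(switch_rate)
  grp <- as.numeric(subjects$group == "patient")

  set.seed(design$seed + 99991L)
  latent <- function(cf, improvement = 0) {
    cf$intercept + cf$b_group * grp * pmax(1 - improvement, 0) +
      cf$b_dwell * dwell_c + cf$b_switch * switch_c +
      rnorm(nrow(subjects), sd = cf$noise_sd)
  }
  score_tbl <- function(timepoint, improvement) {
    mmse <- pmin(pmax(round(latent(link$MMSE, improvement)), 0), 30)
    tug <- pmax(round(latent(link$TUG, improvement), 1), 3)
    ordinal <- function(cf) {
      pmin(pmax(findInterval(latent(cf, improvement),
                             c(0.5, 1.5, 2.5, 3.5)), 0), 4)
    }
    gc_ <- ordinal(link$iNPHGS_c)
    gm_ <- ordinal(link$iNPHGS_m)
    gu_ <- ordinal(link$iNPHGS_u)
    tibble(
      subject_id = subjects$subject_id, group = subjects$group,
      timepoint = timepoint,
      MMSE = mmse, TUG = tug,
      iNPHGS_c = gc_, iNPHGS_m = gm_, iNPHGS_u = gu_,
      iNPHGS_total = gc_ + gm_ + gu_
    )
  }
  pre <- score_tbl("pre", improvement = 0)
  post <- score_tbl("post", improvement = 0.4) %>%
    filter(.data$group == "patient")
  bind_rows(pre, post) %>% arrange(.data$subject_id, .data$timepoint)
}

#' Write a synthetic cohort to plain-text files
#'
#' One TSV per subject (columns `IC01..`), a ground-truth state-sequence TSV
#' sidecar per subject, a cohort manifest + clinical table, and the design's
#' scalar parameters as YAML.
#'
#' @param cohort List from [simulate_cohort()].
#' @param design The [cohort_design()] used.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest tibble of written files.
#' @export
write_cohort <- function(cohort, design, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (i in seq_len(nrow(cohort$subjects))) {
    row <- cohort$subjects[i, ]
    f <- file.path(dir, paste0(row$subject_id, "_timecourses.tsv"))
    write.table(row$timecourses[[1]], f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    g <- file.path(dir, paste0(row$subject_id, "_truestates.tsv"))
    write.table(data.frame(state = row$true_states[[1]]), g, sep = "\t",
                quote = FALSE, row.names = FALSE)
    files <- c(files, f, g)
  }
  manifest <- cohort$subjects %>%
    select("subject_id", "group", "age", "gender", "tr_seconds")
  mf <- file.path(dir, "cohort_manifest.tsv")
  write.table(manifest, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  cf <- file.path(dir, "clinical.tsv")
  write.table(cohort$clinical, cf, sep = "\t", quote = FALSE,
              row.names = FALSE)
  yf <- file.path(dir, "design.yaml")
  yaml::write_yaml(list(
    n_patients = design$n_patients, n_controls = design$n_controls,
    n_timepoints = design$n_timepoints, tr_seconds = design$tr_seconds,
    n_components = design$n_components,
    network_labels = as.list(design$network_labels),
    n_states = length(design$states), noise_sd = design$noise_sd,
    ar_phi = design$ar_phi, seed = design$seed
  ), yf)
  invisible(tibble(file = c(files, mf, cf, yf)))
}

#' Read subject time courses written by [write_cohort()]
#'
#' @param dir Directory containing `cohort_manifest.tsv` and per-subject
#'   TSVs.
#' @return Subjects tibble with a `timecourses` list-column.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "cohort_manifest.tsv")
  if (!file.exists(mf)) abort(sprintf("no cohort manifest at %s", mf))
  manifest <- as_tibble(read.delim(mf))
  manifest$timecourses <- lapply(manifest$subject_id, function(id) {
    as.matrix(read.delim(file.path(dir, paste0(id, "_timecourses.tsv"))))
  })
  manifest
}
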