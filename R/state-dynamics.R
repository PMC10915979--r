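# Vectorise every subject's windows over the upper triangle into one
# (total windows) x (C*(C-1)/2) matrix, with a subject/window index.
.stack_to_matrix <- function(stack) {
  C <- dim(stack$z[[1]])[2]
  ut <- which(upper.tri(matrix(0, C, C)))
  mats <- map(stack$z, function(a) {
    matrix(a, nrow = dim(a)[1])[, (seq_len(C * C))[ut], drop = FALSE]
  })
  idx <- tibble(
    subject_id = rep(stack$subject_id, map_int(mats, nrow)),
    window = unlist(lapply(mats, function(m) seq_len(nrow(m))))
  )
  list(X = do.call(rbind, mats), index = idx, C = C, ut = ut)
}

.unvec_centroid <- function(v, C, ut) {
  m <- matrix(NA_real_, C, C)
  m[ut] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Cluster windowed connectivity matrices into recurring states
#'
#' Each window's Fisher-z matrix is vectorised over its upper triangle and
#' all subjects' windows are pooled; k-means (squared Euclidean,
#' Hartigan-Wong) is run `n_replicates` times from random initialisations and
#' the solution with the lowest within-cluster dispersion is kept. States are
#' relabelled in descending order of total occurrence.
#'
#' @param stack A `dfnc_stack` (typically residualised).
#' @param k Number of states (>= 1).
#' @param n_replicates Number of random restarts.
#' @param seed Integer seed.
#' @return Object of class `state_model`: `k`, `centroids` (k x C x C,
#'   diagonal `NA`), `labels` (tibble subject_id / window / state),
#'   `inertia`, `seed`, `distance_metric`, group metadata.
#' @export
cluster_states <- function(stack, k, n_replicates = 100, seed = 1) {
  if (k < 1) abort("k must be >= 1")
  sm <- .stack_to_matrix(stack)
  if (k > nrow(sm$X)) abort("k exceeds the number of windows")

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  km <- tryCatch(
    suppressWarnings(
      kmeans(sm$X, centers = k, nstart = n_replicates, iter.max = 200)
    ),
    error = function(e) {
      if (grepl("distinct", conditionMessage(e))) {
        abort("k exceeds the number of distinct windows")
      }
      stop(e)
    }
  )
  relabel <- order(tabulate(km$cluster, nbins = k), decreasing = TRUE)
  new_of_old <- match(seq_len(k), relabel)
  labels <- new_of_old[km$cluster]
  centers <- km$centers[relabel, , drop = FALSE]
  centroids <- array(NA_real_, c(k, sm$C, sm$C))
  for (s in seq_len(k)) centroids[s, , ] <- .unvec_centroid(centers[s, ], sm$C, sm$ut)
  ids <- dimnames(stack$z[[1]])[[2]]
  if (!is.null(ids)) dimnames(centroids) <- list(NULL, ids, ids)

  meta_cols <- intersect(c("subject_id", "group", "age", "gender"), names(stack))
  structure(list(
    k = k,
    centroids = centroids,
    labels = sm$index %>% mutate(state = labels),
    inertia = km$tot.withinss,
    between_ss = km$betweenss,
    seed = seed,
    distance_metric = "squared-euclidean",
    relabel_map = relabel,
    subjects = stack[meta_cols]
  ), class = "state_model")
}

#' Select the number of states by the elbow criterion
#'
#' For each candidate k the cluster validity index is the ratio of
#' within-cluster to between-cluster dispersion. The elbow is located as the
#' point of maximum distance between the (normalised) index curve and the
#' chord joining its endpoints — the point where the curve bends away most
#' from its overall decline. Raw second differences of a convex decreasing
#' ratio curve peak at the smallest interior candidate regardless of cluster
#' structure, so they are reported in the curve for inspection but not used
#' for selection. A flat curve (maximum normalised chord distance below
#' `tol`) falls back to the smallest candidate with a warning.
#'
#' @param stack A `dfnc_stack`.
#' @param k_candidates Ascending candidate values (>= 3 of them).
#' @param n_replicates,seed Passed to [cluster_states()].
#' @param tol Flatness tolerance on the normalised chord distance (both axes
#'   scaled to the unit interval).
#' @return List with `k` (chosen) and `curve` (tibble k / index / curvature /
#'   chord_distance).
#' @export
select_k_elbow <- function(stack, k_candidates = 2:8, n_replicates = 100,
                           seed = 1, tol = 0.02) {
  k_candidates <- sort(unique(as.integer(k_candidates)))
  if (length(k_candidates) < 3) abort("need at least 3 candidate k values")
  sm <- .stack_to_matrix(stack)

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  index <- numeric(length(k_candidates))
  for (i in seq_along(k_candidates)) {
    set.seed(seed + i)
    km <- suppressWarnings(
      kmeans(sm$X, centers = k_candidates[i], nstart = n_replicates,
             iter.max = 200)
    )
    index[i] <- km$tot.withinss / km$betweenss
  }
  curvature <- rep(NA_real_, length(index))
  interior <- 2:(length(index) - 1)
  curvature[interior] <- index[interior - 1] - 2 * index[interior] +
    index[interior + 1]
  rng <- max(index) - min(index)
  xs <- (k_candidates - min(k_candidates)) /
    (max(k_candidates) - min(k_candidates))
  ys <- if (rng > 0) (index - min(index)) / rng else rep(0, length(index))
  chord <- ys[1] + (ys[length(ys)] - ys[1]) * xs - ys
  curve <- tibble(k = k_candidates, index = index, curvature = curvature,
                  chord_distance = chord)
  if (rng <= .Machine$double.eps * max(abs(index), 1) ||
      max(chord) < tol) {
    warn("flat validity-index curve: no elbow, returning smallest candidate")
    return(list(k = k_candidates[1], curve = curve))
  }
  list(k = k_candidates[which.max(chord)], curve = curve)
}

#' Fraction of windows spent in each state
#'
#' @param labels Integer state sequence (values in 1..k).
#' @param k Number of states.
#' @return Length-k vector summing to 1.
#' @export
fraction_time <- function(labels, k) {
  .check_labels(labels, k)
  tabulate(labels, nbins = k) / length(labels)
}

#' Mean dwell time per state
#'
#' Mean length (in windows) of the maximal runs of each state; 0 for states
#' never visited.
#'
#' @inheritParams fraction_time
#' @return Length-k vector of mean run lengths.
#' @export
mean_dwell_time <- function(labels, k) {
  .check_labels(labels, k)
  r <- rle(as.integer(labels))
  vapply(seq_len(k), function(s) {
    runs <- r$lengths[r$values == s]
    if (length(runs) == 0) 0 else mean(runs)
  }, numeric(1))
}

#' Number of state transitions in a label sequence
#'
#' @param labels Non-empty state sequence.
#' @return Count of positions where the label changes.
#' @export
n_transitions <- function(labels) {
  if (length(labels) == 0) abort("empty label sequence")
  sum(diff(as.integer(labels)) != 0)
}

.check_labels <- function(labels, k) {
  if (length(labels) == 0) abort("empty label sequence")
  labels <- as.integer(labels)
  if (any(labels < 1 | labels > k)) abort("state label out of range 1..k")
  invisible(labels)
}

#' Temporal-property metrics per subject
#'
#' Fraction time and mean dwell time per state, plus the subject's total
#' transition count and a visited flag, in one tidy tibble. Per-state entry
#' counts (transitions into each state) are included since the raw
#' transition number aggregates over all states.
#'
#' @param model A `state_model` from [cluster_states()].
#' @return Tibble: subject_id, (group), state, fraction_time,
#'   mean_dwell_time, n_transitions, n_entries, visited.
#' @export
state_metrics <- function(model) {
  k <- model$k
  per_subject <- model$labels %>%
    group_by(.data$subject_id) %>%
    summarise(
      fraction_time = list(fraction_time(.data$state, k)),
      mean_dwell_time = list(mean_dwell_time(.data$state, k)),
      n_transitions = n_transitions(.data$state),
      n_entries = list({
        s <- .data$state
        enter <- s[c(TRUE, diff(s) != 0)]
        tabulate(enter, nbins = k)
      }),
      .groups = "drop"
    ) %>%
    mutate(state = list(seq_len(k))) %>%
    tidyr::unnest(c("state", "fraction_time", "mean_dwell_time", "n_entries")) %>%
    mutate(visited = .data$fraction_time > 0)
  left_join(per_subject, model$subjects, by = "subject_id") %>%
    select(dplyr::any_of(c("subject_id", "group", "age", "gender")),
           dplyr::everything())
}

#' Per-group state centroids and occurrence counts
#'
#' For each group and state: the mean of all member windows of that group's
#' subjects (the average instantaneous connectivity), and the count of
#' subjects with at least one window in the state. A state never visited by
#' a group yields a masked (all-`NA`) centroid and count 0.
#'
#' @param stack The `dfnc_stack` the model was fitted on.
#' @param model The `state_model`.
#' @return Tibble: group, state, n_subjects, centroid (list-column of C x C
#'   matrices).
#' @export
group_state_centroids <- function(stack, model) {
  sm <- .stack_to_matrix(stack)
  lab <- model$labels
  grp <- stack$group[match(lab$subject_id, stack$subject_id)]
  out <- list()
  for (g in unique(grp)) {
    for (s in seq_len(model$k)) {
      rows <- which(grp == g & lab$state == s)
      if (length(rows) == 0) {
        cen <- matrix(NA_real_, sm$C, sm$C)
        cnt <- 0L
      } else {
        cen <- .unvec_centroid(colMeans(sm$X[rows, , drop = FALSE]), sm$C, sm$ut)
        cnt <- length(unique(lab$subject_id[rows]))
      }
      out[[length(out) + 1]] <- tibble(group = g, state = s,
                                       n_subjects = cnt, centroid = list(cen))
    }
  }
  bind_rows(out)
}

#' @export
tidy.state_model <- function(x, ...) x$labels

#' @export
glance.state_model <- function(x, ...) {
  tibble(k = x$k, inertia = x$inertia, between_ss = x$between_ss,
         n_windows = nrow(x$labels), seed = x$seed,
         distance_metric = x$distance_metric)
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("state_model: k = %d, %d windows from %d subjects, inertia = %.2f\n",
              x$k, nrow(x$labels), length(unique(x$labels$subject_id)),
              x$inertia))
  occ <- tabulate(x$labels$state, nbins = x$k)
  cat("windows per state:", paste(occ, collapse = " / "), "\n")
  invisible(x)
}
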