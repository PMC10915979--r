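#' Tapered sliding-window weights
#'
#' A rectangle of width `W` convolved with a Gaussian kernel of standard
#' deviation `sigma` (in TRs), truncated to the central `W` samples and
#' renormalised to sum to one. The default (W = 30, sigma = 3) is the
#' conventional taper for sliding-window connectivity.
#'
#' @param window_length Window length W in TRs (>= 2).
#' @param sigma Gaussian SD in TRs (> 0).
#' @return Object of class `tapered_window`: list with `weights` (length W,
#'   symmetric, sums to 1), `window_length`, `sigma`.
#' @export
build_taper <- function(window_length = 30, sigma = 3) {
  W <- window_length
  if (W < 2) abort("window_length must be >= 2")
  if (sigma <= 0) abort("sigma must be > 0")
  half <- max(1L, ceiling(4 * sigma))
  offs <- (-half):half
  kern <- exp(-offs^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  full <- convolve(rep(1, W), rev(kern), type = "open")  # length W + 2*half
  w <- full[(half + 1):(half + W)]
  w <- (w + rev(w)) / 2  # enforce exact symmetry against fp noise
  w <- w / sum(w)
  structure(list(weights = w, window_length = W, sigma = sigma),
            class = "tapered_window")
}

#' Extract tapered sliding-window segments from one subject
#'
#' Window `i` (0-based start `i * step`) covers TRs `[i*step, i*step + W)`.
#' Each segment is centred on its taper-weighted mean and its rows scaled by
#' the square root of the taper weights, so that `crossprod(segment)` is the
#' taper-weighted sample covariance of the window.
#'
#' @param x T x C matrix of IC time courses.
#' @param taper A [build_taper()] object.
#' @param step Step between window starts in TRs (>= 1).
#' @return List with `segments` (list of W x C matrices) and `starts`
#'   (0-based TR indices).
#' @export
extract_windows <- function(x, taper, step = 1) {
  x <- as.matrix(x)
  Tn <- nrow(x)
  W <- taper$window_length
  if (Tn < W) abort(sprintf("scan length %d shorter than window %d", Tn, W))
  if (step < 1) abort("step must be >= 1")
  n <- floor((Tn - W) / step) + 1
  starts <- (seq_len(n) - 1L) * step
  w <- taper$weights
  sw <- sqrt(w)
  segments <- lapply(starts, function(s) {
    seg <- x[(s + 1):(s + W), , drop = FALSE]
    mu <- colSums(seg * w)
    sw * sweep(seg, 2, mu)
  })
  list(segments = segments, starts = as.integer(starts))
}

#' Graphical-lasso precision estimate
#'
#' Maximises the Gaussian log-likelihood `log det(Theta) - tr(S Theta)` minus
#' `lambda` times the L1 norm of the off-diagonal precision entries, by block
#' coordinate descent. At `lambda = 0` this converges to the inverse sample
#' covariance.
#'
#' @param x Either a weighted segment (rows = observations, as produced by
#'   [extract_windows()]) or, with `input = "covariance"`, a C x C sample
#'   covariance matrix.
#' @param lambda L1 penalty (>= 0).
#' @param input Interpretation of `x`.
#' @param tol Convergence tolerance (relative to mean absolute off-diagonal
#'   covariance).
#' @param max_iter Maximum outer cycles.
#' @return C x C symmetric positive-definite precision matrix, with the
#'   estimated covariance as attribute `"covariance"`.
#' @export
glasso_precision <- function(x, lambda, input = c("segment", "covariance"),
                             tol = 1e-7, max_iter = 200) {
  input <- match.arg(input)
  if (lambda < 0) abort("lambda must be >= 0")
  S <- if (input == "segment") crossprod(as.matrix(x)) else as.matrix(x)
  if (any(!is.finite(S))) abort("covariance contains non-finite values")
  v <- diag(S)
  if (any(v < 1e-12)) {
    bad <- colnames(S)[v < 1e-12]
    if (is.null(bad) || !length(bad)) bad <- which(v < 1e-12)
    abort(sprintf("near-zero weighted variance in component(s): %s",
                  paste(bad, collapse = ", ")))
  }
  fit <- .glasso_cd(S, lambda, tol, as.integer(max_iter))
  if (!fit$converged) {
    gap <- sum(diag(S %*% fit$precision)) - nrow(S) +
      lambda * sum(abs(fit$precision - diag(diag(fit$precision))))
    warn(sprintf(
      "graphical lasso did not converge in %d cycles (duality-gap proxy %.3e)",
      fit$iterations, gap))
  }
  theta <- fit$precision
  dimnames(theta) <- dimnames(S)
  attr(theta, "covariance") <- fit$covariance
  theta
}

#' Convert a precision matrix to correlation-scale connectivity
#'
#' Inverts the precision to a covariance and normalises to unit diagonal.
#'
#' @param precision C x C SPD precision matrix.
#' @return C x C correlation matrix.
#' @export
precision_to_fc <- function(precision) {
  precision <- as.matrix(precision)
  attr(precision, "covariance") <- NULL
  covm <- tryCatch(solve(precision), error = function(e) {
    abort("precision matrix is singular")
  })
  stats::cov2cor(covm)
}

# Partial correlations from a precision matrix: -theta_ij / sqrt(theta_ii theta_jj).
.precision_to_partial <- function(precision) {
  pc <- -stats::cov2cor(as.matrix(precision))
  diag(pc) <- 1
  pc
}

#' Select the graphical-lasso penalty by repeated random splits
#'
#' For one subject's windows: `n_repetitions` random half-splits into fit and
#' evaluation windows; at each grid value the precision is fitted on the
#' pooled fit-window covariance and scored by the mean held-out Gaussian
#' log-likelihood `log det(Theta) - tr(S_eval Theta)`. The grid value with the
#' highest mean held-out likelihood wins.
#'
#' @param segments List of weighted window segments for one subject.
#' @param grid Candidate penalties (non-empty, >= 0).
#' @param n_repetitions Number of random splits.
#' @param seed Integer seed.
#' @return Selected penalty, with the score curve as attribute `"scores"`.
#' @export
select_lambda <- function(segments, grid = 10^seq(-2, 0, length.out = 10),
                          n_repetitions = 100, seed = 1) {
  if (length(grid) == 0) abort("empty penalty grid")
  if (length(segments) < 2) abort("need at least 2 windows")
  if (length(grid) == 1) return(grid)
  n <- length(segments)
  covs <- lapply(segments, crossprod)

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  scores <- matrix(NA_real_, n_repetitions, length(grid))
  for (r in seq_len(n_repetitions)) {
    fit_idx <- sample.int(n, max(1, floor(n / 2)))
    S_fit <- Reduce(`+`, covs[fit_idx]) / length(fit_idx)
    S_eval <- Reduce(`+`, covs[-fit_idx]) / (n - length(fit_idx))
    for (g in seq_along(grid)) {
      theta <- tryCatch(
        glasso_precision(S_fit, grid[g], input = "covariance"),
        error = function(e) NULL)
      if (is.null(theta)) next
      scores[r, g] <- determinant(theta, logarithm = TRUE)$modulus -
        sum(S_eval * theta)
    }
  }
  mean_scores <- colMeans(scores, na.rm = TRUE)
  dropped <- !is.finite(mean_scores)
  if (any(dropped)) {
    warn(sprintf("%d grid value(s) dropped (all fits failed)", sum(dropped)))
    mean_scores[dropped] <- -Inf
  }
  best <- grid[which.max(mean_scores)]
  attr(best, "scores") <- tibble(lambda = grid, mean_loglik = mean_scores)
  best
}

#' Dynamic functional network connectivity for a cohort
#'
#' Tapered sliding windows per subject, graphical-lasso regularised
#' covariance per window, conversion to correlation scale (or partial
#' correlations), and Fisher z transform with the diagonal masked.
#'
#' @param subjects Subjects tibble with a `timecourses` list-column.
#' @param window_length,sigma,step Window scheme in TRs.
#' @param lambda Fixed L1 penalty, or `"select"` to pick one per subject via
#'   [select_lambda()].
#' @param lambda_grid,n_repetitions,seed Passed to [select_lambda()] when
#'   `lambda = "select"`.
#' @param fc `"correlation"` (from the regularised covariance; default) or
#'   `"partial"` (negated normalised precision).
#' @return Tibble of class `dfnc_stack`: one row per subject with metadata, a
#'   `z` list-column (n x C x C Fisher-z arrays), `lambda_used` and
#'   `window_starts`. Attributes record the window scheme.
#' @export
dfnc <- function(subjects, window_length = 30, sigma = 3, step = 1,
                 lambda = 0.01, lambda_grid = 10^seq(-2, 0, length.out = 10),
                 n_repetitions = 100, seed = 1,
                 fc = c("correlation", "partial")) {
  fc <- match.arg(fc)
  taper <- build_taper(window_length, sigma)
  rows <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    x <- subjects$timecourses[[i]]
    ew <- extract_windows(x, taper, step)
    lam <- if (identical(lambda, "select")) {
      as.numeric(select_lambda(ew$segments, lambda_grid, n_repetitions,
                               seed = seed + i))
    } else lambda
    n <- length(ew$segments)
    C <- ncol(x)
    z <- array(NA_real_, c(n, C, C))
    for (w in seq_len(n)) {
      theta <- glasso_precision(ew$segments[[w]], lam)
      r <- if (fc == "correlation") precision_to_fc(theta)
           else .precision_to_partial(theta)
      diag(r) <- NA_real_
      z[w, , ] <- fisher_z(r)
    }
    dimnames(z) <- list(NULL, colnames(x), colnames(x))
    rows[[i]] <- tibble(
      subject_id = subjects$subject_id[i],
      lambda_used = lam,
      z = list(z),
      window_starts = list(ew$starts)
    )
  }
  meta <- subjects %>%
    select(!dplyr::any_of(c("timecourses", "true_states")))
  out <- left_join(meta, bind_rows(rows), by = "subject_id")
  attr(out, "window_length") <- window_length
  attr(out, "sigma") <- sigma
  attr(out, "step") <- step
  attr(out, "fc") <- fc
  attr(out, "residualized") <- FALSE
  class(out) <- c("dfnc_stack", class(out))
  out
}

#' Residualise a connectivity stack against nuisance covariates
#'
#' For every connectivity pair: the subject-mean Fisher-z value is regressed
#' across subjects on the covariates (OLS with intercept), and the fitted
#' subject-level effect (minus its grand mean, so the grand intercept is
#' retained) is subtracted from all of that subject's windows. Covariates are
#' subject-level constants, so one regression per pair suffices.
#'
#' @param stack A `dfnc_stack` from [dfnc()].
#' @param covariates Character vector of covariate column names present in
#'   the stack (e.g. `c("age", "gender")`); factors are expanded via
#'   `model.matrix`.
#' @return The stack with adjusted `z` arrays; attribute
#'   `residualized = TRUE`.
#' @export
residualize_stack <- function(stack, covariates = c("age", "gender")) {
  if (!all(covariates %in% names(stack))) {
    abort("missing covariate column(s) in stack")
  }
  df <- as.data.frame(stack[covariates])
  X <- stats::model.matrix(~ ., data = df)
  if (qr(X)$rank < ncol(X)) {
    abort("collinear covariates (design matrix rank-deficient)")
  }
  n_sub <- nrow(stack)
  C <- dim(stack$z[[1]])[2]
  ut <- which(upper.tri(matrix(0, C, C)))
  subj_means <- t(vapply(stack$z, function(a) {
    colMeans(matrix(a, nrow = dim(a)[1]))[ut]
  }, numeric(length(ut))))
  H <- X %*% solve(crossprod(X), t(X))
  fitted <- H %*% subj_means
  adj <- sweep(fitted, 2, colMeans(fitted))  # subject effect net of grand mean
  zs <- stack$z
  for (i in seq_len(n_sub)) {
    a <- zs[[i]]
    m <- matrix(0, C, C)
    m[ut] <- adj[i, ]
    m <- m + t(m)
    shift <- array(rep(m, each = dim(a)[1]), dim = dim(a),
                   dimnames = dimnames(a))
    zs[[i]] <- a - shift
  }
  stack$z <- zs
  attr(stack, "residualized") <- TRUE
  stack
}

#' @export
tidy.dfnc_stack <- function(x, ...) {
  ids <- dimnames(x$z[[1]])[[2]]
  C <- dim(x$z[[1]])[2]
  if (is.null(ids)) ids <- sprintf("IC%02d", seq_len(C))
  ut <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)
  x %>%
    select("subject_id", dplyr::any_of("group"), "z", "window_starts") %>%
    mutate(long = map2(.data$z, .data$window_starts, function(a, st) {
      n <- dim(a)[1]
      flat <- matrix(a, nrow = n)[, (ut[, 2] - 1) * C + ut[, 1], drop = FALSE]
      tibble(window_start = rep(st, times = nrow(ut)),
             comp_a = rep(ids[ut[, 1]], each = n),
             comp_b = rep(ids[ut[, 2]], each = n),
             z = as.vector(flat))
    })) %>%
    select(!dplyr::all_of(c("z", "window_starts"))) %>%
    tidyr::unnest("long")
}
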