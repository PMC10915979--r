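#' Subject-level temporal PCA reduction
#'
#' Retains the top `n_pc` principal temporal directions of a subject's
#' voxel-by-time data. The stored orthonormal operator allows back-projection
#' to the original temporal dimension.
#'
#' @param x T x V matrix (time points by voxels).
#' @param n_pc Number of components to retain (`<= min(T, V)`).
#' @return List of class `ica_reduction`: `reduced` (n_pc x V), `operator`
#'   (T x n_pc, orthonormal columns), `explained_variance`, `singular_values`.
#' @export
subject_reduce <- function(x, n_pc) {
  x <- as.matrix(x)
  if (n_pc > min(dim(x))) abort("n_pc exceeds min(T, V)")
  sv <- svd(x, nu = n_pc, nv = 0)
  d2 <- sv$d^2
  rank_est <- sum(sv$d > max(dim(x)) * .Machine$double.eps * sv$d[1])
  if (rank_est < n_pc) {
    abort(sprintf("input rank %d is below requested n_pc = %d",
                  rank_est, n_pc))
  }
  reduced <- t(sv$u) %*% x
  structure(list(
    reduced = reduced, operator = sv$u,
    explained_variance = sum(d2[seq_len(n_pc)]) / sum(d2),
    singular_values = sv$d
  ), class = "ica_reduction")
}

# Symmetric fixed-point ICA (logcosh contrast) on pre-whitened data.
# X_white: C x V with identity spatial covariance across voxels.
.fastica_symmetric <- function(X_white, seed, max_iter = 500, tol = 1e-8) {
  C <- nrow(X_white)
  V <- ncol(X_white)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  Wm <- matrix(rnorm(C * C), C, C)
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-14)), C) %*%
      t(e$vectors) %*% W
  }
  Wm <- sym_decorrelate(Wm)
  iters <- 0
  for (it in seq_len(max_iter)) {
    iters <- it
    U <- Wm %*% X_white              # C x V current sources
    G <- tanh(U)
    Gp <- 1 - G^2
    W_new <- (G %*% t(X_white)) / V - diag(rowMeans(Gp), C) %*% Wm
    W_new <- sym_decorrelate(W_new)
    delta <- 1 - min(abs(diag(W_new %*% t(Wm))))
    Wm <- W_new
    if (delta < tol) break
  }
  if (iters == max_iter) {
    warn(sprintf("fixed-point ICA did not converge in %d iterations", max_iter))
  }
  list(W = Wm, iterations = iters)
}

#' Group-level spatial ICA estimation
#'
#' Stacks subject-reduced data, applies a group PCA to `n_components`, and
#' unmixes with a symmetric fixed-point ICA (logcosh nonlinearity).
#' Components are given a fixed sign convention (maximum-absolute voxel
#' positive) and a deterministic order (descending explained variance).
#'
#' @param reduced_subjects List of `ica_reduction` objects.
#' @param n_components Number of independent components.
#' @param seed Integer seed for the ICA initialisation.
#' @return List of class `group_ica`: `maps` (C x V spatial sources, unit
#'   variance), `mixing` (rows of the stacked reduced data x C),
#'   `iterations`, `seed`.
#' @export
group_ica_estimate <- function(reduced_subjects, n_components, seed = 1) {
  if (length(reduced_subjects) < 1) abort("no subjects")
  G <- do.call(rbind, lapply(reduced_subjects, function(r) r$reduced))
  if (n_components > min(dim(G))) {
    abort("n_components exceeds the group-reduced rank")
  }
  G <- sweep(G, 1, rowMeans(G))
  sv <- svd(G, nu = n_components, nv = 0)
  if (sv$d[n_components] < max(dim(G)) * .Machine$double.eps * sv$d[1]) {
    abort("group data rank below n_components")
  }
  V <- ncol(G)
  # Whiten: rows of X_white have unit variance across voxels, uncorrelated.
  X_white <- diag(sqrt(V) / sv$d[seq_len(n_components)], n_components) %*%
    t(sv$u) %*% G
  fit <- .fastica_symmetric(X_white, seed)
  S <- fit$W %*% X_white                        # C x V sources, unit variance
  A <- t(G %*% t(S)) / V                        # mixing via projection
  A <- t(A)
  # Sign convention: max-abs voxel of each map positive.
  signs <- vapply(seq_len(nrow(S)), function(i) {
    v <- S[i, ]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  S <- S * signs
  A <- sweep(A, 2, signs, `*`)
  # Deterministic order: descending explained variance (mixing energy).
  ord <- order(colSums(A^2), decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  A <- A[, ord, drop = FALSE]
  rownames(S) <- sprintf("IC%02d", seq_len(nrow(S)))
  structure(list(maps = S, mixing = A, iterations = fit$iterations,
                 seed = seed), class = "group_ica")
}

#' Back-reconstruct subject time courses and spatial maps
#'
#' Each subject's data is reconstructed through its stored reduction
#' operator and regressed on the group spatial maps, yielding subject
#' time courses (T x C); subject-specific maps follow by the reverse
#' regression. Near-constant time-course columns are flagged.
#'
#' @param reduced_subjects List of `ica_reduction` objects (same order as in
#'   estimation).
#' @param group_result A `group_ica` object.
#' @return List per subject: `timecourses` (T x C), `maps` (C x V),
#'   `flagged_components` (near-zero-variance columns).
#' @export
back_reconstruct <- function(reduced_subjects, group_result) {
  S <- group_result$maps
  StS_inv <- solve(tcrossprod(S))
  lapply(reduced_subjects, function(r) {
    if (ncol(r$operator) != nrow(r$reduced)) abort("mismatched reduction operator")
    Xhat <- r$operator %*% r$reduced            # T x V
    TC <- Xhat %*% t(S) %*% StS_inv             # T x C
    colnames(TC) <- rownames(S)
    sds <- apply(TC, 2, sd)
    flagged <- colnames(TC)[sds < 1e-10 * max(sds, 1e-300)]
    Mi <- tryCatch(solve(crossprod(TC), t(TC) %*% Xhat),
                   error = function(e) matrix(NA_real_, ncol(TC), ncol(Xhat)))
    list(timecourses = TC, maps = Mi, flagged_components = flagged)
  })
}

#' Label components by template correlation
#'
#' Assigns every component to the network whose template map has the
#' highest absolute spatial correlation with it; the signed correlation is
#' recorded. Components whose best |r| falls below `floor_r` are flagged
#' `"unassigned"`.
#'
#' @param maps C x V component maps (rows) or a `group_ica` object.
#' @param templates Named list (or N x V matrix with rownames) of network
#'   template maps on the same voxel grid.
#' @param floor_r Minimum absolute correlation for assignment.
#' @return Tibble: component_id, network, correlation (signed, at the
#'   assigned network).
#' @export
label_components <- function(maps, templates, floor_r = 0.2) {
  if (inherits(maps, "group_ica")) maps <- maps$maps
  maps <- as.matrix(maps)
  if (is.list(templates)) {
    templates <- do.call(rbind, templates)
  }
  templates <- as.matrix(templates)
  if (ncol(templates) != ncol(maps)) {
    abort("templates are not on the same voxel grid as the maps")
  }
  nets <- rownames(templates)
  if (is.null(nets)) abort("templates must be named")
  ids <- rownames(maps)
  if (is.null(ids)) ids <- sprintf("IC%02d", seq_len(nrow(maps)))
  R <- cor(t(maps), t(templates))               # C x N
  best <- apply(abs(R), 1, which.max)
  r_best <- R[cbind(seq_len(nrow(maps)), best)]
  network <- ifelse(abs(r_best) >= floor_r, nets[best], "unassigned")
  tibble(component_id = ids, network = network, correlation = r_best)
}

#' Read a 4D NIfTI volume as a time-by-voxel matrix
#'
#' Thin wrapper over the RNifti reader for the optional voxel-data entry
#' path.
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @return List: `data` (T x V matrix), `dim` (spatial dimensions).
#' @export
read_nifti_timeseries <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("the RNifti package is required to read NIfTI files")
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4) abort("expected a 4D volume")
  v <- prod(d[1:3])
  list(data = t(matrix(as.vector(img), nrow = v, ncol = d[4])),
       dim = d[1:3])
}
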