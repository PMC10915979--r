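#' Temporal variability of each component's connectivity profile
#'
#' For component k, `F[i, k]` is the k-th row of window i's connectivity
#' matrix with the (degenerate) self-entry removed. The temporal variability
#' is one minus the temporal stability,
#' `V_k = 1 - sum_{i != j} rho(F[i,k], F[j,k]) / (n (n - 1))`,
#' the mean Pearson correlation over all ordered window pairs. `V_k` is 0
#' when every window is identical and near 1 when profiles are unrelated.
#'
#' Pairs where either profile is constant (undefined correlation) are
#' dropped and the divisor reduced accordingly; the number of dropped pairs
#' is reported per subject.
#'
#' @param stack A `dfnc_stack` (typically residualised Fisher-z matrices).
#' @return Tibble of class `variability_tbl`: subject_id, (group),
#'   component, V, n_windows, n_dropped_pairs.
#' @export
temporal_variability <- function(stack) {
  C <- dim(stack$z[[1]])[2]
  if (C < 3) abort("need at least 3 components for row correlations")
  ids <- dimnames(stack$z[[1]])[[2]]
  if (is.null(ids)) ids <- sprintf("IC%02d", seq_len(C))
  rows <- vector("list", nrow(stack))
  for (i in seq_len(nrow(stack))) {
    a <- stack$z[[i]]
    n <- dim(a)[1]
    if (n < 2) abort("need at least 2 windows")
    V <- numeric(C)
    dropped <- integer(C)
    for (k in seq_len(C)) {
      # n x (C-1) matrix of window profiles for component k (self removed)
      Rk <- matrix(a[, k, -k], nrow = n)
      sds <- apply(Rk, 1, sd)
      ok <- sds > 0
      n_ok <- sum(ok)
      dropped[k] <- n * (n - 1) - n_ok * (n_ok - 1)
      if (n_ok < 2) {
        V[k] <- NA_real_
        next
      }
      cm <- cor(t(Rk[ok, , drop = FALSE]))
      V[k] <- 1 - (sum(cm) - n_ok) / (n_ok * (n_ok - 1))
    }
    rows[[i]] <- tibble(subject_id = stack$subject_id[i],
                        component = ids, V = V,
                        n_windows = n, n_dropped_pairs = dropped)
  }
  meta_cols <- intersect(c("subject_id", "group"), names(stack))
  out <- left_join(bind_rows(rows), stack[meta_cols], by = "subject_id") %>%
    select(dplyr::any_of(c("subject_id", "group")), dplyr::everything())
  class(out) <- c("variability_tbl", class(out))
  out
}

#' Brute-force reference for [temporal_variability()]
#'
#' Explicit double loop over ordered window pairs; intended for validation
#' on small stacks, not production use.
#'
#' @param stack A `dfnc_stack` with a modest number of windows (<= 50).
#' @return Same shape as [temporal_variability()].
#' @export
variability_oracle <- function(stack) {
  C <- dim(stack$z[[1]])[2]
  ids <- dimnames(stack$z[[1]])[[2]]
  if (is.null(ids)) ids <- sprintf("IC%02d", seq_len(C))
  rows <- vector("list", nrow(stack))
  for (i in seq_len(nrow(stack))) {
    a <- stack$z[[i]]
    n <- dim(a)[1]
    if (n > 50) abort("oracle is for small stacks (n <= 50)")
    V <- numeric(C)
    dropped <- integer(C)
    for (k in seq_len(C)) {
      total <- 0
      count <- 0
      drop_k <- 0
      for (p in seq_len(n)) {
        for (q in seq_len(n)) {
          if (p == q) next
          fp <- a[p, k, -k]
          fq <- a[q, k, -k]
          if (sd(fp) == 0 || sd(fq) == 0) {
            drop_k <- drop_k + 1
            next
          }
          total <- total + cor(fp, fq)
          count <- count + 1
        }
      }
      dropped[k] <- drop_k
      V[k] <- if (count == 0) NA_real_ else 1 - total / count
    }
    rows[[i]] <- tibble(subject_id = stack$subject_id[i],
                        component = ids, V = V,
                        n_windows = n, n_dropped_pairs = dropped)
  }
  meta_cols <- intersect(c("subject_id", "group"), names(stack))
  left_join(bind_rows(rows), stack[meta_cols], by = "subject_id") %>%
    select(dplyr::any_of(c("subject_id", "group")), dplyr::everything())
}
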