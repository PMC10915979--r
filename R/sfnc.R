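#' Pearson correlation between IC time courses
#'
#' @param x T x C numeric matrix (rows = time points, columns = components).
#' @return C x C symmetric correlation matrix with unit diagonal.
#' @export
pearson_fc <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) abort("need at least 3 time points")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    abort(sprintf("constant component(s): %s", paste(bad, collapse = ", ")))
  }
  cor(x)
}

#' Fisher z (atanh) transform of correlation values
#'
#' Values with `|r| >= 1` are clipped to `1 - eps` (with a warning) so the
#' transform stays finite; `NA`s (e.g. a masked diagonal) pass through.
#'
#' @param r Correlation value, vector or matrix.
#' @param eps Clipping margin.
#' @return `atanh` of the (clipped) input, same shape.
#' @export
fisher_z <- function(r, eps = 1e-7) {
  clip <- !is.na(r) & abs(r) >= 1
  if (any(clip)) {
    warn(sprintf("%d correlation value(s) with |r| >= 1 clipped", sum(clip)))
    r[clip] <- sign(r[clip]) * (1 - eps)
  }
  atanh(r)
}

#' Static functional network connectivity per subject
#'
#' Whole-scan Pearson correlation between IC time courses, Fisher
#' z-transformed, with the (degenerate) diagonal masked as `NA`.
#'
#' @param subjects Subjects tibble with a `timecourses` list-column (as from
#'   [simulate_cohort()]).
#' @return The input tibble (metadata columns) with an `sfnc` list-column of
#'   C x C Fisher-z matrices; class `sfnc_tbl`.
#' @export
sfnc <- function(subjects) {
  z <- lapply(subjects$timecourses, function(x) {
    r <- pearson_fc(x)
    diag(r) <- NA_real_
    fisher_z(r)
  })
  out <- subjects %>%
    select(!dplyr::any_of(c("timecourses", "true_states"))) %>%
    mutate(sfnc = z)
  class(out) <- c("sfnc_tbl", class(out))
  out
}

#' Aggregate a component-level matrix to network (domain) level
#'
#' Entry (A, B) for distinct networks is the mean of the matrix over all
#' component pairs (a in A, b in B); entry (A, A) is the mean over unordered
#' distinct within-network pairs. Networks holding a single component have an
#' undefined within-network entry, masked as `NA`.
#'
#' @param z C x C symmetric matrix (Fisher-z scale, diagonal ignored).
#' @param assignment Named character vector mapping component id to network,
#'   ordered like the matrix columns.
#' @return N x N symmetric matrix over networks.
#' @export
domain_aggregate <- function(z, assignment) {
  z <- as.matrix(z)
  C <- nrow(z)
  if (length(assignment) != C) abort("every component must be assigned")
  nets <- unique(unname(assignment))
  if (any(!nzchar(nets))) abort("empty network name")
  N <- length(nets)
  out <- matrix(NA_real_, N, N, dimnames = list(nets, nets))
  for (a in seq_len(N)) {
    for (b in a:N) {
      ia <- which(assignment == nets[a])
      ib <- which(assignment == nets[b])
      if (a == b) {
        if (length(ia) < 2) next  # single-component network: masked
        pairs <- utils::combn(ia, 2)
        vals <- z[t(pairs)]
      } else {
        vals <- z[as.matrix(expand.grid(ia, ib))]
      }
      out[a, b] <- out[b, a] <- mean(vals)
    }
  }
  out
}

#' Network-level static connectivity for a cohort
#'
#' @param sfnc_tbl Output of [sfnc()].
#' @param assignment Component-to-network map (default [default_networks()]).
#' @return Tibble with a `domain` list-column of N x N matrices.
#' @export
sfnc_domain <- function(sfnc_tbl, assignment = default_networks()) {
  sfnc_tbl %>%
    mutate(domain = map(.data$sfnc, domain_aggregate, assignment = assignment))
}

#' @export
tidy.sfnc_tbl <- function(x, ...) {
  ids <- colnames(x$sfnc[[1]])
  if (is.null(ids)) ids <- sprintf("IC%02d", seq_len(nrow(x$sfnc[[1]])))
  x %>%
    select("subject_id", dplyr::any_of("group"), "sfnc") %>%
    mutate(long = map(.data$sfnc, function(m) {
      idx <- which(upper.tri(m), arr.ind = TRUE)
      tibble(comp_a = ids[idx[, 1]], comp_b = ids[idx[, 2]],
             z = m[idx])
    })) %>%
    select(!"sfnc") %>%
    tidyr::unnest("long")
}
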