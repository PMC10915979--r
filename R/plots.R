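# ggplot2 display helpers. Matrices are drawn as lower/upper-symmetric
# heatmaps on the Fisher-z scale with a diverging palette.

.matrix_long <- function(m, ids = NULL) {
  C <- nrow(m)
  if (is.null(ids)) ids <- colnames(m)
  if (is.null(ids)) ids <- sprintf("IC%02d", seq_len(C))
  idx <- expand.grid(row = seq_len(C), col = seq_len(C))
  tibble(comp_a = factor(ids[idx$row], levels = ids),
         comp_b = factor(ids[idx$col], levels = rev(ids)),
         value = m[as.matrix(idx)])
}

.fc_fill <- function(limit) {
  scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                       midpoint = 0, limits = c(-limit, limit),
                       na.value = "grey85", name = "z")
}

#' Heatmap of one connectivity matrix
#'
#' @param m C x C matrix (Fisher-z scale, `NA` diagonal allowed).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_fc_matrix <- function(m, title = NULL) {
  d <- .matrix_long(m)
  lim <- max(abs(d$value), na.rm = TRUE)
  ggplot(d, aes(x = .data$comp_a, y = .data$comp_b, fill = .data$value)) +
    geom_tile() +
    .fc_fill(lim) +
    coord_fixed() +
    labs(title = title, x = NULL, y = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5))
}

#' @export
autoplot.state_model <- function(object, ...) {
  k <- object$k
  d <- bind_rows(lapply(seq_len(k), function(s) {
    .matrix_long(object$centroids[s, , ]) %>%
      mutate(state = sprintf("state %d", s))
  }))
  lim <- max(abs(d$value), na.rm = TRUE)
  ggplot(d, aes(x = .data$comp_a, y = .data$comp_b, fill = .data$value)) +
    geom_tile() +
    .fc_fill(lim) +
    coord_fixed() +
    facet_wrap(~state) +
    labs(title = "State centroids", x = NULL, y = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5))
}

#' Temporal-property metrics by group and state
#'
#' @param metrics Tibble from [state_metrics()].
#' @param which One of `"fraction_time"`, `"mean_dwell_time"`.
#' @return A ggplot object (boxplots per state, filled by group).
#' @export
plot_state_metrics <- function(metrics,
                               which = c("fraction_time", "mean_dwell_time")) {
  which <- match.arg(which)
  ggplot(metrics, aes(x = factor(.data$state), y = .data[[which]],
                      fill = .data$group)) +
    geom_boxplot(outlier.size = 0.6) +
    labs(x = "state", y = gsub("_", " ", which)) +
    theme_minimal()
}

#' @export
autoplot.variability_tbl <- function(object, ...) {
  ggplot(object, aes(x = .data$component, y = .data$V,
                     fill = .data$group)) +
    geom_boxplot(outlier.size = 0.6) +
    labs(x = NULL, y = "temporal variability V") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5))
}

#' Elbow curve from [select_k_elbow()]
#'
#' @param curve Tibble with columns `k` and `index`.
#' @param chosen Optional chosen k to highlight.
#' @return A ggplot object.
#' @export
plot_elbow_curve <- function(curve, chosen = NULL) {
  p <- ggplot(curve, aes(x = .data$k, y = .data$index)) +
    geom_line() + geom_point() +
    labs(x = "number of states k", y = "within / between dispersion") +
    theme_minimal()
  if (!is.null(chosen)) {
    p <- p + geom_vline(xintercept = chosen, linetype = "dashed",
                        colour = "#B2182B")
  }
  p
}
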