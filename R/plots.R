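#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-joint affected rates
#'
#' Bar chart of affected rates over the 28 joints in canonical order,
#' coloured by joint group.
#'
#' @param object A `joint_profile` from [affected_rates()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.joint_profile <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(joint = factor(.data$joint, levels = .data$joint))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$joint, y = .data$rate,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "affected rate", fill = "joint group",
      title = sprintf("Affected rate per joint (%s), n = %d patients",
                      attr(object, "symptom"), attr(object, "n_patients"))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Heatmap of the pairwise kappa matrix
#'
#' @param object A `kappa_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kappa_matrix <- function(object, ...) {
  m <- unclass(object)
  lv <- rownames(m)
  df <- tibble::as_tibble(m, rownames = "joint_a") |>
    tidyr::pivot_longer(-"joint_a", names_to = "joint_b",
                        values_to = "kappa") |>
    dplyr::mutate(joint_a = factor(.data$joint_a, levels = lv),
                  joint_b = factor(.data$joint_b, levels = rev(lv)))
  ggplot2::ggplot(df, ggplot2::aes(.data$joint_a, .data$joint_b,
                                   fill = .data$kappa)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 na.value = "grey85", limits = c(0, 1),
                                 oob = scales_squish) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Pairwise kappa (%s)",
                                  attr(object, "symptom"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

# clamp out-of-range fill values into the limits (avoids Suggests: scales)
scales_squish <- function(x, range = c(0, 1), ...) {
  pmin(pmax(x, range[1]), range[2])
}

#' Scatter plot of joint loadings on the first two components
#'
#' @param object A `joint_embedding`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.joint_embedding <- function(object, ...) {
  df <- object$loadings
  pct <- 100 * object$explained[1:2] / sum(object$explained)
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$joint), size = 2.5,
                       vjust = -0.8, show.legend = FALSE) +
    ggplot2::labs(
      x = sprintf("component 1 (%.1f%%)", pct[1]),
      y = sprintf("component 2 (%.1f%%)", pct[2]),
      colour = "joint group",
      title = sprintf("Joint embedding (%s, %s)", object$symptom,
                      object$joint_subset)
    ) +
    ggplot2::theme_minimal()
}

#' Plot subgroup profiles of a fitted model
#'
#' Bar chart of the mean group affected rates per subgroup, annotated with
#' each subgroup's share of evaluations.
#'
#' @param object A `subgroup_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.subgroup_model <- function(object, ...) {
  df <- characterize(object) |>
    tidyr::pivot_longer(dplyr::all_of(joint_group_levels()),
                        names_to = "group", values_to = "mean_rate") |>
    dplyr::mutate(
      subgroup = factor(sprintf("%d (%.1f%%)", .data$subgroup,
                                100 * .data$share),
                        levels = sprintf("%d (%.1f%%)",
                                         characterize(object)$subgroup,
                                         100 * characterize(object)$share))
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$mean_rate,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$subgroup)) +
    ggplot2::labs(x = NULL, y = "mean group affected rate (0-2)",
                  title = "Subgroup profiles (share of evaluations)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
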