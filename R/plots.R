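#' Mutation burden by DNA-repair variant status
#'
#' Box-and-jitter plot of per-sample mutation counts split by the presence
#' of a deleterious HR/MMR/POLE variant.
#'
#' @param status Tibble from [classify_repair()].
#' @param log_scale Show the count axis on log10.
#' @return A ggplot object.
#' @export
plot_burden <- function(status, log_scale = TRUE) {
  df <- mutate(status,
               carrier = factor(ifelse(.data$any_variant, "variant",
                                       "wild-type"),
                                levels = c("wild-type", "variant")))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$carrier, y = .data$tmb)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "DNA repair gene status", y = "mutation count") +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Co-infiltration correlation heat map
#'
#' @param co Tibble from [coinfiltration_matrix()].
#' @return A ggplot tile plot of the pairwise phi coefficients.
#' @export
plot_coinfiltration <- function(co) {
  sym <- bind_rows(co,
                   rename(co, cell_type_1 = "cell_type_2",
                          cell_type_2 = "cell_type_1"))
  ggplot2::ggplot(sym, ggplot2::aes(x = .data$cell_type_1,
                                    y = .data$cell_type_2,
                                    fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1),
                                  na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "phi") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Volcano plot of a differential-expression signature
#'
#' @param sig Tibble from [signature_table()].
#' @param q_cut Highlight genes at or below this q-value.
#' @return A ggplot object (mean difference vs -log10 q).
#' @export
plot_volcano <- function(sig, q_cut = 0.10) {
  df <- filter(sig, !is.na(.data$q))
  df$hit <- df$q <= q_cut
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = -log10(.data$q),
                                   color = .data$hit)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey50",
                                           `TRUE` = "#B2182B"),
                                guide = "none") +
    ggplot2::geom_hline(yintercept = -log10(q_cut), linetype = 2) +
    ggplot2::labs(x = "mean difference (high - low)",
                  y = expression(-log[10] ~ q)) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot for a fitted survival contrast
#'
#' @param object A `km_fit` from [km_logrank_hr()].
#' @param ... Unused.
#' @return A ggplot step-function survival plot annotated with the
#'   log-rank p-value.
#' @export
autoplot.km_fit <- function(object, ...) {
  curves <- tidy(object)
  anchor <- curves |> group_by(.data$group) |>
    summarise(time = 0, estimate = 1, .groups = "drop")
  df <- bind_rows(anchor, curves[c("group", "time", "estimate")]) |>
    arrange(.data$group, .data$time)
  lab <- sprintf("log-rank p = %.3g", object$logrank$p)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$estimate,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::annotate("text", x = max(df$time) * 0.7, y = 0.95,
                      label = lab, hjust = 0) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability",
                  color = NULL) +
    ggplot2::theme_minimal()
}
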