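# ggplot2 views of the main result types.

#' @export
autoplot.confrl_timecourses <- function(object, ...) {
  stopifnot(!is.null(object$values))
  ggplot2::ggplot(
    dplyr::filter(object$values, .data$n2 > 0),
    ggplot2::aes(x = .data$time, y = .data$v_bar,
                 colour = factor(.data$value_rank))
  ) +
    ggplot2::geom_vline(xintercept = -0.5, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::facet_grid(n2 ~ n1, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "trial (0 = first no-feedback trial)",
                  y = "expected value (EUR)", colour = "CS value rank") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.confrl_comparison <- function(object, ...) {
  ggplot2::ggplot(
    object$summary,
    ggplot2::aes(x = stats::reorder(.data$model, .data$mean),
                 y = .data$mean)
  ) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = paste("mean", toupper(object$criterion))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.confrl_confusion <- function(object,
                                      which = c("p_fit_given_gen",
                                                "p_gen_given_fit"), ...) {
  which <- match.arg(which)
  m <- object[[which]]
  df <- tibble::as_tibble(as.table(m), .name_repair = "minimal")
  names(df) <- c("row", "col", "p")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$p)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev(rownames(m))) +
    ggplot2::labs(
      x = if (which == "p_fit_given_gen") "best-fitting model" else
        "generative model",
      y = if (which == "p_fit_given_gen") "generative model" else
        "best-fitting model",
      fill = "p"
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of a generative-performance sweep
#'
#' @param sweep A tibble from [run_generative_sweep()].
#' @return A ggplot object: one bar per sweep node, faceted by effect.
#' @export
plot_effect_sweep <- function(sweep) {
  swept <- setdiff(names(sweep), c("effect", "estimate", "sem", "n"))
  sweep$node <- do.call(paste, c(lapply(swept, function(p) {
    paste0(p, "=", signif(sweep[[p]], 2))
  }), sep = "\n"))
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$node, y = .data$estimate)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$estimate - 2 * .data$sem,
                   ymax = .data$estimate + 2 * .data$sem),
      width = 0.2
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~effect, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "effect estimate (+/- 2 SEM)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 6))
}
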