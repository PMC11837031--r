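#' Plot methods
#'
#' `autoplot.idp_screen()` draws the conventional association overview: one
#' point per IDP and outcome, signed standardised effect on the y axis,
#' grouped by modality, with hierarchically-significant IDPs filled.
#'
#' `autoplot.dse_result()` draws the per-transition fast (D) and slow (S)
#' variance shares over time with the global shares in the subtitle; spikes
#' show up as D peaks, residual structured noise as a high S band.
#'
#' `autoplot.flag_report()` shows flagged versus clean scan counts per
#' modality.
#'
#' @param object An `idp_screen`, `dse_result` or `flag_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-idpscreen
NULL

#' @rdname autoplot-idpscreen
#' @exportS3Method ggplot2::autoplot
autoplot.idp_screen <- function(object, ...) {
  df <- dplyr::mutate(object$results,
                      significant = dplyr::coalesce(.data$rejected, FALSE))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$modality, y = .data$beta)) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$modality,
                                      alpha = .data$significant),
                         width = 0.25, height = 0) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.25, `TRUE` = 1)) +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "standardised effect (per SD of IDP)",
                  alpha = "significant",
                  title = sprintf("IDP association screen (q = %g)",
                                  object$q)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname autoplot-idpscreen
#' @exportS3Method ggplot2::autoplot
autoplot.dse_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$transitions, c("pct_d", "pct_s"),
                            names_to = "component", values_to = "pct") |>
    dplyr::mutate(component = dplyr::recode(.data$component,
                                            pct_d = "fast (D)",
                                            pct_s = "slow (S)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$pct,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 50, linetype = 3) +
    ggplot2::labs(
      x = "transition (t to t+1)", y = "% of mean A-var",
      title = "DSE variance decomposition",
      subtitle = sprintf("global %%D = %.1f, %%S = %.1f, %%E = %.1f",
                         object$global["pct_d"], object$global["pct_s"],
                         object$global["pct_e"])) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-idpscreen
#' @exportS3Method ggplot2::autoplot
autoplot.flag_report <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::count(.data$modality, .data$flagged)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$modality, y = .data$n,
                                   fill = .data$flagged)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "scans", fill = "flagged",
                  title = "IQR outlier flagging") +
    ggplot2::theme_minimal()
}
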