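#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a growth simulation
#'
#' Four-panel summary of a [simulate_growth()] run: canopy assimilation,
#' carbon reserve pool, shoot structural carbon and the water stress factor
#' over time.
#'
#' @param object A `growth_simulation`.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @exportS3Method ggplot2::autoplot
autoplot.growth_simulation <- function(object, ...) {
  ts <- object$timeseries |>
    dplyr::select("time", "A_canopy", "C_p", "shoot_C", "S_w") |>
    tidyr::pivot_longer(-"time", names_to = "quantity", values_to = "value") |>
    dplyr::mutate(quantity = factor(.data$quantity,
      levels = c("A_canopy", "C_p", "shoot_C", "S_w"),
      labels = c(
        "Canopy assimilation (umol/m2/s)", "Carbon reserves (g C)",
        "Shoot structural carbon (g C)", "Water stress factor"
      )
    ))
  ggplot2::ggplot(ts, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8", linewidth = 0.3) +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Time (d)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot leaf response curves
#'
#' Assimilation and its carbon- and light-limited components along a
#' [leaf_response_curve()] transect.
#'
#' @param curve Output of [leaf_response_curve()].
#' @return A `ggplot` object.
#' @export
plot_response_curve <- function(curve) {
  xvar <- intersect(c("I_s", "C_A"), names(curve))[1]
  long <- curve |>
    dplyr::select(dplyr::all_of(xvar), "A", "A_c", "A_j") |>
    tidyr::pivot_longer(-dplyr::all_of(xvar),
      names_to = "rate",
      values_to = "value"
    )
  ggplot2::ggplot(long, ggplot2::aes(.data[[xvar]], .data$value,
    colour = .data$rate, linetype = .data$rate
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = if (xvar == "I_s") "Irradiance (W/m2)" else "Atmospheric CO2 (umol/mol)",
      y = "Assimilation (umol/m2/s)", colour = NULL, linetype = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot phene interaction results
#'
#' Expected (additive-null) versus actual responses with standard-error
#' bars, coloured by interaction class.
#'
#' @param interactions Output of [phene_interactions()].
#' @return A `ggplot` object.
#' @export
plot_phene_interactions <- function(interactions) {
  long <- interactions |>
    dplyr::select("phenotype", "label", "actual", "actual_se", "expected",
      "expected_se") |>
    tidyr::pivot_longer(c("actual", "expected"),
      names_to = "kind",
      values_to = "biomass"
    ) |>
    dplyr::mutate(se = ifelse(.data$kind == "actual", .data$actual_se,
      .data$expected_se
    ))
  ggplot2::ggplot(long, ggplot2::aes(.data$phenotype, .data$biomass,
    fill = .data$kind
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$biomass - .data$se,
        ymax = .data$biomass + .data$se
      ),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "Shoot biomass (g)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
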