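#' Canonical phenotype label for a set of phene states
#'
#' Multi-phene phenotypes are labelled by their sorted phene states joined
#' with `"+"`, so `"steeper+fewer_axials"` and `"fewer_axials+steeper"`
#' refer to the same phenotype.
#'
#' @param phenes Character vector of single-phene state labels.
#' @return A single canonical label.
#' @export
phene_label <- function(phenes) {
  paste(sort(unique(phenes)), collapse = "+")
}

# per-phenotype mean, variance and replicate count
phene_summary <- function(data) {
  stopifnot(
    is.data.frame(data),
    all(c("phenotype", "biomass") %in% names(data))
  )
  out <- data |>
    dplyr::group_by(.data$phenotype) |>
    dplyr::summarise(
      mean = mean(.data$biomass),
      var = stats::var(.data$biomass),
      n = dplyr::n(),
      .groups = "drop"
    )
  if (any(out$n < 2)) {
    stop("every phenotype needs at least 2 replicates for variance estimation",
      call. = FALSE
    )
  }
  out
}

#' Expected response of a phene combination under the additive null model
#'
#' The additive null expectation for a combination of phene states is the
#' reference phenotype's mean response plus the sum of the single-phene
#' deltas (each single-phene mean minus the reference mean). Its variance is
#' the sum of the variances of the summands — each delta contributes
#' `var(single) + var(reference)` and the baseline contributes
#' `var(reference)` — and the standard error divides by the replicate count
#' (`n = 5` in the source simulations; here the table's own count).
#'
#' @param data Tidy table with columns `phenotype`, `replicate`, `biomass`
#'   (g); must contain the reference phenotype and every single-phene
#'   phenotype of the combination.
#' @param combo Character vector of single-phene state labels forming the
#'   combination.
#' @param reference Label of the reference phenotype.
#' @return A one-row tibble with `expected` (g), `se` (g), `var` and `n`.
#' @export
#' @examples
#' tbl <- synthetic_phene_table(
#'   effects = c(a = 2, b = 3),
#'   reference_mean = 10, sd = 0.5, n = 5, seed = 1
#' )
#' expected_additive(tbl, c("a", "b"))
expected_additive <- function(data, combo, reference = "reference") {
  smry <- phene_summary(data)
  if (!reference %in% smry$phenotype) {
    stop("reference phenotype '", reference, "' not found", call. = FALSE)
  }
  missing <- setdiff(combo, smry$phenotype)
  if (length(missing)) {
    stop("missing single-phene phenotype(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  ref <- smry[smry$phenotype == reference, ]
  singles <- smry[match(combo, smry$phenotype), ]
  k <- length(combo)
  expected <- ref$mean + sum(singles$mean - ref$mean)
  variance <- sum(singles$var) + (k + 1) * ref$var
  n <- min(c(ref$n, singles$n))
  tibble::tibble(
    expected = expected, se = sqrt(variance / n), var = variance, n = n
  )
}

#' Classify a phene interaction against the additive expectation
#'
#' The interaction strength is `100 * (actual - expected) / expected`
#' percent. The label is `"synergistic"` when the actual response
#' significantly exceeds the expectation, `"antagonistic"` when it falls
#' significantly short, and `"additive"` otherwise; significance is a
#' two-sided z-comparison on the propagated standard errors at level
#' `alpha`.
#'
#' @param actual,expected Mean responses (g); `expected` must be positive.
#' @param actual_se,expected_se Standard errors of the two means.
#' @param alpha Significance level of the gate.
#' @return A one-row tibble with `percent`, `z`, `p_value`, `significant`
#'   and `label`.
#' @export
classify_interaction <- function(actual, expected, actual_se = 0,
                                 expected_se = 0, alpha = 0.05) {
  if (expected <= 0) {
    stop("expected response must be positive to express a percent deviation",
      call. = FALSE
    )
  }
  stopifnot(actual > 0)
  percent <- 100 * (actual - expected) / expected
  se <- sqrt(actual_se^2 + expected_se^2)
  z <- if (se > 0) (actual - expected) / se else ifelse(actual == expected, 0, Inf * sign(actual - expected))
  p <- 2 * stats::pnorm(-abs(z))
  significant <- is.finite(z) && p < alpha || is.infinite(z)
  label <- if (!significant || actual == expected) {
    "additive"
  } else if (actual > expected) {
    "synergistic"
  } else {
    "antagonistic"
  }
  tibble::tibble(
    percent = percent, z = z, p_value = p,
    significant = significant, label = label
  )
}

#' Phene interaction analysis over a phenotype-biomass table
#'
#' For every multi-phene phenotype in the table (label containing `"+"`), or
#' for an explicit list of combinations, computes the additive-null expected
#' response ([expected_additive()]), the actual mean response, and the
#' interaction classification ([classify_interaction()]).
#'
#' @inheritParams expected_additive
#' @param combos Optional list of character vectors of phene states; by
#'   default every `"+"`-labelled phenotype present in the table.
#' @param alpha Significance level for the interaction gate.
#' @return A tibble with one row per combination: `phenotype`, `actual`,
#'   `actual_se`, `expected`, `expected_se`, `percent`, `z`, `p_value`,
#'   `significant`, `label`.
#' @export
phene_interactions <- function(data, combos = NULL, reference = "reference",
                               alpha = 0.05) {
  smry <- phene_summary(data)
  if (is.null(combos)) {
    labels <- grep("+", setdiff(smry$phenotype, reference),
      fixed = TRUE,
      value = TRUE
    )
    combos <- strsplit(labels, "+", fixed = TRUE)
  }
  rows <- purrr::map(combos, function(combo) {
    lab <- phene_label(combo)
    exp_row <- expected_additive(data, combo, reference = reference)
    act <- smry[smry$phenotype == lab, ]
    if (nrow(act) == 0) {
      stop("no replicates found for combination phenotype '", lab, "'",
        call. = FALSE
      )
    }
    cls <- classify_interaction(act$mean, exp_row$expected,
      actual_se = sqrt(act$var / act$n),
      expected_se = exp_row$se, alpha = alpha
    )
    dplyr::bind_cols(
      tibble::tibble(
        phenotype = lab, actual = act$mean,
        actual_se = sqrt(act$var / act$n),
        expected = exp_row$expected, expected_se = exp_row$se
      ),
      cls
    )
  })
  dplyr::bind_rows(rows)
}

#' Deep-soil carbon deposition per hectare
#'
#' Converts an increase in carbon deposited per plant into per-hectare
#' carbon and CO2-equivalent masses:
#' `kg C/ha = g/plant * plants/m^2 * 10^4 m^2/ha / 10^3 g/kg` and
#' `kg CO2/ha = kg C/ha * 44/12`.
#'
#' @param delta_g_per_plant Additional carbon per plant (g).
#' @param density Planting density (plants m^-2).
#' @return A tibble with `kg_C_ha` and `kg_CO2_ha`.
#' @export
#' @examples
#' carbon_per_hectare(0.3, 8)
carbon_per_hectare <- function(delta_g_per_plant, density) {
  stopifnot(delta_g_per_plant >= 0, density > 0)
  kg_C <- delta_g_per_plant * density * 1e4 / 1e3
  tibble::tibble(kg_C_ha = kg_C, kg_CO2_ha = kg_C * 44 / 12)
}

#' Synthetic phenotype-biomass table with additive true effects
#'
#' Builds a replicate table for a reference phenotype, each single-phene
#' phenotype, and every phenotype named in `combos` (default: the full
#' combination of all phenes), drawing replicates from normal distributions
#' whose means are exactly additive: the combination mean is the reference
#' mean plus the sum of the single-phene effects, optionally shifted by a
#' true `interaction` (g) to emulate synergism or antagonism.
#'
#' @param effects Named numeric vector of single-phene effects (g).
#' @param reference_mean Reference phenotype mean biomass (g).
#' @param sd Replicate standard deviation (g).
#' @param n Replicates per phenotype.
#' @param combos Optional list of character vectors (subsets of
#'   `names(effects)`).
#' @param interaction True deviation from additivity added to every
#'   combination mean (g).
#' @param seed Optional integer seed.
#' @return A tidy tibble with `phenotype`, `replicate`, `biomass`.
#' @export
synthetic_phene_table <- function(effects, reference_mean = 10, sd = 0.5,
                                  n = 5, combos = NULL, interaction = 0,
                                  seed = NULL) {
  stopifnot(length(effects) >= 1, !is.null(names(effects)), n >= 2)
  if (!is.null(seed)) set.seed(seed)
  combos <- combos %||% list(names(effects))
  draw <- function(label, mu) {
    tibble::tibble(
      phenotype = label, replicate = seq_len(n),
      biomass = stats::rnorm(n, mu, sd)
    )
  }
  rows <- list(draw("reference", reference_mean))
  for (nm in names(effects)) {
    rows <- c(rows, list(draw(nm, reference_mean + effects[[nm]])))
  }
  for (combo in combos) {
    stopifnot(all(combo %in% names(effects)))
    mu <- reference_mean + sum(effects[combo]) + interaction
    rows <- c(rows, list(draw(phene_label(combo), mu)))
  }
  dplyr::bind_rows(rows)
}
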