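#' Predict oxygen kinetics for a table of proteins
#'
#' The end-to-end per-protein model: combines the three tunnel migration
#' probabilities, the water-displacement equilibrium from the hydrogen-bond
#' count, and the excess oxygen stabilization into kon, koff and p50 with
#' their categorical classes.
#'
#' @param data a data frame with one row per protein and columns
#'   `id`, `k_LT`, `k_STG8`, `k_E7G` (tunnel migration probabilities in
#'   \[0, 1\]), `n_hbonds` (protein-water hydrogen bonds), `ddE_O2`
#'   (excess oxygen stabilization, kcal/mol) and optionally
#'   `hexacoordinated` (logical).
#' @param constants a [kinetic_constants()] list.
#' @return The input tibble with added columns `KH2O`, `k_tunnels`, `kon`
#'   (M^-1 s^-1), `koff` (s^-1), `p50` (mmHg), `affinity_class`,
#'   `koff_class` and `kon_is_upper_bound` (TRUE for hexacoordinated
#'   proteins, whose 6c state competes with ligand binding).
#' @examples
#' tbl <- tibble::tibble(id = "demo", k_LT = 0.5, k_STG8 = 0, k_E7G = 0,
#'                       n_hbonds = 2, ddE_O2 = 6)
#' predict_rates(tbl)
#' @export
predict_rates <- function(data, constants = kinetic_constants()) {
  need <- c("id", "k_LT", "k_STG8", "k_E7G", "n_hbonds", "ddE_O2")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop_data(paste0("missing required columns: ", paste(miss, collapse = ", ")))
  out <- as_tibble(data)
  if (!"hexacoordinated" %in% names(out)) out$hexacoordinated <- FALSE
  out$hexacoordinated[is.na(out$hexacoordinated)] <- FALSE
  out <- out |>
    mutate(
      k_tunnels = combine_tunnels(.data$k_LT, .data$k_STG8, .data$k_E7G),
      KH2O = water_equilibrium(.data$n_hbonds, constants),
      kon = association_rate(.data$k_tunnels, .data$KH2O, constants),
      koff = dissociation_rate(.data$ddE_O2, constants),
      p50 = ifelse(.data$kon > 0,
                   .data$koff / (.data$kon * constants$o2_solubility), NA_real_),
      affinity_class = ifelse(is.na(.data$p50), NA_character_,
                              classify_affinity(.data$p50, constants)),
      koff_class = classify_koff(.data$koff, constants),
      kon_is_upper_bound = as.logical(.data$hexacoordinated)
    )
  out
}

#' Fit a validation regression of experimental against calculated rates
#'
#' Regresses experimental log10 rates on the model's calculated log10 rates,
#' the comparison behind the model's validation: full-model kon, koff, and
#' the tunnel-only kon predictor (kon/KH2O, i.e. dropping the water term)
#' whose weaker correlation shows the water displacement is a required
#' ingredient.
#'
#' @param data a data frame with the model input columns of
#'   [predict_rates()] plus `log10_kon_exp` (for `response = "kon"` or
#'   `"kon_tunnel_only"`) or `log10_koff_exp` (for `response = "koff"`).
#' @param response which comparison to fit.
#' @param constants a [kinetic_constants()] list.
#' @return An object of class `rate_validation`: the underlying `lm`,
#'   the per-protein tibble (`log10_exp`, `log10_calc`) and the response
#'   label. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
fit_rate_validation <- function(data,
                                response = c("kon", "koff", "kon_tunnel_only"),
                                constants = kinetic_constants()) {
  response <- match.arg(response)
  pred <- predict_rates(data, constants)
  if (response == "koff") {
    if (!"log10_koff_exp" %in% names(data))
      stop_data("need column log10_koff_exp for the koff validation")
    d <- tibble(id = pred$id,
                log10_exp = data$log10_koff_exp,
                log10_calc = log10(pred$koff))
  } else {
    if (!"log10_kon_exp" %in% names(data))
      stop_data("need column log10_kon_exp for the kon validation")
    calc <- if (response == "kon") pred$kon else pred$kon / pred$KH2O
    d <- tibble(id = pred$id,
                log10_exp = data$log10_kon_exp,
                log10_calc = log10(calc))
  }
  d <- d[is.finite(d$log10_calc) & is.finite(d$log10_exp), , drop = FALSE]
  if (nrow(d) < 3) stop_data("need at least 3 finite points for a validation fit")
  fit <- lm(log10_exp ~ log10_calc, data = d)
  structure(list(fit = fit, data = d, response = response),
            class = "rate_validation")
}

#' @export
print.rate_validation <- function(x, ...) {
  g <- glance(x)
  cat("<rate_validation> ", x$response, ": R^2 = ",
      round(g$r.squared, 3), " (n = ", g$n, ")\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_rate_validation
#' @param x a `rate_validation` object.
#' @param ... unused.
#' @export
tidy.rate_validation <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @rdname fit_rate_validation
#' @export
glance.rate_validation <- function(x, ...) {
  s <- summary(x$fit)
  tibble(response = x$response, r.squared = s$r.squared,
         adj.r.squared = s$adj.r.squared, sigma = s$sigma,
         n = nrow(x$data))
}

#' @rdname fit_rate_validation
#' @param object a `rate_validation` object.
#' @export
autoplot.rate_validation <- function(object, ...) {
  lab <- switch(object$response,
                kon = "log10 kon", koff = "log10 koff",
                kon_tunnel_only = "log10 kon (tunnel term only)")
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$log10_calc, y = .data$log10_exp)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = paste(lab, "(calculated)"),
                  y = paste(lab, "(experimental)"),
                  subtitle = sprintf("R² = %.2f",
                                     glance(object)$r.squared)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
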