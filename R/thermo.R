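# Gas constant in kcal mol^-1 K^-1.
.R_KCAL <- 1.987e-3

# Molar concentration of water (M), the aqueous-phase reference of the
# mole-fraction partition coefficient.
.WATER_MOLARITY <- 55.3

#' Membrane partition model for a tryptophan-fluorescence titration
#'
#' Relative fluorescence as a function of total lipid:
#' `F/F0(L) = 1 + (F/F0max - 1) * Kx [L] / ([W] + Kx [L])`, with
#' `[L] = accessible_fraction * lipid_total` the accessible (outer
#' leaflet) lipid and `[W]` the molar concentration of water. Equals 1
#' at zero lipid and saturates at `f_max`.
#'
#' @param lipid_total total lipid concentration(s), molar.
#' @param k_x mole-fraction partition coefficient (> 0).
#' @param f_max saturating relative fluorescence (>= 1).
#' @param accessible_fraction accessible fraction of total lipid,
#'   default 0.6.
#' @param water molar concentration of water, default 55.3.
#' @return predicted F/F0 value(s).
#' @export
#' @examples
#' partition_model(1e-3, k_x = 2.3e6, f_max = 2.65)  # 2.586
partition_model <- function(lipid_total, k_x, f_max,
                            accessible_fraction = 0.6, water = 55.3) {
  if (k_x <= 0) stop("k_x must be > 0")
  if (f_max < 1) stop("f_max must be >= 1")
  if (accessible_fraction <= 0 || accessible_fraction > 1)
    stop("accessible_fraction must be in (0, 1]")
  if (any(lipid_total < 0)) stop("negative lipid concentration")
  L <- accessible_fraction * lipid_total
  1 + (f_max - 1) * k_x * L / (water + k_x * L)
}

#' Fit the membrane partition model to titration data
#'
#' Nonlinear least squares over `(k_x, f_max)` on all replicate points
#' (Levenberg-Marquardt, bounds `k_x` in `[1, 1e10]`, `f_max` in
#' `[1, 20]`; started from `k_x = [W] / median([L])` and the largest
#' observed F/F0). Standard errors come from the Jacobian. When the
#' predicted bound fraction never reaches 0.3 the fit is returned with a
#' low-confidence warning, since `k_x` and `f_max` are then poorly
#' separated (the classic non-saturating-titration caveat).
#'
#' @param data a [simulate_titration()] result, or any data.frame with
#'   columns `lipid_total` and `f_over_f0`.
#' @param accessible_fraction accessible lipid fraction; defaults to the
#'   data attribute, else 0.6.
#' @param temperature temperature in K for the free energy (default 293).
#' @param water molar water concentration (default 55.3).
#' @return object of class `partition_fit`: list with `k_x`, `f_max`,
#'   `k_x_se`, `f_max_se`, `delta_g` (kcal/mol), `temperature`,
#'   `residual_ss`, `low_confidence`, `fitted` (curve table).
#' @export
fit_partition <- function(data, accessible_fraction = NULL,
                          temperature = 293, water = 55.3) {
  if (is.null(accessible_fraction))
    accessible_fraction <- attr(data, "accessible_fraction") %||% 0.6
  conc <- data$lipid_total
  y <- data$f_over_f0
  if (length(unique(conc)) < 4L)
    stop("need >= 4 distinct lipid concentrations")
  if (min(conc) > 0.05 * max(conc))
    stop("need at least one concentration near zero")
  L <- accessible_fraction * conc
  start <- list(k_x = water / stats::median(L[L > 0]), f_max = max(y))
  fit <- minpack.lm::nlsLM(
    y ~ 1 + (f_max - 1) * k_x * L / (water + k_x * L),
    start = start,
    lower = c(k_x = 1, f_max = 1), upper = c(k_x = 1e10, f_max = 20),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!fit$convInfo$isConv)
    stop("partition fit did not converge; final residual sum of squares ",
         signif(sum(stats::residuals(fit)^2), 4))
  co <- summary(fit)$coefficients
  k_x <- co["k_x", "Estimate"]; f_max <- co["f_max", "Estimate"]
  bound_frac <- k_x * L / (water + k_x * L)
  low_conf <- max(bound_frac) < 0.3
  if (low_conf)
    warning("titration does not approach saturation (max bound fraction ",
            signif(max(bound_frac), 2), " < 0.3): k_x is a low-confidence ",
            "estimate")
  grid_L <- seq(0, max(conc), length.out = 100)
  out <- list(k_x = k_x, f_max = f_max,
              k_x_se = co["k_x", "Std. Error"],
              f_max_se = co["f_max", "Std. Error"],
              delta_g = delta_g(k_x, temperature),
              temperature = temperature,
              residual_ss = sum(stats::residuals(fit)^2),
              low_confidence = low_conf,
              fitted = data.frame(
                lipid_total = grid_L,
                f_over_f0 = partition_model(grid_L, k_x, f_max,
                                            accessible_fraction, water)))
  class(out) <- "partition_fit"
  out
}

#' @export
print.partition_fit <- function(x, ...) {
  cat(sprintf("<partition_fit> Kx = %.3g +/- %.2g, F/F0max = %.3g +/- %.2g, dG = %.2f kcal/mol (T = %g K)%s\n",
              x$k_x, x$k_x_se, x$f_max, x$f_max_se, x$delta_g,
              x$temperature,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard free energy of membrane partitioning
#'
#' `dG = -R T ln(k_x)` with `R = 1.987e-3` kcal/(mol K). The default
#' temperature of 293 K corresponds to the room-temperature fluorescence
#' measurements this quantity typically derives from.
#'
#' @param k_x mole-fraction partition coefficient (> 0).
#' @param temperature temperature in K.
#' @return free energy in kcal/mol.
#' @export
#' @examples
#' delta_g(2.3e6)  # about -8.5 kcal/mol
delta_g <- function(k_x, temperature = 293) {
  if (any(k_x <= 0)) stop("k_x must be > 0")
  -.R_KCAL * temperature * log(k_x)
}

#' Free-energy additivity analysis for bivalent toxins
#'
#' Compares the measured partitioning free energy of each bivalent
#' construct with the theoretical value assuming complete additivity of
#' its lobes' monovalent free energies. The penalty (measured minus
#' theoretical, kcal/mol) is positive when the tethered lobes partition
#' more weakly than the additive expectation.
#'
#' @param mono named numeric vector of monovalent lobe free energies
#'   (kcal/mol).
#' @param bivalent_measured named numeric vector of measured bivalent
#'   free energies (kcal/mol).
#' @param composition named list mapping each construct to its character
#'   vector of lobes.
#' @return data.frame with columns `construct`, `measured`,
#'   `theoretical`, `penalty`.
#' @export
#' @examples
#' bivalency_report(c(K1 = -7.5, K2 = -5.8),
#'                  c(DkTx = -8.5),
#'                  list(DkTx = c("K1", "K2")))
bivalency_report <- function(mono, bivalent_measured, composition) {
  constructs <- names(bivalent_measured)
  if (is.null(constructs)) stop("bivalent_measured must be named")
  theo <- vapply(constructs, function(cn) {
    lobes <- composition[[cn]]
    if (is.null(lobes)) stop("no composition for construct ", cn)
    if (!all(lobes %in% names(mono)))
      stop("construct ", cn, " references lobe(s) missing from mono: ",
           paste(setdiff(lobes, names(mono)), collapse = ", "))
    sum(mono[lobes])
  }, numeric(1))
  data.frame(construct = constructs,
             measured = unname(bivalent_measured),
             theoretical = unname(theo),
             penalty = unname(bivalent_measured - theo),
             row.names = NULL)
}

#' Hill dose-response model
#'
#' Normalised current as a function of toxin concentration:
#' `I = i_min + (i_max - i_min) / (1 + (k_d / conc)^s)`. At
#' `conc = k_d` the response is the midpoint `(i_min + i_max) / 2`; the
#' curve rises from `i_min` at zero to `i_max` at saturation.
#'
#' @param conc toxin concentration(s), molar (>= 0).
#' @param k_d apparent dissociation constant, molar (> 0).
#' @param s Hill coefficient (> 0).
#' @param i_min,i_max minimal and maximal normalised current.
#' @return response value(s).
#' @export
hill_model <- function(conc, k_d, s, i_min = 0, i_max = 1) {
  if (k_d <= 0 || s <= 0) stop("k_d and s must be > 0")
  if (any(conc < 0)) stop("negative concentration")
  ifelse(conc == 0, i_min, i_min + (i_max - i_min) / (1 + (k_d / conc)^s))
}

#' Fit the Hill equation to dose-response data
#'
#' Nonlinear least squares over `(k_d, s, i_min, i_max)`
#' (Levenberg-Marquardt), started from the concentration nearest
#' half-maximal response, `s = 1`, and the extreme observations.
#' Standard errors come from the Jacobian. When the responses never
#' span the transition (maximal response less than twice the minimal
#' one above baseline), the fitted `k_d` is flagged as a lower bound,
#' the convention for constructs too weak to titrate to saturation.
#'
#' @param data a [simulate_dose_response()] result, or any data.frame
#'   with columns `concentration` and `response`.
#' @return object of class `hill_fit`: list with `k_d`, `s`, `i_min`,
#'   `i_max`, standard errors, `residual_ss`, `k_d_is_lower_bound`, and
#'   a `fitted` curve table.
#' @export
fit_hill <- function(data) {
  conc <- data$concentration
  y <- data$response
  if (length(unique(conc)) < 4L) stop("need >= 4 concentrations")
  rng <- range(y)
  half <- mean(rng)
  start <- list(k_d = conc[which.min(abs(y - half))], s = 1,
                i_min = rng[1], i_max = rng[2])
  resid_fn <- function(p)
    y - (p["i_min"] + (p["i_max"] - p["i_min"]) /
           (1 + (p["k_d"] / conc)^p["s"]))
  fit <- minpack.lm::nls.lm(
    par = unlist(start), fn = resid_fn,
    lower = c(k_d = .Machine$double.eps, s = 0.05, i_min = -Inf,
              i_max = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!fit$info %in% 1:4)
    stop("Hill fit did not converge (", fit$message,
         "); final residual sum of squares ", signif(fit$deviance, 4))
  p <- fit$par
  # the Jacobian can be singular when the data barely constrain a
  # parameter (e.g. an unreached plateau); report NA errors then
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e)
                   stats::setNames(rep(NA_real_, length(p)), names(p)))
  span <- max(y) - min(y)
  transition_spanned <- max(y) >= 2 * min(y) || min(y) <= 0.05 * span
  if (!transition_spanned)
    warning("responses do not span the transition: k_d should be read ",
            "as a lower bound")
  grid_c <- exp(seq(log(min(conc[conc > 0])), log(max(conc)),
                    length.out = 100))
  out <- list(k_d = unname(p["k_d"]), s = unname(p["s"]),
              i_min = unname(p["i_min"]), i_max = unname(p["i_max"]),
              k_d_se = unname(se["k_d"]), s_se = unname(se["s"]),
              residual_ss = fit$deviance,
              k_d_is_lower_bound = !transition_spanned,
              fitted = data.frame(
                concentration = grid_c,
                response = hill_model(grid_c, p["k_d"], p["s"],
                                      p["i_min"], p["i_max"])))
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> K_D %s %.3g +/- %.2g M, s = %.2f +/- %.2g\n",
              if (x$k_d_is_lower_bound) ">" else "=",
              x$k_d, x$k_d_se, x$s, x$s_se))
  invisible(x)
}

#' Fractional dissociation ratio
#'
#' Current amplitude a fixed time after toxin removal divided by the
#' steady-state current amplitude in the presence of the toxin; near 1
#' for a toxin that stays bound, near 0 for one that dissociates.
#'
#' @param i_after current after toxin removal.
#' @param i_steady steady-state current in the toxin's presence (> 0).
#' @return ratio `i_after / i_steady`.
#' @export
fractional_dissociation <- function(i_after, i_steady) {
  if (any(i_steady <= 0)) stop("steady-state current must be > 0")
  i_after / i_steady
}
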