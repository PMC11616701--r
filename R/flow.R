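# Flow characterisation utilities: Carreau shear-thinning viscosity and the
# dimensionless numbers (Re, Wi, El) describing viscoelastic focusing.

#' Carreau model parameters
#'
#' @param eta0 zero-shear viscosity (Pa s).
#' @param eta_inf infinite-shear viscosity (Pa s), `<= eta0`.
#' @param lambda_c relaxation-time constant (s).
#' @param n_exp power-law index; in (0, 1] for shear-thinning fluids.
#' @return A `carreau_params` object.
#' @export
carreau_params <- function(eta0, eta_inf, lambda_c, n_exp) {
  stopifnot(eta0 >= eta_inf, eta_inf >= 0, lambda_c >= 0,
            n_exp > 0, n_exp <= 1)
  structure(list(eta0 = eta0, eta_inf = eta_inf, lambda_c = lambda_c,
                 n_exp = n_exp), class = "carreau_params")
}

#' @export
print.carreau_params <- function(x, ...) {
  cat(sprintf("carreau_params: eta0 = %.4g Pa s, eta_inf = %.4g Pa s, lambda = %.4g s, n = %.3f\n",
              x$eta0, x$eta_inf, x$lambda_c, x$n_exp))
  invisible(x)
}

#' Carreau viscosity at a shear rate
#'
#' \deqn{\eta(\dot\gamma) = \eta_\infty + (\eta_0 - \eta_\infty)
#'   [1 + (\lambda_c \dot\gamma)^2]^{(n-1)/2}}
#'
#' @param shear_rate shear rate(s), 1/s, >= 0.
#' @param params a [carreau_params()].
#' @return Viscosity in Pa s (monotone non-increasing in shear rate for
#'   n <= 1).
#' @export
carreau_viscosity <- function(shear_rate, params) {
  stopifnot(all(shear_rate >= 0))
  params$eta_inf + (params$eta0 - params$eta_inf) *
    (1 + (params$lambda_c * shear_rate)^2)^((params$n_exp - 1) / 2)
}

#' Fit Carreau parameters to rheology data
#'
#' Nonlinear least squares in log-viscosity space (Levenberg-Marquardt) with
#' bounds enforcing the parameter invariants. Requires at least 6 points
#' spanning at least 2 decades of shear rate. Effectively constant viscosity
#' data are returned directly as a Newtonian fluid (`n = 1`,
#' `eta0 = eta_inf`).
#'
#' @param shear_rates shear rates (1/s).
#' @param viscosities measured viscosities (Pa s).
#' @return List with `params` (a [carreau_params()]) and `diagnostics`
#'   (convergence flag, residual SD in log space, residuals).
#' @export
fit_carreau <- function(shear_rates, viscosities) {
  stopifnot(length(shear_rates) == length(viscosities))
  ok <- is.finite(shear_rates) & is.finite(viscosities) & shear_rates > 0 &
    viscosities > 0
  g <- shear_rates[ok]; v <- viscosities[ok]
  if (length(g) < 6) stop("need at least 6 valid (shear rate, viscosity) points")
  if (log10(max(g) / min(g)) < 2) {
    stop("shear rates must span at least 2 decades")
  }
  if (diff(range(v)) / mean(v) < 1e-6) {
    eta <- mean(v)
    return(list(params = carreau_params(eta, eta, 0, 1),
                diagnostics = list(converged = TRUE, newtonian = TRUE,
                                   sigma_log = 0, residuals = log(v) - log(eta))))
  }
  ord <- order(g)
  g <- g[ord]; v <- v[ord]
  # start values: plateaus from the extremes, knee near the mid-drop
  eta0_0 <- max(v); etainf_0 <- max(min(v) * 0.5, 1e-9)
  vmid <- (log(max(v)) + log(min(v))) / 2
  lam0 <- 1 / g[which.min(abs(log(v) - vmid))]
  dat <- data.frame(g = g, lv = log(v))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      lv ~ log(einf + delta * (1 + (lam * g)^2)^((nn - 1) / 2)),
      data = dat,
      start = list(einf = etainf_0, delta = eta0_0 - etainf_0,
                   lam = lam0, nn = 0.7),
      lower = c(einf = 0, delta = 0, lam = 0, nn = 1e-3),
      upper = c(einf = Inf, delta = Inf, lam = Inf, nn = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    stop("Carreau fit did not converge: ", conditionMessage(fit))
  }
  cf <- stats::coef(fit)
  params <- carreau_params(cf[["einf"]] + cf[["delta"]], cf[["einf"]],
                           cf[["lam"]], cf[["nn"]])
  res <- stats::resid(fit)
  list(params = params,
       diagnostics = list(converged = fit$convInfo$isConv %||% TRUE,
                          newtonian = FALSE,
                          sigma_log = sd(res), residuals = as.numeric(res)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flow condition for dimensionless-number characterisation
#'
#' @param density_kgm3 fluid density (kg/m^3); default 1080 (the density
#'   assumed for the viscoelastic carrier medium).
#' @param mean_velocity_mps mean velocity U (m/s).
#' @param channel_size_m channel characteristic size H (m).
#' @param relaxation_time_s fluid relaxation time lambda (s).
#' @return A `flow_condition` object.
#' @export
flow_condition <- function(mean_velocity_mps, channel_size_m,
                           relaxation_time_s = 0, density_kgm3 = 1080) {
  stopifnot(mean_velocity_mps > 0, channel_size_m > 0,
            relaxation_time_s >= 0, density_kgm3 > 0)
  structure(list(density_kgm3 = density_kgm3,
                 mean_velocity_mps = mean_velocity_mps,
                 channel_size_m = channel_size_m,
                 relaxation_time_s = relaxation_time_s),
            class = "flow_condition")
}

#' Reynolds, Weissenberg and elasticity numbers
#'
#' Conventions used here: `Re = rho U H / eta`, `Wi = lambda U / H`
#' (characteristic shear rate U/H), `El = Wi / Re`.
#'
#' @param cond a [flow_condition()].
#' @param viscosity fluid viscosity (Pa s, > 0), e.g. from
#'   [carreau_viscosity()] at the characteristic shear rate.
#' @return Named list `(Re, Wi, El)`.
#' @export
dimensionless_numbers <- function(cond, viscosity) {
  stopifnot(viscosity > 0)
  Re <- cond$density_kgm3 * cond$mean_velocity_mps * cond$channel_size_m /
    viscosity
  Wi <- cond$relaxation_time_s * cond$mean_velocity_mps / cond$channel_size_m
  list(Re = Re, Wi = Wi, El = Wi / Re)
}
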