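# Two-state equilibrium unfolding with the linear extrapolation model: the
# unfolding free energy depends linearly on denaturant, dG(x) = dG - m*x, and
# the observed CD signal is the population-weighted mixture of linear folded
# and unfolded baselines:
#
#   y(x) = [ b_f + m_f x + (b_u + m_u x) K(x) ] / [ 1 + K(x) ],
#   K(x) = exp(-(dG - m x) / (R T))
#
# The midpoint is C_m = dG / m, where the signal equals the mean of the two
# baselines. Also includes a single-exponential unfolding-kinetics fit with a
# dead-time flag for transitions too fast to resolve.

#' Gas constant in kcal/(K mol)
#' @export
R_KCAL <- 0.001987

#' Two-state unfolding signal
#'
#' @param x Denaturant concentration (M).
#' @param b_f,m_f Folded-baseline intercept and slope.
#' @param b_u,m_u Unfolded-baseline intercept and slope.
#' @param dG Unfolding free energy (kcal/mol) at x = 0.
#' @param m m-value (kcal mol^-1 M^-1).
#' @param T Temperature (K). @param R Gas constant (kcal K^-1 mol^-1).
#' @return Predicted signal.
#' @export
two_state_signal <- function(x, b_f, m_f, b_u, m_u, dG, m,
                             T = 298.15, R = R_KCAL) {
  K <- exp(-(dG - m * x) / (R * T))
  (b_f + m_f * x + (b_u + m_u * x) * K) / (1 + K)
}

default_two_state_start <- function(x, y, T, R) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  n <- length(x)
  lo <- lm(y[1:3] ~ x[1:3])
  hi <- lm(y[(n - 2):n] ~ x[(n - 2):n])
  b_f <- coef(lo)[1]; m_f <- coef(lo)[2]
  b_u <- coef(hi)[1]; m_u <- coef(hi)[2]
  mid <- ((b_f + m_f * x) + (b_u + m_u * x)) / 2
  s <- sign(y - mid)
  cross <- which(diff(s) != 0)
  Cm0 <- if (length(cross)) {
    i <- cross[1]
    d1 <- y[i] - mid[i]; d2 <- y[i + 1] - mid[i + 1]
    x[i] + (x[i + 1] - x[i]) * d1 / (d1 - d2)
  } else mean(range(x))
  # transition width between 25% and 75% unfolded spans 2*ln(3)*RT/m
  frac <- (y - (b_f + m_f * x)) / ((b_u + m_u * x) - (b_f + m_f * x))
  inb <- x[frac > 0.25 & frac < 0.75]
  width <- if (length(inb) >= 2) diff(range(inb)) else diff(range(x)) / 5
  m0 <- max(2 * log(3) * R * T / max(width, 1e-3), 0.2)
  list(b_f = unname(b_f), m_f = unname(m_f), b_u = unname(b_u),
       m_u = unname(m_u), dG = unname(m0 * Cm0), m = unname(m0))
}

#' Fit the two-state unfolding model to a denaturation curve
#'
#' Fits all six parameters (two linear baselines, dG and the m-value) by
#' Levenberg-Marquardt least squares, and reports the midpoint C_m = dG/m
#' with its standard deviation propagated from the (dG, m) covariance.
#' Default initial guesses: baselines from linear fits to the 3 lowest- and
#' 3 highest-x points, C_m from where the signal crosses the baseline
#' midpoint, and m from the width of the central transition. If the first
#' start fails, up to 5 jittered restarts are attempted.
#'
#' @param x Denaturant concentrations (M), >= 8 points spanning both
#'   baselines.
#' @param y CD signal (e.g. mdeg at 222 nm).
#' @param start Optional named list of initial values
#'   (`b_f`, `m_f`, `b_u`, `m_u`, `dG`, `m`).
#' @param T Temperature (K), default 298.15.
#' @param R Gas constant, default 0.001987 kcal/(K mol).
#' @return Object of class `two_state_fit`: estimates and standard deviations
#'   for the six parameters, plus `Cm`, `sd_Cm`, `T`, `R`, `residual_sd` and
#'   the underlying `nls` fit.
#' @export
fit_two_state <- function(x, y, start = NULL, T = 298.15, R = R_KCAL) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 8) stop("need >= 8 points spanning both baselines")
  if (any(x < 0)) stop("denaturant concentrations must be >= 0")
  if (is.null(start)) start <- default_two_state_start(x, y, T, R)

  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                     maxiter = 1024)
  d <- data.frame(x = x, y = y)
  one_fit <- function(st) minpack.lm::nlsLM(
    y ~ two_state_signal(x, b_f, m_f, b_u, m_u, dG, m, T = T, R = R),
    data = d, start = st, control = ctrl)

  fit <- tryCatch(one_fit(start), error = function(e) e)
  tries <- 0
  while (inherits(fit, "error") && tries < 5) {
    tries <- tries + 1
    jit <- lapply(start, function(v) v * (1 + 0.2 * (tries %% 2 * 2 - 1) *
                                            tries / 5) + 0.01 * tries)
    fit <- tryCatch(one_fit(jit), error = function(e) e)
  }
  if (inherits(fit, "error"))
    stop("two-state fit failed to converge: ", conditionMessage(fit))

  cf <- coef(fit)
  if (cf[["m"]] <= 0)
    stop("fit converged to non-positive m-value (", cf[["m"]],
         "); data may not span a transition")
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 6, 6,
                  dimnames = list(names(cf), names(cf))))
  sds <- sqrt(diag(vc))
  dG <- unname(cf[["dG"]]); m <- unname(cf[["m"]])
  Cm <- dG / m
  # error propagation with covariance: Cm = dG/m
  var_Cm <- (1 / m)^2 * vc["dG", "dG"] + (dG / m^2)^2 * vc["m", "m"] -
    2 * (1 / m) * (dG / m^2) * vc["dG", "m"]
  Cmin <- min(x); Cmax <- max(x)
  if (Cm < Cmin || Cm > Cmax)
    warning("fitted midpoint C_m = ", signif(Cm, 3),
            " M lies outside the sampled denaturant range; ",
            "parameters are poorly constrained")
  resid_sd <- sqrt(mean(residuals(fit)^2))
  amp <- abs((cf[["b_u"]] - cf[["b_f"]]) + (cf[["m_u"]] - cf[["m_f"]]) * Cm)
  if (amp <= 5 * resid_sd + 1e-6 * diff(range(y)))
    warning("folded and unfolded baselines coincide at the fitted midpoint: ",
            "no resolvable transition in the data")

  structure(c(as.list(cf),
              list(sd = sds, Cm = Cm,
                   sd_Cm = sqrt(max(var_Cm, 0)),
                   T = T, R = R,
                   residual_sd = resid_sd,
                   fit = fit)),
            class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf("Two-state unfolding fit: dG = %.3f +/- %.3f kcal/mol, m = %.3f +/- %.3f kcal/mol/M, Cm = %.3f +/- %.3f M\n",
              x$dG, x$sd[["dG"]], x$m, x$sd[["m"]], x$Cm, x$sd_Cm))
  invisible(x)
}

#' Fit unfolding kinetics after a denaturant spike
#'
#' Fits a single exponential \eqn{y(t) = y_\infty + \Delta y\, e^{-k_u t}} to
#' a CD trace recorded after mixing protein into concentrated denaturant.
#' When the fitted relaxation time 1/k_u is shorter than the instrument dead
#' time, or when no resolvable amplitude remains (trace already flat), the
#' transition happened within the dead time and `within_dead_time` is set.
#'
#' @param t Time (s), increasing. @param y CD signal.
#' @param dead_time Instrument dead time (s), > 0.
#' @return List with `k_u` (1/s, `NA` when unresolvable), `y_inf`,
#'   `amplitude`, `sd_k_u` and `within_dead_time`.
#' @export
fit_unfolding_kinetics <- function(t, y, dead_time) {
  if (length(t) < 10) stop("need >= 10 points")
  if (is.unsorted(t, strictly = FALSE)) stop("t must be increasing")
  if (!is.numeric(dead_time) || dead_time <= 0) stop("dead time must be > 0")

  noise <- sd(diff(y)) / sqrt(2)
  amp0 <- y[1] - y[length(y)]
  if (abs(amp0) <= 3 * max(noise, .Machine$double.eps))
    return(list(k_u = NA_real_, y_inf = mean(y), amplitude = 0,
                sd_k_u = NA_real_, within_dead_time = TRUE))
  st <- list(y_inf = y[length(y)], dy = amp0,
             k_u = 3 / max(diff(range(t)), 1e-9))
  fit <- tryCatch(minpack.lm::nlsLM(
    y ~ y_inf + dy * exp(-k_u * tt),
    data = list(y = y, tt = t - t[1]), start = st,
    control = minpack.lm::nls.lm.control(maxiter = 1000)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(k_u = NA_real_, y_inf = mean(y), amplitude = 0,
                sd_k_u = NA_real_, within_dead_time = TRUE))
  cf <- coef(fit)
  sdk <- tryCatch(sqrt(diag(vcov(fit)))[["k_u"]],
                  error = function(e) NA_real_)
  # largest excursion against the overall trend, compared with the noise
  overall <- sign(y[length(y)] - y[1])
  z <- overall * y
  if (max(cummax(z) - z) > 6 * max(noise, .Machine$double.eps))
    warning("trace is not monotone beyond noise")
  list(k_u = unname(cf[["k_u"]]), y_inf = unname(cf[["y_inf"]]),
       amplitude = unname(cf[["dy"]]), sd_k_u = sdk,
       within_dead_time = (1 / cf[["k_u"]]) < dead_time)
}
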