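# Proteolytic decay kinetics: the fraction of intact protein over digestion
# time is modeled as f(t) = A0 * exp(-k t), fit globally (one shared A0 and k)
# across biological replicates by nonlinear least squares. Parameter standard
# deviations are square roots of the diagonal of the covariance matrix at the
# optimum.

#' Globally fit a single-exponential decay to replicate time courses
#'
#' Fits \eqn{f(t) = A_0 e^{-kt}} by Levenberg-Marquardt least squares with a
#' single (A0, k) shared across all replicates. Because intensities are
#' pre-normalized to the undigested band, A0 is expected near 1; setting
#' `per_replicate_A0 = TRUE` instead floats one amplitude per replicate with
#' a shared k.
#'
#' @param data Data frame with columns `time_min`, `fraction_intact` and
#'   (optionally) `replicate`; replicates are pooled in the global fit.
#' @param per_replicate_A0 Float one A0 per replicate (shared k)?
#' @return Object of class `decay_fit`: list with `A0`, `k` (1/min),
#'   `sd_A0`, `sd_k`, `residual_sd`, `n_points`, `fit` (the `nls` object) and
#'   `per_replicate_A0` amplitudes when requested.
#' @export
fit_exponential_decay <- function(data, per_replicate_A0 = FALSE) {
  need <- c("time_min", "fraction_intact")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  if (any(data$time_min < 0)) stop("negative time values")
  n_times <- length(unique(data$time_min))
  if (n_times < 2) stop("need >= 2 distinct time points")
  if (n_times < 4)
    warning("only ", n_times, " distinct time points: the fit is exact or ",
            "near-exact and its uncertainties are not estimable")
  if (all(data$fraction_intact == 0)) stop("all fractions are zero")

  t <- data$time_min
  f <- data$fraction_intact
  # log-linear start from positive points
  pos <- f > 0
  st <- unname(coef(lm(log(f[pos]) ~ t[pos])))
  k0 <- max(-st[2], 1e-8)
  A0 <- exp(st[1])
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                     maxiter = 1000)

  if (per_replicate_A0) {
    if (!"replicate" %in% names(data))
      stop("per-replicate amplitudes need a 'replicate' column")
    rep_f <- factor(data$replicate)
    fit <- nls(fraction_intact ~ A[rep_f] * exp(-k * time_min),
               data = list(fraction_intact = f, time_min = t, rep_f = rep_f),
               start = list(A = rep(A0, nlevels(rep_f)), k = k0),
               algorithm = "port",
               control = list(maxiter = 500))
  } else {
    fit <- minpack.lm::nlsLM(fraction_intact ~ A0 * exp(-k * time_min),
                             data = data.frame(fraction_intact = f,
                                               time_min = t),
                             start = list(A0 = A0, k = k0), control = ctrl)
  }
  cf <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) NULL)
  sds <- if (is.null(vc)) rep(NA_real_, length(cf)) else sqrt(diag(vc))
  k_hat <- unname(cf[["k"]])
  if (k_hat <= 0) stop("fit converged to non-positive rate k = ", k_hat)

  structure(list(
    A0 = if (per_replicate_A0) unname(mean(cf[names(cf) != "k"]))
         else unname(cf[["A0"]]),
    k = k_hat,
    sd_A0 = if (per_replicate_A0) NA_real_ else unname(sds[["A0"]]),
    sd_k = unname(sds[["k"]]),
    replicate_A0 = if (per_replicate_A0) cf[names(cf) != "k"] else NULL,
    residual_sd = sqrt(mean(residuals(fit)^2)),
    n_points = length(t),
    fit = fit), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Exponential decay fit: A0 = %.4g +/- %.2g, k = %.4g +/- %.2g /min (n = %d)\n",
              x$A0, x$sd_A0, x$k, x$sd_k, x$n_points))
  invisible(x)
}

#' Pairwise decay-rate contrasts in orders of magnitude
#'
#' For every pair of fitted rates, reports log10(k_i / k_j) with the
#' uncertainty propagated from the fit standard deviations
#' (sd(log10 k) = sd(k) / (k ln 10), added in quadrature).
#'
#' @param fits Named list of `decay_fit` objects (>= 2).
#' @return Data frame with `a`, `b`, `log10_ratio`, `sd`.
#' @export
compare_rates <- function(fits) {
  if (length(fits) < 2) stop("need at least two fits")
  if (is.null(names(fits))) names(fits) <- paste0("fit", seq_along(fits))
  ks <- vapply(fits, function(f) f$k, numeric(1))
  sds <- vapply(fits, function(f) f$sd_k, numeric(1))
  sd_log <- sds / (ks * log(10))
  pairs <- combn(names(fits), 2)
  data.frame(
    a = pairs[1, ], b = pairs[2, ],
    log10_ratio = log10(ks[pairs[1, ]] / ks[pairs[2, ]]),
    sd = sqrt(sd_log[pairs[1, ]]^2 + sd_log[pairs[2, ]]^2),
    row.names = NULL)
}
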