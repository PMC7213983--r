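# Exponential decay and two-state unfolding fits

test_that("noiseless decay data recover the generating parameters", {
  d <- simulate_decay_data(k = 0.05, times = decay_times(0.05), seed = 1,
                           noise_sd = 0)
  fit <- fit_exponential_decay(d)
  expect_equal(fit$k, 0.05, tolerance = 1e-8)
  expect_equal(fit$A0, 1, tolerance = 1e-8)
})

test_that("two points (0,1) and (t*, 1/e) give k = 1/t* in closed form", {
  t_star <- 12
  d <- data.frame(time_min = c(0, t_star), fraction_intact = c(1, exp(-1)))
  fit <- suppressWarnings(fit_exponential_decay(d))
  expect_equal(fit$k, 1 / t_star, tolerance = 1e-8)
})

test_that("a seeded noisy global fit recovers k within 15%", {
  d <- simulate_decay_data(k = 0.1, times = decay_times(0.1), seed = 1234,
                           n_replicates = 3, noise_sd = 0.05)
  fit <- fit_exponential_decay(d)
  expect_lt(abs(fit$k / 0.1 - 1), 0.15)
})

test_that("the per-replicate-amplitude variant still shares one rate", {
  d <- simulate_decay_data(k = 0.1, times = decay_times(0.1), seed = 5,
                           n_replicates = 3, noise_sd = 0.05)
  fit <- fit_exponential_decay(d, per_replicate_A0 = TRUE)
  expect_length(fit$replicate_A0, 3)
  expect_lt(abs(fit$k / 0.1 - 1), 0.15)
})

test_that("degenerate decay inputs are rejected", {
  expect_error(fit_exponential_decay(
    data.frame(time_min = c(0, 1, 2, 3), fraction_intact = rep(0, 4))),
    "zero")
  expect_error(fit_exponential_decay(
    data.frame(time_min = -1:2, fraction_intact = exp(1:-2))), "negative")
})

test_that("recovery error and coverage behave across seeded simulations", {
  k <- 0.01
  rel_err <- numeric(50); covered <- logical(50)
  for (i in 1:50) {
    d <- simulate_decay_data(k, decay_times(k), seed = 7000 + i,
                             n_replicates = 3, noise_sd = 0.05)
    fit <- fit_exponential_decay(d)
    rel_err[i] <- abs(fit$k / k - 1)
    covered[i] <- abs(fit$k - k) <= 2 * fit$sd_k
  }
  expect_lt(median(rel_err), 0.1)
  expect_gte(mean(covered), 0.8)
})

test_that("rate contrasts are reported in orders of magnitude", {
  mk_fit <- function(k, sd_k) structure(list(k = k, sd_k = sd_k),
                                        class = "decay_fit")
  cmp <- compare_rates(list(fast = mk_fit(1, 0.01),
                            slow = mk_fit(0.001, 1e-5)))
  expect_equal(cmp$log10_ratio, 3)
  expect_equal(compare_rates(list(a = mk_fit(0.2, 0.01),
                                  b = mk_fit(0.2, 0.01)))$log10_ratio, 0)
  expect_error(compare_rates(list(mk_fit(1, 0.1))), "at least two")
})

test_that("noiseless two-state curves recover all six parameters", {
  truth <- list(b_f = -20, m_f = 0.1, b_u = -2, m_u = 0.05, dG = 8, m = 1.6)
  d <- simulate_denaturation(truth$dG, truth$m, seed = 1, noise_sd = 0)
  fit <- fit_two_state(d$x_molar, d$signal_mdeg)
  for (p in names(truth))
    expect_equal(fit[[p]], truth[[p]], tolerance = 1e-6)
  expect_equal(fit$Cm * fit$m, fit$dG, tolerance = 1e-9)
})

test_that("the model value at x = dG/m is the baseline midpoint", {
  x_mid <- 8 / 1.6
  y <- two_state_signal(x_mid, -20, 0.1, -2, 0.05, 8, 1.6)
  mid <- ((-20 + 0.1 * x_mid) + (-2 + 0.05 * x_mid)) / 2
  expect_equal(y, mid, tolerance = 1e-12)
})

test_that("thermodynamic parameters are invariant to affine y rescaling", {
  d <- simulate_denaturation(8, 1.6, seed = 2, noise_sd = 0.1)
  f1 <- fit_two_state(d$x_molar, d$signal_mdeg)
  f2 <- fit_two_state(d$x_molar, 3.7 * d$signal_mdeg + 11)
  expect_equal(f2$dG, f1$dG, tolerance = 1e-6)
  expect_equal(f2$m, f1$m, tolerance = 1e-6)
  expect_equal(f2$Cm, f1$Cm, tolerance = 1e-6)
  expect_equal(f2$b_f, 3.7 * f1$b_f + 11, tolerance = 1e-5)
})

test_that("a 4 kcal/mol stability difference shifts Cm by ddG/m", {
  m <- 1.6
  d1 <- simulate_denaturation(5, m, seed = 3, noise_sd = 0)
  d2 <- simulate_denaturation(9, m, seed = 3, noise_sd = 0,
                              x = seq(0, 9, by = 0.375))
  f1 <- fit_two_state(d1$x_molar, d1$signal_mdeg)
  f2 <- fit_two_state(d2$x_molar, d2$signal_mdeg)
  expect_lt(abs((f2$Cm - f1$Cm) - 4 / m) / (4 / m), 0.01)
})

test_that("reported sds match a finite-difference Hessian at the optimum", {
  d <- simulate_denaturation(8, 1.6, seed = 4, noise_sd = 0.15)
  fit <- fit_two_state(d$x_molar, d$signal_mdeg)
  pars <- unlist(fit[c("b_f", "m_f", "b_u", "m_u", "dG", "m")])
  ssr <- function(p) sum((d$signal_mdeg -
    two_state_signal(d$x_molar, p[1], p[2], p[3], p[4], p[5], p[6]))^2)
  np <- length(pars)
  H <- matrix(0, np, np)
  h <- pmax(abs(pars), 1) * 1e-4
  for (i in 1:np) for (j in 1:np) {
    e_i <- e_j <- rep(0, np); e_i[i] <- h[i]; e_j[j] <- h[j]
    H[i, j] <- (ssr(pars + e_i + e_j) - ssr(pars + e_i - e_j) -
                ssr(pars - e_i + e_j) + ssr(pars - e_i - e_j)) /
               (4 * h[i] * h[j])
  }
  sigma2 <- ssr(pars) / (nrow(d) - np)
  sd_fd <- sqrt(diag(sigma2 * solve(H / 2)))
  expect_equal(unname(fit$sd), sd_fd, tolerance = 0.1)
})

test_that("non-transition data raise an error or out-of-range warning", {
  x <- seq(0, 9, by = 0.375)
  y <- -20 + 0.1 * x   # pure folded baseline, no transition
  expect_condition(fit_two_state(x, y))
})

test_that("unfolding kinetics resolve slow rates and flag fast ones", {
  tr <- simulate_kinetic_trace(0.01, seed = 5, noise_sd = 0.05)
  fit <- fit_unfolding_kinetics(tr$t_s, tr$signal, dead_time = 10)
  expect_equal(fit$k_u, 0.01, tolerance = 0.05)
  expect_false(fit$within_dead_time)

  flat <- simulate_kinetic_trace(10, seed = 6, t = seq(0, 600, 2),
                                 noise_sd = 0.05)  # done before first point
  f2 <- fit_unfolding_kinetics(flat$t_s, flat$signal, dead_time = 10)
  expect_true(f2$within_dead_time)

  fast <- simulate_kinetic_trace(0.5, seed = 7, t = seq(0, 20, 0.1),
                                 noise_sd = 0)
  f3 <- fit_unfolding_kinetics(fast$t_s, fast$signal, dead_time = 10)
  expect_true(f3$within_dead_time)   # 1/k = 2 s < 10 s dead time
  expect_equal(f3$k_u, 0.5, tolerance = 1e-4)
})
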