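# Antimicrobial growth-inhibition and NF-kB reporter normalizations

canonical_growth <- function(seed = 11, noise_sd = 0) {
  simulate_growth(list(
    untreated = list(K = 0.8, r = 0.02, t_lag = 240),
    same = list(K = 0.8, r = 0.02, t_lag = 240, concentration_uM = 5),
    half = list(K = 0.4, r = 0.02, t_lag = 240, concentration_uM = 5),
    dead = list(K = 0, r = 0.02, t_lag = 240, concentration_uM = 5)),
    seed = seed, noise_sd = noise_sd)
}

test_that("growth inhibition returns 100/50/0 on the canonical cases", {
  gc <- canonical_growth()
  res <- growth_inhibition(gc, t_eval_hr = 12)   # saturation
  get <- function(trt) res$percent_of_untreated[res$treatment == trt]
  expect_equal(get("untreated"), 100)
  expect_equal(get("same"), 100, tolerance = 1e-9)
  expect_equal(get("dead"), 0, tolerance = 1e-9)
  expect_equal(get("half"), 50, tolerance = 1e-6)
})

test_that("halved carrying capacity reads as 50% +/- 1% under default noise", {
  res <- growth_inhibition(canonical_growth(seed = 12, noise_sd = 0.003),
                           t_eval_hr = 12)
  expect_lt(abs(res$percent_of_untreated[res$treatment == "half"] - 50), 1)
})

test_that("growth inhibition is invariant to a constant OD offset", {
  gc <- canonical_growth(seed = 13, noise_sd = 0.003)
  res1 <- growth_inhibition(gc, t_eval_hr = 7)
  gc$data$od600 <- gc$data$od600 + 0.25
  res2 <- growth_inhibition(gc, t_eval_hr = 7)
  expect_equal(res1$percent_of_untreated, res2$percent_of_untreated,
               tolerance = 1e-9)
})

test_that("evaluation times snap to the grid within half an interval only", {
  gc <- canonical_growth()
  expect_equal(unique(growth_inhibition(gc, t_eval_hr = 7.05)$t_eval_hr),
               7.05)  # 423 min -> nearest grid point 420 min, within 7.5
  expect_error(growth_inhibition(gc, t_eval_hr = 14), "grid")
})

test_that("absent growth signal is an error", {
  gc <- simulate_growth(list(untreated = list(K = 0, r = 0.02, t_lag = 240)),
                        seed = 14, noise_sd = 0)
  expect_error(growth_inhibition(gc, t_eval_hr = 7), "untreated - blank")
})

test_that("reporter anchors invert exactly without noise", {
  pl <- simulate_reporter_plate(c(mock = 0.05, mid = 0.5), seed = 15,
                                noise_cv = 0)
  res <- nfkb_induction(pl)
  get <- function(trt) res$induction[res$treatment == trt]
  expect_equal(get("LPS"), 1)
  expect_equal(get("LPS+PB"), 0)
  expect_equal(get("mid"), 0.5, tolerance = 1e-12)
  expect_equal(get("mock"), 0.05, tolerance = 1e-12)
})

test_that("induction is invariant to per-channel count rescaling", {
  pl <- simulate_reporter_plate(c(mock = 0.1), seed = 16, noise_cv = 0.05)
  res1 <- nfkb_induction(pl)
  pl2 <- pl
  pl2$firefly <- pl2$firefly * 7.3
  pl2$renilla <- pl2$renilla * 0.4
  res2 <- nfkb_induction(pl2)
  expect_equal(res1$induction, res2$induction, tolerance = 1e-12)
})

test_that("noisy plates recover true inductions within 2 SEM most of the time", {
  # 20 plates per run keep 2*SEM close to a 95% interval; at 3 plates the
  # small-sample t-width makes 2*SEM intervals undercover by design
  truth <- c(weak = 0.25, strong = 0.75)
  hits <- 0; runs <- 25
  for (i in seq_len(runs)) {
    res <- nfkb_induction(simulate_reporter_plate(truth, seed = 100 + i,
                                                  noise_cv = 0.05,
                                                  n_bio = 20))
    for (trt in names(truth)) {
      row <- res[res$treatment == trt, ]
      hits <- hits + (abs(row$induction - truth[[trt]]) <= 2 * row$sem)
    }
  }
  expect_gte(hits / (runs * length(truth)), 0.9)
})

test_that("a failed LPS positive control is an error", {
  pl <- simulate_reporter_plate(c(mock = 0), seed = 17, noise_cv = 0)
  swap <- pl$treatment == "LPS"
  pl$firefly[swap] <- pl$firefly[pl$treatment == "LPS+PB"] * 0.5
  expect_error(nfkb_induction(pl), "positive control")
  pl2 <- simulate_reporter_plate(c(mock = 0), seed = 18)
  pl2$renilla[1] <- 0
  expect_error(nfkb_induction(pl2), "renilla")
})

test_that("dose series are tidy, sorted and reject duplicates", {
  d <- data.frame(treatment = "hA8/A9",
                  concentration_uM = c(4, 0.8, 2),
                  response = c(20, 90, 55), sem = 1)
  out <- dose_series(d)
  expect_equal(out$concentration_uM, c(0.8, 2, 4))
  expect_equal(out$response, c(90, 55, 20))
  expect_error(dose_series(rbind(d, d[1, ])), "duplicate")
  expect_error(dose_series(list()), "no results")
  expect_error(dose_series(d[1, ]), ">= 2")
})

test_that("monotone synthetic dose-responses stay monotone end to end", {
  concs <- c(0.4, 0.8, 2, 4, 5)
  res <- lapply(concs, function(cc) {
    gc <- simulate_growth(list(
      untreated = list(K = 0.8, r = 0.02, t_lag = 240),
      treated = list(K = 0.8 * (1 - cc / 6), r = 0.02, t_lag = 240,
                     concentration_uM = cc)),
      seed = 200 + round(cc * 10), noise_sd = 0.002)
    out <- growth_inhibition(gc, t_eval_hr = 12)
    out[out$treatment == "treated", ]
  })
  tab <- dose_series(res)
  expect_equal(tab$concentration_uM, sort(concs))
  expect_true(all(diff(tab$response) < 0))
})
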