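# altAll construction and sequence difference counting

# posterior row with given probabilities on named states, rest spread evenly
post_row <- function(...) {
  p <- c(...)
  rest <- (1 - sum(p)) / (20 - length(p))
  v <- setNames(rep(rest, 20), aa_states())
  v[names(p)] <- p
  v
}

test_that("runner-up above the threshold is substituted, at it is not", {
  tab <- rbind(post_row(A = 0.70, C = 0.25),   # substituted
               post_row(A = 0.80, C = 0.20),   # boundary: strict, kept
               post_row(A = 0.75, C = 0.201))  # just above: substituted
  colnames(tab) <- aa_states()
  aa <- build_altall(tab)
  expect_equal(aa$ml_sequence, "AAA")
  expect_equal(aa$altall_sequence, "CAC")
  expect_equal(aa$substituted_sites, c(1L, 3L))
})

test_that("a 10-site table with three strong runner-ups gives 3 substitutions", {
  runner <- c(0.25, 0.21, 0.30)
  tab <- do.call(rbind, lapply(1:10, function(s) {
    if (s %in% c(2, 5, 9)) post_row(A = 0.6, D = runner[match(s, c(2, 5, 9))])
    else post_row(A = 0.8, D = 0.15)
  }))
  colnames(tab) <- aa_states()
  aa <- build_altall(tab)
  expect_equal(length(aa$substituted_sites), 3L)
  expect_equal(aa$substituted_sites, c(2L, 5L, 9L))
  expect_equal(count_differences(aa$ml_sequence, aa$altall_sequence), 3)
})

test_that("runner-up ties break to the alphabetically first state", {
  tab <- rbind(post_row(M = 0.5, A = 0.25, C = 0.25))
  colnames(tab) <- aa_states()
  aa <- build_altall(tab)
  expect_equal(aa$altall_sequence, "A")
})

test_that("difference count always equals the substituted-site list length", {
  set.seed(403)
  for (rep in 1:20) {
    L <- sample(5:30, 1)
    tab <- do.call(rbind, lapply(seq_len(L), function(s) {
      ml_p <- runif(1, 0.4, 0.95)
      post_row(A = ml_p, C = min(runif(1, 0, 0.4), 1 - ml_p))
    }))
    colnames(tab) <- aa_states()
    aa <- build_altall(tab)
    expect_equal(count_differences(aa$ml_sequence, aa$altall_sequence),
                 length(aa$substituted_sites))
  }
})

test_that("average posterior probability is the mean ML-state PP over sites", {
  tab <- rbind(post_row(A = 0.9), post_row(C = 0.7), post_row(D = 0.5))
  colnames(tab) <- aa_states()
  aa <- build_altall(tab)
  expect_equal(aa$average_pp, mean(c(0.9, 0.7, 0.5)))
})

test_that("non-normalized posterior rows are rejected with the site index", {
  tab <- rbind(post_row(A = 0.9), post_row(A = 0.9))
  colnames(tab) <- aa_states()
  tab[2, ] <- tab[2, ] * 0.8
  expect_error(build_altall(tab), "site.*2")
  expect_error(build_altall(rbind(post_row(A = 0.9)), threshold = 1),
               "threshold")
})

test_that("count_differences is a strict Hamming distance on aligned input", {
  expect_equal(count_differences("ACDEF", "ACDEF"), 0)
  expect_equal(count_differences("ACD", "ACE"), 1)
  expect_equal(count_differences("AC-", "ACD"), 1)  # gap vs residue counts
  expect_error(count_differences("ACD", "AC"), "length")
})

test_that("topology comparisons count, average and union differing sites", {
  tab <- do.call(rbind, lapply(1:10, function(s)
    if (s %in% c(4, 9)) post_row(A = 0.55, C = 0.35) else post_row(A = 0.9)))
  colnames(tab) <- aa_states()
  ref <- build_altall(tab)   # ML all-A, altAll differs at 4 and 9
  ml <- ref$ml_sequence

  same <- compare_across_topologies(list(t1 = ml, t2 = ml), ref)
  expect_equal(unname(same$counts), c(0L, 0L))
  expect_equal(same$mean_differences, 0)

  alt1 <- sub("^(.{3})A", "\\1C", ml)                       # differs at 4
  alt2 <- paste0(substr(ml, 1, 3), "C", substr(ml, 5, 8), "C",
                 substr(ml, 10, 10))                        # differs at 4, 9
  cmp <- compare_across_topologies(list(t1 = alt1, t2 = alt2), ref)
  expect_equal(unname(cmp$counts), c(1L, 2L))
  expect_equal(cmp$mean_differences, 1.5)
  expect_equal(cmp$differing_sites, c(4L, 9L))
  expect_true(cmp$within_altall_set)

  alt3 <- paste0("W", substr(ml, 2, 10))                    # site 1: not in set
  cmp2 <- compare_across_topologies(list(t1 = alt3), ref)
  expect_false(cmp2$within_altall_set)
  expect_error(compare_across_topologies(list(t1 = "AC"), ref), "mismatch")
})
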