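# Responsive-neuron classification, 9-type taxonomy, group comparison,
# stability, spontaneous events.

test_that("classification follows the consecutive-pair threshold rule", {
  expect_equal(classify_response(rep(0, 15))$label, "NONE")

  r <- classify_response(c(0, 3.5, 3.2, rep(0, 12)))
  expect_equal(r$label, "PLUS")
  expect_equal(r$trigger_bin, 1L)

  expect_equal(classify_response(c(3.5, 0, 3.5, rep(0, 12)))$label, "NONE")
  expect_equal(classify_response(c(-3.5, -4, rep(0, 13)))$label, "MINUS")

  # both signs qualify: larger mean |Z| wins
  both <- c(3.2, 3.1, -5, -5, rep(0, 11))
  expect_equal(classify_response(both)$label, "MINUS")
  expect_error(classify_response(c(1)), "at least 2")
})

test_that("classifier matches a brute-force scan on random null traces", {
  set.seed(99)
  mismatches <- 0L
  for (i in 1:2000) {
    z <- cumsum(rnorm(15, sd = 1.5))
    if (classify_response(z)$label != bf_classify(z)) mismatches <- mismatches + 1L
  }
  expect_equal(mismatches, 0L)
})

test_that("raising tone-period values never demotes a PLUS label", {
  set.seed(12)
  for (i in 1:200) {
    z <- rnorm(15, sd = 2)
    lab <- classify_response(z)$label
    up <- classify_response(z + abs(rnorm(1)))$label
    if (lab == "PLUS") expect_equal(up, "PLUS")
  }
})

test_that("taxonomy partitions neurons into the 9 types exactly once", {
  labs <- function(ids, labels) data.frame(neuron_id = ids, label = labels,
                                           stringsAsFactors = FALSE)
  ids <- sprintf("n%02d", 1:4)
  tx <- response_taxonomy(labs(ids, c("PLUS", "PLUS", "NONE", "MINUS")),
                          labs(ids, c("NONE", "PLUS", "NONE", "PLUS")))
  expect_equal(length(tx$counts), 9)
  expect_equal(sum(tx$counts), 4)
  expect_equal(sum(tx$proportions), 1, tolerance = 1e-12)
  expect_equal(tx$dual_proportion, 0.5)  # (PLUS,PLUS) and (MINUS,PLUS)
  expect_equal(tx$counts[["PLUS/NONE"]], 1L)

  # all NONE/NONE
  tx0 <- response_taxonomy(labs(ids, rep("NONE", 4)), labs(ids, rep("NONE", 4)))
  expect_equal(tx0$proportions[["NONE/NONE"]], 1)

  expect_error(response_taxonomy(labs(ids, rep("NONE", 4)),
                                 labs(rev(c(ids[-1], "zz")), rep("NONE", 4))),
               "identical neuron ids")
})

test_that("Fisher comparison matches hypergeometric enumeration and is symmetric", {
  A <- list(count = 10, n = 100); B <- list(count = 10, n = 100)
  r <- compare_type_proportions(A, B)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)

  # direct enumeration for table [[1,9],[9,1]]
  A <- list(count = 1, n = 10); B <- list(count = 9, n = 10)
  r <- compare_type_proportions(A, B)
  probs <- dhyper(0:10, 10, 10, 10)
  p_obs <- dhyper(1, 10, 10, 10)
  expect_equal(r$p_value, sum(probs[probs <= p_obs * (1 + 1e-7)]),
               tolerance = 1e-12)
  r_swap <- compare_type_proportions(B, A)
  expect_equal(r$p_value, r_swap$p_value)
  expect_gt(r$p_value, 0); expect_lte(r$p_value, 1)

  # degenerate zero-count table
  r0 <- compare_type_proportions(list(count = 0, n = 10),
                                 list(count = 0, n = 10))
  expect_true(is.nan(r0$odds_ratio))
  expect_equal(r0$p_value, 1)
  expect_error(compare_type_proportions(list(count = 0, n = 0), B), "empty")
})

test_that("consecutive-tone stability counts only adjacent responsive trials", {
  m <- rbind(c("PLUS", "PLUS", "NONE"),   # adjacent -> counted
             c("PLUS", "NONE", "PLUS"),   # gap -> not counted
             c("NONE", "MINUS", "MINUS"), # adjacent, any sign -> counted
             c("NONE", "NONE", "NONE"))
  r <- consecutive_tone_stability(m)
  expect_equal(r$proportion, 0.5)
  expect_equal(unname(r$stable), c(TRUE, FALSE, TRUE, FALSE))
  expect_error(consecutive_tone_stability(m[, 1, drop = FALSE]), "at least 2")
})

test_that("stability separates planted stable archetypes from pure noise", {
  sim <- make_small_session(c(cs_plus = 0.5, none = 0.5), n = 40, seed = 6,
                            trial_gain_sd = 0)
  zt <- ztransform_pretone(
    align_and_bin(sim$traces, sim$schedule, "CS_PLUS"))  # per-trial
  labs <- classify_per_trial(zt)
  r <- consecutive_tone_stability(labs)
  planted <- sim$truth$archetype == "cs_plus"
  expect_gte(mean(r$stable[planted]), 0.9)
  expect_lt(mean(r$stable[!planted]), 0.2)
})

test_that("spontaneous event rate counts excursions once per window minute", {
  set.seed(21)
  vals <- matrix(rnorm(2 * 3600, sd = 1), 2)
  # one 3-s transient at 100 s on neuron 1, none on neuron 2
  idx <- 1001:1030
  vals[1, idx] <- vals[1, idx] + 8
  tm <- trace_matrix(vals, 10)
  sched <- data.frame(event_type = "NT", onset_s = 320, duration_s = 15)
  r <- spontaneous_event_rate(tm, sched, window = c(0, 300))
  expect_equal(unname(r[1]), 1 / 5)  # 1 event in 5 min
  expect_equal(unname(r[2]), 0)

  flat <- trace_matrix(matrix(1, 1, 3600), 10)
  expect_equal(unname(spontaneous_event_rate(flat, sched, c(0, 300))), 0)
  expect_error(spontaneous_event_rate(tm, sched, c(310, 360)), "overlaps")
})

test_that("estimated spontaneous rate tracks a planted Poisson rate", {
  lambda <- 1  # events per minute, 5-minute windows
  rates <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    x <- rnorm(3000, sd = 1)
    k <- rpois(1, lambda * 5)
    if (k > 0) {
      starts <- sort(sample.int(2900, k))
      # enforce separation so excursions stay distinct
      starts <- starts[c(TRUE, diff(starts) > 60)]
      for (st in starts) x[st:(st + 29)] <- x[st:(st + 29)] + 8
      k <- length(starts)
    }
    tm <- trace_matrix(matrix(x, 1), 10)
    sched <- data.frame(event_type = "NT", onset_s = 400, duration_s = 1)
    est <- spontaneous_event_rate(tm, sched, c(0, 300))
    est - k / 5
  }, numeric(1))
  # unbiased recovery of the planted count in each window
  expect_lt(abs(mean(rates)), 2 * sd(rates) / sqrt(length(rates)) + 0.05)
})
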