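# Alignment, binning, block averaging, pre-tone and whole-session Z-scoring.

make_tm <- function(values, rate = 10) trace_matrix(values, rate)

test_that("binning averages the right half-open sample windows", {
  # value = 0-based frame index; onset at 100 s, 10 Hz:
  # bin 0 = mean(frames 1000..1009) = 1004.5
  tm <- make_tm(matrix(0:1299, nrow = 1, byrow = TRUE), rate = 10)
  sched <- data.frame(event_type = "NT", onset_s = 100, duration_s = 15)
  out <- align_and_bin(tm, sched, "NT", pre_s = 15, tone_s = 15)
  expect_equal(out[1, 1, "0"], 1004.5, ignore_attr = TRUE)
  expect_equal(out[1, 1, "-1"], 994.5, ignore_attr = TRUE)
  expect_equal(out[1, 1, "14"], 1144.5, ignore_attr = TRUE)
})

test_that("constant traces bin to the constant and trial count follows the schedule", {
  tm <- make_tm(matrix(3.7, nrow = 2, ncol = 2000))
  sched <- data.frame(event_type = c("NT", "NT"), onset_s = c(30, 90),
                      duration_s = c(15, 15))
  out <- align_and_bin(tm, sched, "NT")
  expect_equal(dim(out)[2], 2)
  expect_true(all(out == 3.7))
})

test_that("out-of-range windows fail naming the offending event", {
  tm <- make_tm(matrix(0, nrow = 1, ncol = 100))
  sched <- data.frame(event_type = "NT", onset_s = 5, duration_s = 15)
  expect_error(align_and_bin(tm, sched, "NT"), "onset at 5")
  expect_error(align_and_bin(tm, sched, "CS_PLUS"), "no events")
})

test_that("binning and Z-scoring match a loop-written reference on random input", {
  set.seed(31)
  for (rep in 1:5) {
    n_neur <- sample(2:5, 1); n_tr <- sample(2:4, 1)
    rate <- 10
    onsets <- 20 + (seq_len(n_tr) - 1) * 40
    n_samp <- (max(onsets) + 25) * rate
    vals <- matrix(rnorm(n_neur * n_samp), n_neur)
    tm <- make_tm(vals, rate)
    sched <- data.frame(event_type = rep("NT", n_tr), onset_s = onsets,
                        duration_s = 15)
    got <- align_and_bin(tm, sched, "NT", pre_s = 15, tone_s = 15)
    tgrid <- (seq_len(n_samp) - 1) / rate
    for (i in seq_len(n_neur)) for (tr in seq_len(n_tr)) {
      for (b in -15:14) {
        sel <- tgrid >= onsets[tr] + b & tgrid < onsets[tr] + b + 1
        expect_equal(got[i, tr, as.character(b)], mean(vals[i, sel]),
                     tolerance = 1e-10, ignore_attr = TRUE)
      }
    }
    # Z-transform against its own 15 baseline bins, unbiased SD
    zt <- ztransform_pretone(got)
    for (i in seq_len(n_neur)) for (tr in seq_len(n_tr)) {
      base <- got[i, tr, as.character(-15:-1)]
      expect_equal(zt[i, tr, ], (got[i, tr, ] - mean(base)) / sd(base),
                   tolerance = 1e-10, ignore_attr = TRUE)
    }
  }
})

test_that("block averaging means pairs in order and drops odd trailing trials", {
  tm <- make_tm(matrix(rnorm(5 * 2600), 5), rate = 10)
  sched <- data.frame(event_type = rep("NT", 5),
                      onset_s = 20 + (0:4) * 45, duration_s = 15)
  al <- align_and_bin(tm, sched, "NT")
  expect_warning(bl <- block_average(al, 2), "dropping")
  expect_equal(dim(bl)[2], 2)
  expect_equal(bl[, 1, ], (al[, 1, ] + al[, 2, ]) / 2, ignore_attr = TRUE)
  expect_equal(bl[, 2, ], (al[, 3, ] + al[, 4, ]) / 2, ignore_attr = TRUE)

  # trials [A, A] -> one block equal to A
  al2 <- al[, c(1, 1), , drop = FALSE]
  attributes(al2)[c("pre_bins", "tone_bins", "tone_type", "class")] <-
    attributes(al)[c("pre_bins", "tone_bins", "tone_type", "class")]
  bl2 <- block_average(al2, 2)
  expect_equal(bl2[, 1, ], al[, 1, ], ignore_attr = TRUE)
})

test_that("degenerate zero-SD baselines yield flagged zero Z", {
  tm <- make_tm(rbind(rep(1, 600), rnorm(600)), rate = 10)
  sched <- data.frame(event_type = "NT", onset_s = 20, duration_s = 15)
  zt <- ztransform_pretone(align_and_bin(tm, sched, "NT"))
  expect_true(attr(zt, "flags")[1, 1])
  expect_false(attr(zt, "flags")[2, 1])
  expect_true(all(zt[1, 1, ] == 0))
})

test_that("Z outputs are invariant to trace shift and positive scaling", {
  set.seed(5)
  tm <- make_tm(matrix(rnorm(3 * 1200), 3), rate = 10)
  sched <- data.frame(event_type = rep("NT", 2), onset_s = c(20, 60),
                      duration_s = c(15, 15))
  ref <- ztransform_pretone(block_average(align_and_bin(tm, sched, "NT")))
  for (tf in list(function(x) x + 7, function(x) 3.2 * x,
                  function(x) 0.5 * x - 2)) {
    tm2 <- make_tm(tf(unclass(tm)), rate = 10)
    got <- ztransform_pretone(block_average(align_and_bin(tm2, sched, "NT")))
    expect_equal(unclass(got), unclass(ref), tolerance = 1e-10,
                 ignore_attr = TRUE)
    w_ref <- ztransform_whole_session(tm, sched, "NT")
    w_got <- ztransform_whole_session(tm2, sched, "NT")
    expect_equal(as.numeric(w_got), as.numeric(w_ref), tolerance = 1e-10)
  }
})

test_that("whole-session scalar matches its direct formula and flags constants", {
  set.seed(8)
  vals <- matrix(rnorm(2 * 1200), 2)
  vals[2, ] <- 4  # constant neuron
  tm <- make_tm(vals, rate = 10)
  sched <- data.frame(event_type = rep("NT", 2), onset_s = c(20, 60),
                      duration_s = c(15, 15))
  z <- ztransform_whole_session(tm, sched, "NT", tone_s = 15, n_avg = 2)
  # loop oracle: average first-2-presentation windows, z against session
  win <- function(o) vals[1, (o * 10 + 1):(o * 10 + 150)]
  avg <- (win(20) + win(60)) / 2
  expected <- (mean(avg) - mean(vals[1, ])) / sd(vals[1, ])
  expect_equal(as.numeric(z[1]), expected, tolerance = 1e-12)
  expect_equal(as.numeric(z[2]), 0)
  expect_true(attr(z, "flags")[2])
})

test_that("planted CS+ archetypes have larger whole-session CS+ than NT scalars", {
  hits <- vapply(1:10, function(s) {
    sim <- make_small_session(c(cs_plus = 1), n = 20, seed = s)
    z_nt <- ztransform_whole_session(sim$traces, sim$schedule, "NT")
    z_cs <- ztransform_whole_session(sim$traces, sim$schedule, "CS_PLUS")
    mean(z_cs > z_nt)
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
})
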