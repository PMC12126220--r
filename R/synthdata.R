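# Synthetic sessions with planted ground truth: calcium imaging populations,
# two-channel photometry, freezing behavior, and a human startle/eCB cohort.

ARCHETYPES <- c("nt_plus", "cs_plus", "dual_plus",
                "nt_minus", "cs_minus", "dual_mixed", "none")

#' Specify a synthetic neuronal population
#'
#' Defines the composition and response properties of a simulated population
#' of prelimbic neurons. Each neuron belongs to one archetype describing which
#' tone type(s) it responds to and with what sign: `nt_plus` (excited by the
#' novel tone only), `cs_plus` (excited by the conditioned tone only),
#' `dual_plus` (excited by both), `nt_minus` / `cs_minus` (suppressed by one
#' tone type), `dual_mixed` (excited by NT, suppressed by CS+), and `none`
#' (no tone-locked signal).
#'
#' @param n_neurons Number of neurons (>= 1).
#' @param archetype_fractions Named numeric vector of fractions over the seven
#'   archetypes; must sum to 1 (tolerance 1e-9). Missing names default to 0.
#' @param response_amplitude Peak response amplitude, expressed in units of
#'   the standard deviation of 1-second-binned baseline noise (i.e. the
#'   expected peri-tone Z-score peak).
#' @param rise_s,decay_s Time constants (seconds) of the
#'   difference-of-exponentials response kernel.
#' @param noise_sd Standard deviation of the i.i.d. Gaussian frame noise, in
#'   raw trace units (> 0).
#' @param trial_gain_sd SD of the multiplicative trial-to-trial response gain
#'   (gain = max(0, 1 + N(0, trial_gain_sd))); 0 disables trial variability.
#' @param seed Integer seed; expanded per neuron by a counter scheme so that
#'   enlarging the population does not reshuffle existing neurons.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_neurons,
                            archetype_fractions = c(none = 1),
                            response_amplitude = 6,
                            rise_s = 0.5,
                            decay_s = 3,
                            noise_sd = 1,
                            trial_gain_sd = 0.2,
                            seed = 1L) {
  stopifnot(length(n_neurons) == 1, n_neurons >= 1)
  fr <- setNames(numeric(length(ARCHETYPES)), ARCHETYPES)
  if (is.null(names(archetype_fractions)) ||
      !all(names(archetype_fractions) %in% ARCHETYPES)) {
    stop("archetype_fractions must be named with archetype names: ",
         paste(ARCHETYPES, collapse = ", "))
  }
  fr[names(archetype_fractions)] <- archetype_fractions
  if (abs(sum(fr) - 1) > 1e-9) stop("archetype fractions must sum to 1")
  if (any(fr < 0)) stop("archetype fractions must be non-negative")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (rise_s <= 0 || decay_s <= rise_s) stop("need 0 < rise_s < decay_s")
  structure(list(n_neurons = as.integer(n_neurons),
                 archetype_fractions = fr,
                 response_amplitude = response_amplitude,
                 rise_s = rise_s, decay_s = decay_s,
                 noise_sd = noise_sd,
                 trial_gain_sd = trial_gain_sd,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Specify a recording session's tone schedule
#'
#' @param rate_hz Sampling rate in Hz (default 10, the acquisition rate of the
#'   miniscope recordings this pipeline targets).
#' @param tone_duration_s Tone duration in seconds (default 15).
#' @param n_nt_tones,n_cs_tones Number of novel-tone and CS+ presentations.
#' @param iti_s Inter-tone interval in seconds (offset to next onset); must
#'   leave the 15-s pre-tone baseline free of the previous tone if downstream
#'   alignment uses the default baseline.
#' @param pre_session_s Recording time before the first tone (>= the pre-tone
#'   baseline length used downstream).
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(rate_hz = 10,
                         tone_duration_s = 15,
                         n_nt_tones = 4,
                         n_cs_tones = 4,
                         iti_s = 30,
                         pre_session_s = 30) {
  stopifnot(rate_hz > 0, tone_duration_s > 0, iti_s >= 0, pre_session_s >= 0,
            n_nt_tones >= 0, n_cs_tones >= 0)
  if (iti_s <= 0 && (n_nt_tones + n_cs_tones) > 1)
    stop("tones must not overlap: iti_s must be positive")
  structure(list(rate_hz = rate_hz,
                 tone_duration_s = tone_duration_s,
                 n_nt_tones = as.integer(n_nt_tones),
                 n_cs_tones = as.integer(n_cs_tones),
                 iti_s = iti_s,
                 pre_session_s = pre_session_s),
            class = "session_spec")
}

#' Specify a synthetic human fear-conditioning cohort
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param target_r Pearson correlation, in expectation, between log 2-AG
#'   baseline and the CS generalization score (CS-) - (CS+) at recall.
#' @param startle_noise_sd Trial-level EMG amplitude noise SD (a.u.).
#' @param ecb_log_mean,ecb_log_sd Mean and SD of the natural-log 2-AG
#'   baseline distribution.
#' @param seed Integer seed.
#' @return An object of class `human_cohort_spec`.
#' @export
human_cohort_spec <- function(n_subjects,
                              target_r = 0,
                              startle_noise_sd = 2,
                              ecb_log_mean = 1.5,
                              ecb_log_sd = 0.5,
                              seed = 1L) {
  stopifnot(n_subjects >= 3, abs(target_r) <= 1,
            startle_noise_sd >= 0, ecb_log_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 target_r = target_r,
                 startle_noise_sd = startle_noise_sd,
                 ecb_log_mean = ecb_log_mean,
                 ecb_log_sd = ecb_log_sd,
                 seed = as.integer(seed)),
            class = "human_cohort_spec")
}

# Counter-based seed derivation: one master seed plus (stream, counter)
# indices map to an independent set.seed() value < 2^31. Adding neurons or
# trials extends the counter without reshuffling earlier draws.
derive_seed <- function(seed, stream, counter = 0L) {
  as.integer((as.double(seed) * 2654435.0 + stream * 97003.0 +
                counter * 7919.0) %% 2147483629.0)
}

# Tone schedule: NT and CS+ presentations interleaved in presentation order.
build_schedule <- function(sess) {
  types <- character(0)
  nt_left <- sess$n_nt_tones
  cs_left <- sess$n_cs_tones
  while (nt_left > 0 || cs_left > 0) {
    if (nt_left > 0) { types <- c(types, "NT"); nt_left <- nt_left - 1 }
    if (cs_left > 0) { types <- c(types, "CS_PLUS"); cs_left <- cs_left - 1 }
  }
  n <- length(types)
  onsets <- sess$pre_session_s +
    (seq_len(n) - 1) * (sess$tone_duration_s + sess$iti_s)
  sched <- data.frame(event_type = types,
                      onset_s = onsets,
                      duration_s = rep(sess$tone_duration_s, n),
                      stringsAsFactors = FALSE)
  validate_schedule(sched)
  sched
}

validate_schedule <- function(schedule) {
  stopifnot(is.data.frame(schedule),
            all(c("event_type", "onset_s", "duration_s") %in% names(schedule)))
  tones <- schedule[schedule$event_type != "SHOCK", , drop = FALSE]
  if (nrow(tones) > 1) {
    o <- order(tones$onset_s)
    ends <- tones$onset_s[o] + tones$duration_s[o]
    if (any(ends[-length(ends)] > tones$onset_s[o][-1] + 1e-9))
      stop("overlapping tones in event schedule")
  }
  if (is.unsorted(schedule$onset_s)) stop("event onsets must be non-decreasing")
  invisible(schedule)
}

# Difference-of-exponentials response kernel, peak-normalized to 1.
response_kernel <- function(t, rise_s, decay_s) {
  k <- exp(-t / decay_s) - exp(-t / rise_s)
  k[t < 0] <- 0
  tpk <- log(decay_s / rise_s) / (1 / rise_s - 1 / decay_s)
  k / (exp(-tpk / decay_s) - exp(-tpk / rise_s))
}

archetype_signs <- function(archetype) {
  switch(archetype,
         nt_plus    = c(NT = +1, CS_PLUS = 0),
         cs_plus    = c(NT = 0,  CS_PLUS = +1),
         dual_plus  = c(NT = +1, CS_PLUS = +1),
         nt_minus   = c(NT = -1, CS_PLUS = 0),
         cs_minus   = c(NT = 0,  CS_PLUS = -1),
         dual_mixed = c(NT = +1, CS_PLUS = -1),
         none       = c(NT = 0,  CS_PLUS = 0),
         stop("unknown archetype: ", archetype))
}

# Deterministic largest-remainder apportionment of n neurons to archetypes.
apportion <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a synthetic calcium-imaging session
#'
#' Builds a neurons-by-timepoints trace matrix in which each neuron is
#' baseline Gaussian noise plus, for its archetype's stimulus types, a
#' tone-locked difference-of-exponentials transient (negated for suppressed
#' archetypes) with multiplicative trial-to-trial gain. The planted archetype
#' of every neuron is returned as ground truth; it is never written into the
#' data consumed by analysis stages.
#'
#' @param pop A [population_spec()].
#' @param sess A [session_spec()].
#' @return A list with elements `traces` (a [trace_matrix()]), `schedule`
#'   (event data frame with columns event_type, onset_s, duration_s), and
#'   `truth` (data frame neuron_id, archetype).
#' @export
generate_session <- function(pop, sess) {
  stopifnot(inherits(pop, "population_spec"), inherits(sess, "session_spec"))
  sched <- build_schedule(sess)
  dur <- max(sched$onset_s + sched$duration_s) + sess$iti_s
  n_t <- as.integer(round(dur * sess$rate_hz))
  tgrid <- (seq_len(n_t) - 1) / sess$rate_hz

  counts <- apportion(pop$archetype_fractions, pop$n_neurons)
  archetype <- rep(ARCHETYPES, counts)

  # Precompute the kernel contribution of each tone at unit amplitude.
  kern_len_s <- sess$tone_duration_s + 5 * pop$decay_s
  kernels <- lapply(seq_len(nrow(sched)), function(i) {
    rel <- tgrid - sched$onset_s[i]
    use <- rel >= 0 & rel < kern_len_s
    list(idx = which(use),
         val = response_kernel(rel[use], pop$rise_s, pop$decay_s))
  })

  # Peak raw amplitude such that the peri-tone Z-score peak (1-s binned
  # baseline, SD noise_sd / sqrt(rate_hz)) is approximately response_amplitude.
  amp_raw <- pop$response_amplitude * pop$noise_sd / sqrt(sess$rate_hz)

  traces <- matrix(0, nrow = pop$n_neurons, ncol = n_t)
  for (i in seq_len(pop$n_neurons)) {
    set.seed(derive_seed(pop$seed, 1L, i))
    x <- rnorm(n_t, mean = 0, sd = pop$noise_sd)
    signs <- archetype_signs(archetype[i])
    for (j in seq_len(nrow(sched))) {
      s <- signs[[sched$event_type[j]]]
      if (is.null(s) || s == 0) next
      gain <- if (pop$trial_gain_sd > 0)
        max(0, 1 + rnorm(1, sd = pop$trial_gain_sd)) else 1
      x[kernels[[j]]$idx] <- x[kernels[[j]]$idx] +
        s * gain * amp_raw * kernels[[j]]$val
    }
    traces[i, ] <- x
  }
  ids <- sprintf("n%04d", seq_len(pop$n_neurons))
  list(traces = trace_matrix(traces, sess$rate_hz, ids),
       schedule = sched,
       truth = data.frame(neuron_id = ids, archetype = archetype,
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic two-channel photometry session
#'
#' The signal channel carries tone-locked transients whose peak amplitude is a
#' linearly decreasing function of that trial's freezing percentage (the
#' planted direction: high behavioral generalization, low sensor response).
#' The isosbestic channel carries only the shared slow artifact, so a correct
#' dF/F correction removes the artifact and preserves the transients. A
#' per-frame binary freezing series consistent with the per-trial percentages
#' is returned alongside.
#'
#' @param sess A [session_spec()]; all scheduled tones receive a transient.
#' @param trial_freezing Numeric vector, one freezing percentage in \[0, 100\]
#'   per scheduled tone.
#' @param seed Integer seed.
#' @param peak_z_at_0,peak_z_at_100 Planted transient peak (units of baseline
#'   noise SD) at 0% and 100% trial freezing; linear in between.
#' @param noise_sd Per-frame noise SD on each channel (raw units).
#' @param baseline_f Mean fluorescence of both channels (raw units).
#' @return List with `photometry` (data frame t, signal, isosbestic plus a
#'   rate_hz attribute), `freezing` (data frame time_s, freezing in 0/1),
#'   `schedule`, and `truth` (per-trial planted peak amplitudes).
#' @export
generate_photometry <- function(sess, trial_freezing, seed = 1L,
                                peak_z_at_0 = 3, peak_z_at_100 = 1,
                                noise_sd = 1, baseline_f = 100) {
  stopifnot(inherits(sess, "session_spec"),
            all(trial_freezing >= 0 & trial_freezing <= 100))
  sched <- build_schedule(sess)
  if (length(trial_freezing) != nrow(sched))
    stop("need one freezing percentage per scheduled tone (",
         nrow(sched), ")")
  dur <- max(sched$onset_s + sched$duration_s) + sess$iti_s
  n_t <- as.integer(round(dur * sess$rate_hz))
  tgrid <- (seq_len(n_t) - 1) / sess$rate_hz

  set.seed(derive_seed(seed, 2L, 0L))
  artifact <- 2 * sin(2 * pi * tgrid / 120) +
    as.numeric(stats::filter(rnorm(n_t, sd = 0.2), 0.98, method = "recursive"))
  signal <- baseline_f + artifact + rnorm(n_t, sd = noise_sd)
  isos <- baseline_f + artifact + rnorm(n_t, sd = noise_sd)

  peaks <- peak_z_at_0 + (peak_z_at_100 - peak_z_at_0) * trial_freezing / 100
  for (j in seq_len(nrow(sched))) {
    rel <- tgrid - sched$onset_s[j]
    use <- rel >= 0 & rel < sched$duration_s[j] + 10
    signal[use] <- signal[use] + peaks[j] * noise_sd *
      response_kernel(rel[use], 0.5, 3)
  }

  freeze <- integer(n_t)
  for (j in seq_len(nrow(sched))) {
    use <- which(tgrid >= sched$onset_s[j] &
                   tgrid < sched$onset_s[j] + sched$duration_s[j])
    k <- round(length(use) * trial_freezing[j] / 100)
    if (k > 0) freeze[use[sample.int(length(use), k)]] <- 1L
  }

  phot <- data.frame(t = tgrid, signal = signal, isosbestic = isos)
  attr(phot, "rate_hz") <- sess$rate_hz
  list(photometry = phot,
       freezing = data.frame(time_s = tgrid, freezing = freeze),
       schedule = sched,
       truth = data.frame(trial = seq_len(nrow(sched)),
                          freezing_pct = trial_freezing,
                          planted_peak_z = peaks))
}

#' Generate a synthetic human startle/endocannabinoid cohort
#'
#' Each subject receives a multiplicative startle gain (removed by ITI
#' standardization), acquisition and recall trials (4 per cue plus 4 ITI per
#' phase), and two baseline 2-AG measurements whose log-mean correlates with
#' the subject's planted CS generalization score (CS-) - (CS+) at the
#' requested Pearson r, in expectation. AEA is generated as an independent
#' analyte. Trial noise is kept small relative to between-subject spread so
#' correlation attenuation from measurement error is negligible.
#'
#' @param spec A [human_cohort_spec()].
#' @return List with `startle` (subject_id, trial_index, trial_type,
#'   amplitude, phase), `ecb` (subject_id, analyte, value_t1, value_t2), and
#'   `truth` (per-subject planted log 2-AG and generalization score, plus the
#'   target r as an attribute).
#' @export
generate_human_cohort <- function(spec) {
  stopifnot(inherits(spec, "human_cohort_spec"))
  n <- spec$n_subjects
  r <- spec$target_r
  set.seed(derive_seed(spec$seed, 3L, 0L))
  z_ecb <- rnorm(n)
  g_std <- r * z_ecb + sqrt(max(0, 1 - r^2)) * rnorm(n)
  gener <- -0.3 + 0.5 * g_std                 # planted (CS-) - (CS+) score
  log2ag <- spec$ecb_log_mean + spec$ecb_log_sd * z_ecb
  gain <- exp(rnorm(n, sd = 0.4))             # subject EMG gain
  s_csp <- 2.0 + 0.3 * rnorm(n)               # fear-potentiated CS+ level
  s_csm <- s_csp + gener

  ids <- sprintf("s%03d", seq_len(n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(spec$seed, 4L, i))
    mk <- function(phase, type, s_level, k = 4) {
      amp <- pmax(0.1, gain[i] * 50 * s_level +
                    rnorm(k, sd = spec$startle_noise_sd))
      data.frame(subject_id = ids[i], trial_index = seq_len(k),
                 trial_type = type, amplitude = amp, phase = phase,
                 stringsAsFactors = FALSE)
    }
    rows[[i]] <- rbind(
      mk("acquisition", "ITI", 1), mk("acquisition", "CS_PLUS", 1.2),
      mk("acquisition", "CS_MINUS", 1.1),
      mk("recall", "ITI", 1), mk("recall", "CS_PLUS", s_csp[i]),
      mk("recall", "CS_MINUS", s_csm[i]))
  }
  startle <- do.call(rbind, rows)
  startle$trial_index <- stats::ave(seq_len(nrow(startle)),
                                    startle$subject_id, startle$phase,
                                    FUN = seq_along)

  set.seed(derive_seed(spec$seed, 5L, 0L))
  m2ag <- exp(log2ag)
  d <- runif(n, 0, 0.1)
  aea <- exp(rnorm(n, mean = 0.5, sd = 0.4))
  da <- runif(n, 0, 0.1)
  ecb <- rbind(
    data.frame(subject_id = ids, analyte = "2AG",
               value_t1 = m2ag * (1 + d), value_t2 = m2ag * (1 - d),
               stringsAsFactors = FALSE),
    data.frame(subject_id = ids, analyte = "AEA",
               value_t1 = aea * (1 + da), value_t2 = aea * (1 - da),
               stringsAsFactors = FALSE))

  truth <- data.frame(subject_id = ids, log_2ag = log2ag,
                      generalization_true = gener,
                      stringsAsFactors = FALSE)
  attr(truth, "target_r") <- r
  list(startle = startle, ecb = ecb, truth = truth)
}
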