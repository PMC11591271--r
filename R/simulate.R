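## Synthetic swine hemorrhage / resuscitation and LBNP generators.
##
## The simulator emulates a MAP-targeted controlled hemorrhage to 35 mmHg, a
## shock hold, and whole-blood resuscitation to 65 mmHg, with hypovolemia-
## dependent pulse morphology (pulse pressure falls and heart rate rises with
## the blood-volume deficit fraction), slow baseline drift, and additive
## noise. MAP follows a compensated-shock response: it is held near baseline
## until the deficit exceeds a dead-zone fraction, then falls linearly - the
## physiological reason pulse-morphology features can detect hemorrhage
## before MAP does.

#' Simulation configuration
#'
#' Protocol and physiology constants for the synthetic cohort. Defaults are
#' the study conditions: arterial pressure at 500 Hz, volume log at 1/5 Hz,
#' hemorrhage target MAP 35 mmHg, whole-blood resuscitation target 65 mmHg,
#' estimated blood volume 60 mL/kg, 12 subjects in 4 groups.
#'
#' @param sample_rate_analog Analog waveform rate, Hz.
#' @param sample_rate_volume Volume-log rate, Hz (one tick per 5 s).
#' @param heart_rate_baseline Baseline heart rate, beats/min.
#' @param pulse_pressure_baseline Baseline pulse pressure, mmHg.
#' @param map_baseline Baseline mean arterial pressure, mmHg.
#' @param map_hemorrhage_target Hemorrhage MAP target, mmHg.
#' @param map_resus_target Whole-blood resuscitation MAP target, mmHg.
#' @param estimated_blood_volume_constant mL/kg (60 for swine).
#' @param hr_gain,pp_gain,map_gain Unitless couplings of the deficit fraction
#'   to heart rate, pulse pressure, and MAP.
#' @param map_deadzone Deficit fraction below which MAP is fully compensated.
#' @param pp_floor_frac Pulse pressure never falls below this fraction of
#'   baseline.
#' @param bleed_rate_max,bleed_rate_min Bleed controller bounds, mL/min.
#' @param infusion_rate_max Whole-blood infusion bound, mL/min.
#' @param controller_gain Proportional gain, mL/min per mmHg of MAP error.
#' @param baseline_duration Baseline recording length, s (>= 600).
#' @param hold_duration Shock-hold length, s (fixed-duration proxy for the
#'   lactate endpoint).
#' @param resus_min_duration Minimum whole-blood resuscitation length, s.
#' @param max_phase_duration Controller failure horizon per phase, s.
#' @param wb_cap_frac Whole-blood infusion cap as a fraction of total shed
#'   volume (< 1 keeps final BLVM below 1).
#' @param dicrotic_amp Dicrotic-wave amplitude of the beat template
#'   (0 suppresses the lobe and exercises the half-drop fallback).
#' @param drift_amplitude Slow sinusoidal baseline drift amplitude, mmHg.
#' @param drift_period Drift period, s.
#' @param noise_sd Additive Gaussian noise SD, mmHg.
#' @param weight_range Swine weight range, kg (uniform draw).
#' @param lbnp_hdd_range Range of the decompensation vacuum pressure for LBNP
#'   subjects, mmHg.
#' @param lbnp_n_steps,lbnp_step_duration LBNP staircase shape.
#' @param n_subjects,n_groups Cohort size and group count (divisible).
#' @param seed Master seed for cohort generation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(sample_rate_analog = 500,
                       sample_rate_volume = 1 / 5,
                       heart_rate_baseline = 90,
                       pulse_pressure_baseline = 40,
                       map_baseline = 80,
                       map_hemorrhage_target = 35,
                       map_resus_target = 65,
                       estimated_blood_volume_constant = 60,
                       hr_gain = 1.2,
                       pp_gain = 1.5,
                       map_gain = 1.5,
                       map_deadzone = 0.08,
                       pp_floor_frac = 0.25,
                       bleed_rate_max = 200,
                       bleed_rate_min = 30,
                       infusion_rate_max = 200,
                       controller_gain = 25,
                       baseline_duration = 600,
                       hold_duration = 300,
                       resus_min_duration = 330,
                       max_phase_duration = 2400,
                       wb_cap_frac = 0.8,
                       dicrotic_amp = 0.12,
                       drift_amplitude = 1.5,
                       drift_period = 600,
                       noise_sd = 1.0,
                       weight_range = c(40, 60),
                       lbnp_hdd_range = c(55, 95),
                       lbnp_n_steps = 6L,
                       lbnp_step_duration = 150,
                       n_subjects = 12L,
                       n_groups = 4L,
                       seed = 1L) {
  cfg <- as.list(environment())
  pos <- c("sample_rate_analog", "sample_rate_volume", "heart_rate_baseline",
           "pulse_pressure_baseline", "map_baseline", "map_hemorrhage_target",
           "map_resus_target", "estimated_blood_volume_constant",
           "bleed_rate_max", "infusion_rate_max", "controller_gain",
           "baseline_duration", "hold_duration", "resus_min_duration",
           "max_phase_duration")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop("config field must be strictly positive: ", f)
  if (!(map_hemorrhage_target < map_resus_target &&
        map_resus_target < map_baseline))
    stop("require map_hemorrhage_target < map_resus_target < map_baseline")
  if (n_subjects %% n_groups != 0L)
    stop("n_subjects must be divisible by n_groups")
  if (baseline_duration < 600)
    stop("baseline_duration must be at least 600 s")
  if (wb_cap_frac <= 0 || wb_cap_frac >= 1)
    stop("wb_cap_frac must be in (0, 1)")
  structure(cfg, class = "sim_config")
}

## Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Arterial pulse template
#'
#' Beat shape on the phase interval \[0, 1): a half-cosine systolic upstroke,
#' a concave quadratic diastolic decay, and an optional Gaussian dicrotic
#' wave on the downstroke, normalized to \[0, 1\]. With `dicrotic_amp > 0`
#' the downstroke has a genuine second-derivative zero crossing (inflection);
#' with `dicrotic_amp = 0` the downstroke is concave throughout, so landmark
#' detection must fall back to the half-drop.
#'
#' @param u Phase in \[0, 1).
#' @param dicrotic_amp Dicrotic lobe amplitude (template units).
#' @param u_peak Phase of the systolic peak.
#' @param u_dicrotic,dicrotic_width Centre and SD of the dicrotic lobe
#'   (phase units).
#' @param decay_shape Concavity of the diastolic decay (> 0).
#' @return Numeric template values in \[0, 1\].
#' @export
pulse_template <- function(u, dicrotic_amp = 0.12, u_peak = 0.18,
                           u_dicrotic = 0.45, dicrotic_width = 0.06,
                           decay_shape = 0.6) {
  y <- pulse_template_raw(u %% 1, dicrotic_amp, u_peak, u_dicrotic,
                          dicrotic_width, decay_shape)
  rng <- range(pulse_template_raw(seq(0, 1, length.out = 2048),
                                  dicrotic_amp, u_peak, u_dicrotic,
                                  dicrotic_width, decay_shape))
  (y - rng[1L]) / (rng[2L] - rng[1L])
}

## unnormalized template; the diastolic decay 1 - s + k*s*(1-s) is concave
## (second derivative -2k), so without the dicrotic lobe there is no
## inflection after the peak.
pulse_template_raw <- function(u, dicrotic_amp, u_peak, u_dicrotic,
                               dicrotic_width, decay_shape) {
  y <- numeric(length(u))
  up <- u < u_peak
  y[up] <- 0.5 * (1 - cos(pi * u[up] / u_peak))
  s <- (u[!up] - u_peak) / (1 - u_peak)
  y[!up] <- 1 - s + decay_shape * s * (1 - s)
  y + ifelse(u >= u_peak,
             dicrotic_amp * exp(-(u - u_dicrotic)^2 /
                                  (2 * dicrotic_width^2)), 0)
}

## physiology: map deficit fraction -> (MAP, PP, HR) before drift/noise
physiology_state <- function(cfg, deficit, comp = 0) {
  d_eff <- pmax(0, deficit - cfg$map_deadzone) / (1 - cfg$map_deadzone)
  map <- cfg$map_baseline * (1 - cfg$map_gain * d_eff) + comp
  pp <- cfg$pulse_pressure_baseline *
    pmax(cfg$pp_floor_frac, 1 - cfg$pp_gain * deficit)
  hr <- cfg$heart_rate_baseline * (1 + cfg$hr_gain * deficit)
  list(map = map, pp = pp, hr = hr)
}

#' Simulate one swine hemorrhage/resuscitation subject
#'
#' Phases: baseline, feedback-controlled bleed until the windowed MAP reaches
#' the 35 mmHg target, a fixed-duration shock hold with small corrective
#' bleeds keeping MAP near the target, and whole-blood infusion until MAP
#' reaches 65 mmHg, then held to the end of the record. Deterministic given
#' `(config, subject_seed)`.
#'
#' @param config A [sim_config()].
#' @param subject_seed Integer seed for this subject.
#' @param weight_kg Optional fixed weight; drawn from `config$weight_range`
#'   when `NULL`.
#' @param subject_id,group_id Identifiers stored on the record.
#' @return A list of class `subject_record` with fields `subject_id`,
#'   `group_id`, `weight_kg`, `waveform` (`uniform_series`, mmHg),
#'   `volume_log` (data frame: `time_s`, `cum_hem_ml`, `cum_wb_ml`),
#'   `phases` (named times), `seed`.
#' @export
simulate_swine_subject <- function(config, subject_seed, weight_kg = NULL,
                                   subject_id = sprintf("S%03d", subject_seed),
                                   group_id = 0L) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(subject_seed, {
    if (is.null(weight_kg))
      weight_kg <- stats::runif(1, cfg$weight_range[1L], cfg$weight_range[2L])
    ebv <- cfg$estimated_blood_volume_constant * weight_kg
    fs <- cfg$sample_rate_analog
    tick <- 1 / cfg$sample_rate_volume            # 5 s controller cadence
    n_tick_samp <- as.integer(round(tick * fs))
    drift_phase <- stats::runif(1, 0, 2 * pi)
    hr0_jit <- stats::rnorm(1, 0, 2)              # subject-level variation
    pp0_jit <- stats::rnorm(1, 0, 1.5)
    map0_jit <- stats::rnorm(1, 0, 2)
    cfg$heart_rate_baseline <- cfg$heart_rate_baseline + hr0_jit
    cfg$pulse_pressure_baseline <- cfg$pulse_pressure_baseline + pp0_jit
    cfg$map_baseline <- cfg$map_baseline + map0_jit

    max_ticks <- as.integer(ceiling(
      (cfg$baseline_duration + 3 * cfg$max_phase_duration) / tick)) + 4L
    wave <- vector("list", max_ticks)
    vol_t <- numeric(max_ticks + 1L)
    vol_hem <- numeric(max_ticks + 1L)
    vol_wb <- numeric(max_ticks + 1L)

    phase <- "baseline"
    phases <- c(baseline_start = 0, hemorrhage_start = NA, hold_start = NA,
                resus_start = NA, resus_end = NA)
    cum_hem <- 0; cum_wb <- 0
    beat_phase <- 0
    comp <- 0                                     # hold-phase compensation, mmHg
    t_now <- 0
    k <- 0L
    phase_t0 <- 0
    hold_shed_total <- NA_real_                   # shed at start of resus
    last_map_meas <- cfg$map_baseline
    recent <- numeric(0)                          # last 2 ticks of pressure

    repeat {
      k <- k + 1L
      if (k > max_ticks) stop("simulation exceeded maximum record length")
      vol_t[k] <- t_now
      vol_hem[k] <- cum_hem
      vol_wb[k] <- cum_wb

      deficit <- (cum_hem - cum_wb) / ebv
      st <- physiology_state(cfg, deficit, comp)

      # synthesize this 5 s tick at the analog rate
      tt <- t_now + (seq_len(n_tick_samp) - 1L) / fs
      beat_u <- beat_phase + cumsum(rep(st$hr / 60 / fs, n_tick_samp))
      tmpl <- pulse_template(beat_u, dicrotic_amp = cfg$dicrotic_amp)
      dbp <- st$map - st$pp / 3
      drift <- cfg$drift_amplitude *
        sin(2 * pi * tt / cfg$drift_period + drift_phase)
      press <- dbp + st$pp * tmpl + drift
      if (cfg$noise_sd > 0)
        press <- press + stats::rnorm(n_tick_samp, 0, cfg$noise_sd)
      wave[[k]] <- press
      beat_phase <- beat_u[n_tick_samp]
      recent <- c(recent, press)
      if (length(recent) > 2L * n_tick_samp)
        recent <- recent[(length(recent) - 2L * n_tick_samp + 1L):
                           length(recent)]
      map_meas <- mean(recent)
      last_map_meas <- map_meas
      t_next <- t_now + tick

      # controller decision for the next tick
      if (phase == "baseline") {
        if (t_next >= cfg$baseline_duration) {
          phase <- "hemorrhage"; phases["hemorrhage_start"] <- t_next
          phase_t0 <- t_next
        }
      } else if (phase == "hemorrhage") {
        if (map_meas <= cfg$map_hemorrhage_target) {
          phase <- "hold"; phases["hold_start"] <- t_next; phase_t0 <- t_next
        } else if (t_next - phase_t0 > cfg$max_phase_duration) {
          stop("controller failed to reach the hemorrhage MAP target of ",
               cfg$map_hemorrhage_target, " mmHg (phase: hemorrhage)")
        } else {
          err <- map_meas - cfg$map_hemorrhage_target
          rate <- min(max(cfg$controller_gain * err, cfg$bleed_rate_min),
                      cfg$bleed_rate_max)
          cum_hem <- cum_hem + rate * tick / 60
        }
      } else if (phase == "hold") {
        comp <- min(comp + tick / 60, 5)          # slow autoregulatory creep
        err <- map_meas - cfg$map_hemorrhage_target
        if (err > 0.5) {
          rate <- min(cfg$controller_gain * err, cfg$bleed_rate_max)
          cum_hem <- cum_hem + rate * tick / 60
        }
        if (t_next - phase_t0 >= cfg$hold_duration) {
          phase <- "resus"; phases["resus_start"] <- t_next
          phase_t0 <- t_next
          hold_shed_total <- cum_hem
        }
      } else if (phase == "resus") {
        wb_cap <- cfg$wb_cap_frac * hold_shed_total
        reached <- map_meas >= cfg$map_resus_target
        if (!reached && t_next - phase_t0 > cfg$max_phase_duration)
          stop("controller failed to reach the resuscitation MAP target of ",
               cfg$map_resus_target, " mmHg (phase: resus)")
        err <- cfg$map_resus_target - map_meas
        if (err > 0 && cum_wb < wb_cap) {
          rate <- min(max(cfg$controller_gain * err, cfg$bleed_rate_min),
                      cfg$infusion_rate_max)
          cum_wb <- min(cum_wb + rate * tick / 60, wb_cap)
        }
        done_time <- t_next - phase_t0 >= cfg$resus_min_duration
        if (done_time && reached) {
          phases["resus_end"] <- t_next
          vol_t[k + 1L] <- t_next; vol_hem[k + 1L] <- cum_hem
          vol_wb[k + 1L] <- cum_wb
          break
        }
      }
      t_now <- t_next
    }

    waveform <- uniform_series(unlist(wave[seq_len(k)]), fs, 0)
    vol <- data.frame(time_s = vol_t[seq_len(k + 1L)],
                      cum_hem_ml = vol_hem[seq_len(k + 1L)],
                      cum_wb_ml = vol_wb[seq_len(k + 1L)])
    structure(list(subject_id = subject_id, group_id = as.integer(group_id),
                   weight_kg = weight_kg, waveform = waveform,
                   volume_log = vol, phases = phases,
                   seed = as.integer(subject_seed)),
              class = "subject_record")
  })
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf(
    "<subject_record> %s (group %d, %.1f kg): %.0f s record, shed %.0f mL, WB %.0f mL\n",
    x$subject_id, x$group_id, x$weight_kg,
    length(x$waveform$values) / x$waveform$rate,
    max(x$volume_log$cum_hem_ml), max(x$volume_log$cum_wb_ml)))
  invisible(x)
}

#' Simulate a swine cohort
#'
#' `n_subjects` records with weights drawn uniformly from the configured
#' range and round-robin group assignment; per-subject seeds are derived from
#' `config$seed`, so the same config always yields the same cohort.
#'
#' @param config A [sim_config()].
#' @return List of `subject_record`s.
#' @export
simulate_swine_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_subjects %% config$n_groups != 0L)
    stop("n_subjects must be divisible by n_groups")
  lapply(seq_len(config$n_subjects), function(i) {
    simulate_swine_subject(
      config, subject_seed = config$seed * 1000L + i,
      subject_id = sprintf("S%02d", i),
      group_id = (i - 1L) %% config$n_groups)
  })
}

#' Simulate one LBNP (lower body negative pressure) subject
#'
#' Stepwise vacuum staircase rising to the subject's decompensation level
#' (`lbnp_hdd`); pulse pressure falls and heart rate rises with
#' `lbnp / lbnp_hdd` while MAP stays nearly compensated. Used to train the
#' compensatory-reserve (CRM) model.
#'
#' @param config A [sim_config()].
#' @param subject_seed Integer seed.
#' @param subject_id Identifier.
#' @return A list of class `lbnp_record` with fields `subject_id`, `waveform`
#'   (`uniform_series`), `lbnp_schedule` (data frame `time_s`, `lbnp_mmhg`),
#'   `lbnp_hdd`, `baseline_duration`, `seed`.
#' @export
simulate_lbnp_subject <- function(config, subject_seed,
                                  subject_id = sprintf("L%03d", subject_seed)) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(subject_seed, {
    hdd <- stats::runif(1, cfg$lbnp_hdd_range[1L], cfg$lbnp_hdd_range[2L])
    fs <- cfg$sample_rate_analog
    base_dur <- 300
    n_steps <- cfg$lbnp_n_steps
    step_dur <- cfg$lbnp_step_duration
    seg_lbnp <- c(0, hdd * seq_len(n_steps) / n_steps)
    seg_dur <- c(base_dur, rep(step_dur, n_steps))
    seg_t0 <- cumsum(c(0, seg_dur[-length(seg_dur)]))
    drift_phase <- stats::runif(1, 0, 2 * pi)
    hr0 <- cfg$heart_rate_baseline + stats::rnorm(1, 0, 2)
    pp0 <- cfg$pulse_pressure_baseline + stats::rnorm(1, 0, 1.5)
    map0 <- cfg$map_baseline + stats::rnorm(1, 0, 2)

    beat_phase <- 0
    wave <- vector("list", length(seg_lbnp))
    for (i in seq_along(seg_lbnp)) {
      frac <- seg_lbnp[i] / hdd
      pp <- pp0 * max(cfg$pp_floor_frac, 1 - 0.6 * frac)
      hr <- hr0 * (1 + 0.5 * frac)
      map <- map0 - 5 * frac                     # nearly compensated
      n <- as.integer(round(seg_dur[i] * fs))
      tt <- seg_t0[i] + (seq_len(n) - 1L) / fs
      beat_u <- beat_phase + cumsum(rep(hr / 60 / fs, n))
      tmpl <- pulse_template(beat_u, dicrotic_amp = cfg$dicrotic_amp)
      press <- (map - pp / 3) + pp * tmpl +
        cfg$drift_amplitude * sin(2 * pi * tt / cfg$drift_period + drift_phase)
      if (cfg$noise_sd > 0) press <- press + stats::rnorm(n, 0, cfg$noise_sd)
      wave[[i]] <- press
      beat_phase <- beat_u[n]
    }
    schedule <- data.frame(time_s = seg_t0, lbnp_mmhg = seg_lbnp)
    structure(list(subject_id = subject_id,
                   waveform = uniform_series(unlist(wave), fs, 0),
                   lbnp_schedule = schedule, lbnp_hdd = hdd,
                   baseline_duration = base_dur,
                   seed = as.integer(subject_seed)),
              class = "lbnp_record")
  })
}

#' Simulate an LBNP cohort
#' @param config A [sim_config()].
#' @param n Number of LBNP subjects.
#' @return List of `lbnp_record`s.
#' @export
simulate_lbnp_cohort <- function(config, n = 4L) {
  lapply(seq_len(n), function(i)
    simulate_lbnp_subject(config, subject_seed = config$seed * 1000L + 500L + i,
                          subject_id = sprintf("L%02d", i)))
}

#' Write / read a subject record as plain text
#'
#' One two-column waveform file (`time_s`, `pressure_mmhg`), one three-column
#' volume file (`time_s`, `cum_hem_ml`, `cum_wb_ml`), and one JSON sidecar
#' (weight, phases, group, seed).
#'
#' @param record A `subject_record`.
#' @param dir Output directory (created if needed).
#' @return `read_subject_record` returns a `subject_record`.
#' @export
write_subject_record <- function(record, dir) {
  stopifnot(inherits(record, "subject_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- record$waveform
  utils::write.table(
    data.frame(time_s = series_times(w), pressure_mmhg = w$values),
    file.path(dir, "waveform.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.table(record$volume_log, file.path(dir, "volume.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(subject_id = record$subject_id, group_id = record$group_id,
         weight_kg = record$weight_kg, phases = as.list(record$phases),
         seed = record$seed),
    file.path(dir, "subject.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_subject_record
#' @export
read_subject_record <- function(dir) {
  w <- utils::read.table(file.path(dir, "waveform.tsv"), header = TRUE,
                         sep = "\t")
  rate <- 1 / stats::median(diff(w$time_s))
  meta <- jsonlite::read_json(file.path(dir, "subject.json"),
                              simplifyVector = TRUE)
  structure(list(subject_id = meta$subject_id,
                 group_id = as.integer(meta$group_id),
                 weight_kg = meta$weight_kg,
                 waveform = uniform_series(w$pressure_mmhg, rate,
                                           w$time_s[1L]),
                 volume_log = utils::read.table(file.path(dir, "volume.tsv"),
                                                header = TRUE, sep = "\t"),
                 phases = unlist(meta$phases), seed = meta$seed),
            class = "subject_record")
}
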