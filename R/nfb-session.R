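#' Neurofeedback session schedule
#'
#' The trial's session layout: a 3-minute rest baseline (no feedback,
#' used for threshold calibration) followed by 20 minutes of training split
#' into seven periods (six 3-minute periods and one final 2-minute period).
#'
#' @param rest_s rest baseline duration in seconds.
#' @param periods ordered training period durations in seconds.
#' @return An object of class `session_schedule`.
#' @export
#' @examples
#' sch <- session_schedule()
#' sum(sch$periods) / 60 # 20 minutes
session_schedule <- function(rest_s = 180,
                             periods = c(180, 180, 180, 180, 180, 180, 120)) {
  assert_scalar_pos(rest_s, "rest_s")
  stopifnot(is.numeric(periods), all(periods > 0))
  structure(list(rest_s = rest_s, periods = periods),
            class = "session_schedule")
}

.session_log <- function(df, rest_amps, session_number, mode, plant = NULL,
                         schedule = NULL) {
  structure(
    list(log = df, rest_amps = rest_amps,
         rest_baseline_amp = mean(rest_amps),
         session_number = session_number, mode = mode, plant = plant,
         schedule = schedule),
    class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf(
    "<session_log> session %d (%s): %d epochs, rest baseline %.2f uV, reward rate %.1f%%\n",
    x$session_number, x$mode, nrow(x$log), x$rest_baseline_amp,
    100 * mean(x$log$reward)))
  invisible(x)
}

#' Simulate one closed-loop neurofeedback session
#'
#' Runs the plant through the rest baseline (no drive), calibrates the
#' reward threshold at the target quantile of the rest amplitudes, then
#' simulates the seven training periods at one feedback epoch per `dt`
#' seconds. In `active` mode a rewarded epoch (amplitude below threshold)
#' applies full suppression drive on the next step, closing the loop; in
#' `sham` mode the plant never receives contingent drive. The threshold is
#' re-examined only at period boundaries, using the trailing 30 s of
#' feedback epochs ([adapt_threshold()]).
#'
#' @param plant a [plant_state()]; the returned log carries the final state
#'   so sessions can be chained.
#' @param schedule a [session_schedule()].
#' @param mode `"active"` or `"sham"`.
#' @param session_number session index (1-19).
#' @param seed RNG seed for the plant noise.
#' @param target_reward,hi,lo controller parameters (see
#'   [calibrate_threshold()] and [adapt_threshold()]).
#' @param dt feedback epoch step in seconds (default 0.4, the 0.5 s epoch /
#'   0.1 s overlap hop).
#' @return A `session_log`: data frame `log` with columns `time`,
#'   `alpha_amp`, `threshold`, `reward`, `period`, plus the rest amplitudes,
#'   rest baseline, mode, and the final plant state.
#' @export
run_session <- function(plant, schedule = session_schedule(),
                        mode = c("active", "sham"), session_number = 1,
                        seed = NULL, target_reward = 0.65, hi = 0.90,
                        lo = 0.50, dt = 0.4) {
  stopifnot(inherits(plant, "plant_state"),
            inherits(schedule, "session_schedule"))
  mode <- match.arg(mode)
  local_seed(seed, {
    n_rest <- round(schedule$rest_s / dt)
    rest_amps <- numeric(n_rest)
    for (e in seq_len(n_rest)) {
      plant <- plant_step(plant, 0, dt)
      rest_amps[e] <- plant$alpha_current
    }
    thr <- calibrate_threshold(rest_amps, target_reward)

    n_win <- round(30 / dt) # 30 s adaptation window
    n_per <- round(schedule$periods / dt)
    n_tot <- sum(n_per)
    amp <- thr_v <- numeric(n_tot)
    rew <- logical(n_tot)
    per <- rep(seq_along(n_per), n_per)
    i <- 0L
    last_reward <- FALSE
    for (p in seq_along(n_per)) {
      if (p > 1L) {
        w <- amp[max(1L, i - n_win + 1L):i]
        thr <- adapt_threshold(w, thr, target_reward, hi, lo)
      }
      for (e in seq_len(n_per[p])) {
        i <- i + 1L
        drive <- if (mode == "active" && last_reward) 1 else 0
        plant <- plant_step(plant, drive, dt)
        amp[i] <- plant$alpha_current
        thr_v[i] <- thr
        rew[i] <- amp[i] < thr
        last_reward <- rew[i]
      }
    }
    df <- data.frame(time = seq_len(n_tot) * dt, alpha_amp = amp,
                     threshold = thr_v, reward = rew, period = per)
    .session_log(df, rest_amps, session_number, mode, plant, schedule)
  })
}

#' Run the reward controller over a precomputed amplitude stream
#'
#' Applies threshold calibration, the epoch reward rule and period-boundary
#' adaptation to fixed rest/training amplitude sequences (no plant in the
#' loop). This is the open-loop view of the controller, used to verify the
#' stationary reward rate of the percentile calibration rule.
#'
#' @param rest_amps rest-baseline per-epoch amplitudes.
#' @param train_amps training per-epoch amplitudes; length must match the
#'   schedule at step `dt`.
#' @inheritParams run_session
#' @return A `session_log` (mode `"active"`).
#' @export
#' @examples
#' set.seed(1)
#' log <- controller_replay(rlnorm(450), rlnorm(3000))
#' mean(log$log$reward) # ~ 0.65
controller_replay <- function(rest_amps, train_amps,
                              schedule = session_schedule(),
                              target_reward = 0.65, hi = 0.90, lo = 0.50,
                              dt = 0.4, session_number = 1) {
  stopifnot(inherits(schedule, "session_schedule"))
  n_per <- round(schedule$periods / dt)
  if (length(train_amps) != sum(n_per)) {
    stop(sprintf("`train_amps` must have %d epochs for this schedule",
                 sum(n_per)), call. = FALSE)
  }
  thr <- calibrate_threshold(rest_amps, target_reward)
  n_win <- round(30 / dt)
  n_tot <- sum(n_per)
  thr_v <- numeric(n_tot)
  per <- rep(seq_along(n_per), n_per)
  i <- 0L
  for (p in seq_along(n_per)) {
    if (p > 1L) {
      w <- train_amps[max(1L, i - n_win + 1L):i]
      thr <- adapt_threshold(w, thr, target_reward, hi, lo)
    }
    idx <- i + seq_len(n_per[p])
    thr_v[idx] <- thr
    i <- i + n_per[p]
  }
  rew <- train_amps < thr_v
  df <- data.frame(time = seq_len(n_tot) * dt, alpha_amp = train_amps,
                   threshold = thr_v, reward = rew, period = per)
  .session_log(df, rest_amps, session_number, "active",
               schedule = schedule)
}

#' Simulate a yoked sham session
#'
#' The sham participant is shown the reward sequence recorded from a
#' matched active ("donor") session of the same session number, while their
#' own plant runs free of contingent drive; displayed feedback is therefore
#' statistically identical to active feedback but uncorrelated with the
#' recipient's own alpha amplitude.
#'
#' @param donor_log an active-mode `session_log` to replay.
#' @param recipient_plant the sham participant's [plant_state()].
#' @param seed RNG seed for the recipient plant noise.
#' @param session_number must match the donor's (checked; default takes the
#'   donor's).
#' @param dt feedback epoch step in seconds.
#' @return A `session_log` with mode `"sham"`: `alpha_amp` is the
#'   recipient's own amplitude, `reward` and `threshold` are the displayed
#'   (donor) sequences.
#' @export
yoked_sham_session <- function(donor_log, recipient_plant, seed = NULL,
                               session_number = NULL, dt = 0.4) {
  stopifnot(inherits(donor_log, "session_log"),
            inherits(recipient_plant, "plant_state"))
  if (donor_log$mode != "active") {
    stop("donor session must be active-mode", call. = FALSE)
  }
  session_number <- session_number %||% donor_log$session_number
  if (session_number != donor_log$session_number) {
    stop("sham session number must match the donor session", call. = FALSE)
  }
  schedule <- donor_log$schedule %||% session_schedule()
  local_seed(seed, {
    plant <- recipient_plant
    n_rest <- round(schedule$rest_s / dt)
    rest_amps <- numeric(n_rest)
    for (e in seq_len(n_rest)) {
      plant <- plant_step(plant, 0, dt)
      rest_amps[e] <- plant$alpha_current
    }
    n_tot <- nrow(donor_log$log)
    amp <- numeric(n_tot)
    for (i in seq_len(n_tot)) {
      plant <- plant_step(plant, 0, dt)
      amp[i] <- plant$alpha_current
    }
    df <- data.frame(time = donor_log$log$time, alpha_amp = amp,
                     threshold = donor_log$log$threshold,
                     reward = donor_log$log$reward,
                     period = donor_log$log$period)
    .session_log(df, rest_amps, session_number, "sham", plant, schedule)
  })
}

#' Per-period alpha change relative to the session rest baseline
#'
#' @param log a `session_log` with positive rest baseline.
#' @return Numeric vector: per training period, `100 * (mean period
#'   amplitude - rest baseline) / rest baseline`.
#' @export
percent_change_from_rest <- function(log) {
  stopifnot(inherits(log, "session_log"))
  b <- log$rest_baseline_amp
  if (!is.finite(b) || b <= 0) {
    stop("rest baseline amplitude must be positive", call. = FALSE)
  }
  means <- tapply(log$log$alpha_amp, log$log$period, mean)
  as.numeric(100 * (means - b) / b)
}
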