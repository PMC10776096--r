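# Closed-loop probe alignment simulation
#
# A proportional controller drives a stepper motor that rotates the
# ultrasound probe so the fibers appear horizontal: each control cycle the
# fiber angle measured in the image is multiplied by the gain kp = -0.2 to
# give an incremental rotation, quantized to whole motor steps of 1.8 deg
# with the fractional remainder carried to the next cycle, executed with a
# velocity profile bounded by v_max = 1.75 rad/s, and clamped by end switches
# at +/-45 deg.

#' Controller and motor state
#'
#' @param probe_angle Current probe rotation in degrees.
#' @param kp Proportional gain (default -0.2; negative so a positive measured
#'   angle rotates the probe to reduce it).
#' @param step_size Motor step size in degrees (default 1.8, i.e. 200 steps
#'   per revolution).
#' @param limit End-switch travel limit in degrees (default 45).
#' @param v_max Maximum angular velocity in rad/s (default 1.75).
#' @param step_residual Fractional steps carried between cycles.
#' @param direct_dt Per-step interval in seconds for short (< 5 step)
#'   commands executed directly (default 0.02).
#' @return An object of class `controller_state`.
#' @export
controller_state <- function(probe_angle = 0, kp = -0.2, step_size = 1.8,
                             limit = 45, v_max = 1.75, step_residual = 0,
                             direct_dt = 0.02) {
  if (step_size <= 0) pa_stop("pa_param_error", "step_size must be positive")
  if (v_max <= 0) pa_stop("pa_param_error", "v_max must be positive")
  if (abs(probe_angle) > limit)
    pa_stop("pa_param_error", "|probe_angle| must not exceed the %g deg limit", limit)
  structure(list(probe_angle = probe_angle, kp = kp, step_size = step_size,
                 limit = limit, v_max = v_max, step_residual = step_residual,
                 direct_dt = direct_dt, at_limit = abs(probe_angle) >= limit),
            class = "controller_state")
}

#' One proportional control step
#'
#' The commanded incremental rotation is `kp * measured_angle` degrees. Raw
#' steps are `delta / step_size` plus the carried residual; the command is the
#' nearest whole step count (rounding half away from zero) and the new
#' fractional residual is persisted in the state. Without the residual the
#' printed gain and step size would imply a 4.5 deg deadband; carrying it lets
#' the loop settle within half a step of the target. Once the measured angle
#' is within half a step of the 0 deg target the residual is not accumulated
#' further (a quantized actuator cannot improve on that), which pins the
#' settled loop inside +/- step_size / 2 instead of drifting into a slow
#' limit cycle.
#'
#' @param measured_angle Fiber angle measured in the image (degrees).
#' @param state A [controller_state()].
#' @return List with `command` (a `motor_command`) and the updated `state`.
#' @export
control_step <- function(measured_angle, state) {
  stopifnot(inherits(state, "controller_state"))
  if (!is.finite(measured_angle))
    pa_stop("pa_param_error", "measured_angle must be finite")
  if (abs(measured_angle) <= state$step_size / 2) {
    # inside the quantization window: hold, and stop integrating the residual
    state$step_residual <- 0
    command <- structure(list(n_steps = 0, per_step_times = numeric(0)),
                         class = "motor_command")
    return(list(command = command, state = state))
  }
  delta <- state$kp * measured_angle
  raw <- delta / state$step_size + state$step_residual
  n <- round_half_away(raw) # numeric: step counts can exceed integer range
  state$step_residual <- raw - n
  command <- structure(
    list(n_steps = n,
         per_step_times = velocity_profile(n, v_max = state$v_max,
                                           step_size = state$step_size,
                                           direct_dt = state$direct_dt)),
    class = "motor_command")
  list(command = command, state = state)
}

#' Per-step timing of a motor command
#'
#' Commands of fewer than five steps are executed directly at a constant
#' rate. Longer commands use a symmetric smoothed profile with an exponential
#' rise to `v_max` and mirrored fall, `v(i) = v_max (1 - exp(-ramp_i / tau))`
#' with `ramp_i = min(i, n + 1 - i)` and `tau = max(1, n / 5)`, so the
#' instantaneous velocity never reaches `v_max` and jerk at the ends is
#' avoided.
#'
#' @param n_steps Signed or unsigned step count.
#' @param v_max Velocity bound in rad/s (default 1.75).
#' @param step_size Step size in degrees (default 1.8).
#' @param direct_dt Constant per-step interval for direct execution (s).
#' @param direct_threshold Commands with `|n| <` this many steps run directly
#'   (default 5).
#' @return Numeric vector of per-step durations in seconds (length `|n|`).
#' @export
velocity_profile <- function(n_steps, v_max = 1.75, step_size = 1.8,
                             direct_dt = 0.02, direct_threshold = 5) {
  n <- abs(round(n_steps))
  if (n == 0) return(numeric(0))
  if (n > 1e6)
    pa_stop("pa_param_error",
            "refusing to build a per-step timing vector for %g steps", n)
  if (n < direct_threshold) return(rep(direct_dt, n))
  tau <- max(1, n / 5)
  i <- seq_len(n)
  ramp <- pmin(i, n + 1 - i)
  v <- v_max * (1 - exp(-ramp / tau))
  (step_size * pi / 180) / v
}

#' Apply a motor command to the state
#'
#' Rotates the probe by `n_steps * step_size` degrees, truncating at the
#' end-switch limit: when the limit is hit, untaken steps are discarded, the
#' probe angle saturates exactly at the limit, `at_limit` is set and the step
#' residual is zeroed.
#'
#' @param state A [controller_state()].
#' @param command A `motor_command` from [control_step()].
#' @return The updated `controller_state`.
#' @export
apply_command <- function(state, command) {
  stopifnot(inherits(state, "controller_state"))
  target <- state$probe_angle + command$n_steps * state$step_size
  if (abs(target) > state$limit) {
    state$probe_angle <- sign(target) * state$limit
    state$at_limit <- TRUE
    state$step_residual <- 0
  } else {
    state$probe_angle <- target
    state$at_limit <- abs(target) >= state$limit
  }
  state
}

#' Reference homing motion
#'
#' Initializes the motor without a rotary encoder: rotate across the complete
#' range of motion between the two end switches, count the steps, then rotate
#' half of them back so a symmetric span homes the probe to 0 deg.
#'
#' @param span_degrees Total travel between end switches (default 90).
#' @param step_size Motor step size in degrees (default 1.8).
#' @return List with `counted_steps`, `steps_back`, `home_angle` (deviation
#'   from mid-span after homing, 0 for an even count over an exact-multiple
#'   span), `residual_degrees` (span remainder when not an integer multiple
#'   of the step size) and `degenerate` (TRUE when at most one step spans the
#'   range).
#' @export
reference_motion <- function(span_degrees = 90, step_size = 1.8) {
  if (span_degrees <= 0) pa_stop("pa_param_error", "span must be positive")
  if (step_size <= 0) pa_stop("pa_param_error", "step_size must be positive")
  counted <- as.integer(floor(span_degrees / step_size + 1e-9))
  residual <- span_degrees - counted * step_size
  degenerate <- counted <= 1L
  steps_back <- counted %/% 2L
  home_angle <- span_degrees / 2 - steps_back * step_size
  list(counted_steps = counted, steps_back = steps_back,
       home_angle = home_angle, residual_degrees = residual,
       degenerate = degenerate)
}

#' Run the closed alignment loop against phantom dynamics
#'
#' Each control cycle the phantom's true pennation angle is combined with the
#' current probe rotation into the apparent fiber angle in the image
#' (`apparent = theta_true + probe_angle`, so the negative gain drives the
#' apparent angle toward the 0 deg control target), the angle is measured
#' either by the ideal oracle or by the full image pipeline on a freshly
#' rendered phantom, and the resulting command is applied with quantization,
#' residual carry and end-switch clamping. A sensor failure in a cycle holds
#' the motor (no step) and logs NA.
#'
#' @param protocol A [trial_protocol()] providing the activation and
#'   pennation dynamics.
#' @param config A [phantom_config()] used by the `"hough"` sensor.
#' @param state Initial [controller_state()].
#' @param sensor `"ideal"` (oracle returning the apparent angle exactly) or
#'   `"hough"` (render a phantom at the apparent angle and run
#'   [estimate_fiber_angle()]).
#' @param cycle_rate Control cycles per second (default the 19 Hz video rate).
#' @param seed Seed for per-cycle phantom rendering.
#' @return An object of class `closed_loop_result`: data.frame `trace` with
#'   columns `t`, `theta_true`, `probe_angle`, `measured_angle`, `n_steps`,
#'   plus `alignment_error` (absolute measured angle), the final state and
#'   run parameters.
#' @export
run_closed_loop <- function(protocol, config = phantom_config(),
                            state = controller_state(),
                            sensor = c("ideal", "hough"),
                            cycle_rate = 19, seed = 1L) {
  stopifnot(inherits(protocol, "trial_protocol"),
            inherits(state, "controller_state"))
  sensor <- match.arg(sensor)
  if (cycle_rate <= 0) pa_stop("pa_param_error", "cycle_rate must be positive")
  n <- as.integer(round(protocol$duration * cycle_rate))
  tt <- (seq_len(n) - 1) / cycle_rate
  a <- protocol$activation_profile(tt)
  theta_true <- protocol$theta_rest + protocol$delta_theta * a

  trace <- data.frame(t = tt, theta_true = theta_true, probe_angle = NA_real_,
                      measured_angle = NA_real_, n_steps = NA_real_)
  n_failures <- 0L
  for (k in seq_len(n)) {
    apparent <- theta_true[k] + state$probe_angle
    measured <- if (sensor == "ideal") {
      apparent
    } else {
      cfg_k <- config
      cfg_k$fiber_angle <- clamp(apparent, -89.9, 90)
      cfg_k$seed <- as.integer(derive_seed(seed, k))
      roi <- generate_bmode_phantom(cfg_k)
      tryCatch(estimate_fiber_angle(roi)$angle,
               pennalign_error = function(e) NA_real_)
    }
    if (is.na(measured)) {
      n_failures <- n_failures + 1L
      trace$n_steps[k] <- 0 # hold: sensor failed, no step issued
    } else {
      cs <- control_step(measured, state)
      state <- apply_command(cs$state, cs$command)
      trace$n_steps[k] <- cs$command$n_steps
    }
    trace$measured_angle[k] <- measured
    trace$probe_angle[k] <- state$probe_angle
  }
  structure(list(trace = trace,
                 alignment_error = abs(trace$measured_angle),
                 final_state = state, sensor = sensor,
                 cycle_rate = cycle_rate, n_failures = n_failures,
                 protocol = protocol, seed = seed),
            class = "closed_loop_result")
}

#' @export
print.closed_loop_result <- function(x, ...) {
  err <- x$alignment_error[!is.na(x$alignment_error)]
  cat(sprintf(paste0("<closed_loop_result> %d cycles @ %g Hz (%s sensor), ",
                     "%d sensor failures\n"),
              nrow(x$trace), x$cycle_rate, x$sensor, x$n_failures))
  cat(sprintf("  mean |error| %.2f deg, final |error| %.2f deg, final probe %.1f deg\n",
              mean(err), tail(err, 1), x$final_state$probe_angle))
  invisible(x)
}

#' Write a closed-loop run to disk
#'
#' @param result A [run_closed_loop()] result.
#' @param dir Output directory (created if needed); writes `trace.csv` and a
#'   `manifest.json` with gains, rates and seed.
#' @return `dir`, invisibly.
#' @export
write_closed_loop <- function(result, dir) {
  stopifnot(inherits(result, "closed_loop_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$trace, file.path(dir, "trace.csv"), row.names = FALSE)
  st <- result$final_state
  manifest <- list(sensor = result$sensor, cycle_rate = result$cycle_rate,
                   kp = st$kp, step_size = st$step_size, limit = st$limit,
                   v_max = st$v_max, seed = result$seed,
                   n_failures = result$n_failures)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
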