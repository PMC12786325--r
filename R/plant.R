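#' PID controller gains
#'
#' Gains of the discrete PID controller that regulates the medium level of the
#' open culture dish. The controller acts on the level error in mm and emits a
#' dimensionless flow command that the pump converts to a flow rate via its
#' gain (see [plant_params()]).
#'
#' @param kp proportional gain (flow-command units per mm of error).
#' @param ki integral gain (per mm\eqn{\cdot}s).
#' @param kd derivative gain (per mm/s).
#' @param ts control interval in seconds.
#' @return an object of class `controller_gains`.
#' @export
#' @examples
#' controller_gains(kp = 0.3) # proportional-only, the bench default
controller_gains <- function(kp = 0.3, ki = 0, kd = 0, ts = 0.1) {
  check_finite_scalar(kp, "kp", min = 0)
  check_finite_scalar(ki, "ki", min = 0)
  check_finite_scalar(kd, "kd", min = 0)
  check_finite_scalar(ts, "ts", min = 0, strict_min = TRUE)
  structure(list(kp = kp, ki = ki, kd = kd, ts = ts),
            class = "controller_gains")
}

#' PID controller state
#'
#' Running state of the discrete controller: the setpoint, the accumulated
#' (rectangular-rule) integral of the error, and the previous-step error used
#' by the backward-difference derivative. Both history terms start at zero.
#'
#' @param setpoint target liquid level in mm.
#' @return an object of class `controller_state`.
#' @export
controller_state <- function(setpoint) {
  check_finite_scalar(setpoint, "setpoint")
  structure(list(setpoint = setpoint, integral_accum = 0, prev_error = 0),
            class = "controller_state")
}

#' Open-dish fluid plant parameters
#'
#' Physical description of the culture dish and its actuation: dish surface
#' area, evaporative loss, the pump gain translating a unit controller command
#' into a flow rate, actuator saturation, and the quantum of the laser
#' distance sensor (0.1 mm, i.e. 100 um precision).
#'
#' @param dish_area dish surface area in mm^2.
#' @param evaporation_rate evaporative loss in uL/min.
#' @param pump_gain flow in uL/min produced per unit of controller command.
#' @param max_flow actuator saturation in uL/min (applies to |flow|).
#' @param sensor_quantum level sensor resolution in mm (0 disables
#'   quantization).
#' @param initial_level starting level in mm.
#' @return an object of class `plant_params`.
#' @seealso [reference_plant()] for the default bench configuration.
#' @export
plant_params <- function(dish_area, evaporation_rate = 0, pump_gain = 1000,
                         max_flow = Inf, sensor_quantum = 0.1,
                         initial_level = 5) {
  check_finite_scalar(dish_area, "dish_area", min = 0, strict_min = TRUE)
  check_finite_scalar(evaporation_rate, "evaporation_rate", min = 0)
  check_finite_scalar(pump_gain, "pump_gain", min = 0, strict_min = TRUE)
  if (!is.numeric(max_flow) || length(max_flow) != 1L || is.na(max_flow) ||
      max_flow <= 0) {
    stop_bad_arg("max_flow", "must be a single positive number (Inf allowed)")
  }
  check_finite_scalar(sensor_quantum, "sensor_quantum", min = 0)
  check_finite_scalar(initial_level, "initial_level", min = 0)
  if (evaporation_rate >= max_flow) {
    stop_bad_arg("evaporation_rate",
                 "must be smaller than the saturated actuator flow")
  }
  structure(list(dish_area = dish_area, evaporation_rate = evaporation_rate,
                 pump_gain = pump_gain, max_flow = max_flow,
                 sensor_quantum = sensor_quantum,
                 initial_level = initial_level),
            class = "plant_params")
}

#' Reference bench plant
#'
#' The default plant used for controller validation: a 6 mm diameter medium
#' well (28.27 mm^2), a peristaltic pump delivering 5 uL/min of flow per
#' thousandth of a unit command (5 mL/min per unit command) saturating at
#' 5 mL/min, 20 uL/min evaporation at 37 C, and a 0.1 mm laser sensor quantum.
#' With the proportional-only gains `Kp = 0.3` this loop has a closed-loop
#' time constant of about 1.1 s, so a +2 mm level disturbance settles to
#' within 0.2 mm of the setpoint in under 3 s.
#'
#' @param initial_level starting level in mm.
#' @return an object of class `plant_params`.
#' @export
#' @examples
#' reference_plant()
reference_plant <- function(initial_level = 5) {
  plant_params(dish_area = pi * 3^2, evaporation_rate = 20, pump_gain = 5000,
               max_flow = 5000, sensor_quantum = 0.1,
               initial_level = initial_level)
}

#' One discrete PID control step
#'
#' Positional-form discrete PID with rectangular integration and a
#' backward-difference derivative:
#' \deqn{u(t) = K_p e(t) + K_i \sum_{\tau \le t} e(\tau) T_s +
#'       K_d \frac{e(t) - e(t-1)}{T_s}}
#' where \eqn{e(t)} is the setpoint minus the measured level and \eqn{T_s} the
#' control interval. The one-step delay of the error corresponds to the unit
#' delay operator of the z-domain formulation of the controller.
#'
#' @param gains a [controller_gains()] object.
#' @param state a [controller_state()] object.
#' @param measured_level measured level in mm.
#' @param freeze_integral if `TRUE`, the integral accumulator is not advanced
#'   (conditional-integration anti-windup, used while the actuator is
#'   saturated).
#' @return a list with `command` (flow-command units) and `state`, the updated
#'   controller state.
#' @export
#' @examples
#' st <- controller_state(setpoint = 5)
#' pid_command(controller_gains(kp = 0.3), st, measured_level = 4)$command
pid_command <- function(gains, state, measured_level, freeze_integral = FALSE) {
  stopifnot(inherits(gains, "controller_gains"),
            inherits(state, "controller_state"))
  if (!is.numeric(measured_level) || length(measured_level) != 1L ||
      !is.finite(measured_level)) {
    stop_bad_arg("measured_level", "must be a single finite number")
  }
  e <- state$setpoint - measured_level
  integral <- if (freeze_integral) state$integral_accum else
    state$integral_accum + e * gains$ts
  command <- gains$kp * e + gains$ki * integral +
    gains$kd * (e - state$prev_error) / gains$ts
  state$integral_accum <- integral
  state$prev_error <- e
  list(command = command, state = state)
}

#' Advance the fluid plant by one interval
#'
#' Mass balance of the open dish: the level changes by the net volumetric
#' rate (actuated flow minus evaporation) divided by the dish area. A dry
#' dish clips at level 0 with a warning.
#'
#' @param params a [plant_params()] object.
#' @param level current true level in mm.
#' @param net_flow actuated flow in uL/min (positive = inflow).
#' @param dt time step in seconds.
#' @return the new level in mm.
#' @export
plant_step <- function(params, level, net_flow, dt) {
  stopifnot(inherits(params, "plant_params"))
  check_finite_scalar(dt, "dt", min = 0, strict_min = TRUE)
  check_finite_scalar(net_flow, "net_flow")
  new_level <- level +
    (net_flow - params$evaporation_rate) * dt / 60 / params$dish_area
  if (new_level < 0) {
    warning("dish ran dry: level clipped at 0 mm", call. = FALSE)
    new_level <- 0
  }
  new_level
}

#' Simulate the closed liquid-level control loop
#'
#' Runs the full loop at the controller interval `ts`: the true level is
#' quantized by the sensor, fed to the discrete PID, the command is converted
#' to a flow by the pump gain and saturated at `max_flow`, and the plant is
#' advanced by the mass balance. The integral accumulator is frozen while the
#' actuator is saturated (anti-windup). A level disturbance is modelled as an
#' instantaneous step added to the true level.
#'
#' @param params a [plant_params()] object.
#' @param gains a [controller_gains()] object.
#' @param setpoint target level in mm.
#' @param duration simulated time in seconds; must be a multiple of
#'   `gains$ts`.
#' @param disturbance numeric vector `c(time_s, step_mm)`; the step is added
#'   to the level at the first control instant `>= time_s`.
#' @return an object of class `level_trace`: a data frame with columns
#'   `time_s`, `level_mm` (true level at the measurement instant),
#'   `measured_mm` (quantized), `command` (controller output) and
#'   `flow_ul_min` (saturated actuated flow applied over the following
#'   interval).
#' @export
#' @examples
#' tr <- run_closed_loop(reference_plant(initial_level = 7),
#'                       controller_gains(kp = 0.3), setpoint = 5,
#'                       duration = 10)
#' max(abs(tr$level_mm[tr$time_s >= 3] - 5))
run_closed_loop <- function(params, gains, setpoint, duration,
                            disturbance = c(time_s = 0, step_mm = 0)) {
  stopifnot(inherits(params, "plant_params"),
            inherits(gains, "controller_gains"))
  check_finite_scalar(setpoint, "setpoint")
  check_finite_scalar(duration, "duration", min = 0, strict_min = TRUE)
  if (length(disturbance) != 2L || any(!is.finite(disturbance))) {
    stop_bad_arg("disturbance", "must be c(time_s, step_mm), both finite")
  }
  n_steps <- round(duration / gains$ts)
  if (abs(n_steps * gains$ts - duration) > 1e-9) {
    stop_bad_arg("duration", "must be a multiple of the control interval ts")
  }
  d_time <- disturbance[[1]]
  d_step <- disturbance[[2]]
  if (d_time > duration) {
    stop_bad_arg("disturbance", "disturbance time exceeds the run duration")
  }
  escape <- 10 * max(abs(d_step), 1)

  state <- controller_state(setpoint)
  level <- params$initial_level
  times <- (seq_len(n_steps) - 1L) * gains$ts
  levels <- measured <- commands <- flows <- numeric(n_steps)
  disturbed <- FALSE

  for (k in seq_len(n_steps)) {
    if (!disturbed && times[k] >= d_time) {
      level <- level + d_step
      disturbed <- TRUE
    }
    if (abs(level - setpoint) > escape) {
      stop(sprintf(
        "closed loop diverging: |level - setpoint| = %.2f mm at t = %.2f s",
        abs(level - setpoint), times[k]), call. = FALSE)
    }
    meas <- if (params$sensor_quantum > 0) {
      round(level / params$sensor_quantum) * params$sensor_quantum
    } else level
    res <- pid_command(gains, state, meas)
    flow <- res$command * params$pump_gain
    if (abs(flow) > params$max_flow) {
      flow <- sign(flow) * params$max_flow
      if (gains$ki > 0) { # anti-windup: redo the step with a frozen integral
        res <- pid_command(gains, state, meas, freeze_integral = TRUE)
      }
    }
    state <- res$state
    levels[k] <- level
    measured[k] <- meas
    commands[k] <- res$command
    flows[k] <- flow
    level <- plant_step(params, level, flow, gains$ts)
  }

  structure(
    data.frame(time_s = times, level_mm = levels, measured_mm = measured,
               command = commands, flow_ul_min = flows),
    class = c("level_trace", "data.frame"),
    setpoint = setpoint, params = params, gains = gains,
    disturbance = c(time_s = d_time, step_mm = d_step))
}

#' @export
print.level_trace <- function(x, ...) {
  sp <- attr(x, "setpoint")
  cat(sprintf("Closed-loop level trace: %d steps, ts = %g s, setpoint %g mm\n",
              nrow(x), attr(x, "gains")$ts, sp))
  dev <- abs(x$level_mm - sp)
  cat(sprintf("  final level %.3f mm; max deviation %.3f mm\n",
              x$level_mm[nrow(x)], max(dev)))
  invisible(x)
}

#' @export
plot.level_trace <- function(x, ...) {
  sp <- attr(x, "setpoint")
  plot(x$time_s, x$level_mm, type = "l", xlab = "time (s)",
       ylab = "level (mm)", ...)
  lines(x$time_s, x$measured_mm, col = "grey60", lty = 3)
  abline(h = sp, col = "red", lty = 2)
  abline(h = sp + c(-0.2, 0.2), col = "red", lty = 3)
  invisible(x)
}

#' Periodic medium-exchange flow schedule
#'
#' Builds the bolus schedule used for automated medium exchange and vesicle
#' collection: a fixed volume delivered over a fixed duration, repeated at a
#' fixed period (e.g. 600 uL over 1 min every 20 min for 24 h).
#'
#' @param bolus_ul bolus volume in uL.
#' @param bolus_duration_s duration of each bolus in seconds.
#' @param period_s period between bolus starts in seconds.
#' @param total_s total schedule span in seconds.
#' @return an object of class `flow_schedule`: a data frame with columns
#'   `start_s`, `duration_s`, `rate_ul_min`.
#' @export
#' @examples
#' sched <- make_flow_schedule(600, 60, 20 * 60, 24 * 3600)
#' nrow(sched) # 72 boluses over 24 h
make_flow_schedule <- function(bolus_ul, bolus_duration_s, period_s, total_s) {
  check_finite_scalar(bolus_ul, "bolus_ul", min = 0, strict_min = TRUE)
  check_finite_scalar(bolus_duration_s, "bolus_duration_s", min = 0,
                      strict_min = TRUE)
  check_finite_scalar(period_s, "period_s", min = 0, strict_min = TRUE)
  check_finite_scalar(total_s, "total_s", min = 0, strict_min = TRUE)
  if (bolus_duration_s >= period_s) {
    stop_bad_arg("bolus_duration_s", "must be shorter than the period")
  }
  n_events <- max(1, ceiling(total_s / period_s - 1e-9))
  starts <- (seq_len(n_events) - 1) * period_s
  structure(
    data.frame(start_s = starts, duration_s = bolus_duration_s,
               rate_ul_min = bolus_ul / bolus_duration_s * 60),
    class = c("flow_schedule", "data.frame"))
}
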