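#' Instrument model for the simulated sorter
#'
#' A linear stand-in for the sorter's fluidics: sample flow is
#' `flow_per_pressure * pressure` (mL/s), so the event rate at a true cell
#' concentration `c` is `c * flow_per_pressure * pressure` events/s. The
#' controller holds the observed event rate near `eps_target` by a clamped
#' multiplicative proportional law (see [adjust_pressure()]). The per-phase
#' constants cover the sample-independent parts of a session: tube
#' transport, gate computation and GUI/setup control.
#'
#' @param flow_per_pressure sample flow per pressure unit, (mL/s)/unit.
#' @param pressure_min,pressure_max admissible pressure range (units).
#' @param eps_target desired event rate, events/s.
#' @param controller_gain exponent of the multiplicative update (0 < gain
#'   <= 1; 0.5 is a stable default under Poisson rate noise).
#' @param control_period controller tick in seconds.
#' @param transport_time,gating_time,control_time fixed phase durations in
#'   seconds.
#' @return An object of class `instrument_model`.
#' @export
instrument_model <- function(flow_per_pressure = 2e-4, pressure_min = 1,
                             pressure_max = 10, eps_target = 2000,
                             controller_gain = 0.5, control_period = 1,
                             transport_time = 40, gating_time = 12,
                             control_time = 30) {
  bad <- function(msg) sg_stop("sortgate_error_invalid_config", msg)
  if (!is.numeric(flow_per_pressure) || flow_per_pressure <= 0) bad("flow_per_pressure must be > 0")
  if (!is.numeric(pressure_min) || !is.numeric(pressure_max) || pressure_min >= pressure_max) {
    bad("pressure_min must be smaller than pressure_max")
  }
  if (!is.numeric(eps_target) || eps_target <= 0) bad("eps_target must be > 0")
  if (!is.numeric(controller_gain) || controller_gain <= 0 || controller_gain > 1) {
    bad("controller_gain must lie in (0, 1]")
  }
  if (!is.numeric(control_period) || control_period <= 0) bad("control_period must be > 0")
  for (t in c(transport_time, gating_time, control_time)) {
    if (!is.numeric(t) || t < 0) bad("phase durations must be >= 0")
  }
  structure(list(flow_per_pressure = flow_per_pressure,
                 pressure_min = pressure_min, pressure_max = pressure_max,
                 eps_target = eps_target, controller_gain = controller_gain,
                 control_period = control_period,
                 transport_time = transport_time, gating_time = gating_time,
                 control_time = control_time),
            class = "instrument_model")
}

#' Plan of one sample's sort
#'
#' @param gate fitted `gate_polygon` for this sample.
#' @param n_profile events to measure during profiling.
#' @param n_sort cells to sort (the routine protocol collects 1,200 cells
#'   per sample into a 96-well rescue plate).
#' @return An object of class `sort_plan`.
#' @export
sort_plan <- function(gate, n_profile = 10000, n_sort = 1200) {
  bad <- function(msg) sg_stop("sortgate_error_invalid_config", msg)
  if (!inherits(gate, "gate_polygon")) bad("gate must be a gate_polygon")
  if (!is.numeric(n_profile) || n_profile < 1) bad("n_profile must be > 0")
  if (!is.numeric(n_sort) || n_sort < 1) bad("n_sort must be > 0")
  structure(list(gate = gate, n_profile = as.integer(n_profile),
                 n_sort = as.integer(n_sort)),
            class = "sort_plan")
}

#' Estimate sample concentration from the observed event rate
#'
#' At sample flow `flow_per_pressure * pressure` (mL/s), an observed event
#' rate of `eps_observed` events/s implies a concentration of
#' `eps_observed / (flow_per_pressure * pressure)` cells/mL.
#'
#' @param eps_observed observed event rate, events/s (>= 0).
#' @param pressure current sample pressure, within the model's limits.
#' @param model an [instrument_model()].
#' @return Estimated concentration in cells/mL.
#' @export
estimate_concentration <- function(eps_observed, pressure, model = instrument_model()) {
  if (!is.numeric(eps_observed) || eps_observed < 0) {
    sg_stop("sortgate_error_invalid_config", "eps_observed must be >= 0")
  }
  if (!is.numeric(pressure) || pressure <= 0) {
    sg_stop("sortgate_error_invalid_config", "pressure must be > 0")
  }
  if (pressure < model$pressure_min || pressure > model$pressure_max) {
    sg_stop("sortgate_error_invalid_config",
            sprintf("pressure %.3g outside instrument limits [%g, %g]",
                    pressure, model$pressure_min, model$pressure_max))
  }
  eps_observed / (model$flow_per_pressure * pressure)
}

#' One step of the event-rate pressure controller
#'
#' Clamped multiplicative proportional update
#' `pressure * (eps_target / eps_observed)^gain`. The target rate is a
#' fixed point: when the observed rate equals the target the pressure is
#' returned unchanged. A zero observed rate (empty or clogged sample line)
#' returns the maximum pressure with a warning, drawing as hard as the
#' instrument allows.
#'
#' @param current current pressure (units).
#' @param eps_observed observed event rate, events/s.
#' @param model an [instrument_model()].
#' @return New pressure within `[pressure_min, pressure_max]`.
#' @export
adjust_pressure <- function(current, eps_observed, model = instrument_model()) {
  if (!is.finite(current) || !is.finite(eps_observed)) {
    sg_stop("sortgate_error_invalid_config", "pressure and event rate must be finite")
  }
  if (eps_observed == 0) {
    warning("observed event rate is 0; setting maximal sample pressure")
    return(model$pressure_max)
  }
  if (eps_observed == model$eps_target) return(current)
  p <- current * (model$eps_target / eps_observed)^model$controller_gain
  min(max(p, model$pressure_min), model$pressure_max)
}

#' Simulate one sample's instrument session
#'
#' Streams the sample's events (in their stored, shuffled order) at a
#' Poisson event rate set by the true concentration, the instrument's
#' pressure-to-flow mapping and the current pressure. The session profiles
#' `n_profile` events while estimating the concentration, then sorts —
#' counting events inside the gate — until `n_sort` cells are collected or
#' the sample is exhausted. The pressure controller runs every
#' `control_period` seconds in both phases; the seed governs only the
#' Poisson arrival noise.
#'
#' @param table the sample's [event_table()].
#' @param plan a [sort_plan()] whose gate was fitted on this sample's
#'   profile.
#' @param model an [instrument_model()].
#' @param seed integer seed for the arrival noise.
#' @param concentration true cell concentration in cells/mL (default 2e6,
#'   a typical small-culture prep).
#' @return An object of class `sort_result` with fields `sample_id`,
#'   `events_profiled`, `events_sorted`, `events_examined`,
#'   `estimated_concentration`, `pressure_trace` (matrix of time/pressure),
#'   `phase_times` (named: profiling, sorting, transport, gating, control),
#'   `total_time` and `completed`. Exhausting the sample before `n_sort`
#'   yields `completed = FALSE` with the shortfall in `events_sorted`,
#'   not an error.
#' @export
run_session <- function(table, plan, model = instrument_model(), seed = 1L,
                        concentration = 2e6) {
  stopifnot(inherits(table, "event_table"), inherits(plan, "sort_plan"),
            inherits(model, "instrument_model"))
  if (!is.numeric(concentration) || concentration <= 0) {
    sg_stop("sortgate_error_invalid_config", "concentration must be > 0")
  }
  xy <- axis_values(table, plan$gate$axis)
  gv <- ring_open(plan$gate$vertices)
  n <- table$n_events
  dt <- model$control_period

  withr::with_seed(as.integer(seed), {
    pressure <- (model$pressure_min + model$pressure_max) / 2
    t_now <- 0
    trace_t <- numeric(0); trace_p <- numeric(0)
    i <- 0L                      # events consumed so far
    profiled <- 0L
    sorted <- 0L
    examined_sort <- 0L
    t_profile <- 0; t_sort <- 0
    pressure_volume <- 0         # integral of pressure dt over profiling

    stream_phase <- function(need_fun, count_fun) {
      # returns elapsed time; consumes events until need_fun says stop or
      # the table is exhausted
      elapsed <- 0
      repeat {
        if (i >= n || need_fun() <= 0L) break
        rate <- concentration * model$flow_per_pressure * pressure
        nk <- rpois(1L, rate * dt)
        avail <- n - i
        if (nk > 0L) {
          need <- need_fun()
          take_all <- min(nk, avail)
          used <- count_fun(i, take_all, need)
          frac <- if (used$stop && nk > 0L) used$consumed / nk else 1
          i <<- i + used$consumed
          elapsed <- elapsed + dt * frac
          t_now <<- t_now + dt * frac
          if (used$stop) break
        } else {
          elapsed <- elapsed + dt
          t_now <<- t_now + dt
        }
        eps_obs <- if (nk > 0L) nk / dt else 0
        pressure <<- suppressWarnings(adjust_pressure(pressure, eps_obs, model))
        trace_t <<- c(trace_t, t_now); trace_p <<- c(trace_p, pressure)
      }
      elapsed
    }

    # --- profiling phase
    t_profile <- stream_phase(
      need_fun = function() plan$n_profile - profiled,
      count_fun = function(at, avail_n, need) {
        take <- min(avail_n, need)
        profiled <<- profiled + take
        pressure_volume <<- pressure_volume + pressure * dt * (take / max(avail_n, 1L))
        list(consumed = take, stop = take >= need)
      })
    est_conc <- if (pressure_volume > 0) {
      profiled / (model$flow_per_pressure * pressure_volume)
    } else 0

    # --- sorting phase
    t_sort <- stream_phase(
      need_fun = function() plan$n_sort - sorted,
      count_fun = function(at, avail_n, need) {
        idx <- (at + 1L):(at + avail_n)
        ing <- point_in_polygon(xy[idx, 1], xy[idx, 2], gv[, 1], gv[, 2])
        hits <- cumsum(ing)
        if (hits[avail_n] >= need) {
          upto <- which(hits >= need)[1]
          sorted <<- sorted + need
          examined_sort <<- examined_sort + upto
          list(consumed = upto, stop = TRUE)
        } else {
          sorted <<- sorted + hits[avail_n]
          examined_sort <<- examined_sort + avail_n
          list(consumed = avail_n, stop = FALSE)
        }
      })

    phase_times <- c(profiling = t_profile, sorting = t_sort,
                     transport = model$transport_time,
                     gating = model$gating_time,
                     control = model$control_time)
    structure(list(sample_id = table$sample_id,
                   events_profiled = profiled,
                   events_sorted = sorted,
                   events_examined = profiled + examined_sort,
                   estimated_concentration = est_conc,
                   pressure_trace = cbind(time = trace_t, pressure = trace_p),
                   phase_times = phase_times,
                   total_time = sum(phase_times),
                   completed = sorted >= plan$n_sort),
              class = "sort_result")
  })
}

#' @export
print.sort_result <- function(x, ...) {
  cat(sprintf("<sort_result> '%s': profiled %d, sorted %d (%s), est. conc %.3g cells/mL, %.1f s\n",
              x$sample_id, x$events_profiled, x$events_sorted,
              if (x$completed) "completed" else "shortfall", x$estimated_concentration,
              x$total_time))
  invisible(x)
}
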