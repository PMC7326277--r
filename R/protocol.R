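# Pulling protocols and the top-level mechanochemical simulation loop.

#' Build a probe pulling schedule
#'
#' The four canonical loading conditions, in decreasing order of step size:
#' \describe{
#'   \item{i}{five 500 nm probe displacement steps at 150 s intervals;}
#'   \item{ii}{mixed steps 250, 250, 250, 500, 500 nm;}
#'   \item{iii}{five 250 nm steps;}
#'   \item{iv}{control — no probe, no attached filaments, but the upper
#'     boundary rises following the Case i height profile so that box
#'     geometry is matched.}
#' }
#' Each displacement is delivered over 100 mechanical sub-steps in 1 s of
#' simulated time; motors and crosslinkers enter solution at 5 s.
#'
#' @param case one of \code{"i"}, \code{"ii"}, \code{"iii"}, \code{"iv"}.
#' @param interval time between pulling events (s).
#' @param n_events number of pulling events.
#' @param release_probe_at optional time (s) at which anchored filaments
#'   detach from the probe.
#' @param tail_time evolution time after the last event (s); defaults to
#'   \code{interval}, giving the canonical 900 s total for five events.
#' @param step optional step-size override (nm, >= 0) applied to every
#'   event; \code{step = 0} with anchors kept gives the static-probe
#'   variant.
#' @return A list of class \code{acto_schedule} with fields \code{times},
#'   \code{steps} (nm), \code{boundary_only}, \code{duration}, etc.
#' @examples
#' s <- make_schedule("ii")
#' rbind(s$times, s$steps)
#' @export
make_schedule <- function(case = c("i", "ii", "iii", "iv"), interval = 150,
                          n_events = 5L, release_probe_at = NULL,
                          tail_time = interval, step = NULL) {
  case <- match.arg(case)
  if (n_events < 0) stop("n_events must be >= 0")
  steps <- switch(case,
    i = rep(500, n_events),
    ii = {
      s <- rep(500, n_events)
      s[seq_len(min(3L, n_events))] <- 250
      s
    },
    iii = rep(250, n_events),
    iv = rep(500, n_events))
  if (!is.null(step)) {
    if (step < 0) stop("step must be >= 0")
    steps <- rep(step, n_events)
  }
  times <- interval * seq_len(n_events)
  sched <- list(case = case, times = times, steps = steps,
                interval = interval,
                boundary_only = (case == "iv"),
                substeps = 100L, substep_dt = 0.01,
                release_time = 5,
                release_probe_at = release_probe_at,
                duration = if (n_events > 0) times[n_events] + tail_time
                           else tail_time)
  class(sched) <- "acto_schedule"
  sched
}

#' @export
print.acto_schedule <- function(x, ...) {
  cat("pulling schedule (case ", x$case, "): ", length(x$times),
      " events\n", sep = "")
  if (length(x$times))
    cat("  t =", paste(x$times, collapse = ", "), "s; d =",
        paste(x$steps, collapse = ", "), "nm",
        if (x$boundary_only) "(boundary only)" else "", "\n")
  cat("  total duration:", x$duration, "s\n")
  invisible(x)
}

#' Displace the probe (one pulling event)
#'
#' Moves the probe center, its anchor points, and the upper boundary up by
#' \code{d} nm in 100 sub-steps of \code{d/100} nm, mechanically
#' re-equilibrating the network after each sub-step. The whole event takes
#' 1 s of simulated time during which no chemistry fires: the structural
#' change is a purely mechanical response. With no probe in the state
#' (control case) only the upper boundary rises.
#'
#' @param state an \code{acto_state}.
#' @param d total displacement (nm, >= 0); 0 advances the clock only.
#' @param substeps number of sub-steps.
#' @return The displaced, re-minimized state (clock advanced by 1 s).
#' @export
apply_pull <- function(state, d, substeps = 100L) {
  if (d < 0) stop("displacement must be >= 0")
  if (d == 0) {
    state$t <- state$t + 1
    return(state)
  }
  dz <- d / substeps
  for (k in seq_len(substeps)) {
    state$box[3] <- state$box[3] + dz
    if (!is.null(state$probe))
      state$probe$center[3] <- state$probe$center[3] + dz
    state <- minimize_network(state)
    if (!isTRUE(attr(state, "converged")) &&
        attr(state, "iterations") >= state$params$minimize_maxit)
      warning("minimization did not converge in pull sub-step ", k)
  }
  state$t <- state$t + 1
  state
}

#' Detach all anchored filaments from the probe
#'
#' Removes every anchor spring; affected filaments join the free pool
#' (both ends chemically active). The probe body remains as a passive
#' repulsive boundary object.
#'
#' @param state an \code{acto_state}.
#' @return The modified state. Calling this with nothing anchored is a
#'   warning no-op.
#' @export
release_probe <- function(state) {
  att <- which(vapply(state$filaments, `[[`, TRUE, "attached"))
  if (!length(att)) {
    warning("no anchored filaments; nothing released")
    return(state)
  }
  for (i in att) {
    state$filaments[[i]]$attached <- FALSE
    state$filaments[[i]]$anchor <- NA_integer_
  }
  if (!is.null(state$probe))
    state$probe$anchor_dirs <- state$probe$anchor_dirs[0, , drop = FALSE]
  state
}

release_species <- function(state) {
  if (isTRUE(state$released)) return(state)
  state$pools["linker"] <- state$pools["linker"] + state$pending["linker"]
  state$pools["motor"] <- state$pools["motor"] + state$pending["motor"]
  if (!is.null(state$grid)) {
    # scatter released species uniformly over compartments
    dims <- state$grid$dims
    ncomp <- prod(dims)
    for (sp in 2:3) {
      n <- state$pending[c("linker", "motor")[sp - 1]]
      if (n > 0) {
        tab <- tabulate(sample.int(ncomp, n, replace = TRUE), nbins = ncomp)
        state$grid$counts[, , , sp] <- state$grid$counts[, , , sp] +
          array(tab, dim = dims)
      }
    }
  }
  state$pending[] <- 0
  state$released <- TRUE
  state
}

#' Run a full mechanochemical simulation
#'
#' Initializes the network, releases motors and crosslinkers into solution
#' at the schedule's release time, and then alternates stochastic
#' chemistry (in \code{chem_mech_interval} slices, each followed by
#' mechanical minimization) with the scheduled probe pulling events.
#' Snapshots are collected at \code{snapshot_interval} (1 s default), one
#' immediately before and one immediately after every pull.
#'
#' @param params an \code{acto_params}; for case iv use
#'   \code{n_attached = 0}.
#' @param schedule an \code{acto_schedule} from [make_schedule()].
#' @param seed RNG seed; fixed seed gives a reproducible trajectory.
#' @param progress print a line per protocol phase.
#' @param log_file optional path; one tab-separated row per
#'   mechanochemical cycle with the post-minimization energy breakdown
#'   and the chemistry event count.
#' @return A list of class \code{acto_trajectory}: \code{snapshots} (list
#'   of \code{acto_snapshot}), \code{times}, \code{params},
#'   \code{schedule}, \code{seed}.
#' @export
run_simulation <- function(params, schedule, seed = 1L, progress = FALSE,
                           log_file = NULL) {
  if (schedule$boundary_only && params$n_attached != 0L)
    stop("boundary-only (case iv) schedules require n_attached = 0")
  if (!is.null(log_file))
    cat(paste(c("time", "stretch", "bend", "excluded_volume", "boundary",
                "motor", "linker", "anchor", "total", "events"),
              collapse = "\t"), "\n", sep = "", file = log_file)
  state <- init_network(params, seed)
  snaps <- list(snapshot(state))
  take <- function(st) {
    if (abs(snaps[[length(snaps)]]$t - st$t) < 1e-9) return(invisible())
    snaps[[length(snaps) + 1L]] <<- snapshot(st)
  }

  probe_pending <- schedule$release_probe_at
  chem_to <- function(state, t_target) {
    # chemistry/minimization alternation with snapshots on the 1 s grid
    si <- state$params$snapshot_interval
    while (state$t < t_target - 1e-9) {
      if (!state$released && state$t + 1e-9 >= schedule$release_time)
        state <- release_species(state)
      if (!is.null(probe_pending) && state$t + 1e-9 >= probe_pending) {
        state <- release_probe(state)
        probe_pending <<- NULL
      }
      step <- min(state$params$chem_mech_interval, t_target - state$t)
      if (!state$released)
        step <- min(step, schedule$release_time - state$t)
      if (!is.null(probe_pending))
        step <- min(step, probe_pending - state$t)
      if (step <= 1e-9) next
      t_snap_due <- (floor(state$t / si + 1e-9) + 1) * si
      state <- advance_chemistry(state, step)
      n_ev <- sum(attr(state, "n_events"))
      state <- minimize_network(state)
      if (!is.null(log_file))
        cat(paste(c(format(state$t), format(attr(state, "energy_terms")),
                    format(attr(state, "energy")), n_ev), collapse = "\t"),
            "\n", sep = "", file = log_file, append = TRUE)
      if (state$t + 1e-9 >= t_snap_due) take(state)
    }
    state
  }

  events <- seq_along(schedule$times)
  t_cursor <- 0
  for (k in events) {
    state <- chem_to(state, schedule$times[k])
    take(state)                        # pre-pull snapshot
    if (progress)
      message("t = ", round(state$t), " s: pull ", k, " (d = ",
              schedule$steps[k], " nm)")
    state <- apply_pull(state, schedule$steps[k], schedule$substeps)
    take(state)                        # post-pull snapshot
  }
  state <- chem_to(state, schedule$duration)
  if (abs(snaps[[length(snaps)]]$t - state$t) > 1e-9) take(state)

  traj <- list(snapshots = snaps,
               times = vapply(snaps, `[[`, 1, "t"),
               params = params, schedule = schedule, seed = seed,
               final_state = state)
  class(traj) <- "acto_trajectory"
  traj
}

#' @export
print.acto_trajectory <- function(x, ...) {
  cat("trajectory:", length(x$snapshots), "snapshots, t in [",
      min(x$times), ",", max(x$times), "] s, case",
      x$schedule$case, "\n")
  invisible(x)
}
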