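# Small hand-built states and snapshots for unit tests.

# a state containing explicitly placed filaments (list of bead matrices),
# with no probe and a large box so boundary terms are negligible
state_from_beads <- function(bead_list, nmono_list = NULL, params = NULL,
                             box = c(3000, 3000, 3000)) {
  p <- params %||% default_parameters(n_free = 1L, n_attached = 0L)
  fils <- lapply(seq_along(bead_list), function(i) {
    b <- bead_list[[i]]
    nm <- if (is.null(nmono_list)) rep(40L, nrow(b) - 1L) else nmono_list[[i]]
    list(beads = b, nmono = as.integer(nm), attached = FALSE,
         anchor = NA_integer_)
  })
  st <- list(params = p, t = 0, box = box, filaments = fils,
             motors = actopull:::empty_bonds(),
             linkers = actopull:::empty_bonds(),
             probe = NULL,
             pools = c(actin = 0, linker = 0, motor = 0),
             pending = c(linker = 0, motor = 0),
             released = TRUE, grid = NULL)
  class(st) <- "acto_state"
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# straight filament along +z starting at `from`, n_cyl full cylinders
straight_fil <- function(from, n_cyl = 1, axis = c(0, 0, 1), l = 108) {
  axis <- axis / sqrt(sum(axis^2))
  t(sapply(0:n_cyl, function(k) from + k * l * axis))
}

# randomized small state: a few short filaments near the box center plus
# optionally a linker and a motor bond at plausible separations
random_small_state <- function(seed, with_bonds = TRUE) {
  set.seed(seed)
  p <- default_parameters(n_free = 1L, n_attached = 0L)
  beads <- list()
  n_f <- 4L
  for (i in seq_len(n_f)) {
    from <- runif(3, 1200, 1800)
    ax <- rnorm(3)
    k <- sample(2:3, 1)
    beads[[i]] <- straight_fil(from, k, ax)
  }
  st <- state_from_beads(beads, params = p)
  # small random kinks so bending/EV terms are active
  for (i in seq_len(n_f)) {
    b <- st$filaments[[i]]$beads
    st$filaments[[i]]$beads <- b + matrix(rnorm(length(b), 0, 4),
                                          nrow(b), 3)
  }
  if (with_bonds) {
    lc <- candidate_binding_pairs(st, "linker")
    if (nrow(lc) > 0) {
      r <- sample.int(nrow(lc), 1)
      st$linkers <- data.frame(f1 = lc$f1[r], c1 = lc$c1[r], s1 = lc$s1[r],
                               f2 = lc$f2[r], c2 = lc$c2[r], s2 = lc$s2[r],
                               rest = runif(1, 30, 40))
    }
    mc <- candidate_binding_pairs(st, "motor")
    if (nrow(mc) > 0) {
      r <- sample.int(nrow(mc), 1)
      st$motors <- data.frame(f1 = mc$f1[r], c1 = mc$c1[r], s1 = mc$s1[r],
                              f2 = mc$f2[r], c2 = mc$c2[r], s2 = mc$s2[r],
                              rest = runif(1, 175, 225))
    }
  }
  st
}

# snapshot from explicit beads (analysis-metric fixtures)
snapshot_from_beads <- function(bead_list, nmono_list = NULL,
                                box = c(3000, 3000, 1250)) {
  snp <- list(t = 0, box = box,
              filaments = lapply(seq_along(bead_list), function(i) {
                b <- bead_list[[i]]
                nm <- if (is.null(nmono_list)) rep(40L, nrow(b) - 1L)
                      else nmono_list[[i]]
                list(beads = b, nmono = as.integer(nm), attached = FALSE)
              }),
              bonds = data.frame(), probe = NULL)
  class(snp) <- "acto_snapshot"
  snp
}

# cached desk-scale protocol runs shared across test files (tempdir keyed);
# two pulls at 50 s spacing, 40 s of evolution after the last pull
desk_run_cached <- function(case, seed, motor_conc = 2) {
  dir <- file.path(tempdir(), "actopull-runs")
  dir.create(dir, showWarnings = FALSE)
  key <- file.path(dir, sprintf("run_%s_%d_%g.rds", case, seed, motor_conc))
  if (file.exists(key)) return(readRDS(key))
  p <- if (case == "iv")
    desk_small_parameters(n_attached = 0L, motor_conc = motor_conc)
  else desk_small_parameters(motor_conc = motor_conc)
  sch <- make_schedule(case, interval = 50, n_events = 2, tail_time = 40)
  traj <- run_simulation(p, sch, seed = seed)
  traj$final_state <- NULL      # keep the cache light
  saveRDS(traj, key)
  traj
}

# time series of one metric, deduplicated at pull boundaries
metric_series <- function(traj, metric, diameter = 500) {
  m <- trajectory_metrics(traj, metric, diameter = diameter)
  m <- m[m$metric == metric, ]
  m[!duplicated(m$time), c("time", "value")]
}

# net rate of change of a metric over a time window (nm/s etc.)
net_rate <- function(series, from, to) {
  d <- series[series$time >= from & series$time <= to, ]
  if (nrow(d) < 2) return(NA_real_)
  (d$value[nrow(d)] - d$value[1]) / (d$time[nrow(d)] - d$time[1])
}
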