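# Next reaction method (Gibson-Bruck) core: reaction channels with
# scheduled absolute firing times held in an indexed binary min-heap.
# When a propensity changes from a to a' the pending time is rescaled,
# t' = t + (a/a') (t_old - t), without redrawing the underlying uniform;
# only the fired channel draws a fresh exponential.

nrm_new <- function(capacity = 64L) {
  e <- new.env(parent = emptyenv())
  e$a <- numeric(capacity)       # propensities
  e$tf <- rep(Inf, capacity)     # scheduled firing times
  e$heap <- integer(capacity)    # heap of channel ids keyed by tf
  e$pos <- integer(capacity)     # channel id -> heap slot (0 = absent)
  e$nch <- 0L
  e$nh <- 0L
  e$t <- 0
  e
}

nrm_grow <- function(e, need) {
  cap <- length(e$a)
  if (need <= cap) return(invisible())
  new_cap <- max(need, 2L * cap)
  e$a <- c(e$a, numeric(new_cap - cap))
  e$tf <- c(e$tf, rep(Inf, new_cap - cap))
  e$heap <- c(e$heap, integer(new_cap - cap))
  e$pos <- c(e$pos, integer(new_cap - cap))
  invisible()
}

heap_swap <- function(e, i, j) {
  hi <- e$heap[i]; hj <- e$heap[j]
  e$heap[i] <- hj; e$heap[j] <- hi
  e$pos[hj] <- i; e$pos[hi] <- j
}

heap_up <- function(e, i) {
  while (i > 1L) {
    par <- i %/% 2L
    if (e$tf[e$heap[i]] < e$tf[e$heap[par]]) {
      heap_swap(e, i, par)
      i <- par
    } else break
  }
}

heap_down <- function(e, i) {
  n <- e$nh
  repeat {
    l <- 2L * i
    if (l > n) break
    m <- if (l + 1L <= n && e$tf[e$heap[l + 1L]] < e$tf[e$heap[l]]) l + 1L else l
    if (e$tf[e$heap[m]] < e$tf[e$heap[i]]) {
      heap_swap(e, i, m)
      i <- m
    } else break
  }
}

heap_fix <- function(e, id) {
  i <- e$pos[id]
  heap_up(e, i)
  heap_down(e, e$pos[id])
}

# register a channel with propensity a; draws its first firing time
nrm_add <- function(e, a) {
  id <- e$nch + 1L
  nrm_grow(e, id)
  e$nch <- id
  e$a[id] <- a
  e$tf[id] <- if (a > 0) e$t + rexp(1L) / a else Inf
  e$nh <- e$nh + 1L
  e$heap[e$nh] <- id
  e$pos[id] <- e$nh
  heap_up(e, e$nh)
  id
}

# Gibson-Bruck propensity update for a non-fired channel
nrm_update <- function(e, id, a_new) {
  a_old <- e$a[id]
  if (a_new == a_old) return(invisible())
  t_old <- e$tf[id]
  if (a_new <= 0) {
    e$tf[id] <- Inf
  } else if (a_old > 0 && is.finite(t_old)) {
    e$tf[id] <- e$t + (a_old / a_new) * (t_old - e$t)
  } else {
    e$tf[id] <- e$t + rexp(1L) / a_new
  }
  e$a[id] <- a_new
  heap_fix(e, id)
  invisible()
}

# redraw the fired channel (optionally with a new propensity)
nrm_redraw <- function(e, id, a_new = e$a[id]) {
  e$a[id] <- a_new
  e$tf[id] <- if (a_new > 0) e$t + rexp(1L) / a_new else Inf
  heap_fix(e, id)
  invisible()
}

nrm_peek <- function(e) {
  if (e$nh == 0L) return(NULL)
  id <- e$heap[1L]
  if (!is.finite(e$tf[id])) return(NULL)
  list(id = id, time = e$tf[id])
}

#' Simulate a mass-action network with the next reaction method
#'
#' Exact stochastic simulation of a well-mixed reaction network using the
#' Gibson-Bruck next reaction method (indexed priority queue, rescaled
#' firing times). Propensity of reaction j is
#' \code{k[j] * prod(falling factorials of reactant copies)}.
#'
#' This is the same scheduling core the actomyosin simulator runs on,
#' exposed for small networks and for validation against the direct
#' Gillespie method ([ssa_direct()]).
#'
#' @param x0 named or unnamed integer vector of initial copy numbers.
#' @param reactants species x reactions matrix of reactant stoichiometries.
#' @param change species x reactions matrix of net copy-number changes.
#' @param k per-reaction rate constants.
#' @param t_end stop time (s).
#' @param max_events event cap.
#' @return List with \code{state} (final copies), \code{t}, \code{counts}
#'   (events fired per reaction), \code{times} and \code{which} (event log).
#' @examples
#' # A + B -> C at k = 1
#' nrm_mass_action(c(50, 50, 0), matrix(c(1, 1, 0)), matrix(c(-1, -1, 1)),
#'                 1e-2, t_end = 5)$state
#' @export
nrm_mass_action <- function(x0, reactants, change, k, t_end,
                            max_events = 1e6) {
  x <- as.numeric(x0)
  nr <- ncol(reactants)
  prop <- function(j) {
    a <- k[j]
    for (s in which(reactants[, j] > 0)) {
      m <- reactants[s, j]
      a <- a * prod(x[s] - seq_len(m) + 1)
    }
    max(a, 0)
  }
  e <- nrm_new(nr)
  for (j in seq_len(nr)) nrm_add(e, prop(j))
  counts <- integer(nr)
  times <- numeric(0)
  which_r <- integer(0)
  n_ev <- 0L
  repeat {
    nxt <- nrm_peek(e)
    if (is.null(nxt) || nxt$time > t_end || n_ev >= max_events) break
    j <- nxt$id
    e$t <- nxt$time
    x <- x + change[, j]
    counts[j] <- counts[j] + 1L
    n_ev <- n_ev + 1L
    times <- c(times, e$t)
    which_r <- c(which_r, j)
    nrm_redraw(e, j, prop(j))
    for (j2 in seq_len(nr)) if (j2 != j) nrm_update(e, j2, prop(j2))
  }
  list(state = x, t = min(e$t, t_end), counts = counts,
       times = times, which = which_r)
}

#' Direct-method Gillespie simulation (reference oracle)
#'
#' Plain direct stochastic simulation algorithm for the same mass-action
#' systems as [nrm_mass_action()]; used as the independent statistical
#' reference when validating the next-reaction scheduler.
#'
#' @inheritParams nrm_mass_action
#' @return Same structure as [nrm_mass_action()].
#' @export
ssa_direct <- function(x0, reactants, change, k, t_end, max_events = 1e6) {
  x <- as.numeric(x0)
  nr <- ncol(reactants)
  props <- function() {
    a <- numeric(nr)
    for (j in seq_len(nr)) {
      aj <- k[j]
      for (s in which(reactants[, j] > 0)) {
        m <- reactants[s, j]
        aj <- aj * prod(x[s] - seq_len(m) + 1)
      }
      a[j] <- max(aj, 0)
    }
    a
  }
  t <- 0
  counts <- integer(nr)
  times <- numeric(0)
  which_r <- integer(0)
  n_ev <- 0L
  repeat {
    a <- props()
    a0 <- sum(a)
    if (a0 <= 0 || n_ev >= max_events) break
    t <- t + rexp(1L) / a0
    if (t > t_end) break
    j <- sample.int(nr, 1L, prob = a)
    x <- x + change[, j]
    counts[j] <- counts[j] + 1L
    n_ev <- n_ev + 1L
    times <- c(times, t)
    which_r <- c(which_r, j)
  }
  list(state = x, t = min(t, t_end), counts = counts,
       times = times, which = which_r)
}
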