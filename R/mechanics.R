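# Potential energy, analytic forces, and conjugate-gradient minimization.

energy_grad_topo <- function(topo, state, want_grad = TRUE) {
  p <- state$params
  energy_grad_cpp(topo$X,
                  topo$cb1, topo$cb2, topo$cl0, topo$cfil, topo$cidx,
                  p$stretch_k, p$bending_energy,
                  topo$ba, topo$bb, topo$bc,
                  topo$e1a, topo$e1b, topo$f1,
                  topo$e2a, topo$e2b, topo$f2,
                  topo$bond_k, topo$bond_l0, topo$bond_type,
                  topo$anch_bead, topo$anch_pt, p$anchor_k,
                  state$box, p$boundary_eps, p$boundary_lambda,
                  !is.null(state$probe),
                  if (is.null(state$probe)) c(0, 0, 0) else state$probe$center,
                  if (is.null(state$probe)) 0 else state$probe$radius,
                  p$excluded_volume_k, p$cylinder_length,
                  want_grad)
}

#' Total potential energy of the network
#'
#' Sums cylinder stretching, inter-cylinder bending, pairwise excluded
#' volume, boundary and probe repulsion, and motor/linker/anchor spring
#' terms. See the package vignette for the functional forms.
#'
#' @param state an \code{acto_state}.
#' @return A list of class \code{acto_energy} with per-term energies
#'   (pN nm) and \code{total}.
#' @examples
#' st <- init_network(desk_small_parameters(n_free = 5L, n_attached = 0L), 1)
#' total_energy(st)$terms
#' @export
total_energy <- function(state) {
  topo <- build_topology(state)
  res <- energy_grad_topo(topo, state, want_grad = FALSE)
  out <- list(terms = res$terms, total = res$total)
  class(out) <- "acto_energy"
  out
}

#' @export
print.acto_energy <- function(x, ...) {
  cat("network potential energy (pN nm)\n")
  print(round(x$terms, 4))
  cat("total:", format(x$total), "\n")
  invisible(x)
}

#' Net force on every bead
#'
#' Analytic negative gradient of [total_energy()] with respect to every
#' bead coordinate. The probe and its anchor points are not degrees of
#' freedom; anchored beads feel their anchor springs.
#'
#' @param state an \code{acto_state}.
#' @return Matrix (number of beads x 3) of forces in pN.
#' @export
net_forces <- function(state) {
  topo <- build_topology(state)
  res <- energy_grad_topo(topo, state, want_grad = TRUE)
  -res$grad
}

max_force <- function(G) {
  if (nrow(G) == 0) return(0)
  sqrt(max(rowSums(G^2)))
}

#' Mechanically equilibrate the network
#'
#' Gradient-based energy minimization of all bead coordinates
#' (limited-memory quasi-Newton steps with backtracking line search) until
#' the largest per-bead force magnitude drops below \code{force_tol} or
#' the iteration cap is reached. Chemistry and topology are untouched;
#' energy never increases across the call.
#'
#' @param state an \code{acto_state}.
#' @param force_tol convergence threshold on the max per-bead force (pN).
#' @param maxit iteration cap.
#' @return The state with updated bead positions; attributes
#'   \code{converged} (logical), \code{iterations} and \code{energy}
#'   record the outcome. Non-convergence within the cap is reported with a
#'   warning but the (improved) state is still returned.
#' @export
minimize_network <- function(state, force_tol = state$params$force_tol,
                             maxit = state$params$minimize_maxit) {
  topo <- build_topology(state)
  if (nrow(topo$X) == 0) return(state)
  p <- state$params
  out <- minimize_cpp(topo$X,
                      topo$cb1, topo$cb2, topo$cl0, topo$cfil, topo$cidx,
                      p$stretch_k, p$bending_energy,
                      topo$ba, topo$bb, topo$bc,
                      topo$e1a, topo$e1b, topo$f1,
                      topo$e2a, topo$e2b, topo$f2,
                      topo$bond_k, topo$bond_l0, topo$bond_type,
                      topo$anch_bead, topo$anch_pt, p$anchor_k,
                      state$box, p$boundary_eps, p$boundary_lambda,
                      !is.null(state$probe),
                      if (is.null(state$probe)) c(0, 0, 0)
                      else state$probe$center,
                      if (is.null(state$probe)) 0 else state$probe$radius,
                      p$excluded_volume_k, p$cylinder_length,
                      force_tol, as.integer(maxit))
  if (!out$converged && out$iter >= maxit)
    warning("minimization hit the iteration cap (", maxit,
            ") at max force ", signif(out$max_force, 3), " pN > ",
            force_tol, " pN")
  state <- set_state_coords(state, out$X)
  attr(state, "converged") <- out$converged
  attr(state, "iterations") <- out$iter
  attr(state, "energy") <- out$total
  attr(state, "energy_terms") <- out$terms
  state
}

# tension magnitude k*|l - l0| of every motor (type = "motor") or linker
# bond, from current geometry
bond_tensions <- function(state, type = c("motor", "linker")) {
  type <- match.arg(type)
  df <- if (type == "motor") state$motors else state$linkers
  if (nrow(df) == 0) return(numeric(0))
  k <- if (type == "motor")
    state$params$motor_head_k
  else state$params$linker_k
  vapply(seq_len(nrow(df)), function(i) {
    p1 <- site_xyz(state, df$f1[i], df$c1[i], df$s1[i])
    p2 <- site_xyz(state, df$f2[i], df$c2[i], df$s2[i])
    l <- sqrt(sum((p2 - p1)^2))
    k * abs(l - df$rest[i])
  }, numeric(1))
}

# repulsive force magnitude from walls and probe at a point, and distance
# to the nearest surface (used by the polymerization ratchet)
boundary_force_at <- function(state, x) {
  p <- state$params
  eps <- p$boundary_eps
  lam <- p$boundary_lambda
  f <- c(0, 0, 0)
  dmin <- Inf
  for (k in 1:3) {
    d0 <- x[k]
    d1 <- state$box[k] - x[k]
    dmin <- min(dmin, d0, d1)
    f[k] <- f[k] + eps / lam * exp(-max(d0, -40 * lam) / lam)
    f[k] <- f[k] - eps / lam * exp(-max(d1, -40 * lam) / lam)
  }
  if (!is.null(state$probe)) {
    v <- x - state$probe$center
    r <- sqrt(sum(v^2))
    d <- r - state$probe$radius
    dmin <- min(dmin, d)
    if (r > 1e-9)
      f <- f + v / r * eps / lam * exp(-max(d, -40 * lam) / lam)
  }
  list(force = sqrt(sum(f^2)), dmin = dmin)
}
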