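# Network state construction and bookkeeping.
#
# A SystemState (class "acto_state") is a plain list:
#   params    acto_params
#   t         clock (s)
#   box       c(x, y, z) nm; the top face (z) rises during pulling
#   filaments list; each filament is list(beads = k x 3 matrix ordered
#             minus -> plus, nmono = integer monomers per cylinder
#             (length k-1), attached = flag, anchor = probe anchor index)
#   motors    data.frame(f1,c1,s1,f2,c2,s2,rest): site = (filament,
#             cylinder index, binding site 1..4)
#   linkers   same schema
#   probe     list(center, radius, anchor_dirs m x 3 unit vectors) or NULL
#   pools     named integer counts of diffusing species (actin = G-actin,
#             linker, motor = NMII mini-filaments)
#   pending   species injected into solution at the release time
#   grid      compartment occupancy array (grid mode) or NULL

empty_bonds <- function() {
  data.frame(f1 = integer(), c1 = integer(), s1 = integer(),
             f2 = integer(), c2 = integer(), s2 = integer(),
             rest = numeric())
}

site_fraction <- function(s) (2 * s - 1) / 8

fil_monomers <- function(fil) sum(fil$nmono)

#' Build the initial actomyosin network
#'
#' Places \code{n_free} randomly positioned and oriented seed filaments of
#' \code{seed_monomers} monomers each (one full cylinder by default) in the
#' box, plus \code{n_attached} filaments hanging vertically from anchor
#' points on the lower hemisphere of the probe, their minus ends held by
#' stiff harmonic springs. The diffusive G-actin pool is topped up so that
#' total actin (F + G) equals \code{actin_conc}. Motor and crosslinker
#' copies are computed but held out of solution until the release time of
#' the simulation protocol.
#'
#' @param params an \code{acto_params} list.
#' @param seed integer RNG seed; equal seeds give identical states.
#' @return A \code{SystemState} (class \code{acto_state}).
#' @examples
#' st <- init_network(desk_small_parameters(), seed = 1)
#' length(st$filaments)
#' @export
init_network <- function(params, seed = 1L) {
  validate_parameters(params)
  set.seed(seed)
  p <- params
  box <- c(p$box_x, p$box_y, p$box_z)
  seed_len <- p$seed_monomers * p$monomer_rise
  margin <- 5

  probe <- NULL
  if (p$n_attached > 0) {
    m <- p$n_attached
    z <- -runif(m)                     # lower hemisphere, area-uniform in z
    az <- runif(m, 0, 2 * pi)
    r_xy <- sqrt(pmax(0, 1 - z^2))
    dirs <- cbind(r_xy * cos(az), r_xy * sin(az), z)
    probe <- list(center = c(box[1] / 2, box[2] / 2, box[3]),
                  radius = p$probe_radius, anchor_dirs = dirs)
  } else if (p$probe_radius > 0 && isTRUE(p$keep_probe)) {
    probe <- list(center = c(box[1] / 2, box[2] / 2, box[3]),
                  radius = p$probe_radius, anchor_dirs = matrix(0, 0, 3))
  }

  fils <- vector("list", p$n_free + p$n_attached)
  fails <- 0L
  clear_of_probe <- function(b) {
    is.null(probe) ||
      sqrt(sum((b - probe$center)^2)) > probe$radius + margin
  }
  for (i in seq_len(p$n_free)) {
    ok <- FALSE
    for (try in seq_len(1000L)) {
      ctr <- runif(3) * (box - 2 * margin) + margin
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      b1 <- ctr - u * seed_len / 2
      b2 <- ctr + u * seed_len / 2
      if (all(b1 > margin) && all(b2 > margin) &&
          all(b1 < box - margin) && all(b2 < box - margin) &&
          clear_of_probe(b1) && clear_of_probe(b2)) {
        ok <- TRUE
        break
      }
      fails <- fails + 1L
    }
    if (!ok) stop("seed filament placement failed after 1000 retries (",
                  fails, " rejections so far)")
    fils[[i]] <- list(beads = rbind(b1, b2, deparse.level = 0),
                      nmono = p$seed_monomers, attached = FALSE, anchor = NA_integer_)
  }
  if (p$n_attached > 0) {
    anch <- sweep(probe$anchor_dirs * probe$radius, 2, probe$center, "+")
    for (j in seq_len(p$n_attached)) {
      b1 <- anch[j, ]
      b2 <- b1 + c(0, 0, -seed_len)    # vertical, plus end pointing down
      fils[[p$n_free + j]] <- list(beads = rbind(b1, b2, deparse.level = 0),
                                   nmono = p$seed_monomers,
                                   attached = TRUE, anchor = j)
    }
  }

  vol <- prod(box) * 1e-9
  n_total_actin <- copy_number(p$actin_conc, vol)
  n_f <- (p$n_free + p$n_attached) * p$seed_monomers
  if (n_total_actin < n_f)
    stop("actin_conc too low for the requested seed filaments")
  mini_conc <- p$motor_conc / p$heads_per_minifilament
  state <- list(
    params = p, t = 0, box = box, filaments = fils,
    motors = empty_bonds(), linkers = empty_bonds(),
    probe = probe,
    pools = c(actin = n_total_actin - n_f, linker = 0, motor = 0),
    pending = c(linker = copy_number(p$linker_conc, vol),
                motor = copy_number(mini_conc, vol)),
    released = FALSE,
    grid = NULL
  )
  if (!p$well_mixed) state$grid <- init_grid(state)
  class(state) <- "acto_state"
  state
}

init_grid <- function(state) {
  p <- state$params
  dims <- pmax(1L, round(state$box / p$compartment_size))
  counts <- array(0L, dim = c(dims, 3))
  # scatter each pool uniformly over compartments
  ncomp <- prod(dims)
  for (sp in 1:3) {
    n <- state$pools[c("actin", "linker", "motor")[sp]]
    if (n > 0) {
      tab <- tabulate(sample.int(ncomp, n, replace = TRUE), nbins = ncomp)
      counts[, , , sp] <- array(tab, dim = dims)
    }
  }
  list(counts = counts, dims = dims, size = p$compartment_size)
}

probe_anchor_points <- function(state) {
  if (is.null(state$probe) || nrow(state$probe$anchor_dirs) == 0)
    return(matrix(0, 0, 3))
  sweep(state$probe$anchor_dirs * state$probe$radius, 2,
        state$probe$center, "+")
}

# Flatten filament bead coordinates and bond/anchor references into the
# arrays the compiled energy kernel consumes (0-based indices).
build_topology <- function(state) {
  p <- state$params
  fils <- state$filaments
  nb <- vapply(fils, function(f) nrow(f$beads), 1L)
  off <- c(0L, cumsum(nb))
  X <- do.call(rbind, lapply(fils, `[[`, "beads"))
  cb1 <- integer(0); cb2 <- integer(0); cl0 <- numeric(0)
  cfil <- integer(0); cidx <- integer(0)
  ba <- integer(0); bb <- integer(0); bc <- integer(0)
  for (i in seq_along(fils)) {
    k <- nb[i]
    if (k < 2) next
    idx <- off[i] + seq_len(k)        # 1-based global bead ids
    cb1 <- c(cb1, idx[-k]); cb2 <- c(cb2, idx[-1])
    cl0 <- c(cl0, fils[[i]]$nmono * p$monomer_rise)
    cfil <- c(cfil, rep.int(i, k - 1L)); cidx <- c(cidx, seq_len(k - 1L))
    if (k >= 3) {
      ba <- c(ba, idx[1:(k - 2)]); bb <- c(bb, idx[2:(k - 1)])
      bc <- c(bc, idx[3:k])
    }
  }
  bond_arrays <- function(df, k) {
    if (nrow(df) == 0)
      return(list(e1a = integer(0), e1b = integer(0), f1 = numeric(0),
                  e2a = integer(0), e2b = integer(0), f2 = numeric(0),
                  k = numeric(0), l0 = numeric(0)))
    list(e1a = off[df$f1] + df$c1, e1b = off[df$f1] + df$c1 + 1L,
         f1 = site_fraction(df$s1),
         e2a = off[df$f2] + df$c2, e2b = off[df$f2] + df$c2 + 1L,
         f2 = site_fraction(df$s2),
         k = rep_len(k, nrow(df)), l0 = df$rest)
  }
  mo <- bond_arrays(state$motors, p$motor_head_k)
  li <- bond_arrays(state$linkers, p$linker_k)
  attached <- which(vapply(fils, `[[`, TRUE, "attached"))
  anch_bead <- integer(0); anch_pt <- matrix(0, 0, 3)
  if (length(attached) && !is.null(state$probe)) {
    pts <- probe_anchor_points(state)
    aidx <- vapply(fils[attached], `[[`, 1L, "anchor")
    anch_bead <- off[attached] + 1L   # minus-end bead
    anch_pt <- pts[aidx, , drop = FALSE]
  }
  list(X = X, off = off, nb = nb,
       cb1 = cb1 - 1L, cb2 = cb2 - 1L, cl0 = cl0, cfil = cfil, cidx = cidx,
       ba = ba - 1L, bb = bb - 1L, bc = bc - 1L,
       e1a = c(mo$e1a, li$e1a) - 1L, e1b = c(mo$e1b, li$e1b) - 1L,
       f1 = c(mo$f1, li$f1),
       e2a = c(mo$e2a, li$e2a) - 1L, e2b = c(mo$e2b, li$e2b) - 1L,
       f2 = c(mo$f2, li$f2),
       bond_k = c(mo$k, li$k), bond_l0 = c(mo$l0, li$l0),
       bond_type = c(rep.int(0L, length(mo$k)), rep.int(1L, length(li$k))),
       anch_bead = anch_bead - 1L, anch_pt = anch_pt)
}

set_state_coords <- function(state, X) {
  nb <- vapply(state$filaments, function(f) nrow(f$beads), 1L)
  off <- c(0L, cumsum(nb))
  for (i in seq_along(state$filaments))
    state$filaments[[i]]$beads <- X[(off[i] + 1):(off[i] + nb[i]), , drop = FALSE]
  state
}

#' Extract a self-contained snapshot from a state
#'
#' A snapshot carries the geometry needed by every analysis metric (bead
#' coordinates, per-cylinder monomer counts, bond endpoint coordinates,
#' probe pose, box dimensions) without referencing the live state.
#'
#' @param state an \code{acto_state}.
#' @return A list of class \code{acto_snapshot}.
#' @export
snapshot <- function(state) {
  bond_coords <- function(df, type) {
    if (nrow(df) == 0)
      return(data.frame(type = character(), x1 = numeric(), y1 = numeric(),
                        z1 = numeric(), x2 = numeric(), y2 = numeric(),
                        z2 = numeric(), rest = numeric()))
    p1 <- t(vapply(seq_len(nrow(df)), function(i)
      site_xyz(state, df$f1[i], df$c1[i], df$s1[i]), numeric(3)))
    p2 <- t(vapply(seq_len(nrow(df)), function(i)
      site_xyz(state, df$f2[i], df$c2[i], df$s2[i]), numeric(3)))
    data.frame(type = type, x1 = p1[, 1], y1 = p1[, 2], z1 = p1[, 3],
               x2 = p2[, 1], y2 = p2[, 2], z2 = p2[, 3], rest = df$rest)
  }
  snp <- list(
    t = state$t, box = state$box,
    filaments = lapply(state$filaments, function(f)
      list(beads = f$beads, nmono = f$nmono, attached = f$attached)),
    bonds = rbind(bond_coords(state$motors, "MOTOR"),
                  bond_coords(state$linkers, "LINKER")),
    probe = if (!is.null(state$probe))
      list(center = state$probe$center, radius = state$probe$radius)
  )
  class(snp) <- "acto_snapshot"
  snp
}

site_xyz <- function(state, f, c, s) {
  b <- state$filaments[[f]]$beads
  fr <- site_fraction(s)
  (1 - fr) * b[c, ] + fr * b[c + 1, ]
}

#' @export
print.acto_state <- function(x, ...) {
  nf <- length(x$filaments)
  natt <- sum(vapply(x$filaments, `[[`, TRUE, "attached"))
  cat("actomyosin network state at t =", format(x$t), "s\n")
  cat("  box:", paste(round(x$box), collapse = " x "), "nm\n")
  cat("  filaments:", nf, "(", natt, "probe-attached )\n")
  cat("  F-actin monomers:", sum(vapply(x$filaments, fil_monomers, 1)), "\n")
  cat("  pools (G-actin, linker, mini-filament):",
      paste(x$pools, collapse = ", "), "\n")
  cat("  motors bound:", nrow(x$motors), " linkers bound:", nrow(x$linkers), "\n")
  invisible(x)
}

#' @export
print.acto_snapshot <- function(x, ...) {
  cat("snapshot at t =", format(x$t), "s;", length(x$filaments),
      "filaments;", nrow(x$bonds), "bonds\n")
  invisible(x)
}

#' Total actin monomer count (F-actin plus diffusive G-actin)
#'
#' Conserved exactly by every operation in the package; used by the
#' conservation property tests.
#'
#' @param state an \code{acto_state}.
#' @return Named vector with components \code{F}, \code{G}, \code{total}.
#' @export
actin_census <- function(state) {
  f <- sum(vapply(state$filaments, fil_monomers, 1))
  g <- unname(state$pools["actin"])
  c(F = f, G = g, total = f + g)
}
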