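# Synthetic inputs: controlled-geometry snapshots and trace sets for
# testing the analysis metrics. All fixtures are deterministic given seed.

make_fixture_snapshot <- function(fil_list, box) {
  snp <- list(t = 0, box = box,
              filaments = lapply(fil_list, function(b)
                list(beads = b, nmono = rep(40L, nrow(b) - 1L),
                     attached = FALSE)),
              bonds = data.frame(type = character(), x1 = numeric(),
                                 y1 = numeric(), z1 = numeric(),
                                 x2 = numeric(), y2 = numeric(),
                                 z2 = numeric(), rest = numeric()),
              probe = NULL)
  class(snp) <- "acto_snapshot"
  snp
}

#' Generate a synthetic geometry fixture
#'
#' Controlled stand-ins for network geometries and traced 3D polylines:
#' \describe{
#'   \item{bundle}{\code{n} straight filaments parallel to Z packed in a
#'     central cylinder of 500 nm diameter (alignment index 1 and bundle
#'     fraction 1 by construction).}
#'   \item{isotropic}{\code{n} straight filaments with uniformly random
#'     3D orientations (alignment index 0.5 in expectation).}
#'   \item{planar}{\code{n} filaments lying in the XY plane (alignment
#'     index 0).}
#'   \item{synthetic_traces}{random-walk polylines sampled on the
#'     anisotropic confocal voxel grid (dx = dy = 0.178 um, dz = 0.25 um)
#'     with a tunable upward drift \code{z_bias} in [0, 1]; returned as a
#'     \code{TraceSet} data.frame in um.}
#' }
#'
#' @param kind fixture kind (see above).
#' @param n number of filaments or traces (> 0).
#' @param seed RNG seed.
#' @param n_cyl cylinders per filament (snapshot kinds).
#' @param n_points points per trace (trace kind).
#' @param z_bias drift of the trace walk toward +Z (trace kind).
#' @return An \code{acto_snapshot}, or a \code{TraceSet} data.frame for
#'   \code{synthetic_traces}.
#' @examples
#' alignment_index(generate_fixture("bundle", 20, seed = 1))
#' @export
generate_fixture <- function(kind = c("bundle", "isotropic", "planar",
                                      "synthetic_traces"),
                             n, seed = 1L, n_cyl = 5L, n_points = 25L,
                             z_bias = 0) {
  kind <- match.arg(kind)
  if (n <= 0) stop("n must be > 0")
  set.seed(seed)
  box <- c(3000, 3000, 1250)
  L <- n_cyl * 108
  if (kind == "bundle") {
    ctr <- box / 2
    fils <- lapply(seq_len(n), function(i) {
      r <- 240 * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      x0 <- ctr[1] + r * cos(th)
      y0 <- ctr[2] + r * sin(th)
      z0 <- runif(1, 10, max(box[3] - L - 10, 20))
      cbind(x0, y0, seq(z0, z0 + L, length.out = n_cyl + 1L))
    })
    return(make_fixture_snapshot(fils, box))
  }
  if (kind == "isotropic" || kind == "planar") {
    fils <- lapply(seq_len(n), function(i) {
      if (kind == "isotropic") {
        u <- rnorm(3)
      } else {
        u <- c(rnorm(2), 0)
      }
      u <- u / sqrt(sum(u^2))
      ctr <- runif(3) * (box - 2 * L) + L
      sweep(outer(seq(-L / 2, L / 2, length.out = n_cyl + 1L), u), 2,
            ctr, "+")
    })
    return(make_fixture_snapshot(fils, box))
  }
  # synthetic_traces: voxel-grid random walks with controlled Z drift
  dx <- 0.178; dz <- 0.25
  rows <- list()
  for (tr in seq_len(n)) {
    p <- c(runif(2, 0, 20), runif(1, 0, 5))
    pts <- matrix(NA_real_, n_points, 3)
    pts[1, ] <- p
    for (k in 2:n_points) {
      if (runif(1) < z_bias) {
        step <- c(0, 0, dz)
      } else {
        ax <- sample.int(3L, 1L)
        step <- c(0, 0, 0)
        step[ax] <- sample(c(-1, 1), 1L) * if (ax == 3L) dz else dx
      }
      p <- p + step
      pts[k, ] <- p
    }
    rows[[tr]] <- data.frame(trace_id = tr, point_index = seq_len(n_points),
                             x_um = pts[, 1], y_um = pts[, 2],
                             z_um = pts[, 3])
  }
  do.call(rbind, rows)
}
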