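# Geometry metrics: alignment index, polarity, bundle-region F-actin
# fraction and recruitment rate, radius of gyration, axial and radial
# mass distributions.

#' Segment vectors and monomer weights of a snapshot
#'
#' One segment per cylinder (bead-to-bead displacement), weighted by the
#' cylinder's monomer count.
#'
#' @param snp an \code{acto_snapshot}.
#' @return list(segments = m x 3 matrix, weights).
#' @export
snapshot_segments <- function(snp) {
  segs <- list(); w <- list()
  for (f in snp$filaments) {
    b <- f$beads
    k <- nrow(b)
    if (k < 2) next
    segs[[length(segs) + 1L]] <- b[-1, , drop = FALSE] - b[-k, , drop = FALSE]
    w[[length(w) + 1L]] <- f$nmono
  }
  list(segments = do.call(rbind, segs), weights = unlist(w))
}

# F-actin monomer positions interpolated along each cylinder at the
# monomer-rise spacing
monomer_positions <- function(snp) {
  out <- list()
  for (f in snp$filaments) {
    b <- f$beads
    for (ci in seq_along(f$nmono)) {
      m <- f$nmono[ci]
      if (m < 1) next
      fr <- (seq_len(m) - 0.5) / m
      out[[length(out) + 1L]] <-
        (1 - fr) %o% b[ci, ] + fr %o% b[ci + 1L, ]
    }
  }
  do.call(rbind, out)
}

#' Alignment index along the force (Z) axis
#'
#' Mean cosine of the acute angle between each segment and the Z axis,
#' \code{< |dz| / sqrt(dx^2 + dy^2 + dz^2) >}: 1 for perfect alignment
#' with Z, 0 for segments perpendicular to it. For a snapshot, one segment
#' per cylinder weighted by its monomer count.
#'
#' @param x an m x 3 matrix of segment vectors (nm), or an
#'   \code{acto_snapshot}.
#' @param weights optional per-segment weights (matrix method).
#' @param ... unused.
#' @return Scalar in [0, 1].
#' @examples
#' alignment_index(cbind(0, 0, rnorm(10)))            # 1: parallel to Z
#' alignment_index(cbind(1, 1, sqrt(2)))              # cos 45 deg
#' @export
alignment_index <- function(x, ...) UseMethod("alignment_index")

#' @rdname alignment_index
#' @export
alignment_index.matrix <- function(x, weights = NULL, ...) {
  if (nrow(x) == 0) stop("need at least one segment")
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm < 1e-12)) stop("zero-length segment")
  ct <- abs(x[, 3]) / nrm
  if (is.null(weights)) mean(ct) else sum(weights * ct) / sum(weights)
}

#' @rdname alignment_index
#' @export
alignment_index.acto_snapshot <- function(x, ...) {
  sw <- snapshot_segments(x)
  alignment_index(sw$segments, weights = sw$weights)
}

#' Alignment index of traced polylines
#'
#' Experimental-style estimator: along every trace, all point pairs a
#' fixed number of points apart define segments; the per-pair alignment
#' cosines are averaged within each trace, and the per-trace means are
#' then averaged (unweighted) across traces.
#'
#' @param traces a \code{TraceSet}: data.frame with columns
#'   \code{trace_id}, \code{point_index}, \code{x_um}, \code{y_um},
#'   \code{z_um} (as read by [read_traces()]), or a list of n x 3 point
#'   matrices.
#' @param spacing index separation of paired points (default 10).
#' @return Scalar in [0, 1].
#' @export
trace_alignment_index <- function(traces, spacing = 10L) {
  if (is.data.frame(traces)) {
    traces <- lapply(split(traces, traces$trace_id), function(d) {
      d <- d[order(d$point_index), ]
      as.matrix(d[, c("x_um", "y_um", "z_um")])
    })
  }
  per_trace <- numeric(0)
  for (m in traces) {
    n <- nrow(m)
    if (n <= spacing) next
    i <- seq_len(n - spacing)
    seg <- m[i + spacing, , drop = FALSE] - m[i, , drop = FALSE]
    seg <- seg[sqrt(rowSums(seg^2)) > 1e-12, , drop = FALSE]  # coincident pairs carry no angle
    if (nrow(seg) == 0) next
    per_trace <- c(per_trace, alignment_index(seg))
  }
  if (!length(per_trace))
    stop("no trace has more than 'spacing' points: no pairs to average")
  mean(per_trace)
}

#' Filament polarity alignment distribution
#'
#' Signed cosine of the angle between each filament's minus-to-plus
#' end-to-end vector and +Z; spans [-1, 1] and flips sign under polarity
#' reversal (the unsigned alignment index does not).
#'
#' @param snp an \code{acto_snapshot}.
#' @return Numeric vector, one value per non-degenerate filament; the
#'   number of skipped (zero end-to-end) filaments is attached as
#'   attribute \code{"skipped"}.
#' @export
polarity_alignment_distribution <- function(snp) {
  if (!length(snp$filaments)) stop("snapshot has no filaments")
  vals <- numeric(0)
  skipped <- 0L
  for (f in snp$filaments) {
    v <- f$beads[nrow(f$beads), ] - f$beads[1, ]
    n <- sqrt(sum(v^2))
    if (n < 1e-12) {
      skipped <- skipped + 1L
      next
    }
    vals <- c(vals, v[3] / n)
  }
  attr(vals, "skipped") <- skipped
  vals
}

#' F-actin fraction in the bundle region
#'
#' The bundle region is the vertical cylinder of the given diameter
#' (default 500 nm) centered on the probe axis (box midpoint in x, y) and
#' spanning the current box height. Returns the fraction of F-actin
#' monomers (interpolated along each cylinder) inside it.
#'
#' @param snp an \code{acto_snapshot}.
#' @param diameter bundle-region diameter (nm).
#' @return Fraction in [0, 1].
#' @export
bundle_fraction <- function(snp, diameter = 500) {
  pos <- monomer_positions(snp)
  if (is.null(pos) || nrow(pos) == 0) stop("snapshot has no F-actin")
  ax <- snp$box[1:2] / 2
  r2 <- rowSums(sweep(pos[, 1:2, drop = FALSE], 2, ax)^2)
  inside <- r2 <= (diameter / 2)^2 & pos[, 3] >= 0 & pos[, 3] <= snp$box[3]
  mean(inside)
}

#' Windowed recruitment rate (least-squares slopes)
#'
#' Ordinary least-squares slope of a time series over consecutive
#' windows (default 50 s), timestamped at the window centers.
#'
#' @param series data.frame with columns \code{time}, \code{value}.
#' @param window window width (s).
#' @return data.frame(time, slope); windows with fewer than two points are
#'   skipped with a warning.
#' @export
recruitment_rate <- function(series, window = 50) {
  stopifnot(all(c("time", "value") %in% names(series)))
  t0 <- min(series$time)
  idx <- floor((series$time - t0) / window)
  out_t <- numeric(0)
  out_s <- numeric(0)
  skipped <- 0L
  for (w in sort(unique(idx))) {
    d <- series[idx == w, ]
    if (nrow(d) < 2) {
      skipped <- skipped + 1L
      next
    }
    out_t <- c(out_t, t0 + (w + 0.5) * window)
    out_s <- c(out_s, unname(coef(lm(value ~ time, data = d))[2]))
  }
  if (skipped > 0)
    warning(skipped, " window(s) with < 2 points skipped")
  data.frame(time = out_t, slope = out_s)
}

#' Radius of gyration of the F-actin mass
#'
#' Root mean square distance of interpolated F-actin monomer positions
#' from their center of mass.
#'
#' @param snp an \code{acto_snapshot}.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(snp) {
  pos <- monomer_positions(snp)
  if (is.null(pos) || nrow(pos) == 0) stop("snapshot has no F-actin")
  com <- colMeans(pos)
  sqrt(mean(rowSums(sweep(pos, 2, com)^2)))
}

#' Rate of change of the radius of gyration
#'
#' Finite differences of an Rg time series, timestamped at interval
#' midpoints.
#'
#' @param series data.frame(time, value) with strictly increasing times.
#' @return data.frame(time, rate) in nm/s.
#' @export
rg_rate <- function(series) {
  stopifnot(all(c("time", "value") %in% names(series)))
  if (is.unsorted(series$time, strictly = TRUE))
    stop("times must be strictly increasing")
  n <- nrow(series)
  if (n < 2) stop("need at least two points")
  data.frame(time = (series$time[-1] + series$time[-n]) / 2,
             rate = diff(series$value) / diff(series$time))
}

#' Axial (Z) distribution of F-actin and its standard deviation
#'
#' Histogram of interpolated monomer z-coordinates (normalized to unit
#' mass, half-open bins [lo, hi)) plus the population standard deviation
#' of z.
#'
#' @param snp an \code{acto_snapshot}.
#' @param bin bin width (nm, > 0).
#' @return list(mids, density, sigma).
#' @export
z_distribution <- function(snp, bin = 50) {
  if (bin <= 0) stop("bin width must be > 0")
  pos <- monomer_positions(snp)
  if (is.null(pos) || nrow(pos) == 0) stop("snapshot has no F-actin")
  z <- pos[, 3]
  lo <- floor(min(z) / bin) * bin
  edges <- seq(lo, max(z) + bin, by = bin)
  counts <- tabulate(findInterval(z, edges), nbins = length(edges) - 1L)
  list(mids = edges[-length(edges)] + bin / 2,
       density = counts / length(z),
       sigma = sqrt(mean((z - mean(z))^2)))
}

#' Radial distribution of F-actin about the central vertical axis
#'
#' Histogram of monomer distances from the box's central vertical axis,
#' normalized to unit mass.
#'
#' @inheritParams z_distribution
#' @return list(mids, density).
#' @export
radial_distribution <- function(snp, bin = 50) {
  if (bin <= 0) stop("bin width must be > 0")
  pos <- monomer_positions(snp)
  if (is.null(pos) || nrow(pos) == 0) stop("snapshot has no F-actin")
  ax <- snp$box[1:2] / 2
  r <- sqrt(rowSums(sweep(pos[, 1:2, drop = FALSE], 2, ax)^2))
  edges <- seq(0, max(r) + bin, by = bin)
  counts <- tabulate(findInterval(r, edges), nbins = length(edges) - 1L)
  list(mids = edges[-length(edges)] + bin / 2,
       density = counts / length(r))
}

#' Metric time series of a trajectory
#'
#' Evaluates analysis metrics on every snapshot of a trajectory.
#'
#' @param traj an \code{acto_trajectory} (or list of snapshots).
#' @param metrics subset of \code{c("alignment", "bundle", "rg", "sigma")}.
#' @param diameter bundle-region diameter (nm).
#' @return data.frame(time, metric, value).
#' @export
trajectory_metrics <- function(traj,
                               metrics = c("alignment", "bundle", "rg"),
                               diameter = 500) {
  snaps <- if (inherits(traj, "acto_trajectory")) traj$snapshots else traj
  metrics <- match.arg(metrics, c("alignment", "bundle", "rg", "sigma"),
                       several.ok = TRUE)
  rows <- list()
  for (s in snaps) {
    for (m in metrics) {
      v <- switch(m,
        alignment = alignment_index(s),
        bundle = bundle_fraction(s, diameter),
        rg = radius_of_gyration(s),
        sigma = z_distribution(s)$sigma)
      rows[[length(rows) + 1L]] <- data.frame(time = s$t, metric = m,
                                              value = v)
    }
  }
  do.call(rbind, rows)
}
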