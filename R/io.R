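# Plain-text trajectory serialization and trace-file reading.
#
# Format (line-oriented, versioned, nm/s units, repr-exact floats):
#   ACTOPULL_TRAJ v1
#   SNAPSHOT t box_x box_y box_z
#   FILAMENT id attached n_beads
#   x y z                       (one line per bead, minus to plus)
#   NMONO m1 m2 ... m(n_beads-1)
#   MOTOR x1 y1 z1 x2 y2 z2 rest
#   LINKER x1 y1 z1 x2 y2 z2 rest
#   PROBE cx cy cz r

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write a trajectory to a plain-text file
#'
#' Lossless at full double precision; [read_trajectory()] inverts it
#' field-for-field.
#'
#' @param traj an \code{acto_trajectory} or list of \code{acto_snapshot}.
#' @param path output file.
#' @export
write_trajectory <- function(traj, path) {
  snaps <- if (inherits(traj, "acto_trajectory")) traj$snapshots else traj
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("ACTOPULL_TRAJ v1", con)
  for (s in snaps) {
    writeLines(paste("SNAPSHOT", fmt_num(s$t), fmt_num(s$box[1]),
                     fmt_num(s$box[2]), fmt_num(s$box[3])), con)
    for (i in seq_along(s$filaments)) {
      f <- s$filaments[[i]]
      writeLines(paste("FILAMENT", i, as.integer(f$attached),
                       nrow(f$beads)), con)
      writeLines(apply(f$beads, 1, function(r)
        paste(fmt_num(r), collapse = " ")), con)
      writeLines(paste("NMONO", paste(f$nmono, collapse = " ")), con)
    }
    if (!is.null(s$bonds) && nrow(s$bonds))
      writeLines(paste(s$bonds$type,
                       fmt_num(s$bonds$x1), fmt_num(s$bonds$y1),
                       fmt_num(s$bonds$z1), fmt_num(s$bonds$x2),
                       fmt_num(s$bonds$y2), fmt_num(s$bonds$z2),
                       fmt_num(s$bonds$rest)), con)
    if (!is.null(s$probe))
      writeLines(paste("PROBE", fmt_num(s$probe$center[1]),
                       fmt_num(s$probe$center[2]),
                       fmt_num(s$probe$center[3]),
                       fmt_num(s$probe$radius)), con)
  }
  invisible(path)
}

#' Read a plain-text trajectory file
#'
#' Validates the record grammar, the format version, and that snapshot
#' times are non-decreasing; malformed input raises an error naming the
#' offending line.
#'
#' @param path file written by [write_trajectory()].
#' @return List of \code{acto_snapshot} (class \code{acto_trajectory_file}).
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "ACTOPULL_TRAJ v1")
    stop("unrecognized trajectory format/version in ", path)
  bad <- function(i, what) stop("malformed ", what, " record at line ", i)
  snaps <- list()
  cur <- NULL
  bonds <- NULL
  i <- 2L
  n <- length(lines)
  flush_snap <- function() {
    if (is.null(cur)) return()
    cur$bonds <<- if (length(bonds))
      do.call(rbind, bonds)
    else data.frame(type = character(), x1 = numeric(), y1 = numeric(),
                    z1 = numeric(), x2 = numeric(), y2 = numeric(),
                    z2 = numeric(), rest = numeric())
    class(cur) <<- "acto_snapshot"
    snaps[[length(snaps) + 1L]] <<- cur
    if (length(snaps) > 1 &&
        snaps[[length(snaps)]]$t < snaps[[length(snaps) - 1L]]$t)
      stop("snapshot times decrease at line ", i)
    cur <<- NULL
    bonds <<- NULL
  }
  while (i <= n) {
    ln <- lines[i]
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(tok)) { i <- i + 1L; next }
    key <- tok[1]
    if (key == "SNAPSHOT") {
      if (length(tok) != 5) bad(i, "SNAPSHOT")
      flush_snap()
      v <- suppressWarnings(as.numeric(tok[-1]))
      if (anyNA(v)) bad(i, "SNAPSHOT")
      cur <- list(t = v[1], box = v[2:4], filaments = list(), bonds = NULL,
                  probe = NULL)
      i <- i + 1L
    } else if (key == "FILAMENT") {
      if (is.null(cur) || length(tok) != 4) bad(i, "FILAMENT")
      nb <- suppressWarnings(as.integer(tok[4]))
      if (is.na(nb) || nb < 2 || i + nb + 1L > n + 1L) bad(i, "FILAMENT")
      beads <- matrix(NA_real_, nb, 3)
      for (b in seq_len(nb)) {
        v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + b]),
                                                  "\\s+")[[1]]))
        if (length(v) != 3 || anyNA(v)) bad(i + b, "bead coordinate")
        beads[b, ] <- v
      }
      nm_tok <- strsplit(trimws(lines[i + nb + 1L]), "\\s+")[[1]]
      if (nm_tok[1] != "NMONO") bad(i + nb + 1L, "NMONO")
      nmono <- suppressWarnings(as.integer(nm_tok[-1]))
      if (length(nmono) != nb - 1L || anyNA(nmono)) bad(i + nb + 1L, "NMONO")
      cur$filaments[[length(cur$filaments) + 1L]] <-
        list(beads = beads, nmono = nmono, attached = tok[3] == "1")
      i <- i + nb + 2L
    } else if (key %in% c("MOTOR", "LINKER")) {
      if (is.null(cur) || length(tok) != 8) bad(i, key)
      v <- suppressWarnings(as.numeric(tok[-1]))
      if (anyNA(v)) bad(i, key)
      bonds[[length(bonds) + 1L]] <-
        data.frame(type = key, x1 = v[1], y1 = v[2], z1 = v[3],
                   x2 = v[4], y2 = v[5], z2 = v[6], rest = v[7])
      i <- i + 1L
    } else if (key == "PROBE") {
      if (is.null(cur) || length(tok) != 5) bad(i, "PROBE")
      v <- suppressWarnings(as.numeric(tok[-1]))
      if (anyNA(v)) bad(i, "PROBE")
      cur$probe <- list(center = v[1:3], radius = v[4])
      i <- i + 1L
    } else {
      bad(i, paste0("unknown '", key, "'"))
    }
  }
  flush_snap()
  class(snaps) <- "acto_trajectory_file"
  snaps
}

#' Read a 3D trace file (CSV)
#'
#' Consumes exported filament-trace coordinates: columns \code{trace_id},
#' \code{point_index}, \code{x_um}, \code{y_um}, \code{z_um}. Raw
#' anisotropic-voxel coordinates are accepted as-is, since the alignment
#' index operates on physical coordinates.
#'
#' @param path CSV file.
#' @return data.frame (a \code{TraceSet}) sorted by trace and point index.
#' @export
read_traces <- function(path) {
  d <- read.csv(path)
  need <- c("trace_id", "point_index", "x_um", "y_um", "z_um")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("trace file lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(d[, c("x_um", "y_um", "z_um")]))))
    stop("non-finite coordinates in trace file")
  d[order(d$trace_id, d$point_index), need]
}
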