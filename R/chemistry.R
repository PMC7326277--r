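# Stochastic reaction engine for the actomyosin network: treadmilling,
# motor/linker binding and unbinding, motor walking, and (in grid mode)
# compartment-hop diffusion, simulated with the next reaction method.
#
# Channel layout. Reactions with identical per-instance rates are grouped
# into one aggregate channel whose propensity is the per-instance rate
# times the instance count (exact for exponential clocks); the fired
# instance is drawn uniformly -- or ratchet-weighted for polymerization --
# at execution time. Force-dependent bond channels are per bond. Forces are
# frozen between mechanical minimizations: propensities are set from the
# geometry at entry and only copy numbers, occupancy, and walking-induced
# site moves update them during a call.

KIND_POLY_PLUS_FREE <- 1L
KIND_POLY_MINUS_FREE <- 2L
KIND_DEPOLY_PLUS_FREE <- 3L
KIND_DEPOLY_MINUS_FREE <- 4L
KIND_POLY_PLUS_ATT <- 5L
KIND_DEPOLY_PLUS_ATT <- 6L
KIND_MOTOR_BIND <- 7L
KIND_LINKER_BIND <- 8L
KIND_MOTOR_UNBIND <- 9L
KIND_MOTOR_WALK <- 10L
KIND_LINKER_UNBIND <- 11L
KIND_POLY_END <- 12L
KIND_DIFFUSION <- 13L
KIND_POLY_AGG <- 14L
KIND_DEPOLY_AGG <- 15L

kind_names <- c("poly_plus", "poly_minus", "depoly_plus", "depoly_minus",
                "poly_plus_att", "depoly_plus_att", "motor_bind",
                "linker_bind", "motor_unbind", "motor_walk", "linker_unbind",
                "poly", "diffusion", "poly", "depoly")

# site table: one row per (filament, cylinder, binding site)
site_table <- function(state) {
  fils <- state$filaments
  rows <- lapply(seq_along(fils), function(i) {
    b <- fils[[i]]$beads
    k <- nrow(b) - 1L
    if (k < 1L) return(NULL)
    fr <- site_fraction(1:4)
    cyl <- rep(seq_len(k), each = 4L)
    f <- rep(fr, k)
    p1 <- b[cyl, , drop = FALSE]
    p2 <- b[cyl + 1L, , drop = FALSE]
    cbind(fil = i, cyl = cyl, s = rep(1:4, k),
          (1 - f) * p1 + f * p2)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c("fil", "cyl", "s", "x", "y", "z")
  m
}

occ_key <- function(f, c, s) paste(f, c, s, sep = ".")

#' Candidate binding-site pairs
#'
#' All unoccupied binding-site pairs whose current separation lies within
#' the species' rest-length range ([175, 225] nm for motors, [30, 40] nm
#' for crosslinkers), excluding pairs on the same or adjacent cylinders of
#' one filament. Each cylinder carries 4 binding sites at fractional
#' positions 1/8, 3/8, 5/8, 7/8.
#'
#' @param state an \code{acto_state}.
#' @param species \code{"motor"} or \code{"linker"}.
#' @return data.frame with columns f1, c1, s1, f2, c2, s2, dist (nm).
#' @export
candidate_binding_pairs <- function(state, species = c("motor", "linker")) {
  species <- match.arg(species)
  st <- site_table(state)
  if (is.null(st) || nrow(st) == 0)
    return(data.frame(f1 = integer(), c1 = integer(), s1 = integer(),
                      f2 = integer(), c2 = integer(), s2 = integer(),
                      dist = numeric()))
  p <- state$params
  rng <- if (species == "motor") c(p$motor_rest_min, p$motor_rest_max)
         else c(p$linker_rest_min, p$linker_rest_max)
  df <- if (species == "motor") state$motors else state$linkers
  occ <- rep(FALSE, nrow(st))
  if (nrow(df) > 0) {
    keys <- occ_key(st[, "fil"], st[, "cyl"], st[, "s"])
    used <- c(occ_key(df$f1, df$c1, df$s1), occ_key(df$f2, df$c2, df$s2))
    occ <- keys %in% used
  }
  # a global cylinder id so the C++ side can test adjacency within filament
  pr <- candidate_pairs_cpp(st[, c("x", "y", "z"), drop = FALSE],
                            as.integer(st[, "fil"]), as.integer(st[, "cyl"]),
                            occ, rng[1], rng[2])
  if (nrow(pr) == 0)
    return(data.frame(f1 = integer(), c1 = integer(), s1 = integer(),
                      f2 = integer(), c2 = integer(), s2 = integer(),
                      dist = numeric()))
  i <- pr[, 1]; j <- pr[, 2]
  d <- sqrt(rowSums((st[i, c("x", "y", "z"), drop = FALSE] -
                     st[j, c("x", "y", "z"), drop = FALSE])^2))
  data.frame(f1 = st[i, "fil"], c1 = st[i, "cyl"], s1 = st[i, "s"],
             f2 = st[j, "fil"], c2 = st[j, "cyl"], s2 = st[j, "s"],
             dist = d)
}

#' Peek at the next scheduled reaction
#'
#' Builds the reaction set for the current state and returns the earliest
#' scheduled event without firing it, or \code{NULL} when no reaction has
#' positive propensity ("no event").
#'
#' @param state an \code{acto_state}.
#' @return \code{list(time, kind)} or \code{NULL}.
#' @export
next_reaction <- function(state) {
  res <- advance_chemistry(state, dt = Inf, max_events = 0L, peek = TRUE)
  res
}

#' Advance the stochastic chemistry
#'
#' Fires reactions in time order with the next reaction method until the
#' clock advances by \code{dt}. Polymerization consumes one G-actin from
#' the tip's compartment and extends the terminal cylinder (splitting into
#' a fresh cylinder past 40 monomers); depolymerization reverses this and
#' releases G-actin; removing a cylinder releases any bond attached to it;
#' motor walking moves one bound side one binding site (27 nm) toward the
#' plus end. Species counts are conserved exactly. Forces entering the
#' rate laws are taken from the entry geometry and held frozen, matching
#' the alternating mechanochemical cycle.
#'
#' @param state an \code{acto_state}.
#' @param dt time to advance (s, > 0).
#' @param max_events optional event cap.
#' @param track_events if TRUE, attach an event log (time, kind) as
#'   attribute \code{"events"}.
#' @param peek internal: return the first scheduled reaction instead.
#' @return The advanced state; attribute \code{"n_events"} counts fired
#'   reactions by kind.
#' @export
advance_chemistry <- function(state, dt, max_events = Inf,
                              track_events = FALSE, peek = FALSE) {
  if (!peek && (!is.finite(dt) || dt <= 0)) stop("dt must be > 0")
  p <- state$params
  fils <- state$filaments
  nfil <- length(fils)
  grid_mode <- !p$well_mixed && !is.null(state$grid)
  t0 <- state$t
  t_end <- t0 + dt

  NG <- unname(state$pools["actin"])
  NL <- unname(state$pools["linker"])
  NM <- unname(state$pools["motor"])

  is_att <- vapply(fils, `[[`, TRUE, "attached")
  free_ids <- which(!is_att)
  att_ids <- which(is_att)
  nmono_tot <- vapply(fils, fil_monomers, 1)

  # ratchet weights from the frozen entry geometry
  w_plus <- rep(1, nfil)
  w_minus <- rep(1, nfil)
  for (i in seq_len(nfil)) {
    b <- fils[[i]]$beads
    bfp <- boundary_force_at(state, b[nrow(b), ])
    if (bfp$dmin < p$monomer_rise)
      w_plus[i] <- exp(-bfp$force / p$poly_char_force)
    if (!is_att[i]) {
      bfm <- boundary_force_at(state, b[1, ])
      if (bfm$dmin < p$monomer_rise)
        w_minus[i] <- exp(-bfm$force / p$poly_char_force)
    }
  }
  wpf_uniform <- all(w_plus[free_ids] == 1)
  wmf_uniform <- all(w_minus[free_ids] == 1)
  wpa_uniform <- all(w_plus[att_ids] == 1)

  # candidate site pairs and occupancy from the frozen entry geometry
  # (skipped entirely for species with no copies anywhere)
  have_motor <- NM > 0 || nrow(state$motors) > 0
  have_linker <- NL > 0 || nrow(state$linkers) > 0
  cand_m <- if (have_motor) candidate_binding_pairs(state, "motor")
            else empty_bonds()
  cand_l <- if (have_linker) candidate_binding_pairs(state, "linker")
            else empty_bonds()
  occ_m <- new.env(parent = emptyenv())
  occ_l <- new.env(parent = emptyenv())

  # bond store (preallocated columns, active flags)
  nb0 <- nrow(state$motors) + nrow(state$linkers)
  cap_b <- max(64L, 2L * nb0)
  b_type <- integer(cap_b)      # 1 motor, 2 linker
  b_f1 <- integer(cap_b); b_c1 <- integer(cap_b); b_s1 <- integer(cap_b)
  b_f2 <- integer(cap_b); b_c2 <- integer(cap_b); b_s2 <- integer(cap_b)
  b_rest <- numeric(cap_b); b_active <- logical(cap_b)
  b_chu <- integer(cap_b); b_chw <- integer(cap_b)
  n_b <- 0L

  conv <- p$compartment_size^3 / prod(state$box)
  k_motor <- p$motor_head_k
  fc_catch <- p$motor_unbind_force * p$heads_per_side
  fc_stall <- p$motor_stall_force * p$heads_per_side

  site_pos <- function(f, c, s) {
    b <- fils[[f]]$beads
    fr <- site_fraction(s)
    (1 - fr) * b[c, ] + fr * b[c + 1L, ]
  }
  bond_tension <- function(i) {
    pp1 <- site_pos(b_f1[i], b_c1[i], b_s1[i])
    pp2 <- site_pos(b_f2[i], b_c2[i], b_s2[i])
    l <- sqrt(sum((pp2 - pp1)^2))
    k <- if (b_type[i] == 1L) k_motor else p$linker_k
    k * abs(l - b_rest[i])
  }

  e <- nrm_new(256L)
  e$t <- t0
  ch_kind <- integer(0)
  ch_bond <- integer(0)
  ch_fil <- integer(0)       # per-end poly (grid mode)
  ch_end <- integer(0)       # 1 plus, 2 minus
  ch_comp <- integer(0)      # diffusion (grid mode)
  ch_spec <- integer(0)

  add_channel <- function(kind, a, bond = 0L, fil = 0L, end = 0L,
                          comp = 0L, spec = 0L) {
    id <- nrm_add(e, a)
    ch_kind[id] <<- kind
    ch_bond[id] <<- bond
    ch_fil[id] <<- fil
    ch_end[id] <<- end
    ch_comp[id] <<- comp
    ch_spec[id] <<- spec
    id
  }

  # ---- grid-mode helpers -------------------------------------------------
  gdims <- if (grid_mode) state$grid$dims else c(1L, 1L, 1L)
  gsize <- if (grid_mode) state$grid$size else 0
  gA <- NULL; gL <- NULL; gM <- NULL
  diff_ch <- NULL
  comp_of <- function(x) {
    ijk <- pmin(pmax(floor(x / gsize), 0), gdims - 1L)
    as.integer(1L + ijk[1] + gdims[1] * (ijk[2] + gdims[2] * ijk[3]))
  }
  if (grid_mode) {
    gA <- as.vector(state$grid$counts[, , , 1])
    gL <- as.vector(state$grid$counts[, , , 2])
    gM <- as.vector(state$grid$counts[, , , 3])
    ncomp <- prod(gdims)
    diff_ch <- matrix(0L, ncomp, 3)
    drates <- c(p$diff_actin, p$diff_linker, p$diff_motor)
    for (sp in 1:3) {
      cnt <- switch(sp, gA, gL, gM)
      for (cmp in seq_len(ncomp))
        diff_ch[cmp, sp] <- add_channel(KIND_DIFFUSION, drates[sp] * cnt[cmp],
                                        comp = cmp, spec = sp)
    }
  }

  # ---- treadmilling channels --------------------------------------------
  # well-mixed: every polymerization propensity scales with the same G
  # count, so the three end-types share one channel; the type is resolved
  # at firing time from the (frozen) ratchet-weight shares. Analogously
  # depolymerization shares one channel over the eligible-filament counts.
  elig <- nmono_tot > p$min_monomers
  tip_comp_plus <- integer(nfil)
  tip_comp_minus <- integer(nfil)
  end_ch_plus <- integer(nfil)
  end_ch_minus <- integer(nfil)
  ch_poly <- 0L; ch_depoly <- 0L
  ch_dp_free <- 0L; ch_dm_free <- 0L; ch_dp_att <- 0L
  poly_s1 <- p$poly_plus * sum(w_plus[free_ids])    # frozen shares
  poly_s2 <- p$poly_minus * sum(w_minus[free_ids])
  poly_s3 <- p$poly_plus * sum(w_plus[att_ids])
  poly_stot <- poly_s1 + poly_s2 + poly_s3
  dep_shares <- function() {
    nef <- sum(elig[free_ids])
    nea <- sum(elig[att_ids])
    c(p$depoly_plus * nef, p$depoly_minus * nef, p$depoly_plus * nea)
  }
  dsh <- dep_shares()
  if (grid_mode) {
    for (i in seq_len(nfil)) {
      b <- fils[[i]]$beads
      tip_comp_plus[i] <- comp_of(b[nrow(b), ])
      tip_comp_minus[i] <- comp_of(b[1, ])
      end_ch_plus[i] <- add_channel(KIND_POLY_END,
        p$poly_plus * gA[tip_comp_plus[i]] * w_plus[i], fil = i, end = 1L)
      if (!is_att[i])
        end_ch_minus[i] <- add_channel(KIND_POLY_END,
          p$poly_minus * gA[tip_comp_minus[i]] * w_minus[i], fil = i, end = 2L)
    }
    ch_dp_free <- add_channel(KIND_DEPOLY_PLUS_FREE, dsh[1])
    ch_dm_free <- add_channel(KIND_DEPOLY_MINUS_FREE, dsh[2])
    ch_dp_att <- add_channel(KIND_DEPOLY_PLUS_ATT, dsh[3])
  } else {
    ch_poly <- add_channel(KIND_POLY_AGG, conv * NG * poly_stot)
    ch_depoly <- add_channel(KIND_DEPOLY_AGG, sum(dsh))
  }

  # ---- binding channels --------------------------------------------------
  cand_avail_m <- nrow(cand_m) > 0
  cand_avail_l <- nrow(cand_l) > 0
  mb_coef <- p$motor_bind * p$heads_per_minifilament
  ch_mb <- add_channel(KIND_MOTOR_BIND, if (cand_avail_m) mb_coef * NM else 0)
  ch_lb <- add_channel(KIND_LINKER_BIND,
                       if (cand_avail_l) p$linker_bind * NL else 0)

  register_bond <- function(type, f1, c1, s1, f2, c2, s2, rest) {
    n_b <<- n_b + 1L
    i <- n_b
    if (i > length(b_type)) {   # grow columns
      grow <- length(b_type)
      b_type <<- c(b_type, integer(grow)); b_f1 <<- c(b_f1, integer(grow))
      b_c1 <<- c(b_c1, integer(grow)); b_s1 <<- c(b_s1, integer(grow))
      b_f2 <<- c(b_f2, integer(grow)); b_c2 <<- c(b_c2, integer(grow))
      b_s2 <<- c(b_s2, integer(grow)); b_rest <<- c(b_rest, numeric(grow))
      b_active <<- c(b_active, logical(grow))
      b_chu <<- c(b_chu, integer(grow)); b_chw <<- c(b_chw, integer(grow))
    }
    b_type[i] <<- type
    b_f1[i] <<- f1; b_c1[i] <<- c1; b_s1[i] <<- s1
    b_f2[i] <<- f2; b_c2[i] <<- c2; b_s2[i] <<- s2
    b_rest[i] <<- rest; b_active[i] <<- TRUE
    occ <- if (type == 1L) occ_m else occ_l
    assign(occ_key(f1, c1, s1), i, envir = occ)
    assign(occ_key(f2, c2, s2), i, envir = occ)
    ten <- bond_tension(i)
    if (type == 1L) {
      b_chu[i] <<- add_channel(KIND_MOTOR_UNBIND,
        2 * mechanochemical_rate(p$motor_unbind0, ten, "catch", fc_catch),
        bond = i)
      b_chw[i] <<- add_channel(KIND_MOTOR_WALK,
        2 * mechanochemical_rate(p$motor_walk_rate0, ten, "stall", fc_stall),
        bond = i)
    } else {
      b_chu[i] <<- add_channel(KIND_LINKER_UNBIND,
        mechanochemical_rate(p$linker_unbind0, ten, "slip",
                             p$linker_char_force), bond = i)
    }
    i
  }
  df <- state$motors
  for (r in seq_len(nrow(df)))
    register_bond(1L, df$f1[r], df$c1[r], df$s1[r],
                  df$f2[r], df$c2[r], df$s2[r], df$rest[r])
  df <- state$linkers
  for (r in seq_len(nrow(df)))
    register_bond(2L, df$f1[r], df$c1[r], df$s1[r],
                  df$f2[r], df$c2[r], df$s2[r], df$rest[r])

  if (peek) {
    nxt <- nrm_peek(e)
    if (is.null(nxt)) return(NULL)
    return(list(time = nxt$time, kind = kind_names[ch_kind[nxt$id]]))
  }

  # ---- propensity refresh helpers ---------------------------------------
  upd_poly <- function() {
    if (!grid_mode) nrm_update(e, ch_poly, conv * NG * poly_stot)
  }
  upd_depoly <- function() {
    dsh <<- dep_shares()
    if (grid_mode) {
      nrm_update(e, ch_dp_free, dsh[1])
      nrm_update(e, ch_dm_free, dsh[2])
      nrm_update(e, ch_dp_att, dsh[3])
    } else {
      nrm_update(e, ch_depoly, sum(dsh))
    }
  }
  upd_bind <- function() {
    nrm_update(e, ch_mb, if (cand_avail_m) mb_coef * NM else 0)
    nrm_update(e, ch_lb, if (cand_avail_l) p$linker_bind * NL else 0)
  }
  upd_end_channels <- function(cmp) {   # grid: G count changed in cmp
    nrm_update(e, diff_ch[cmp, 1], p$diff_actin * gA[cmp])
    for (i in which(tip_comp_plus == cmp))
      if (end_ch_plus[i] > 0)
        nrm_update(e, end_ch_plus[i], p$poly_plus * gA[cmp] * w_plus[i])
    for (i in which(tip_comp_minus == cmp))
      if (end_ch_minus[i] > 0)
        nrm_update(e, end_ch_minus[i], p$poly_minus * gA[cmp] * w_minus[i])
  }
  gain_G <- function(cmp) {
    NG <<- NG + 1
    if (grid_mode) { gA[cmp] <<- gA[cmp] + 1L; upd_end_channels(cmp) }
    else upd_poly()
  }
  lose_G <- function(cmp) {
    NG <<- NG - 1
    if (grid_mode) { gA[cmp] <<- gA[cmp] - 1L; upd_end_channels(cmp) }
    else upd_poly()
  }

  release_bond <- function(i) {
    occ <- if (b_type[i] == 1L) occ_m else occ_l
    rm(list = c(occ_key(b_f1[i], b_c1[i], b_s1[i]),
                occ_key(b_f2[i], b_c2[i], b_s2[i])), envir = occ)
    b_active[i] <<- FALSE
    nrm_update(e, b_chu[i], 0)
    if (b_type[i] == 1L) nrm_update(e, b_chw[i], 0)
    if (b_type[i] == 1L) NM <<- NM + 1 else NL <<- NL + 1
    if (grid_mode) {
      mid <- (site_pos(b_f1[i], b_c1[i], b_s1[i]) +
              site_pos(b_f2[i], b_c2[i], b_s2[i])) / 2
      cmp <- comp_of(mid)
      if (b_type[i] == 1L) gM[cmp] <<- gM[cmp] + 1L else gL[cmp] <<- gL[cmp] + 1L
      nrm_update(e, diff_ch[cmp, if (b_type[i] == 1L) 3 else 2],
                 (if (b_type[i] == 1L) p$diff_motor else p$diff_linker) *
                 (if (b_type[i] == 1L) gM[cmp] else gL[cmp]))
    }
    # a freed site may re-enable binding
    if (b_type[i] == 1L && !cand_avail_m && nrow(cand_m) > 0)
      cand_avail_m <<- TRUE
    if (b_type[i] == 2L && !cand_avail_l && nrow(cand_l) > 0)
      cand_avail_l <<- TRUE
    upd_bind()
  }

  # bonds referencing cylinder cyl of filament f are released; shift others
  drop_cylinder_bonds <- function(f, cyl, shift = 0L) {
    for (i in seq_len(n_b)) {
      if (!b_active[i]) next
      hit <- (b_f1[i] == f && b_c1[i] == cyl) ||
             (b_f2[i] == f && b_c2[i] == cyl)
      if (hit) release_bond(i)
    }
    if (shift != 0L) {
      # two-phase re-keying: remove every old key before assigning any new
      # one (sequential rm/assign can transiently collide when neighboring
      # sites on the same filament shift together)
      touched <- integer(0)
      for (i in seq_len(n_b)) {
        if (!b_active[i]) next
        if (b_f1[i] != f && b_f2[i] != f) next
        occ <- if (b_type[i] == 1L) occ_m else occ_l
        if (b_f1[i] == f) {
          rm(list = occ_key(f, b_c1[i], b_s1[i]), envir = occ)
          b_c1[i] <<- b_c1[i] + shift
        }
        if (b_f2[i] == f) {
          rm(list = occ_key(f, b_c2[i], b_s2[i]), envir = occ)
          b_c2[i] <<- b_c2[i] + shift
        }
        touched <- c(touched, i)
      }
      for (i in touched) {
        occ <- if (b_type[i] == 1L) occ_m else occ_l
        if (b_f1[i] == f)
          assign(occ_key(f, b_c1[i], b_s1[i]), i, envir = occ)
        if (b_f2[i] == f)
          assign(occ_key(f, b_c2[i], b_s2[i]), i, envir = occ)
      }
    }
  }

  do_poly <- function(i, end) {   # end: 1 plus, 2 minus
    fil <- fils[[i]]
    b <- fil$beads
    k <- nrow(b)
    if (end == 1L) {
      ax <- b[k, ] - b[k - 1L, ]
      ax <- ax / sqrt(sum(ax^2))
      nc <- length(fil$nmono)
      if (fil$nmono[nc] < p$monomers_per_cylinder) {
        fil$nmono[nc] <- fil$nmono[nc] + 1L
        fil$beads[k, ] <- b[k, ] + ax * p$monomer_rise
      } else {
        fil$beads <- rbind(b, b[k, ] + ax * p$monomer_rise, deparse.level = 0)
        fil$nmono <- c(fil$nmono, 1L)
      }
      cmp <- if (grid_mode) tip_comp_plus[i] else 1L
    } else {
      ax <- b[1, ] - b[2, ]
      ax <- ax / sqrt(sum(ax^2))
      if (fil$nmono[1] < p$monomers_per_cylinder) {
        fil$nmono[1] <- fil$nmono[1] + 1L
        fil$beads[1, ] <- b[1, ] + ax * p$monomer_rise
      } else {
        fil$beads <- rbind(b[1, ] + ax * p$monomer_rise, b, deparse.level = 0)
        fil$nmono <- c(1L, fil$nmono)
        drop_cylinder_bonds(i, 0L, shift = 1L)   # indices shift up
      }
      cmp <- if (grid_mode) tip_comp_minus[i] else 1L
    }
    fils[[i]] <<- fil
    nmono_tot[i] <<- nmono_tot[i] + 1
    if (!elig[i] && nmono_tot[i] > p$min_monomers) {
      elig[i] <<- TRUE
      upd_depoly()
    }
    lose_G(cmp)
  }

  do_depoly <- function(i, end) {
    fil <- fils[[i]]
    b <- fil$beads
    k <- nrow(b)
    if (end == 1L) {
      nc <- length(fil$nmono)
      if (fil$nmono[nc] > 1L) {
        ax <- b[k, ] - b[k - 1L, ]
        ax <- ax / sqrt(sum(ax^2))
        fil$nmono[nc] <- fil$nmono[nc] - 1L
        fil$beads[k, ] <- b[k, ] - ax * p$monomer_rise
      } else {
        drop_cylinder_bonds(i, nc)
        fil$beads <- b[-k, , drop = FALSE]
        fil$nmono <- fil$nmono[-nc]
      }
      cmp <- if (grid_mode) tip_comp_plus[i] else 1L
    } else {
      if (fil$nmono[1] > 1L) {
        ax <- b[1, ] - b[2, ]
        ax <- ax / sqrt(sum(ax^2))
        fil$nmono[1] <- fil$nmono[1] - 1L
        fil$beads[1, ] <- b[1, ] - ax * p$monomer_rise
      } else {
        drop_cylinder_bonds(i, 1L, shift = -1L)
        fil$beads <- b[-1, , drop = FALSE]
        fil$nmono <- fil$nmono[-1]
      }
      cmp <- if (grid_mode) tip_comp_minus[i] else 1L
    }
    fils[[i]] <<- fil
    nmono_tot[i] <<- nmono_tot[i] - 1
    if (elig[i] && nmono_tot[i] <= p$min_monomers) {
      elig[i] <<- FALSE
      upd_depoly()
    }
    gain_G(cmp)
  }

  pick_in <- function(ids, w, uniform) {
    n <- length(ids)
    if (n == 1L) return(ids)
    if (uniform) ids[sample.int(n, 1L)]
    else ids[sample.int(n, 1L, prob = w)]
  }

  fire_poly_agg <- function() {
    u <- runif(1) * poly_stot
    if (u < poly_s1) {
      i <- pick_in(free_ids, w_plus[free_ids], wpf_uniform)
      do_poly(i, 1L)
      KIND_POLY_PLUS_FREE
    } else if (u < poly_s1 + poly_s2) {
      i <- pick_in(free_ids, w_minus[free_ids], wmf_uniform)
      do_poly(i, 2L)
      KIND_POLY_MINUS_FREE
    } else {
      i <- pick_in(att_ids, w_plus[att_ids], wpa_uniform)
      do_poly(i, 1L)
      KIND_POLY_PLUS_ATT
    }
  }

  fire_depoly_agg <- function() {
    u <- runif(1) * sum(dsh)
    if (u < dsh[1]) {
      ids <- free_ids[elig[free_ids]]
      if (length(ids)) do_depoly(ids[sample.int(length(ids), 1L)], 1L)
      KIND_DEPOLY_PLUS_FREE
    } else if (u < dsh[1] + dsh[2]) {
      ids <- free_ids[elig[free_ids]]
      if (length(ids)) do_depoly(ids[sample.int(length(ids), 1L)], 2L)
      KIND_DEPOLY_MINUS_FREE
    } else {
      ids <- att_ids[elig[att_ids]]
      if (length(ids)) do_depoly(ids[sample.int(length(ids), 1L)], 1L)
      KIND_DEPOLY_PLUS_ATT
    }
  }

  site_free <- function(occ, f, c, s) !exists(occ_key(f, c, s), envir = occ)

  pick_candidate <- function(cand, occ) {
    n <- nrow(cand)
    for (try in seq_len(50L)) {
      r <- sample.int(n, 1L)
      if (site_free(occ, cand$f1[r], cand$c1[r], cand$s1[r]) &&
          site_free(occ, cand$f2[r], cand$c2[r], cand$s2[r]) &&
          cand$c1[r] <= length(fils[[cand$f1[r]]]$nmono) &&
          cand$c2[r] <= length(fils[[cand$f2[r]]]$nmono))
        return(r)
    }
    for (r in seq_len(n)) {    # exhaustive fallback
      if (site_free(occ, cand$f1[r], cand$c1[r], cand$s1[r]) &&
          site_free(occ, cand$f2[r], cand$c2[r], cand$s2[r]) &&
          cand$c1[r] <= length(fils[[cand$f1[r]]]$nmono) &&
          cand$c2[r] <= length(fils[[cand$f2[r]]]$nmono))
        return(r)
    }
    0L
  }

  do_bind <- function(type) {
    cand <- if (type == 1L) cand_m else cand_l
    occ <- if (type == 1L) occ_m else occ_l
    r <- pick_candidate(cand, occ)
    if (r == 0L) {   # candidate list exhausted: gate the channel off
      if (type == 1L) cand_avail_m <<- FALSE else cand_avail_l <<- FALSE
      upd_bind()
      return(invisible())
    }
    rest <- if (type == 1L) runif(1, p$motor_rest_min, p$motor_rest_max)
            else runif(1, p$linker_rest_min, p$linker_rest_max)
    register_bond(type, cand$f1[r], cand$c1[r], cand$s1[r],
                  cand$f2[r], cand$c2[r], cand$s2[r], rest)
    if (type == 1L) NM <<- NM - 1 else NL <<- NL - 1
    if (grid_mode) {
      mid <- (site_pos(cand$f1[r], cand$c1[r], cand$s1[r]) +
              site_pos(cand$f2[r], cand$c2[r], cand$s2[r])) / 2
      cmp <- comp_of(mid)
      cnt <- if (type == 1L) gM else gL
      # consume from the pair's compartment when possible, else from the
      # fullest compartment (bookkeeping fallback)
      if (cnt[cmp] <= 0L) cmp <- which.max(cnt)
      if (type == 1L) {
        gM[cmp] <<- gM[cmp] - 1L
        nrm_update(e, diff_ch[cmp, 3], p$diff_motor * gM[cmp])
      } else {
        gL[cmp] <<- gL[cmp] - 1L
        nrm_update(e, diff_ch[cmp, 2], p$diff_linker * gL[cmp])
      }
    }
    upd_bind()
  }

  do_walk <- function(i) {
    side <- sample.int(2L, 1L)
    f <- if (side == 1L) b_f1[i] else b_f2[i]
    cc <- if (side == 1L) b_c1[i] else b_c2[i]
    s <- if (side == 1L) b_s1[i] else b_s2[i]
    nc <- length(fils[[f]]$nmono)
    if (s < 4L) { s2 <- s + 1L; c2 <- cc }
    else if (cc < nc) { s2 <- 1L; c2 <- cc + 1L }
    else return(invisible())            # at the plus-most site: blocked
    if (!site_free(occ_m, f, c2, s2)) return(invisible())  # occupied: no-op
    rm(list = occ_key(f, cc, s), envir = occ_m)
    assign(occ_key(f, c2, s2), i, envir = occ_m)
    if (side == 1L) { b_c1[i] <<- c2; b_s1[i] <<- s2 }
    else { b_c2[i] <<- c2; b_s2[i] <<- s2 }
    ten <- bond_tension(i)
    nrm_update(e, b_chu[i],
      2 * mechanochemical_rate(p$motor_unbind0, ten, "catch", fc_catch))
    nrm_update(e, b_chw[i],
      2 * mechanochemical_rate(p$motor_walk_rate0, ten, "stall", fc_stall))
  }

  do_diffuse <- function(cmp, sp) {
    dir <- sample.int(6L, 1L)
    k <- (dir - 1L) %/% 2L + 1L
    step <- if (dir %% 2L == 1L) 1L else -1L
    idx0 <- cmp - 1L
    ijk <- c(idx0 %% gdims[1], (idx0 %/% gdims[1]) %% gdims[2],
             idx0 %/% (gdims[1] * gdims[2]))
    ijk[k] <- ijk[k] + step
    if (ijk[k] < 0L || ijk[k] >= gdims[k]) return(invisible())  # reflect
    cmp2 <- as.integer(1L + ijk[1] + gdims[1] * (ijk[2] + gdims[2] * ijk[3]))
    if (sp == 1L) {
      if (gA[cmp] <= 0L) return(invisible())
      gA[cmp] <<- gA[cmp] - 1L; gA[cmp2] <<- gA[cmp2] + 1L
      upd_end_channels(cmp); upd_end_channels(cmp2)
    } else if (sp == 2L) {
      if (gL[cmp] <= 0L) return(invisible())
      gL[cmp] <<- gL[cmp] - 1L; gL[cmp2] <<- gL[cmp2] + 1L
      nrm_update(e, diff_ch[cmp, 2], p$diff_linker * gL[cmp])
      nrm_update(e, diff_ch[cmp2, 2], p$diff_linker * gL[cmp2])
    } else {
      if (gM[cmp] <= 0L) return(invisible())
      gM[cmp] <<- gM[cmp] - 1L; gM[cmp2] <<- gM[cmp2] + 1L
      nrm_update(e, diff_ch[cmp, 3], p$diff_motor * gM[cmp])
      nrm_update(e, diff_ch[cmp2, 3], p$diff_motor * gM[cmp2])
    }
  }

  # ---- main loop ---------------------------------------------------------
  n_events <- integer(length(kind_names))
  ev_t <- numeric(0); ev_k <- integer(0)
  n_fired <- 0L
  repeat {
    nxt <- nrm_peek(e)
    if (is.null(nxt) || nxt$time > t_end || n_fired >= max_events) break
    id <- nxt$id
    e$t <- nxt$time
    kind <- ch_kind[id]
    fired <- kind
    if (kind == KIND_POLY_AGG) {
      fired <- fire_poly_agg()
    } else if (kind == KIND_DEPOLY_AGG) {
      fired <- fire_depoly_agg()
    } else if (kind == KIND_MOTOR_BIND) {
      do_bind(1L)
    } else if (kind == KIND_LINKER_BIND) {
      do_bind(2L)
    } else if (kind == KIND_MOTOR_UNBIND || kind == KIND_LINKER_UNBIND) {
      release_bond(ch_bond[id])
    } else if (kind == KIND_MOTOR_WALK) {
      do_walk(ch_bond[id])
    } else if (kind == KIND_POLY_END) {
      i <- ch_fil[id]
      if (ch_end[id] == 1L) do_poly(i, 1L) else do_poly(i, 2L)
      fired <- if (is_att[i]) KIND_POLY_PLUS_ATT else
        if (ch_end[id] == 1L) KIND_POLY_PLUS_FREE else KIND_POLY_MINUS_FREE
    } else if (kind == KIND_DIFFUSION) {
      do_diffuse(ch_comp[id], ch_spec[id])
    } else {                            # grid-mode depoly channels
      fired <- kind
      if (kind == KIND_DEPOLY_PLUS_FREE) {
        ids <- free_ids[elig[free_ids]]
        if (length(ids)) do_depoly(ids[sample.int(length(ids), 1L)], 1L)
      } else if (kind == KIND_DEPOLY_MINUS_FREE) {
        ids <- free_ids[elig[free_ids]]
        if (length(ids)) do_depoly(ids[sample.int(length(ids), 1L)], 2L)
      } else if (kind == KIND_DEPOLY_PLUS_ATT) {
        ids <- att_ids[elig[att_ids]]
        if (length(ids)) do_depoly(ids[sample.int(length(ids), 1L)], 1L)
      }
    }
    n_fired <- n_fired + 1L
    n_events[fired] <- n_events[fired] + 1L
    if (track_events) { ev_t <- c(ev_t, e$t); ev_k <- c(ev_k, fired) }
    nrm_redraw(e, id)
  }

  # ---- write back --------------------------------------------------------
  keep <- which(b_active[seq_len(n_b)])
  mot <- keep[b_type[keep] == 1L]
  lin <- keep[b_type[keep] == 2L]
  state$filaments <- fils
  state$pools <- c(actin = NG, linker = NL, motor = NM)
  state$motors <- data.frame(f1 = b_f1[mot], c1 = b_c1[mot], s1 = b_s1[mot],
                             f2 = b_f2[mot], c2 = b_c2[mot], s2 = b_s2[mot],
                             rest = b_rest[mot])
  state$linkers <- data.frame(f1 = b_f1[lin], c1 = b_c1[lin], s1 = b_s1[lin],
                              f2 = b_f2[lin], c2 = b_c2[lin], s2 = b_s2[lin],
                              rest = b_rest[lin])
  state$t <- t_end
  if (grid_mode) {
    state$grid$counts[, , , 1] <- gA
    state$grid$counts[, , , 2] <- gL
    state$grid$counts[, , , 3] <- gM
  }
  attr(state, "n_events") <- setNames(n_events, kind_names)
  if (track_events)
    attr(state, "events") <- data.frame(time = ev_t, kind = kind_names[ev_k])
  state
}
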