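# Energy model and minimizer. Spot values follow directly from the
# printed mechanical constants; gradients are checked against central
# finite differences of the scalar energy.

test_that("per-term energy spot values are exact", {
  p <- default_parameters(n_free = 1L, n_attached = 0L)

  # straight interior filament at rest length: all terms zero
  st <- state_from_beads(list(straight_fil(c(1500, 1500, 1200), 3)))
  e <- total_energy(st)
  expect_equal(e$total, 0, tolerance = 1e-12)

  # one full cylinder stretched by 1 nm: 0.5 * 100 * 1^2 = 50 pN nm
  st <- state_from_beads(list(rbind(c(1500, 1500, 1200),
                                    c(1500, 1500, 1309))))
  e <- total_energy(st)
  expect_equal(unname(e$terms["stretch"]), 50)

  # two cylinders at a right angle sharing a bead: k_b (1 - cos 90) = 672.5
  st <- state_from_beads(list(rbind(c(1500, 1500, 1200),
                                    c(1500, 1500, 1308),
                                    c(1500, 1608, 1308))))
  e <- total_energy(st)
  expect_equal(unname(e$terms["bend"]), 672.5)
  expect_equal(unname(e$terms["stretch"]), 0, tolerance = 1e-9)

  # single bead at one screening length from a wall: 41 * exp(-1)
  st <- state_from_beads(list(rbind(c(1500, 1500, 2.7),
                                    c(1500, 1500, 110.7))),
                         nmono_list = list(40L))
  e <- total_energy(st)
  expect_equal(unname(e$terms["boundary"]), 41 * exp(-1), tolerance = 1e-6)
})

test_that("analytic forces match finite differences on random states", {
  worst <- 0
  for (seed in 1:25) {
    st <- random_small_state(seed)
    topo <- actopull:::build_topology(st)
    eg <- actopull:::energy_grad_topo(topo, st)
    h <- 1e-5
    for (trial in 1:8) {
      i <- sample(nrow(topo$X), 1)
      k <- sample(3, 1)
      t2 <- topo
      t2$X[i, k] <- t2$X[i, k] + h
      ep <- actopull:::energy_grad_topo(t2, st, want_grad = FALSE)$total
      t2$X[i, k] <- t2$X[i, k] - 2 * h
      em <- actopull:::energy_grad_topo(t2, st, want_grad = FALSE)$total
      fd <- (ep - em) / (2 * h)
      denom <- max(1, abs(fd))
      worst <- max(worst, abs(fd - eg$grad[i, k]) / denom)
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("stretched cylinder end-bead force is k_s * dl", {
  st <- state_from_beads(list(rbind(c(1500, 1500, 1200),
                                    c(1500, 1500, 1309))))
  F <- net_forces(st)
  expect_equal(abs(F[2, 3]), 100, tolerance = 1e-9)
  expect_equal(F[1, 3], -F[2, 3], tolerance = 1e-9)
})

test_that("energy is invariant under rigid-body moves of an interior network", {
  st <- random_small_state(11)
  e0 <- total_energy(st)$total
  # translation
  st_t <- st
  for (i in seq_along(st_t$filaments))
    st_t$filaments[[i]]$beads <- st_t$filaments[[i]]$beads +
      matrix(c(37, -22, 15), nrow(st_t$filaments[[i]]$beads), 3, byrow = TRUE)
  expect_equal(total_energy(st_t)$total, e0, tolerance = 1e-9 * max(1, e0))
  # rotation about the box center
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ctr <- st$box / 2
  st_r <- st
  for (i in seq_along(st_r$filaments))
    st_r$filaments[[i]]$beads <-
      sweep(sweep(st_r$filaments[[i]]$beads, 2, ctr) %*% t(R), 2, ctr, "+")
  expect_equal(total_energy(st_r)$total, e0, tolerance = 1e-9 * max(1, e0))
})

test_that("minimize is a descent method and is idempotent at a minimum", {
  for (seed in 1:5) {
    st <- random_small_state(seed + 100)
    e0 <- total_energy(st)$total
    st1 <- minimize_network(st, force_tol = 0.5)
    e1 <- attr(st1, "energy")
    expect_lte(e1, e0 + 1e-9)
    # idempotence: re-minimizing an equilibrated state changes nothing
    st2 <- minimize_network(st1, force_tol = 0.5)
    expect_equal(attr(st2, "iterations"), 0L)
    expect_equal(attr(st2, "energy"), e1, tolerance = 1e-12)
  }
})

test_that("a bent filament relaxes and an over-stretched linker approaches rest", {
  # two-cylinder filament bent to 90 degrees, free ends
  st <- state_from_beads(list(rbind(c(1500, 1500, 1200),
                                    c(1500, 1500, 1308),
                                    c(1500, 1608, 1308))))
  st1 <- minimize_network(st, force_tol = 0.1)
  b <- st1$filaments[[1]]$beads
  u <- b[2, ] - b[1, ]
  v <- b[3, ] - b[2, ]
  cosphi <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  expect_gt(cosphi, 0.9)     # bend angle far below the initial 90 degrees
  expect_lt(attr(st1, "energy"), total_energy(st)$total)

  # two parallel filaments joined by a linker stretched far past rest
  beads <- list(straight_fil(c(1400, 1500, 1200), 2),
                straight_fil(c(1500, 1500, 1200), 2))
  st <- state_from_beads(beads)
  st$linkers <- data.frame(f1 = 1L, c1 = 1L, s1 = 2L,
                           f2 = 2L, c2 = 1L, s2 = 2L, rest = 35)
  len0 <- actopull:::bond_tensions(st, "linker") / st$params$linker_k + 35
  st1 <- minimize_network(st, force_tol = 0.1)
  len1 <- actopull:::bond_tensions(st1, "linker") / st1$params$linker_k + 35
  expect_lt(abs(len1 - 35), abs(len0 - 35))

  # oracle: greedy coordinate descent on the same instance agrees on the
  # direction of relaxation
  oracle <- st
  for (sweep_i in 1:50) {
    for (i in seq_along(oracle$filaments)) {
      b <- oracle$filaments[[i]]$beads
      for (r in seq_len(nrow(b))) for (k in 1:3) {
        for (step in c(2, -2, 0.5, -0.5)) {
          cand <- oracle
          cand$filaments[[i]]$beads[r, k] <- b[r, k] + step
          if (total_energy(cand)$total < total_energy(oracle)$total)
            oracle <- cand
        }
      }
    }
  }
  len_or <- actopull:::bond_tensions(oracle, "linker") /
    oracle$params$linker_k + 35
  expect_lt(abs(len_or - 35), abs(len0 - 35))
  # both routes end below the starting energy
  expect_lt(total_energy(oracle)$total, total_energy(st)$total)
})

test_that("excluded volume grows without bound as cylinders approach overlap", {
  sep <- c(50, 20, 10, 5, 2, 1)
  e <- vapply(sep, function(d) {
    st <- state_from_beads(list(
      straight_fil(c(1500, 1500, 1200), 1, axis = c(1, 0, 0)),
      straight_fil(c(1500, 1500 + d, 1200), 1, axis = c(0, 1, 0))))
    unname(total_energy(st)$terms["excluded_volume"])
  }, numeric(1))
  expect_true(all(diff(e) > 0))
  expect_gt(e[length(e)] / e[1], 1e4)
})
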