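# Rate laws, the next-reaction scheduler, and the reaction dynamics.

test_that("force-dependent rate laws reproduce the printed base rates and forms", {
  # zero load returns the base rate for every law (continuity at F = 0)
  expect_equal(mechanochemical_rate(0.3, 0, "slip", 17.2), 0.3)
  expect_equal(mechanochemical_rate(0.2, 0, "catch", 126), 0.2)
  expect_equal(mechanochemical_rate(0.2, 0, "stall", 15), 0.2)
  expect_equal(mechanochemical_rate(0.151, 0, "ratchet", 1.5), 0.151)
  expect_equal(mechanochemical_rate(5, 99, "constant"), 5)
  # characteristic-force evaluations
  expect_equal(mechanochemical_rate(0.3, 17.2, "slip", 17.2), 0.3 * exp(1))
  expect_equal(mechanochemical_rate(7, 15, "stall", 15), 0)
  expect_equal(mechanochemical_rate(0.151, 1.5, "ratchet", 1.5),
               0.151 * exp(-1))
  # guards
  expect_error(mechanochemical_rate(1, -1, "slip", 10), "magnitude")
  expect_error(mechanochemical_rate(-1, 0, "slip", 10), "base rate")
  expect_error(mechanochemical_rate(1, 1, "slip", 0), "characteristic")
})

test_that("candidate pairs respect species rest-length ranges and exclusions", {
  two_parallel <- function(gap) {
    state_from_beads(list(straight_fil(c(1500, 1500, 1200), 1),
                          straight_fil(c(1500 + gap, 1500, 1200), 1)))
  }
  st <- two_parallel(35)
  expect_gt(nrow(candidate_binding_pairs(st, "linker")), 0)
  expect_equal(nrow(candidate_binding_pairs(st, "motor")), 0)
  st <- two_parallel(200)
  expect_equal(nrow(candidate_binding_pairs(st, "linker")), 0)
  expect_gt(nrow(candidate_binding_pairs(st, "motor")), 0)
  # single filament: same/adjacent-cylinder exclusion leaves nothing in range
  st1 <- state_from_beads(list(straight_fil(c(1500, 1500, 1100), 2)))
  expect_equal(nrow(candidate_binding_pairs(st1, "linker")), 0)
  expect_equal(nrow(candidate_binding_pairs(st1, "motor")), 0)
  # occupied sites are excluded
  st <- two_parallel(35)
  cand <- candidate_binding_pairs(st, "linker")
  st$linkers <- cand[1, c("f1", "c1", "s1", "f2", "c2", "s2")]
  st$linkers$rest <- 35
  cand2 <- candidate_binding_pairs(st, "linker")
  expect_lt(nrow(cand2), nrow(cand))
})

test_that("single-channel waiting times are exponential", {
  set.seed(1)
  # constant-propensity birth reaction, a = 2/s
  out <- nrm_mass_action(x0 = 0, reactants = matrix(0, 1, 1),
                         change = matrix(1, 1, 1), k = 2,
                         t_end = 5000, max_events = 1e4)
  waits <- diff(c(0, out$times))
  expect_equal(mean(waits), 0.5, tolerance = 0.05)
  ks <- suppressWarnings(ks.test(waits, "pexp", rate = 2))
  expect_gt(ks$p.value, 0.001)
})

test_that("competing channels fire in proportion to their propensities", {
  set.seed(2)
  # two constant-rate channels a1 = 3, a2 = 1
  out <- nrm_mass_action(x0 = 0, reactants = matrix(0, 1, 2),
                         change = matrix(c(1, 1), 1, 2), k = c(3, 1),
                         t_end = 1e5, max_events = 1e4)
  frac <- out$counts[1] / sum(out$counts)
  se <- sqrt(0.75 * 0.25 / sum(out$counts))
  expect_lt(abs(frac - 0.75), 4 * se)
})

test_that("next reaction method matches the direct SSA on a 3-reaction network", {
  # A -> B, B -> A, A + B -> 2B over a fixed horizon
  reactants <- matrix(c(1, 0, 0,
                        0, 1, 0,
                        1, 1, 0), nrow = 3)
  change <- matrix(c(-1, 1, 0,
                     1, -1, 0,
                     -1, 1, 0), nrow = 3)
  k <- c(1, 0.7, 0.002)
  x0 <- c(80, 40, 0)
  set.seed(3)
  a <- nrm_mass_action(x0, reactants, change, k, t_end = 2,
                       max_events = 2e4)
  b <- ssa_direct(x0, reactants, change, k, t_end = 2, max_events = 2e4)
  # event-count marginals agree (three proportion comparisons)
  ta <- sum(a$counts)
  tb <- sum(b$counts)
  expect_gt(ta, 100)
  for (j in 1:3) {
    pa <- a$counts[j] / ta
    pb <- b$counts[j] / tb
    se <- sqrt(pa * (1 - pa) / ta + pb * (1 - pb) / tb)
    expect_lt(abs(pa - pb), 5 * max(se, 1e-3))
  }
  # repeated-run mean of final A agrees between the two algorithms
  fa <- replicate(40, nrm_mass_action(x0, reactants, change, k, 2)$state[1])
  fb <- replicate(40, ssa_direct(x0, reactants, change, k, 2)$state[1])
  expect_lt(abs(mean(fa) - mean(fb)),
            4 * sqrt(var(fa) / 40 + var(fb) / 40) + 1e-9)
})

test_that("zero total propensity yields no event", {
  out <- nrm_mass_action(x0 = c(5), reactants = matrix(1, 1, 1),
                         change = matrix(-1, 1, 1), k = 0, t_end = 10)
  expect_equal(sum(out$counts), 0)
  # network state with nothing possible: short ineligible filament, empty pools
  st <- state_from_beads(list(rbind(c(1500, 1500, 1200),
                                    c(1500, 1500, 1208.1))),
                         nmono_list = list(3L))
  expect_null(next_reaction(st))
})

test_that("species are conserved exactly across chemistry", {
  set.seed(4)
  p <- desk_small_parameters(actin_conc = 3)
  st <- init_network(p, seed = 5)
  st <- actopull:::release_species(st)
  tot_actin <- unname(actin_census(st)["total"])
  tot_link <- unname(st$pools["linker"])
  tot_mot <- unname(st$pools["motor"])
  for (rep in 1:4) {
    st <- advance_chemistry(st, 1)
    st <- minimize_network(st)
    expect_equal(unname(actin_census(st)["total"]), tot_actin)
    expect_equal(unname(st$pools["linker"]) + nrow(st$linkers), tot_link)
    expect_equal(unname(st$pools["motor"]) + nrow(st$motors), tot_mot)
  }
  expect_gt(nrow(st$motors) + nrow(st$linkers), 0)
})

test_that("well-mixed treadmilling follows the mean-field kinetics", {
  # dG/dt = -(k+p + k+m) c_hat G n_f + (k-p + k-m) n_f with the
  # compartment-rate convention c_hat = (0.5 um)^3 / V_box
  set.seed(6)
  p <- default_parameters(n_free = 20L, n_attached = 0L,
                          motor_conc = 0, linker_conc = 0,
                          box_x = 3000, box_y = 3000, box_z = 3000)
  # 20 short seeds near the box center: tips never reach the walls, so
  # the mean-field ODE applies without ratchet corrections
  beads <- lapply(1:20, function(i) {
    ctr <- c(1500, 1500, 1500) + runif(3, -300, 300)
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    rbind(ctr - 54 * u, ctr + 54 * u, deparse.level = 0)
  })
  st <- state_from_beads(beads, params = p, box = c(3000, 3000, 3000))
  st$pools["actin"] <- 3265
  conv <- p$compartment_size^3 / prod(st$box)
  nf <- 20
  lam <- (p$poly_plus + p$poly_minus) * conv * nf
  inflow <- (p$depoly_plus + p$depoly_minus) * nf
  g_inf <- inflow / lam
  g0 <- unname(st$pools["actin"])
  ode_g <- function(t) g_inf + (g0 - g_inf) * exp(-lam * t)
  gs <- c()
  for (tt in 1:3) {
    st <- advance_chemistry(st, 50)
    gs <- c(gs, unname(st$pools["actin"]))
  }
  expect_equal(gs[1], ode_g(50), tolerance = 0.1)
  # by t = 150 (2.3 relaxation times) the pool is near the balance point
  expect_equal(gs[3], ode_g(150), tolerance = 0.1)
  expect_equal(gs[3], g_inf, tolerance = 0.15)
  # filaments stayed clear of the walls
  X <- do.call(rbind, lapply(st$filaments, `[[`, "beads"))
  expect_true(all(X > 200 & X < 2800))
})

test_that("an isolated relaxed linker unbinds at the zero-load rate", {
  set.seed(8)
  mk <- function() {
    p <- default_parameters(n_free = 1L, n_attached = 0L,
                            poly_plus = 0, poly_minus = 0,
                            depoly_plus = 0, depoly_minus = 0,
                            motor_bind = 0, linker_bind = 0)
    st <- state_from_beads(list(straight_fil(c(1465, 1500, 1200), 2),
                                straight_fil(c(1500, 1500, 1200), 2)),
                           params = p)
    cand <- candidate_binding_pairs(st, "linker")
    r <- 1
    st$linkers <- cand[r, c("f1", "c1", "s1", "f2", "c2", "s2")]
    st$linkers$rest <- cand$dist[r]      # bound at rest: zero load
    st
  }
  st0 <- mk()
  waits <- replicate(250, {
    st <- advance_chemistry(st0, 40, max_events = 1L, track_events = TRUE)
    ev <- attr(st, "events")
    if (nrow(ev) == 1 && ev$kind == "linker_unbind") ev$time else NA_real_
  })
  waits <- waits[!is.na(waits)]
  expect_gt(length(waits), 200)
  expect_equal(mean(waits), 1 / 0.3, tolerance = 0.2)
  ks <- suppressWarnings(ks.test(waits, "pexp", rate = 0.3))
  expect_gt(ks$p.value, 0.001)
})

test_that("motor walking steps toward the plus end and stalls under load", {
  set.seed(9)
  p <- default_parameters(n_free = 1L, n_attached = 0L,
                          poly_plus = 0, poly_minus = 0,
                          depoly_plus = 0, depoly_minus = 0,
                          motor_bind = 0, linker_bind = 0,
                          motor_unbind0 = 0, motor_walk_rate0 = 5)
  st <- state_from_beads(list(straight_fil(c(1300, 1500, 1200), 3),
                              straight_fil(c(1500, 1500, 1200), 3)),
                         params = p)
  cand <- candidate_binding_pairs(st, "motor")
  expect_gt(nrow(cand), 0)
  st$motors <- cand[1, c("f1", "c1", "s1", "f2", "c2", "s2")]
  st$motors$rest <- cand$dist[1]
  pos0 <- c(st$motors$c1, st$motors$s1, st$motors$c2, st$motors$s2)
  st2 <- advance_chemistry(st, 5)
  pos1 <- c(st2$motors$c1, st2$motors$s1, st2$motors$c2, st2$motors$s2)
  # site index (cylinder, site) advanced on at least one side
  adv1 <- pos1[1] * 4 + pos1[2] - (pos0[1] * 4 + pos0[2])
  adv2 <- pos1[3] * 4 + pos1[4] - (pos0[3] * 4 + pos0[4])
  expect_gte(adv1, 0)
  expect_gte(adv2, 0)
  expect_gt(adv1 + adv2, 0)
})

test_that("zero G-actin with depolymerization disabled freezes lengths", {
  p <- default_parameters(n_free = 1L, n_attached = 0L,
                          depoly_plus = 0, depoly_minus = 0,
                          motor_bind = 0, linker_bind = 0)
  st <- state_from_beads(list(straight_fil(c(1500, 1500, 1100), 2)),
                         params = p)
  st2 <- advance_chemistry(st, 10)
  expect_identical(vapply(st2$filaments, actopull:::fil_monomers, 1),
                   vapply(st$filaments, actopull:::fil_monomers, 1))
})

test_that("grid-mode diffusion equilibrates to uniform occupancy", {
  set.seed(10)
  p <- default_parameters(n_free = 1L, n_attached = 0L, well_mixed = FALSE,
                          box_x = 1500, box_y = 1500, box_z = 1000,
                          poly_plus = 0, poly_minus = 0,
                          depoly_plus = 0, depoly_minus = 0,
                          motor_bind = 0, linker_bind = 0,
                          actin_conc = 0.5, motor_conc = 0, linker_conc = 0)
  st <- init_network(p, seed = 10)
  # concentrate every G-actin copy in one corner compartment
  n <- sum(st$grid$counts[, , , 1])
  st$grid$counts[, , , 1] <- 0L
  st$grid$counts[1, 1, 1, 1] <- n
  st <- advance_chemistry(st, 0.5)
  counts <- as.vector(st$grid$counts[, , , 1])
  expect_equal(sum(counts), n)
  chi <- chisq.test(counts)
  expect_gt(chi$p.value, 1e-4)
})
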