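# Pulling schedules, probe displacement, and the simulation loop.

test_that("make_schedule encodes the four loading cases", {
  s1 <- make_schedule("i")
  expect_equal(s1$times, c(150, 300, 450, 600, 750))
  expect_equal(s1$steps, rep(500, 5))
  expect_equal(s1$duration, 900)
  expect_false(s1$boundary_only)
  # case i final top-boundary height: 1250 + 5 x 500
  expect_equal(1250 + sum(s1$steps), 3750)

  s2 <- make_schedule("ii")
  expect_equal(s2$steps, c(250, 250, 250, 500, 500))

  s3 <- make_schedule("iii")
  expect_equal(sum(s3$steps), 1250)

  s4 <- make_schedule("iv")
  expect_true(s4$boundary_only)
  expect_equal(s4$steps, s1$steps)   # boundary follows the case i profile

  expect_error(make_schedule("v"))
  expect_error(make_schedule("i", n_events = -1), "n_events")
})

test_that("apply_pull raises probe and boundary in sub-steps without chemistry", {
  p <- desk_small_parameters(n_free = 6L, n_attached = 2L)
  st <- init_network(p, seed = 2)
  st <- minimize_network(st)
  cen0 <- actin_census(st)
  z0 <- st$box[3]
  pz0 <- st$probe$center[3]

  # d = 0: clock only
  st0 <- apply_pull(st, 0)
  expect_equal(st0$t, st$t + 1)
  expect_equal(st0$box, st$box)

  st1 <- apply_pull(st, 250)
  expect_equal(st1$box[3], z0 + 250, tolerance = 1e-9)
  expect_equal(st1$probe$center[3], pz0 + 250, tolerance = 1e-9)
  expect_equal(st1$t, st$t + 1)
  expect_identical(actin_census(st1), cen0)      # no chemistry during pull
  expect_identical(nrow(st1$motors), nrow(st$motors))
  # anchored minus ends follow the probe upward
  att <- which(vapply(st1$filaments, `[[`, TRUE, "attached"))
  dz <- vapply(att, function(i) st1$filaments[[i]]$beads[1, 3] -
                 st$filaments[[i]]$beads[1, 3], numeric(1))
  expect_true(all(dz > 200))
  expect_error(apply_pull(st, -5), ">= 0")
})

test_that("release_probe frees anchored filaments once and warns after", {
  p <- desk_small_parameters(n_free = 4L, n_attached = 3L)
  st <- init_network(p, seed = 3)
  expect_equal(sum(vapply(st$filaments, `[[`, TRUE, "attached")), 3)
  st1 <- release_probe(st)
  expect_equal(sum(vapply(st1$filaments, `[[`, TRUE, "attached")), 0)
  expect_false(is.null(st1$probe))     # probe stays as a passive obstacle
  expect_warning(st2 <- release_probe(st1), "nothing released")
  expect_equal(sum(vapply(st2$filaments, `[[`, TRUE, "attached")), 0)
})

test_that("a zero-duration schedule yields only the initial snapshot", {
  p <- desk_small_parameters(n_free = 4L, n_attached = 0L)
  sch <- make_schedule("iv", n_events = 0L, tail_time = 0)
  traj <- run_simulation(p, sch, seed = 4)
  expect_length(traj$snapshots, 1)
  expect_equal(traj$times, 0)
})

test_that("simulation clock is reconstructible from the schedule", {
  p <- desk_small_parameters(n_free = 6L, n_attached = 2L, actin_conc = 3)
  sch <- make_schedule("i", interval = 10, n_events = 2, tail_time = 10)
  traj <- run_simulation(p, sch, seed = 5)
  expect_equal(sch$duration, 30)
  expect_equal(max(traj$times), 30)
  # pre- and post-pull snapshots at t_event and t_event + 1
  expect_true(all(c(10, 11, 20, 21) %in% round(traj$times, 6)))
  expect_true(!is.unsorted(traj$times))
  # during each pull the boundary rose by the step size
  snp_pre <- traj$snapshots[[which(traj$times == 10)[1]]]
  snp_post <- traj$snapshots[[which(traj$times == 11)[1]]]
  expect_equal(snp_post$box[3] - snp_pre$box[3], 500, tolerance = 1e-9)
  # chemistry events are zero during the pull: F-actin unchanged
  f_pre <- sum(vapply(snp_pre$filaments, function(f) sum(f$nmono), 1))
  f_post <- sum(vapply(snp_post$filaments, function(f) sum(f$nmono), 1))
  expect_equal(f_pre, f_post)
})

test_that("probe release during a run frees filaments and the network relaxes", {
  p <- desk_small_parameters(n_free = 6L, n_attached = 2L, actin_conc = 3)
  sch <- make_schedule("i", interval = 5, n_events = 1, tail_time = 15,
                       release_probe_at = 10)
  traj <- run_simulation(p, sch, seed = 6)
  last <- traj$snapshots[[length(traj$snapshots)]]
  expect_equal(sum(vapply(last$filaments, `[[`, TRUE, "attached")), 0)
  first <- traj$snapshots[[1]]
  expect_equal(sum(vapply(first$filaments, `[[`, TRUE, "attached")), 2)
})
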