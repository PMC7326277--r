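# Geometry metrics. Closed-form cases are asserted exactly; sampling
# cases against their analytic limits.

test_that("alignment index hits the closed-form extremes and values", {
  expect_equal(alignment_index(cbind(0, 0, runif(50, 1, 5))), 1)
  xy <- cbind(rnorm(50), rnorm(50), 0)
  expect_equal(alignment_index(xy), 0)
  expect_equal(alignment_index(matrix(c(1, 1, sqrt(2)), 1)), sqrt(2) / 2)
  # polarity reversal leaves the unsigned index unchanged
  segs <- matrix(rnorm(300), ncol = 3)
  expect_equal(alignment_index(segs), alignment_index(-segs))
  expect_error(alignment_index(matrix(0, 1, 3)), "zero-length")
  expect_error(alignment_index(matrix(numeric(0), 0, 3)), "at least one")
})

test_that("uniformly random orientations average to one half", {
  set.seed(20)
  u <- matrix(rnorm(15000), ncol = 3)
  expect_equal(alignment_index(u), 0.5, tolerance = 0.02)
})

test_that("alignment is invariant to translation and rotation about Z", {
  set.seed(21)
  snp <- generate_fixture("isotropic", 60, seed = 21)
  a0 <- alignment_index(snp)
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  snp2 <- snp
  for (i in seq_along(snp2$filaments))
    snp2$filaments[[i]]$beads <-
      snp2$filaments[[i]]$beads %*% t(R) + 100
  expect_equal(alignment_index(snp2), a0, tolerance = 1e-12)
})

test_that("trace alignment uses two-level averaging over 10-point pairs", {
  z21 <- cbind(0, 0, seq(0, 5, length.out = 21))
  x21 <- cbind(seq(0, 5, length.out = 21), 0, 0)
  expect_equal(trace_alignment_index(list(z21)), 1)
  expect_equal(trace_alignment_index(list(x21)), 0)
  # one trace along Z (per-trace mean 1), one along X (0): unweighted 0.5,
  # even if the X trace is much longer
  x81 <- cbind(seq(0, 20, length.out = 81), 0, 0)
  expect_equal(trace_alignment_index(list(z21, x81)), 0.5)
  # traces at or below the pairing spacing are skipped; all-short errors
  expect_error(trace_alignment_index(list(z21[1:10, ])), "no pairs")
  # data.frame input path
  df <- data.frame(trace_id = rep(1:2, each = 21),
                   point_index = rep(1:21, 2),
                   x_um = c(z21[, 1], x21[, 1]),
                   y_um = c(z21[, 2], x21[, 2]),
                   z_um = c(z21[, 3], x21[, 3]))
  expect_equal(trace_alignment_index(df), 0.5)
})

test_that("polarity alignment is signed and spans [-1, 1]", {
  up <- snapshot_from_beads(list(straight_fil(c(100, 100, 100), 2)))
  expect_equal(polarity_alignment_distribution(up)[1], 1)
  down <- snapshot_from_beads(list(straight_fil(c(100, 100, 400), 2,
                                                axis = c(0, 0, -1))))
  expect_equal(polarity_alignment_distribution(down)[1], -1)
  set.seed(22)
  iso <- generate_fixture("isotropic", 400, seed = 22)
  v <- polarity_alignment_distribution(iso)
  expect_true(all(v >= -1 & v <= 1))
  expect_equal(mean(v), 0, tolerance = 0.1)
  expect_gt(max(v), 0.8)
  expect_lt(min(v), -0.8)
})

test_that("bundle fraction is the in-cylinder F-actin share and complements to one", {
  # all beads on the probe axis
  ax <- snapshot_from_beads(list(straight_fil(c(1500, 1500, 100), 3)))
  expect_equal(bundle_fraction(ax), 1)
  # far corner filament
  off <- snapshot_from_beads(list(straight_fil(c(200, 200, 100), 3)))
  expect_equal(bundle_fraction(off), 0)
  # monomers spread uniformly over the 3 x 3 um cross-section: area ratio
  set.seed(23)
  n <- 6000
  beads <- lapply(seq_len(n), function(i) {
    xy <- runif(2, 0, 3000)
    rbind(c(xy, 500), c(xy, 502.7))
  })
  snp <- snapshot_from_beads(beads, nmono_list = rep(list(1L), n))
  p_hat <- bundle_fraction(snp)
  p_true <- pi * 0.25^2 / 9
  expect_equal(p_hat, p_true, tolerance = 0.2)
  expect_lt(abs(p_hat - p_true), 4 * sqrt(p_true * (1 - p_true) / n))
})

test_that("recruitment rate recovers exact and noisy linear slopes", {
  tt <- seq(0, 199, by = 1)
  const <- data.frame(time = tt, value = rep(3, length(tt)))
  rr <- recruitment_rate(const, window = 50)
  expect_equal(rr$slope, rep(0, 4))
  expect_equal(rr$time, c(25, 75, 125, 175))
  lin <- data.frame(time = tt, value = 2 + 0.31 * tt)
  expect_equal(recruitment_rate(lin, 50)$slope, rep(0.31, 4))
  # line + gaussian noise: slopes within the analytic OLS 4-sigma band
  set.seed(24)
  sigma <- 0.5
  noisy <- data.frame(time = tt, value = 2 + 0.31 * tt +
                        rnorm(length(tt), 0, sigma))
  sl <- recruitment_rate(noisy, 50)$slope
  t50 <- 0:49
  se <- sigma / sqrt(sum((t50 - mean(t50))^2))
  expect_true(all(abs(sl - 0.31) < 4 * se))
})

test_that("radius of gyration matches closed forms and its rate is a finite difference", {
  one <- snapshot_from_beads(list(rbind(c(0, 0, 0), c(0, 0, 2.7))),
                             nmono_list = list(1L))
  expect_equal(radius_of_gyration(one), 0, tolerance = 1e-9)
  # two equal masses at z = 0 and z = 2 (single 2-monomer cylinder
  # interpolates monomers at z = 0.5 and 1.5 -> Rg = 0.5)
  two <- snapshot_from_beads(list(rbind(c(0, 0, 0), c(0, 0, 2))),
                             nmono_list = list(2L))
  expect_equal(radius_of_gyration(two), 0.5)
  # 8 unit masses at unit-cube corners: Rg = sqrt(3)/2
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  beads <- lapply(seq_len(8), function(i)
    rbind(corners[i, ] - c(0, 0, 0.5), corners[i, ] + c(0, 0, 0.5)))
  snp <- snapshot_from_beads(beads, nmono_list = rep(list(1L), 8))
  expect_equal(radius_of_gyration(snp), sqrt(3) / 2)
  rg <- data.frame(time = c(0, 2, 4), value = c(10, 8, 7))
  rr <- rg_rate(rg)
  expect_equal(rr$rate, c(-1, -0.5))
  expect_equal(rr$time, c(1, 3))
  expect_error(rg_rate(data.frame(time = c(2, 1), value = 1:2)), "increasing")
})

test_that("z and radial distributions have the stated moments", {
  at_z <- function(zs) snapshot_from_beads(
    lapply(zs, function(z) rbind(c(1500, 1500, z - 1.35),
                                 c(1500, 1500, z + 1.35))),
    nmono_list = rep(list(1L), length(zs)))
  expect_equal(z_distribution(at_z(rep(300, 5)))$sigma, 0, tolerance = 1e-9)
  expect_equal(z_distribution(at_z(c(0, 100)))$sigma, 50)
  set.seed(25)
  H <- 1000
  zd <- z_distribution(at_z(runif(4000, 0, H)), bin = 25)
  expect_equal(zd$sigma, H / sqrt(12), tolerance = 0.05)
  expect_equal(sum(zd$density), 1)
  rd <- radial_distribution(at_z(rep(300, 4)), bin = 50)
  expect_equal(sum(rd$density), 1)
  expect_error(z_distribution(at_z(100), bin = 0), "bin")
})
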