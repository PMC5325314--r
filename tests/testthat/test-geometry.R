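test_that("icosphere bead shells have the expected structure", {
  for (lvl in 0:2) {
    g <- build_enzyme(core_radius = 1.5, subdivision_level = lvl)
    expect_equal(nrow(g$centers), 10 * 4^lvl + 2)
    radii <- sqrt(rowSums(g$centers^2))
    expect_lt(max(abs(radii - 1.5)), 1e-9)
  }
  g1 <- build_enzyme()
  # active site sits on the +z axis
  act <- g1$centers[g1$active_site, ]
  expect_equal(act, c(0, 0, 1.5), tolerance = 1e-9)
  # nearest-neighbour spacing at level 1 on a 1.5 nm core: the two edge
  # classes of the once-subdivided icosahedron, 0.526 R and 0.547 R
  d <- as.matrix(dist(g1$centers)); diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_gt(min(nn), 0.75)
  expect_lt(max(nn), 0.85)
})

test_that("the enzyme-enzyme complex keeps the active site collinear and exposed", {
  g <- build_enzyme()
  cx <- build_complex(g, separation = 1.4)
  act <- cx$centers[cx$active_site, ]
  c1 <- cx$core_centers[1, ]; c2 <- cx$core_centers[2, ]
  expect_equal(sqrt(sum((c1 - c2)^2)), 1.4, tolerance = 1e-9)
  expect_equal(sqrt(sum((act - c1)^2)), 1.5, tolerance = 1e-9)
  expect_equal(sqrt(sum((act - c2)^2)), 2.9, tolerance = 1e-9)
  # collinear: active site, both centers on one line
  v1 <- act - c1; v2 <- c2 - c1
  cross <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
             v1[1] * v2[2] - v1[2] * v2[1])
  expect_lt(sqrt(sum(cross^2)), 1e-9)
  # merged spheres swallow some beads
  expect_lt(nrow(cx$centers), 2 * nrow(g$centers))
  # a wide separation removes nothing and doubles the count
  far <- build_complex(g, separation = 2 * (1.5 + 0.37) + 0.1)
  expect_equal(nrow(far$centers), 2 * nrow(g$centers))
})

test_that("the repulsive bead potential and force are consistent", {
  g <- build_enzyme()
  sigma <- 0.37 + 0.4
  # beyond the cutoff everything vanishes
  far <- lj_energy_force(c(0, 0, 10), g)
  expect_equal(far$U, 0)
  expect_equal(far$F, c(0, 0, 0))

  # single bead at r = sigma: the 12-6 term is exactly zero, leaving the
  # WCA offset epsilon; at the cutoff the energy vanishes exactly
  g1 <- enzyme_geometry(matrix(0, 1, 3), 0.37, 0.37, 1)
  eps <- 0.3
  u <- lj_energy_force(c(sigma, 0, 0), g1, eps_lj = eps)
  expect_equal(u$U, eps, tolerance = 1e-12)
  u_cut <- lj_energy_force(c(2^(1 / 6) * sigma * (1 + 1e-9), 0, 0), g1,
                           eps_lj = eps)
  expect_equal(u_cut$U, 0)

  # central finite differences reproduce the force at random positions
  set.seed(41)
  h <- 1e-6
  for (i in 1:25) {
    pos <- rnorm(3); pos <- pos / sqrt(sum(pos^2)) * runif(1, 1.9, 2.3)
    ana <- lj_energy_force(pos, g, eps_lj = 0.2)
    num <- vapply(1:3, function(k) {
      e <- numeric(3); e[k] <- h
      (lj_energy_force(pos - e, g, eps_lj = 0.2)$U -
         lj_energy_force(pos + e, g, eps_lj = 0.2)$U) / (2 * h)
    }, numeric(1))
    scale <- max(sqrt(sum(ana$F^2)), 1e-8)
    expect_lt(max(abs(ana$F - num)) / scale, 1e-6)
  }

  # compiled and reference implementations agree bitwise-closely
  for (i in 1:10) {
    pos <- rnorm(3); pos <- pos / sqrt(sum(pos^2)) * runif(1, 1.9, 2.3)
    a <- lj_energy_force(pos, g, eps_lj = 0.15)
    b <- chankin:::.lj_cpp(pos, g$centers, g$bead_radius, 0.4, 0.15)
    expect_equal(a$U, b$U, tolerance = 1e-12)
    expect_equal(a$F, b$F, tolerance = 1e-12)
  }
})
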