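test_that("classical Euclidean distance matches brute-force summation", {
  expect_identical(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean_distance(c(1, 0), c(0, 1)), sqrt(2), tolerance = 1e-12)
  for (seed in 1:5) {
    x <- with_seed_test(seed, stats::rnorm(8))
    y <- with_seed_test(seed + 10, stats::rnorm(8))
    acc <- 0
    for (i in 1:8) acc <- acc + (x[i] - y[i])^2
    expect_equal(euclidean_distance(x, y), sqrt(acc), tolerance = 1e-12)
  }
  expect_error(euclidean_distance(1:2, 1:3), "length mismatch")
})

test_that("amplitude embedding keeps the norm and builds a unit state", {
  v <- c(3, 0, 4, 0)
  emb <- amplitude_embed(v)
  expect_equal(emb$norm, 5)
  expect_equal(emb$unit, v / 5, tolerance = 1e-12)
  expect_equal(sum(emb$unit^2), 1, tolerance = 1e-12)
  expect_null(amplitude_embed(c(0, 0))$unit)
  expect_error(amplitude_embed(c(1, 2, 3)), "power of two")
})

test_that("the magnitude qubit and data register have the stated forms", {
  A <- amplitude_embed(c(3, 0)); B <- amplitude_embed(c(0, 4))
  phi <- build_phi(A, B)
  expect_equal(phi$Z, 25)
  expect_equal(phi$state, c(0.6, -0.8), tolerance = 1e-12)
  u <- amplitude_embed(c(1, 0))
  expect_equal(build_phi(u, amplitude_embed(c(0, 1)))$state, c(1, -1) / sqrt(2),
               tolerance = 1e-12)
  z <- amplitude_embed(c(0, 0))
  expect_equal(build_phi(u, z)$state, c(1, 0))
  expect_equal(build_phi(u, z)$Z, 1)
  expect_error(build_phi(z, z), "zero norm")

  # psi: ancilla last; A = B factorizes as A (x) (|0>+|1>)/sqrt(2)
  psi_same <- build_psi(u, u)
  expect_equal(psi_same, as.vector(kronecker(c(1, 0), c(1, 1) / sqrt(2))),
               tolerance = 1e-12)
  for (seed in 1:5) {
    a <- amplitude_embed(with_seed_test(seed, stats::rnorm(4)))
    b <- amplitude_embed(with_seed_test(seed + 9, stats::rnorm(4)))
    expect_equal(sum(build_psi(a, b)^2), 1, tolerance = 1e-12)
  }
  expect_error(build_psi(u, amplitude_embed(c(1, 0, 0, 0))), "dimension mismatch")
})

test_that("the SWAP-test control statistic matches its closed form", {
  u1 <- amplitude_embed(c(1, 0)); u2 <- amplitude_embed(c(0, 1))
  expect_equal(swap_test_p0(build_psi(u1, u1), build_phi(u1, u1)$state), 0.5,
               tolerance = 1e-12)
  expect_equal(swap_test_p0(build_psi(u1, u2), build_phi(u1, u2)$state), 0.75,
               tolerance = 1e-12)
  # p0 = 1/2 + 1/2 ||<phi|psi>||^2, contracting psi's ancilla against phi
  for (seed in 1:10) {
    A <- amplitude_embed(with_seed_test(seed, stats::rnorm(4)))
    B <- amplitude_embed(with_seed_test(seed + 30, stats::rnorm(4)))
    phi <- build_phi(A, B)
    psi <- build_psi(A, B)
    contracted <- psi[c(TRUE, FALSE)] * phi$state[1L] +
      psi[c(FALSE, TRUE)] * phi$state[2L]
    p0 <- swap_test_p0(psi, phi$state)
    expect_equal(p0, 0.5 + 0.5 * sum(contracted^2), tolerance = 1e-12)
    expect_gte(p0, 0.5)
    expect_lte(p0, 1)
  }
})

test_that("distance inversion handles the boundary and clamps shot noise", {
  expect_identical(as.numeric(distance_from_p0(0.5, 2)), 0)
  expect_equal(as.numeric(distance_from_p0(0.75, 2)), sqrt(2), tolerance = 1e-12)
  expect_equal(as.numeric(distance_from_p0(1, 2)), 2, tolerance = 1e-12)
  d <- distance_from_p0(0.4999, 2)
  expect_identical(as.numeric(d), 0)
  expect_true(isTRUE(attr(d, "clamped")))
})

test_that("exact quantum distance equals the classical oracle across dimensions", {
  for (dim in c(2L, 4L, 16L)) {
    for (i in 1:50) {
      x <- with_seed_test(1000L * dim + i, stats::rnorm(dim))
      y <- with_seed_test(2000L * dim + i, stats::rnorm(dim))
      expect_equal(quantum_distance(x, y), euclidean_distance(x, y),
                   tolerance = 1e-9)
    }
  }
})

test_that("quantum distance is symmetric and zero on identical inputs", {
  for (seed in 1:10) {
    x <- with_seed_test(seed, stats::rnorm(8))
    y <- with_seed_test(seed + 77, stats::rnorm(8))
    expect_equal(quantum_distance(x, y), quantum_distance(y, x), tolerance = 1e-12)
    expect_equal(quantum_distance(x, x), 0, tolerance = 1e-7)
  }
})

test_that("sampled distances fall within propagated error bounds", {
  shots <- 10000L
  ok <- 0L
  n_trials <- 200L
  for (t in seq_len(n_trials)) {
    x <- with_seed_test(t, stats::rnorm(4))
    y <- with_seed_test(t + 500, stats::rnorm(4))
    D <- euclidean_distance(x, y)
    A <- amplitude_embed(x); B <- amplitude_embed(y)
    phi <- build_phi(A, B)
    p0 <- 0.5 + D^2 / (4 * phi$Z)
    sigma_p0 <- sqrt(p0 * (1 - p0) / shots)
    sigma_D <- 2 * phi$Z * sigma_p0 / max(D, 1e-6)
    Dhat <- quantum_distance(x, y, backend = "sampling", shots = shots, seed = t)
    if (abs(Dhat - D) <= 5 * sigma_D) ok <- ok + 1L
  }
  expect_gte(ok / n_trials, 0.99)
})

test_that("candidate ranking orders by distance with deterministic ties", {
  rg <- unit_ranges()
  lig <- molecule_chain(h = c(0.9, 0.55), hb = c(0.8, 0.6), role = "ligand")
  prot <- random_chain(12, rg, seed = 21)
  prot <- plant_site(prot, lig, offset = 2, mode = "exact-continuous", ranges = rg)
  prot <- plant_site(prot, lig, offset = 8, mode = "exact-binary", ranges = rg,
                     jitter = 0.02, seed = 5)
  pos <- scan_matches(prot, lig, rg)
  expect_true(all(c(2L, 8L) %in% pos))
  ranked <- rank_candidates(lig, pos, prot, rg)
  expect_identical(ranked$start_offset[1L], 2L)
  expect_lt(ranked$distance[1L], 1e-6)
  expect_gt(ranked$distance[ranked$start_offset == 8L], 0)
  expect_identical(ranked$rank, seq_len(nrow(ranked)))
  expect_true(!is.unsorted(ranked$distance))
  # permutation invariance
  ranked2 <- rank_candidates(lig, rev(pos), prot, rg)
  expect_identical(ranked, ranked2)
  # empty candidate set
  expect_identical(nrow(rank_candidates(lig, integer(0), prot, rg)), 0L)
})

test_that("sampled ranking reports per-candidate confidence intervals", {
  rg <- unit_ranges()
  lig <- molecule_chain(h = c(0.9, 0.2), hb = c(0.7, 0.1), role = "ligand")
  prot <- random_chain(10, rg, seed = 33)
  prot <- plant_site(prot, lig, offset = 4, mode = "exact-binary", ranges = rg,
                     jitter = 0.03, seed = 3)
  pos <- scan_matches(prot, lig, rg)
  ctl <- dock_control(backend = "sampling", shots = 5000, seed = 11)
  ranked <- rank_candidates(lig, pos, prot, rg, ctl)
  expect_true(all(c("distance_lo", "distance_hi") %in% names(ranked)))
  expect_true(all(ranked$distance_lo <= ranked$distance + 1e-12))
  expect_true(all(ranked$distance_hi >= ranked$distance - 1e-12))
  expect_identical(ranked, rank_candidates(lig, pos, prot, rg, ctl))
})
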