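test_that("oracle and diffusion reflections are unitary, Hermitian and self-inverse", {
  for (spec in list(list(n = 2, N = 2, seed = 1), list(n = 3, N = 3, seed = 2),
                    list(n = 3, N = 6, seed = 3))) {
    basis <- random_labels(spec$N, spec$n, seed = spec$seed)
    s <- build_superposition(basis)
    O <- oracle_matrix(basis[1L], spec$n)
    G <- diffusion_matrix(s)
    for (M in list(O, G)) {
      expect_equal(M, t(M), tolerance = 1e-12)                 # Hermitian (real)
      expect_equal(M %*% t(M), diag(nrow(M)), tolerance = 1e-12) # unitary
      expect_equal(M %*% M, diag(nrow(M)), tolerance = 1e-12)    # self-inverse
    }
    # eigenvector actions
    v <- superposition_vector(s)
    expect_equal(as.numeric(G %*% v), v, tolerance = 1e-12)
    w <- with_seed_test(spec$seed, stats::rnorm(2^spec$n))
    w <- w - sum(w * v) * v
    expect_equal(as.numeric(G %*% w), -w, tolerance = 1e-12)
    e_t <- numeric(2^spec$n); e_t[label_to_index_test(basis[1L]) + 1L] <- 1
    expect_equal(as.numeric(O %*% e_t), -e_t, tolerance = 1e-12)
    e_o <- numeric(2^spec$n); e_o[1L] <- 1
    if (basis[1L] != strrep("0", spec$n)) {
      expect_equal(as.numeric(O %*% e_o), e_o, tolerance = 1e-12)
    }
    r <- with_seed_test(spec$seed + 10, stats::rnorm(2^spec$n))
    expect_equal(as.numeric(O %*% (O %*% r)), r, tolerance = 1e-12)
  }
  expect_error(oracle_matrix("101", 2), "qubits")
})

test_that("the iteration policy stays below sqrt(N) at the single-item optimum", {
  expect_identical(choose_iterations(6), 1L)
  expect_identical(choose_iterations(3), 1L)
  expect_identical(choose_iterations(2), 1L)
  expect_identical(choose_iterations(100), 7L)
  for (N in 2:64) {
    k <- choose_iterations(N)
    expect_identical(k, max(1L, as.integer(floor(pi / 4 * sqrt(N)))))
    if (N >= 4) expect_lt(k, sqrt(N))
  }
  expect_error(choose_iterations(1), "deterministic")
})

test_that("exact Grover probabilities follow the closed form for an in-set target", {
  for (N in 2:32) {
    width <- max(2L, ceiling(log2(N)))
    basis <- random_labels(N, width, seed = N)
    s <- build_superposition(basis)
    target <- basis[1L]
    theta <- asin(1 / sqrt(N))
    for (k in 1:5) {
      p <- measured_probability(run_grover(s, target, k), target)
      expect_equal(p, sin((2 * k + 1) * theta)^2, tolerance = 1e-10)
    }
  }
})

test_that("exact Grover agrees with an independent brute-force matrix oracle", {
  for (seed in 1:10) {
    N <- with_seed_test(seed, sample(2:12, 1))
    basis <- random_labels(N, 4, seed = seed + 50)
    s <- build_superposition(basis)
    target <- basis[1L]
    k <- choose_iterations(N)
    expect_equal(measured_probability(run_grover(s, target, k), target),
                 brute_grover_p(basis, target, k), tolerance = 1e-10)
  }
})

test_that("a target outside the subspace is never amplified", {
  basis <- c("1101", "1000", "1111")
  s <- build_superposition(basis)
  for (k in 1:3) {
    for (diff in c("matrix", "ancilla")) {
      p <- measured_probability(run_grover(s, "0000", k, diffusion = diff), "0000")
      expect_identical(p, 0)
    }
  }
})

test_that("matrix and ancilla diffusion paths give identical distributions", {
  for (seed in 1:12) {
    N <- with_seed_test(seed, sample(2:10, 1))
    width <- with_seed_test(seed + 20, sample(4:5, 1))
    basis <- random_labels(N, width, seed = seed + 40)
    s <- build_superposition(basis)
    target <- basis[with_seed_test(seed + 60, sample(N, 1))]
    k <- with_seed_test(seed + 80, sample(1:3, 1))
    m1 <- run_grover(s, target, k, diffusion = "matrix")
    m2 <- run_grover(s, target, k, diffusion = "ancilla")
    all_labels <- union(names(m1$outcome), names(m2$outcome))
    for (lab in all_labels) {
      expect_equal(measured_probability(m1, lab), measured_probability(m2, lab),
                   tolerance = 1e-10)
    }
  }
})

test_that("norm is preserved through every Grover iteration", {
  basis <- random_labels(6, 4, seed = 9)
  s <- build_superposition(basis)
  for (k in 1:5) {
    m <- run_grover(s, basis[2L], k)
    expect_equal(sum(m$outcome), 1, tolerance = 1e-10)
  }
})

test_that("sampled frequencies concentrate around the exact probability", {
  s <- build_superposition(c("0100", "1100", "1111", "0001", "1010", "0011"))
  p <- measured_probability(run_grover(s, "1100", 1), "1100")
  shots <- 10000L
  sigma <- sqrt(p * (1 - p) / shots)
  ok <- 0L
  n_trials <- 200L
  for (t in seq_len(n_trials)) {
    m <- run_grover(s, "1100", 1, backend = "sampling", shots = shots, seed = t)
    expect_identical(sum(m$outcome), shots)
    phat <- measured_probability(m, "1100")
    if (abs(phat - p) <= 5 * sigma) ok <- ok + 1L
  }
  expect_gte(ok / n_trials, 0.99)
  # fixed seed reproduces counts exactly
  m1 <- run_grover(s, "1100", 1, backend = "sampling", shots = 500, seed = 31)
  m2 <- run_grover(s, "1100", 1, backend = "sampling", shots = 500, seed = 31)
  expect_identical(m1$outcome, m2$outcome)
})

test_that("presence is decided by the 1/N threshold, inclusive at the two-state extreme", {
  s6 <- build_superposition(c("0100", "1100", "1111", "0001", "1010", "0011"))
  d6 <- decide_presence(run_grover(s6, "1100", 1), "1100", 6)
  expect_true(d6$present)
  expect_equal(d6$p_target, 49 / 54, tolerance = 1e-10)
  expect_equal(d6$threshold, 1 / 6)

  d_absent <- decide_presence(run_grover(s6, "0000", 1), "0000", 6)
  expect_false(d_absent$present)
  expect_identical(d_absent$p_target, 0)

  # two-state subspace: a present target sits at exactly p = 1/2 = 1/N and
  # must still be detected; an absent one stays at 0
  s2 <- build_superposition(c("01", "10"))
  d2 <- decide_presence(run_grover(s2, "01", 1), "01", 2)
  expect_equal(d2$p_target, 0.5, tolerance = 1e-12)
  expect_true(d2$present)
  expect_false(decide_presence(run_grover(s2, "11", 1), "11", 2)$present)
  expect_error(decide_presence(run_grover(s2, "01", 1), "01", 1), ">= 2")
})

test_that("the register capacity guard rejects oversized searches", {
  basis <- random_labels(3, 6, seed = 5)
  s <- build_superposition(basis)
  expect_error(run_grover(s, basis[1L], 1, qubit_budget = 5), "capacity")
  expect_error(run_grover(s, basis[1L], 1, diffusion = "ancilla", qubit_budget = 6),
               "capacity")
})
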