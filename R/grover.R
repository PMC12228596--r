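#' Dense statevector of a subspace superposition
#'
#' Expands a [build_superposition()] object into the full `2^n` real
#' statevector over the canonical big-endian basis (leftmost bit of a label
#' is the most significant).
#'
#' @param s A `"superposition"`.
#' @return Numeric vector of length `2^n_qubits`, unit norm.
#' @export
superposition_vector <- function(s) {
  stopifnot(inherits(s, "superposition"))
  v <- numeric(2^s$n_qubits)
  v[vapply(s$basis, label_to_index, numeric(1L)) + 1L] <- s$amplitude
  v
}

#' Oracle reflection about the target basis state
#'
#' The explicit unitary `I - 2|x><x|`: it flips the sign of the target basis
#' amplitude and fixes every other basis state. Hermitian, self-inverse.
#'
#' @param target Bitstring of the marked basis state.
#' @param n_qubits Register width; must equal `nchar(target)`.
#' @return A `2^n x 2^n` numeric matrix.
#' @export
oracle_matrix <- function(target, n_qubits) {
  assert_bitstring(target, "target")
  if (nchar(target) != n_qubits) {
    stop(sprintf("target has %d bits, register has %d qubits",
                 nchar(target), n_qubits), call. = FALSE)
  }
  d <- 2^n_qubits
  O <- diag(d)
  i <- label_to_index(target) + 1L
  O[i, i] <- -1
  O
}

#' Diffusion reflection about the initial superposition
#'
#' The explicit unitary `2|s><s| - I`: it fixes the superposition state and
#' negates every vector orthogonal to it. Hermitian, self-inverse.
#'
#' @param s A `"superposition"`.
#' @return A `2^n x 2^n` numeric matrix.
#' @export
diffusion_matrix <- function(s) {
  v <- superposition_vector(s)
  2 * tcrossprod(v) - diag(length(v))
}

#' Grover iteration count for a subspace of N basis states
#'
#' The search needs fewer than `sqrt(N)` iterations; the single-marked-item
#' optimum `floor(pi/4 * sqrt(N))` is used, floored at one iteration (for
#' N of 2 or 3 the optimum rounds to zero but at least one oracle call is
#' needed to amplify).
#'
#' @param N Number of basis states in the superposition, `N >= 2`.
#' @return Integer iteration count `k >= 1`.
#' @examples
#' choose_iterations(6)   # 1
#' choose_iterations(100) # 7
#' @export
choose_iterations <- function(N) {
  N <- as.integer(N)
  if (is.na(N) || N < 2L) {
    stop("choose_iterations: N must be >= 2 (N = 1 is the deterministic path)",
         call. = FALSE)
  }
  max(1L, as.integer(floor(pi / 4 * sqrt(N))))
}

# Wrap a probability vector over 2^n basis states as a measurement
# distribution: exact probabilities, or seeded multinomial counts.
measure_statevector <- function(probs, n_qubits, backend, shots, seed) {
  keep <- which(probs > .Machine$double.eps)
  labels <- vapply(keep - 1L, index_to_label, character(1L), n = n_qubits)
  if (backend == "exact") {
    structure(list(outcome = stats::setNames(probs[keep], labels),
                   shots = "exact", seed = NULL, n_qubits = n_qubits),
              class = "measurement")
  } else {
    stopifnot(is.numeric(shots), shots >= 1L)
    counts <- with_seed(seed, as.vector(stats::rmultinom(1L, size = as.integer(shots),
                                                         prob = probs[keep])))
    structure(list(outcome = stats::setNames(counts, labels),
                   shots = as.integer(shots), seed = seed, n_qubits = n_qubits),
              class = "measurement")
  }
}

#' @export
print.measurement <- function(x, ...) {
  kind <- if (identical(x$shots, "exact")) "exact probabilities"
          else sprintf("%d shots", x$shots)
  cat(sprintf("<measurement over %d qubits (%s)>\n", x$n_qubits, kind))
  print(sort(x$outcome, decreasing = TRUE))
  invisible(x)
}

#' Probability of one outcome in a measurement distribution
#'
#' @param dist A `"measurement"` from [run_grover()] or friends.
#' @param label Outcome bitstring.
#' @return Estimated probability (exact probability, or count / shots).
#' @export
measured_probability <- function(dist, label) {
  stopifnot(inherits(dist, "measurement"))
  assert_bitstring(label, "label")
  x <- dist$outcome[label]
  p <- if (is.na(x)) 0 else unname(x)
  if (identical(dist$shots, "exact")) p else p / dist$shots
}

#' Run the subspace Grover search
#'
#' Prepares the non-uniform superposition over the distinct window labels,
#' applies `k` Grover iterations (oracle reflection about the ligand label,
#' then diffusion reflection about the initial superposition) and measures
#' the register. Two interchangeable diffusion implementations are provided:
#' `"matrix"` applies the explicit unitary `2|s><s| - I`; `"ancilla"` runs
#' the amplitude-amplification form on one extra qubit, building the
#' reflection from the state-preparation unitary and a zero-controlled phase
#' kickback. Both yield the same register distribution (up to a global
#' phase).
#'
#' @param s A `"superposition"` over `N >= 1` basis states.
#' @param target Bitstring of the marked (ligand) basis state, same width as
#'   the superposition labels.
#' @param k Number of Grover iterations (>= 1); see [choose_iterations()].
#' @param backend `"exact"` (statevector probabilities) or `"sampling"`
#'   (seeded finite-shot counts).
#' @param shots Shot count for the sampling backend.
#' @param seed Seed for the sampling backend (`NULL` uses the current RNG
#'   stream).
#' @param diffusion `"matrix"` or `"ancilla"`.
#' @param qubit_budget Capacity guard on the register width.
#' @return A `"measurement"` distribution over the search register.
#' @examples
#' s <- build_superposition(c("1101", "1000", "1111"))
#' run_grover(s, "1111", k = 1) # p(1111) = 25/27
#' @export
run_grover <- function(s, target, k, backend = c("exact", "sampling"),
                       shots = 4096L, seed = NULL,
                       diffusion = c("matrix", "ancilla"),
                       qubit_budget = 12L) {
  backend <- match.arg(backend)
  diffusion <- match.arg(diffusion)
  stopifnot(inherits(s, "superposition"), k >= 1L)
  assert_bitstring(target, "target")
  n <- s$n_qubits
  if (nchar(target) != n) {
    stop(sprintf("target has %d bits, superposition has %d qubits",
                 nchar(target), n), call. = FALSE)
  }
  if (n + (diffusion == "ancilla") > qubit_budget) {
    stop(sprintf("capacity: search needs %d qubits, budget is %d",
                 n + (diffusion == "ancilla"), qubit_budget), call. = FALSE)
  }
  probs <- if (diffusion == "matrix") {
    grover_probs_matrix(s, target, k)
  } else {
    grover_probs_ancilla(s, target, k)
  }
  measure_statevector(probs, n, backend, shots, seed)
}

#' @rdname run_grover
#' @export
run_grover_ancilla <- function(s, target, k, backend = c("exact", "sampling"),
                               shots = 4096L, seed = NULL, qubit_budget = 12L) {
  run_grover(s, target, k, backend = match.arg(backend), shots = shots,
             seed = seed, diffusion = "ancilla", qubit_budget = qubit_budget)
}

# Explicit-unitary route: dense oracle and diffusion matrices applied to the
# full statevector.
grover_probs_matrix <- function(s, target, k) {
  v <- superposition_vector(s)
  O <- oracle_matrix(target, s$n_qubits)
  G <- diffusion_matrix(s)
  for (i in seq_len(k)) v <- as.vector(G %*% (O %*% v))
  v^2
}

# Amplitude-amplification route on n + 1 qubits. The diffusion is built as
# A (I - 2|0..0><0..0|) A^T with A the state-preparation unitary (Householder
# reflection taking |0..0> to |s>); the zero-state phase flip is realized by
# phase kickback off an ancilla prepared in |->: an X on the ancilla,
# controlled on the register being all-zero. Register marginals match the
# matrix route; the global phase (-1)^k is unobservable.
grover_probs_ancilla <- function(s, target, k) {
  n <- s$n_qubits
  d <- 2^n
  sv <- superposition_vector(s)
  A <- prep_unitary(sv)
  # M[a + 1, r + 1]: amplitude of register index r with ancilla bit a
  M <- outer(c(1, -1) / sqrt(2), sv)
  t_idx <- label_to_index(target) + 1L
  for (i in seq_len(k)) {
    M[, t_idx] <- -M[, t_idx]      # oracle phase flip on the register
    M <- M %*% A                   # A^T on the register (A is orthogonal)
    M[, 1L] <- M[2:1, 1L]          # X on ancilla, controlled on register |0..0>
    M <- M %*% t(A)                # A on the register
  }
  colSums(M^2)                     # trace out the ancilla
}

# Real orthogonal state-preparation unitary: first column equals `v` (unit
# vector). Householder reflection mapping e1 to v; identity when v == e1.
prep_unitary <- function(v) {
  d <- length(v)
  e1 <- c(1, numeric(d - 1L))
  w <- e1 - v
  nw2 <- sum(w^2)
  if (nw2 < 1e-24) return(diag(d))
  diag(d) - 2 * tcrossprod(w) / nw2
}

#' Decide whether the target is present from a measurement
#'
#' Applies the `1/N` presence threshold: the target label is declared present
#' when its estimated probability reaches `1/N`, where `N` is the number of
#' basis states in the searched superposition. The threshold derives from the
#' two-state extreme: with `N = 2` a present target sits at exactly
#' `p = 1/2 = 1/N` after one iteration (no amplification is possible in a
#' two-dimensional subspace), so the boundary is inclusive — a present target
#' at the extreme must still be detected. An absent target has `p = 0` on the
#' exact backend, far below any threshold.
#'
#' @param dist A `"measurement"`.
#' @param target Target bitstring.
#' @param N Number of basis states in the searched superposition (>= 2).
#' @return An object of class `"presence_decision"`: list with `target`,
#'   `p_target`, `threshold`, `present`, `shots`.
#' @export
decide_presence <- function(dist, target, N) {
  N <- as.integer(N)
  if (is.na(N) || N < 2L) {
    stop("decide_presence: N must be >= 2 (a single-state subspace is compared directly)",
         call. = FALSE)
  }
  p <- measured_probability(dist, target)
  thr <- 1 / N
  structure(list(target = target, p_target = p, threshold = thr,
                 present = p >= thr - 1e-9, shots = dist$shots),
            class = "presence_decision")
}

#' @export
print.presence_decision <- function(x, ...) {
  cat(sprintf("<presence: |%s> p = %.6f %s threshold 1/N = %.6f -> %s>\n",
              x$target, x$p_target, if (x$present) ">=" else "<",
              x$threshold, if (x$present) "PRESENT" else "absent"))
  invisible(x)
}
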