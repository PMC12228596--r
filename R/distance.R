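#' Classical Euclidean distance
#'
#' Reference implementation of the distance the quantum pipeline estimates:
#' `sqrt(sum((X - Y)^2))`. Used as the validation oracle for the SWAP-test
#' route.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Non-negative numeric scalar.
#' @export
euclidean_distance <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) {
    stop(sprintf("length mismatch: %d vs %d", length(x), length(y)), call. = FALSE)
  }
  sqrt(sum((x - y)^2))
}

#' Amplitude embedding of a real vector
#'
#' Encodes a real vector as the amplitudes of a normalized quantum state,
#' keeping the original norm so distances on the raw vectors can be
#' recovered.
#'
#' @param raw Numeric vector; its length must be a power of two (pad with
#'   zeros beforehand if needed).
#' @return An object of class `"embedded_vector"`: list with `raw`, `norm`
#'   and `unit` (the unit statevector, or `NULL` for the zero vector).
#' @export
amplitude_embed <- function(raw) {
  stopifnot(is.numeric(raw), length(raw) >= 1L)
  n <- log2(length(raw))
  if (abs(n - round(n)) > 1e-9) {
    stop("amplitude_embed: vector length must be a power of two", call. = FALSE)
  }
  nrm <- sqrt(sum(raw^2))
  structure(list(raw = as.numeric(raw), norm = nrm,
                 unit = if (nrm > 0) raw / nrm else NULL),
            class = "embedded_vector")
}

#' Magnitude qubit for the SWAP-test distance
#'
#' The single-qubit state `(|A| |0> - |B| |1>) / sqrt(Z)` with
#' `Z = |A|^2 + |B|^2`, carrying the two vector magnitudes.
#'
#' @param A,B `"embedded_vector"` objects; at least one must have positive
#'   norm.
#' @return List with `state` (length-2 numeric) and `Z`.
#' @export
build_phi <- function(A, B) {
  stopifnot(inherits(A, "embedded_vector"), inherits(B, "embedded_vector"))
  Z <- A$norm^2 + B$norm^2
  if (Z <= 0) stop("build_phi: both input vectors have zero norm", call. = FALSE)
  list(state = c(A$norm, -B$norm) / sqrt(Z), Z = Z)
}

#' Entangled data register for the SWAP-test distance
#'
#' The `(n + 1)`-qubit state `(|A> (x) |0> + |B> (x) |1>) / sqrt(2)`, with
#' the ancilla as the last (least significant) qubit.
#'
#' @param A,B `"embedded_vector"` objects with unit states of equal length.
#' @return Numeric statevector over `n + 1` qubits.
#' @export
build_psi <- function(A, B) {
  stopifnot(inherits(A, "embedded_vector"), inherits(B, "embedded_vector"))
  if (is.null(A$unit) || is.null(B$unit)) {
    stop("build_psi: both inputs must have positive norm", call. = FALSE)
  }
  if (length(A$unit) != length(B$unit)) {
    stop(sprintf("dimension mismatch: %d vs %d", length(A$unit), length(B$unit)),
         call. = FALSE)
  }
  as.vector(kronecker(A$unit, c(1, 0)) + kronecker(B$unit, c(0, 1))) / sqrt(2)
}

#' SWAP test between the data register and the magnitude qubit
#'
#' Simulates the SWAP-test circuit: a control qubit in `|0>` gets a Hadamard,
#' then a controlled-SWAP exchanges the ancilla qubit of `psi` (its last
#' qubit) with the `phi` qubit, then a second Hadamard; `p0` is the
#' probability of measuring the control in `|0>`. On the exact backend
#' `p0 = 1/2 + 1/2 * || <phi|psi> ||^2`, contracting the ancilla of `psi`
#' against `phi`; the sampling backend returns the seeded empirical fraction
#' of 0-outcomes.
#'
#' @param psi Statevector from [build_psi()] (any `n + 1`-qubit real state).
#' @param phi Length-2 numeric state from [build_phi()].
#' @param backend `"exact"` or `"sampling"`.
#' @param shots Positive shot count (sampling backend).
#' @param seed Sampling seed.
#' @param qubit_budget Capacity guard on the total simulated register.
#' @return `p0` in `[0, 1]` (exact values lie in `[0.5, 1]`).
#' @export
swap_test_p0 <- function(psi, phi, backend = c("exact", "sampling"),
                         shots = 10000L, seed = NULL, qubit_budget = 16L) {
  backend <- match.arg(backend)
  stopifnot(is.numeric(psi), is.numeric(phi), length(phi) == 2L)
  npsi <- log2(length(psi))
  if (abs(npsi - round(npsi)) > 1e-9 || npsi < 1) {
    stop("swap_test_p0: psi length must be a power of two >= 2", call. = FALSE)
  }
  npsi <- as.integer(round(npsi))
  if (npsi + 2L > qubit_budget) {
    stop(sprintf("capacity: SWAP test needs %d qubits, budget is %d",
                 npsi + 2L, qubit_budget), call. = FALSE)
  }
  # Register layout (big-endian): control | psi qubits | phi qubit.
  rest <- as.vector(kronecker(psi, phi))                 # statevector without the control
  d <- length(rest)
  # Control starts in |0>; after the first Hadamard both control branches
  # carry rest / sqrt(2).
  h0 <- rest / sqrt(2)
  h1 <- h0
  # Controlled-SWAP of the last psi qubit (bit 1 of the rest index) with the
  # phi qubit (bit 0), acting on the control = 1 branch only.
  r <- seq_len(d) - 1L
  a <- bitwAnd(bitwShiftR(r, 1L), 1L)
  b <- bitwAnd(r, 1L)
  swapped <- bitwOr(bitwAnd(r, bitwNot(3L)), bitwOr(bitwShiftL(b, 1L), a)) + 1L
  h1 <- h1[swapped]
  # Second H on control; measure the control.
  f0 <- (h0 + h1) / sqrt(2)
  p0 <- sum(f0^2)
  p0 <- min(max(p0, 0), 1)
  if (backend == "exact") return(p0)
  stopifnot(shots >= 1L)
  with_seed(seed, stats::rbinom(1L, size = as.integer(shots), prob = p0)) /
    as.integer(shots)
}

#' Euclidean distance from the SWAP-test statistic
#'
#' Inverts the control-qubit statistic: `D = sqrt(4 * Z * (p0 - 0.5))`. A
#' sampled `p0` marginally below 0.5 (shot noise) is clamped to 0.5, giving
#' distance 0; the result then carries attribute `clamped = TRUE`.
#'
#' @param p0 Control-qubit 0-probability.
#' @param Z Magnitude normalizer `|A|^2 + |B|^2` from [build_phi()].
#' @return Non-negative distance (attribute `clamped` flags shot-noise
#'   clamping).
#' @export
distance_from_p0 <- function(p0, Z) {
  stopifnot(is.numeric(p0), length(p0) == 1L, is.numeric(Z), Z > 0)
  # exact-backend float jitter around 0.5 is not shot noise; only flag
  # deviations beyond numerical precision
  clamped <- p0 < 0.5 - 1e-12
  d <- sqrt(4 * Z * (max(p0, 0.5) - 0.5))
  if (clamped) attr(d, "clamped") <- TRUE
  d
}

#' Quantum Euclidean distance between two real vectors
#'
#' Full pipeline: amplitude-embed both vectors, build the entangled data
#' register and the magnitude qubit, run the SWAP test and invert the
#' statistic. On the exact backend this equals [euclidean_distance()] of the
#' raw vectors.
#'
#' @param x,y Numeric vectors of equal power-of-two length, not both zero.
#' @inheritParams swap_test_p0
#' @return Distance estimate (see [distance_from_p0()] for the shot-noise
#'   clamp).
#' @examples
#' quantum_distance(c(1, 0), c(0, 1)) # sqrt(2)
#' @export
quantum_distance <- function(x, y, backend = c("exact", "sampling"),
                             shots = 10000L, seed = NULL, qubit_budget = 16L) {
  backend <- match.arg(backend)
  A <- amplitude_embed(x)
  B <- amplitude_embed(y)
  if (A$norm == 0 || B$norm == 0) {
    # A zero vector has no unit state to entangle; the distance reduces to
    # the other vector's magnitude.
    return(max(A$norm, B$norm))
  }
  phi <- build_phi(A, B)
  psi <- build_psi(A, B)
  p0 <- swap_test_p0(psi, phi$state, backend = backend, shots = shots,
                     seed = seed, qubit_budget = qubit_budget)
  distance_from_p0(p0, phi$Z)
}

#' Rank candidate docking sites by quantum Euclidean distance
#'
#' Second-encodes the ligand and each candidate protein slice as amplitude
#' states, estimates the quantum Euclidean distance between the ligand state
#' and each candidate state with the SWAP test, and ranks candidates by
#' ascending distance (ties broken by ascending start offset). The site
#' closest to the ligand state ranks first: it is the best available docking
#' site.
#'
#' @param ligand,protein [molecule_chain()] objects.
#' @param positions Integer vector of 0-based candidate start offsets (as
#'   returned by [locate_docking_sites()]); every candidate slice must fit in
#'   the protein.
#' @param ranges An [interaction_ranges()].
#' @param control A [dock_control()]. With the sampling backend the result
#'   gains `p0`, `se` and 95% interval columns from binomial error
#'   propagation.
#' @return A data frame with columns `start_offset`, `label`, `p0`,
#'   `distance`, `clamped`, `rank` (plus `distance_lo`/`distance_hi` when
#'   sampling), sorted by rank.
#' @export
rank_candidates <- function(ligand, positions, protein, ranges,
                            control = dock_control()) {
  stopifnot(inherits(ligand, "molecule_chain"), inherits(protein, "molecule_chain"))
  L <- n_sites(ligand)
  positions <- as.integer(positions)
  if (length(positions) == 0L) {
    out <- data.frame(start_offset = integer(0), label = character(0),
                      p0 = numeric(0), distance = numeric(0),
                      clamped = logical(0), rank = integer(0))
    return(out)
  }
  lig_state <- encode_chain_amplitude(ligand, ranges,
                                      qubit_budget = control$qubit_budget)
  sampling <- control$backend == "sampling"
  rows <- lapply(seq_along(positions), function(i) {
    pos <- positions[i]
    slice <- chain_slice(protein, pos, L)
    cand_state <- encode_chain_amplitude(slice, ranges,
                                         qubit_budget = control$qubit_budget)
    A <- amplitude_embed(lig_state)
    B <- amplitude_embed(cand_state)
    phi <- build_phi(A, B)
    psi <- build_psi(A, B)
    p0 <- swap_test_p0(psi, phi$state, backend = control$backend,
                       shots = control$shots,
                       seed = derive_seed(control$seed, 10000L + i),
                       qubit_budget = control$qubit_budget)
    d <- distance_from_p0(p0, phi$Z)
    row <- data.frame(start_offset = pos,
                      label = encode_chain_binary(slice, ranges),
                      p0 = p0, distance = as.numeric(d),
                      clamped = isTRUE(attr(d, "clamped")),
                      stringsAsFactors = FALSE)
    if (sampling) {
      se_p0 <- sqrt(max(p0 * (1 - p0), 0) / control$shots)
      lo <- distance_from_p0(max(p0 - 1.96 * se_p0, 0), phi$Z)
      hi <- distance_from_p0(min(p0 + 1.96 * se_p0, 1), phi$Z)
      row$distance_lo <- as.numeric(lo)
      row$distance_hi <- as.numeric(hi)
    }
    row
  })
  out <- do.call(rbind, rows)
  ord <- order(out$distance, out$start_offset)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
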