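#' Control parameters for the docking search pipeline
#'
#' @param backend `"exact"` (statevector probabilities; the default for
#'   decisions and ranking) or `"sampling"` (seeded finite-shot emulation of
#'   a simulator run).
#' @param shots Shots per measurement on the sampling backend.
#' @param seed Master seed for the sampling backend; every measurement in a
#'   run derives its own child seed from it, so a full run is reproducible
#'   bit-for-bit. Ignored by the exact backend.
#' @param iterations `"auto"` ([choose_iterations()], the single-marked-item
#'   optimum) or a fixed positive integer.
#' @param diffusion Diffusion implementation: `"matrix"` (explicit unitary)
#'   or `"ancilla"` (amplitude amplification on one extra qubit).
#' @param qubit_budget Largest register the backends may allocate.
#' @return An object of class `"dock_control"`.
#' @export
dock_control <- function(backend = c("exact", "sampling"), shots = 4096L,
                         seed = NULL, iterations = "auto",
                         diffusion = c("matrix", "ancilla"),
                         qubit_budget = 12L) {
  backend <- match.arg(backend)
  diffusion <- match.arg(diffusion)
  if (backend == "sampling") {
    stopifnot(is.numeric(shots), length(shots) == 1L, shots >= 1L)
  }
  if (!identical(iterations, "auto")) {
    stopifnot(is.numeric(iterations), length(iterations) == 1L, iterations >= 1L)
    iterations <- as.integer(iterations)
  }
  stopifnot(is.numeric(qubit_budget), qubit_budget >= 2L)
  structure(list(backend = backend, shots = as.integer(shots), seed = seed,
                 iterations = iterations, diffusion = diffusion,
                 qubit_budget = as.integer(qubit_budget)),
            class = "dock_control")
}
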