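#' Threshold a continuous property value to one qubit (first encoding)
#'
#' The binary (search) encoding maps a property value to one bit at the
#' midpoint of its allowed range: values in `[min, mid)` map to 0 and values
#' in the closed upper interval `[mid, max]` map to 1, with
#' `mid = (min + max) / 2`. The midpoint itself belongs to the upper bin.
#'
#' @param value Numeric scalar within `range` (inclusive).
#' @param range A [property_range()].
#' @return Integer 0 or 1.
#' @examples
#' map_value_to_bit(0.2, property_range(0, 1)) # 0
#' map_value_to_bit(0.5, property_range(0, 1)) # 1: midpoint maps up
#' @export
map_value_to_bit <- function(value, range) {
  stopifnot(inherits(range, "property_range"), is.numeric(value), length(value) == 1L)
  if (value < range[1L] || value > range[2L]) {
    stop(sprintf("value %.6g outside range [%g, %g]", value, range[1L], range[2L]),
         call. = FALSE)
  }
  mid <- (range[1L] + range[2L]) / 2
  if (value < mid) 0L else 1L
}

#' Binary label of one interaction site
#'
#' Two bits per site: the left (first) bit is the thresholded hydrophobic
#' value, the right bit the thresholded hydrogen-bonding value.
#'
#' @param h,hb Numeric property values.
#' @param ranges An [interaction_ranges()].
#' @return A 2-character bitstring.
#' @export
encode_site_binary <- function(h, hb, ranges) {
  stopifnot(inherits(ranges, "interaction_ranges"))
  paste0(map_value_to_bit(h, ranges$h), map_value_to_bit(hb, ranges$hb))
}

#' Binary label of a whole chain (first encoding)
#'
#' Concatenates per-site two-bit labels in chain order; the first site
#' occupies the leftmost bits. The result names the computational basis state
#' used by the search stage.
#'
#' @param chain A [molecule_chain()].
#' @param ranges An [interaction_ranges()].
#' @return A bitstring of length `2 * n_sites(chain)`.
#' @examples
#' rg <- interaction_ranges()
#' lig <- molecule_chain(h = c(0.9, 0.1, 0.6), hb = c(0.7, 0.8, 0.2), role = "ligand")
#' encode_chain_binary(lig, rg) # "110110"
#' @export
encode_chain_binary <- function(chain, ranges) {
  stopifnot(inherits(chain, "molecule_chain"))
  validate_in_range(chain, ranges)
  bits <- vapply(seq_len(n_sites(chain)), function(i) {
    tryCatch(encode_site_binary(chain$h[i], chain$hb[i], ranges),
             error = function(e) stop(sprintf("site %d: %s", i - 1L, conditionMessage(e)),
                                      call. = FALSE))
  }, character(1L))
  paste(bits, collapse = "")
}

#' Amplitude pair of one property value (second encoding)
#'
#' Encodes a continuous value as a one-qubit superposition
#' \eqn{\alpha|0\rangle + \beta|1\rangle} whose amplitudes interpolate
#' linearly between the range endpoints:
#' \deqn{\alpha = \frac{max - v}{\sqrt{(max-v)^2 + (v-min)^2}}, \qquad
#'       \beta  = \frac{v - min}{\sqrt{(max-v)^2 + (v-min)^2}}.}
#' At the lower endpoint the state is \eqn{|0\rangle}, at the upper endpoint
#' \eqn{|1\rangle}, at the midpoint the balanced superposition. Amplitudes
#' are real and non-negative; \eqn{\beta} is strictly increasing in `value`.
#'
#' @param value Numeric scalar within `range` (inclusive).
#' @param range A [property_range()].
#' @return Numeric `c(alpha, beta)` with `alpha^2 + beta^2 == 1`.
#' @export
amplitude_pair <- function(value, range) {
  stopifnot(inherits(range, "property_range"), is.numeric(value), length(value) == 1L)
  if (value < range[1L] || value > range[2L]) {
    stop(sprintf("value %.6g outside range [%g, %g]", value, range[1L], range[2L]),
         call. = FALSE)
  }
  up <- range[[2L]] - value
  lo <- value - range[[1L]]
  unname(c(up, lo) / sqrt(up^2 + lo^2))
}

#' Amplitude state of one interaction site
#'
#' Tensor product of the two per-property one-qubit states: with hydrophobic
#' amplitudes `(a, b)` and hydrogen-bonding amplitudes `(c, d)` the site state
#' is `ac|00> + ad|01> + bc|10> + bd|11>` (hydrophobic qubit on the left).
#'
#' @inheritParams encode_site_binary
#' @return Numeric length-4 statevector in basis order `00, 01, 10, 11`.
#' @export
encode_site_amplitude <- function(h, hb, ranges) {
  stopifnot(inherits(ranges, "interaction_ranges"))
  ab <- amplitude_pair(h, ranges$h)
  cd <- amplitude_pair(hb, ranges$hb)
  as.vector(kronecker(ab, cd))
}

#' Amplitude statevector of a whole chain (second encoding)
#'
#' Tensor product of per-site amplitude states over `2 * n_sites(chain)`
#' qubits; the first site occupies the most significant (leftmost) bits of
#' the big-endian basis labels. The result is a unit vector used by the
#' SWAP-test distance stage.
#'
#' @param chain A [molecule_chain()].
#' @param ranges An [interaction_ranges()].
#' @param qubit_budget Maximum number of qubits the backend may allocate;
#'   chains needing more raise a capacity error.
#' @return Numeric statevector of length `4^n_sites(chain)`, unit norm.
#' @export
encode_chain_amplitude <- function(chain, ranges, qubit_budget = 16L) {
  stopifnot(inherits(chain, "molecule_chain"))
  validate_in_range(chain, ranges)
  n_qubits <- 2L * n_sites(chain)
  if (n_qubits > qubit_budget) {
    stop(sprintf("capacity: chain needs %d qubits, budget is %d",
                 n_qubits, qubit_budget), call. = FALSE)
  }
  state <- 1
  for (i in seq_len(n_sites(chain))) {
    state <- as.vector(kronecker(state, encode_site_amplitude(chain$h[i], chain$hb[i], ranges)))
  }
  state
}
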