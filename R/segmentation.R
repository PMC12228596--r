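#' Segment a protein label into ligand-sized windows
#'
#' Slices the binary label of a protein into consecutive, non-overlapping
#' windows of `2 * ligand_sites` bits from the left. A trailing remainder
#' shorter than one window is dropped (the lattice model has no partial
#' sites); callers that need to audit coverage read the dropped bit count
#' from the `"dropped_bits"` attribute.
#'
#' @param protein_label Bitstring from [encode_chain_binary()].
#' @param ligand_sites Number of interaction sites of the ligand (>= 1).
#' @return A data frame with class `"window_set"`: columns `start_site`
#'   (0-based site offset of the window within the labelled chain) and
#'   `label` (the window's bitstring).
#' @examples
#' segment_windows("1111110110001111", 2)
#' @export
segment_windows <- function(protein_label, ligand_sites) {
  assert_bitstring(protein_label, "protein_label")
  stopifnot(ligand_sites >= 1L)
  wbits <- 2L * as.integer(ligand_sites)
  nbits <- nchar(protein_label)
  n_win <- nbits %/% wbits
  if (n_win < 1L) {
    stop(sprintf("protein label (%d bits) shorter than one %d-bit window",
                 nbits, wbits), call. = FALSE)
  }
  starts <- (seq_len(n_win) - 1L) * wbits
  labels <- substring(protein_label, starts + 1L, starts + wbits)
  out <- data.frame(start_site = starts %/% 2L, label = labels,
                    stringsAsFactors = FALSE)
  attr(out, "dropped_bits") <- nbits - n_win * wbits
  class(out) <- c("window_set", class(out))
  out
}

#' Deduplicate window labels, keeping the latest occurrence
#'
#' A single occurrence answers the presence question, so only the last
#' occurrence of each duplicate label is kept; output order is the order of
#' those last occurrences.
#'
#' @param labels Character vector of equal-length bitstrings.
#' @return Character vector of distinct labels.
#' @examples
#' unique_latest(c("1111", "1101", "1000", "1111")) # 1101 1000 1111
#' @export
unique_latest <- function(labels) {
  stopifnot(is.character(labels), length(labels) >= 1L)
  rev(unique(rev(labels)))
}

#' Uniform superposition over distinct basis labels
#'
#' The search subspace state: each of the `N` distinct labels carries real
#' amplitude `1/sqrt(N)`.
#'
#' @param basis Character vector of distinct equal-length bitstrings.
#' @return An object of class `"superposition"`: list with `basis`,
#'   `amplitude` (`1/sqrt(N)`) and `n_qubits`.
#' @export
build_superposition <- function(basis) {
  stopifnot(is.character(basis), length(basis) >= 1L)
  lens <- unique(nchar(basis))
  if (length(lens) != 1L) stop("basis labels must have equal length", call. = FALSE)
  if (anyDuplicated(basis)) {
    stop("basis labels must be distinct (deduplicate with unique_latest first)",
         call. = FALSE)
  }
  for (b in basis) assert_bitstring(b, "basis label")
  structure(list(basis = basis, amplitude = 1 / sqrt(length(basis)),
                 n_qubits = lens),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition: %d basis state%s over %d qubits, amplitude 1/sqrt(%d)>\n",
              length(x$basis), if (length(x$basis) == 1L) "" else "s",
              x$n_qubits, length(x$basis)))
  cat(" ", paste(sprintf("|%s>", x$basis), collapse = " + "), "\n")
  invisible(x)
}

#' Shift a protein chain by dropping leading sites
#'
#' Realigns the window grid: the shifted chain starts at the original site
#' `offset`, so windows of the shifted chain cover start offsets congruent to
#' `offset` modulo the ligand size. Downstream results report positions
#' relative to the original protein by adding `offset` back.
#'
#' @param protein A [molecule_chain()].
#' @param offset Number of leading sites to drop (0-based; `0` is identity).
#' @return A [molecule_chain()].
#' @export
shift_chain <- function(protein, offset) {
  stopifnot(inherits(protein, "molecule_chain"))
  offset <- as.integer(offset)
  if (offset < 0L || offset >= n_sites(protein)) {
    stop(sprintf("shift offset %d outside chain of %d sites",
                 offset, n_sites(protein)), call. = FALSE)
  }
  if (offset == 0L) return(protein)
  chain_slice(protein, offset, n_sites(protein) - offset)
}

#' Bisect a range of windows
#'
#' Splits a window index range on a window boundary: the left part takes
#' `ceiling(w / 2)` windows, the right part the rest.
#'
#' @param lo,hi Inclusive 1-based window indices, `hi > lo`.
#' @return List with integer ranges `left = c(lo, mid)`,
#'   `right = c(mid + 1, hi)`.
#' @export
bisect_windows <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (hi <= lo) stop("bisect_windows: range must contain at least 2 windows",
                     call. = FALSE)
  mid <- lo + ((hi - lo + 1L + 1L) %/% 2L) - 1L  # ceiling-left rule
  list(left = c(lo, mid), right = c(mid + 1L, hi))
}

#' Localize candidate docking sites with the shift + bisection controller
#'
#' For each shift offset `0 ... L-1` (`L` = ligand site count) the protein is
#' shifted, binary-encoded and segmented into ligand-sized windows; the
#' controller then recursively narrows window ranges. At each range it builds
#' the unique-latest superposition over the range's window labels; a range
#' with a single distinct label is compared to the ligand label directly
#' (deterministic), otherwise a Grover presence test decides whether the
#' ligand label is in the range. A present single-window range emits that
#' window's start offset in the original protein; a present multi-window
#' range is bisected and both halves are searched; an absent range is pruned.
#'
#' @param protein,ligand [molecule_chain()] objects; the ligand must not be
#'   longer than the protein.
#' @param ranges An [interaction_ranges()].
#' @param control A [dock_control()] (backend, shots, seed, iteration policy,
#'   diffusion implementation, qubit budget).
#' @return List with `positions` (sorted distinct 0-based start offsets of
#'   windows whose label equals the ligand's), `ligand_label`, and `trace`
#'   (one row per decision: shift, window range, number of unique labels `N`,
#'   decision method, iterations `k`, measured target probability, threshold
#'   and outcome; plus one row per skipped shift or dropped remainder).
#' @export
locate_docking_sites <- function(protein, ligand, ranges,
                                 control = dock_control()) {
  stopifnot(inherits(protein, "molecule_chain"), inherits(ligand, "molecule_chain"))
  L <- n_sites(ligand)
  P <- n_sites(protein)
  if (L > P) stop("ligand has more sites than the protein", call. = FALSE)
  lig_label <- encode_chain_binary(ligand, ranges)

  trace <- list()
  found <- integer(0)
  n_calls <- 0L

  note <- function(shift, lo, hi, N, method, k, p, thr, decision) {
    trace[[length(trace) + 1L]] <<- data.frame(
      shift = shift, window_lo = lo, window_hi = hi, n_unique = N,
      method = method, iterations = k, p_target = p, threshold = thr,
      decision = decision, stringsAsFactors = FALSE)
  }

  for (offset in seq.int(0L, L - 1L)) {
    if (P - offset < L) {
      note(offset, NA, NA, NA, "skip", NA, NA, NA, "shifted chain shorter than one window")
      next
    }
    shifted <- shift_chain(protein, offset)
    plabel <- encode_chain_binary(shifted, ranges)
    ws <- segment_windows(plabel, L)
    if (attr(ws, "dropped_bits") > 0L) {
      note(offset, NA, NA, NA, "truncate", NA, NA, NA,
           sprintf("dropped %d-bit trailing remainder", attr(ws, "dropped_bits")))
    }

    search_range <- function(lo, hi) {
      basis <- unique_latest(ws$label[lo:hi])
      N <- length(basis)
      if (N == 1L) {
        present <- identical(basis, lig_label)
        note(offset, lo, hi, N, "deterministic", NA, NA, NA,
             if (present) "present" else "absent")
      } else {
        s <- build_superposition(basis)
        k <- if (identical(control$iterations, "auto")) choose_iterations(N)
             else as.integer(control$iterations)
        n_calls <<- n_calls + 1L
        dist <- run_grover(s, lig_label, k,
                           backend = control$backend, shots = control$shots,
                           seed = derive_seed(control$seed, n_calls),
                           diffusion = control$diffusion,
                           qubit_budget = control$qubit_budget)
        dec <- decide_presence(dist, lig_label, N)
        present <- dec$present
        note(offset, lo, hi, N, paste0("grover-", control$diffusion), k,
             dec$p_target, dec$threshold, if (present) "present" else "absent")
      }
      if (!present) return(invisible(NULL))
      if (lo == hi) {
        found <<- c(found, offset + (lo - 1L) * L)
      } else {
        halves <- bisect_windows(lo, hi)
        search_range(halves$left[1L], halves$left[2L])
        search_range(halves$right[1L], halves$right[2L])
      }
      invisible(NULL)
    }
    search_range(1L, nrow(ws))
  }

  list(positions = sort(unique(found)),
       ligand_label = lig_label,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(shift = integer(0), window_lo = integer(0),
                    window_hi = integer(0), n_unique = integer(0),
                    method = character(0), iterations = integer(0),
                    p_target = numeric(0), threshold = numeric(0),
                    decision = character(0)))
}
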