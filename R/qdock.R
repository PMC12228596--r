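#' Locate and rank protein-ligand docking sites
#'
#' The main entry point of the package: runs the full pipeline on a protein
#' and ligand given in interaction space. The protein is binary-encoded,
#' shifted and segmented into ligand-sized windows; a Grover search
#' restricted to the subspace of distinct window labels, driven by a
#' recursive bisection controller, localizes every window whose binary label
#' equals the ligand's; the located candidates are then amplitude-encoded
#' and ranked by the SWAP-test quantum Euclidean distance to the ligand
#' state, smallest distance first.
#'
#' @param protein,ligand [molecule_chain()] objects; the ligand must not
#'   have more sites than the protein.
#' @param ranges An [interaction_ranges()] giving the allowed value range of
#'   each interaction property.
#' @param control A [dock_control()].
#' @return An object of class `"qdock"`: list with
#'   \describe{
#'     \item{candidates}{data frame from [rank_candidates()] (one row per
#'       located site: `start_offset`, `label`, `p0`, `distance`, `rank`).}
#'     \item{positions}{0-based start offsets located by the search.}
#'     \item{ligand_label}{the ligand's binary label.}
#'     \item{trace}{per-decision search trace from [locate_docking_sites()].}
#'     \item{protein, ligand, ranges, control}{the inputs.}
#'   }
#' @examples
#' rg <- interaction_ranges()
#' lig <- molecule_chain(h = c(0.9, 0.8), hb = c(0.9, 0.1), role = "ligand")
#' prot <- random_chain(10, rg, seed = 7, role = "protein")
#' prot <- plant_site(prot, lig, offset = 4, mode = "exact-continuous", ranges = rg)
#' fit <- qdock(prot, lig, rg)
#' fit
#' @export
qdock <- function(protein, ligand, ranges = interaction_ranges(),
                  control = dock_control()) {
  stopifnot(inherits(control, "dock_control"))
  located <- locate_docking_sites(protein, ligand, ranges, control)
  candidates <- rank_candidates(ligand, located$positions, protein, ranges, control)
  structure(list(candidates = candidates,
                 positions = located$positions,
                 ligand_label = located$ligand_label,
                 trace = located$trace,
                 protein = protein, ligand = ligand,
                 ranges = ranges, control = control),
            class = "qdock")
}

#' @export
print.qdock <- function(x, ...) {
  cat(sprintf("Quantum docking-site search: %d-site protein, %d-site ligand (|%s>)\n",
              n_sites(x$protein), n_sites(x$ligand), x$ligand_label))
  cat(sprintf("Backend: %s%s, diffusion: %s\n", x$control$backend,
              if (x$control$backend == "sampling")
                sprintf(" (%d shots, seed %s)", x$control$shots,
                        if (is.null(x$control$seed)) "none" else x$control$seed)
              else "",
              x$control$diffusion))
  if (nrow(x$candidates) == 0L) {
    cat("No docking site found for this ligand.\n")
  } else {
    cat(sprintf("%d candidate docking site%s (ascending quantum Euclidean distance):\n",
                nrow(x$candidates), if (nrow(x$candidates) == 1L) "" else "s"))
    print(x$candidates, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.qdock <- function(object, ...) {
  tr <- object$trace
  grover_rows <- grepl("^grover", tr$method)
  out <- list(
    n_candidates = nrow(object$candidates),
    best = if (nrow(object$candidates)) object$candidates[1L, ] else NULL,
    n_grover_calls = sum(grover_rows),
    n_deterministic = sum(tr$method == "deterministic"),
    truncations = tr$decision[tr$method == "truncate"],
    clamped = if (nrow(object$candidates)) sum(object$candidates$clamped) else 0L,
    fit = object)
  class(out) <- "summary.qdock"
  out
}

#' @export
print.summary.qdock <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nSearch effort: %d Grover presence tests, %d deterministic comparisons\n",
              x$n_grover_calls, x$n_deterministic))
  if (length(x$truncations)) {
    cat("Uncovered trailing remainders:\n")
    for (t in x$truncations) cat("  -", t, "\n")
  }
  if (x$clamped > 0L) {
    cat(sprintf("%d candidate distance(s) clamped at zero due to shot noise\n", x$clamped))
  }
  invisible(x)
}

#' @export
as.data.frame.qdock <- function(x, ...) x$candidates

#' Plot ranked docking candidates
#'
#' Bar plot of the quantum Euclidean distance of each located candidate,
#' ordered by rank; the best (closest) site is leftmost. Sampled fits with
#' interval columns draw the 95% interval as error bars.
#'
#' @param x A `"qdock"` fit.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.qdock <- function(x, ...) {
  cand <- x$candidates
  if (nrow(cand) == 0L) {
    stop("no candidates to plot: the search found no docking site", call. = FALSE)
  }
  mids <- graphics::barplot(cand$distance,
                            names.arg = sprintf("@%d", cand$start_offset),
                            xlab = "candidate start offset (rank order)",
                            ylab = "quantum Euclidean distance",
                            main = "Ranked docking candidates", ...)
  if (!is.null(cand$distance_lo)) {
    graphics::arrows(mids, cand$distance_lo, mids, cand$distance_hi,
                     angle = 90, code = 3, length = 0.04)
  }
  invisible(mids)
}
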