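#' Random interaction chain
#'
#' Draws per-site hydrophobic and hydrogen-bonding values independently and
#' uniformly within their allowed ranges. Reproducible per seed; the
#' caller's RNG state is left untouched.
#'
#' @param n_sites Number of interaction sites (>= 1).
#' @param ranges An [interaction_ranges()].
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @param role `"protein"` or `"ligand"`.
#' @return A [molecule_chain()].
#' @export
random_chain <- function(n_sites, ranges = interaction_ranges(), seed = NULL,
                         role = c("protein", "ligand")) {
  role <- match.arg(role)
  stopifnot(n_sites >= 1L, inherits(ranges, "interaction_ranges"))
  with_seed(seed, {
    h <- stats::runif(n_sites, ranges$h[1L], ranges$h[2L])
    hb <- stats::runif(n_sites, ranges$hb[1L], ranges$hb[2L])
    molecule_chain(h, hb, role = role)
  })
}

#' Plant a docking site into a protein chain
#'
#' Overwrites `n_sites(ligand)` consecutive protein sites starting at
#' `offset` so that the slice matches the ligand:
#' \describe{
#'   \item{`"exact-continuous"`}{copies the ligand's continuous values — the
#'     slice's amplitude state equals the ligand's, so its quantum Euclidean
#'     distance is 0.}
#'   \item{`"exact-binary"`}{draws values that reproduce the ligand's binary
#'     labels without equalling its continuous values: each value is drawn
#'     uniformly from `[v - jitter, v + jitter]` around the ligand value `v`,
#'     which must lie inside the value's half-interval (same bit); the
#'     planted slice is found by the binary search but keeps a positive
#'     distance.}
#' }
#'
#' @param protein,ligand [molecule_chain()] objects.
#' @param offset 0-based plant offset; `offset + n_sites(ligand)` must not
#'   exceed the protein length.
#' @param mode `"exact-binary"` or `"exact-continuous"`.
#' @param ranges An [interaction_ranges()].
#' @param jitter Half-width of the jitter window (exact-binary mode; must be
#'   positive and small enough to stay inside each value's half-interval).
#' @param seed Integer seed for the jitter draws.
#' @return The modified protein [molecule_chain()].
#' @export
plant_site <- function(protein, ligand, offset,
                       mode = c("exact-binary", "exact-continuous"),
                       ranges = interaction_ranges(), jitter = 0.02,
                       seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(protein, "molecule_chain"), inherits(ligand, "molecule_chain"))
  L <- n_sites(ligand)
  offset <- as.integer(offset)
  if (offset < 0L || offset + L > n_sites(protein)) {
    stop(sprintf("plant offset %d with %d-site ligand outside %d-site protein",
                 offset, L, n_sites(protein)), call. = FALSE)
  }
  idx <- seq.int(offset + 1L, offset + L)
  if (mode == "exact-continuous") {
    protein$h[idx] <- ligand$h
    protein$hb[idx] <- ligand$hb
    return(protein)
  }
  stopifnot(is.numeric(jitter), jitter > 0)
  draw <- function(v, range) {
    mid <- (range[1L] + range[2L]) / 2
    # half-interval of v's bit: [min, mid) or [mid, max]
    lo <- if (v < mid) range[1L] else mid
    hi <- if (v < mid) mid else range[2L]
    if (v - jitter < lo || v + jitter > hi) {
      stop(sprintf(
        "fixture error: jitter %.4g around value %.4g crosses the label boundary [%g, %g)",
        jitter, v, lo, hi), call. = FALSE)
    }
    stats::runif(1L, v - jitter, v + jitter)
  }
  with_seed(seed, {
    protein$h[idx] <- vapply(ligand$h, draw, numeric(1L), range = ranges$h)
    protein$hb[idx] <- vapply(ligand$hb, draw, numeric(1L), range = ranges$hb)
  })
  protein
}

#' Realize a binary label as a continuous chain
#'
#' Builds a chain whose [encode_chain_binary()] equals the given label:
#' 0-bits become the lower quarter point of the range, 1-bits the upper
#' quarter point (both safely inside their half-intervals).
#'
#' @param label Bitstring of even length.
#' @param ranges An [interaction_ranges()].
#' @param role Chain role.
#' @return A [molecule_chain()].
#' @examples
#' rg <- interaction_ranges()
#' encode_chain_binary(chain_from_label("1100", rg, "ligand"), rg) # "1100"
#' @export
chain_from_label <- function(label, ranges = interaction_ranges(),
                             role = c("protein", "ligand")) {
  role <- match.arg(role)
  assert_bitstring(label, "label")
  if (nchar(label) %% 2L != 0L) {
    stop("label length must be even (2 bits per site)", call. = FALSE)
  }
  bits <- as.integer(strsplit(label, "", fixed = TRUE)[[1L]])
  quarter <- function(bit, range) {
    range[1L] + (range[2L] - range[1L]) * ifelse(bit == 1L, 0.75, 0.25)
  }
  molecule_chain(h = quarter(bits[c(TRUE, FALSE)], ranges$h),
                 hb = quarter(bits[c(FALSE, TRUE)], ranges$hb),
                 role = role)
}

#' Random protein guaranteed to contain no docking site for a ligand
#'
#' Rejection-sampling negative control: redraws until no contiguous
#' ligand-sized slice of the protein has the ligand's binary label (verified
#' by the classical substring scan over all offsets).
#'
#' @param n_sites Protein size.
#' @param ligand A [molecule_chain()].
#' @param ranges An [interaction_ranges()].
#' @param seed Integer seed.
#' @param max_tries Attempts before giving up.
#' @return A protein [molecule_chain()] with no matching slice.
#' @export
negative_chain <- function(n_sites, ligand, ranges = interaction_ranges(),
                           seed = NULL, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    prot <- random_chain(n_sites, ranges, seed = derive_seed(seed, i),
                         role = "protein")
    if (length(scan_matches(prot, ligand, ranges)) == 0L) return(prot)
  }
  stop("negative_chain: could not draw a match-free protein (ligand label too likely)",
       call. = FALSE)
}

#' Classical substring scan for matching slices
#'
#' Brute-force reference for the quantum search: returns every 0-based
#' offset at which the contiguous ligand-sized slice of the protein has a
#' binary label equal to the ligand's.
#'
#' @param protein,ligand [molecule_chain()] objects.
#' @param ranges An [interaction_ranges()].
#' @return Integer vector of 0-based offsets (possibly empty).
#' @export
scan_matches <- function(protein, ligand, ranges = interaction_ranges()) {
  L <- n_sites(ligand)
  P <- n_sites(protein)
  if (L > P) return(integer(0))
  lig_label <- encode_chain_binary(ligand, ranges)
  plabel <- encode_chain_binary(protein, ranges)
  offsets <- 0:(P - L)
  hit <- vapply(offsets, function(o) {
    substring(plabel, 2L * o + 1L, 2L * o + 2L * L) == lig_label
  }, logical(1L))
  offsets[hit]
}

#' Write the bundled demonstration instances as CSV fixtures
#'
#' Generates a small suite of chain files under `dir`, all synthetic:
#' \itemize{
#'   \item the worked search instance with protein label
#'     `1111110110001111` and ligand `1111` (`demo16_*`);
#'   \item the 12-site instance with protein label
#'     `010011001111000110100011` and ligand `1100` (`demo12_*`), the
#'     instance used for the simulator probability checks;
#'   \item seeded random shape instances: 4-site protein / 1-site ligand,
#'     10-site / 2-site, 27-site / 3-site, each with one exact-continuous
#'     planted site (`shapeP_L_*`);
#'   \item a negative pair with no docking site (`negative_*`).
#' }
#' Bitstring instances are realized as continuous chains whose binary
#' encodings equal the stated labels (under unit ranges).
#'
#' @param dir Output directory (created if missing).
#' @param ranges An [interaction_ranges()].
#' @param seed Integer seed for the randomized instances.
#' @return Invisibly, a character vector of the written file paths.
#' @export
fixture_suite <- function(dir, ranges = interaction_ranges(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(chain, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    write_chain_csv(chain, p)
    paths <<- c(paths, p)
  }
  put(chain_from_label("1111110110001111", ranges, "protein"), "demo16_protein")
  put(chain_from_label("1111", ranges, "ligand"), "demo16_ligand")
  put(chain_from_label("010011001111000110100011", ranges, "protein"), "demo12_protein")
  put(chain_from_label("1100", ranges, "ligand"), "demo12_ligand")
  shapes <- list(c(4L, 1L), c(10L, 2L), c(27L, 3L))
  for (i in seq_along(shapes)) {
    P <- shapes[[i]][1L]; L <- shapes[[i]][2L]
    lig <- random_chain(L, ranges, seed = derive_seed(seed, 2L * i), role = "ligand")
    prot <- random_chain(P, ranges, seed = derive_seed(seed, 2L * i + 1L),
                         role = "protein")
    prot <- plant_site(prot, lig, offset = (P - L) %/% 2L,
                       mode = "exact-continuous", ranges = ranges)
    put(prot, sprintf("shape%d_%d_protein", P, L))
    put(lig, sprintf("shape%d_%d_ligand", P, L))
  }
  lig <- random_chain(2L, ranges, seed = derive_seed(seed, 99L), role = "ligand")
  put(negative_chain(12L, lig, ranges, seed = derive_seed(seed, 100L)),
      "negative_protein")
  put(lig, "negative_ligand")
  invisible(paths)
}
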