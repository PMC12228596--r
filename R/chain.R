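#' Allowed range of an interaction property
#'
#' A closed interval `[minimum, maximum]` bounding the continuous values a
#' property (hydrophobic interaction strength or hydrogen-bonding strength)
#' may take. The bounds are strict: `minimum < maximum`.
#'
#' @param minimum,maximum Numeric scalars, `minimum < maximum`.
#' @return An object of class `"property_range"`: a length-2 numeric vector
#'   `c(minimum, maximum)`.
#' @examples
#' property_range(0, 1)
#' @export
property_range <- function(minimum, maximum) {
  stopifnot(is.numeric(minimum), is.numeric(maximum),
            length(minimum) == 1L, length(maximum) == 1L,
            is.finite(minimum), is.finite(maximum))
  if (!(minimum < maximum)) {
    stop("property_range: minimum must be strictly less than maximum", call. = FALSE)
  }
  structure(c(minimum = minimum, maximum = maximum), class = "property_range")
}

#' Property ranges for both interaction types
#'
#' Bundles the allowed range of the hydrophobic interaction value and of the
#' hydrogen-bonding value. Both default to `[0, 1]`; the model treats the
#' properties as abstract reals, so the units are whatever the user's
#' interaction model supplies.
#'
#' @param h [property_range()] for the hydrophobic interaction.
#' @param hb [property_range()] for hydrogen bonding.
#' @return An object of class `"interaction_ranges"`, a list with elements
#'   `h` and `hb`.
#' @examples
#' interaction_ranges(h = property_range(-2, 2))
#' @export
interaction_ranges <- function(h = property_range(0, 1),
                               hb = property_range(0, 1)) {
  stopifnot(inherits(h, "property_range"), inherits(hb, "property_range"))
  structure(list(h = h, hb = hb), class = "interaction_ranges")
}

#' Molecule chain in interaction space
#'
#' An ordered chain of lattice interaction sites, each carrying a hydrophobic
#' interaction value `h` and a hydrogen-bonding value `hb`. A chain represents
#' either a protein or a ligand; site order is the chain order, indexed from
#' the first site.
#'
#' @param h,hb Numeric vectors of equal positive length: per-site property
#'   values.
#' @param role `"protein"` or `"ligand"`.
#' @return An object of class `"molecule_chain"`: a list with numeric vectors
#'   `h`, `hb` and the `role` string.
#' @examples
#' lig <- molecule_chain(h = c(0.9, 0.2), hb = c(0.8, 0.1), role = "ligand")
#' n_sites(lig)
#' @export
molecule_chain <- function(h, hb, role = c("protein", "ligand")) {
  role <- match.arg(role)
  stopifnot(is.numeric(h), is.numeric(hb))
  if (length(h) < 1L || length(h) != length(hb)) {
    stop("molecule_chain: h and hb must be numeric vectors of equal length >= 1",
         call. = FALSE)
  }
  if (anyNA(h) || anyNA(hb)) stop("molecule_chain: property values must not be NA",
                                  call. = FALSE)
  structure(list(h = as.numeric(h), hb = as.numeric(hb), role = role),
            class = "molecule_chain")
}

#' Number of interaction sites in a chain
#' @param chain A [molecule_chain()].
#' @return Integer site count.
#' @export
n_sites <- function(chain) {
  stopifnot(inherits(chain, "molecule_chain"))
  length(chain$h)
}

#' Extract a contiguous run of sites from a chain
#'
#' @param chain A [molecule_chain()].
#' @param start 0-based site offset of the first site of the slice.
#' @param length Number of sites to take.
#' @return A [molecule_chain()] with the same role.
#' @export
chain_slice <- function(chain, start, length) {
  stopifnot(inherits(chain, "molecule_chain"))
  n <- n_sites(chain)
  if (start < 0 || length < 1 || start + length > n) {
    stop(sprintf("chain_slice: slice [%d, %d) outside chain of %d sites",
                 start, start + length, n), call. = FALSE)
  }
  idx <- seq.int(start + 1L, start + length)
  molecule_chain(chain$h[idx], chain$hb[idx], role = chain$role)
}

#' @export
print.molecule_chain <- function(x, ...) {
  cat(sprintf("<molecule_chain: %s, %d interaction site%s>\n", x$role,
              n_sites(x), if (n_sites(x) == 1L) "" else "s"))
  print(utils::head(data.frame(index = seq_along(x$h) - 1L, h = x$h, hb = x$hb), 10L))
  if (n_sites(x) > 10L) cat(sprintf("... %d more sites\n", n_sites(x) - 10L))
  invisible(x)
}

# Check that every site value lies inside its property range (inclusive).
# Errors name the first offending 0-based site index.
validate_in_range <- function(chain, ranges) {
  stopifnot(inherits(chain, "molecule_chain"), inherits(ranges, "interaction_ranges"))
  for (prop in c("h", "hb")) {
    rg <- ranges[[prop]]
    v <- chain[[prop]]
    bad <- which(v < rg[1L] | v > rg[2L])
    if (length(bad)) {
      stop(sprintf("site %d: %s value %.6g outside range [%g, %g]",
                   bad[1L] - 1L, prop, v[bad[1L]], rg[1L], rg[2L]), call. = FALSE)
    }
  }
  invisible(chain)
}
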