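# Shared fixtures: unit ranges and a few canonical chains, all built in code.

unit_ranges <- function() interaction_ranges()

# 3-site ligand whose binary label is 110110 under unit ranges.
ligand3 <- function() {
  molecule_chain(h = c(0.9, 0.1, 0.6), hb = c(0.7, 0.8, 0.2), role = "ligand")
}

# 6-site protein whose binary label is 111110011010 under unit ranges.
protein6 <- function() {
  molecule_chain(h = c(0.8, 0.9, 0.7, 0.3, 0.6, 0.55),
                 hb = c(0.6, 0.8, 0.2, 0.9, 0.1, 0.3), role = "protein")
}

# Random distinct bitstrings of a given width.
random_labels <- function(n, width, seed) {
  with_seed_test(seed, {
    pool <- vapply(sample.int(2^width, n) - 1L, function(i) {
      paste(rev(as.integer(intToBits(i))[seq_len(width)]), collapse = "")
    }, character(1L))
    pool
  })
}

# Local seed scoping for test code (keeps tests order-independent).
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

label_to_index_test <- function(label) {
  bits <- as.integer(strsplit(label, "")[[1L]])
  sum(bits * 2^(rev(seq_along(bits)) - 1L))
}

# Independent brute-force Grover oracle: dense reflections assembled from
# first principles (outer products over explicitly listed basis vectors),
# kept separate from the package's circuit path.
brute_grover_p <- function(basis, target, k) {
  width <- nchar(basis[1L])
  d <- 2^width
  to_index <- function(label) {
    bits <- as.integer(strsplit(label, "")[[1L]])
    sum(bits * 2^(rev(seq_along(bits)) - 1L)) + 1L
  }
  v <- numeric(d)
  v[vapply(basis, to_index, numeric(1L))] <- 1 / sqrt(length(basis))
  e <- numeric(d); e[to_index(target)] <- 1
  O <- diag(d) - 2 * outer(e, e)
  G <- 2 * outer(v, v) - diag(d)
  x <- v
  for (i in seq_len(k)) x <- G %*% (O %*% x)
  as.numeric(x[to_index(target)]^2)
}
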