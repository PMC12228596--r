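#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
# seed = NULL means "use the current RNG stream as-is".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a parent seed and a stream index,
# staying inside the 32-bit signed integer range.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 69069 + 12345 + as.numeric(index)) %% 2147483647)
}

is_bitstring <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && grepl("^[01]+$", x)
}

assert_bitstring <- function(x, what = "label") {
  if (!is_bitstring(x)) {
    stop(sprintf("%s must be a non-empty string over {0,1}, got: %s",
                 what, deparse(substitute(x))), call. = FALSE)
  }
  invisible(x)
}

# Big-endian bitstring -> 0-based basis index (leftmost bit most significant).
label_to_index <- function(label) {
  bits <- as.integer(strsplit(label, "", fixed = TRUE)[[1]])
  sum(bits * 2^(rev(seq_along(bits)) - 1L))
}

# 0-based basis index -> big-endian bitstring of width n.
index_to_label <- function(index, n) {
  paste(rev(as.integer(intToBits(index))[seq_len(n)]), collapse = "")
}
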