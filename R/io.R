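#' Read and write interaction chains as CSV
#'
#' Chain files have the header `index,h,hb` with one row per interaction
#' site; `index` is 0-based and must be contiguous ascending. Ranges are not
#' stored in the CSV — they belong to the run configuration. The round trip
#' is lossless to full double precision.
#'
#' @param path File path.
#' @param role Chain role to attach on read.
#' @return [read_chain_csv()] returns a [molecule_chain()];
#'   [write_chain_csv()] invisibly returns `path`.
#' @export
read_chain_csv <- function(path, role = c("protein", "ligand")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop(sprintf("chain file not found: %s", path), call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, colClasses = c("integer", "numeric", "numeric")),
    error = function(e) stop(sprintf("%s: malformed chain CSV (%s)",
                                     path, conditionMessage(e)), call. = FALSE))
  if (!identical(names(df), c("index", "h", "hb"))) {
    stop(sprintf("%s: header must be 'index,h,hb', got '%s'",
                 path, paste(names(df), collapse = ",")), call. = FALSE)
  }
  if (nrow(df) < 1L) stop(sprintf("%s: chain file has no sites", path), call. = FALSE)
  expected <- seq_len(nrow(df)) - 1L
  if (!identical(as.integer(df$index), expected)) {
    miss <- setdiff(expected, df$index)
    bad <- if (length(miss)) sprintf("missing index %d", miss[1L])
           else sprintf("unexpected index %d at line %d",
                        df$index[which(df$index != expected)[1L]],
                        which(df$index != expected)[1L] + 1L)
    stop(sprintf("%s: indices must be contiguous ascending from 0 (%s)", path, bad),
         call. = FALSE)
  }
  if (anyNA(df$h) || anyNA(df$hb)) {
    line <- which(is.na(df$h) | is.na(df$hb))[1L] + 1L
    stop(sprintf("%s: non-numeric cell at line %d", path, line), call. = FALSE)
  }
  molecule_chain(df$h, df$hb, role = role)
}

#' @rdname read_chain_csv
#' @param chain A [molecule_chain()].
#' @export
write_chain_csv <- function(chain, path) {
  stopifnot(inherits(chain, "molecule_chain"))
  df <- data.frame(index = seq_len(n_sites(chain)) - 1L,
                   h = format(chain$h, digits = 17, trim = TRUE, scientific = FALSE),
                   hb = format(chain$hb, digits = 17, trim = TRUE, scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' Accepts YAML (`.yaml`/`.yml`, requires the yaml package) or JSON. Known
#' keys: `h_min`, `h_max`, `hb_min`, `hb_max` (property ranges) and the
#' [dock_control()] keys `backend`, `shots`, `seed`, `iterations`,
#' `diffusion`, `qubit_budget`. Missing keys take the package defaults.
#'
#' @param path Config file path.
#' @return List with elements `ranges` ([interaction_ranges()]) and
#'   `control` ([dock_control()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML config requires the 'yaml' package; use JSON instead",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg)) cfg <- list()
  grab <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  ranges <- interaction_ranges(
    h = property_range(grab("h_min", 0), grab("h_max", 1)),
    hb = property_range(grab("hb_min", 0), grab("hb_max", 1)))
  control <- dock_control(
    backend = grab("backend", "exact"),
    shots = grab("shots", 4096L),
    seed = grab("seed", NULL),
    iterations = grab("iterations", "auto"),
    diffusion = grab("diffusion", "matrix"),
    qubit_budget = grab("qubit_budget", 12L))
  list(ranges = ranges, control = control)
}

#' Write a machine-readable docking report
#'
#' Serializes a [qdock()] fit as JSON: an echo of the inputs (MD5 hashes of
#' the chain files when paths are supplied, ranges, control parameters), the
#' candidate table, a search-trace summary and any warnings (shot-noise
#' clamps, dropped trailing remainders). Rerunning the same configuration on
#' the exact backend reproduces the file byte-for-byte.
#'
#' @param fit A `"qdock"` object.
#' @param path Output path for the JSON report.
#' @param protein_path,ligand_path Optional source file paths to hash into
#'   the input echo.
#' @return Invisibly, the report list.
#' @export
write_report <- function(fit, path, protein_path = NULL, ligand_path = NULL) {
  stopifnot(inherits(fit, "qdock"))
  hash <- function(p) if (is.null(p)) NULL else unname(tools::md5sum(p))
  tr <- fit$trace
  warnings <- c(
    tr$decision[tr$method == "truncate"],
    if (any(fit$candidates$clamped))
      sprintf("distance clamped to 0 by shot noise at offset(s) %s",
              paste(fit$candidates$start_offset[fit$candidates$clamped],
                    collapse = ", ")))
  report <- list(
    inputs = list(
      protein_md5 = hash(protein_path),
      ligand_md5 = hash(ligand_path),
      protein_sites = n_sites(fit$protein),
      ligand_sites = n_sites(fit$ligand),
      ligand_label = fit$ligand_label,
      ranges = list(h = as.numeric(fit$ranges$h), hb = as.numeric(fit$ranges$hb)),
      control = fit$control[c("backend", "shots", "iterations", "diffusion",
                              "qubit_budget")],
      seed = fit$control$seed),
    search = list(
      n_decisions = nrow(tr),
      n_grover_calls = sum(grepl("^grover", tr$method)),
      trace = tr),
    candidates = fit$candidates,
    warnings = as.list(warnings))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(report)
}
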