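#' Construct a structural connectome
#'
#' Bundles region-to-region coupling weights and inter-region fibre
#' distances into a validated `connectome` object. Weights are the
#' dimensionless long-range coupling strengths `M` that scale the delayed
#' postsynaptic-potential input each region receives; distances (mm) are
#' converted to conduction delays by [compute_delays()].
#'
#' @param weights Square numeric matrix of non-negative coupling weights.
#' @param distances Square numeric matrix of non-negative distances in mm
#'   with a zero diagonal; same dimension as `weights`.
#' @param labels Optional character vector of region names; defaults to
#'   `"region_1"`, `"region_2"`, ...
#'
#' @return A `connectome` object: a list with elements `n_regions`,
#'   `labels`, `weights` and `distances`.
#' @export
#' @examples
#' conn <- connectome(diag(3), matrix(0, 3, 3))
#' conn$n_regions
connectome <- function(weights, distances, labels = NULL) {
  weights <- as.matrix(weights)
  distances <- as.matrix(distances)
  storage.mode(weights) <- "double"
  storage.mode(distances) <- "double"
  if (nrow(weights) != ncol(weights))
    stop("connectome weights must be a square matrix, got ",
         nrow(weights), "x", ncol(weights), call. = FALSE)
  if (nrow(distances) != ncol(distances))
    stop("connectome distances must be a square matrix, got ",
         nrow(distances), "x", ncol(distances), call. = FALSE)
  if (nrow(weights) != nrow(distances))
    stop("weights (", nrow(weights), "x", ncol(weights),
         ") and distances (", nrow(distances), "x", ncol(distances),
         ") do not match", call. = FALSE)
  n <- nrow(weights)
  if (is.null(labels)) labels <- paste0("region_", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("labels must have one entry per region", call. = FALSE)
  obj <- structure(
    list(n_regions = n, labels = labels,
         weights = unname(weights), distances = unname(distances)),
    class = "connectome")
  validate_connectome(obj)
  obj
}

validate_connectome <- function(conn) {
  if (!all(is.finite(conn$weights)))
    stop("connectome weights contain non-finite values", call. = FALSE)
  if (!all(is.finite(conn$distances)))
    stop("connectome distances contain non-finite values", call. = FALSE)
  if (any(conn$weights < 0))
    stop("connectome weights must be non-negative", call. = FALSE)
  if (any(conn$distances < 0))
    stop("connectome distances must be non-negative", call. = FALSE)
  if (any(diag(conn$distances) != 0))
    stop("connectome distances must have a zero diagonal", call. = FALSE)
  invisible(conn)
}

#' @export
print.connectome <- function(x, ...) {
  cat("connectome:", x$n_regions, "regions\n")
  cat("  weights:  max", format(max(x$weights), digits = 4),
      " density", format(mean(x$weights > 0), digits = 3), "\n")
  cat("  distances: max", format(max(x$distances), digits = 4), "mm\n")
  invisible(x)
}

read_matrix_file <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = sep,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' Read a connectome from plain-text matrix files
#'
#' Reads whitespace- or comma-delimited numeric matrices (one row per
#' line) for weights and distances, plus an optional labels file (one
#' region name per line), and validates them into a [connectome()].
#'
#' @param weights_path,distances_path Paths to square numeric matrix
#'   files of equal dimension.
#' @param labels_path Optional path to a region-name file.
#'
#' @return A `connectome` object.
#' @seealso [write_connectome()]
#' @export
read_connectome <- function(weights_path, distances_path,
                            labels_path = NULL) {
  w <- read_matrix_file(weights_path)
  d <- read_matrix_file(distances_path)
  labels <- if (!is.null(labels_path)) readLines(labels_path) else NULL
  connectome(w, d, labels)
}

#' Write a connectome to plain-text matrix files
#'
#' Inverse of [read_connectome()]; values are written with full `%.17g`
#' precision so a read/write round trip reproduces the matrices exactly.
#'
#' @param conn A `connectome`.
#' @param weights_path,distances_path,labels_path Output paths; labels
#'   are only written when `labels_path` is given.
#' @return `conn`, invisibly.
#' @export
write_connectome <- function(conn, weights_path, distances_path,
                             labels_path = NULL) {
  validate_connectome(conn)
  write_mat <- function(m, path) {
    lines <- apply(m, 1L, function(row)
      paste(sprintf("%.17g", row), collapse = "\t"))
    writeLines(lines, path)
  }
  write_mat(conn$weights, weights_path)
  write_mat(conn$distances, distances_path)
  if (!is.null(labels_path)) writeLines(conn$labels, labels_path)
  invisible(conn)
}

#' Normalise connectome weights
#'
#' Empirical structural-connectivity matrices span several orders of
#' magnitude; before simulation they are brought onto a bounded scale.
#' `max_one` divides by the matrix maximum, `log_scaled` applies
#' `log(1 + w)` and then divides by the new maximum (compressing the
#' heavy tail of streamline-count-like weights), `none` is the identity.
#'
#' @param conn A `connectome`.
#' @param mode One of `"max_one"`, `"log_scaled"`, `"none"`.
#' @return A `connectome` with transformed weights.
#' @export
normalize_weights <- function(conn,
                              mode = c("max_one", "log_scaled", "none")) {
  mode <- match.arg(mode)
  w <- conn$weights
  if (mode == "none") return(conn)
  if (mode == "log_scaled") w <- log1p(w)
  mx <- max(w)
  if (mx <= 0)
    stop("cannot normalize an all-zero weight matrix", call. = FALSE)
  conn$weights <- w / mx
  conn
}

#' Derive conduction delays from distances
#'
#' Converts fibre distances (mm) into integer integration-step delays:
#' `round(distance / speed / dt)` with round-half-to-even, where
#' `distance / speed` gives the delay in ms (mm divided by m/s). Delays
#' of 0 steps are allowed for very short tracts (instantaneous coupling
#' at the integration resolution).
#'
#' @param conn A `connectome`.
#' @param speed Conduction speed in m/s (default 2.5).
#' @param dt Integration step in ms.
#' @return A `delay_table` object: list with `delays_steps` (integer
#'   matrix), `speed` and `dt`.
#' @export
#' @examples
#' conn <- connectome(matrix(1, 2, 2), matrix(c(0, 25, 25, 0), 2, 2))
#' compute_delays(conn, speed = 2.5, dt = 0.1)$delays_steps
compute_delays <- function(conn, speed = 2.5, dt = 0.1) {
  if (!is.numeric(speed) || length(speed) != 1L || speed <= 0)
    stop("speed must be a single positive number (m/s)", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number (ms)", call. = FALSE)
  delay_ms <- conn$distances / speed   # mm / (m/s) = ms
  steps <- round(delay_ms / dt)        # round-half-to-even
  storage.mode(steps) <- "integer"
  structure(list(delays_steps = steps, speed = speed, dt = dt),
            class = "delay_table")
}
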