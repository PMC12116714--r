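#' Read a panel of functions from a wide CSV file
#'
#' The file must have a header row, a first column holding the grid and one
#' column per function. Grids on a domain other than `[0, 1]` are rescaled
#' affinely to `[0, 1]` with a warning (registration is invariant to this
#' common reparameterization); the original domain is kept as the `"domain"`
#' attribute. With `long = TRUE` the file is instead expected in long format
#' with columns `t`, `fun`, `value`.
#'
#' @param path CSV path.
#' @param long Read long format instead of wide.
#' @return A wide tibble (`t` plus one column per function).
#' @export
read_functions <- function(path, long = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (long) {
    need <- c("t", "fun", "value")
    if (!all(need %in% names(df)))
      stop("read_functions: long format needs columns t, fun, value", call. = FALSE)
    df <- tidyr::pivot_wider(tibble::as_tibble(df), names_from = "fun",
                             values_from = "value")
    df <- df[order(df$t), ]
  }
  for (j in seq_along(df)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[j]]))))
    if (length(bad) > 0)
      stop(sprintf("read_functions: non-numeric cell at row %d, column '%s'",
                   bad[1], names(df)[j]), call. = FALSE)
    df[[j]] <- as.numeric(df[[j]])
  }
  grid <- df[[1]]
  if (anyDuplicated(grid))
    stop(sprintf("read_functions: duplicate grid value at row %d",
                 anyDuplicated(grid)), call. = FALSE)
  if (is.unsorted(grid))
    stop("read_functions: grid column must be increasing", call. = FALSE)
  domain <- range(grid)
  if (abs(domain[1]) > 1e-8 || abs(domain[2] - 1) > 1e-8) {
    warning(sprintf("read_functions: rescaling domain [%g, %g] to [0, 1]",
                    domain[1], domain[2]))
    grid <- (grid - domain[1]) / (domain[2] - domain[1])
  }
  out <- tibble::as_tibble(df)
  out[[1]] <- grid
  names(out)[1] <- "t"
  attr(out, "domain") <- domain
  out
}

#' Write a panel of functions to a wide CSV file
#' @param data Wide data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_functions <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

SYSTEM_SCHEMA <- "seqreg-particles-1"

# internal: md5 of a serialized object (via a temporary file)
payload_md5 <- function(payload) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  serialize(payload, con, version = 3)
  close(con)
  unname(tools::md5sum(tmp))
}

#' Save / load a particle system
#'
#' The store is a single versioned RDS container holding all particle arrays,
#' weights, data, hyperparameters and the RNG state, plus an integrity
#' checksum. `load_system` rejects unknown schema versions and corrupted
#' payloads. Saving and re-saving a loaded system is byte-identical.
#'
#' @param system A [particle_system].
#' @param path File path for the store.
#' @return `save_system` returns `path` invisibly; `load_system` returns the
#'   [particle_system].
#' @export
save_system <- function(system, path) {
  stopifnot(inherits(system, "particle_system"))
  payload <- unclass(system)
  payload$rng_state <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  obj <- list(schema = SYSTEM_SCHEMA, checksum = payload_md5(payload),
              payload = payload)
  saveRDS(obj, path, version = 3)
  invisible(path)
}

#' @param restore_rng Restore the RNG state recorded at save time.
#' @rdname save_system
#' @export
load_system <- function(path, restore_rng = FALSE) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("load_system: unreadable store: ", conditionMessage(e), call. = FALSE))
  if (!identical(obj$schema, SYSTEM_SCHEMA))
    stop("load_system: unknown schema version: ", obj$schema, call. = FALSE)
  if (!identical(unname(obj$checksum), unname(payload_md5(obj$payload))))
    stop("load_system: checksum mismatch, store is corrupted", call. = FALSE)
  payload <- obj$payload
  if (restore_rng && !is.null(payload$rng_state))
    assign(".Random.seed", payload$rng_state, globalenv())
  payload$rng_state <- NULL
  structure(payload, class = "particle_system")
}
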