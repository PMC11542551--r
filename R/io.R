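#' Write a simulated experiment to disk
#'
#' Emits the standard trio: `measurements.csv` (one row per nucleus with well
#' metadata), `latent.csv` (ground-truth latent tracks) and `sidecar.json`
#' (full generator parameters, design and seed), so a simulated experiment is
#' fully reconstructible.
#'
#' @param experiment a `sim_experiment` from [simulate_experiment()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "sim_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(experiment$measurements, file.path(dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(experiment$latent, file.path(dir, "latent.csv"),
                   row.names = FALSE)
  sidecar <- list(params = unclass(experiment$params),
                  design = unclass(experiment$design))
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a per-nucleus measurement table
#'
#' Reads a delimited measurement table (as written by [write_experiment()] or
#' exported from an imaging pipeline) and checks the columns the calling
#' module needs.
#'
#' @param path CSV path.
#' @return a tibble of nucleus records.
#' @export
read_measurements <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  needed <- c("plate", "well", "condition", "median_gfp")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    stop("measurement table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x
}
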