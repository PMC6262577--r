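#' Read and write stopped-flow trace CSV files
#'
#' Trace files are two-column CSVs `time_s,F` with an optional comment
#' header `#F0=<value>`; when the header is absent, F0 defaults to the
#' first fluorescence sample.
#'
#' @param path File path.
#' @return [read_trace_csv()] returns a [fluorescence_trace()].
#' @export
read_trace_csv <- function(path) {
  header <- readLines(path, n = 5L)
  f0_line <- grep("^#F0=", header, value = TRUE)
  dat <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("time_s", "F") %in% names(dat)))
  f0 <- if (length(f0_line)) as.numeric(sub("^#F0=", "", f0_line[1])) else dat$F[1]
  fluorescence_trace(dat$time_s, dat$F, f0 = f0)
}

#' @rdname read_trace_csv
#' @param trace A [fluorescence_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#F0=%.17g", trace_f0(trace)), con)
  utils::write.csv(data.frame(time_s = trace$time_s, F = trace$f),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write simulated volume traces (`time_s,v_rel`)
#'
#' @param path File path.
#' @return A `volume_trace` data frame.
#' @export
read_volume_csv <- function(path) {
  dat <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("time_s", "v_rel") %in% names(dat)))
  class(dat) <- c("volume_trace", "data.frame")
  dat
}

#' @rdname read_volume_csv
#' @param trace A `volume_trace`.
#' @export
write_volume_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time_s, v_rel = trace$v_rel),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write MD coordinate-stream CSV files
#'
#' Format: columns `frame,mol_id,kind,x,y,z` with a required `#dt_ps=`
#' comment header giving the frame spacing in ps.
#'
#' @param path File path.
#' @return A [trajectory()].
#' @export
read_trajectory_csv <- function(path) {
  header <- readLines(path, n = 5L)
  dt_line <- grep("^#dt_ps=", header, value = TRUE)
  if (!length(dt_line)) {
    stop("invalid trajectory: missing #dt_ps= header in ", path)
  }
  dt_ps <- as.numeric(sub("^#dt_ps=", "", dt_line[1]))
  dat <- utils::read.csv(path, comment.char = "#")
  trajectory(dat, dt_ps = dt_ps)
}

#' @rdname read_trajectory_csv
#' @param traj A [trajectory()].
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#dt_ps=%.17g", traj$dt_ps), con)
  utils::write.csv(traj$frames, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pore-radius profile CSV (`z_A,radius_A`)
#'
#' Two-column CSV as produced by converting HOLE output: pore-axis
#' coordinate and radius, both in Angstrom.
#'
#' @param path File path.
#' @return Data frame with columns `z_A`, `radius_A`.
#' @export
read_pore_profile_csv <- function(path) {
  dat <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("z_A", "radius_A") %in% names(dat)))
  dat
}
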