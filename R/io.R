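#' Write a length-force trace to delimited text with a YAML sidecar
#'
#' The trace samples go to a tab-separated file (columns \code{time},
#' \code{strain}, \code{stress}) and the scalar metadata (drive frequency,
#' amplitude, condition, fiber geometry) to \code{<path>.yml}, so a trace
#' round-trips losslessly through plain text.
#'
#' @param trace a \code{"length_force_trace"}.
#' @param path output file path (the sidecar gets \code{.yml} appended).
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "length_force_trace"))
  utils::write.table(
    data.frame(time = trace$time, strain = trace$strain,
               stress = trace$stress),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(drive_frequency = trace$drive_frequency,
               amplitude = trace$amplitude,
               condition = trace$condition)
  geom <- trace$meta$geometry
  if (!is.null(geom))
    side$geometry <- list(length = geom$length,
                          cross_sectional_area = geom$cross_sectional_area)
  yaml::write_yaml(side, paste0(path, ".yml"))
  invisible(path)
}

#' Read a length-force trace written by [write_trace()]
#'
#' @param path path given to [write_trace()].
#' @return A \code{"length_force_trace"}.
#' @export
read_trace <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  side <- yaml::read_yaml(paste0(path, ".yml"))
  meta <- list()
  if (!is.null(side$geometry))
    meta$geometry <- fiber_geometry(side$geometry$length,
                                    side$geometry$cross_sectional_area)
  length_force_trace(tab$time, tab$strain, tab$stress,
                     drive_frequency = side$drive_frequency,
                     amplitude = side$amplitude,
                     condition = if (is.null(side$condition)) list()
                                 else side$condition,
                     meta = meta)
}

#' Write a modulus spectrum to tab-separated text
#'
#' The strain amplitude travels in a commented header line so the file
#' stays a single self-contained TSV.
#'
#' @param spectrum a \code{"modulus_spectrum"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "modulus_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# amplitude: %.17g", attr(spectrum, "amplitude")), con)
  utils::write.table(as.data.frame(spectrum), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a modulus spectrum written by [write_spectrum()]
#'
#' @param path path given to [write_spectrum()].
#' @return A \code{"modulus_spectrum"}.
#' @export
read_spectrum <- function(path) {
  first <- readLines(path, n = 1L)
  amp <- as.numeric(sub("^# amplitude:\\s*", "", first))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  modulus_spectrum(tab$frequency, tab$elastic, tab$viscous, amplitude = amp)
}
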