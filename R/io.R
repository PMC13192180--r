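# Readers/writers for the fixture formats: two-column delimited traces,
# float32 binary traces with a JSON sidecar, single-channel TIFF images,
# plate CSVs, PSD/Sholl exports.

#' Write a trace as two-column delimited text
#'
#' Columns \code{time_s}, \code{voltage_mV}, tab-separated with a header.
#' @param trace a \code{\linkS4class{Trace}}.
#' @param path output file.
#' @export
writeTraceText <- function(trace, path) {
  utils::write.table(
    data.frame(time_s = traceTimes(trace), voltage_mV = trace@samples),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read a two-column delimited trace
#'
#' Expects columns time and voltage (header optional); the sampling rate is
#' inferred from the median time step.
#' @param path input file.
#' @return a \code{\linkS4class{Trace}}.
#' @export
readTraceText <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "")
  fs <- 1 / stats::median(diff(d[[1]]))
  Trace(d[[2]], fs = fs, t0 = d[[1]][1])
}

#' Write a trace as raw float32 with a JSON sidecar
#'
#' The sidecar \code{<path>.json} records \code{fs}, \code{t0}, \code{n}
#' and the units.
#' @param trace a \code{\linkS4class{Trace}}.
#' @param path output binary file.
#' @export
writeTraceBinary <- function(trace, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(trace@samples, con, size = 4, endian = "little")
  jsonlite::write_json(
    list(fs = trace@fs, t0 = trace@t0, n = length(trace@samples),
         units = "mV", dtype = "float32"),
    paste0(path, ".json"), auto_unbox = TRUE)
}

#' Read a raw float32 trace with its JSON sidecar
#' @param path binary file written by \code{\link{writeTraceBinary}}.
#' @return a \code{\linkS4class{Trace}}.
#' @export
readTraceBinary <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = meta$n, size = 4, endian = "little")
  Trace(x, fs = meta$fs, t0 = meta$t0)
}

#' Write a channel image as single-channel TIFF
#' @param img a \code{\linkS4class{ChannelImage}}.
#' @param path output TIFF path.
#' @export
writeChannelTiff <- function(img, path) {
  tiff::writeTIFF(img@pixels, path, bits.per.sample = 16L)
  jsonlite::write_json(list(pixel_um = img@pixelUm, channel = img@channel),
                       paste0(path, ".json"), auto_unbox = TRUE)
}

#' Read a single-channel TIFF as a ChannelImage
#' @param path TIFF path; a sidecar \code{<path>.json} may carry
#'   \code{pixel_um} and \code{channel}.
#' @param pixelUm pixel size, overriding/replacing the sidecar.
#' @param channel channel label, overriding/replacing the sidecar.
#' @return a \code{\linkS4class{ChannelImage}}.
#' @export
readChannelTiff <- function(path, pixelUm = NULL, channel = NULL) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(pixelUm)) pixelUm <- meta$pixel_um
    if (is.null(channel)) channel <- meta$channel
  }
  stopifnot2(!is.null(pixelUm) && !is.null(channel),
             "pixelUm and channel required (no sidecar found)")
  ChannelImage(m, pixelUm, channel)
}

#' Export a PSD as two-column delimited text
#' @param psd a \code{\linkS4class{PSDEstimate}}.
#' @param path output file.
#' @export
writePsdText <- function(psd, path) {
  utils::write.table(
    data.frame(freq_hz = psd@freqs, power_mv2_per_hz = psd@power),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Export Sholl profiles as CSV
#' @param profiles list of \code{\linkS4class{ShollProfile}}s.
#' @param path output CSV.
#' @export
writeShollCsv <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p)
    data.frame(cell_id = p@cellId, radius_um = p@radii,
               intersections = p@intersections)))
  utils::write.csv(rows, path, row.names = FALSE)
}
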