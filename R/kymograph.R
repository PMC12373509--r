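#' Kymograph container
#'
#' A space-time intensity matrix: rows are time points, columns positions
#' along the invasion axis. Positions are depths from the origin (the
#' reservoir boundary for simulated slabs), so invasion proceeds toward
#' larger coordinates.
#'
#' @param intensity numeric matrix `[n_times x n_positions]`, >= 0.
#' @param positions strictly increasing position coordinates, um.
#' @param times strictly increasing time coordinates, s.
#' @param origin coordinate of the condensate boundary (or centre) the
#'   front displacement is measured from.
#' @return An object of class `kymograph`.
#' @export
kymograph <- function(intensity, positions, times, origin = 0) {
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(times))
    stop("intensity must have one row per time point")
  if (ncol(intensity) != length(positions))
    stop("intensity must have one column per position")
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(intensity))) stop("intensity must be finite")
  if (any(intensity < 0)) intensity[intensity < 0] <- 0 # background-subtraction clamp
  structure(list(intensity = intensity, positions = positions,
                 times = times, origin = origin),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d frames x %d positions, t in [%g, %g] s, x in [%g, %g] um\n",
              length(x$times), length(x$positions),
              min(x$times), max(x$times), min(x$positions), max(x$positions)))
  invisible(x)
}

#' Read / write kymographs as delimited text
#'
#' `write_kymograph` stores the intensity matrix as a TSV (rows = time,
#' columns = position) plus a JSON sidecar `<file>.meta.json` holding the
#' coordinates, origin and any extra metadata; `read_kymograph` reads the
#' pair back.
#'
#' @param kym a [kymograph()].
#' @param file path of the TSV file.
#' @param meta optional named list stored in the sidecar (e.g. echoed
#'   simulation parameters).
#' @return `write_kymograph` returns `file` invisibly; `read_kymograph`
#'   returns a `kymograph` (with a `"meta"` attribute if present).
#' @export
write_kymograph <- function(kym, file, meta = list()) {
  stopifnot(inherits(kym, "kymograph"))
  utils::write.table(kym$intensity, file, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  side <- list(positions = kym$positions, times = kym$times,
               origin = kym$origin,
               dx_um = if (length(kym$positions) > 1) diff(kym$positions[1:2]) else NA,
               dt_s = if (length(kym$times) > 1) diff(kym$times[1:2]) else NA,
               meta = meta)
  jsonlite::write_json(side, paste0(file, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(file) {
  mat <- as.matrix(utils::read.table(file, sep = "\t", header = FALSE))
  dimnames(mat) <- NULL
  metafile <- paste0(file, ".meta.json")
  if (file.exists(metafile)) {
    side <- jsonlite::read_json(metafile, simplifyVector = TRUE)
    k <- kymograph(mat, positions = side$positions, times = side$times,
                   origin = side$origin)
    attr(k, "meta") <- side$meta
    k
  } else {
    kymograph(mat, positions = seq_len(ncol(mat)) - 1, times = seq_len(nrow(mat)) - 1)
  }
}

#' Export a kymograph as a multi-page TIFF
#'
#' Each time frame is tiled as a one-row image page; intensities are
#' rescaled to `[0, 1]`. Requires the `tiff` package.
#'
#' @inheritParams write_kymograph
#' @param height number of identical pixel rows per page (for viewing).
#' @return `file`, invisibly.
#' @export
write_kymograph_tiff <- function(kym, file, height = 32) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  rng <- range(kym$intensity)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_along(kym$times), function(i) {
    row <- (kym$intensity[i, ] - rng[1]) / scale
    matrix(rep(row, each = height), nrow = height, byrow = FALSE)
  })
  tiff::writeTIFF(pages, file)
  invisible(file)
}
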