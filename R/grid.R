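#' Construct a wavelength grid
#'
#' @param start_nm first wavelength in nm (default 1100)
#' @param step_nm channel spacing in nm (default 2)
#' @param n_channels number of channels (default 700)
#'
#' @details The defaults reproduce the acquisition grid of a scanning NIR
#' spectrophotometer covering 1100--2498 nm at 2 nm resolution, the grid on
#' which all predictor indices in model reports are expressed.
#'
#' @return a \linkS4class{WavelengthGrid}
#' @examples
#' g <- nirGrid()
#' indexToWavelength(347, g)   # 1792
#' wavelengthToIndex(1392, g)  # 147
#' @export
nirGrid <- function(start_nm = 1100, step_nm = 2, n_channels = 700L) {
  new("WavelengthGrid", start_nm = as.numeric(start_nm),
      step_nm = as.numeric(step_nm), n_channels = as.integer(n_channels))
}

#' End wavelength of a grid
#' @param grid a \linkS4class{WavelengthGrid}
#' @return last wavelength in nm
#' @export
gridEnd <- function(grid) {
  grid@start_nm + grid@step_nm * (grid@n_channels - 1L)
}

#' All wavelengths of a grid, in ascending order
#'
#' @param x a \linkS4class{WavelengthGrid} or \linkS4class{SpectraSet}
#' @return numeric vector of wavelengths (nm)
#' @export
setMethod("wavelengths", "WavelengthGrid", function(x) {
  x@start_nm + x@step_nm * (seq_len(x@n_channels) - 1)
})

#' Convert between 1-based predictor indices and wavelengths
#'
#' The mapping is \code{nm = start_nm + step_nm * (i - 1)}; on the default
#' grid index 1 is 1100 nm, index 347 is 1792 nm, index 700 is 2498 nm.
#' Both directions are exact and round-trip.
#'
#' @param i 1-based predictor index (vectorized)
#' @param nm wavelength in nm, which must lie exactly on the grid
#' @param grid a \linkS4class{WavelengthGrid}
#' @return the other representation
#' @export
setMethod("indexToWavelength", signature(i = "numeric", grid = "WavelengthGrid"),
  function(i, grid) {
    if (any(i != round(i)))
      stop("predictor index must be integral")
    i <- as.integer(round(i))
    bad <- i < 1L | i > grid@n_channels
    if (any(bad))
      stop(sprintf("predictor index out of range: %s (grid has channels 1..%d, %g-%g nm)",
                   paste(i[bad], collapse = ", "), grid@n_channels,
                   grid@start_nm, gridEnd(grid)))
    grid@start_nm + grid@step_nm * (i - 1L)
  })

#' @rdname indexToWavelength
#' @export
setMethod("wavelengthToIndex", signature(nm = "numeric", grid = "WavelengthGrid"),
  function(nm, grid) {
    pos <- (nm - grid@start_nm) / grid@step_nm
    i <- as.integer(round(pos))
    off <- abs(pos - i) > 1e-9
    bad <- off | i < 0L | i >= grid@n_channels
    if (any(bad))
      stop(sprintf("wavelength not on the grid: %s nm (grid is %g-%g nm in %g nm steps)",
                   paste(nm[bad], collapse = ", "),
                   grid@start_nm, gridEnd(grid), grid@step_nm))
    i + 1L
  })

setMethod("show", "WavelengthGrid", function(object) {
  cat(sprintf("WavelengthGrid: %g-%g nm, step %g nm, %d channels\n",
              object@start_nm, gridEnd(object), object@step_nm,
              object@n_channels))
})
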