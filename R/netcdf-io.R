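# NetCDF I/O in the LUH2 "states" dialect: 12 named fraction variables with
# (lon, lat, time) dimensions on a regular lon-lat grid.

#' Write a lon-lat grid to a LUH2-style "states" NetCDF file
#'
#' Writes the 12 fraction layers as double-precision variables named
#' `primf, primn, secdf, secdn, pastr, range, urban, c3ann, c3per, c4ann,
#' c4per, c3nfx`, with `lon`, `lat` and `time` (calendar year) dimensions.
#' Ocean cells (zero land fraction) hold zeros in every layer.
#'
#' @param grid A lon-lat [LandUseGrid-class] with the 12 LUH2 type labels.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [readLandUseGrid()] for the inverse; the round trip reproduces
#'   fractions exactly.
#' @export
writeLUH2States <- function(grid, path) {
  stopifnot(is(grid, "LandUseGrid"))
  md <- metadata(grid)
  if (md$gridType != "lonlat") {
    .err("ecodivParameterError", "only lon-lat grids use the LUH2 states dialect")
  }
  if (!identical(sort(typeLabels(grid)), sort(.LUH2_TYPES))) {
    .err("ecodivParameterError", "grid must carry the 12 LUH2 type labels")
  }
  lonC <- (md$lonEdges[-1L] + md$lonEdges[-length(md$lonEdges)]) / 2
  latC <- (md$latEdges[-1L] + md$latEdges[-length(md$latEdges)]) / 2
  years <- gridYears(grid)
  dimLon <- ncdf4::ncdim_def("lon", "degrees_east", lonC)
  dimLat <- ncdf4::ncdim_def("lat", "degrees_north", latC)
  dimTime <- ncdf4::ncdim_def("time", "year", as.numeric(years))
  vars <- lapply(.LUH2_TYPES, function(v) {
    ncdf4::ncvar_def(v, "1", list(dimLon, dimLat, dimTime), prec = "double")
  })
  nc <- tryCatch(
    ncdf4::nc_create(path, vars),
    error = function(e) .err("ecodivIOError", "cannot write '%s': %s",
                             path, conditionMessage(e))
  )
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  nx <- md$nx
  ny <- md$ny
  for (v in .LUH2_TYPES) {
    a <- assay(grid, v)
    # cells are row-major from the south-west with lon fastest, matching the
    # (lon, lat, time) array layout directly
    ncdf4::ncvar_put(nc, v, array(a, dim = c(nx, ny, length(years))))
  }
  invisible(path)
}

#' Read a LUH2-style "states" NetCDF file
#'
#' Expects the 12 LUH2 fraction variables on a regular lon-lat grid with a
#' `time` dimension holding calendar years. Latitude order may be ascending or
#' descending; cells are stored row-major from the south-west corner. The
#' per-cell land fraction is taken as the sum of the 12 fractions and must be
#' constant over time within 1e-6.
#'
#' @param path Path to the NetCDF file.
#' @return A lon-lat [LandUseGrid-class].
#' @export
readLandUseGrid <- function(path) {
  nc <- tryCatch(
    ncdf4::nc_open(path),
    error = function(e) .err("ecodivIOError", "cannot open '%s': %s",
                             path, conditionMessage(e))
  )
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  missing <- setdiff(.LUH2_TYPES, names(nc$var))
  if (length(missing)) {
    .err("ecodivSchemaError", "not a LUH2 states file: missing variable(s) %s",
         paste(missing, collapse = ", "))
  }
  lon <- nc$dim$lon$vals
  lat <- nc$dim$lat$vals
  years <- as.integer(round(nc$dim$time$vals))
  flipLat <- length(lat) > 1L && lat[1L] > lat[2L]
  if (flipLat) lat <- rev(lat)
  edgesFrom <- function(centers) {
    if (length(centers) == 1L) {
      step <- 0.25
    } else {
      steps <- diff(centers)
      if (max(abs(steps - steps[1L])) > 1e-6) {
        .err("ecodivSchemaError", "grid spacing is not uniform")
      }
      step <- steps[1L]
    }
    c(centers - step / 2, centers[length(centers)] + step / 2)
  }
  lonEdges <- edgesFrom(lon)
  latEdges <- edgesFrom(lat)
  nx <- length(lon)
  ny <- length(lat)
  nYears <- length(years)
  fractions <- lapply(.LUH2_TYPES, function(v) {
    a <- ncdf4::ncvar_get(nc, v, collapse_degen = FALSE)
    a <- array(a, dim = c(nx, ny, nYears))
    if (flipLat) a <- a[, ny:1, , drop = FALSE]
    if (min(a) < -1e-6 || max(a) > 1 + 1e-6) {
      .err("ecodivDataError", "variable '%s' has fractions outside [0, 1]", v)
    }
    a[a < 0] <- 0
    a[a > 1] <- 1
    matrix(a, nrow = nx * ny, ncol = nYears)
  })
  names(fractions) <- .LUH2_TYPES
  tot <- Reduce(`+`, fractions)
  dev <- max(abs(tot - tot[, 1L]))
  if (dev > 1e-6) {
    .err("ecodivDataError",
         "land fraction (sum of states) varies over time by %.3g", dev)
  }
  LandUseGrid(
    fractions = fractions, years = years,
    xEdges = .projX(lonEdges), yEdges = .projY(latEdges),
    gridType = "lonlat", lonEdges = lonEdges, latEdges = latEdges
  )
}

#' Write a zone assignment table to CSV
#'
#' @param grid A [LandUseGrid-class] with zones assigned by [overlayZones()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeZoneAssignment <- function(grid, path) {
  utils::write.csv(zoneAssignment(grid), path, row.names = FALSE)
  invisible(path)
}
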