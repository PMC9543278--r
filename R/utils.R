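# Shared constants and low-level helpers.

# Authalic Earth radius (km): the sphere with the same surface area as the
# WGS84 ellipsoid, so projected cell areas integrate to the true land surface.
.EARTH_RADIUS_KM <- 6371.0072

# Cylindrical equal-area projection with standard parallel 0 degrees.
# x = R * lambda, y = R * sin(phi); any lon-lat rectangle maps to an
# axis-aligned rectangle whose area equals its true spherical area.
.projX <- function(lonDeg) .EARTH_RADIUS_KM * lonDeg * pi / 180
.projY <- function(latDeg) .EARTH_RADIUS_KM * sin(latDeg * pi / 180)
.invProjLon <- function(x) x / .EARTH_RADIUS_KM * 180 / pi
.invProjLat <- function(y) asin(pmin(1, pmax(-1, y / .EARTH_RADIUS_KM))) * 180 / pi

# Classed conditions so callers can distinguish parameter, schema, data,
# geometry, coverage, mapping, allocation and I/O failures.
.err <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ecodivError", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

.assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    .err("ecodivParameterError", "'%s' must be a single finite number", name)
  }
  invisible(x)
}

# Overlap lengths between two 1-D interval partitions given by their edges.
# O[i, j] = length of the intersection of target interval i and source
# interval j; exactly zero when intervals only touch.
.overlap1d <- function(targetEdges, sourceEdges) {
  nt <- length(targetEdges) - 1L
  ns <- length(sourceEdges) - 1L
  lo <- outer(targetEdges[-(nt + 1L)], sourceEdges[-(ns + 1L)], pmax)
  hi <- outer(targetEdges[-1L], sourceEdges[-1L], pmin)
  ov <- hi - lo
  ov[ov < 0] <- 0
  ov
}

# Sparse rectangle-overlap operator between two axis-aligned grids in
# projected coordinates. Cells are indexed row-major from the south-west
# corner (x fastest), so the operator is the Kronecker product of the 1-D
# y and x overlap matrices. Entries are overlap areas in km^2.
.overlapOperator <- function(targetX, targetY, sourceX, sourceY) {
  ox <- Matrix::Matrix(.overlap1d(targetX, sourceX), sparse = TRUE)
  oy <- Matrix::Matrix(.overlap1d(targetY, sourceY), sparse = TRUE)
  if (sum(ox) == 0 || sum(oy) == 0) {
    .err("ecodivGeometryError", "grids do not overlap in projected space")
  }
  kronecker(oy, ox)
}

# Sample n elements from x without replacement, robust to length(x) == 1.
.resample <- function(x, n) x[sample.int(length(x), n)]

# Interdecile bounds with the inclusive linear-interpolation quantile
# definition (stats::quantile type 7).
.interdecile <- function(x) {
  stats::quantile(x, probs = c(0.1, 0.9), type = 7, names = FALSE, na.rm = TRUE)
}

# Deterministic fingerprint of a configuration object, recorded in output
# tables so reruns can be matched to their settings.
.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeBin(serialize(config, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}
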