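## Idealized spherical 10-10 electrode geometry.
##
## Electrodes live on the outer surface of the spherical head model.
## Coordinates: x toward the right preauricular point, y toward the nasion,
## z toward the vertex.  Positions are constructed from the 10-10 layout
## rules rather than tabulated: the circumferential ring is sampled every
## 18 degrees of azimuth, midline electrodes every 22.5 degrees of
## inclination, and intermediate electrodes are placed by equal-fraction
## great-circle interpolation between their midline and ring anchors.

## spherical -> cartesian; inclination i from vertex, azimuth a from nasion,
## positive toward the right ear (both degrees)
.sph2cart <- function(incl, azim) {
  i <- incl * pi / 180
  a <- azim * pi / 180
  c(sin(i) * sin(a), sin(i) * cos(a), cos(i))
}

## great-circle interpolation between unit vectors
.slerp <- function(p, q, f) {
  w <- acos(max(-1, min(1, sum(p * q))))
  if (w < 1e-12) return(p)
  (sin((1 - f) * w) * p + sin(f * w) * q) / sin(w)
}

.montage_unit_positions <- function() {
  ring <- function(az) .sph2cart(90, az)
  mid <- function(incl, back = FALSE) .sph2cart(incl, if (back) 180 else 0)
  pos <- list(
    Fp1 = ring(-18), Fp2 = ring(18),
    F7 = ring(-54), F8 = ring(54),
    T7 = ring(-90), T8 = ring(90),
    P7 = ring(-126), P8 = ring(126),
    O1 = ring(-162), O2 = ring(162), Oz = ring(180),
    Fz = mid(45), Cz = c(0, 0, 1), Pz = mid(45, TRUE),
    ## intermediate rows: slerp(midline anchor, ring anchor, fraction)
    AF3 = .slerp(.sph2cart(67.5, 0), ring(-36), 0.5),
    AF4 = .slerp(.sph2cart(67.5, 0), ring(36), 0.5),
    F3 = .slerp(mid(45), ring(-54), 0.5),
    F4 = .slerp(mid(45), ring(54), 0.5),
    FC1 = .slerp(.sph2cart(22.5, 0), ring(-72), 0.25),
    FC2 = .slerp(.sph2cart(22.5, 0), ring(72), 0.25),
    FC5 = .slerp(.sph2cart(22.5, 0), ring(-72), 0.75),
    FC6 = .slerp(.sph2cart(22.5, 0), ring(72), 0.75),
    C3 = .slerp(c(0, 0, 1), ring(-90), 0.5),
    C4 = .slerp(c(0, 0, 1), ring(90), 0.5),
    CP1 = .slerp(.sph2cart(22.5, 180), ring(-108), 0.25),
    CP2 = .slerp(.sph2cart(22.5, 180), ring(108), 0.25),
    CP5 = .slerp(.sph2cart(22.5, 180), ring(-108), 0.75),
    CP6 = .slerp(.sph2cart(22.5, 180), ring(108), 0.75),
    P3 = .slerp(mid(45, TRUE), ring(-126), 0.5),
    P4 = .slerp(mid(45, TRUE), ring(126), 0.5),
    PO3 = .slerp(.sph2cart(67.5, 180), ring(-144), 0.5),
    PO4 = .slerp(.sph2cart(67.5, 180), ring(144), 0.5)
  )
  m <- t(vapply(pos, function(p) p / sqrt(sum(p^2)), numeric(3)))
  colnames(m) <- c("x", "y", "z")
  m
}

#' Standard 32-channel 10-10 montage on the spherical head model
#'
#' Returns electrode positions on the scalp sphere (outer shell of the
#' head model, radius 0.10 m by default) for a 32-channel subset of the
#' 10-10 system, or for any subset of its labels.
#'
#' @param channels character vector of 10-10 labels to keep, in order.
#'   Default: all 32.
#' @param radius scalp sphere radius in meters.
#' @return matrix (channels x 3) of positions in meters, rownames = labels.
#' @examples
#' el <- montage_1010()
#' dim(el)
#' el["Cz", ]
#' @export
montage_1010 <- function(channels = NULL, radius = 0.10) {
  m <- .montage_unit_positions()
  ## canonical ordering: anterior to posterior, left to right
  order32 <- c("Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
               "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
               "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
               "PO3", "PO4", "O1", "Oz", "O2")
  m <- m[order32, , drop = FALSE]
  if (!is.null(channels)) {
    unknown <- setdiff(channels, rownames(m))
    if (length(unknown))
      stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
    m <- m[channels, , drop = FALSE]
  }
  m * radius
}
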