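#' Hemisegment geometry
#'
#' Describes the bounding box, axis conventions and midline of a single
#' abdominal hemisegment of the larval ventral nerve cord. Coordinates are
#' right-handed and in micrometers: axis 1 is medial-lateral (x), axis 2 is
#' dorsal-ventral (y), axis 3 is anterior-posterior (z). The origin sits at
#' the anterior-dorsal-medial corner, so the midline plane is the medial face
#' of the box (x = origin for a left hemisegment). A right hemisegment
#' occupies the mirror box on the other side of the midline: reflecting it
#' across the midline reproduces the corresponding left geometry.
#'
#' @param length_ml medial-lateral extent (um), > 0
#' @param height_dv dorsal-ventral extent (um), > 0
#' @param depth_ap anterior-posterior extent (um), > 0
#' @param side `"left"` or `"right"`
#' @param origin 3-vector (um); the anterior-dorsal-medial corner
#' @param neuropil_exponent superellipsoid exponent of the neuropil outline
#'   inscribed in the box (2 = ellipsoid; larger values are boxier)
#' @return an object of class `hemisegment_geometry` with elements
#'   `length_ml`, `height_dv`, `depth_ap`, `side`, `origin`, `box` (2 x 3
#'   matrix of lower/upper corners), and `midline` (list with `normal` and
#'   `offset` such that the plane is `{p : p . normal = offset}`).
#' @examples
#' g <- make_geometry(20, 20, 20)
#' hemisegment_centroid(g)
#' @export
make_geometry <- function(length_ml, height_dv, depth_ap,
                          side = c("left", "right"),
                          origin = c(0, 0, 0),
                          neuropil_exponent = 2.5) {
  side <- match.arg(side)
  ext <- c(length_ml, height_dv, depth_ap)
  if (any(!is.finite(ext)) || any(ext <= 0)) {
    stop("hemisegment extents must be positive and finite", call. = FALSE)
  }
  if (length(origin) != 3 || any(!is.finite(origin))) {
    stop("origin must be a finite 3-vector", call. = FALSE)
  }
  origin <- as.numeric(origin)
  # medial face carries the midline; a right hemisegment extends to -x
  if (side == "left") {
    lower <- origin
    upper <- origin + ext
  } else {
    lower <- origin - c(ext[1], 0, 0)
    upper <- origin + c(0, ext[2], ext[3])
  }
  box <- rbind(lower = lower, upper = upper)
  colnames(box) <- c("ml", "dv", "ap")
  structure(
    list(
      length_ml = length_ml, height_dv = height_dv, depth_ap = depth_ap,
      side = side, origin = origin, box = box,
      midline = list(normal = c(1, 0, 0), offset = origin[1]),
      neuropil_exponent = neuropil_exponent
    ),
    class = "hemisegment_geometry"
  )
}

#' @export
print.hemisegment_geometry <- function(x, ...) {
  cat(sprintf(
    "<hemisegment_geometry> %s side, %.3g x %.3g x %.3g um (ml x dv x ap)\n",
    x$side, x$length_ml, x$height_dv, x$depth_ap
  ))
  invisible(x)
}

#' Hemisegment centroid
#'
#' The midpoint of the hemisegment's medial-lateral, dorsal-ventral and
#' anterior-posterior extents, in world coordinates. This is the anchor of
#' the centroid-frame ("manual registration") procedure.
#'
#' @param geometry a [make_geometry()] object
#' @return numeric 3-vector (um)
#' @export
hemisegment_centroid <- function(geometry) {
  stopifnot(inherits(geometry, "hemisegment_geometry"))
  as.numeric((geometry$box["lower", ] + geometry$box["upper", ]) / 2)
}

#' Reflect points across a plane
#'
#' @param points n x 3 matrix (or length-3 vector) of um coordinates
#' @param plane list with unit-ish `normal` and scalar `offset`
#'   (`{p : p . normal = offset}`)
#' @return reflected coordinates, same shape as the input
#' @export
reflect_points <- function(points, plane) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  n <- plane$normal / sqrt(sum(plane$normal^2))
  d <- plane$offset / sqrt(sum(plane$normal^2))
  s <- drop(p %*% n) - d
  out <- p - 2 * outer(s, n)
  if (is.null(dim(points))) drop(out) else out
}

#' Membership test for the neuropil outline
#'
#' The neuropil is modelled as an axis-aligned superellipsoid inscribed in
#' the hemisegment box (a smooth, boxy outline resembling the N-Cadherin
#' territory), with exponent taken from the geometry.
#'
#' @param points n x 3 matrix of um coordinates
#' @param geometry a [make_geometry()] object
#' @param shrink optional scale factor (< 1 shrinks the outline)
#' @return logical vector, TRUE when inside the neuropil
#' @export
point_in_neuropil <- function(points, geometry, shrink = 1) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  centre <- hemisegment_centroid(geometry)
  semi <- (geometry$box["upper", ] - geometry$box["lower", ]) / 2 * shrink
  e <- geometry$neuropil_exponent
  u <- abs(sweep(p, 2, centre, "-"))
  u <- sweep(u, 2, semi, "/")
  rowSums(u^e) <= 1
}

#' Rasterize the neuropil outline into a binary mask
#'
#' @param geometry a [make_geometry()] object
#' @param voxel_size length-3 voxel size (um); default matches the confocal
#'   acquisition (0.1 x 0.1 laterally, 0.22 axially)
#' @param shrink optional scale factor for the outline
#' @return a `neuropil_mask`: a [volume3d()] with logical data and a `side`
#' @export
make_neuropil_mask <- function(geometry, voxel_size = c(0.1, 0.1, 0.22),
                               shrink = 1) {
  v <- volume_grid(geometry, voxel_size)
  ctr <- voxel_centers(v)
  v$data <- array(point_in_neuropil(ctr, geometry, shrink = shrink), dim(v$data))
  class(v) <- c("neuropil_mask", class(v))
  v$side <- geometry$side
  v
}
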