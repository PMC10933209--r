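#' Periodic simulation cells
#'
#' A `box_spec` describes the periodic cell as three lattice vectors (the rows
#' of a 3x3 matrix, in Angstrom). Constructors are provided for the cell
#' shapes in common use: cubic, orthorhombic, truncated octahedron (the
#' triclinic cell with a = b = c and alpha = beta = gamma = 109.4712 degrees,
#' cos = -1/3, as used by AMBER octahedral boxes) and general triclinic.
#'
#' @param a,b,c Cell edge lengths in Angstrom.
#' @param lengths Numeric vector of the three edge lengths, Angstrom.
#' @param angles Numeric vector of the three cell angles alpha, beta, gamma
#'   in degrees.
#' @return An object of class `box_spec` with elements `shape`, `vectors`
#'   (3x3 matrix, rows = lattice vectors), `lengths` and `angles`.
#' @examples
#' box_volume(cubic_box(180))                 # 5.832e6 A^3
#' box_volume(truncated_octahedron_box(180))  # ~4.49e6 A^3 = 180^3 * sqrt(16/27)
#' @name box_spec
NULL

new_box_spec <- function(shape, vectors, lengths, angles) {
  vol <- abs(det(vectors))
  if (!is.finite(vol) || vol <= 1e-9)
    stop("degenerate box: lattice vectors must span positive volume")
  structure(list(shape = shape, vectors = vectors,
                 lengths = lengths, angles = angles),
            class = "box_spec")
}

#' @rdname box_spec
#' @export
cubic_box <- function(a) orthorhombic_box(a, a, a)

#' @rdname box_spec
#' @export
orthorhombic_box <- function(a, b, c) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  v <- diag(c(a, b, c))
  shape <- if (a == b && b == c) "cubic" else "orthorhombic"
  new_box_spec(shape, v, c(a, b, c), c(90, 90, 90))
}

#' @rdname box_spec
#' @export
truncated_octahedron_box <- function(a) {
  ang <- 109.4712206344907  # acos(-1/3) in degrees
  box <- triclinic_box(c(a, a, a), rep(ang, 3))
  box$shape <- "truncated_octahedron"
  box
}

#' @rdname box_spec
#' @export
triclinic_box <- function(lengths, angles) {
  stopifnot(length(lengths) == 3, length(angles) == 3)
  al <- angles[1] * pi / 180; be <- angles[2] * pi / 180; ga <- angles[3] * pi / 180
  a <- lengths[1]; b <- lengths[2]; c <- lengths[3]
  # standard crystallographic construction, a along x, b in the xy plane
  v <- matrix(0, 3, 3)
  v[1, ] <- c(a, 0, 0)
  v[2, ] <- c(b * cos(ga), b * sin(ga), 0)
  cx <- c * cos(be)
  cy <- c * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz2 <- c^2 - cx^2 - cy^2
  if (cz2 <= 0) stop("degenerate box: cell angles are inconsistent")
  v[3, ] <- c(cx, cy, sqrt(cz2))
  new_box_spec("triclinic", v, lengths, angles)
}

#' @export
print.box_spec <- function(x, ...) {
  cat(sprintf("<box_spec> %s; lengths %s A; angles %s deg; volume %.4g A^3\n",
              x$shape, paste(signif(x$lengths, 6), collapse = " x "),
              paste(signif(x$angles, 6), collapse = "/"), box_volume(x)))
  invisible(x)
}

as_box_matrix <- function(box) {
  if (inherits(box, "box_spec")) return(box$vectors)
  if (is.matrix(box) && all(dim(box) == c(3, 3))) return(box)
  stop("box must be a box_spec or a 3x3 matrix of lattice vectors")
}

#' Cell volume
#'
#' Scalar triple product of the lattice vectors. For a truncated octahedron
#' of edge parameter a this equals a^3 * sqrt(16/27).
#'
#' @param box A [box_spec] (or bare 3x3 lattice-vector matrix).
#' @return Volume in cubic Angstrom.
#' @export
box_volume <- function(box) {
  v <- abs(det(as_box_matrix(box)))
  if (v <= 1e-9) stop("degenerate box: lattice vectors must span positive volume")
  v
}

#' Minimum-image displacement between points in a periodic cell
#'
#' Returns the shortest displacement `b - a` over all periodic images.
#' Fractional-coordinate rounding supplies the candidate image; for
#' non-orthorhombic cells the 27 neighbouring images are searched as well,
#' which is exact for cells no more skewed than the truncated octahedron.
#'
#' @param box A [box_spec].
#' @param a,b Points as length-3 vectors or n x 3 matrices (Angstrom).
#' @return An n x 3 matrix of displacement vectors.
#' @export
minimum_image_displacement <- function(box, a, b) {
  m <- as_box_matrix(box)
  box_volume(m)  # validates
  a <- rbind(a); b <- rbind(b)
  storage.mode(a) <- "double"; storage.mode(b) <- "double"
  mi_disp_cpp(m, a, b)
}

#' @rdname minimum_image_displacement
#' @return `minimum_image_distance`: numeric vector of distances, Angstrom.
#' @export
minimum_image_distance <- function(box, a, b) {
  d <- minimum_image_displacement(box, a, b)
  sqrt(rowSums(d^2))
}

# perpendicular widths (face-to-face distances) of the cell
box_widths <- function(box) as.numeric(box_widths_cpp(as_box_matrix(box)))
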