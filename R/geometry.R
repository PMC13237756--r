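#' Convert spherical electrode angles to Cartesian unit vectors
#'
#' Angle convention: \code{theta} is the polar angle measured from the
#' superior (vertex) axis, \code{phi} the azimuth measured from the
#' right-lateral axis toward the anterior axis, both in degrees. The result
#' is (ml, ap, is) = (sin theta cos phi, sin theta sin phi, cos theta), a
#' unit vector with ML pointing right, AP anterior and IS superior.
#'
#' @param theta polar angle(s), degrees, in [0, 180]
#' @param phi azimuth(s), degrees, in [-180, 180]
#' @return numeric matrix (n x 3) with columns ml, ap, is
#' @examples
#' sphericalToCartesian(0, 0)     # vertex: (0, 0, 1)
#' sphericalToCartesian(90, 90)   # nasion direction: (0, 1, 0)
#' @export
sphericalToCartesian <- function(theta, phi) {
  if (length(theta) != length(phi))
    stop("theta and phi must have equal length", call. = FALSE)
  bad <- which(theta < 0 | theta > 180)
  if (length(bad))
    stop("theta out of [0, 180] degrees: ", theta[bad[1]], call. = FALSE)
  bad <- which(phi < -180 | phi > 180)
  if (length(bad))
    stop("phi out of [-180, 180] degrees: ", phi[bad[1]], call. = FALSE)
  # sinpi/cospi keep axis-aligned angles exact (sin(180 deg) == 0, not 1e-16)
  st <- sinpi(theta / 180); ct <- cospi(theta / 180)
  sp <- sinpi(phi / 180);   cp <- cospi(phi / 180)
  m <- cbind(ml = st * cp, ap = st * sp, is = ct)
  rownames(m) <- names(theta)
  m
}

#' Invert the Cartesian mapping back to spherical angles
#'
#' @param coords numeric matrix (n x 3) of unit vectors, columns ml/ap/is
#' @return data.frame with theta_deg, phi_deg (phi of the vertex is 0 by
#'   convention)
#' @export
cartesianToSpherical <- function(coords) {
  coords <- rbind(coords)
  is_ <- pmin(1, pmax(-1, coords[, 3]))
  theta <- acos(is_) * 180 / pi
  phi <- atan2(coords[, 2], coords[, 1]) * 180 / pi
  phi[theta < 1e-12] <- 0
  data.frame(theta_deg = theta, phi_deg = phi)
}

#' Great-circle (angular) distance between unit vectors
#'
#' @param a,b unit 3-vectors or n x 3 matrices
#' @return angular distance(s), radians
#' @export
greatCircleDistance <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  d <- rowSums(a * b)
  acos(pmin(1, pmax(-1, d)))
}

#' Construct an ElectrodeLayout from labels and spherical angles
#'
#' @param labels character channel names
#' @param theta,phi spherical angles, degrees (see
#'   \code{\link{sphericalToCartesian}})
#' @return an \linkS4class{ElectrodeLayout}
#' @export
electrodeLayout <- function(labels, theta, phi) {
  if (anyDuplicated(labels))
    stop("duplicate electrode labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  coords <- sphericalToCartesian(theta, phi)
  rownames(coords) <- labels
  new("ElectrodeLayout", labels = as.character(labels),
      theta = as.numeric(theta), phi = as.numeric(phi), coords = coords)
}

#' k-nearest-neighbor graph on a montage
#'
#' For each electrode, the k smallest great-circle distances to other
#' electrodes; ties broken by label order. Used for Hjorth Laplacian
#' interpolation.
#'
#' @param layout an \linkS4class{ElectrodeLayout}
#' @param k neighbors per electrode, 1 <= k <= n - 1
#' @return a \linkS4class{NeighborGraph}
#' @export
nearestNeighbors <- function(layout, k = 4) {
  n <- length(layout@labels)
  if (k < 1 || k > n - 1)
    stop("k must lie in [1, ", n - 1, "], got ", k, call. = FALSE)
  co <- layout@coords
  dots <- tcrossprod(co)
  ang <- acos(pmin(pmax(dots, -1), 1))
  nb <- matrix(0L, n, k)
  dist <- matrix(0, n, k)
  for (i in seq_len(n)) {
    d <- ang[i, ]
    ord <- order(d, seq_len(n))        # stable: ties by index (label order)
    ord <- ord[ord != i][seq_len(k)]
    nb[i, ] <- ord
    dist[i, ] <- d[ord]
  }
  new("NeighborGraph", labels = layout@labels, neighbors = nb,
      distances = dist)
}
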