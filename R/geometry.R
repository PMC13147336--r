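# Geometric primitives: plane fits, helix axes, dihedrals, superposition,
# centres of mass, Shrake-Rupley SASA. All coordinates in Angstrom, all
# angles in degrees.

#' Total-least-squares plane fit
#'
#' Fits a plane to \code{>= 3} non-collinear points by taking the smallest
#' principal component of the centred coordinates as the normal.
#'
#' @param points numeric \code{n x 3} matrix, \code{n >= 3}.
#' @param referenceUp optional 3-vector; when supplied, the normal is flipped
#'   so that \code{dot(normal, referenceUp) >= 0}.
#' @return list with \code{centroid}, \code{normal} (unit 3-vector) and
#'   \code{rmsResidual} (Angstrom).
#' @examples
#' sq <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0))
#' fitPlane(sq)$normal   # +-(0,0,1), residual 0
#' @export
fitPlane <- function(points, referenceUp = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    .stopf("degenerateGeometryError", "plane fit needs >= 3 points, got %d",
           nrow(points))
  ctr <- colMeans(points)
  x <- sweep(points, 2L, ctr)
  sv <- svd(x)
  # collinear: second singular value vanishes relative to the first
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1e-12))
    .stopf("degenerateGeometryError", "points are collinear; plane undefined")
  normal <- sv$v[, 3L]
  if (!is.null(referenceUp) && sum(normal * referenceUp) < 0) normal <- -normal
  res <- x %*% normal
  list(centroid = ctr, normal = as.numeric(normal),
       rmsResidual = sqrt(mean(res^2)))
}

#' Helix axis from C-alpha positions
#'
#' Estimates the axis of a short helix from ordered C-alpha positions using
#' local helix centres: within each window of 4 consecutive C-alphas the two
#' interior bisectors point toward the axis, giving local centre estimates;
#' a total-least-squares line is then fit through the centres. For 8--12
#' residue helices this is markedly less biased than a PCA of the raw
#' C-alphas, which is distorted by the helical winding. Collinear input
#' degrades gracefully to a direct line fit.
#'
#' @param ca numeric \code{n x 3} matrix of ordered C-alpha positions,
#'   \code{n >= 5}.
#' @return list with \code{point} (a point on the axis), \code{direction}
#'   (unit vector oriented N- to C-terminus) and \code{risePerResidue}
#'   (Angstrom).
#' @export
fitHelixAxis <- function(ca) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  if (n < 5L)
    .stopf("insufficientDataError",
           "helix axis fit needs >= 5 C-alpha positions, got %d", n)

  bisector <- function(i) {
    v1 <- ca[i - 1L, ] - ca[i, ]
    v2 <- ca[i + 1L, ] - ca[i, ]
    b <- v1 / .vnorm(v1) + v2 / .vnorm(v2)
    if (.vnorm(b) < 1e-8) return(NULL)   # locally straight
    .unit(b)
  }

  centers <- list()
  for (i in 2L:(n - 2L)) {
    u1 <- bisector(i)
    u2 <- bisector(i + 1L)
    if (is.null(u1) || is.null(u2)) next
    h <- .cross(u1, u2)
    if (.vnorm(h) < 1e-8) next
    h <- .unit(h)
    dp <- ca[i + 1L, ] - ca[i, ]
    if (sum(h * dp) < 0) h <- -h
    rise <- sum(h * dp)
    chord <- dp - rise * h
    dphi <- acos(max(-1, min(1, sum(u1 * u2))))
    if (dphi < 1e-6) next
    radius <- .vnorm(chord) / (2 * sin(dphi / 2))
    centers[[length(centers) + 1L]] <- ca[i, ] + radius * u1
    centers[[length(centers) + 1L]] <- ca[i + 1L, ] + radius * u2
  }

  if (length(centers) >= 2L) pts <- do.call(rbind, centers) else pts <- ca

  ctr <- colMeans(pts)
  x <- sweep(pts, 2L, ctr)
  sv <- svd(x)
  dir <- as.numeric(sv$v[, 1L])
  if (sum(dir * (ca[n, ] - ca[1L, ])) < 0) dir <- -dir

  proj <- as.numeric(ca %*% dir)
  rise <- mean(diff(proj))
  list(point = ctr, direction = dir, risePerResidue = rise)
}

#' Torsion (dihedral) angle of four points
#'
#' IUPAC sign convention: 0 for the cis (eclipsed) arrangement, 180 for
#' trans; positive angles are clockwise looking from p2 to p3. Result in
#' \code{(-180, 180]} degrees.
#'
#' @param p1,p2,p3,p4 3-vectors.
#' @return angle in degrees.
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (.vnorm(b1) < 1e-9 || .vnorm(b2) < 1e-9 || .vnorm(b3) < 1e-9)
    .stopf("degenerateGeometryError",
           "coincident consecutive points; dihedral undefined")
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .unit(b2))
  ang <- .rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
  .wrap180(ang)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of \code{mobile} onto \code{reference} with a
#' proper rotation (det +1) found by SVD of the cross-covariance matrix.
#' The aligned coordinates are \code{mobile \%*\% rotation + translation}
#' (row-vector convention, translation recycled over rows).
#'
#' @param reference,mobile paired \code{n x 3} matrices, \code{n >= 3}.
#' @return list with \code{rotation} (3x3, det +1), \code{translation}
#'   (3-vector) and \code{rmsd} (Angstrom).
#' @export
superpose <- function(reference, mobile) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  if (nrow(reference) != nrow(mobile))
    .stopf("degenerateGeometryError", "point lists must be paired")
  if (nrow(reference) < 3L)
    .stopf("degenerateGeometryError", "superposition needs >= 3 point pairs")
  cr <- colMeans(reference); cm <- colMeans(mobile)
  Q <- sweep(reference, 2L, cr)
  P <- sweep(mobile, 2L, cm)
  if (max(abs(P)) < 1e-9 || max(abs(Q)) < 1e-9)
    .stopf("degenerateGeometryError", "all points coincident")
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  aligned <- P %*% R
  rmsd <- sqrt(mean(rowSums((aligned - Q)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% R), rmsd = rmsd)
}

#' Ensemble RMSD to the iterative mean structure
#'
#' Superposes all models onto model 1, computes the mean coordinates,
#' re-superposes every model onto the mean and iterates until the mean moves
#' by less than \code{tol}; reports the mean and standard deviation of the
#' per-model RMSDs to the converged mean structure. This is the usual "RMSD
#' of the bundle" convention for NMR ensembles.
#'
#' @param ensemble a [StructureEnsemble-class] with \code{>= 2} models.
#' @param spec a [SelectionSpec-class] choosing the atoms (e.g. main chain).
#' @param tol convergence threshold on the mean-structure shift (Angstrom).
#' @return list with \code{mean}, \code{sd}, \code{perModel} (numeric vector)
#'   and \code{meanStructure} (\code{n x 3}).
#' @export
ensembleRMSD <- function(ensemble, spec = selectionSpec(), tol = 1e-4) {
  stopifnot(is(ensemble, "StructureEnsemble"))
  if (nModels(ensemble) < 2L)
    .stopf("insufficientDataError", "ensemble RMSD needs >= 2 models")
  idx <- selectAtoms(ensemble, spec)
  nm <- nModels(ensemble)
  mats <- lapply(seq_len(nm), function(m) modelCoords(ensemble, m)[idx, , drop = FALSE])

  ref <- mats[[1L]]
  aligned <- lapply(mats, function(x) {
    s <- superpose(ref, x)
    x %*% s$rotation + matrix(s$translation, nrow(x), 3L, byrow = TRUE)
  })
  meanS <- Reduce(`+`, aligned) / nm
  repeat {
    aligned <- lapply(mats, function(x) {
      s <- superpose(meanS, x)
      x %*% s$rotation + matrix(s$translation, nrow(x), 3L, byrow = TRUE)
    })
    newMean <- Reduce(`+`, aligned) / nm
    shift <- sqrt(mean(rowSums((newMean - meanS)^2)))
    meanS <- newMean
    if (shift < tol) break
  }
  per <- vapply(aligned, function(x) sqrt(mean(rowSums((x - meanS)^2))),
                numeric(1L))
  list(mean = mean(per), sd = stats::sd(per), perModel = per,
       meanStructure = meanS)
}

#' Centre of mass
#'
#' @param positions numeric \code{n x 3} matrix.
#' @param elements character vector of element symbols (needed for mass
#'   weighting).
#' @param weighting \code{"mass"} (standard atomic weights) or
#'   \code{"geometric"} (unweighted mean).
#' @return 3-vector.
#' @export
centerOfMass <- function(positions, elements = NULL,
                         weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  positions <- as.matrix(positions)
  if (nrow(positions) < 1L)
    .stopf("emptySelectionError", "centre of mass of an empty atom set")
  if (weighting == "geometric") return(colMeans(positions))
  if (is.null(elements))
    .stopf("elementError", "mass weighting requires element symbols")
  w <- atomicMass(elements)
  as.numeric(crossprod(positions, w) / sum(w))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Places \code{nSpherePoints} quasi-uniform points on a sphere of radius
#' \code{r_atom + probeRadius} around each reported atom and counts the
#' fraction not occluded by any neighbouring expanded sphere. Occluding
#' context is the whole model; reported atoms are the selection.
#'
#' @param coords numeric \code{n x 3} matrix of all model atoms (context).
#' @param radii numeric vector of van der Waals radii for all atoms
#'   (Angstrom); see [vdwRadius()].
#' @param reportIndex integer indices of atoms whose areas are reported
#'   (default: all).
#' @param probeRadius probe radius in Angstrom (water: 1.4).
#' @param nSpherePoints number of test points per atom (>= 100).
#' @return list with \code{perAtom} (named by index, Angstrom^2) and
#'   \code{total}.
#' @export
shrakeRupleySASA <- function(coords, radii, reportIndex = NULL,
                             probeRadius = 1.4, nSpherePoints = 960L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(radii) != n)
    .stopf("radiusAssignmentError",
           "need one radius per atom (%d radii for %d atoms)", length(radii), n)
  if (anyNA(radii))
    .stopf("radiusAssignmentError", "atom without an assigned radius")
  if (nSpherePoints < 100L)
    .stopf("validationError", "nSpherePoints must be >= 100")
  if (is.null(reportIndex)) reportIndex <- seq_len(n)
  sp <- .spherePoints(as.integer(nSpherePoints))
  rExp <- radii + probeRadius
  out <- numeric(length(reportIndex))
  for (k in seq_along(reportIndex)) {
    i <- reportIndex[k]
    ri <- rExp[i]
    pts <- sweep(sp * ri, 2L, coords[i, ], `+`)
    dc <- sqrt(rowSums(sweep(coords, 2L, coords[i, ])^2))
    nb <- which(dc < ri + rExp & seq_len(n) != i)
    free <- rep(TRUE, nrow(pts))
    for (j in nb) {
      if (!any(free)) break
      d2 <- rowSums(sweep(pts[free, , drop = FALSE], 2L, coords[j, ])^2)
      free[free] <- d2 >= rExp[j]^2
    }
    out[k] <- 4 * pi * ri^2 * mean(free)
  }
  names(out) <- as.character(reportIndex)
  list(perAtom = out, total = sum(out))
}
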