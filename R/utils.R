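# Internal vector/rotation helpers shared across modules.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}

.cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

## Rotation matrix for a right-handed rotation by `angle` degrees about `axis`
## (Rodrigues). Applied to row-vector coordinates as x %*% t(R), or x %*% R for
## the inverse; we consistently use `coords %*% t(R)`.
.rotationMatrix <- function(axis, angle) {
  u <- .unit(axis)
  th <- .deg2rad(angle)
  ct <- cos(th); st <- sin(th)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3L, 3L, byrow = TRUE)
  diag(3L) * ct + st * K + (1 - ct) * (u %o% u)
}

.applyRotation <- function(coords, R) coords %*% t(R)

## Fold an angle in degrees into (-180, 180].
.wrap180 <- function(x) {
  x <- ((x + 180) %% 360) - 180
  ifelse(x <= -180, x + 360, ifelse(x == -180, 180, x))
}

## Fold an axis-type angle (sign of direction irrelevant) into (-90, 90].
.wrap90 <- function(x) {
  x <- .wrap180(x)
  x[x > 90] <- x[x > 90] - 180
  x[x <= -90] <- x[x <= -90] + 180
  x
}

## Circular mean/sd (degrees) for torsion-angle aggregation.
.circularMean <- function(x) {
  r <- .deg2rad(x)
  .rad2deg(atan2(mean(sin(r)), mean(cos(r))))
}

.circularSd <- function(x) {
  m <- .circularMean(x)
  dev <- .wrap180(x - m)
  sqrt(sum(dev^2) / max(1L, length(dev) - 1L))
}

## NeRF atom placement: position of atom D given A, B, C, the C-D bond length
## (Angstrom), the B-C-D bond angle and the A-B-C-D dihedral (degrees, IUPAC).
.placeAtom <- function(a, b, c, bond, angle, dihedral) {
  th <- .deg2rad(angle)
  ph <- .deg2rad(dihedral)
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), -sin(th) * sin(ph))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

## Deterministic quasi-uniform points on the unit sphere (golden-spiral).
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

## A seed stream derived from one user seed; keeps derived seeds < 2^31.
.deriveSeeds <- function(seed, n) {
  (as.numeric(seed) * 7919 + 104729 * seq_len(n)) %% 2147483647
}

.stopf <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "mimochromeError",
                                                   "error", "condition")))
}
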