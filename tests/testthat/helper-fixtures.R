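# Shared fixtures and independent oracles, all built in code.

## a small jitter-free sandwich, cached across tests
.sandwich0 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- assembleSandwich(
        sandwichBlueprint(targetInterhelicalAngle = 64, targetThetaHis = 20,
                          metalOffset = 7.0, jitterSd = 0, nModels = 1L))
    cache
  }
})

## brute-force rigid superposition: random-quaternion search over rotations,
## translation absorbed by centering. Independent of the SVD route.
bruteForceRmsd <- function(reference, mobile, nSamples = 200000L, seed = 7L) {
  set.seed(seed)
  Q <- sweep(reference, 2L, colMeans(reference))
  P <- sweep(mobile, 2L, colMeans(mobile))
  H <- crossprod(P, Q)
  sp <- sum(P^2); sq <- sum(Q^2); n <- nrow(P)
  q <- matrix(stats::rnorm(4L * nSamples), ncol = 4L)
  q <- q / sqrt(rowSums(q^2))
  a <- q[, 1L]; b <- q[, 2L]; c <- q[, 3L]; d <- q[, 4L]
  # tr(R' H) expanded over quaternion rotation-matrix entries
  tr <- (a^2 + b^2 - c^2 - d^2) * H[1, 1] +
    2 * (b * c - a * d) * H[2, 1] + 2 * (b * d + a * c) * H[3, 1] +
    2 * (b * c + a * d) * H[1, 2] + (a^2 - b^2 + c^2 - d^2) * H[2, 2] +
    2 * (c * d - a * b) * H[3, 2] +
    2 * (b * d - a * c) * H[1, 3] + 2 * (c * d + a * b) * H[2, 3] +
    (a^2 - b^2 - c^2 + d^2) * H[3, 3]
  sqrt(pmax(0, (sp + sq - 2 * max(tr)) / n))
}

## closed-form accessible area of two overlapping probe-expanded spheres
twoSphereSASA <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  h1 <- (R2^2 - (d - R1)^2) / (2 * d)
  h2 <- (R1^2 - (d - R2)^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h1 + 4 * pi * R2^2 - 2 * pi * R2 * h2
}

randomRotation <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4L); q <- q / sqrt(sum(q^2))
  a <- q[1L]; b <- q[2L]; c <- q[3L]; d <- q[4L]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3L, 3L, byrow = TRUE)
}

rotateEnsemble <- function(ensemble, R, shift = c(0, 0, 0)) {
  for (m in seq_len(nModels(ensemble)))
    ensemble@coords[, , m] <- ensemble@coords[, , m] %*% t(R) +
      matrix(shift, nAtoms(ensemble), 3L, byrow = TRUE)
  ensemble
}
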