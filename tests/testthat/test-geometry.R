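# Geometric primitives: plane/axis fits, dihedrals, superposition, centre
# of mass, Shrake-Rupley SASA.

test_that("plane fit recovers exact and noisy planes", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  p <- fitPlane(sq)
  expect_equal(abs(p$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(p$rmsResidual, 0, tolerance = 1e-12)

  tri <- rbind(c(0, 0, 1), c(2, 0, 3), c(0, 5, -1))
  expect_equal(fitPlane(tri)$rmsResidual, 0, tolerance = 1e-9)

  # Monte-Carlo: points on a known tilted plane + N(0, 0.05 A) noise
  set.seed(11)
  n0 <- c(1, 2, 2) / 3
  basis <- svd(diag(3) - n0 %o% n0)$u[, 1:2]
  pts <- matrix(stats::runif(200, -3, 3), 100, 2) %*% t(basis) +
    matrix(stats::rnorm(300, 0, 0.05), 100, 3)
  rec <- fitPlane(pts, referenceUp = n0)
  ang <- acos(min(1, sum(rec$normal * n0))) * 180 / pi
  expect_lt(ang, 2)

  expect_error(fitPlane(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
               class = "degenerateGeometryError")
  # normal sign follows the supplied reference direction
  expect_gte(sum(fitPlane(sq, referenceUp = c(0, 0, -1))$normal *
                   c(0, 0, -1)), 0)
})

test_that("dihedral angle follows the IUPAC convention and round-trips", {
  p2 <- c(0, 1, 0); p3 <- c(0, 0, 0)
  expect_equal(dihedralAngle(c(1, 1, 0), p2, p3, c(1, 0, 0)), 0)
  expect_equal(dihedralAngle(c(1, 1, 0), p2, p3, c(-1, 0, 0)), 180)

  # side chain built at chi1 = -157 comes back exactly
  h <- buildIdealHelix(c("ALA", "LEU", "ALA"), -57, -47,
                       chi = list("2" = c(chi1 = -157, chi2 = 82)))
  sc <- sideChainChi(h, 1, "T", 2)
  expect_equal(sc$chi1, -157, tolerance = 1e-6)
  expect_equal(sc$chi2, 82, tolerance = 1e-6)

  expect_error(dihedralAngle(p2, p2, p3, c(1, 0, 0)),
               class = "degenerateGeometryError")
})

test_that("helix axis fit gives the canonical rise and is equivariant", {
  h <- buildIdealHelix(rep("ALA", 12), -57, -47)
  ca <- modelCoords(h, 1)[atoms(h)$atom == "CA", ]
  ax <- fitHelixAxis(ca)
  expect_equal(ax$risePerResidue, 1.5, tolerance = 0.1)

  R <- randomRotation(3)
  axR <- fitHelixAxis(ca %*% t(R))
  expect_equal(axR$direction, as.numeric(R %*% ax$direction),
               tolerance = 1e-6)

  # collinear points: direct line fit along the line
  line <- cbind(seq(0, 10, length.out = 6), 0, 0)
  axL <- fitHelixAxis(line)
  expect_equal(abs(axL$direction), c(1, 0, 0), tolerance = 1e-9)

  expect_error(fitHelixAxis(ca[1:4, ]), class = "insufficientDataError")
})

test_that("superposition matches identity, rigid and brute-force cases", {
  set.seed(21)
  ref <- matrix(stats::rnorm(150), 50, 3)

  s0 <- superpose(ref, ref)
  expect_equal(s0$rmsd, 0, tolerance = 1e-12)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)

  R <- randomRotation(5)
  mob <- ref %*% t(R) + matrix(c(3, -2, 5), 50, 3, byrow = TRUE)
  s1 <- superpose(ref, mob)
  expect_lt(s1$rmsd, 1e-9)
  expect_equal(det(s1$rotation), 1, tolerance = 1e-9)

  # noisy case against the random-quaternion search oracle
  set.seed(22)
  mobN <- mob + matrix(stats::rnorm(150, 0, 0.5), 50, 3)
  s2 <- superpose(ref, mobN)
  oracle <- bruteForceRmsd(ref, mobN)
  expect_lt(abs(s2$rmsd - oracle) / oracle, 0.10)
  expect_lte(s2$rmsd, oracle + 1e-9)  # SVD optimum cannot be beaten

  # symmetry of the optimal rmsd
  expect_equal(superpose(ref, mobN)$rmsd, superpose(mobN, ref)$rmsd,
               tolerance = 1e-9)

  expect_error(superpose(ref[1:2, ], mob[1:2, ]),
               class = "degenerateGeometryError")
  expect_error(superpose(matrix(1, 4, 3), matrix(1, 4, 3)),
               class = "degenerateGeometryError")

  # cross-check the rotation against an established implementation
  fit <- suppressWarnings(
    bio3d::fit.xyz(as.numeric(t(ref)), as.numeric(t(mobN))))
  expect_equal(s2$rmsd,
               sqrt(mean(rowSums((matrix(fit, ncol = 3, byrow = TRUE) -
                                    ref)^2))),
               tolerance = 1e-6)
})

test_that("ensemble RMSD matches the small-sample jitter expectation", {
  bp <- sandwichBlueprint(jitterSd = 0, nModels = 3L)
  ens <- assembleSandwich(bp)
  r0 <- ensembleRMSD(ens)
  expect_equal(r0$mean, 0, tolerance = 1e-9)
  expect_equal(r0$sd, 0, tolerance = 1e-9)

  # per-coordinate N(0, sigma^2) jitter: per-model RMSD to the n-model mean
  # has expectation ~ sqrt(3) * sigma * sqrt((n-1)/n)
  sigma <- 0.3; n <- 20L
  ens2 <- assembleSandwich(sandwichBlueprint(jitterSd = sigma, nModels = n,
                                             seed = 4L))
  r <- ensembleRMSD(ens2, selectionSpec(atomNames = c("N", "CA", "C", "O")))
  expect_equal(r$mean, sqrt(3) * sigma * sqrt((n - 1) / n), tolerance = 0.15)
  expect_gt(r$sd, 0)
})

test_that("centre of mass handles weighting and errors", {
  expect_equal(centerOfMass(rbind(c(1, 0, 0), c(-1, 0, 0)),
                            c("C", "C")), c(0, 0, 0))
  expect_equal(centerOfMass(rbind(c(2, 3, 4)), "N"), c(2, 3, 4))
  z <- centerOfMass(rbind(c(0, 0, 0), c(0, 0, 1)), c("C", "O"))[3]
  expect_equal(z, 15.999 / (12.011 + 15.999), tolerance = 1e-6)
  expect_equal(centerOfMass(rbind(c(0, 0, 0), c(0, 0, 1)),
                            weighting = "geometric")[3], 0.5)
  expect_error(centerOfMass(rbind(c(0, 0, 0)), "XX"), class = "elementError")
})

test_that("Shrake-Rupley SASA matches sphere oracles and is monotone", {
  iso <- shrakeRupleySASA(matrix(0, 1, 3), 1.6, probeRadius = 1.4,
                          nSpherePoints = 960L)
  expect_equal(iso$total, 4 * pi * 3.0^2, tolerance = 0.01 * 4 * pi * 9)

  far <- shrakeRupleySASA(rbind(c(0, 0, 0), c(10, 0, 0)), c(1.6, 1.6))
  expect_equal(far$total, 2 * 4 * pi * 3.0^2, tolerance = 0.02 * 8 * pi * 9)

  # overlapping pair vs the closed-form two-sphere area
  ov <- shrakeRupleySASA(rbind(c(0, 0, 0), c(2, 0, 0)), c(1.6, 1.6))
  expect_equal(ov$total, twoSphereSASA(1.6, 1.6, 2), tolerance = 0.02 *
                 twoSphereSASA(1.6, 1.6, 2))

  # removing a context atom never decreases a reported atom's area
  tri <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 1.5, 0))
  full <- shrakeRupleySASA(tri, rep(1.6, 3), reportIndex = 1L)
  fewer <- shrakeRupleySASA(tri[-2, , drop = FALSE], rep(1.6, 2),
                            reportIndex = 1L)
  expect_gte(fewer$perAtom[[1]], full$perAtom[[1]])

  expect_error(shrakeRupleySASA(matrix(0, 1, 3), NA_real_),
               class = "radiusAssignmentError")
  expect_error(shrakeRupleySASA(matrix(0, 1, 3), 1.6, nSpherePoints = 50L),
               class = "validationError")
})

test_that("angles and distances are invariant under rigid transforms", {
  ens <- .sandwich0()
  R <- randomRotation(17)
  ensR <- rotateEnsemble(ens, R, shift = c(5, -3, 12))
  expect_equal(hisTheta(ensR, 1)$theta, hisTheta(ens, 1)$theta,
               tolerance = 1e-6)
  expect_equal(coToChainCoM(ensR, 1, "D"), coToChainCoM(ens, 1, "D"),
               tolerance = 1e-9)
  caT <- function(e) modelCoords(e, 1)[atoms(e)$chain == "T" &
                                         atoms(e)$atom == "CA", ]
  caD <- function(e) modelCoords(e, 1)[atoms(e)$chain == "D" &
                                         atoms(e)$atom == "CA", ]
  a0 <- interhelicalAngle(fitHelixAxis(caT(ens)), fitHelixAxis(caD(ens)))
  a1 <- interhelicalAngle(fitHelixAxis(caT(ensR)), fitHelixAxis(caD(ensR)))
  expect_equal(a1, a0, tolerance = 1e-6)
})
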