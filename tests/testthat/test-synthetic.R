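# Synthetic generators: ideal helices, the porphyrin template, sandwich
# assembly ground truth, NOE peaks, spectra.

test_that("ideal helix construction is exact and rejects bad input", {
  h <- buildIdealHelix(rep("ALA", 12), -57, -47)
  bd <- backboneDihedrals(h, 1, "T")
  expect_equal(bd$phi[-1], rep(-57, 11), tolerance = 1e-6)
  expect_equal(bd$psi[-12], rep(-47, 11), tolerance = 1e-6)

  one <- buildIdealHelix("ALA")
  bd1 <- backboneDihedrals(one, 1, "T")
  expect_true(all(is.na(bd1$phi)) && all(is.na(bd1$psi)))

  expect_error(buildIdealHelix(character()), class = "sequenceError")
  expect_error(buildIdealHelix(c("ALA", "ZZZ")), class = "sequenceError")

  # nonstandard residues build their side-chain topology
  hx <- buildIdealHelix(c("ALA", "AIB", "DAB", "ALA"), -57, -47)
  at <- atoms(hx)
  expect_true(all(c("CB1", "CB2") %in% at$atom[at$resno == 2]))
  expect_true(all(c("CG", "ND") %in% at$atom[at$resno == 3]))
})

test_that("the porphyrin template is planar with orthogonal N-N axes", {
  pt <- porphyrinTemplate()
  at <- atoms(pt); xyz <- modelCoords(pt, 1)
  topo <- topology(pt)
  ring <- xyz[at$atom %in% topo@ringAtoms, ]
  expect_lt(max(abs(fitPlane(ring)$rmsResidual)), 0.01)
  ax1 <- xyz[at$atom == "N23", ] - xyz[at$atom == "N21", ]
  ax2 <- xyz[at$atom == "N24", ] - xyz[at$atom == "N22", ]
  ang <- acos(abs(sum(ax1 * ax2)) / sqrt(sum(ax1^2) * sum(ax2^2))) * 180 / pi
  expect_equal(ang, 90, tolerance = 0.5)
  expect_equal(unname(xyz[at$atom == topo@metalAtom, ]), c(0, 0, 0))
  validObject(topo)
})

test_that("jitter-free assembly reproduces the blueprint exactly", {
  for (cfg in list(c(21, -33.4), c(64, 20), c(96, 35))) {
    bp <- sandwichBlueprint(targetInterhelicalAngle = cfg[1],
                            targetThetaHis = cfg[2], jitterSd = 0,
                            nModels = 1L)
    ens <- assembleSandwich(bp)
    truth <- ens@metadata$truth
    expect_equal(truth$interhelicalAngle, cfg[1], tolerance = 0.5)
    expect_equal(truth$thetaHis, cfg[2], tolerance = 0.5)
    expect_equal(truth$metalOffset, 7.7, tolerance = 0.05)
    # His NE2 sits at bonding distance from the metal
    at <- atoms(ens); xyz <- modelCoords(ens, 1)
    ne2 <- xyz[at$chain == "T" & at$resno == truth$hisResidue &
                 at$atom == "NE2", ]
    metal <- xyz[at$atom == topology(ens)@metalAtom & at$hetero, ]
    expect_equal(sqrt(sum((ne2 - metal)^2)), 2.0, tolerance = 1e-6)
  }
})

test_that("generators are deterministic given their seed", {
  bp <- sandwichBlueprint(jitterSd = 0.3, nModels = 5L, seed = 11L)
  e1 <- assembleSandwich(bp)
  e2 <- assembleSandwich(bp)
  expect_identical(e1@coords, e2@coords)

  p1 <- generateNoePeaks(e1, cutoff = 4.5, noiseCv = 0.1, seed = 3L)
  p2 <- generateNoePeaks(e2, cutoff = 4.5, noiseCv = 0.1, seed = 3L)
  expect_identical(p1, p2)

  g1 <- generateMossbauer(data.frame(delta = 0.4, deltaEQ = 1.5,
                                     gamma = 0.3, areaFraction = 1),
                          noiseSd = 0.01, seed = 5L)
  g2 <- generateMossbauer(data.frame(delta = 0.4, deltaEQ = 1.5,
                                     gamma = 0.3, areaFraction = 1),
                          noiseSd = 0.01, seed = 5L)
  expect_identical(g1$spectrum@signal, g2$spectrum@signal)
  expect_equal(g1$truth$doublets$delta, 0.4)
})

test_that("jittered ensembles have positive descriptor spread around the truth", {
  bp <- sandwichBlueprint(jitterSd = 0.3, nModels = 20L, seed = 1L)
  ens <- assembleSandwich(bp)
  dt <- describeEnsemble(ens, nSpherePoints = 120L)
  pm <- perModel(dt)
  expect_gt(stats::sd(pm$interhelical_angle), 0)
  expect_gt(stats::sd(pm$theta_his), 0)
  expect_equal(mean(pm$interhelical_angle), 21, tolerance = 3)
  expect_equal(mean(pm$co_to_com_distance), 7.7, tolerance = 0.2)
})

test_that("anchoring position drives the measured regioisomer pattern", {
  for (cfg in list(list(anchor = 18, theta = -33.4, isomer = "isomer_1"),
                   list(anchor = 2, theta = 35.1, isomer = "isomer_2"))) {
    bp <- sandwichBlueprint(tdAnchorPosition = cfg$anchor,
                            targetThetaHis = cfg$theta, jitterSd = 0,
                            nModels = 1L)
    ens <- assembleSandwich(bp)
    cp <- contactPattern(ens)
    iso <- assignRegioisomer(cp, topology(ens))
    expect_equal(iso$isomer, cfg$isomer)
    expect_equal(iso$tdAnchorPosition, cfg$anchor)
  }
})

test_that("NOE peak generation follows the r^-6 law with a cutoff", {
  df <- data.frame(chain = "A", resno = c(1L, 2L), resname = "ALA",
                   atom = c("HA", "HA"), element = "H", hetero = FALSE)
  d <- 3.3
  ens <- new("StructureEnsemble", atoms = df,
             coords = array(rbind(c(0, 0, 0), c(d, 0, 0)), dim = c(2, 3, 1)),
             topology = NULL, metadata = list())
  pk <- generateNoePeaks(ens, cutoff = 5, scale = 100, noiseCv = 0)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$intensity, 100 / d^6, tolerance = 1e-12)

  none <- generateNoePeaks(ens, cutoff = 2.0)
  expect_equal(nrow(none), 0L)
  expect_error(generateNoePeaks(ens, cutoff = 9), class = "validationError")
})

test_that("sterically impossible blueprints raise an assembly error", {
  bp <- sandwichBlueprint(metalOffset = 3.0, jitterSd = 0, nModels = 1L)
  expect_error(assembleSandwich(bp), class = "assemblyError")
})
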