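# Ensemble descriptors: interhelical angle, families, His theta, metal-CoM
# distance, rotamers, Ramachandran regions, H-bonds, conformational shifts.

test_that("interhelical angle spans [0, 180] and is symmetric", {
  ax <- function(d) list(direction = d / sqrt(sum(d^2)))
  expect_equal(interhelicalAngle(ax(c(0, 0, 1)), ax(c(0, 0, 1))), 0)
  expect_equal(interhelicalAngle(ax(c(0, 0, 1)), ax(c(0, 0, -1))), 180)
  a <- ax(c(1, 2, 3)); b <- ax(c(-2, 1, 0.5))
  expect_equal(interhelicalAngle(a, b), interhelicalAngle(b, a))
  expect_gt(interhelicalAngle(a, b), 0)
})

test_that("family clustering splits on a gap and labels deterministically", {
  one <- clusterFamilies(c(20, 21, 22, 23, 24.5))
  expect_equal(unique(one$labels), 1L)

  # bimodal 12 + 8 constructed sample (gap >> threshold)
  set.seed(8)
  v <- c(stats::rnorm(12, 60, 5), stats::rnorm(8, 95, 5))
  cl <- clusterFamilies(v)
  expect_equal(cl$families$n, c(12L, 8L))
  expect_equal(cl$families$mean[1], 60, tolerance = 6)
  expect_equal(cl$families$mean[2], 95, tolerance = 6)
  expect_equal(cl$labels[1:12], rep(1L, 12))   # larger family is family 1
  expect_identical(clusterFamilies(v), cl)     # deterministic
})

test_that("His theta matches construction, folds into (-90, 90], flips under reflection", {
  ens <- .sandwich0()  # built at theta = +20
  th <- hisTheta(ens, 1)
  expect_equal(th$theta, 20, tolerance = 0.5)
  expect_gt(th$theta, -90)
  expect_lte(th$theta, 90)

  # rigid-transform invariance is covered in the geometry tests; reflection
  # (a chirality flip) must flip the sign
  mir <- ens
  mir@coords[, 3, 1] <- -mir@coords[, 3, 1]
  expect_equal(hisTheta(mir, 1)$theta, -20, tolerance = 0.5)

  expect_error(hisTheta(ens, 1, hisChain = "D", hisResidue = 1),
               class = "topologyError")
})

test_that("generator ensembles recover blueprint theta and metal offset", {
  bp <- sandwichBlueprint(targetInterhelicalAngle = 64, targetThetaHis = 20,
                          metalOffset = 7.0, jitterSd = 0.3, nModels = 20L,
                          seed = 2L)
  ens <- assembleSandwich(bp)
  ms <- ensembleMean(ens)
  expect_equal(hisTheta(ms, 1)$theta, 20, tolerance = 2)
  expect_equal(coToChainCoM(ms, 1, "D"), 7.0, tolerance = 0.2)
  # jitter-free construction identity
  truth <- ens@metadata$truth
  expect_equal(truth$thetaHis, 20, tolerance = 0.5)
  expect_equal(truth$metalOffset, 7.0, tolerance = 0.05)
})

test_that("rotamer classification reproduces the worked examples", {
  expect_equal(classifyRotamer(-175, 64)$label, "tp")
  expect_equal(classifyRotamer(-80, 172)$label, "mt")
  expect_equal(classifyRotamer(60, 60)$label, "pp")
  expect_equal(classifyRotamer(-161, 170)$label, "tt")
  # circular nearest: -179 is closer to t (180) than to m (-60)
  expect_equal(classifyRotamer(-179, -50)$label, "tm")
})

test_that("backbone dihedrals round-trip the generator and respect termini", {
  h <- buildIdealHelix(rep("ALA", 8), -57, -47)
  bd <- backboneDihedrals(h, 1, "T")
  expect_true(is.na(bd$phi[1]))
  expect_true(is.na(bd$psi[nrow(bd)]))
  expect_equal(bd$phi[-1], rep(-57, 7), tolerance = 1e-6)
  expect_equal(bd$psi[-nrow(bd)], rep(-47, 7), tolerance = 1e-6)

  st <- backboneDihedralStats(h, "T", c(2, 7))
  expect_equal(st$phiMean, -57, tolerance = 1e-6)
  expect_equal(st$psiMean, -47, tolerance = 1e-6)

  # chain break: pull residues 5+ far away -> dihedrals absent at the break
  broken <- h
  at <- atoms(broken)
  sel <- at$resno >= 5
  broken@coords[sel, 1, 1] <- broken@coords[sel, 1, 1] + 50
  bdB <- backboneDihedrals(broken, 1, "T")
  expect_true(is.na(bdB$phi[5]))
  expect_true(is.na(bdB$psi[4]))
})

test_that("Ramachandran regions match worked examples and tile the grid", {
  expect_equal(unname(ramachandranRegion(-68, -36)), "favored")
  expect_equal(unname(ramachandranRegion(0, 0)), "disallowed")
  grid <- expand.grid(phi = seq(-175, 175, 10), psi = seq(-175, 175, 10))
  labs <- ramachandranRegion(grid$phi, grid$psi)
  expect_false(anyNA(labs))
  expect_true(all(labs %in% c("favored", "additionally_allowed",
                              "generously_allowed", "disallowed")))
})

test_that("hydrogen bonds obey geometric criteria and occupancy counts models", {
  # ideal linear N-H...O=C at 2.9 A donor-acceptor distance
  mk <- function(shift) {
    df <- data.frame(
      chain = c("A", "A", "A", "B", "B"),
      resno = c(1L, 1L, 1L, 2L, 2L),
      resname = "ALA",
      atom = c("N", "H", "CA", "O", "C"),
      element = c("N", "H", "C", "O", "C"),
      hetero = FALSE)
    xyz <- rbind(c(0, 0, 0), c(1.01, 0, 0), c(-0.7, 1.2, 0),
                 c(2.9 + shift, 0, 0), c(3.9 + shift, 0.6, 0))
    list(df = df, xyz = xyz)
  }
  m <- mk(0)
  ens1 <- new("StructureEnsemble", atoms = m$df,
              coords = array(m$xyz, dim = c(5, 3, 1)),
              topology = NULL, metadata = list())
  hb1 <- detectHBonds(ens1)
  expect_equal(nrow(hb1), 1L)
  expect_equal(hb1$occupancy, 1.0)
  expect_equal(hb1$meanDistance, 2.9, tolerance = 1e-6)

  far <- mk(1.6)  # 4.5 A: beyond the 3.5 A cutoff
  ensF <- new("StructureEnsemble", atoms = far$df,
              coords = array(far$xyz, dim = c(5, 3, 1)),
              topology = NULL, metadata = list())
  expect_equal(nrow(detectHBonds(ensF)), 0L)

  # 20-model ensemble where the contact holds in exactly 15 models
  co <- array(NA_real_, dim = c(5, 3, 20))
  for (k in 1:20) co[, , k] <- mk(if (k <= 15) 0 else 1.6)$xyz
  ens20 <- new("StructureEnsemble", atoms = m$df, coords = co,
               topology = NULL, metadata = list())
  hb20 <- detectHBonds(ens20)
  expect_equal(hb20$nPresent, 15L)
  expect_equal(hb20$occupancy, 0.75)
})

test_that("helical generator output shows the i,i+4 hydrogen-bond ladder", {
  h <- buildIdealHelix(rep("ALA", 10), -57, -47)
  hb <- suppressWarnings(detectHBonds(h))
  pairs <- paste(hb$donor, hb$acceptor)
  expect_true(all(grepl(":N .*:O$", pairs)))
  don <- as.integer(sub("^T(\\d+):N", "\\1", hb$donor))
  acc <- as.integer(sub("^T(\\d+):O", "\\1", hb$acceptor))
  expect_true(all(don - acc == 4L))
  expect_true(all(hb$occupancy == 1))
})

test_that("conformational shifts subtract random-coil values and flag direction", {
  obs <- data.frame(resno = 1:3, resname = c("LEU", "ALA", "GLY"),
                    nucleus = "HA", shift = c(4.34, 3.90, 4.10))
  cs <- conformationalShifts(obs)
  expect_equal(cs$shift, c(0, 3.90 - 4.32, 4.10 - 3.96), tolerance = 1e-9)
  expect_equal(cs$direction, c("coincident", "upfield", "downfield"))

  helical <- data.frame(resno = 1:5, resname = "ALA", nucleus = "HA",
                        shift = 4.32 - 0.3)
  expect_true(all(conformationalShifts(helical)$direction == "upfield"))
  expect_equal(unname(attr(conformationalShifts(helical), "summary")["upfield"]), 5L)

  bad <- data.frame(resno = 1, resname = "XXX", nucleus = "HA", shift = 4)
  expect_error(conformationalShifts(bad), class = "lookupError")
})

test_that("the descriptor table aggregates are recomputable from its rows", {
  ens <- assembleSandwich(sandwichBlueprint(jitterSd = 0.2, nModels = 10L,
                                            seed = 6L))
  dt <- describeEnsemble(ens, nSpherePoints = 120L)
  pm <- perModel(dt)
  ag <- aggregates(dt)
  expect_equal(nrow(pm), 10L)
  for (f in ag$family) {
    sub <- pm[pm$family == f, ]
    expect_equal(ag$interhelical_mean[ag$family == f],
                 mean(sub$interhelical_angle))
    expect_equal(ag$sasa_sd[ag$family == f], stats::sd(sub$porphyrin_sasa))
  }
  expect_true(all(pm$porphyrin_sasa > 0))
})
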