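# Maltempo admixed-spin analysis, Moessbauer simulation/fitting,
# spin-state classification.

test_that("Maltempo fraction reproduces the worked example and the pure limits", {
  expect_equal(maltempoFraction(gx = 5.92, gy = 3.56)$a52Squared, 0.37,
               tolerance = 1e-12)
  expect_equal(maltempoFraction(gPerp = 4)$a52Squared, 0)
  expect_equal(maltempoFraction(gPerp = 6)$a52Squared, 1)
  expect_true(maltempoFraction(gPerp = 6.3)$clamped)
  # monotone increasing in g_perp
  g <- seq(3.6, 6.4, by = 0.2)
  a <- vapply(g, function(x) maltempoFraction(gPerp = x)$a52Squared,
              numeric(1))
  expect_true(all(diff(a) >= 0))
  expect_error(maltempoFraction(gPerp = 3.2), class = "rangeError")
  expect_error(maltempoFraction(gPerp = 6.8), class = "rangeError")
  expect_error(maltempoFraction(gx = 5.9), class = "validationError")
})

test_that("simulated doublets place lines at delta +- deltaEQ/2", {
  v <- seq(-4, 4, length.out = 2001)
  one <- data.frame(delta = 0.42, deltaEQ = 1.47, gamma = 0.3,
                    areaFraction = 1)
  sp <- simulateMossbauer(one, v, totalDepth = 1, noiseSd = 0)
  pk <- v[order(sp@signal, decreasing = TRUE)[1:2]]
  expect_equal(sort(pk), c(0.42 - 1.47 / 2, 0.42 + 1.47 / 2),
               tolerance = 0.01)

  # degenerate splitting: one line of doubled depth at delta
  deg <- data.frame(delta = 0.4, deltaEQ = 0, gamma = 0.3, areaFraction = 1)
  spD <- simulateMossbauer(deg, v, 1, 0)
  expect_equal(v[which.max(spD@signal)], 0.4, tolerance = 0.01)
  expect_equal(max(spD@signal), 2 * max(sp@signal), tolerance = 0.02)

  expect_error(simulateMossbauer(one, seq(-1, 1, length.out = 100), 1, 0),
               class = "coverageError")
  expect_error(simulateMossbauer(transform(one, areaFraction = 0.8), v, 1, 0),
               class = "validationError")
})

test_that("integrated doublet areas follow the configured ratio", {
  # two doublets with disjoint velocity support: the half-axis integrals
  # are a numeric-integration oracle for the area fractions
  v <- seq(-8, 8, length.out = 8001)
  dd <- data.frame(delta = c(-3, 3), deltaEQ = c(1, 1), gamma = 0.2,
                   areaFraction = c(0.53, 0.47))
  sp <- simulateMossbauer(dd, v, 1, 0)
  dv <- diff(v)[1]
  left <- sum(sp@signal[v < 0]) * dv
  total <- sum(sp@signal) * dv
  expect_equal(left / total, 0.53, tolerance = 0.01)

  # and the same ratio with the solid-state regioisomer-1 linewidth/shape
  dd2 <- data.frame(delta = c(-3, 3), deltaEQ = c(1.47, 3.20), gamma = 0.30,
                    areaFraction = c(0.53, 0.47))
  sp2 <- simulateMossbauer(dd2, v, 1, 0)
  expect_equal(sum(sp2@signal[v < 0]) / sum(sp2@signal), 0.53,
               tolerance = 0.01)
})

test_that("fitting a noiseless single doublet recovers parameters exactly", {
  v <- seq(-4, 4, length.out = 512)
  one <- data.frame(delta = 0.42, deltaEQ = 1.47, gamma = 0.30,
                    areaFraction = 1)
  sp <- simulateMossbauer(one, v, 1, 0)
  fit <- fitMossbauer(sp, 1, init = one)
  tb <- doublets(fit)
  expect_equal(tb$delta, 0.42, tolerance = 1e-6)
  expect_equal(tb$deltaEQ, 1.47, tolerance = 1e-6)
  expect_equal(tb$gamma, 0.30, tolerance = 1e-6)
  expect_equal(tb$areaFraction, 1)
  expect_true(fit@converged)
})

test_that("two-doublet recovery at 1% noise meets the stated tolerances", {
  v <- seq(-4, 4, length.out = 512)
  truth <- data.frame(delta = c(0.42, 0.40), deltaEQ = c(1.47, 3.20),
                      gamma = 0.30, areaFraction = c(0.53, 0.47))
  sp <- simulateMossbauer(truth, v, totalDepth = 1, noiseSd = 0.01,
                          seed = 41L)
  fit <- fitMossbauer(sp, 2, seed = 41L)
  tb <- doublets(fit)   # ordered by ascending splitting
  expect_equal(tb$delta, c(0.42, 0.40), tolerance = 0.02)
  expect_equal(tb$deltaEQ, c(1.47, 3.20), tolerance = 0.05)
  expect_equal(100 * tb$areaFraction[1], 53, tolerance = 3)
  expect_equal(sum(tb$areaFraction), 1, tolerance = 1e-12)
})

test_that("simulate-fit round trip holds over random parameter sets", {
  v <- seq(-5, 5, length.out = 512)
  set.seed(1234)
  dErr <- qErr <- numeric(20)
  for (k in 1:20) {
    truth <- data.frame(
      delta = stats::runif(2, 0.2, 0.6),
      deltaEQ = sort(stats::runif(2, 0.6, 3.4)),
      gamma = stats::runif(1, 0.25, 0.40),
      areaFraction = NA)
    a <- stats::runif(1, 0.35, 0.65)
    truth$areaFraction <- c(a, 1 - a)
    # keep the two doublets separable by more than a linewidth
    truth$deltaEQ[2] <- max(truth$deltaEQ[2],
                            truth$deltaEQ[1] + 3 * truth$gamma[1])
    sp <- simulateMossbauer(truth, v, 1, noiseSd = 0.01, seed = 1000L + k)
    tb <- doublets(fitMossbauer(sp, 2, seed = k))
    dErr[k] <- max(abs(tb$delta - truth$delta))
    qErr[k] <- max(abs(tb$deltaEQ - truth$deltaEQ))
  }
  expect_lte(stats::median(dErr), 0.02)
  expect_lte(stats::median(qErr), 0.05)
})

test_that("near-degenerate doublets trigger an identifiability note", {
  v <- seq(-4, 4, length.out = 512)
  truth <- data.frame(delta = c(0.40, 0.42), deltaEQ = c(1.40, 1.55),
                      gamma = 0.30, areaFraction = c(0.5, 0.5))
  sp <- simulateMossbauer(truth, v, 1, noiseSd = 0.005, seed = 9L)
  fit <- fitMossbauer(sp, 2, init = truth)
  expect_true(length(fit@notes) > 0)
  expect_match(fit@notes[1], "identifiable")
})

test_that("spin-state classification matches the literature ranges", {
  expect_equal(classifySpinState(0.42, 1.47)$labels, "six_coord_HS")
  expect_equal(classifySpinState(0.40, 3.20)$labels, "QS_candidate")
  expect_equal(classifySpinState(1.30, 3.00)$labels, "unclassified")
  expect_equal(classifySpinState(0.30, 0.70)$labels, "five_coord_HS")
  # multiple matches are all reported (5c and 6c delta windows overlap)
  multi <- classifySpinState(0.40, 1.0,
                             ranges = data.frame(
                               label = c("a", "b"),
                               deltaMin = 0.3, deltaMax = 0.5,
                               eqMin = c(0.5, 0.9), eqMax = c(1.2, 2.0)))
  expect_setequal(multi$labels, c("a", "b"))
  # distances to non-matching ranges are reported and deterministic
  d <- classifySpinState(1.30, 3.00)$distances
  expect_true(all(d > 0))
  expect_identical(classifySpinState(1.30, 3.00),
                   classifySpinState(1.30, 3.00))
})

test_that("spectra round-trip through the two-column text format", {
  v <- seq(-4, 4, length.out = 256)
  sp <- simulateMossbauer(
    data.frame(delta = 0.4, deltaEQ = 1.5, gamma = 0.3, areaFraction = 1),
    v, 1, noiseSd = 0.01, seed = 2L)
  f <- withr::local_tempfile(fileext = ".dat")
  writeSpectrum(sp, f)
  back <- readSpectrum(f)
  expect_equal(back@velocity, sp@velocity, tolerance = 1e-9)
  expect_equal(back@signal, sp@signal, tolerance = 1e-9)
})
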