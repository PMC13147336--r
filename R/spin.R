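# Spin-state spectroscopy: Maltempo quantum-admixed-spin analysis from EPR
# g-values, zero-field Moessbauer quadrupole-doublet simulation and
# least-squares fitting, and spin-state classification from (delta, DeltaEQ).

#' Maltempo quantum-admixed spin fraction from perpendicular g-values
#'
#' For a quantum-mechanically admixed S = 3/2 / S = 5/2 state the weight of
#' the S = 5/2 component is \code{a52 = (g_perp - 4) / 2}, with
#' \code{g_perp} the arithmetic mean of the two perpendicular g-values when
#' a full g-set is supplied. The pure limits are \code{g_perp = 4}
#' (S = 3/2) and \code{g_perp = 6} (S = 5/2); values outside [3.5, 6.5] are
#' physically implausible for this treatment and rejected.
#'
#' @param gPerp perpendicular g-value, or omit and supply \code{gx},
#'   \code{gy}.
#' @param gx,gy the two perpendicular g-values of a full g-set.
#' @return list with \code{a52Squared} (clamped to [0, 1]),
#'   \code{gPerpUsed}, and \code{clamped} (logical flag).
#' @examples
#' maltempoFraction(gx = 5.92, gy = 3.56)$a52Squared  # 0.37
#' @export
maltempoFraction <- function(gPerp = NULL, gx = NULL, gy = NULL) {
  if (is.null(gPerp)) {
    if (is.null(gx) || is.null(gy))
      .stopf("validationError", "supply gPerp or both gx and gy")
    gPerp <- (gx + gy) / 2
  }
  if (gPerp < 3.5 || gPerp > 6.5)
    .stopf("rangeError",
           "g_perp = %.3f outside the physically plausible range [3.5, 6.5]",
           gPerp)
  raw <- (gPerp - 4) / 2
  a52 <- max(0, min(1, raw))
  list(a52Squared = a52, gPerpUsed = gPerp, clamped = !isTRUE(all.equal(raw, a52)))
}

## unit-height Lorentzian with FWHM gamma
.lorentz <- function(v, v0, gamma) {
  hw2 <- (gamma / 2)^2
  hw2 / ((v - v0)^2 + hw2)
}

## noiseless forward model: doublets is a data.frame(delta, deltaEQ, gamma,
## areaFraction). Line depth per doublet is proportional to
## areaFraction / gamma so that areaFraction is a true integrated-area
## fraction even with unequal linewidths; with a shared gamma this reduces
## to plain areaFraction weighting. Depth is normalized so that
## `totalDepth` is the summed depth coefficient.
.mossbauerModel <- function(velocity, doublets, totalDepth) {
  w <- doublets$areaFraction / doublets$gamma
  w <- w / sum(w)
  sig <- numeric(length(velocity))
  for (k in seq_len(nrow(doublets))) {
    d <- doublets[k, ]
    sig <- sig + totalDepth * w[k] *
      (.lorentz(velocity, d$delta - d$deltaEQ / 2, d$gamma) +
         .lorentz(velocity, d$delta + d$deltaEQ / 2, d$gamma)) / 2
  }
  sig
}

#' Simulate a zero-field Moessbauer spectrum of quadrupole doublets
#'
#' Each doublet contributes two equal-depth Lorentzian lines at
#' \code{delta +- deltaEQ/2} with shared FWHM \code{gamma}; doublets are
#' weighted by their integrated-area fractions (which must sum to 1) and
#' additive Gaussian noise is applied with the given seed. The signal is
#' the baseline-subtracted absorption depth (positive values = absorption).
#'
#' @param doublets data.frame with columns \code{delta}, \code{deltaEQ},
#'   \code{gamma}, \code{areaFraction} (mm/s; fractions sum to 1).
#' @param velocity monotone velocity grid (mm/s) covering every line
#'   \code{+- 3 gamma}.
#' @param totalDepth total absorption depth scale.
#' @param noiseSd additive noise standard deviation (same units as depth).
#' @param seed integer seed for the noise.
#' @return a [MossbauerSpectrum-class].
#' @export
simulateMossbauer <- function(doublets, velocity = seq(-4, 4, length.out = 512L),
                              totalDepth = 1.0, noiseSd = 0.0, seed = 1L) {
  doublets <- as.data.frame(doublets)
  need <- c("delta", "deltaEQ", "gamma", "areaFraction")
  stopifnot(all(need %in% names(doublets)))
  if (any(doublets$gamma <= 0))
    .stopf("validationError", "linewidths must be positive")
  if (any(doublets$deltaEQ < 0))
    .stopf("validationError", "quadrupole splittings must be >= 0")
  if (abs(sum(doublets$areaFraction) - 1) > 1e-9)
    .stopf("validationError", "area fractions must sum to 1")
  lines <- c(doublets$delta - doublets$deltaEQ / 2,
             doublets$delta + doublets$deltaEQ / 2)
  margin <- 3 * max(doublets$gamma)
  if (min(lines) - margin < min(velocity) ||
      max(lines) + margin > max(velocity))
    .stopf("coverageError",
           "velocity grid does not cover all lines +- 3 gamma")
  sig <- .mossbauerModel(velocity, doublets, totalDepth)
  if (noiseSd > 0) {
    set.seed(seed)
    sig <- sig + stats::rnorm(length(sig), 0, noiseSd)
  }
  new("MossbauerSpectrum", velocity = as.numeric(velocity),
      signal = sig, noiseSd = noiseSd)
}

#' Read / write two-column velocity spectra
#'
#' Plain text: velocity (mm/s) and signal, whitespace-separated, optional
#' header.
#'
#' @param path file path.
#' @return a [MossbauerSpectrum-class].
#' @export
readSpectrum <- function(path) {
  if (!file.exists(path)) .stopf("ioError", "file not found: %s", path)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (is.character(df[[1L]])) df <- df[-1L, , drop = FALSE]
  new("MossbauerSpectrum", velocity = as.numeric(df[[1L]]),
      signal = as.numeric(df[[2L]]), noiseSd = NA_real_)
}

#' @rdname readSpectrum
#' @param spectrum a [MossbauerSpectrum-class].
#' @export
writeSpectrum <- function(spectrum, path) {
  utils::write.table(
    data.frame(velocity = spectrum@velocity, signal = spectrum@signal),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fit quadrupole doublets to a Moessbauer spectrum
#'
#' Nonlinear least squares (Levenberg-Marquardt) on the Lorentzian-doublet
#' forward model plus a constant baseline. When no initial parameter sets
#' are given, a seeded multistart (default 20 starts with dispersed
#' splittings and shifts) is used and the best-converged solution kept.
#' Fitted area fractions are normalized to sum to 1 and doublets are
#' reported in ascending order of quadrupole splitting. Near-degenerate
#' doublets (splitting difference below the linewidth) are flagged as an
#' identifiability note.
#'
#' @param spectrum a [MossbauerSpectrum-class].
#' @param nDoublets number of doublets (1 to 3).
#' @param init optional data.frame like the \code{doublets} argument of
#'   [simulateMossbauer()] to start from.
#' @param nStarts multistart count when \code{init} is absent.
#' @param seed seed for the multistart dispersion.
#' @return a [MossbauerFit-class].
#' @export
fitMossbauer <- function(spectrum, nDoublets = 2L, init = NULL,
                         nStarts = 20L, seed = 1L) {
  stopifnot(is(spectrum, "MossbauerSpectrum"))
  nDoublets <- as.integer(nDoublets)
  if (!nDoublets %in% 1:3)
    .stopf("validationError", "nDoublets must be 1, 2 or 3")
  v <- spectrum@velocity; y <- spectrum@signal
  nPar <- 4L * nDoublets + 1L
  if (length(v) < 10L * nPar)
    .stopf("validationError",
           "need >= %d points for %d doublet(s), got %d", 10L * nPar,
           nDoublets, length(v))

  ## parameter vector: per doublet (delta, deltaEQ, log gamma, log weight),
  ## then baseline; depth is carried by the unnormalized weights
  predict_ <- function(p) {
    base <- p[nPar]
    s <- numeric(length(v))
    for (k in seq_len(nDoublets)) {
      q <- p[(4L * (k - 1L) + 1L):(4L * k)]
      g <- exp(q[3L]); wt <- exp(q[4L])
      s <- s + wt * (.lorentz(v, q[1L] - q[2L] / 2, g) +
                       .lorentz(v, q[1L] + q[2L] / 2, g)) / 2
    }
    s + base
  }
  resid_ <- function(p) y - predict_(p)

  span <- range(v)
  depth0 <- max(y) - stats::median(y)
  starts <- list()
  if (!is.null(init)) {
    init <- as.data.frame(init)
    w0 <- init$areaFraction / init$gamma
    w0 <- w0 * depth0 / sum(w0)
    p0 <- c(rbind(init$delta, init$deltaEQ, log(init$gamma),
                  log(pmax(w0, 1e-6)))[],
            stats::median(y))
    starts[[1L]] <- p0
  } else {
    set.seed(seed)
    for (s in seq_len(nStarts)) {
      p0 <- numeric(nPar)
      for (k in seq_len(nDoublets)) {
        p0[4L * (k - 1L) + 1L] <- stats::runif(1L, span[1L] / 4, span[2L] / 4)
        p0[4L * (k - 1L) + 2L] <- stats::runif(1L, 0.2, 0.8 * diff(span) / 2)
        p0[4L * (k - 1L) + 3L] <- log(stats::runif(1L, 0.15, 0.6))
        p0[4L * (k - 1L) + 4L] <- log(depth0 / nDoublets *
                                        stats::runif(1L, 0.5, 1.5))
      }
      p0[nPar] <- stats::median(y)
      starts[[s]] <- p0
    }
  }

  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500L, ptol = 1e-12, ftol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    .stopf("fitError", "no multistart converged")

  p <- best$fit$par
  tab <- data.frame(delta = numeric(nDoublets), deltaEQ = numeric(nDoublets),
                    gamma = numeric(nDoublets), weight = numeric(nDoublets))
  for (k in seq_len(nDoublets)) {
    q <- p[(4L * (k - 1L) + 1L):(4L * k)]
    tab$delta[k] <- q[1L]
    tab$deltaEQ[k] <- abs(q[2L])
    tab$gamma[k] <- exp(q[3L])
    tab$weight[k] <- exp(q[4L])
  }
  # integrated area of a doublet = weight * pi * gamma / 2
  area <- tab$weight * tab$gamma
  tab$areaFraction <- area / sum(area)
  tab <- tab[order(tab$deltaEQ), ]
  rownames(tab) <- NULL

  notes <- character()
  if (nDoublets >= 2L) {
    dq <- diff(sort(tab$deltaEQ))
    if (any(dq < max(tab$gamma)))
      notes <- c(notes, sprintf(
        "doublet splittings differ by less than the linewidth (min diff %.3f, max gamma %.3f): weakly identifiable",
        min(dq), max(tab$gamma)))
  }

  res <- resid_(p)
  new("MossbauerFit",
      doublets = tab[, c("delta", "deltaEQ", "gamma", "areaFraction")],
      baseline = p[nPar], totalDepth = sum(tab$weight),
      residualSd = stats::sd(res),
      converged = best$fit$info %in% 1:4, notes = notes)
}

#' Default spin-state classification ranges
#'
#' Literature ranges for ferric heme: five-coordinate high-spin
#' (\code{deltaEQ} 0.4-1.0, \code{delta} 0.25-0.43 mm/s), six-coordinate
#' high-spin (\code{deltaEQ} 1.22-2.07, \code{delta} 0.32-0.45 mm/s), and a
#' quantum-admixed-spin candidate window (high-spin-like \code{delta}
#' 0.25-0.45 with \code{deltaEQ} above 2.5 mm/s).
#'
#' @return data.frame with columns \code{label}, \code{deltaMin},
#'   \code{deltaMax}, \code{eqMin}, \code{eqMax}.
#' @export
spinStateRanges <- function() {
  data.frame(
    label = c("five_coord_HS", "six_coord_HS", "QS_candidate"),
    deltaMin = c(0.25, 0.32, 0.25),
    deltaMax = c(0.43, 0.45, 0.45),
    eqMin = c(0.40, 1.22, 2.50),
    eqMax = c(1.00, 2.07, Inf),
    stringsAsFactors = FALSE)
}

#' Classify the spin/coordination state from Moessbauer parameters
#'
#' Returns every matching label (never silently picking one when several
#' match) together with the distance of the point to each non-matching
#' range; "unclassified" when nothing matches.
#'
#' @param delta isomer shift, mm/s.
#' @param deltaEQ quadrupole splitting, mm/s.
#' @param ranges classification table (default [spinStateRanges()]).
#' @return list with \code{labels} (character) and \code{distances}
#'   (named numeric, 0 for matches).
#' @examples
#' classifySpinState(0.42, 1.47)$labels  # six_coord_HS
#' classifySpinState(0.40, 3.20)$labels  # QS_candidate
#' @export
classifySpinState <- function(delta, deltaEQ, ranges = spinStateRanges()) {
  distTo <- function(x, lo, hi) max(0, lo - x, x - hi)
  d <- vapply(seq_len(nrow(ranges)), function(i) {
    sqrt(distTo(delta, ranges$deltaMin[i], ranges$deltaMax[i])^2 +
           distTo(deltaEQ, ranges$eqMin[i], ranges$eqMax[i])^2)
  }, numeric(1L))
  names(d) <- ranges$label
  labels <- ranges$label[d == 0]
  if (!length(labels)) labels <- "unclassified"
  list(labels = labels, distances = d)
}
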