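# Per-model and ensemble descriptors: interhelical angle and family
# clustering, axial-His orientation angle theta, metal-to-chain
# centre-of-mass distance, porphyrin SASA, rotamers, Ramachandran regions,
# hydrogen bonds with occupancy, conformational shifts.

#' Interhelical angle between two oriented helix axes
#'
#' The angle between the two N-to-C oriented axis directions, in
#' \code{[0, 180]} degrees. Deliberately not folded to \code{[0, 90]}:
#' antiparallel packings are reported as obtuse angles.
#'
#' @param axisA,axisB axis objects from [fitHelixAxis()] (or any list with a
#'   unit \code{direction}).
#' @return angle in degrees.
#' @export
interhelicalAngle <- function(axisA, axisB) {
  d <- sum(.unit(axisA$direction) * .unit(axisB$direction))
  .rad2deg(acos(max(-1, min(1, d))))
}

#' Cluster per-model angle values into families
#'
#' 1-D single-linkage agglomeration: the sorted values are split into two
#' families iff the largest inter-point gap exceeds \code{gapThreshold},
#' otherwise all models form one family. The larger family receives label 1
#' (ties broken toward the lower mean).
#'
#' @param values numeric vector (degrees), length >= 2.
#' @param gapThreshold minimum gap (degrees) that separates families.
#' @return list with \code{labels} (integer per value) and \code{families}
#'   (data.frame: \code{family}, \code{n}, \code{mean}, \code{sd}).
#' @export
clusterFamilies <- function(values, gapThreshold = 20) {
  stopifnot(length(values) >= 2L)
  o <- order(values)
  gaps <- diff(values[o])
  labels <- rep(1L, length(values))
  if (length(gaps) && max(gaps) > gapThreshold) {
    cut <- which.max(gaps)
    grp <- c(rep(1L, cut), rep(2L, length(values) - cut))
    labels[o] <- grp
    n1 <- sum(grp == 1L); n2 <- sum(grp == 2L)
    m1 <- mean(values[labels == 1L]); m2 <- mean(values[labels == 2L])
    flip <- n2 > n1 || (n2 == n1 && m2 < m1)
    if (flip) labels <- 3L - labels
  }
  fams <- sort(unique(labels))
  families <- data.frame(
    family = fams,
    n = vapply(fams, function(f) sum(labels == f), integer(1L)),
    mean = vapply(fams, function(f) mean(values[labels == f]), numeric(1L)),
    sd = vapply(fams, function(f) stats::sd(values[labels == f]), numeric(1L)))
  list(labels = labels, families = families)
}

.porphyrinAtomIndex <- function(ensemble, names) {
  topo <- topology(ensemble)
  at <- atoms(ensemble)
  idx <- which(at$resname == topo@residueName & at$atom %in% names)
  idx[match(names, at$atom[idx])]
}

.imidazoleNames <- c("CG", "ND1", "CD2", "CE1", "NE2")

## ring protons are coplanar with the imidazole and extend its footprint;
## including them when present conditions the plane fit much better on
## noisy coordinates
.imidazolePlaneNames <- c(.imidazoleNames, "HD1", "HD2", "HE1", "HE2")

#' Coordinate-mean structure of an ensemble
#'
#' Per-atom mean coordinates over all models. Assumes the bundle is already
#' superposed (as deposited NMR ensembles and the synthetic generator's
#' output are); use [ensembleRMSD()]'s iterative mean when it is not.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @return a 1-model [StructureEnsemble-class].
#' @export
ensembleMean <- function(ensemble) {
  stopifnot(is(ensemble, "StructureEnsemble"))
  m <- apply(ensemble@coords, c(1L, 2L), mean)
  new("StructureEnsemble", atoms = ensemble@atoms,
      coords = array(m, dim = c(nrow(m), 3L, 1L)),
      topology = ensemble@topology,
      metadata = c(ensemble@metadata, list(meanOf = nModels(ensemble))))
}

#' Axial-histidine orientation angle theta
#'
#' Orientation of the axial His imidazole relative to the porphyrin frame:
#' the porphyrin plane is fit to the 24 macrocycle atoms and the imidazole
#' plane to the 5 ring atoms; the imidazole normal is projected onto the
#' porphyrin plane and theta is the signed acute angle from the N21-to-N23
#' reference axis to that projection. The sign follows the right-hand rule
#' about the porphyrin normal oriented toward the His-bearing side, and the
#' angle is folded into \code{(-90, 90]} (plane normals are sign-free).
#' Theta flips sign under reflection of the model, so it distinguishes the
#' two diastereomeric arrangements.
#'
#' @param ensemble a [StructureEnsemble-class] with a porphyrin topology.
#' @param model model index.
#' @param hisChain,hisResidue chain and residue number of the axial His.
#' @return list with \code{theta} (signed degrees), \code{porphyrinPlane},
#'   \code{imidazolePlane}, \code{referenceAxis}.
#' @export
hisTheta <- function(ensemble, model = 1L, hisChain = "T", hisResidue = 6L) {
  stopifnot(is(ensemble, "StructureEnsemble"))
  topo <- topology(ensemble)
  if (!is(topo, "PorphyrinTopology"))
    .stopf("topologyError", "ensemble has no porphyrin topology")
  at <- atoms(ensemble)
  xyz <- modelCoords(ensemble, model)

  ringIdx <- which(at$resname == topo@residueName & at$atom %in% topo@ringAtoms)
  if (length(ringIdx) < 3L)
    .stopf("topologyError", "porphyrin macrocycle atoms not found")
  n21 <- which(at$resname == topo@residueName & at$atom == "N21")
  n23 <- which(at$resname == topo@residueName & at$atom == "N23")
  if (length(n21) != 1L || length(n23) != 1L)
    .stopf("topologyError", "pyrrole nitrogens N21/N23 not found")

  ringOnly <- which(at$chain == hisChain & at$resno == hisResidue &
                      at$atom %in% .imidazoleNames)
  if (length(ringOnly) < 3L)
    .stopf("topologyError",
           "need >= 3 imidazole ring atoms for His %s%d, found %d",
           hisChain, hisResidue, length(ringOnly))
  imidIdx <- which(at$chain == hisChain & at$resno == hisResidue &
                     at$atom %in% .imidazolePlaneNames)

  porph <- fitPlane(xyz[ringIdx, , drop = FALSE])
  imid <- fitPlane(xyz[imidIdx, , drop = FALSE])

  # porphyrin normal oriented toward the His-bearing side
  np <- porph$normal
  if (sum(np * (imid$centroid - porph$centroid)) < 0) np <- -np

  h <- imid$normal
  tilt <- .rad2deg(acos(min(1, abs(sum(h * np)))))
  if (tilt < 10)
    .stopf("illDefinedOrientationError",
           "imidazole plane within 10 degrees of the porphyrin plane")

  proj <- h - sum(h * np) * np
  proj <- .unit(proj)
  ## N21 -> N23 reference axis; estimated through the centroids of the two
  ## opposite pyrrole rings when their atoms are present (same axis for an
  ## ideal macrocycle, far less sensitive to coordinate noise than the
  ## two bare nitrogen positions)
  pyrA <- which(at$resname == topo@residueName &
                  at$atom %in% c("N21", "C1", "C2", "C3", "C4"))
  pyrC <- which(at$resname == topo@residueName &
                  at$atom %in% c("N23", "C11", "C12", "C13", "C14"))
  ref <- if (length(pyrA) == 5L && length(pyrC) == 5L)
    .unit(colMeans(xyz[pyrC, , drop = FALSE]) -
            colMeans(xyz[pyrA, , drop = FALSE]))
  else .unit(xyz[n23, ] - xyz[n21, ])
  theta <- .rad2deg(atan2(sum(.cross(ref, proj) * np), sum(ref * proj)))
  list(theta = .wrap90(theta), porphyrinPlane = porph, imidazolePlane = imid,
       referenceAxis = ref)
}

#' Metal-to-chain centre-of-mass distance
#'
#' Euclidean distance between the central metal ion and the mass-weighted
#' centre of mass of a chain's backbone atoms.
#'
#' @param ensemble a [StructureEnsemble-class] with porphyrin topology.
#' @param model model index.
#' @param chain chain id (default the distal chain "D").
#' @param residueRange optional inclusive \code{c(lo, hi)}; default all.
#' @param backboneNames backbone atom names.
#' @return distance in Angstrom.
#' @export
coToChainCoM <- function(ensemble, model = 1L, chain = "D",
                         residueRange = NULL,
                         backboneNames = c("N", "CA", "C", "O")) {
  stopifnot(is(ensemble, "StructureEnsemble"))
  topo <- topology(ensemble)
  at <- atoms(ensemble)
  xyz <- modelCoords(ensemble, model)
  mi <- which(at$atom == topo@metalAtom & at$hetero)
  if (length(mi) != 1L)
    .stopf("topologyError", "metal atom %s not found", topo@metalAtom)
  keep <- at$chain == chain & at$atom %in% backboneNames
  if (!is.null(residueRange))
    keep <- keep & at$resno >= residueRange[1L] & at$resno <= residueRange[2L]
  idx <- which(keep)
  if (!length(idx))
    .stopf("emptySelectionError", "no backbone atoms selected on chain %s", chain)
  com <- centerOfMass(xyz[idx, , drop = FALSE], at$element[idx], "mass")
  .vnorm(xyz[mi, ] - com)
}

#' Classify a side-chain rotamer from chi1/chi2
#'
#' Each torsion is mapped to the nearest canonical staggered value on the
#' circle: \code{p} = +60, \code{t} = 180, \code{m} = -60 degrees (the
#' letter scheme of the penultimate rotamer library); the label concatenates
#' the chi1 and chi2 letters.
#'
#' @param chi1,chi2 torsion angles in degrees.
#' @return list with \code{chi1}, \code{chi2}, \code{label}.
#' @examples
#' classifyRotamer(-175, 64)$label  # "tp"
#' classifyRotamer(-80, 172)$label  # "mt"
#' @export
classifyRotamer <- function(chi1, chi2) {
  canon <- c(p = 60, t = 180, m = -60)
  pick <- function(chi) {
    d <- abs(.wrap180(chi - canon))
    names(canon)[which.min(d)]
  }
  list(chi1 = chi1, chi2 = chi2, label = paste0(pick(chi1), pick(chi2)))
}

#' Side-chain chi1/chi2 of one residue
#'
#' chi1 = N-CA-CB-CG (OG1/CG1 for Thr/Ile/Val), chi2 = CA-CB-CG-CD1/ND1/CD.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param model model index.
#' @param chain,resno residue address.
#' @return list with \code{chi1}, \code{chi2} (NA when atoms are missing)
#'   and \code{label} from [classifyRotamer()] when both are defined.
#' @export
sideChainChi <- function(ensemble, model = 1L, chain, resno) {
  at <- atoms(ensemble)
  xyz <- modelCoords(ensemble, model)
  get <- function(nm) {
    i <- which(at$chain == chain & at$resno == resno & at$atom %in% nm)
    if (length(i)) xyz[i[1L], ] else NULL
  }
  n <- get("N"); ca <- get("CA"); cb <- get("CB")
  g <- get(c("CG", "OG", "OG1", "CG1", "SG"))
  d <- get(c("CD", "CD1", "ND1", "OD1", "SD", "ND"))
  chi1 <- if (!is.null(n) && !is.null(ca) && !is.null(cb) && !is.null(g))
    dihedralAngle(n, ca, cb, g) else NA_real_
  chi2 <- if (!is.null(ca) && !is.null(cb) && !is.null(g) && !is.null(d))
    dihedralAngle(ca, cb, g, d) else NA_real_
  label <- if (!is.na(chi1) && !is.na(chi2))
    classifyRotamer(chi1, chi2)$label else NA_character_
  list(chi1 = chi1, chi2 = chi2, label = label)
}

#' Backbone phi/psi dihedrals of one chain
#'
#' Standard phi (C-, N, CA, C) and psi (N, CA, C, N+) torsions. Angles are
#' undefined (NA) at chain termini and across chain breaks (consecutive
#' residues are considered bonded when the C--N distance is < 2.0 Angstrom).
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param model model index.
#' @param chain chain id.
#' @return data.frame with \code{resno}, \code{phi}, \code{psi}.
#' @export
backboneDihedrals <- function(ensemble, model = 1L, chain) {
  at <- atoms(ensemble)
  xyz <- modelCoords(ensemble, model)
  res <- sort(unique(at$resno[at$chain == chain & !at$hetero]))
  if (!length(res))
    .stopf("emptySelectionError", "no residues on chain %s", chain)
  pos <- function(rn, nm) {
    i <- which(at$chain == chain & at$resno == rn & at$atom == nm)
    if (length(i)) xyz[i[1L], ] else NULL
  }
  bonded <- function(r1, r2) {
    c1 <- pos(r1, "C"); n2 <- pos(r2, "N")
    !is.null(c1) && !is.null(n2) && .vnorm(n2 - c1) < 2.0
  }
  out <- data.frame(resno = res, phi = NA_real_, psi = NA_real_)
  for (k in seq_along(res)) {
    rn <- res[k]
    n <- pos(rn, "N"); ca <- pos(rn, "CA"); cc <- pos(rn, "C")
    if (is.null(n) || is.null(ca) || is.null(cc)) next
    if (k > 1L && res[k - 1L] == rn - 1L && bonded(rn - 1L, rn)) {
      cp <- pos(rn - 1L, "C")
      if (!is.null(cp)) out$phi[k] <- dihedralAngle(cp, n, ca, cc)
    }
    if (k < length(res) && res[k + 1L] == rn + 1L && bonded(rn, rn + 1L)) {
      nn <- pos(rn + 1L, "N")
      if (!is.null(nn)) out$psi[k] <- dihedralAngle(n, ca, cc, nn)
    }
  }
  out
}

#' Circular phi/psi statistics over a residue range and the whole ensemble
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param chain chain id.
#' @param residueRange inclusive \code{c(lo, hi)}.
#' @return list with circular \code{phiMean}, \code{phiSd}, \code{psiMean},
#'   \code{psiSd} (degrees) pooled over residues and models.
#' @export
backboneDihedralStats <- function(ensemble, chain, residueRange) {
  phis <- c(); psis <- c()
  for (m in seq_len(nModels(ensemble))) {
    bd <- backboneDihedrals(ensemble, m, chain)
    bd <- bd[bd$resno >= residueRange[1L] & bd$resno <= residueRange[2L], ]
    phis <- c(phis, bd$phi[!is.na(bd$phi)])
    psis <- c(psis, bd$psi[!is.na(bd$psi)])
  }
  list(phiMean = .circularMean(phis), phiSd = .circularSd(phis),
       psiMean = .circularMean(psis), psiSd = .circularSd(psis))
}

#' Ramachandran region of a phi/psi pair
#'
#' Lookup in the packaged simplified PROCHECK-style 10x10 degree region
#' grid. Every cell maps to exactly one of \code{favored},
#' \code{additionally_allowed}, \code{generously_allowed},
#' \code{disallowed}.
#'
#' @param phi,psi backbone torsions in degrees (vectorized).
#' @return character vector of region labels.
#' @examples
#' ramachandranRegion(-68, -36)  # "favored"
#' ramachandranRegion(0, 0)      # "disallowed"
#' @export
ramachandranRegion <- function(phi, psi) {
  g <- .ramaGrid()
  cell <- function(x) pmax(-175, pmin(175, floor(.wrap180(x) / 10) * 10 + 5))
  code <- g$region[match(paste(cell(phi), cell(psi)), paste(g$phi, g$psi))]
  c(F = "favored", A = "additionally_allowed", G = "generously_allowed",
    D = "disallowed")[code]
}

## Ideal amide hydrogen on a backbone nitrogen: along the in-plane bisector
## opposite the two heavy-atom neighbours.
.buildAmideH <- function(n, cPrev, ca, bond = 1.01) {
  n + bond * .unit(.unit(n - cPrev) + .unit(n - ca))
}

#' Detect hydrogen bonds with ensemble occupancy
#'
#' Geometric criteria per model: donor-to-acceptor heavy-atom distance
#' \code{<= dMax} and D-H...A angle \code{>= angleMin}. Donors are N and O
#' atoms carrying a hydrogen; when hydrogens are absent they are built at
#' ideal geometry (amide N-H 1.01 Angstrom along the bisector of the two
#' heavy neighbours; rotatable hydroxyl O-H 0.96 Angstrom oriented toward
#' the candidate acceptor, i.e. hydroxyls are scored at their optimal
#' rotamer). Donors whose hydrogen cannot be built are skipped with a
#' warning. Identical donor/acceptor pairs are merged across models;
#' occupancy is the fraction of models in which the bond is present.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param dMax heavy-atom distance cutoff, Angstrom.
#' @param angleMin minimum D-H...A angle, degrees.
#' @return data.frame: donor/acceptor ids, mean distance and angle over the
#'   models where present, \code{nPresent}, \code{occupancy}.
#' @export
detectHBonds <- function(ensemble, dMax = 3.5, angleMin = 120) {
  at <- atoms(ensemble)
  nm <- nModels(ensemble)

  atomId <- function(i) paste0(at$chain[i], at$resno[i], ":", at$atom[i])
  isH <- at$element == "H"
  heavyN <- which(at$element == "N")
  # donor oxygens: rotatable hydroxyls only (carbonyls cannot donate)
  heavyO <- which(at$element == "O" & at$atom %in% c("OG", "OG1", "OH"))
  accIdx <- which(at$element == "O")  # carbonyl/carboxyl/hydroxyl/hydroxide

  found <- new.env(parent = emptyenv())
  skipped <- character()

  for (m in seq_len(nm)) {
    xyz <- modelCoords(ensemble, m)
    nearH <- function(i) {
      cand <- which(isH)
      if (!length(cand)) return(integer())
      d <- sqrt(rowSums(sweep(xyz[cand, , drop = FALSE], 2L, xyz[i, ])^2))
      cand[d < 1.3]
    }
    for (di in c(heavyN, heavyO)) {
      isO <- at$element[di] == "O"
      hs <- nearH(di)
      buildable <- FALSE
      if (!length(hs)) {
        if (!isO && at$atom[di] == "N") {
          cPrev <- which(at$chain == at$chain[di] &
                           at$resno == at$resno[di] - 1L & at$atom == "C")
          ca <- which(at$chain == at$chain[di] & at$resno == at$resno[di] &
                        at$atom == "CA")
          buildable <- length(cPrev) == 1L && length(ca) == 1L
          if (buildable)
            hpos <- .buildAmideH(xyz[di, ], xyz[cPrev, ], xyz[ca, ])
        } else if (isO && at$atom[di] %in% c("OG", "OG1", "OH")) {
          buildable <- TRUE  # oriented toward the acceptor, per pair below
        }
        if (!length(hs) && !buildable) {
          skipped <- c(skipped, atomId(di))
          next
        }
      }
      dAcc <- sqrt(rowSums(sweep(xyz[accIdx, , drop = FALSE], 2L, xyz[di, ])^2))
      for (k in which(dAcc <= dMax & dAcc > 1.8)) {
        ai <- accIdx[k]
        if (ai == di) next
        if (at$chain[ai] == at$chain[di] && at$resno[ai] == at$resno[di]) next
        ang <- -Inf
        if (length(hs)) {
          for (h in hs) {
            v1 <- xyz[di, ] - xyz[h, ]; v2 <- xyz[ai, ] - xyz[h, ]
            a <- .rad2deg(acos(max(-1, min(1, sum(v1 * v2) /
                                             (.vnorm(v1) * .vnorm(v2))))))
            ang <- max(ang, a)
          }
        } else if (isO) {
          ang <- 180  # hydroxyl H built pointing at this acceptor
        } else {
          hpos_ <- hpos
          v1 <- xyz[di, ] - hpos_; v2 <- xyz[ai, ] - hpos_
          ang <- .rad2deg(acos(max(-1, min(1, sum(v1 * v2) /
                                             (.vnorm(v1) * .vnorm(v2))))))
        }
        if (ang >= angleMin) {
          key <- paste(atomId(di), atomId(ai), sep = " -> ")
          rec <- if (exists(key, envir = found)) get(key, envir = found)
                 else list(models = integer(), d = numeric(), a = numeric())
          if (!m %in% rec$models) {
            rec$models <- c(rec$models, m)
            rec$d <- c(rec$d, dAcc[k]); rec$a <- c(rec$a, ang)
            assign(key, rec, envir = found)
          }
        }
      }
    }
  }

  if (length(unique(skipped)))
    warning("donor(s) without buildable hydrogen skipped: ",
            paste(unique(skipped), collapse = ", "), call. = FALSE)

  keys <- ls(found)
  if (!length(keys))
    return(data.frame(donor = character(), acceptor = character(),
                      meanDistance = numeric(), meanAngle = numeric(),
                      nPresent = integer(), occupancy = numeric()))
  recs <- lapply(keys, get, envir = found)
  parts <- strsplit(keys, " -> ", fixed = TRUE)
  out <- data.frame(
    donor = vapply(parts, `[`, character(1L), 1L),
    acceptor = vapply(parts, `[`, character(1L), 2L),
    meanDistance = vapply(recs, function(r) mean(r$d), numeric(1L)),
    meanAngle = vapply(recs, function(r) mean(r$a), numeric(1L)),
    nPresent = vapply(recs, function(r) length(r$models), integer(1L)),
    stringsAsFactors = FALSE)
  out$occupancy <- out$nPresent / nm
  out[order(-out$occupancy, out$donor), ]
}

#' Conformational chemical shifts relative to random coil
#'
#' shift = delta_obs - delta_rc; negative values are upfield (the helical
#' signature for alpha protons facing an aromatic ring system).
#'
#' @param observed data.frame with columns \code{resno}, \code{resname},
#'   \code{nucleus}, \code{shift} (ppm).
#' @param rcTable random-coil reference table (default [randomCoilTable()]).
#' @return data.frame with \code{deltaObs}, \code{deltaRc}, \code{shift} and
#'   \code{direction}; the counts of upfield/downfield shifts are attached
#'   as attribute \code{"summary"}.
#' @export
conformationalShifts <- function(observed, rcTable = randomCoilTable()) {
  need <- c("resno", "resname", "nucleus", "shift")
  stopifnot(all(need %in% names(observed)))
  i <- match(paste(observed$resname, observed$nucleus),
             paste(rcTable$resname, rcTable$nucleus))
  if (anyNA(i))
    .stopf("lookupError", "no random-coil entry for: %s",
           paste(unique(paste(observed$resname[is.na(i)],
                              observed$nucleus[is.na(i)])), collapse = ", "))
  out <- data.frame(resno = observed$resno, resname = observed$resname,
                    nucleus = observed$nucleus,
                    deltaObs = observed$shift, deltaRc = rcTable$shift[i])
  out$shift <- out$deltaObs - out$deltaRc
  out$direction <- ifelse(out$shift < 0, "upfield",
                          ifelse(out$shift > 0, "downfield", "coincident"))
  attr(out, "summary") <- c(upfield = sum(out$shift < 0),
                            downfield = sum(out$shift > 0))
  out
}

#' Full descriptor table for a sandwich ensemble
#'
#' Computes, per model: the interhelical angle between the proximal (TD) and
#' distal (D) helix axes, the axial-His orientation angle theta, the
#' metal-to-D-chain centre-of-mass distance, and the solvent-accessible
#' surface area of the porphyrin (24 macrocycle atoms + metal, whole-model
#' context). Models are clustered into interhelical-angle families and
#' per-family mean/sd aggregates are reported.
#'
#' @param ensemble a [StructureEnsemble-class] with porphyrin topology.
#' @param tdChain,dChain chain ids of the proximal and distal helices.
#' @param tdRange,dRange residue ranges used for the axis fits (defaults:
#'   the helical cores 2-13 and 2-9).
#' @param hisResidue residue number of the axial His on the TD chain.
#' @param comRange residue range for the D-chain centre of mass
#'   (default: whole chain).
#' @param probeRadius,nSpherePoints SASA parameters.
#' @param gapThreshold family-clustering gap (degrees).
#' @return a [DescriptorTable-class].
#' @export
describeEnsemble <- function(ensemble, tdChain = "T", dChain = "D",
                             tdRange = c(2, 13), dRange = c(2, 9),
                             hisResidue = 6L, comRange = NULL,
                             probeRadius = 1.4, nSpherePoints = 960L,
                             gapThreshold = 20) {
  stopifnot(is(ensemble, "StructureEnsemble"))
  topo <- topology(ensemble)
  at <- atoms(ensemble)
  nm <- nModels(ensemble)

  caIdx <- function(chain, range) {
    i <- which(at$chain == chain & at$atom == "CA" &
                 at$resno >= range[1L] & at$resno <= range[2L])
    i[order(at$resno[i])]
  }
  tdCA <- caIdx(tdChain, tdRange)
  dCA <- caIdx(dChain, dRange)

  sasaIdx <- which(at$resname == topo@residueName &
                     at$atom %in% c(topo@ringAtoms, topo@metalAtom) |
                     (at$atom == topo@metalAtom & at$hetero))
  heavy <- which(at$element != "H")
  radii <- vdwRadius(at$element[heavy])
  if (anyNA(radii))
    .stopf("radiusAssignmentError", "no radius for element(s): %s",
           paste(unique(at$element[heavy][is.na(radii)]), collapse = ", "))

  pm <- data.frame(model = seq_len(nm), interhelical_angle = NA_real_,
                   theta_his = NA_real_, co_to_com_distance = NA_real_,
                   porphyrin_sasa = NA_real_)
  for (m in seq_len(nm)) {
    xyz <- modelCoords(ensemble, m)
    aTD <- fitHelixAxis(xyz[tdCA, , drop = FALSE])
    aD <- fitHelixAxis(xyz[dCA, , drop = FALSE])
    pm$interhelical_angle[m] <- interhelicalAngle(aTD, aD)
    pm$theta_his[m] <- hisTheta(ensemble, m, tdChain, hisResidue)$theta
    pm$co_to_com_distance[m] <- coToChainCoM(ensemble, m, dChain, comRange)
    rep_ <- match(intersect(sasaIdx, heavy), heavy)
    s <- shrakeRupleySASA(xyz[heavy, , drop = FALSE], radii,
                          reportIndex = rep_, probeRadius = probeRadius,
                          nSpherePoints = nSpherePoints)
    pm$porphyrin_sasa[m] <- s$total
  }

  if (nm >= 2L) {
    cl <- clusterFamilies(pm$interhelical_angle, gapThreshold)
    pm$family <- cl$labels
  } else pm$family <- 1L

  aggRows <- lapply(sort(unique(pm$family)), function(f) {
    sub <- pm[pm$family == f, ]
    data.frame(family = f, n = nrow(sub),
               interhelical_mean = mean(sub$interhelical_angle),
               interhelical_sd = stats::sd(sub$interhelical_angle),
               theta_mean = mean(sub$theta_his),
               theta_sd = stats::sd(sub$theta_his),
               co_com_mean = mean(sub$co_to_com_distance),
               co_com_sd = stats::sd(sub$co_to_com_distance),
               sasa_mean = mean(sub$porphyrin_sasa),
               sasa_sd = stats::sd(sub$porphyrin_sasa))
  })
  new("DescriptorTable", perModel = pm, aggregates = do.call(rbind, aggRows))
}
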