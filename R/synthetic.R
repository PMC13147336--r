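# Synthetic-data generators: ideal helices with nonstandard residues,
# an idealized deuteroporphyrin template, full helix-porphyrin-helix
# sandwich ensembles with known ground truth, NOE peak lists, and
# quadrupole-doublet spectra. Every generator is deterministic given its
# seed.

## ---- residue geometry -----------------------------------------------------

.BB <- list(nCa = 1.458, caC = 1.525, cN = 1.329, cO = 1.231,
            angNCaC = 111.2, angCaCN = 116.2, angCNCa = 121.7,
            angCaCO = 120.8)

.knownResidues <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                    "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                    "THR", "TRP", "TYR", "VAL", "AIB", "DAB")

## Append one atom row to the growing model.
.addAtom <- function(model, chain, resno, resname, atom, element, xyz,
                     hetero = FALSE) {
  model[[length(model) + 1L]] <- list(chain = chain, resno = resno,
                                      resname = resname, atom = atom,
                                      element = element, hetero = hetero,
                                      x = xyz[1L], y = xyz[2L], z = xyz[3L])
  model
}

.modelToEnsemble <- function(model, topology = NULL, metadata = list()) {
  df <- do.call(rbind, lapply(model, function(a)
    data.frame(chain = a$chain, resno = a$resno, resname = a$resname,
               atom = a$atom, element = a$element, hetero = a$hetero,
               x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)))
  coords <- array(as.matrix(df[, c("x", "y", "z")]),
                  dim = c(nrow(df), 3L, 1L))
  new("StructureEnsemble",
      atoms = df[, c("chain", "resno", "resname", "atom", "element", "hetero")],
      coords = coords, topology = topology, metadata = metadata)
}

## Tetrahedral C-beta position (L-configuration) given N, CA, C.
.placeCB <- function(n, ca, cc, bond = 1.53) {
  u1 <- .unit(n - ca); u2 <- .unit(cc - ca)
  bis <- -.unit(u1 + u2)
  nrm <- .unit(.cross(u1, u2))  # sign fixes L-chirality
  half <- .deg2rad(54.75)
  ca + bond * (cos(half) * bis + sin(half) * nrm)
}

## Build the side chain of one residue; backbone atoms already placed.
## chi: named numeric (chi1, chi2); missing torsions default to staggered.
.buildSideChain <- function(model, chain, resno, resname, n, ca, cc, chi) {
  chi1 <- if (!is.null(chi[["chi1"]]) && !is.na(chi[["chi1"]])) chi[["chi1"]] else 180
  chi2 <- if (!is.null(chi[["chi2"]]) && !is.na(chi[["chi2"]])) chi[["chi2"]] else 180
  add <- function(mo, atom, el, pos) .addAtom(mo, chain, resno, resname, atom, el, pos)

  if (resname == "GLY") return(model)
  if (resname == "AIB") {
    # two beta methyls flank the alpha carbon
    u1 <- .unit(n - ca); u2 <- .unit(cc - ca)
    bis <- -.unit(u1 + u2); nrm <- .unit(.cross(u1, u2))
    half <- .deg2rad(54.75)
    cb1 <- ca + 1.53 * (cos(half) * bis + sin(half) * nrm)
    cb2 <- ca + 1.53 * (cos(half) * bis - sin(half) * nrm)
    model <- add(model, "CB1", "C", cb1)
    model <- add(model, "CB2", "C", cb2)
    model <- add(model, "MB1", "H", cb1 + 1.0 * .unit(cb1 - ca))  # methyl stub
    model <- add(model, "MB2", "H", cb2 + 1.0 * .unit(cb2 - ca))
    return(model)
  }

  cb <- .placeCB(n, ca, cc)
  model <- add(model, "CB", "C", cb)
  ha <- ca + 1.09 * .unit(ca - ((n + cc + cb) / 3))
  model <- add(model, "HA", "H", ha)

  if (resname %in% c("ALA")) {
    model <- add(model, "MB", "H", cb + 1.0 * .unit(cb - ca))
    return(model)
  }
  if (resname == "SER") {
    og <- .placeAtom(n, ca, cb, 1.42, 110.8, chi1)
    return(add(model, "OG", "O", og))
  }
  if (resname == "THR") {
    og <- .placeAtom(n, ca, cb, 1.42, 110.8, chi1)
    cg2 <- .placeAtom(n, ca, cb, 1.53, 110.5, chi1 - 120)
    model <- add(model, "OG1", "O", og)
    return(add(model, "CG2", "C", cg2))
  }
  if (resname == "LEU") {
    cg <- .placeAtom(n, ca, cb, 1.53, 116.3, chi1)
    cd1 <- .placeAtom(ca, cb, cg, 1.53, 110.7, chi2)
    cd2 <- .placeAtom(ca, cb, cg, 1.53, 110.7, chi2 + 122)
    model <- add(model, "CG", "C", cg)
    model <- add(model, "CD1", "C", cd1)
    model <- add(model, "CD2", "C", cd2)
    model <- add(model, "MD1", "H", cd1 + 1.0 * .unit(cd1 - cg))
    return(add(model, "MD2", "H", cd2 + 1.0 * .unit(cd2 - cg)))
  }
  if (resname == "HIS") {
    cg <- .placeAtom(n, ca, cb, 1.50, 113.8, chi1)
    nd1 <- .placeAtom(ca, cb, cg, 1.38, 122.7, chi2)
    cd2 <- .placeAtom(ca, cb, cg, 1.36, 131.0, chi2 + 180)
    ce1 <- .placeAtom(cb, cg, nd1, 1.32, 109.3, 180)
    ne2 <- .placeAtom(cg, nd1, ce1, 1.32, 108.4, 0)
    model <- add(model, "CG", "C", cg)
    model <- add(model, "ND1", "N", nd1)
    model <- add(model, "CD2", "C", cd2)
    model <- add(model, "CE1", "C", ce1)
    model <- add(model, "NE2", "N", ne2)
    ring <- (cg + nd1 + cd2 + ce1 + ne2) / 5
    model <- add(model, "HD1", "H", nd1 + 1.01 * .unit(nd1 - ring))
    model <- add(model, "HE1", "H", ce1 + 1.08 * .unit(ce1 - ring))
    return(add(model, "HD2", "H", cd2 + 1.08 * .unit(cd2 - ring)))
  }
  if (resname == "DAB") {
    cg <- .placeAtom(n, ca, cb, 1.53, 114.0, chi1)
    nd <- .placeAtom(ca, cb, cg, 1.47, 112.0, chi2)
    model <- add(model, "CG", "C", cg)
    model <- add(model, "ND", "N", nd)
    model <- add(model, "HD1", "H", nd + 1.01 * .unit(nd - cg) +
                   c(0.35, 0, 0) * 0)  # stub along the C-N extension
    return(add(model, "HD2", "H",
               .placeAtom(cb, cg, nd, 1.01, 109.5, 60)))
  }
  # generic gamma extension for the remaining residue types
  gname <- if (resname %in% c("CYS")) "SG" else "CG"
  gel <- if (gname == "SG") "S" else "C"
  cg <- .placeAtom(n, ca, cb, if (gel == "S") 1.81 else 1.53, 114.0, chi1)
  model <- add(model, gname, gel, cg)
  if (resname %in% c("GLN", "GLU", "LYS", "ARG", "MET", "ILE")) {
    dname <- switch(resname, GLN = "CD", GLU = "CD", LYS = "CD", ARG = "CD",
                    MET = "SD", ILE = "CD1")
    del <- if (dname == "SD") "S" else "C"
    cd <- .placeAtom(ca, cb, cg, if (del == "S") 1.81 else 1.52, 112.6, chi2)
    model <- add(model, dname, del, cd)
    if (resname == "LYS") {
      ce <- .placeAtom(cb, cg, cd, 1.52, 112.6, 180)
      nz <- .placeAtom(cg, cd, ce, 1.47, 112.0, 180)
      model <- add(model, "CE", "C", ce)
      model <- add(model, "NZ", "N", nz)
    }
    if (resname == "ARG") {
      ne <- .placeAtom(cb, cg, cd, 1.46, 112.0, 180)
      cz <- .placeAtom(cg, cd, ne, 1.33, 124.0, 180)
      model <- add(model, "NE", "N", ne)
      model <- add(model, "CZ", "C", cz)
    }
  }
  if (resname %in% c("ASP", "ASN")) {
    od <- .placeAtom(ca, cb, cg, 1.25, 120.0, chi2)
    model <- add(model, if (resname == "ASP") "OD1" else "OD1", "O", od)
  }
  model
}

#' Build an ideal helical peptide model
#'
#' Constructs a peptide chain at uniform backbone torsions from standard
#' bond lengths and angles (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom;
#' angles 111.2/116.2/121.7 degrees; omega 180). Backbone N, CA, C, O plus
#' amide hydrogens and alpha-proton stubs are always built; side chains are
#' built from rotamer templates (full rings/branches for His, Leu, Dab,
#' Aib; progressively simpler stubs otherwise). Methyl and amine protons
#' are represented as single pseudo-atom stubs for NOE generation.
#' Recomputing [backboneDihedrals()] on the result returns (phi, psi)
#' exactly.
#'
#' @param sequence character vector of 3-letter residue codes (Aib and Dab
#'   supported).
#' @param phi,psi backbone torsions in degrees, recycled over residues.
#' @param chain chain id for the model.
#' @param chi named list: \code{chi[[resno]]} is a numeric with entries
#'   \code{chi1}/\code{chi2} for that residue (defaults: staggered 180).
#' @return a 1-model [StructureEnsemble-class].
#' @export
buildIdealHelix <- function(sequence, phi = -57, psi = -47, chain = "T",
                            chi = list()) {
  sequence <- toupper(sequence)
  if (!length(sequence)) .stopf("sequenceError", "empty sequence")
  bad <- setdiff(sequence, .knownResidues)
  if (length(bad))
    .stopf("sequenceError", "unknown residue code(s): %s",
           paste(unique(bad), collapse = ", "))
  nres <- length(sequence)
  phi <- rep_len(phi, nres); psi <- rep_len(psi, nres)

  N <- matrix(NA_real_, nres, 3L)
  CA <- matrix(NA_real_, nres, 3L)
  C <- matrix(NA_real_, nres, 3L)

  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(.BB$nCa, 0, 0)
  th <- .deg2rad(.BB$angNCaC)
  C[1L, ] <- CA[1L, ] + .BB$caC * c(-cos(th), sin(th), 0)
  for (i in seq_len(nres - 1L)) {
    N[i + 1L, ] <- .placeAtom(N[i, ], CA[i, ], C[i, ], .BB$cN, .BB$angCaCN,
                              psi[i])
    CA[i + 1L, ] <- .placeAtom(CA[i, ], C[i, ], N[i + 1L, ], .BB$nCa,
                               .BB$angCNCa, 180)       # trans peptide bond
    C[i + 1L, ] <- .placeAtom(C[i, ], N[i + 1L, ], CA[i + 1L, ], .BB$caC,
                              .BB$angNCaC, phi[i + 1L])
  }

  model <- list()
  for (i in seq_len(nres)) {
    rn <- sequence[i]
    model <- .addAtom(model, chain, i, rn, "N", "N", N[i, ])
    if (i > 1L)
      model <- .addAtom(model, chain, i, rn, "H", "H",
                        .buildAmideH(N[i, ], C[i - 1L, ], CA[i, ]))
    model <- .addAtom(model, chain, i, rn, "CA", "C", CA[i, ])
    model <- .addAtom(model, chain, i, rn, "C", "C", C[i, ])
    # carbonyl O: sp2, anti to the next amide N (psi + 180)
    o <- .placeAtom(N[i, ], CA[i, ], C[i, ], .BB$cO, .BB$angCaCO,
                    psi[i] + 180)
    model <- .addAtom(model, chain, i, rn, "O", "O", o)
    ch <- if (!is.null(chi[[as.character(i)]])) chi[[as.character(i)]]
          else c(chi1 = NA_real_, chi2 = NA_real_)
    model <- .buildSideChain(model, chain, i, rn, N[i, ], CA[i, ], C[i, ], ch)
  }
  .modelToEnsemble(model, metadata = list(phi = phi, psi = psi))
}

## ---- porphyrin template ---------------------------------------------------

#' Idealized planar deuteroporphyrin template
#'
#' The 24-atom macrocycle in the z = 0 plane with the metal at the origin:
#' pyrrole nitrogens N21-N24 on the +x/+y/-x/-y axes (so the N21-N23 and
#' N22-N24 axes are exactly orthogonal), alpha/beta ring carbons and meso
#' carbons at idealized radii, methyl substituents at ring positions 3, 7,
#' 12, 17, ring hydrogens at the deutero positions 8 and 13 and at the meso
#' carbons, and propionyl groups (with methylene proton stubs) at the
#' anchoring positions 2 and 18.
#'
#' @param metal element/atom name of the central metal (default "CO").
#' @return a 1-model [StructureEnsemble-class] (chain "P", hetero atoms)
#'   carrying the default topology.
#' @export
porphyrinTemplate <- function(metal = "CO") {
  topo <- defaultTopology()
  rN <- 2.05; rA <- 3.05; rB <- 4.25; rM <- 3.45
  at <- function(r, angDeg) r * c(cos(.deg2rad(angDeg)), sin(.deg2rad(angDeg)), 0)

  model <- list()
  add <- function(mo, atom, el, pos)
    .addAtom(mo, "P", 1L, topo@residueName, atom, el, pos, hetero = TRUE)

  # pyrrole rings A-D centred at 0/90/180/270 degrees
  nNames <- c("N21", "N22", "N23", "N24")
  alphaNames <- list(c("C1", "C4"), c("C6", "C9"), c("C11", "C14"),
                     c("C16", "C19"))
  betaNames <- list(c("C2", "C3"), c("C7", "C8"), c("C12", "C13"),
                    c("C17", "C18"))
  ctrAng <- c(0, 90, 180, 270)
  pos <- list()
  for (k in 1:4) {
    a0 <- ctrAng[k]
    pos[[nNames[k]]] <- at(rN, a0)
    pos[[alphaNames[[k]][1L]]] <- at(rA, a0 - 18)
    pos[[alphaNames[[k]][2L]]] <- at(rA, a0 + 18)
    pos[[betaNames[[k]][1L]]] <- at(rB, a0 - 11)
    pos[[betaNames[[k]][2L]]] <- at(rB, a0 + 11)
  }
  pos[["C5"]] <- at(rM, 45); pos[["C10"]] <- at(rM, 135)
  pos[["C15"]] <- at(rM, 225); pos[["C20"]] <- at(rM, 315)
  for (nm in topo@ringAtoms)
    model <- add(model, nm, substr(nm, 1L, 1L), pos[[nm]])

  radial <- function(base, dist) pos[[base]] + dist * .unit(pos[[base]])
  # methyls (position: 3 -> CMA, 7 -> CMB, 12 -> CMC, 17 -> CMD)
  meth <- c(CMA = "C3", CMB = "C7", CMC = "C12", CMD = "C17")
  for (nm in names(meth)) {
    p <- radial(meth[[nm]], 1.50)
    model <- add(model, nm, "C", p)
    model <- .addAtom(model, "P", 1L, topo@residueName, sub("C", "HM", nm),
                      "H", p + 1.0 * .unit(p), hetero = TRUE)
  }
  # ring hydrogens at the deutero beta positions and the meso carbons
  for (h in list(c("H8", "C8"), c("H13", "C13"), c("H5", "C5"),
                 c("H10", "C10"), c("H15", "C15"), c("H20", "C20")))
    model <- add(model, h[1L], "H", radial(h[2L], 1.08))

  # propionyls at positions 2 (atoms *A) and 18 (atoms *D), bent off-plane
  prop <- function(mo, base, suffix) {
    dirR <- .unit(pos[[base]])
    ca_ <- pos[[base]] + 1.52 * dirR
    cb_ <- ca_ + 1.53 * .unit(dirR + c(0, 0, 0.8))
    cg_ <- cb_ + 1.52 * .unit(dirR + c(0, 0, -0.4))
    mo <- add(mo, paste0("CA", suffix), "C", ca_)
    mo <- add(mo, paste0("CB", suffix), "C", cb_)
    mo <- add(mo, paste0("CG", suffix), "C", cg_)
    perp <- .unit(.cross(dirR, c(0, 0, 1)))
    mo <- add(mo, paste0("HA", suffix, "1"), "H", ca_ + 1.0 * perp)
    mo <- add(mo, paste0("HA", suffix, "2"), "H", ca_ - 1.0 * perp)
    mo <- add(mo, paste0("HB", suffix, "1"), "H", cb_ + 1.0 * perp)
    add(mo, paste0("HB", suffix, "2"), "H", cb_ - 1.0 * perp)
  }
  model <- prop(model, "C2", "A")
  model <- prop(model, "C18", "D")

  model <- .addAtom(model, "P", 2L, toupper(metal), toupper(metal),
                    toupper(metal), c(0, 0, 0), hetero = TRUE)
  topo@metalAtom <- toupper(metal)
  .modelToEnsemble(model, topology = topo)
}

## ---- sandwich assembly ----------------------------------------------------

#' Construct a [SandwichBlueprint-class]
#'
#' Defaults emulate the study system: a 14-mer proximal (TD) chain bearing
#' the axial His6, a 10-mer distal (D) chain with Aib3/Aib7 and the Dab9
#' anchoring residue, an interhelical angle of 21 degrees, a His angle
#' theta of -33.4 degrees, TD anchored at propionyl 18 (regioisomer 1), a
#' metal-to-D-chain offset of 7.7 Angstrom, 20 models and 0.3 Angstrom
#' coordinate jitter.
#'
#' @param tdSequence,dSequence residue-code vectors.
#' @param targetInterhelicalAngle degrees.
#' @param targetThetaHis signed degrees.
#' @param tdAnchorPosition 2 or 18.
#' @param metalOffset Angstrom.
#' @param jitterSd Angstrom.
#' @param nModels integer.
#' @param seed integer.
#' @return a [SandwichBlueprint-class].
#' @export
sandwichBlueprint <- function(
    tdSequence = c("ASP", "LEU", "GLN", "GLN", "LEU", "HIS", "SER", "GLN",
                   "LYS", "ARG", "LYS", "ILE", "THR", "LEU"),
    dSequence = c("ASP", "GLU", "AIB", "GLN", "LEU", "SER", "AIB", "GLN",
                  "DAB", "ARG"),
    targetInterhelicalAngle = 21, targetThetaHis = -33.4,
    tdAnchorPosition = 18, metalOffset = 7.7, jitterSd = 0.3,
    nModels = 20L, seed = 1L) {
  new("SandwichBlueprint", tdSequence = toupper(tdSequence),
      dSequence = toupper(dSequence),
      targetInterhelicalAngle = targetInterhelicalAngle,
      targetThetaHis = targetThetaHis,
      tdAnchorPosition = as.numeric(tdAnchorPosition),
      metalOffset = metalOffset, jitterSd = jitterSd,
      nModels = as.integer(nModels), seed = as.integer(seed))
}

.transformModelDf <- function(df, R = diag(3L), shift = c(0, 0, 0)) {
  xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
  df$x <- xyz[, 1L] + shift[1L]
  df$y <- xyz[, 2L] + shift[2L]
  df$z <- xyz[, 3L] + shift[3L]
  df
}

.dfOf <- function(ens) {
  cbind(atoms(ens), as.data.frame(modelCoords(ens, 1L)))
}

#' Assemble a synthetic helix-porphyrin-helix sandwich ensemble
#'
#' Places the porphyrin template in the z = 0 plane with the metal at the
#' origin; positions the proximal (TD) helix below the plane with the His6
#' N-epsilon at 2.0 Angstrom from the metal (bond along z) and the
#' imidazole plane rotated so the measured orientation angle theta equals
#' the blueprint value; places the distal (D) helix on the opposite face
#' with its axis at the blueprint interhelical angle to the TD axis and its
#' backbone centre of mass at the blueprint metal offset. The D helix is
#' spun about its own axis (and mirrored between the two equivalent axis
#' azimuths) to bring the Dab9 side-chain amine close to the propionyl that
#' anchors the D chain (position 2 when the TD chain is anchored at 18, and
#' vice versa) while avoiding steric clashes. Per-model isotropic N(0,
#' jitterSd^2) coordinate jitter is then applied with the blueprint seed.
#'
#' Any non-bonded heavy-atom pair between moieties closer than 2.4 Angstrom
#' in the jitter-free structure raises an assembly error.
#'
#' @param blueprint a [SandwichBlueprint-class].
#' @return a [StructureEnsemble-class]; the exact jitter-free ground truth
#'   (realized interhelical angle, theta, metal offset) is stored in
#'   \code{metadata(...)$truth} together with the blueprint.
#' @export
assembleSandwich <- function(blueprint) {
  stopifnot(is(blueprint, "SandwichBlueprint"))
  validObject(blueprint)
  porph <- porphyrinTemplate()
  topo <- topology(porph)
  porphDf <- .dfOf(porph)

  ## --- proximal (TD) helix: His frame -> metal bond along +z -------------
  hisNo <- which(blueprint@tdSequence == "HIS")[1L]
  if (is.na(hisNo))
    .stopf("assemblyError", "TD sequence carries no His residue")
  # side-chain rotamers are fixed construction constants: the His rotamer
  # extends the NE2 lone pair away from the helix so the helix lies
  # alongside the porphyrin plane, and the pocket residues (Leu2/Leu5/Lys9)
  # face the ring at van der Waals distance without clashing
  chi <- list()
  chi[[as.character(hisNo)]] <- c(chi1 = 120, chi2 = 0)
  for (rn in seq_along(blueprint@tdSequence)) {
    key <- as.character(rn)
    if (rn == hisNo) next
    if (blueprint@tdSequence[rn] == "LEU")
      chi[[key]] <- if (rn == hisNo - 1L) c(chi1 = -90, chi2 = -90)
                    else c(chi1 = -157, chi2 = 82)
  }
  td <- buildIdealHelix(blueprint@tdSequence, -60, -45, chain = "T", chi = chi)
  tdDf <- .dfOf(td)

  hsel <- tdDf$resno == hisNo
  imid <- as.matrix(tdDf[hsel & tdDf$atom %in% .imidazoleNames,
                         c("x", "y", "z")])
  ne2 <- as.numeric(tdDf[hsel & tdDf$atom == "NE2", c("x", "y", "z")])
  ce1 <- as.numeric(tdDf[hsel & tdDf$atom == "CE1", c("x", "y", "z")])
  cd2 <- as.numeric(tdDf[hsel & tdDf$atom == "CD2", c("x", "y", "z")])

  e1 <- fitPlane(imid)$normal
  e2 <- ne2 - (ce1 + cd2) / 2          # in-plane, toward the metal lone pair
  e2 <- .unit(e2 - sum(e2 * e1) * e1)
  e3 <- .cross(e1, e2)
  Ffrm <- cbind(e1, e2, e3)
  Gfrm <- cbind(c(1, 0, 0), c(0, 0, 1), .cross(c(1, 0, 0), c(0, 0, 1)))
  R <- Gfrm %*% t(Ffrm)
  tdDf <- .transformModelDf(tdDf, R, -as.numeric(R %*% ne2) + c(0, 0, -2.0))

  ## measure theta on the provisional placement, then correct by a rotation
  ## about z (which leaves the NE2-metal bond invariant). Theta is folded
  ## into (-90, 90], so the correction is degenerate modulo 180 degrees:
  ## of the two equivalent TD azimuths, take the one whose C-terminal end
  ## faces the propionyl that anchors the distal chain (the covalent
  ## linker the real molecule would impose).
  ens0 <- .bindSandwich(porphDf, tdDf, NULL, topo)
  th0 <- hisTheta(ens0, 1L, "T", hisNo)$theta

  dAnchor <- if (blueprint@tdAnchorPosition == 18) "2" else "18"
  anchorAtoms <- topo@propionylAttachment[[dAnchor]]
  anchorPt <- colMeans(as.matrix(
    porphDf[porphDf$atom %in% anchorAtoms, c("x", "y", "z")]))
  azAnchor <- atan2(anchorPt[2L], anchorPt[1L])

  tdCA0 <- as.matrix(tdDf[tdDf$atom == "CA", c("x", "y", "z")])
  cterm0 <- tdCA0[nrow(tdCA0), ] - tdCA0[1L, ]
  gBase <- th0 - blueprint@targetThetaHis
  gPick <- NULL
  for (g in c(gBase, gBase + 180)) {
    ct <- as.numeric(.rotationMatrix(c(0, 0, 1), g) %*% cterm0)
    mis <- abs(.wrap180(.rad2deg(atan2(ct[2L], ct[1L]) - azAnchor)))
    if (is.null(gPick) || mis < gPick$mis) gPick <- list(g = g, mis = mis)
  }
  tdDf <- .transformModelDf(tdDf, .rotationMatrix(c(0, 0, 1), gPick$g))

  tdCA <- as.matrix(tdDf[tdDf$atom == "CA", c("x", "y", "z")])
  axTD <- fitHelixAxis(tdCA)
  u <- axTD$direction

  ## --- distal (D) helix --------------------------------------------------
  d0 <- buildIdealHelix(blueprint@dSequence, -60, -45, chain = "D")
  dDf0 <- .dfOf(d0)
  dCA0 <- as.matrix(dDf0[dDf0$atom == "CA", c("x", "y", "z")])
  w <- fitHelixAxis(dCA0)$direction

  vCandidates <- .targetDirections(u, blueprint@targetInterhelicalAngle)

  best <- NULL
  for (v in vCandidates) {
    Rv <- .alignVectors(w, v)
    for (spin in seq(0, 350, by = 10)) {
      Rs <- .rotationMatrix(v, spin) %*% Rv
      cand0 <- .transformModelDf(dDf0, Rs)
      bbIdx <- cand0$atom %in% c("N", "CA", "C", "O")
      com <- c(mean(cand0$x[bbIdx]), mean(cand0$y[bbIdx]),
               mean(cand0$z[bbIdx]))
      # backbone CoM on the sphere |CoM| = offset, tilted toward the anchor
      # propionyl azimuth to shorten the Dab9-propionyl linker
      for (psi in seq(0, 40, by = 10)) {
        target <- blueprint@metalOffset *
          c(sin(.deg2rad(psi)) * cos(azAnchor),
            sin(.deg2rad(psi)) * sin(azAnchor), cos(.deg2rad(psi)))
        cand <- .transformModelDf(cand0, diag(3L), target - com)
        ndSel <- cand$resname == "DAB" & cand$atom == "ND"
        dist <- if (any(ndSel))
          .vnorm(as.numeric(cand[which(ndSel)[1L], c("x", "y", "z")]) -
                   anchorPt)
        else 0
        clash <- .minInterDist(cand, porphDf) < 2.4 ||
          .minInterDist(cand, tdDf) < 2.4 ||
          min(cand$z[cand$element != "H"]) < 0
        score <- dist + if (clash) 1e3 else 0
        if (is.null(best) || score < best$score)
          best <- list(df = cand, score = score, v = v)
      }
    }
  }
  dDf <- best$df
  if (best$score >= 1e3)
    .stopf("assemblyError",
           "no clash-free distal-helix placement for the requested geometry")

  ## --- clash check + ground truth ----------------------------------------
  if (.minInterDist(tdDf, porphDf, exemptBond = TRUE) < 2.4 ||
      .minInterDist(tdDf, dDf) < 2.4)
    .stopf("assemblyError", "steric clash below 2.4 Angstrom in assembly")

  ens1 <- .bindSandwich(porphDf, tdDf, dDf, topo)
  dCA <- as.matrix(dDf[dDf$atom == "CA" & dDf$resno >= 2 & dDf$resno <= 9,
                       c("x", "y", "z")])
  truth <- list(
    interhelicalAngle = interhelicalAngle(
      fitHelixAxis(tdCA[2:13, , drop = FALSE]), fitHelixAxis(dCA)),
    thetaHis = hisTheta(ens1, 1L, "T", hisNo)$theta,
    metalOffset = coToChainCoM(ens1, 1L, "D"),
    hisResidue = hisNo)

  ## --- jittered models ----------------------------------------------------
  base <- ens1@coords[, , 1L]
  nm <- blueprint@nModels
  coords <- array(NA_real_, dim = c(nrow(base), 3L, nm))
  set.seed(blueprint@seed)
  for (m in seq_len(nm))
    coords[, , m] <- base + stats::rnorm(length(base), 0, blueprint@jitterSd)

  new("StructureEnsemble", atoms = ens1@atoms, coords = coords,
      topology = topo,
      metadata = list(blueprint = blueprint, truth = truth))
}

## directions v with angle(u, v) = t (degrees); prefer in-plane (small |vz|)
## solutions, fall back to the tilted circle otherwise
.targetDirections <- function(u, t) {
  ct <- cos(.deg2rad(t))
  uh <- c(u[1L], u[2L], 0)
  ch <- .vnorm(uh)
  out <- list()
  if (ch > 1e-9 && abs(ct / ch) <= 1) {
    beta <- acos(max(-1, min(1, ct / ch)))
    azu <- atan2(u[2L], u[1L])
    for (s in c(1, -1))
      out[[length(out) + 1L]] <- c(cos(azu + s * beta), sin(azu + s * beta), 0)
  } else {
    p <- if (abs(u[3L]) < 0.999) .unit(.cross(u, c(0, 0, 1))) else c(1, 0, 0)
    q <- .cross(u, p)
    st <- sin(.deg2rad(t))
    gz <- if (abs(st) > 1e-9) max(-1, min(1, -ct * u[3L] / (st * q[3L]))) else 0
    gamma <- asin(gz)
    for (g in unique(c(gamma, pi - gamma))) {
      wv <- cos(g) * p + sin(g) * q
      out[[length(out) + 1L]] <- ct * u + st * wv
    }
  }
  out
}

## rotation mapping unit vector a onto unit vector b
.alignVectors <- function(a, b) {
  a <- .unit(a); b <- .unit(b)
  ax <- .cross(a, b)
  s <- .vnorm(ax)
  if (s < 1e-12) {
    if (sum(a * b) > 0) return(diag(3L))
    p <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(.rotationMatrix(.unit(.cross(a, p)), 180))
  }
  .rotationMatrix(ax, .rad2deg(atan2(s, sum(a * b))))
}

## minimum heavy-atom distance between two moiety data.frames
.minInterDist <- function(dfA, dfB, exemptBond = FALSE) {
  A <- as.matrix(dfA[dfA$element != "H", c("x", "y", "z")])
  B <- as.matrix(dfB[dfB$element != "H", c("x", "y", "z")])
  if (exemptBond) {
    # the His NE2-metal coordination bond (2.0 A) is intentional
    ne2 <- dfA$atom == "NE2" & dfA$element != "H"
    A <- as.matrix(dfA[dfA$element != "H" & !ne2, c("x", "y", "z")])
  }
  if (!nrow(A) || !nrow(B)) return(Inf)
  dm <- sqrt(outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B))
  min(dm, na.rm = TRUE)
}

.bindSandwich <- function(porphDf, tdDf, dDf, topo) {
  df <- rbind(tdDf, if (!is.null(dDf)) dDf, porphDf)
  coords <- array(as.matrix(df[, c("x", "y", "z")]), dim = c(nrow(df), 3L, 1L))
  new("StructureEnsemble",
      atoms = df[, c("chain", "resno", "resname", "atom", "element", "hetero")],
      coords = coords, topology = topo, metadata = list())
}

## ---- NOE peaks and spectra ------------------------------------------------

#' Generate NOE peaks from a model with the inverse-sixth-power law
#'
#' Emits one peak per proton(-stub) pair closer than \code{cutoff}, with
#' intensity \code{c / d^6} modulated by multiplicative Gaussian noise of
#' coefficient of variation \code{noiseCv} (floored at a small positive
#' minimum). The true distance is carried along for recovery tests.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param model model index.
#' @param cutoff distance cutoff in Angstrom (2 to 7).
#' @param scale the calibration constant \code{c}.
#' @param noiseCv coefficient of variation of the intensity noise.
#' @param seed integer seed.
#' @return data.frame peak list: \code{chain_a,res_a,atom_a,chain_b,res_b,
#'   atom_b,intensity,distance}.
#' @export
generateNoePeaks <- function(ensemble, model = 1L, cutoff = 5.0, scale = 1.0,
                             noiseCv = 0.0, seed = 1L) {
  if (cutoff < 2 || cutoff > 7)
    .stopf("validationError", "cutoff must be in [2, 7] Angstrom")
  at <- atoms(ensemble)
  xyz <- modelCoords(ensemble, model)
  hIdx <- which(at$element == "H")
  empty <- data.frame(chain_a = character(), res_a = integer(),
                      atom_a = character(), chain_b = character(),
                      res_b = integer(), atom_b = character(),
                      intensity = numeric(), distance = numeric())
  if (length(hIdx) < 2L) return(empty)
  H <- xyz[hIdx, , drop = FALSE]
  dm <- as.matrix(stats::dist(H))
  pairs <- which(upper.tri(dm) & dm <= cutoff & dm > 0, arr.ind = TRUE)
  if (!nrow(pairs)) return(empty)
  ia <- hIdx[pairs[, 1L]]; ib <- hIdx[pairs[, 2L]]
  d <- dm[pairs]
  set.seed(seed)
  noise <- if (noiseCv > 0) 1 + stats::rnorm(length(d), 0, noiseCv) else 1
  data.frame(chain_a = at$chain[ia], res_a = at$resno[ia],
             atom_a = at$atom[ia], chain_b = at$chain[ib],
             res_b = at$resno[ib], atom_b = at$atom[ib],
             intensity = pmax(1e-9, scale / d^6 * noise), distance = d,
             stringsAsFactors = FALSE)
}

#' Generate a quadrupole-doublet spectrum with stored ground truth
#'
#' Thin wrapper over [simulateMossbauer()] that returns the simulated
#' spectrum together with the exact generating parameters, for recovery
#' assertions.
#'
#' @inheritParams simulateMossbauer
#' @return list with \code{spectrum} (a [MossbauerSpectrum-class]) and
#'   \code{truth} (the generating doublet table, depth and noise).
#' @export
generateMossbauer <- function(doublets, velocity = seq(-4, 4, length.out = 512L),
                              totalDepth = 1.0, noiseSd = 0.0, seed = 1L) {
  sp <- simulateMossbauer(doublets, velocity, totalDepth, noiseSd, seed)
  list(spectrum = sp,
       truth = list(doublets = doublets, totalDepth = totalDepth,
                    noiseSd = noiseSd, seed = seed))
}
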