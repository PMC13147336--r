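#' @import methods
NULL

#' Porphyrin topology description
#'
#' Describes the macrocycle of the porphyrin cofactor (deuteroporphyrin IX by
#' default): the 24 heavy-atom ring names including the four pyrrole nitrogens
#' N21--N24, the meso positions (5, 10, 15, 20), the ring substituent
#' positions, the two propionyl attachment points (ring positions 2 and 18
#' that anchor the peptide chains), and the metal atom name.
#'
#' @slot residueName residue code used for the porphyrin in coordinate files.
#' @slot ringAtoms character vector of the 24 macrocycle heavy-atom names.
#' @slot mesoAtoms named character vector mapping meso positions
#'   ("5","10","15","20") to atom names.
#' @slot substituents named list mapping ring positions
#'   ("2","3","7","8","12","13","17","18") to substituent atom-name groups.
#' @slot propionylAttachment named list mapping positions "2" and "18" to the
#'   linker (propionyl) atom names.
#' @slot metalAtom atom name of the central metal.
#' @slot residueRegistry named list mapping nonstandard residue codes (e.g.
#'   "AIB", "DAB") to descriptions used by the reader.
#'
#' @seealso [defaultTopology()], [readTopologyConfig()]
#' @exportClass PorphyrinTopology
setClass("PorphyrinTopology",
  representation(
    residueName = "character",
    ringAtoms = "character",
    mesoAtoms = "character",
    substituents = "list",
    propionylAttachment = "list",
    metalAtom = "character",
    residueRegistry = "list"
  )
)

setValidity("PorphyrinTopology", function(object) {
  msgs <- character()
  if (length(object@ringAtoms) != 24L)
    msgs <- c(msgs, "ringAtoms must name exactly 24 macrocycle atoms")
  for (n in c("N21", "N22", "N23", "N24"))
    if (!n %in% object@ringAtoms)
      msgs <- c(msgs, sprintf("pyrrole nitrogen %s missing from ringAtoms", n))
  if (!all(c("2", "18") %in% names(object@propionylAttachment)))
    msgs <- c(msgs, "propionyl attachment positions 2 and 18 must both be mapped")
  if (length(msgs)) msgs else TRUE
})

#' Multi-model structure ensemble
#'
#' An ordered set of models (e.g. the 20 refined structures of an NMR bundle)
#' sharing one atom-identity table. Coordinates are stored as an
#' \code{n_atoms x 3 x n_models} array in Angstrom; the atom table carries
#' chain, residue number, residue name, atom name, element and a hetero flag.
#' Identity of the atom list across models is a class invariant: ensembles
#' whose models disagree cannot be constructed.
#'
#' @slot atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resname}, \code{atom}, \code{element}, \code{hetero}.
#' @slot coords numeric array, dim \code{c(nrow(atoms), 3, n_models)}.
#' @slot topology a [PorphyrinTopology-class] (or \code{NULL}).
#' @slot metadata free-form named list.
#'
#' @seealso [readEnsemble()], [assembleSandwich()], [selectAtoms()]
#' @exportClass StructureEnsemble
setClass("StructureEnsemble",
  representation(
    atoms = "data.frame",
    coords = "array",
    topology = "ANY",
    metadata = "list"
  )
)

setValidity("StructureEnsemble", function(object) {
  msgs <- character()
  at <- object@atoms
  need <- c("chain", "resno", "resname", "atom", "element", "hetero")
  if (!all(need %in% names(at)))
    msgs <- c(msgs, paste("atom table must have columns:",
                          paste(need, collapse = ", ")))
  d <- dim(object@coords)
  if (length(d) != 3L || d[2L] != 3L)
    msgs <- c(msgs, "coords must be an n_atoms x 3 x n_models array")
  else {
    if (d[1L] != nrow(at))
      msgs <- c(msgs, "coords first dimension must match the atom table")
    if (d[3L] < 1L) msgs <- c(msgs, "at least one model is required")
    if (!all(is.finite(object@coords)))
      msgs <- c(msgs, "all coordinates must be finite")
  }
  if (all(need %in% names(at))) {
    key <- paste(at$chain, at$resno, at$atom)
    if (anyDuplicated(key))
      msgs <- c(msgs, "(chain, residue number, atom name) must be unique")
  }
  if (length(msgs)) msgs else TRUE
})

#' Atom selection specification
#'
#' Filters for chains, a residue-number range, atom names, and the hetero
#' flag. Empty filters mean "no restriction". Selections are resolved against
#' the shared atom table of an ensemble, so a selection always picks the same
#' atoms in every model.
#'
#' @slot chain character vector of chain ids (empty = all).
#' @slot resnoRange numeric of length 0 or 2 (inclusive range).
#' @slot atomNames character vector of atom names (empty = all).
#' @slot hetero logical: \code{NA} = all, otherwise must match.
#'
#' @seealso [selectionSpec()], [selectAtoms()]
#' @exportClass SelectionSpec
setClass("SelectionSpec",
  representation(
    chain = "character",
    resnoRange = "numeric",
    atomNames = "character",
    hetero = "logical"
  ),
  prototype(chain = character(), resnoRange = numeric(),
            atomNames = character(), hetero = NA)
)

setValidity("SelectionSpec", function(object) {
  if (!length(object@resnoRange) %in% c(0L, 2L))
    return("resnoRange must be empty or c(lo, hi)")
  TRUE
})

#' Construct a [SelectionSpec-class]
#'
#' @param chain chain ids to keep (default: all).
#' @param resnoRange inclusive residue-number range \code{c(lo, hi)}
#'   (default: all).
#' @param atomNames atom names to keep (default: all).
#' @param hetero \code{NA} for all atoms, \code{TRUE} for hetero-only,
#'   \code{FALSE} for polymer-only.
#' @return a \code{SelectionSpec}.
#' @examples
#' selectionSpec(chain = "D", resnoRange = c(1, 10),
#'               atomNames = c("N", "CA", "C", "O"))
#' @export
selectionSpec <- function(chain = character(), resnoRange = numeric(),
                          atomNames = character(), hetero = NA) {
  new("SelectionSpec", chain = as.character(chain),
      resnoRange = as.numeric(resnoRange),
      atomNames = as.character(atomNames), hetero = as.logical(hetero))
}

#' Descriptor table for a structure ensemble
#'
#' Per-model geometric descriptors together with ensemble aggregates
#' (per interhelical-angle family). Produced by [describeEnsemble()].
#'
#' @slot perModel data.frame, one row per model.
#' @slot aggregates data.frame of per-family mean/sd summaries.
#'
#' @exportClass DescriptorTable
setClass("DescriptorTable",
  representation(perModel = "data.frame", aggregates = "data.frame")
)

setValidity("DescriptorTable", function(object) {
  if (nrow(object@perModel) < 1L) return("descriptor table must be non-empty")
  TRUE
})

#' Moessbauer velocity spectrum
#'
#' A baseline-normalized absorption spectrum on a strictly monotone velocity
#' grid (mm/s). \code{signal} is the absorption depth (positive = more
#' absorption).
#'
#' @slot velocity numeric velocity grid, mm/s, strictly monotone.
#' @slot signal numeric absorption values, same length.
#' @slot noiseSd estimate of the additive noise standard deviation.
#'
#' @seealso [simulateMossbauer()], [fitMossbauer()]
#' @exportClass MossbauerSpectrum
setClass("MossbauerSpectrum",
  representation(velocity = "numeric", signal = "numeric", noiseSd = "numeric")
)

setValidity("MossbauerSpectrum", function(object) {
  msgs <- character()
  if (length(object@velocity) != length(object@signal))
    msgs <- c(msgs, "velocity and signal must have the same length")
  d <- diff(object@velocity)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    msgs <- c(msgs, "velocity grid must be strictly monotone")
  if (length(msgs)) msgs else TRUE
})

#' Fitted Moessbauer quadrupole-doublet model
#'
#' Result of [fitMossbauer()]: per-doublet isomer shift \eqn{\delta},
#' quadrupole splitting \eqn{\Delta E_Q}, Lorentzian FWHM \eqn{\Gamma}
#' (all mm/s) and integrated area fraction, plus baseline, total depth and
#' residual statistics. Doublets are ordered by ascending \eqn{\Delta E_Q}.
#'
#' @slot doublets data.frame with columns \code{delta}, \code{deltaEQ},
#'   \code{gamma}, \code{areaFraction}.
#' @slot baseline fitted constant baseline.
#' @slot totalDepth fitted total absorption depth.
#' @slot residualSd residual standard deviation.
#' @slot converged logical.
#' @slot notes character vector of fit warnings (e.g. identifiability).
#'
#' @exportClass MossbauerFit
setClass("MossbauerFit",
  representation(doublets = "data.frame", baseline = "numeric",
                 totalDepth = "numeric", residualSd = "numeric",
                 converged = "logical", notes = "character")
)

#' Blueprint for a synthetic helix-porphyrin-helix sandwich
#'
#' Ground-truth parameters for [assembleSandwich()]: the two peptide
#' sequences (three-letter codes; Aib and Dab supported), the target
#' interhelical angle and axial-His orientation angle \eqn{\theta} (degrees),
#' which propionyl position (2 or 18) anchors the proximal chain, the
#' metal-to-distal-chain centre-of-mass offset (Angstrom), the per-model
#' isotropic coordinate jitter (Angstrom), the number of models and the seed.
#'
#' @slot tdSequence character vector, proximal (His-bearing) chain.
#' @slot dSequence character vector, distal chain.
#' @slot targetInterhelicalAngle degrees in [0, 180].
#' @slot targetThetaHis signed degrees in (-90, 90].
#' @slot tdAnchorPosition 2 or 18.
#' @slot metalOffset Angstrom.
#' @slot jitterSd Angstrom, >= 0.
#' @slot nModels integer >= 1.
#' @slot seed integer.
#'
#' @seealso [sandwichBlueprint()], [assembleSandwich()]
#' @exportClass SandwichBlueprint
setClass("SandwichBlueprint",
  representation(
    tdSequence = "character", dSequence = "character",
    targetInterhelicalAngle = "numeric", targetThetaHis = "numeric",
    tdAnchorPosition = "numeric", metalOffset = "numeric",
    jitterSd = "numeric", nModels = "integer", seed = "integer"
  )
)

setValidity("SandwichBlueprint", function(object) {
  msgs <- character()
  if (object@nModels < 1L) msgs <- c(msgs, "nModels must be >= 1")
  if (object@jitterSd < 0) msgs <- c(msgs, "jitterSd must be >= 0")
  if (!object@tdAnchorPosition %in% c(2, 18))
    msgs <- c(msgs, "tdAnchorPosition must be 2 or 18")
  if (length(msgs)) msgs else TRUE
})
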