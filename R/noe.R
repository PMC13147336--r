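# NOE intensity-to-distance calibration, restraint-class bookkeeping, and
# rule-based regioisomer / diastereomer assignment from dipolar contact
# patterns.

#' Read a NOE peak list from tabular text
#'
#' Expected columns: \code{chain_a, res_a, atom_a, chain_b, res_b, atom_b,
#' intensity} (tab- or whitespace-separated, header required).
#'
#' @param path path to the peak table.
#' @return data.frame peak list.
#' @export
readPeakList <- function(path) {
  if (!file.exists(path)) .stopf("ioError", "file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chain_a", "res_a", "atom_a", "chain_b", "res_b", "atom_b",
            "intensity")
  if (!all(need %in% names(df)))
    .stopf("parseError", "peak list must have columns: %s",
           paste(need, collapse = ", "))
  df
}

#' Sequence-separation class of an atom pair
#'
#' \code{intraresidue}: same chain, same residue; \code{sequential}: same
#' chain, |i-j| = 1; \code{medium}: same chain, 2 <= |i-j| <= 4;
#' \code{long}: |i-j| >= 5, inter-chain, or peptide-to-porphyrin.
#'
#' @param chainA,resA,chainB,resB pair addresses (vectorized).
#' @return character vector of classes.
#' @export
restraintClass <- function(chainA, resA, chainB, resB) {
  sep <- abs(resA - resB)
  ifelse(chainA != chainB, "long",
         ifelse(sep == 0, "intraresidue",
                ifelse(sep == 1, "sequential",
                       ifelse(sep <= 4, "medium", "long"))))
}

#' Calibrate NOE intensities into distance upper bounds
#'
#' Single-reference isolated-spin-pair calibration: \code{upper = d_ref *
#' (I_ref / I)^(1/6)}, clamped to \code{[1.8, 7.0]} Angstrom. Bounds are
#' invariant under a common rescaling of all intensities and the reference.
#' Per-class reference pairs can be supplied via \code{classReferences} for
#' CALIBA-style class-specific curves.
#'
#' @param peaks data.frame peak list (see [readPeakList()]).
#' @param dRef reference distance (Angstrom, in [1.8, 5.5]).
#' @param iRef reference intensity (> 0).
#' @param classReferences optional named list
#'   \code{list(medium = c(dRef=, iRef=), ...)} overriding the global
#'   reference per sequence-separation class.
#' @param clamp lower/upper bound clamp (Angstrom).
#' @return data.frame of restraints: the pair columns, \code{upper_bound},
#'   \code{seq_class}, and the pre-clamp \code{raw_bound}.
#' @export
calibrateNOE <- function(peaks, dRef, iRef, classReferences = NULL,
                         clamp = c(1.8, 7.0)) {
  if (any(peaks$intensity <= 0))
    .stopf("validationError", "all peak intensities must be positive")
  if (iRef <= 0) .stopf("validationError", "reference intensity must be > 0")
  if (dRef < 1.8 || dRef > 5.5)
    .stopf("validationError", "reference distance must be in [1.8, 5.5]")
  cls <- restraintClass(peaks$chain_a, peaks$res_a, peaks$chain_b, peaks$res_b)
  dr <- rep(dRef, nrow(peaks)); ir <- rep(iRef, nrow(peaks))
  for (cl in names(classReferences)) {
    sel <- cls == cl
    dr[sel] <- classReferences[[cl]][["dRef"]]
    ir[sel] <- classReferences[[cl]][["iRef"]]
  }
  raw <- dr * (ir / peaks$intensity)^(1 / 6)
  out <- peaks[, c("chain_a", "res_a", "atom_a", "chain_b", "res_b", "atom_b")]
  out$upper_bound <- pmin(clamp[2L], pmax(clamp[1L], raw))
  out$seq_class <- cls
  out$raw_bound <- raw
  out
}

#' Count restraints per sequence-separation class
#'
#' @param restraints data.frame with a \code{seq_class} column (and pair
#'   columns for the peptide/porphyrin tally).
#' @param nResidues number of peptide residues for the per-residue average.
#' @param porphyrinChain chain id of the porphyrin moiety, for the separate
#'   peptide-to-porphyrin tally (default "P"; NULL to skip).
#' @return list with \code{counts} (named: intraresidue, sequential, medium,
#'   long), \code{total}, \code{perResidue} (rounded to nearest integer),
#'   \code{perResidueRaw}, and \code{porphyrinContacts}.
#' @examples
#' # the class counts 123/91/74/70 over 24 residues average 15 per residue
#' @export
countRestraintClasses <- function(restraints, nResidues,
                                  porphyrinChain = "P") {
  stopifnot(nResidues >= 1L)
  lv <- c("intraresidue", "sequential", "medium", "long")
  counts <- vapply(lv, function(cl) sum(restraints$seq_class == cl),
                   integer(1L))
  total <- sum(counts)
  porph <- NA_integer_
  if (!is.null(porphyrinChain) &&
      all(c("chain_a", "chain_b") %in% names(restraints)))
    porph <- sum(restraints$chain_a == porphyrinChain |
                   restraints$chain_b == porphyrinChain)
  list(counts = counts, total = total,
       perResidue = round(total / nResidues),
       perResidueRaw = total / nResidues,
       porphyrinContacts = porph)
}

#' Write restraints in a CYANA-style upper-limit flat format
#'
#' One line per restraint: residue number, residue name placeholder, atom
#' name for both partners, then the upper bound in Angstrom.
#'
#' @param restraints data.frame from [calibrateNOE()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeUpperLimits <- function(restraints, path) {
  if (!nrow(restraints))
    .stopf("validationError", "refusing to write an empty restraint list")
  lines <- sprintf("%4d %-5s %-5s %4d %-5s %-5s %8.2f",
                   restraints$res_a, restraints$chain_a, restraints$atom_a,
                   restraints$res_b, restraints$chain_b, restraints$atom_b,
                   restraints$upper_bound)
  writeLines(lines, path)
  invisible(path)
}

#' Dipolar contact pattern of an anchor proton
#'
#' Measures, in one model, which porphyrin ring positions (substituents,
#' meso protons, propionyl groups) lie within \code{cutoff} of the anchor
#' proton(s), expressed in ring-position labels ("2", "3", ..., "20").
#'
#' @param ensemble a [StructureEnsemble-class] with porphyrin topology.
#' @param model model index.
#' @param anchorChain,anchorResidue,anchorAtoms address of the anchor
#'   proton(s), e.g. the Dab9 side-chain amine protons.
#' @param cutoff Angstrom.
#' @return list with \code{anchor} (label) and \code{positions} (character
#'   set of contacted ring positions).
#' @export
contactPattern <- function(ensemble, model = 1L, anchorChain = "D",
                           anchorResidue = 9L,
                           anchorAtoms = c("HD1", "HD2"), cutoff = 4.5) {
  topo <- topology(ensemble)
  at <- atoms(ensemble)
  xyz <- modelCoords(ensemble, model)
  ai <- which(at$chain == anchorChain & at$resno == anchorResidue &
                at$atom %in% anchorAtoms)
  if (!length(ai))
    .stopf("emptySelectionError", "anchor atoms not found (%s %d: %s)",
           anchorChain, anchorResidue, paste(anchorAtoms, collapse = ","))
  posMap <- c(topo@substituents,
              lapply(topo@mesoAtoms, identity))
  hit <- character()
  for (p in names(posMap)) {
    pi <- which(at$resname == topo@residueName & at$atom %in%
                  c(posMap[[p]],
                    # include the attached proton stubs of the group
                    paste0("H", posMap[[p]]),
                    sub("^C", "H", posMap[[p]]),
                    sub("^C", "HM", posMap[[p]]),
                    unlist(lapply(posMap[[p]], function(a)
                      paste0("H", substr(a, 2, 4), 1:2)))))
    if (!length(pi)) next
    dm <- sqrt(outer(rowSums(xyz[ai, , drop = FALSE]^2),
                     rowSums(xyz[pi, , drop = FALSE]^2), `+`) -
                 2 * xyz[ai, , drop = FALSE] %*% t(xyz[pi, , drop = FALSE]))
    if (min(dm) <= cutoff) hit <- c(hit, p)
  }
  list(anchor = sprintf("%s%d %s", anchorChain, anchorResidue,
                        paste(anchorAtoms, collapse = "/")),
       positions = unique(hit))
}

#' Assign the regioisomer from the anchoring contact pattern
#'
#' The distal-chain position-9 side-chain amine proton contacts the
#' propionyl that carries the distal chain: contacts to propionyl 2 mean
#' the proximal (TD) chain is anchored at position 18 (regioisomer 1);
#' contacts to propionyl 18 mean the TD chain is anchored at position 2
#' (regioisomer 2). Contacts to both propionyls are ambiguous; an empty
#' contact set is undetermined.
#'
#' @param pattern a contact pattern (list with \code{positions}), e.g. from
#'   [contactPattern()].
#' @param topology a [PorphyrinTopology-class] (defines the two propionyl
#'   positions; default [defaultTopology()]).
#' @return list with \code{isomer} ("isomer_1" or "isomer_2") and
#'   \code{tdAnchorPosition} (18 or 2).
#' @export
assignRegioisomer <- function(pattern, topology = defaultTopology()) {
  props <- names(topology@propionylAttachment)   # "2", "18"
  hits <- intersect(pattern$positions, props)
  if (!length(hits))
    .stopf("undeterminedError",
           "no propionyl contacts in the pattern; regioisomer undetermined")
  if (length(hits) > 1L)
    .stopf("ambiguityError",
           "contacts to both propionyls (2 and 18); regioisomer ambiguous")
  if (hits == "2") list(isomer = "isomer_1", tdAnchorPosition = 18)
  else list(isomer = "isomer_2", tdAnchorPosition = 2)
}

## ring positions on the two sides of the macrocycle, as seen along the
## N21-N23 axis: the 3..10 side and the 12..17 side
.ringSideA <- c("3", "5", "7", "8", "10")
.ringSideB <- c("12", "13", "15", "17")

#' Assign the diastereomer from Leu5 ring contacts and helix handedness
#'
#' Rule table: with a right-handed helix, a proximal chain anchored at
#' propionyl 18 whose Leu5 contacts the 3/5/7/8/10 side of the ring sits
#' above the porphyrin plane (Delta); anchored at 2 with contacts on the
#' 12/13/15/17 side it sits below the plane, which is again Delta. The two
#' mirrored anchor/side combinations give Lambda. Left-handed helices
#' (D-peptides) invert every call.
#'
#' @param leu5Contacts contact pattern (list with \code{positions} drawn
#'   from ring substituent/meso position labels).
#' @param tdAnchorPosition 2 or 18.
#' @param helixHandedness "right" (natural L-peptides) or "left".
#' @return "Delta" or "Lambda".
#' @export
assignDiastereomer <- function(leu5Contacts, tdAnchorPosition,
                               helixHandedness = c("right", "left")) {
  helixHandedness <- match.arg(helixHandedness)
  stopifnot(tdAnchorPosition %in% c(2, 18))
  pos <- leu5Contacts$positions
  inA <- any(pos %in% .ringSideA)
  inB <- any(pos %in% .ringSideB)
  if (!inA && !inB)
    .stopf("undeterminedError", "no ring-side contacts; diastereomer undetermined")
  if (inA && inB)
    .stopf("ambiguityError", "contacts span both ring sides; ambiguous")
  side <- if (inA) "A" else "B"
  call <- if ((tdAnchorPosition == 18 && side == "A") ||
                (tdAnchorPosition == 2 && side == "B")) "Delta" else "Lambda"
  if (helixHandedness == "left")
    call <- if (call == "Delta") "Lambda" else "Delta"
  call
}
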