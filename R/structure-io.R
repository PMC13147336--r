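# Multi-model structure I/O. PDB parsing and writing are delegated to bio3d;
# a light pre-scan of the raw MODEL blocks supplies the line-level parse
# diagnostics and the per-model atom-identity consistency check that the
# ensemble invariant requires (identical atom lists in every model, never
# silently repaired).

#' Load the default porphyrin/nonstandard-residue topology
#'
#' Reads the packaged deuteroporphyrin IX registry (Aib, Dab and the DPX
#' macrocycle). Deposited structure files may use other residue/atom codes;
#' supply your own config via [readTopologyConfig()] in that case.
#'
#' @return a [PorphyrinTopology-class].
#' @export
defaultTopology <- function() readTopologyConfig(.extdata("topology_dpix.yaml"))

#' Read a topology registry from a YAML config file
#'
#' The file layout mirrors the packaged \code{topology_dpix.yaml}: a
#' \code{porphyrin} block (residue name, metal atom, 24 ring atom names,
#' meso/substituent/propionyl position maps) and a \code{residues} block
#' registering nonstandard residue codes.
#'
#' @param path path to a YAML file.
#' @return a [PorphyrinTopology-class].
#' @export
readTopologyConfig <- function(path) {
  if (!file.exists(path))
    .stopf("ioError", "topology config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  p <- cfg$porphyrin
  if (is.null(p))
    .stopf("topologyError", "config %s has no 'porphyrin' block", path)
  new("PorphyrinTopology",
      residueName = as.character(p$residue_name),
      ringAtoms = as.character(unlist(p$ring_atoms)),
      mesoAtoms = vapply(p$meso_atoms, as.character, character(1L)),
      substituents = lapply(p$substituents, as.character),
      propionylAttachment = lapply(p$propionyl_attachment, as.character),
      metalAtom = as.character(p$metal_atom),
      residueRegistry = as.list(cfg$residues))
}

## Pre-scan a PDB file: per-model atom identity keys with line-level errors.
.scanPdbModels <- function(lines, path) {
  isAtom <- grepl("^(ATOM  |HETATM)", lines)
  isModel <- grepl("^MODEL", lines)
  modelOf <- cumsum(isModel)
  if (!any(isModel)) modelOf[] <- 1L
  atomLines <- which(isAtom)
  if (!length(atomLines))
    .stopf("parseError", "%s: no ATOM/HETATM records", path)
  for (ln in atomLines) {
    rec <- lines[ln]
    if (nchar(rec) < 54L)
      .stopf("parseError", "%s line %d: truncated coordinate record", path, ln)
    xyz <- suppressWarnings(as.numeric(c(substr(rec, 31, 38),
                                         substr(rec, 39, 46),
                                         substr(rec, 47, 54))))
    if (anyNA(xyz))
      .stopf("parseError", "%s line %d: non-numeric coordinates", path, ln)
  }
  key <- paste(trimws(substr(lines[atomLines], 13, 16)),
               trimws(substr(lines[atomLines], 18, 21)),
               trimws(substr(lines[atomLines], 22, 22)),
               trimws(substr(lines[atomLines], 23, 26)))
  split(key, pmax(1L, modelOf[atomLines]))
}

#' Read a multi-model structure ensemble from a PDB file
#'
#' One model per \code{MODEL} record (a file without \code{MODEL} records is
#' a 1-model ensemble). Atom identity (chain, residue, atom name) must be
#' identical across models; a mismatch raises a consistency error naming the
#' offending model. Hetero residues must be covered by the topology registry
#' (deuteroporphyrin, Aib, Dab by default), otherwise a topology error names
#' the unknown residue.
#'
#' @param path path to a PDB file.
#' @param topologyConfig optional path to a YAML topology config
#'   (see [readTopologyConfig()]); defaults to the packaged registry.
#' @return a [StructureEnsemble-class].
#' @export
readEnsemble <- function(path, topologyConfig = NULL) {
  if (!file.exists(path)) .stopf("ioError", "file not found: %s", path)
  topo <- if (is.null(topologyConfig)) defaultTopology()
          else readTopologyConfig(topologyConfig)

  lines <- readLines(path, warn = FALSE)
  keys <- .scanPdbModels(lines, path)
  if (length(keys) > 1L) {
    ref <- keys[[1L]]
    for (m in 2L:length(keys)) {
      if (length(keys[[m]]) != length(ref) || any(keys[[m]] != ref)) {
        bad <- if (length(keys[[m]]) != length(ref))
          sprintf("%d atoms vs %d in model 1", length(keys[[m]]), length(ref))
        else sprintf("first mismatch at atom %d (%s vs %s)",
                     which(keys[[m]] != ref)[1L],
                     keys[[m]][which(keys[[m]] != ref)[1L]],
                     ref[which(keys[[m]] != ref)[1L]])
        .stopf("consistencyError",
               "%s: atom identity differs between model %d and model 1 (%s)",
               path, m, bad)
      }
    }
  }

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  nm <- nrow(pdb$xyz)
  na <- nrow(at)
  coords <- array(NA_real_, dim = c(na, 3L, nm))
  for (m in seq_len(nm))
    coords[, , m] <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)

  element <- trimws(at$elesy)
  noEl <- is.na(element) | element == ""
  if (any(noEl))  # fall back on the first letter of the atom name
    element[noEl] <- substr(gsub("[^A-Za-z].*", "", trimws(at$elety[noEl])), 1, 1)

  atomsDf <- data.frame(
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    resname = trimws(at$resid),
    atom = trimws(at$elety),
    element = toupper(element),
    hetero = at$type == "HETATM",
    stringsAsFactors = FALSE)

  known <- c(names(topo@residueRegistry), topo@residueName,
             "HOH", "WAT", bio3d::aa.table$aa3)
  hetRes <- unique(atomsDf$resname[atomsDf$hetero])
  unknown <- setdiff(hetRes, known)
  # a lone metal HETATM is identified through the topology metal atom name
  unknown <- unknown[!unknown %in% atomsDf$resname[atomsDf$atom == topo@metalAtom]]
  if (length(unknown))
    .stopf("topologyError",
           "unknown hetero residue(s) with no topology mapping: %s",
           paste(unknown, collapse = ", "))

  new("StructureEnsemble", atoms = atomsDf, coords = coords,
      topology = topo, metadata = list(source = path))
}

#' Write a structure ensemble to a multi-model PDB file
#'
#' Coordinates are serialized at 0.001 Angstrom precision (PDB fixed
#' format); reading the file back reproduces them to that precision.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeEnsemble <- function(ensemble, path) {
  stopifnot(is(ensemble, "StructureEnsemble"))
  at <- ensemble@atoms
  nm <- nModels(ensemble)
  xyz <- t(vapply(seq_len(nm),
                  function(m) as.numeric(t(modelCoords(ensemble, m))),
                  numeric(3L * nAtoms(ensemble))))
  ok <- tryCatch({
    bio3d::write.pdb(file = path, xyz = xyz,
                     type = ifelse(at$hetero, "HETATM", "ATOM"),
                     resno = at$resno, resid = at$resname,
                     chain = ifelse(at$chain == "", " ", at$chain),
                     eleno = seq_len(nrow(at)), elety = at$atom,
                     elesy = at$element)
    # bio3d's multi-model writer emits every record as ATOM; restore the
    # HETATM flag from the atom table (atom order is fixed within models)
    if (any(at$hetero)) {
      lines <- readLines(path, warn = FALSE)
      coordLn <- grepl("^(ATOM  |HETATM)", lines)
      het <- rep_len(at$hetero, sum(coordLn))
      lines[coordLn][het] <- sub("^ATOM  ", "HETATM", lines[coordLn][het])
      writeLines(lines, path)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    .stopf("ioError", "cannot write %s: %s", path, conditionMessage(ok))
  invisible(path)
}

#' Select atoms of an ensemble
#'
#' Resolves a [SelectionSpec-class] against the shared atom table; because
#' all models share one atom list, the same atoms (in file order) are
#' selected in every model. An empty selection is an explicit error, never a
#' silent empty result.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param spec a [SelectionSpec-class].
#' @return integer vector of atom indices (ascending, i.e. order-preserving),
#'   usable to subset [modelCoords()] rows and the [atoms()] table.
#' @export
selectAtoms <- function(ensemble, spec = selectionSpec()) {
  stopifnot(is(ensemble, "StructureEnsemble"), is(spec, "SelectionSpec"))
  at <- ensemble@atoms
  keep <- rep(TRUE, nrow(at))
  if (length(spec@chain)) keep <- keep & at$chain %in% spec@chain
  if (length(spec@resnoRange))
    keep <- keep & at$resno >= spec@resnoRange[1L] &
      at$resno <= spec@resnoRange[2L]
  if (length(spec@atomNames)) keep <- keep & at$atom %in% spec@atomNames
  if (!is.na(spec@hetero)) keep <- keep & at$hetero == spec@hetero
  idx <- which(keep)
  if (!length(idx))
    .stopf("emptySelectionError", "selection matches no atoms")
  idx
}

#' Subset an ensemble to a selection
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param spec a [SelectionSpec-class] (or an integer index vector).
#' @return a [StructureEnsemble-class] restricted to the selected atoms, in
#'   the original atom order.
#' @export
subsetEnsemble <- function(ensemble, spec) {
  idx <- if (is.numeric(spec)) as.integer(spec) else selectAtoms(ensemble, spec)
  at <- ensemble@atoms[idx, , drop = FALSE]
  rownames(at) <- NULL
  new("StructureEnsemble", atoms = at,
      coords = ensemble@coords[idx, , , drop = FALSE],
      topology = ensemble@topology, metadata = ensemble@metadata)
}

#' Write an analysis report
#'
#' Tabular (\code{"tsv"}) output has a deterministic column order and fixed
#' numeric precision; structured (\code{"json"}) output round-trips values
#' losslessly and can be re-read with [readReport()]. A
#' [DescriptorTable-class] is written as its per-model rows followed by its
#' aggregate rows (marked in a \code{row_type} column).
#'
#' @param x a data.frame, a [DescriptorTable-class], or a named list of
#'   scalars/vectors (json only).
#' @param path output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @param digits significant digits for tsv serialization.
#' @return invisibly, \code{path}.
#' @export
writeReport <- function(x, path, format = c("tsv", "json"), digits = 6L) {
  format <- match.arg(format)
  if (is(x, "DescriptorTable")) {
    pm <- cbind(row_type = "model", x@perModel)
    ag <- x@aggregates
    agg <- cbind(row_type = "aggregate", ag)
    x <- merge(pm, agg, all = TRUE, sort = FALSE)
    x <- x[order(x$row_type != "model"), , drop = FALSE]
  }
  if (is.data.frame(x) && nrow(x) == 0L)
    .stopf("validationError", "refusing to write an empty table")
  if (is.list(x) && !is.data.frame(x) && length(x) == 0L)
    .stopf("validationError", "refusing to write an empty report")
  ok <- tryCatch({
    if (format == "tsv") {
      y <- x
      num <- vapply(y, is.numeric, logical(1L))
      y[num] <- lapply(y[num], signif, digits = digits)
      utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                           dataframe = "columns")
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    .stopf("ioError", "cannot write %s: %s", path, conditionMessage(ok))
  invisible(path)
}

#' Re-read a structured (json) report written by [writeReport()]
#'
#' @param path path to a json report.
#' @return the deserialized object (data.frames come back as data.frames).
#' @export
readReport <- function(path) {
  if (!file.exists(path)) .stopf("ioError", "file not found: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
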