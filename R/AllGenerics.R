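#' @include AllClasses.R
NULL

#' Accessors for ensembles and result objects
#'
#' \code{nModels} and \code{nAtoms} give the ensemble dimensions;
#' \code{atoms} returns the shared atom-identity table; \code{modelCoords}
#' the \code{n_atoms x 3} coordinate matrix of one model; \code{topology}
#' the attached [PorphyrinTopology-class]; \code{perModel} and
#' \code{aggregates} the two faces of a [DescriptorTable-class];
#' \code{doublets} the fitted doublet table of a [MossbauerFit-class].
#'
#' @param x object.
#' @param model 1-based model index.
#' @return see individual descriptions.
#' @name accessors
#' @aliases nModels nAtoms atoms modelCoords topology perModel aggregates
#'   doublets
NULL

#' @rdname accessors
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("modelCoords", function(x, model = 1L) standardGeneric("modelCoords"))
#' @rdname accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))
#' @rdname accessors
#' @export
setGeneric("perModel", function(x) standardGeneric("perModel"))
#' @rdname accessors
#' @export
setGeneric("aggregates", function(x) standardGeneric("aggregates"))
#' @rdname accessors
#' @export
setGeneric("doublets", function(x) standardGeneric("doublets"))

#' @rdname accessors
setMethod("nModels", "StructureEnsemble", function(x) dim(x@coords)[3L])
#' @rdname accessors
setMethod("nAtoms", "StructureEnsemble", function(x) nrow(x@atoms))
#' @rdname accessors
setMethod("atoms", "StructureEnsemble", function(x) x@atoms)
#' @rdname accessors
setMethod("modelCoords", "StructureEnsemble", function(x, model = 1L) {
  stopifnot(model >= 1L, model <= nModels(x))
  m <- x@coords[, , model, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  colnames(m) <- c("x", "y", "z")
  m
})
#' @rdname accessors
setMethod("topology", "StructureEnsemble", function(x) x@topology)
#' @rdname accessors
setMethod("perModel", "DescriptorTable", function(x) x@perModel)
#' @rdname accessors
setMethod("aggregates", "DescriptorTable", function(x) x@aggregates)
#' @rdname accessors
setMethod("doublets", "MossbauerFit", function(x) x@doublets)

setMethod("show", "StructureEnsemble", function(object) {
  cat(sprintf("StructureEnsemble: %d model(s), %d atoms\n",
              nModels(object), nAtoms(object)))
  ch <- table(object@atoms$chain[!object@atoms$hetero])
  if (length(ch))
    cat("  chains:", paste(sprintf("%s (%d atoms)", names(ch), ch),
                           collapse = ", "), "\n")
  nh <- sum(object@atoms$hetero)
  if (nh) cat(sprintf("  hetero atoms: %d\n", nh))
  if (is(object@topology, "PorphyrinTopology"))
    cat(sprintf("  porphyrin: %s (metal %s)\n",
                object@topology@residueName, object@topology@metalAtom))
})

setMethod("show", "PorphyrinTopology", function(object) {
  cat(sprintf("PorphyrinTopology '%s': 24 ring atoms, metal %s\n",
              object@residueName, object@metalAtom))
  cat("  propionyl attachment at ring positions:",
      paste(names(object@propionylAttachment), collapse = ", "), "\n")
})

setMethod("show", "DescriptorTable", function(object) {
  cat(sprintf("DescriptorTable: %d model(s)\n", nrow(object@perModel)))
  print(utils::head(object@perModel, 5L))
  if (nrow(object@perModel) > 5L) cat("  ...\n")
  cat("aggregates:\n")
  print(object@aggregates)
})

setMethod("show", "MossbauerSpectrum", function(object) {
  cat(sprintf(
    "MossbauerSpectrum: %d points, velocity %.2f .. %.2f mm/s (noise sd %.4g)\n",
    length(object@velocity), min(object@velocity), max(object@velocity),
    object@noiseSd))
})

setMethod("show", "MossbauerFit", function(object) {
  cat(sprintf("MossbauerFit: %d doublet(s), residual sd %.4g%s\n",
              nrow(object@doublets), object@residualSd,
              if (object@converged) "" else " [not converged]"))
  print(object@doublets, digits = 4L)
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

setMethod("show", "SandwichBlueprint", function(object) {
  cat(sprintf(
    paste0("SandwichBlueprint: TD %d-mer / D %d-mer, interhelical %.1f deg, ",
           "theta(His) %.1f deg, anchor %d, offset %.1f A, jitter %.2f A, ",
           "%d model(s), seed %d\n"),
    length(object@tdSequence), length(object@dSequence),
    object@targetInterhelicalAngle, object@targetThetaHis,
    as.integer(object@tdAnchorPosition), object@metalOffset,
    object@jitterSd, object@nModels, object@seed))
})
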