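# Packaged lookup tables: atomic masses, van der Waals radii, random-coil
# 1H shifts, Ramachandran region grid. All shipped as documented TSV files
# under extdata and cached per session.

.pkgCache <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "mimochrome")
  if (!nzchar(path))
    path <- file.path("inst", "extdata", file)  # pre-install (tests via pkgload)
  if (!file.exists(path)) stop("packaged data file not found: ", file)
  path
}

.loadTable <- function(file) {
  key <- paste0("tbl:", file)
  if (!exists(key, envir = .pkgCache))
    assign(key, utils::read.delim(.extdata(file), stringsAsFactors = FALSE),
           envir = .pkgCache)
  get(key, envir = .pkgCache)
}

#' Standard atomic masses
#'
#' @param elements character vector of element symbols (case-insensitive).
#' @return numeric vector of masses (u).
#' @export
atomicMass <- function(elements) {
  tbl <- .loadTable("atomic_masses.tsv")
  m <- tbl$mass[match(toupper(elements), tbl$element)]
  if (anyNA(m))
    .stopf("elementError", "unknown element(s): %s",
           paste(unique(elements[is.na(m)]), collapse = ", "))
  m
}

#' Van der Waals radii (Bondi-type)
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of radii (Angstrom); \code{NA} for unknown
#'   elements (callers decide whether that is an error).
#' @export
vdwRadius <- function(elements) {
  tbl <- .loadTable("vdw_radii.tsv")
  tbl$radius[match(toupper(elements), tbl$element)]
}

#' Random-coil 1H chemical shifts
#'
#' Wishart-style random-coil alpha-proton reference shifts, supplemented with
#' entries for the nonstandard residues Aib (beta-methyl) and Dab.
#'
#' @return data.frame with columns \code{resname}, \code{nucleus},
#'   \code{shift} (ppm).
#' @export
randomCoilTable <- function() .loadTable("random_coil_1h.tsv")

.ramaGrid <- function() .loadTable("ramachandran_regions.tsv")
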