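# Element radii tables. vdW values follow the common crystallographic set
# (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80; unknown elements fall back to
# 1.70 A). Covalent radii are single-bond values used for bond inference.

.vdwTable <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
               FE = 1.80, ZN = 1.39, MG = 1.73, CA = 1.74, MN = 1.80,
               "NA" = 2.27, K = 2.75, CU = 1.40, H = 1.20)

.covTable <- c(C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
               SE = 1.20, F = 0.57, CL = 1.02, BR = 1.20, I = 1.39,
               H = 0.31)

#' Van der Waals radii by element
#'
#' @param element character vector of element symbols (case-insensitive).
#' @param table optional named numeric vector overriding the built-in radii.
#' @param default radius used for elements absent from the table (Angstrom).
#' @return numeric vector of radii, Angstrom.
#' @export
vdwRadius <- function(element, table = NULL, default = 1.70) {
  tab <- .vdwTable
  if (!is.null(table)) tab[names(table)] <- table
  r <- unname(tab[toupper(element)])
  r[is.na(r)] <- default
  r
}

#' Covalent radii by element
#'
#' @inheritParams vdwRadius
#' @return numeric vector of single-bond covalent radii, Angstrom.
#' @export
covalentRadius <- function(element, table = NULL, default = 0.77) {
  tab <- .covTable
  if (!is.null(table)) tab[names(table)] <- table
  r <- unname(tab[toupper(element)])
  r[is.na(r)] <- default
  r
}

.standardResidues <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE")  # selenomethionine counted as a standard protein residue

.waterResidues <- c("HOH", "DOD", "WAT", "H2O")
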