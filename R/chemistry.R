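# Chemical reference tables: van der Waals radii, amino-acid alphabets,
# charged-atom and hydrogen-bond donor/acceptor definitions.

# Fixed published element radii (Angstrom). Heavy atoms only; hydrogens are
# excluded from all surface and contact computations.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                FE = 1.80, ZN = 1.39, MG = 1.73, CA = 1.97, MN = 1.80,
                "NA" = 2.27, K = 2.75, CU = 1.40, NI = 1.63, CO = 1.80)

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

.AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
          "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
.AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
names(.AA1) <- .AA3

# Common nonstandard residues mapped to their parent amino acid.
.AA_PARENT <- c(MSE = "MET", SEC = "CYS", PYL = "LYS", HSD = "HIS",
                HSE = "HIS", HSP = "HIS", CSO = "CYS", SEP = "SER",
                TPO = "THR", PTR = "TYR", MLY = "LYS", HYP = "PRO")

# Side-chain atoms carrying formal charge: N atoms of Arg/Lys/His (positive)
# and O atoms of Asp/Glu (negative).
.CHARGED_POS <- list(ARG = c("NE", "NH1", "NH2"),
                     LYS = "NZ",
                     HIS = c("ND1", "NE2"))
.CHARGED_NEG <- list(ASP = c("OD1", "OD2"),
                     GLU = c("OE1", "OE2"))

# Heavy-atom hydrogen-bond donors/acceptors per residue type, with the
# covalent antecedent used for the angular criterion. Backbone N (donor,
# antecedent CA) and O (acceptor, antecedent C) apply to every residue.
.HB_DONORS <- list(
  ARG = list(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
  ASN = list(ND2 = "CG"),
  GLN = list(NE2 = "CD"),
  HIS = list(ND1 = "CG", NE2 = "CD2"),
  LYS = list(NZ = "CE"),
  SER = list(OG = "CB"),
  THR = list(OG1 = "CB"),
  TRP = list(NE1 = "CD1"),
  TYR = list(OH = "CZ")
)
.HB_ACCEPTORS <- list(
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1", GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", MET = "SD"
)

#' Van der Waals radius of a chemical element
#'
#' Returns the heavy-atom van der Waals radius used throughout the package
#' (C 1.70, N 1.55, O 1.52, S 1.80 Angstrom, plus common hetero elements).
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  if (anyNA(r)) {
    bad <- unique(element[is.na(r)])
    stop("No van der Waals radius for element(s): ", paste(bad, collapse = ", "))
  }
  unname(r)
}

#' Convert three-letter residue codes to one-letter codes
#'
#' Nonstandard residues are mapped to their parent amino acid when known,
#' otherwise to "X".
#'
#' @param resid Character vector of three-letter residue codes.
#' @return Character vector of one-letter codes.
#' @export
aa321 <- function(resid) {
  resid <- toupper(resid)
  parent <- .AA_PARENT[resid]
  resid[!is.na(parent)] <- parent[!is.na(parent)]
  out <- .AA1[resid]
  out[is.na(out)] <- "X"
  unname(out)
}

#' The BLOSUM62 substitution matrix
#'
#' Standard half-bit integer BLOSUM62 matrix (from Biostrings), restricted to
#' the 20 standard amino acids plus X.
#'
#' @return Integer matrix with one-letter amino-acid row/column names.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  keep <- c(.AA1, "X")
  e$BLOSUM62[keep, keep]
}

# BLOSUM62 score of two one-letter amino acids (vectorized).
blosum_score <- function(a, b, mat = blosum62()) {
  a[!a %in% rownames(mat)] <- "X"
  b[!b %in% rownames(mat)] <- "X"
  mat[cbind(a, b)]
}
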