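# Structure model: parsing of two-chain complexes and the atom table used by
# all downstream computations.

#' Read a two-chain complex from a PDB or mmCIF file
#'
#' Parses an atomic-coordinate file (format chosen from the file extension:
#' `.cif`/`.mmcif` is read as mmCIF, anything else as PDB) and returns the two
#' requested chains as a `complex_structure`. Alternate locations are resolved
#' to the highest-occupancy record. Hydrogens and waters are kept in the atom
#' table but flagged, and are excluded from every surface and contact
#' computation.
#'
#' @param path Path to a PDB or mmCIF file.
#' @param chains Character vector of length 2: the receptor and ligand chain
#'   identifiers to extract.
#' @param id Optional structure identifier; defaults to the file name.
#' @return An object of class `complex_structure`; see [as_complex_structure()].
#' @export
read_structure <- function(path, chains, id = NULL) {
  if (!file.exists(path)) stop("File not found: ", path)
  if (length(chains) != 2L) stop("`chains` must name exactly two chains")
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  }
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  missing_ch <- setdiff(chains, unique(at$chain))
  if (length(missing_ch) > 0)
    stop("Chain(s) not present in ", path, ": ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  at <- at[at$chain %in% chains, , drop = FALSE]

  # Resolve alternate locations: keep the highest-occupancy record per atom.
  if (any(at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety)
    ord <- order(key, -at$o, at$alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$resid, at$elety)), ,
             drop = FALSE]
    at <- at[order(match(at$chain, chains), at$resno, at$insert), , drop = FALSE]
  }

  element <- toupper(at$elesy)
  element[is.na(element) | element == ""] <- guess_element(at$elety[is.na(element) | element == ""])

  atoms <- data.frame(
    eleno = at$eleno, elety = at$elety, resid = toupper(at$resid),
    chain = at$chain, resno = at$resno, insert = at$insert,
    x = at$x, y = at$y, z = at$z, o = at$o,
    element = element, stringsAsFactors = FALSE
  )
  as_complex_structure(atoms, chains = chains,
                       id = if (is.null(id)) basename(path) else id)
}

# Infer the element from a PDB atom name (digits stripped; two-letter
# elements recognized for common cases).
guess_element <- function(elety) {
  nm <- gsub("[0-9'\"]", "", toupper(trimws(elety)))
  two <- c("SE", "FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CU", "NI", "CO")
  el <- substr(nm, 1, 1)
  el[nm %in% two] <- nm[nm %in% two]
  el
}

#' Build a complex structure from an atom table
#'
#' Constructs the container used by every operation in the package from a
#' data frame of atoms. Derives element-based polarity flags, backbone flags,
#' van der Waals radii and per-residue identifiers.
#'
#' @param atoms Data frame with columns `elety`, `resid`, `chain`, `resno`,
#'   `x`, `y`, `z` and optionally `insert`, `element`, `eleno`, `o`.
#' @param chains Character vector of length 2 (receptor, ligand chain ids).
#' @param id Structure identifier string.
#' @return A list of class `complex_structure` with elements `atoms` (the
#'   augmented atom table), `chains` and `id`. Flag columns: `is_backbone`,
#'   `is_polar` (element N/O), `is_apolar` (side-chain C/S), `is_hydrogen`,
#'   `is_water`; `res_uid` is `"chain:resno:insert"`.
#' @export
as_complex_structure <- function(atoms, chains, id = "complex") {
  stopifnot(is.data.frame(atoms))
  need <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) stop("atoms lacks column(s): ", paste(miss, collapse = ", "))
  if (length(chains) != 2L || chains[1] == chains[2])
    stop("`chains` must be two distinct chain identifiers")
  if (!all(chains %in% atoms$chain)) stop("both chains must be non-empty")
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$eleno)) atoms$eleno <- seq_len(nrow(atoms))
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$elety)
  atoms$element <- toupper(atoms$element)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")

  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  atoms$is_water <- atoms$resid %in% c("HOH", "WAT", "DOD")
  atoms$is_backbone <- atoms$elety %in% .BACKBONE_ATOMS
  atoms$is_polar <- atoms$element %in% c("N", "O")
  atoms$is_apolar <- !atoms$is_backbone & atoms$element %in% c("C", "S")
  atoms$vdw <- NA_real_
  heavy <- !atoms$is_hydrogen
  atoms$vdw[heavy] <- vdw_radius(atoms$element[heavy])
  atoms$res_uid <- paste(atoms$chain, atoms$resno, atoms$insert, sep = ":")

  std <- atoms[!atoms$is_water & !atoms$is_hydrogen &
                 (atoms$resid %in% c(.AA3, names(.AA_PARENT))), , drop = FALSE]
  for (ch in chains) {
    if (sum(std$chain == ch) == 0)
      stop("chain ", ch, " contains no standard amino-acid residue")
  }

  structure(list(atoms = atoms, chains = chains, id = id),
            class = "complex_structure")
}

# Heavy protein atoms used in all surface/contact computations.
protein_atoms <- function(x) {
  a <- x$atoms
  a[!a$is_hydrogen & !a$is_water, , drop = FALSE]
}

#' Residue table of a complex structure
#'
#' One row per (non-water) residue with its reference point: the Cb atom, or
#' Ca for glycine (and for any residue lacking a Cb).
#'
#' @param x A `complex_structure`.
#' @return Data frame with columns `res_uid`, `chain`, `resno`, `insert`,
#'   `resid`, `aa` (one-letter code) and reference coordinates `rx`, `ry`,
#'   `rz` (NA when neither Cb nor Ca is present).
#' @export
residue_table <- function(x) {
  a <- protein_atoms(x)
  first <- !duplicated(a$res_uid)
  res <- data.frame(res_uid = a$res_uid[first], chain = a$chain[first],
                    resno = a$resno[first], insert = a$insert[first],
                    resid = a$resid[first], stringsAsFactors = FALSE)
  res$aa <- aa321(res$resid)
  cb <- a[a$elety == "CB", ]
  ca <- a[a$elety == "CA", ]
  ref <- rbind(cb, ca[!(ca$res_uid %in% cb$res_uid), ])
  m <- match(res$res_uid, ref$res_uid)
  res$rx <- ref$x[m]; res$ry <- ref$y[m]; res$rz <- ref$z[m]
  res[order(match(res$chain, x$chains), res$resno, res$insert), , drop = FALSE]
}

#' Amino-acid sequence of one chain
#'
#' @param x A `complex_structure`.
#' @param chain Chain identifier.
#' @return Single string of one-letter codes in residue order.
#' @export
chain_sequence <- function(x, chain) {
  res <- residue_table(x)
  paste(res$aa[res$chain == chain], collapse = "")
}

#' @export
print.complex_structure <- function(x, ...) {
  res <- residue_table(x)
  cat("Complex structure:", x$id, "\n")
  for (ch in x$chains) {
    n <- sum(res$chain == ch)
    cat(sprintf("  chain %s: %d residues\n", ch, n))
  }
  cat(sprintf("  %d heavy protein atoms\n", nrow(protein_atoms(x))))
  invisible(x)
}

#' Write a complex structure to a PDB file
#'
#' @param x A `complex_structure`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure_pdb <- function(x, path) {
  a <- x$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = a$chain, insert = a$insert,
                   o = a$o, b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}
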