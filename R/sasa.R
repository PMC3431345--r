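# Solvent-accessible surface area: Shrake-Rupley style numerical SASA on a
# deterministic spiral point set, and per-residue buried area upon binding.

# Deterministic, quasi-uniform points on the unit sphere (Fibonacci spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area of a complex or its isolated chains
#'
#' Numerical SASA: each heavy protein atom is expanded by the probe radius and
#' sampled with a deterministic spiral point set; points inside any other
#' expanded atom are buried. In `context = "monomer"` each chain is computed
#' in isolation (occlusion only by atoms of the same chain); in
#' `context = "complex"` both chains occlude each other. Hydrogens and waters
#' never contribute.
#'
#' @param x A `complex_structure`.
#' @param context `"complex"` or `"monomer"`.
#' @param probe_radius Probe radius in Angstrom (water: 1.4).
#' @param n_points Number of surface sample points per atom (>= 100).
#' @return An object of class `sasa_result`: list with `atoms` (data frame
#'   `res_uid`, `chain`, `elety`, `area`), `residues` (data frame `res_uid`,
#'   `chain`, `area`), `context`, `probe_radius`, `n_points`.
#' @export
compute_sasa <- function(x, context = c("complex", "monomer"),
                         probe_radius = 1.4, n_points = 960) {
  context <- match.arg(context)
  if (n_points < 100) stop("n_points must be >= 100")
  a <- protein_atoms(x)
  if (anyNA(a$vdw)) {
    bad <- a[is.na(a$vdw), ]
    stop("atom(s) without radius: ",
         paste(paste0(bad$res_uid, "/", bad$elety), collapse = ", "))
  }
  pts <- sphere_points(n_points)
  area <- numeric(nrow(a))
  groups <- if (context == "monomer") split(seq_len(nrow(a)), a$chain) else
    list(seq_len(nrow(a)))
  for (idx in groups) {
    xyz <- as.matrix(a[idx, c("x", "y", "z")])
    rad <- a$vdw[idx] + probe_radius
    n <- length(idx)
    # pairwise squared distances for neighbor lists
    d2 <- as.matrix(stats::dist(xyz))^2
    for (k in seq_len(n)) {
      rk <- rad[k]
      nb <- which(d2[k, ] < (rk + rad)^2)
      nb <- nb[nb != k]
      p <- pts * rk
      p <- sweep(p, 2, xyz[k, ], "+")
      free <- rep(TRUE, n_points)
      if (length(nb) > 0) {
        # closest occluders first: prunes the candidate points fastest
        nb <- nb[order(d2[k, nb])]
        for (j in nb) {
          if (!any(free)) break
          dx <- p[free, 1] - xyz[j, 1]
          dy <- p[free, 2] - xyz[j, 2]
          dz <- p[free, 3] - xyz[j, 3]
          free[free] <- (dx * dx + dy * dy + dz * dz) >= rad[j]^2
        }
      }
      area[idx[k]] <- 4 * pi * rk^2 * sum(free) / n_points
    }
  }
  atoms <- data.frame(res_uid = a$res_uid, chain = a$chain, elety = a$elety,
                      area = area, stringsAsFactors = FALSE)
  rs <- stats::aggregate(area ~ res_uid + chain, data = atoms, FUN = sum)
  structure(list(atoms = atoms, residues = rs, context = context,
                 probe_radius = probe_radius, n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("SASA (%s context, probe %.2f A, %d points/atom)\n",
              x$context, x$probe_radius, x$n_points))
  cat(sprintf("  total area: %.1f A^2 over %d residues\n",
              sum(x$atoms$area), nrow(x$residues)))
  invisible(x)
}

#' Per-residue buried surface area upon binding
#'
#' dASA(residue) = SASA in the isolated chain minus SASA in the complex.
#' Residues far from the partner chain have dASA ~ 0; residues fully covered
#' by the partner bury their whole monomer SASA.
#'
#' @param x A `complex_structure`.
#' @param probe_radius,n_points Passed to [compute_sasa()].
#' @param sasa_monomer,sasa_complex Optional precomputed [compute_sasa()]
#'   results (to avoid recomputation inside pipelines).
#' @return Data frame with columns `res_uid`, `chain`, `sasa_monomer`,
#'   `sasa_complex`, `delta`.
#' @export
delta_rasa <- function(x, probe_radius = 1.4, n_points = 960,
                       sasa_monomer = NULL, sasa_complex = NULL) {
  if (is.null(sasa_monomer))
    sasa_monomer <- compute_sasa(x, "monomer", probe_radius, n_points)
  if (is.null(sasa_complex))
    sasa_complex <- compute_sasa(x, "complex", probe_radius, n_points)
  mono <- sasa_monomer$residues
  comp <- sasa_complex$residues
  m <- match(mono$res_uid, comp$res_uid)
  out <- data.frame(res_uid = mono$res_uid, chain = mono$chain,
                    sasa_monomer = mono$area, sasa_complex = comp$area[m],
                    stringsAsFactors = FALSE)
  out$delta <- out$sasa_monomer - out$sasa_complex
  out
}
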