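# Synthetic complexes and interolog pairs with planted, known interface
# features: the test bed standing in for an external structure dataset.
#
# Geometry: each chain is a jittered square lattice of residues; chain A lies
# in the z = 0 plane with side chains pointing +z, chain B faces it at z =
# `gap` with side chains pointing -z. Side chains are simplified straight
# templates with real atom names and elements, so SASA, contact typing,
# hydrogen-bond geometry and patch detection all operate unmodified. Planted
# interactions are tuned by scaling side-chain extension so that the two tip
# atoms sit at an exact target distance.

# Side-chain templates: per heavy atom, lateral offset `l` (along a unit
# in-plane direction) and height `dz` above Ca (Cb at 1.53 A).
.SC_TEMPLATES <- list(
  GLY = data.frame(name = character(), l = numeric(), dz = numeric()),
  ALA = data.frame(name = "CB", l = 0, dz = 1.53),
  SER = data.frame(name = c("CB", "OG"), l = c(0, 0), dz = c(1.53, 2.9)),
  CYS = data.frame(name = c("CB", "SG"), l = c(0, 0), dz = c(1.53, 3.0)),
  THR = data.frame(name = c("CB", "OG1", "CG2"), l = c(0, 0.7, -0.7),
                   dz = c(1.53, 2.8, 2.8)),
  VAL = data.frame(name = c("CB", "CG1", "CG2"), l = c(0, 0.5, -0.5),
                   dz = c(1.53, 2.8, 2.8)),
  LEU = data.frame(name = c("CB", "CG", "CD1", "CD2"), l = c(0, 0, 0.8, -0.8),
                   dz = c(1.53, 2.8, 4.1, 4.1)),
  ILE = data.frame(name = c("CB", "CG1", "CG2", "CD1"), l = c(0, 0.7, -0.7, 0.7),
                   dz = c(1.53, 2.8, 2.8, 4.1)),
  MET = data.frame(name = c("CB", "CG", "SD", "CE"), l = c(0, 0, 0, 0),
                   dz = c(1.53, 2.8, 4.1, 5.4)),
  PRO = data.frame(name = c("CB", "CG", "CD"), l = c(0, 0.7, -0.7),
                   dz = c(1.53, 2.6, 2.6)),
  PHE = data.frame(name = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                   l = c(0, 0, 1.2, -1.2, 1.2, -1.2, 0),
                   dz = c(1.53, 2.8, 3.6, 3.6, 5.0, 5.0, 5.8)),
  TYR = data.frame(name = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
                   l = c(0, 0, 1.2, -1.2, 1.2, -1.2, 0, 0),
                   dz = c(1.53, 2.8, 3.6, 3.6, 5.0, 5.0, 5.8, 7.1)),
  TRP = data.frame(name = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3",
                            "CZ2", "CZ3", "CH2"),
                   l = c(0, 0, 1.1, -1.1, 1.1, 0, -2.2, 0.8, -2.2, -1.0),
                   dz = c(1.53, 2.8, 3.7, 3.7, 5.0, 5.0, 4.4, 6.2, 5.8, 6.6)),
  ASP = data.frame(name = c("CB", "CG", "OD1", "OD2"), l = c(0, 0, 0.8, -0.8),
                   dz = c(1.53, 2.8, 3.6, 3.6)),
  GLU = data.frame(name = c("CB", "CG", "CD", "OE1", "OE2"),
                   l = c(0, 0, 0, 0.8, -0.8), dz = c(1.53, 2.8, 4.1, 4.9, 4.9)),
  ASN = data.frame(name = c("CB", "CG", "OD1", "ND2"), l = c(0, 0, 0.8, -0.8),
                   dz = c(1.53, 2.8, 3.6, 3.6)),
  GLN = data.frame(name = c("CB", "CG", "CD", "OE1", "NE2"),
                   l = c(0, 0, 0, 0.8, -0.8), dz = c(1.53, 2.8, 4.1, 4.9, 4.9)),
  LYS = data.frame(name = c("CB", "CG", "CD", "CE", "NZ"), l = rep(0, 5),
                   dz = c(1.53, 2.8, 4.1, 5.4, 6.6)),
  ARG = data.frame(name = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
                   l = c(0, 0, 0, 0, 0, 0.8, -0.8),
                   dz = c(1.53, 2.8, 4.1, 5.4, 6.6, 7.4, 7.4)),
  HIS = data.frame(name = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
                   l = c(0, 0, 0.9, -0.9, 0.9, -0.9),
                   dz = c(1.53, 2.8, 3.6, 3.6, 5.0, 5.0))
)

sc_tip <- function(aa) {
  t <- .SC_TEMPLATES[[aa]]
  if (nrow(t) == 0) stop("glycine has no side-chain tip")
  t[which.max(t$dz), ]
}

# Run expr with a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

#' Specification for a synthetic two-chain complex
#'
#' Defines the toy lattice and every planted interface feature: salt bridges,
#' hydrogen-bond pairs, one contiguous apolar patch per side, isolated apolar
#' contact pairs, one anchor residue protruding into a pocket, and one
#' support-region site.
#'
#' @param nx,ny Lattice dimensions per chain (residues).
#' @param spacing Lattice spacing in Angstrom (> 3.8).
#' @param gap Distance between the two Ca planes.
#' @param n_salt_bridges,n_hbonds,n_scatter_apolar Planted feature counts.
#' @param patch_cells Dimensions (cells) of the planted apolar patch block.
#' @param anchor Plant an anchor residue (Trp in a Leu-lined pocket).
#' @param support_site Plant one support-region residue (an under-layer of
#'   residues raises its monomer burial).
#' @param salt_bridge_distance,hbond_distance,patch_contact_distance,scatter_contact_distance
#'   Target tip-atom distances for the planted interactions (Angstrom).
#' @param anchor_tip Height of the anchor side-chain tip above the chain-A
#'   plane.
#' @param jitter Uniform xy jitter half-width applied per lattice cell.
#' @param seed Integer seed (placement of the random features).
#' @return A list of class `toy_spec`.
#' @export
toy_spec <- function(nx = 11, ny = 11, spacing = 4.9, gap = 9.2,
                     n_salt_bridges = 2, n_hbonds = 2, patch_cells = c(2, 2),
                     n_scatter_apolar = 2, anchor = TRUE, support_site = TRUE,
                     salt_bridge_distance = 2.9, hbond_distance = 3.0,
                     patch_contact_distance = 4.2,
                     scatter_contact_distance = 4.0, anchor_tip = 5.8,
                     jitter = 0.05, seed = 1) {
  if (spacing <= 3.8) stop("lattice spacing must exceed 3.8 A")
  spec <- as.list(environment())
  class(spec) <- "toy_spec"
  spec
}

#' Build a synthetic two-chain complex with planted interface features
#'
#' Constructs the lattice complex described by a [toy_spec()] and returns the
#' structure together with a ground-truth ledger of every planted feature.
#' Planted salt bridges sit at the requested N-O distance (detected by
#' [salt_bridges()]), hydrogen-bond pairs satisfy the geometric criteria of
#' [hydrogen_bonds()], the apolar patch blocks are contiguous under the patch
#' adjacency rule and face each other, and the anchor residue buries > 100
#' A^2 by construction.
#'
#' @param spec A [toy_spec()].
#' @return A list of class `toy_complex`: `structure` (a
#'   `complex_structure`), `ledger` (planted features: `salt_bridges`,
#'   `hbonds`, `patch_a`, `patch_b`, `scatter`, `anchor`, `support`,
#'   `planted` = all planted uids), `spec`.
#' @export
build_toy_complex <- function(spec = toy_spec()) {
  with_seed(spec$seed, build_toy_complex_impl(spec))
}

build_toy_complex_impl <- function(spec) {
  nx <- spec$nx; ny <- spec$ny; a <- spec$spacing; z0 <- spec$gap
  if (nx < 7 || ny < 7) stop("lattice must be at least 7 x 7")
  jx <- matrix(stats::runif(nx * ny, -spec$jitter, spec$jitter), nx, ny)
  jy <- matrix(stats::runif(nx * ny, -spec$jitter, spec$jitter), nx, ny)
  cx <- function(i, j) (i - 1) * a + jx[i, j]
  cy <- function(i, j) (j - 1) * a + jy[i, j]

  # per-cell residue plan, per chain: aa, stretch factor, lateral direction
  plan <- list(A = list(), B = list())
  key <- function(i, j) paste(i, j, sep = ",")
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    plan$A[[key(i, j)]] <- list(aa = "ALA", f = 1, lat = c(1, 0))
    plan$B[[key(i, j)]] <- list(aa = "ALA", f = 1, lat = c(1, 0))
  }
  status <- matrix("plain", nx, ny)
  ring1 <- function(i, j) {
    d <- expand.grid(di = -1:1, dj = -1:1)
    d <- d[!(d$di == 0 & d$dj == 0), ]
    out <- cbind(i + d$di, j + d$dj)
    out[out[, 1] >= 1 & out[, 1] <= nx & out[, 2] >= 1 & out[, 2] <= ny, ,
        drop = FALSE]
  }
  mark <- function(cells, what) {
    for (r in seq_len(nrow(cells))) status[cells[r, 1], cells[r, 2]] <<- what
  }

  # stretch factors so that the two tip atoms sit at distance d
  plant_pair <- function(i, j, aa_a, aa_b, d, lat_a = c(1, 0),
                         lat_b = c(1, 0)) {
    ta <- sc_tip(aa_a); tb <- sc_tip(aa_b)
    pa <- c(cx(i, j), cy(i, j)) + lat_a * ta$l
    pb <- c(cx(i, j), cy(i, j)) + lat_b * tb$l
    p <- sqrt(sum((pa - pb)^2))
    if (p >= d) stop("infeasible planted pair: lateral offset ", round(p, 2),
                     " exceeds target distance ", d)
    dz <- sqrt(d^2 - p^2)
    ztip <- (z0 - dz) / 2
    fa <- (ztip - 1.53) / (ta$dz - 1.53)
    fb <- (ztip - 1.53) / (tb$dz - 1.53)
    if (fa <= 0.05 || fb <= 0.05)
      stop("infeasible planted pair: gap too small for ", aa_a, "/", aa_b)
    plan$A[[key(i, j)]] <<- list(aa = aa_a, f = fa, lat = lat_a)
    plan$B[[key(i, j)]] <<- list(aa = aa_b, f = fb, lat = lat_b)
  }

  center <- c(ceiling(nx / 2), ceiling(ny / 2))
  ledger <- list(salt_bridges = NULL, hbonds = NULL, patch_a = character(),
                 patch_b = character(), scatter = NULL, anchor = NULL,
                 support = NULL)
  cells_of <- list()  # feature name -> cells, resolved to uids later

  # --- anchor: Trp at the A-side center protruding into a Leu-lined pocket
  if (spec$anchor) {
    i <- center[1]; j <- center[2]
    f_trp <- (spec$anchor_tip - 1.53) / (sc_tip("TRP")$dz - 1.53)
    plan$A[[key(i, j)]] <- list(aa = "TRP", f = f_trp, lat = c(1, 0))
    plan$B[[key(i, j)]] <- list(aa = "GLY", f = 1, lat = c(1, 0))
    r1 <- ring1(i, j)
    for (r in seq_len(nrow(r1))) {
      ii <- r1[r, 1]; jj <- r1[r, 2]
      plan$A[[key(ii, jj)]] <- list(aa = "GLY", f = 1, lat = c(1, 0))
      ortho <- abs(ii - i) + abs(jj - j) == 1  # 4-neighborhood lines the pocket
      if (ortho) {
        to_center <- c(cx(i, j) - cx(ii, jj), cy(i, j) - cy(ii, jj))
        to_center <- to_center / sqrt(sum(to_center^2))
        f_leu <- (z0 - spec$anchor_tip + 2.3 - 1.53) / (sc_tip("LEU")$dz - 1.53)
        plan$B[[key(ii, jj)]] <- list(aa = "LEU", f = f_leu, lat = to_center)
      }
    }
    mark(rbind(center, r1), "anchor")
    cells_of$anchor <- matrix(center, 1)
    cells_of$pocket <- r1[abs(r1[, 1] - i) + abs(r1[, 2] - j) == 1, ,
                          drop = FALSE]
  }

  # --- apolar patch block (both sides), with a Gly moat around it
  pw <- spec$patch_cells[1]; ph <- spec$patch_cells[2]
  if (pw * ph > 0) {
    bi <- 2:(1 + pw); bj <- 2:(1 + ph)
    block <- as.matrix(expand.grid(bi, bj))
    moat <- unique(do.call(rbind, lapply(seq_len(nrow(block)), function(r)
      ring1(block[r, 1], block[r, 2]))))
    moat <- moat[!paste(moat[, 1], moat[, 2]) %in% paste(block[, 1], block[, 2]), ,
                 drop = FALSE]
    if (spec$anchor) {
      keep_out <- rbind(cells_of$anchor, cells_of$pocket)
      if (any(paste(block[, 1], block[, 2]) %in%
              paste(keep_out[, 1], keep_out[, 2])) ||
          any(paste(moat[, 1], moat[, 2]) %in%
              paste(keep_out[, 1], keep_out[, 2])))
        stop("lattice too small to separate patch block from anchor zone")
    }
    diag_lat <- c(1, 1) / sqrt(2)
    for (r in seq_len(nrow(block)))
      plant_pair(block[r, 1], block[r, 2], "LEU", "LEU",
                 spec$patch_contact_distance, diag_lat, diag_lat)
    for (r in seq_len(nrow(moat))) {
      plan$A[[key(moat[r, 1], moat[r, 2])]] <- list(aa = "GLY", f = 1,
                                                    lat = c(1, 0))
      plan$B[[key(moat[r, 1], moat[r, 2])]] <- list(aa = "GLY", f = 1,
                                                    lat = c(1, 0))
    }
    mark(rbind(block, moat), "patch")
    cells_of$patch <- block
  }

  # --- support site: one cell backed by an under-layer ring (chain A)
  under <- NULL
  if (spec$support_site) {
    si <- nx - 2; sj <- ny - 2
    if (status[si, sj] != "plain") stop("lattice too small for support site")
    mark(rbind(c(si, sj), ring1(si, sj)), "support")
    cells_of$support <- matrix(c(si, sj), 1)
    ang <- seq(0, 2 * pi, length.out = 9)[-9]
    under <- data.frame(x = cx(si, sj) + 3.46 * cos(ang),
                        y = cy(si, sj) + 3.46 * sin(ang), z = -3.4)
  }

  # --- randomly placed single-cell features: salt bridges, hbonds, scatter
  interior <- as.matrix(expand.grid(2:(nx - 1), 2:(ny - 1)))
  interior <- interior[sample.int(nrow(interior)), , drop = FALSE]
  take_cell <- function() {
    for (r in seq_len(nrow(interior))) {
      i <- interior[r, 1]; j <- interior[r, 2]
      if (status[i, j] != "plain") next
      nb <- ring1(i, j)
      if (!all(status[nb] %in% c("plain", "reserved"))) next
      status[i, j] <<- "feature"
      # a Gly moat isolates the feature's side chains from all other
      # side-chain carbons (prevents spurious patch adjacencies)
      for (r2 in seq_len(nrow(nb))) {
        ii <- nb[r2, 1]; jj <- nb[r2, 2]
        plan$A[[key(ii, jj)]] <<- list(aa = "GLY", f = 1, lat = c(1, 0))
        plan$B[[key(ii, jj)]] <<- list(aa = "GLY", f = 1, lat = c(1, 0))
        status[ii, jj] <<- "reserved"
      }
      return(c(i, j))
    }
    stop("infeasible spec: not enough free lattice cells for planted features")
  }
  sb_cells <- hb_cells <- sc_cells <- NULL
  for (k in seq_len(spec$n_salt_bridges)) {
    cell <- take_cell()
    pos <- sample(c("LYS", "ARG"), 1); neg <- sample(c("GLU", "ASP"), 1)
    if (stats::runif(1) < 0.5)
      plant_pair(cell[1], cell[2], pos, neg, spec$salt_bridge_distance)
    else
      plant_pair(cell[1], cell[2], neg, pos, spec$salt_bridge_distance)
    sb_cells <- rbind(sb_cells, cell)
  }
  for (k in seq_len(spec$n_hbonds)) {
    cell <- take_cell()
    don <- sample(c("SER", "THR"), 1); acc <- sample(c("ASN", "GLN"), 1)
    if (stats::runif(1) < 0.5)
      plant_pair(cell[1], cell[2], don, acc, spec$hbond_distance)
    else
      plant_pair(cell[1], cell[2], acc, don, spec$hbond_distance)
    hb_cells <- rbind(hb_cells, cell)
  }
  diag_lat <- c(1, 1) / sqrt(2)
  for (k in seq_len(spec$n_scatter_apolar)) {
    cell <- take_cell()
    plant_pair(cell[1], cell[2], "VAL", "VAL", spec$scatter_contact_distance,
               diag_lat, diag_lat)
    sc_cells <- rbind(sc_cells, cell)
  }
  cells_of$salt_bridges <- sb_cells
  cells_of$hbonds <- hb_cells
  cells_of$scatter <- sc_cells

  # --- emit atoms
  make_residue <- function(aa, chain, resno, ca, orient, lat, f) {
    t <- .SC_TEMPLATES[[aa]]
    bb <- data.frame(
      elety = c("N", "CA", "C", "O"),
      x = ca[1] + c(-1.45, 0, 1.45, 1.95), y = ca[2] + c(0.5, 0, 0.5, 1.55),
      z = ca[3], stringsAsFactors = FALSE)
    sc <- NULL
    if (nrow(t) > 0) {
      dz <- ifelse(t$dz <= 1.53, t$dz, 1.53 + (t$dz - 1.53) * f)
      sc <- data.frame(elety = t$name, x = ca[1] + lat[1] * t$l,
                       y = ca[2] + lat[2] * t$l, z = ca[3] + orient * dz,
                       stringsAsFactors = FALSE)
    }
    at <- rbind(bb, sc)
    at$resid <- aa; at$chain <- chain; at$resno <- resno
    at
  }
  atoms <- list(); uid_map <- list(A = list(), B = list())
  for (ch in c("A", "B")) {
    resno <- 0
    zca <- if (ch == "A") 0 else z0
    orient <- if (ch == "A") 1 else -1
    for (j in seq_len(ny)) for (i in seq_len(nx)) {
      resno <- resno + 1
      p <- plan[[ch]][[key(i, j)]]
      # glycine cells ride at the Cb plane so their Ca reference point keeps
      # the same neighbor geometry as the Cb of side-chain-bearing cells
      zres <- if (p$aa == "GLY") zca + orient * 1.5 else zca
      atoms[[length(atoms) + 1]] <-
        make_residue(p$aa, ch, resno, c(cx(i, j), cy(i, j), zres), orient,
                     p$lat, p$f)
      uid_map[[ch]][[key(i, j)]] <- paste(ch, resno, "", sep = ":")
    }
    if (ch == "A" && !is.null(under)) {
      for (r in seq_len(nrow(under))) {
        resno <- resno + 1
        atoms[[length(atoms) + 1]] <-
          make_residue("ALA", "A", resno,
                       c(under$x[r], under$y[r], under$z[r]), -1, c(1, 0), 1)
      }
    }
  }
  atoms <- do.call(rbind, atoms)
  x <- as_complex_structure(atoms, chains = c("A", "B"), id = "toy-complex")

  uid_at <- function(ch, cells) {
    if (is.null(cells)) return(character())
    vapply(seq_len(nrow(cells)),
           function(r) uid_map[[ch]][[key(cells[r, 1], cells[r, 2])]], "")
  }
  pairdf <- function(cells) {
    if (is.null(cells)) return(data.frame(uid_a = character(),
                                          uid_b = character()))
    data.frame(uid_a = uid_at("A", cells), uid_b = uid_at("B", cells),
               stringsAsFactors = FALSE)
  }
  ledger$salt_bridges <- pairdf(cells_of$salt_bridges)
  ledger$hbonds <- pairdf(cells_of$hbonds)
  ledger$scatter <- pairdf(cells_of$scatter)
  ledger$patch_a <- uid_at("A", cells_of$patch)
  ledger$patch_b <- uid_at("B", cells_of$patch)
  if (spec$anchor) {
    ledger$anchor <- uid_at("A", cells_of$anchor)
    ledger$pocket <- uid_at("B", cells_of$pocket)
  }
  if (spec$support_site) ledger$support <- uid_at("A", cells_of$support)
  ledger$planted <- unique(c(ledger$salt_bridges$uid_a, ledger$salt_bridges$uid_b,
                             ledger$hbonds$uid_a, ledger$hbonds$uid_b,
                             ledger$scatter$uid_a, ledger$scatter$uid_b,
                             ledger$patch_a, ledger$patch_b,
                             ledger$anchor, ledger$pocket, ledger$support))
  structure(list(structure = x, ledger = ledger, spec = spec),
            class = "toy_complex")
}

#' @export
print.toy_complex <- function(x, ...) {
  cat("Synthetic complex:", x$spec$nx, "x", x$spec$ny, "lattice per chain\n")
  cat(sprintf("  planted: %d salt bridges, %d hbond pairs, %d+%d patch residues, %d scatter pairs\n",
              nrow(x$ledger$salt_bridges), nrow(x$ledger$hbonds),
              length(x$ledger$patch_a), length(x$ledger$patch_b),
              nrow(x$ledger$scatter)))
  if (!is.null(x$ledger$anchor)) cat("  anchor:", x$ledger$anchor, "\n")
  invisible(x)
}

#' Perturbation specification for deriving an interolog
#'
#' @param mutation_rate Per-residue probability of a BLOSUM62-weighted
#'   substitution at interface residues.
#' @param switch_rate Expected fraction of eligible interface residues
#'   displaced out of the interface (rim-biased: per-residue probabilities
#'   are proportional to rim 2 : support 1 : core 0.5, rescaled so their mean
#'   is `switch_rate`).
#' @param rewire_rate Per-residue probability that a contact-making residue
#'   has its side chain displaced laterally (half a lattice cell, <= 2.5 A),
#'   changing its contact partners while staying at the interface.
#' @param protect Character vector of `res_uid`s never perturbed.
#' @param seed Integer seed.
#' @return A list of class `perturbation_spec`.
#' @export
perturbation_spec <- function(mutation_rate = 0, switch_rate = 0,
                              rewire_rate = 0, protect = character(),
                              seed = 1) {
  rates <- c(mutation_rate, switch_rate, rewire_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  structure(list(mutation_rate = mutation_rate, switch_rate = switch_rate,
                 rewire_rate = rewire_rate, protect = protect, seed = seed),
            class = "perturbation_spec")
}

#' Derive a synthetic interolog from a toy complex
#'
#' Applies BLOSUM62-weighted substitutions, rim-biased displacement of
#' residues out of the interface, and bounded lateral side-chain rewiring to
#' a copy of the complex, returning the perturbed structure together with the
#' exact residue correspondence (ground truth, independent of any alignment)
#' and the realized perturbation events.
#'
#' @param toy A [build_toy_complex()] result (or a `complex_structure`).
#' @param perturbation A [perturbation_spec()].
#' @return A list of class `toy_interolog`: `structure` (the perturbed
#'   complex), `map` (named uid vector, original -> interolog; the identity
#'   on residue identifiers), `events` (list `mutated`, `switched`,
#'   `rewired`), `expected` (list with `switch_fraction` and
#'   `n_eligible_switch`), `perturbation`.
#' @export
derive_interolog <- function(toy, perturbation = perturbation_spec()) {
  x <- if (inherits(toy, "toy_complex")) toy$structure else toy
  with_seed(perturbation$seed, derive_interolog_impl(x, perturbation))
}

derive_interolog_impl <- function(x, pert) {
  atoms <- x$atoms
  iface <- interface_residues(x)
  burial <- residue_burial(x)
  region <- stats::setNames(
    classify_subregions(burial$bi_monomer, burial$bi_complex),
    burial$res_uid)
  res <- residue_table(x)
  chain_of <- stats::setNames(res$chain, res$res_uid)

  eligible <- setdiff(iface, pert$protect)

  # --- substitutions (BLOSUM62-weighted target amino acid)
  mutated <- character()
  if (pert$mutation_rate > 0 && length(eligible) > 0) {
    B62 <- blosum62()
    hit <- eligible[stats::runif(length(eligible)) < pert$mutation_rate]
    for (u in hit) {
      old3 <- res$resid[res$res_uid == u]
      old1 <- aa321(old3)
      others <- setdiff(.AA1, old1)
      w <- exp(0.3 * B62[old1, others])
      new1 <- sample(others, 1, prob = w)
      new3 <- .AA3[match(new1, .AA1)]
      sel <- atoms$res_uid == u
      ca <- atoms[sel & atoms$elety == "CA", c("x", "y", "z")]
      orient <- if (chain_of[u] == "A") 1 else -1
      bb <- atoms[sel & atoms$is_backbone, , drop = FALSE]
      t <- .SC_TEMPLATES[[new3]]
      sc <- NULL
      if (nrow(t) > 0) {
        sc <- bb[rep(1, nrow(t)), , drop = FALSE]
        sc$elety <- t$name
        sc$x <- ca$x + t$l; sc$y <- ca$y
        sc$z <- ca$z + orient * t$dz
        sc$element <- guess_element(t$name)
      }
      keep <- atoms[!sel, , drop = FALSE]
      bb$resid <- new3
      if (!is.null(sc)) sc$resid <- new3
      atoms <- rbind(keep, bb, sc)
      mutated <- c(mutated, u)
    }
  }

  # --- switching out: rim-biased displacement away from the interface
  switched <- character()
  if (pert$switch_rate > 0 && length(eligible) > 0) {
    w <- c(core = 0.5, support = 1, rim = 2)[region[eligible]]
    w[is.na(w)] <- 1
    p <- pmin(1, pert$switch_rate * w / mean(w))
    hit <- eligible[stats::runif(length(eligible)) < p]
    for (u in hit) {
      sel <- atoms$res_uid == u
      atoms$z[sel] <- atoms$z[sel] + if (chain_of[u] == "A") -20 else 20
      switched <- c(switched, u)
    }
  }

  # --- rewiring: bounded lateral side-chain displacement
  rewired <- character()
  if (pert$rewire_rate > 0) {
    contacts <- atomic_contacts(x)
    candidates <- setdiff(union(contacts$uid_a, contacts$uid_b),
                          c(pert$protect, switched))
    hit <- candidates[stats::runif(length(candidates)) < pert$rewire_rate]
    for (u in hit) {
      sel <- atoms$res_uid == u & !atoms$is_backbone & atoms$elety != "CB"
      if (!any(sel)) next
      dir <- sample(list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)), 1)[[1]]
      atoms$x[sel] <- atoms$x[sel] + 2.45 * dir[1]
      atoms$y[sel] <- atoms$y[sel] + 2.45 * dir[2]
      rewired <- c(rewired, u)
    }
  }

  atoms <- atoms[order(match(atoms$chain, x$chains), atoms$resno), ]
  xb <- as_complex_structure(
    atoms[, c("elety", "resid", "chain", "resno", "insert", "x", "y", "z",
              "o", "element")],
    chains = x$chains, id = paste0(x$id, "-interolog"))
  map <- stats::setNames(res$res_uid, res$res_uid)
  structure(list(structure = xb, map = map,
                 events = list(mutated = mutated, switched = switched,
                               rewired = rewired),
                 expected = list(switch_fraction = pert$switch_rate,
                                 n_eligible_switch = length(eligible)),
                 perturbation = pert),
            class = "toy_interolog")
}

#' Write the exact correspondence of a synthetic pair as aligned FASTA
#'
#' One file per chain, two ungapped aligned sequences each (the synthetic
#' interolog preserves residue numbering, so the true alignment has no gaps).
#'
#' @param toy A `toy_complex` (or `complex_structure`).
#' @param interolog A [derive_interolog()] result.
#' @param dir Output directory.
#' @return Character vector of file paths, one per chain.
#' @export
write_true_alignment <- function(toy, interolog, dir = ".") {
  xa <- if (inherits(toy, "toy_complex")) toy$structure else toy
  xb <- interolog$structure
  paths <- character(2)
  for (k in 1:2) {
    ch <- xa$chains[k]
    paths[k] <- file.path(dir, paste0("chain_", ch, ".afa"))
    writeLines(c(paste0(">", xa$id, "_", ch), chain_sequence(xa, ch),
                 paste0(">", xb$id, "_", ch), chain_sequence(xb, ch)),
               paths[k])
  }
  paths
}

#' Simulate a residue feature table from a logistic model
#'
#' Draws the six features from fixed study distributions (BLOSUM62 score of a
#' uniformly random amino-acid pair; environment similarity Normal(1.5,
#' 1.5^2); percent identity Uniform(10, 100); region core/support/rim with
#' probabilities 0.25/0.25/0.5; atomic contacts 1 + Poisson(8); center
#' distance Uniform(0, 1)), computes each residue's probability under
#' `model`, and samples Bernoulli labels.
#'
#' @param n Number of residues.
#' @param model A `logistic_model` (e.g. [switching_out_model()]).
#' @param seed Integer seed.
#' @return Data frame of features plus `prob` and `label`.
#' @export
simulate_logistic_dataset <- function(n, model = switching_out_model(),
                                      seed = 1) {
  stopifnot(n >= 1)
  with_seed(seed, {
    B62 <- blosum62()
    aa_pairs <- cbind(sample(.AA1, n, replace = TRUE),
                      sample(.AA1, n, replace = TRUE))
    d <- data.frame(
      sim_res = B62[aa_pairs],
      sim_env = stats::rnorm(n, 1.5, 1.5),
      seq_id = stats::runif(n, 10, 100),
      region = sample(c("core", "support", "rim"), n, replace = TRUE,
                      prob = c(0.25, 0.25, 0.5)),
      n_contacts = 1 + stats::rpois(n, 8),
      dist_center = stats::runif(n),
      stringsAsFactors = FALSE)
    d$prob <- logistic_score(d, model)
    d$label <- stats::rbinom(n, 1, d$prob)
    d
  })
}
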