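# Apolar patches: detection as connected clusters of side-chain C/S surface
# atoms, cross-interolog merging, patch contact bundles, and random-patch
# null models.

new_patch <- function(id, chain, atom_keys, residues, regions = NULL) {
  comp <- c(core = 0, support = 0, rim = 0)
  if (!is.null(regions)) {
    tb <- table(regions[residues])
    comp[names(tb)] <- as.numeric(tb)
  }
  list(id = id, chain = chain, atoms = atom_keys, residues = sort(residues),
       n_atoms = length(atom_keys), composition = comp, provenance = id)
}

#' Detect apolar patches on each side of an interface
#'
#' A patch is a connected cluster of side-chain C/S surface atoms (monomer
#' SASA > 0) of interface residues of one chain, where two atoms are adjacent
#' if within the patch adjacency cutoff. Clusters with fewer than 4 atoms or
#' fewer than 2 residues are discarded.
#'
#' @param x A `complex_structure`.
#' @param interface Character vector of interface `res_uid`s.
#' @param config A [contact_config()].
#' @param sasa_monomer Monomer-context [compute_sasa()] result (computed if
#'   `NULL`).
#' @param regions Optional named sub-region labels used for patch composition.
#' @return Named list (one element per chain) of patches; each patch is a list
#'   with `id`, `chain`, `atoms` (keys `"res_uid/elety"`), `residues`,
#'   `n_atoms`, `composition` (core/support/rim residue counts).
#' @export
detect_patches <- function(x, interface, config = contact_config(),
                           sasa_monomer = NULL, regions = NULL) {
  if (is.null(sasa_monomer))
    sasa_monomer <- compute_sasa(x, "monomer", config$probe_radius,
                                 config$n_points)
  sa <- apolar_surface_atoms(x, interface, sasa_monomer)
  out <- list()
  for (ch in x$chains) {
    a <- sa[sa$chain == ch, , drop = FALSE]
    patches <- list()
    if (nrow(a) >= 4) {
      d2 <- as.matrix(stats::dist(as.matrix(a[, c("x", "y", "z")])))^2
      adj <- d2 <= config$patch_adjacency_cutoff^2
      diag(adj) <- FALSE
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      comp <- igraph::components(g)$membership
      k <- 0
      for (cid in unique(comp)) {
        sel <- comp == cid
        residues <- unique(a$res_uid[sel])
        if (sum(sel) >= 4 && length(residues) >= 2) {
          k <- k + 1
          patches[[k]] <- new_patch(paste0(ch, "-", k), ch,
                                    paste(a$res_uid[sel], a$elety[sel],
                                          sep = "/"),
                                    residues, regions)
        }
      }
    }
    out[[ch]] <- patches
  }
  out
}

#' Merge patches across two interologs into a one-to-one correspondence
#'
#' Builds, per chain pair, the bipartite residue-overlap graph between the
#' patches of complex A and the patches of complex B (a patch of A overlaps a
#' patch of B when any of its residues maps into the B patch). Any patch
#' overlapping several patches on the other side triggers the merging of
#' those patches; merging is iterated to a fixpoint, which equals collapsing
#' every connected component of the overlap graph. The final patch mapping is
#' injective in both directions.
#'
#' @param patchesA,patchesB Patch lists from [detect_patches()] (named by
#'   chain).
#' @param map Named character vector mapping residue `res_uid`s of A to those
#'   of B (from [chain_correspondence()]).
#' @return List with `a`, `b` (merged patch lists, named by chain of A and of
#'   B respectively) and `mapping` (data frame `patch_a`, `patch_b`; NA for
#'   unmapped patches).
#' @export
merge_patches_across_interologs <- function(patchesA, patchesB, map) {
  rev_side <- function(sideA, sideB) {
    nA <- length(sideA); nB <- length(sideB)
    if (nA == 0 && nB == 0)
      return(list(a = sideA, b = sideB,
                  mapping = data.frame(patch_a = character(),
                                       patch_b = character())))
    # overlap adjacency between A patches and B patches
    overlap <- matrix(FALSE, nA, nB)
    if (nA > 0 && nB > 0) {
      for (i in seq_len(nA)) {
        mapped <- unname(map[sideA[[i]]$residues])
        mapped <- mapped[!is.na(mapped)]
        for (j in seq_len(nB))
          overlap[i, j] <- length(intersect(mapped, sideB[[j]]$residues)) > 0
      }
    }
    # connected components of the bipartite graph = merge fixpoint
    parent <- seq_len(nA + nB)
    findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (nA > 0 && nB > 0) {
      for (i in seq_len(nA)) for (j in seq_len(nB)) {
        if (overlap[i, j]) {
          ri <- findp(i); rj <- findp(nA + j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
    comp <- vapply(seq_len(nA + nB), findp, integer(1))
    merge_group <- function(side, idx, tag) {
      if (length(idx) == 1) return(side[[idx]])
      p <- side[[idx[1]]]
      for (k in idx[-1]) {
        q <- side[[k]]
        p$atoms <- union(p$atoms, q$atoms)
        p$residues <- sort(union(p$residues, q$residues))
        p$composition <- p$composition + q$composition
        p$provenance <- c(p$provenance, q$provenance)
      }
      p$n_atoms <- length(p$atoms)
      p$id <- paste0(p$id, "+")
      p
    }
    outA <- list(); outB <- list(); map_rows <- list()
    for (cid in unique(comp)) {
      ia <- which(comp[seq_len(nA)] == cid)
      ib <- which(comp[nA + seq_len(nB)] == cid)
      pa <- if (length(ia) > 0) merge_group(sideA, ia) else NULL
      pb <- if (length(ib) > 0) merge_group(sideB, ib) else NULL
      if (!is.null(pa)) outA[[length(outA) + 1]] <- pa
      if (!is.null(pb)) outB[[length(outB) + 1]] <- pb
      map_rows[[length(map_rows) + 1]] <-
        data.frame(patch_a = if (is.null(pa)) NA_character_ else pa$id,
                   patch_b = if (is.null(pb)) NA_character_ else pb$id,
                   stringsAsFactors = FALSE)
    }
    list(a = outA, b = outB, mapping = do.call(rbind, map_rows))
  }
  chainsA <- names(patchesA); chainsB <- names(patchesB)
  a <- list(); b <- list(); mapping <- list()
  for (k in seq_along(chainsA)) {
    r <- rev_side(patchesA[[chainsA[k]]], patchesB[[chainsB[k]]])
    a[[chainsA[k]]] <- r$a
    b[[chainsB[k]]] <- r$b
    mapping[[k]] <- r$mapping
  }
  list(a = a, b = b, mapping = do.call(rbind, mapping))
}

#' Patch contact bundles
#'
#' Two patches (one per side of the interface) are in contact if at least one
#' apolar atomic contact links them; the bundle records the total apolar
#' contact count and, per patch, the fraction of its residues actively
#' contacting the partner patch.
#'
#' @param patches Patch list from [detect_patches()] (two sides).
#' @param apolar Apolar residue-pair edges from [apolar_contacts()].
#' @param chains Chain identifiers, side 1 first.
#' @return Data frame with one row per contacting patch pair: `patch_1`,
#'   `patch_2`, `weight` (apolar atomic contacts), `participation_1`,
#'   `participation_2`.
#' @export
patch_contact_bundles <- function(patches, apolar, chains = names(patches)) {
  s1 <- patches[[chains[1]]]; s2 <- patches[[chains[2]]]
  rows <- list()
  for (p in s1) for (q in s2) {
    sel <- apolar$uid_a %in% p$residues & apolar$uid_b %in% q$residues
    if (any(sel)) {
      rows[[length(rows) + 1]] <- data.frame(
        patch_1 = p$id, patch_2 = q$id, weight = sum(apolar$weight[sel]),
        participation_1 = length(unique(apolar$uid_a[sel])) / length(p$residues),
        participation_2 = length(unique(apolar$uid_b[sel])) / length(q$residues),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(patch_1 = character(), patch_2 = character(),
                      weight = numeric(), participation_1 = numeric(),
                      participation_2 = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Random patches matched to real apolar patches
#'
#' For every real patch of an interface model, grows a connected random patch
#' over the interface residue-adjacency graph (structural neighbors at 8 A,
#' same chain) from a random seed residue until it reaches the real patch's
#' atom count, rejection-sampling (up to `max_tries`) toward the real patch's
#' core/support/rim residue composition within plus or minus 1 per class.
#' With `facing = TRUE` the seed residue is drawn among residues with at
#' least one inter-chain atomic contact, so the random patch faces the
#' partner side.
#'
#' @param im An [interface_model()].
#' @param seed Integer seed (reproducible output).
#' @param facing Constrain random patches to face the partner chain.
#' @param max_tries Rejection-sampling budget per patch.
#' @return Patch list shaped like `im$patches`; each random patch carries a
#'   `target_id` naming the real patch it mirrors.
#' @export
random_patches <- function(im, seed, facing = TRUE, max_tries = 1000) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  x <- im$structure
  res <- im$residues
  regions <- stats::setNames(res$region[res$interface],
                             res$res_uid[res$interface])
  nb <- structural_neighbors(x, im$config$neighbor_radius, "monomer")
  sa <- apolar_surface_atoms(x, im$interface, im$sasa_monomer)
  atoms_of <- split(paste(sa$res_uid, sa$elety, sep = "/"), sa$res_uid)
  n_atoms_of <- function(uids)
    sum(lengths(atoms_of[intersect(uids, names(atoms_of))]))
  contact_uids <- union(im$contacts$atomic$uid_a, im$contacts$atomic$uid_b)

  grow_one <- function(ch, target_atoms) {
    pool <- res$res_uid[res$interface & res$chain == ch]
    seeds <- if (facing) intersect(pool, contact_uids) else pool
    if (length(seeds) == 0) seeds <- pool
    members <- sample(seeds, 1)
    repeat {
      if (n_atoms_of(members) >= target_atoms) break
      frontier <- setdiff(intersect(unique(unlist(nb[members])), pool), members)
      if (length(frontier) == 0) break
      members <- c(members, sample(frontier, 1))
    }
    members
  }
  comp_ok <- function(members, target_comp) {
    got <- c(core = 0, support = 0, rim = 0)
    tb <- table(regions[members])
    got[names(tb)] <- as.numeric(tb)
    all(abs(got - target_comp) <= 1)
  }

  out <- list()
  for (ch in names(im$patches)) {
    rp <- list()
    for (p in im$patches[[ch]]) {
      best <- NULL
      for (try in seq_len(max_tries)) {
        members <- grow_one(ch, p$n_atoms)
        best <- members
        if (comp_ok(members, p$composition)) break
        if (try == max_tries)
          warning("random patch for ", p$id,
                  " did not match composition after ", max_tries,
                  " tries; best effort returned")
      }
      atoms <- unlist(atoms_of[intersect(best, names(atoms_of))],
                      use.names = FALSE)
      q <- new_patch(paste0("rand-", p$id), ch, atoms, best, regions)
      q$target_id <- p$id
      rp[[length(rp) + 1]] <- q
    }
    out[[ch]] <- rp
  }
  out
}
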