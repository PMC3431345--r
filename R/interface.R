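# Interface detection, burial-index classification into core/support/rim,
# geometric-center distances and anchor residues.

#' Structural neighbors of each residue
#'
#' Two residues are structural neighbors if their Cb atoms (Ca for glycine)
#' are within `radius` of one another. In `context = "monomer"` only
#' within-chain pairs count; in `context = "complex"` pairs across chains
#' count as well. Residues lacking both Cb and Ca are excluded with a warning.
#'
#' @param x A `complex_structure`.
#' @param radius Neighbor radius in Angstrom (8 for structural neighbors,
#'   10 for the extended neighbors used by burial indices).
#' @param context `"complex"` or `"monomer"`.
#' @return Named list: for each residue `res_uid`, the character vector of its
#'   neighbors' `res_uid`s (self excluded; symmetric relation).
#' @export
structural_neighbors <- function(x, radius = 8,
                                 context = c("complex", "monomer")) {
  context <- match.arg(context)
  res <- residue_table(x)
  if (anyNA(res$rx)) {
    warning("residue(s) without Cb/Ca reference excluded: ",
            paste(res$res_uid[is.na(res$rx)], collapse = ", "))
    res <- res[!is.na(res$rx), , drop = FALSE]
  }
  xyz <- as.matrix(res[, c("rx", "ry", "rz")])
  d2 <- as.matrix(stats::dist(xyz))^2
  adj <- d2 <= radius^2
  diag(adj) <- FALSE
  if (context == "monomer")
    adj <- adj & outer(res$chain, res$chain, "==")
  out <- lapply(seq_len(nrow(res)), function(i) res$res_uid[adj[i, ]])
  names(out) <- res$res_uid
  out
}

#' Burial index from an extended-neighbor count
#'
#' Piecewise-linear index of residue burial: 0 for 15 neighbors or fewer, 1
#' for 24 or more, and (n - 15)/9 in between (1/9 for 16 neighbors, 2/9 for
#' 17, ...).
#'
#' @param n Integer vector of extended-neighbor counts (10 A radius).
#' @return Numeric vector in \[0, 1\].
#' @export
burial_index <- function(n) {
  if (any(n < 0)) stop("neighbor counts must be non-negative")
  pmin(1, pmax(0, (n - 15) / 9))
}

#' Interface residues of a complex
#'
#' A residue is at the interface if it gains at least one structural neighbor
#' (8 A, Cb/Ca) upon complexation, or makes at least one inter-chain atomic
#' contact.
#'
#' @param x A `complex_structure`.
#' @param contacts Atomic contacts from [atomic_contacts()] (computed if
#'   `NULL`).
#' @param config A [contact_config()].
#' @return Character vector of interface residue `res_uid`s (both chains).
#' @export
interface_residues <- function(x, contacts = NULL, config = contact_config()) {
  if (is.null(contacts)) contacts <- atomic_contacts(x, config)
  nb <- structural_neighbors(x, config$neighbor_radius, "complex")
  res <- residue_table(x)
  chain_of <- stats::setNames(res$chain, res$res_uid)
  gained <- names(nb)[vapply(names(nb), function(u) {
    any(chain_of[nb[[u]]] != chain_of[u])
  }, logical(1))]
  sort(union(gained, union(contacts$uid_a, contacts$uid_b)))
}

# Per-residue extended-neighbor counts and burial indices in both contexts.
residue_burial <- function(x, config = contact_config()) {
  nb_m <- structural_neighbors(x, config$extended_radius, "monomer")
  nb_c <- structural_neighbors(x, config$extended_radius, "complex")
  uid <- names(nb_c)
  data.frame(res_uid = uid,
             n_neighbors_monomer = lengths(nb_m)[uid],
             n_neighbors_complex = lengths(nb_c)[uid],
             bi_monomer = burial_index(lengths(nb_m)[uid]),
             bi_complex = burial_index(lengths(nb_c)[uid]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify interface residues into core, support and rim
#'
#' Core: the burial index rises by more than 0.5 upon complexation (the
#' residue becomes much more buried). Support: not core, but the average of
#' the monomer and complex burial indices exceeds 0.6 (buried in both). Rim:
#' everything else. Comparisons are strict, as printed.
#'
#' @param bi_monomer,bi_complex Numeric vectors of burial indices.
#' @return Character vector of labels `"core"`, `"support"`, `"rim"`.
#' @export
classify_subregions <- function(bi_monomer, bi_complex) {
  ifelse(bi_complex - bi_monomer > 0.5, "core",
         ifelse((bi_monomer + bi_complex) / 2 > 0.6, "support", "rim"))
}

#' Normalized distances to the interface geometric center
#'
#' The center is the centroid of the Cb/Ca reference points of all interface
#' residues (both chains); each residue's Euclidean distance to it is divided
#' by the maximum over the interface, so the maximum is exactly 1.
#'
#' @param x A `complex_structure`.
#' @param interface Character vector of interface `res_uid`s (>= 2 for a
#'   non-degenerate result; a single-residue interface returns 0 with a
#'   warning).
#' @return List with `distances` (named numeric in \[0, 1\]) and `center`
#'   (3-vector).
#' @export
interface_center_distances <- function(x, interface) {
  res <- residue_table(x)
  res <- res[res$res_uid %in% interface & !is.na(res$rx), , drop = FALSE]
  if (nrow(res) == 0) stop("no interface residues with reference points")
  xyz <- as.matrix(res[, c("rx", "ry", "rz")])
  center <- colMeans(xyz)
  d <- sqrt(rowSums(sweep(xyz, 2, center)^2))
  if (nrow(res) == 1 || max(d) == 0) {
    if (nrow(res) == 1) warning("single-residue interface: distances set to 0")
    d <- rep(0, nrow(res))
  } else {
    d <- d / max(d)
  }
  list(distances = stats::setNames(d, res$res_uid), center = center)
}

#' Anchor residues of an interface
#'
#' Up to `max_anchors` residues from the core and support sub-regions (both
#' chains pooled) burying the most solvent-accessible surface area upon
#' binding, and in any case more than `min_dasa` A^2. Ties are broken by
#' (chain, residue number).
#'
#' @param regions Named character vector of sub-region labels per interface
#'   `res_uid`.
#' @param dasa Named numeric vector of buried areas (dASA) per `res_uid`.
#' @param max_anchors Maximum number of anchors (default 3).
#' @param min_dasa Minimum buried area in A^2 (default 80, strict).
#' @return Character vector of anchor `res_uid`s (possibly empty), most
#'   buried first.
#' @export
anchor_residues <- function(regions, dasa, max_anchors = 3, min_dasa = 80) {
  cand <- names(regions)[regions %in% c("core", "support")]
  cand <- cand[!is.na(dasa[cand]) & dasa[cand] > min_dasa]
  if (length(cand) == 0) return(character())
  parts <- strsplit(cand, ":", fixed = TRUE)
  chain <- vapply(parts, `[`, "", 1)
  resno <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  ord <- order(-dasa[cand], chain, resno)
  cand[ord][seq_len(min(max_anchors, length(cand)))]
}

#' Full interface model of a complex
#'
#' Runs the per-complex pipeline: SASA in monomer and complex contexts,
#' interface detection, burial-index sub-regions, typed contacts, apolar
#' patches, geometric-center distances and anchors.
#'
#' @param x A `complex_structure`.
#' @param config A [contact_config()].
#' @return An object of class `interface_model`: list with `residues` (one
#'   row per residue: identity, interface flag, burial indices, sub-region,
#'   `delta_rasa`, `n_contacts`, `dist_center`, `is_anchor`), `interface`
#'   (uids), `contacts` (list: `atomic`, `graph`, `charged`, `salt_bridges`,
#'   `hbonds`, `apolar`), `patches`, `anchors`, `center`, `sasa_monomer`,
#'   `sasa_complex`, `structure`, `config`.
#' @export
interface_model <- function(x, config = contact_config()) {
  stopifnot(inherits(x, "complex_structure"))
  sasa_m <- compute_sasa(x, "monomer", config$probe_radius, config$n_points)
  sasa_c <- compute_sasa(x, "complex", config$probe_radius, config$n_points)
  dasa <- delta_rasa(x, sasa_monomer = sasa_m, sasa_complex = sasa_c)

  ac <- atomic_contacts(x, config)
  graph <- residue_contact_graph(ac)
  iface <- interface_residues(x, contacts = ac, config = config)

  burial <- residue_burial(x, config)
  res <- residue_table(x)
  res <- merge(res, burial, by = "res_uid", all.x = TRUE, sort = FALSE)
  res$interface <- res$res_uid %in% iface
  res$region <- NA_character_
  res$region[res$interface] <- classify_subregions(
    res$bi_monomer[res$interface], res$bi_complex[res$interface])
  res$delta_rasa <- dasa$delta[match(res$res_uid, dasa$res_uid)]

  ncont <- c(table(c(graph$uid_a[rep(seq_len(nrow(graph)), graph$weight)],
                     graph$uid_b[rep(seq_len(nrow(graph)), graph$weight)])))
  res$n_contacts <- ifelse(is.na(match(res$res_uid, names(ncont))), 0,
                           as.numeric(ncont[res$res_uid]))

  cd <- interface_center_distances(x, iface)
  res$dist_center <- cd$distances[res$res_uid]

  regions <- stats::setNames(res$region[res$interface],
                             res$res_uid[res$interface])
  dvec <- stats::setNames(res$delta_rasa, res$res_uid)
  anchors <- anchor_residues(regions, dvec, config$anchor_max,
                             config$anchor_min_dasa)
  res$is_anchor <- res$res_uid %in% anchors

  contacts <- list(
    atomic = ac, graph = graph,
    charged = charged_contacts(x, config$charged_cutoff),
    salt_bridges = salt_bridges(x, config),
    hbonds = hydrogen_bonds(x, config),
    apolar = apolar_contacts(x, iface, config, sasa_monomer = sasa_m)
  )
  patches <- detect_patches(x, iface, config, sasa_monomer = sasa_m,
                            regions = regions)

  res <- res[order(match(res$chain, x$chains), res$resno, res$insert), ]
  rownames(res) <- NULL
  structure(list(residues = res, interface = iface, contacts = contacts,
                 patches = patches, anchors = anchors, center = cd$center,
                 sasa_monomer = sasa_m, sasa_complex = sasa_c,
                 structure = x, config = config),
            class = "interface_model")
}

#' @export
print.interface_model <- function(x, ...) {
  r <- x$residues[x$residues$interface, ]
  cat("Interface model:", x$structure$id, "\n")
  cat(sprintf("  interface: %d residues (core %d, support %d, rim %d)\n",
              nrow(r), sum(r$region == "core"), sum(r$region == "support"),
              sum(r$region == "rim")))
  cat(sprintf("  contacts: %d atomic (%d residue pairs), %d salt bridges, %d hbonds, %d apolar pairs\n",
              nrow(x$contacts$atomic), nrow(x$contacts$graph),
              nrow(x$contacts$salt_bridges), nrow(x$contacts$hbonds),
              nrow(x$contacts$apolar)))
  np <- vapply(x$patches, length, integer(1))
  cat(sprintf("  apolar patches: %d + %d; anchors: %s\n", np[1], np[2],
              if (length(x$anchors)) paste(x$anchors, collapse = ", ") else "none"))
  invisible(x)
}
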