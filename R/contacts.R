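# Inter-chain contact detection and typing: atomic, residue-level, charged,
# salt-bridge, hydrogen-bond and apolar contacts.

#' Contact-detection configuration
#'
#' Distance thresholds (Angstrom) used across the pipeline. Salt bridges are
#' charged contacts at a tighter cutoff, so `salt_bridge_cutoff` must not
#' exceed `charged_cutoff`. The charged-contact default is 5.5 A; 6.0 A is an
#' equally valid published choice and can be set here.
#'
#' @param atomic_cutoff Heavy-atom inter-chain contact cutoff (default 5.0).
#' @param charged_cutoff N(+)...O(-) charged-contact cutoff (default 5.5).
#' @param salt_bridge_cutoff Salt-bridge cutoff (default 3.5).
#' @param hbond_cutoff Donor-acceptor heavy-atom cutoff (default 3.5).
#' @param hbond_min_angle Minimum antecedent-donor-acceptor angle in degrees
#'   (default 90).
#' @param apolar_cutoff Side-chain C/S to C/S contact cutoff (default 4.5).
#' @param patch_adjacency_cutoff Intra-chain C/S adjacency cutoff used to grow
#'   apolar patches (default 4.5, the same proximity criterion as apolar
#'   contacts).
#' @param neighbor_radius Structural-neighbor radius on Cb (Ca for Gly)
#'   reference points (default 8).
#' @param extended_radius Extended-neighbor radius used by burial indices
#'   (default 10).
#' @param anchor_min_dasa Minimum buried area for anchor residues (default 80).
#' @param anchor_max Maximum number of anchors per interface (default 3).
#' @param probe_radius,n_points SASA parameters (defaults 1.4 A, 960 points).
#' @return A list of class `contact_config`.
#' @export
contact_config <- function(atomic_cutoff = 5.0, charged_cutoff = 5.5,
                           salt_bridge_cutoff = 3.5, hbond_cutoff = 3.5,
                           hbond_min_angle = 90, apolar_cutoff = 4.5,
                           patch_adjacency_cutoff = 4.5,
                           neighbor_radius = 8, extended_radius = 10,
                           anchor_min_dasa = 80, anchor_max = 3,
                           probe_radius = 1.4, n_points = 960) {
  cfg <- list(atomic_cutoff = atomic_cutoff, charged_cutoff = charged_cutoff,
              salt_bridge_cutoff = salt_bridge_cutoff, hbond_cutoff = hbond_cutoff,
              hbond_min_angle = hbond_min_angle, apolar_cutoff = apolar_cutoff,
              patch_adjacency_cutoff = patch_adjacency_cutoff,
              neighbor_radius = neighbor_radius, extended_radius = extended_radius,
              anchor_min_dasa = anchor_min_dasa, anchor_max = anchor_max,
              probe_radius = probe_radius, n_points = n_points)
  if (any(vapply(cfg, function(v) !is.numeric(v) || v <= 0, logical(1))))
    stop("all contact_config values must be positive numbers")
  if (cfg$salt_bridge_cutoff > cfg$charged_cutoff)
    stop("salt_bridge_cutoff must not exceed charged_cutoff")
  class(cfg) <- "contact_config"
  cfg
}

# All pairs between two coordinate sets within `cutoff`; returns index pairs
# and distances. Plain all-pairs distance computation.
cross_pairs <- function(xyz1, xyz2, cutoff) {
  if (nrow(xyz1) == 0 || nrow(xyz2) == 0)
    return(data.frame(i = integer(), j = integer(), distance = numeric()))
  d2 <- outer(rowSums(xyz1^2), rowSums(xyz2^2), "+") - 2 * xyz1 %*% t(xyz2)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  data.frame(i = hit[, 1], j = hit[, 2],
             distance = sqrt(pmax(0, d2[hit])))
}

#' Inter-chain atomic contacts
#'
#' Heavy-atom pairs across the two chains within the atomic cutoff.
#'
#' @param x A `complex_structure`.
#' @param config A [contact_config()].
#' @return Data frame with one row per atom pair: `uid_a`, `uid_b` (residue
#'   identifiers, chain 1 first), `elety_a`, `elety_b`, `distance`.
#' @export
atomic_contacts <- function(x, config = contact_config()) {
  a <- protein_atoms(x)
  a1 <- a[a$chain == x$chains[1], , drop = FALSE]
  a2 <- a[a$chain == x$chains[2], , drop = FALSE]
  p <- cross_pairs(as.matrix(a1[, c("x", "y", "z")]),
                   as.matrix(a2[, c("x", "y", "z")]), config$atomic_cutoff)
  data.frame(uid_a = a1$res_uid[p$i], uid_b = a2$res_uid[p$j],
             elety_a = a1$elety[p$i], elety_b = a2$elety[p$j],
             distance = p$distance, stringsAsFactors = FALSE)
}

#' Group atomic contacts into a residue contact graph
#'
#' @param contacts Atomic-contact table from [atomic_contacts()] (or any data
#'   frame with `uid_a`, `uid_b`).
#' @return Data frame of residue-pair edges with `uid_a`, `uid_b` and
#'   `weight` (the number of atomic contacts between the pair).
#' @export
residue_contact_graph <- function(contacts) {
  if (nrow(contacts) == 0)
    return(data.frame(uid_a = character(), uid_b = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  key <- paste(contacts$uid_a, contacts$uid_b, sep = "|")
  tab <- table(key)
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  data.frame(uid_a = vapply(parts, `[`, "", 1),
             uid_b = vapply(parts, `[`, "", 2),
             weight = as.numeric(tab), stringsAsFactors = FALSE)
}

# Table of charged side-chain atoms present in the structure.
charged_atoms <- function(a) {
  pos <- neg <- rep(FALSE, nrow(a))
  for (res in names(.CHARGED_POS))
    pos <- pos | (a$resid == res & a$elety %in% .CHARGED_POS[[res]])
  for (res in names(.CHARGED_NEG))
    neg <- neg | (a$resid == res & a$elety %in% .CHARGED_NEG[[res]])
  cbind(a, charge_pos = pos, charge_neg = neg)
}

#' Charged contacts and salt bridges
#'
#' Contacts between a side-chain N atom of Arg/Lys/His and a side-chain O
#' atom of Asp/Glu within `cutoff`. Salt bridges are charged contacts at the
#' (tighter) salt-bridge cutoff: `salt_bridges(x)` is
#' `charged_contacts(x, cutoff = config$salt_bridge_cutoff)`.
#'
#' @param x A `complex_structure`.
#' @param cutoff Distance threshold in Angstrom.
#' @param inter_chain If `TRUE` (default) only pairs across the two chains;
#'   if `FALSE`, only pairs within a chain (used for charge-fate scenarios).
#' @return Data frame of residue-pair edges: `uid_a`, `uid_b`, `weight`
#'   (number of N...O atom pairs), `sign_a` (`"+"` or `"-"`: the charge on the
#'   `uid_a` side). For inter-chain edges `uid_a` is always on chain 1.
#' @export
charged_contacts <- function(x, cutoff = 5.5, inter_chain = TRUE) {
  a <- charged_atoms(protein_atoms(x))
  empty <- data.frame(uid_a = character(), uid_b = character(),
                      weight = numeric(), sign_a = character(),
                      stringsAsFactors = FALSE)
  posn <- a[a$charge_pos, , drop = FALSE]
  nego <- a[a$charge_neg, , drop = FALSE]
  if (nrow(posn) == 0 || nrow(nego) == 0) return(empty)
  p <- cross_pairs(as.matrix(posn[, c("x", "y", "z")]),
                   as.matrix(nego[, c("x", "y", "z")]), cutoff)
  if (nrow(p) == 0) return(empty)
  same <- posn$chain[p$i] == nego$chain[p$j]
  p <- if (inter_chain) p[!same, , drop = FALSE] else
    p[same & posn$res_uid[p$i] != nego$res_uid[p$j], , drop = FALSE]
  if (nrow(p) == 0) return(empty)
  # orient: chain-1 residue first for inter-chain edges, else positive first
  first_pos <- if (inter_chain) posn$chain[p$i] == x$chains[1] else TRUE
  ua <- ifelse(first_pos, posn$res_uid[p$i], nego$res_uid[p$j])
  ub <- ifelse(first_pos, nego$res_uid[p$j], posn$res_uid[p$i])
  sa <- ifelse(first_pos, "+", "-")
  key <- paste(ua, ub, sa, sep = "|")
  tab <- table(key)
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  data.frame(uid_a = vapply(parts, `[`, "", 1),
             uid_b = vapply(parts, `[`, "", 2),
             weight = as.numeric(tab),
             sign_a = vapply(parts, `[`, "", 3), stringsAsFactors = FALSE)
}

#' @rdname charged_contacts
#' @param config A [contact_config()] supplying the salt-bridge cutoff.
#' @export
salt_bridges <- function(x, config = contact_config(), inter_chain = TRUE) {
  charged_contacts(x, cutoff = config$salt_bridge_cutoff,
                   inter_chain = inter_chain)
}

# Donor and acceptor atom tables with donor antecedents, for hydrogen bonds.
hb_atoms <- function(a) {
  don <- list(); acc <- list()
  # backbone N donor (except proline) with antecedent CA; backbone O/OXT acceptor
  bbN <- a[a$elety == "N" & a$resid != "PRO", , drop = FALSE]
  if (nrow(bbN) > 0) don[["bbN"]] <- cbind(bbN, antecedent = "CA", bb = TRUE)
  bbO <- a[a$elety %in% c("O", "OXT"), , drop = FALSE]
  if (nrow(bbO) > 0) acc[["bbO"]] <- cbind(bbO, bb = TRUE)
  for (res in names(.HB_DONORS)) {
    for (at in names(.HB_DONORS[[res]])) {
      sel <- a[a$resid == res & a$elety == at, , drop = FALSE]
      if (nrow(sel) > 0)
        don[[paste(res, at)]] <- cbind(sel, antecedent = .HB_DONORS[[res]][[at]],
                                       bb = FALSE)
    }
  }
  for (res in names(.HB_ACCEPTORS)) {
    sel <- a[a$resid == res & a$elety %in% .HB_ACCEPTORS[[res]], , drop = FALSE]
    if (nrow(sel) > 0) acc[[paste(res, "sc")]] <- cbind(sel, bb = FALSE)
  }
  list(donors = do.call(rbind, don), acceptors = do.call(rbind, acc))
}

#' Inter-chain hydrogen bonds
#'
#' Geometric, hydrogen-free criterion: donor and acceptor heavy atoms across
#' the two chains with donor-acceptor distance within the cutoff and an
#' antecedent-donor-acceptor angle of at least `hbond_min_angle` degrees.
#' Bonds where both atoms are backbone N/O are excluded.
#'
#' @param x A `complex_structure`.
#' @param config A [contact_config()].
#' @return Data frame of residue-pair edges: `uid_a` (chain 1), `uid_b`,
#'   `weight` (number of donor-acceptor pairs).
#' @export
hydrogen_bonds <- function(x, config = contact_config()) {
  a <- protein_atoms(x)
  hb <- hb_atoms(a)
  empty <- data.frame(uid_a = character(), uid_b = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (is.null(hb$donors) || is.null(hb$acceptors)) return(empty)
  keep <- list()
  for (dir in 1:2) {
    don <- hb$donors[hb$donors$chain == x$chains[dir], , drop = FALSE]
    acc <- hb$acceptors[hb$acceptors$chain == x$chains[3 - dir], , drop = FALSE]
    if (nrow(don) == 0 || nrow(acc) == 0) next
    p <- cross_pairs(as.matrix(don[, c("x", "y", "z")]),
                     as.matrix(acc[, c("x", "y", "z")]), config$hbond_cutoff)
    if (nrow(p) == 0) next
    p <- p[!(don$bb[p$i] & acc$bb[p$j]), , drop = FALSE]
    if (nrow(p) == 0) next
    # antecedent-donor-acceptor angle
    ante_key <- paste(don$res_uid[p$i], don$antecedent[p$i])
    atom_key <- paste(a$res_uid, a$elety)
    am <- match(ante_key, atom_key)
    ok <- !is.na(am)
    ang <- rep(NA_real_, nrow(p))
    if (any(ok)) {
      v1 <- as.matrix(a[am[ok], c("x", "y", "z")]) -
        as.matrix(don[p$i[ok], c("x", "y", "z")])
      v2 <- as.matrix(acc[p$j[ok], c("x", "y", "z")]) -
        as.matrix(don[p$i[ok], c("x", "y", "z")])
      cosang <- rowSums(v1 * v2) /
        (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
      ang[ok] <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    }
    # donors with a missing antecedent atom are skipped (angle undefined)
    p <- p[ok & ang >= config$hbond_min_angle, , drop = FALSE]
    if (nrow(p) == 0) next
    ua <- if (dir == 1) don$res_uid[p$i] else acc$res_uid[p$j]
    ub <- if (dir == 1) acc$res_uid[p$j] else don$res_uid[p$i]
    keep[[dir]] <- data.frame(uid_a = ua, uid_b = ub, stringsAsFactors = FALSE)
  }
  if (length(keep) == 0) return(empty)
  residue_contact_graph(do.call(rbind, keep))
}

# Side-chain C/S atoms of interface residues with monomer SASA > 0.
apolar_surface_atoms <- function(x, interface, sasa_monomer) {
  a <- protein_atoms(x)
  akey <- paste(a$res_uid, a$elety)
  skey <- paste(sasa_monomer$atoms$res_uid, sasa_monomer$atoms$elety)
  a$msasa <- sasa_monomer$atoms$area[match(akey, skey)]
  a[a$is_apolar & a$res_uid %in% interface & !is.na(a$msasa) & a$msasa > 0, ,
    drop = FALSE]
}

#' Inter-chain apolar contacts
#'
#' Contacts between side-chain C or S surface atoms (monomer SASA > 0) of
#' interface residues, across the two chains, within the apolar cutoff. Any
#' residue type may contribute through its side-chain carbons.
#'
#' @param x A `complex_structure`.
#' @param interface Character vector of interface residue `res_uid`s.
#' @param config A [contact_config()].
#' @param sasa_monomer A monomer-context [compute_sasa()] result (computed if
#'   `NULL`).
#' @return Data frame of residue-pair edges: `uid_a` (chain 1), `uid_b`,
#'   `weight` (number of apolar atomic contacts).
#' @export
apolar_contacts <- function(x, interface, config = contact_config(),
                            sasa_monomer = NULL) {
  if (is.null(sasa_monomer))
    sasa_monomer <- compute_sasa(x, "monomer", config$probe_radius,
                                 config$n_points)
  sa <- apolar_surface_atoms(x, interface, sasa_monomer)
  a1 <- sa[sa$chain == x$chains[1], , drop = FALSE]
  a2 <- sa[sa$chain == x$chains[2], , drop = FALSE]
  p <- cross_pairs(as.matrix(a1[, c("x", "y", "z")]),
                   as.matrix(a2[, c("x", "y", "z")]), config$apolar_cutoff)
  residue_contact_graph(data.frame(uid_a = a1$res_uid[p$i],
                                   uid_b = a2$res_uid[p$j],
                                   stringsAsFactors = FALSE))
}
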