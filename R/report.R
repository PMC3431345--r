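# Full interolog comparison: builds both interface models, the residue
# correspondence, and every conservation statistic.

# Jaccard conservation of patch contact bundles between two interologs,
# after cross-interolog patch merging.
patch_bundle_conservation <- function(merged, apolar_a, apolar_b,
                                      chains_a, chains_b) {
  ba <- patch_contact_bundles(merged$a, apolar_a, chains_a)
  bb <- patch_contact_bundles(merged$b, apolar_b, chains_b)
  a2b <- stats::setNames(merged$mapping$patch_b, merged$mapping$patch_a)
  b2a <- stats::setNames(merged$mapping$patch_a, merged$mapping$patch_b)
  ka <- paste(ba$patch_1, ba$patch_2, sep = "|")
  kb <- paste(b2a[bb$patch_1], b2a[bb$patch_2], sep = "|")
  keys <- union(ka, kb)
  if (length(keys) == 0)
    return(list(ratio = NA_real_, conserved = 0, nonconserved = 0,
                bundles_a = ba, bundles_b = bb))
  ma <- match(keys, ka); mb <- match(keys, kb)
  in_a <- !is.na(ma); in_b <- !is.na(mb)
  w <- ifelse(in_a & in_b, (ba$weight[ma] + bb$weight[mb]) / 2,
              ifelse(in_a, ba$weight[ma], bb$weight[mb]))
  conserved <- sum(w[in_a & in_b]); nonconserved <- sum(w[xor(in_a, in_b)])
  list(ratio = conserved / (conserved + nonconserved), conserved = conserved,
       nonconserved = nonconserved, bundles_a = ba, bundles_b = bb)
}

# Split apolar residue-pair edges by patch membership of their endpoints:
# both endpoints in a patch / exactly one / none.
apolar_by_membership <- function(apolar, patches, chains) {
  in_patch_1 <- unique(unlist(lapply(patches[[chains[1]]], `[[`, "residues")))
  in_patch_2 <- unique(unlist(lapply(patches[[chains[2]]], `[[`, "residues")))
  n_in <- (apolar$uid_a %in% in_patch_1) + (apolar$uid_b %in% in_patch_2)
  list(both = apolar[n_in == 2, , drop = FALSE],
       one = apolar[n_in == 1, , drop = FALSE],
       none = apolar[n_in == 0, , drop = FALSE])
}

# Per-residue conserved share of atomic-contact weight (A-side keys), used to
# label residues for the contact-conservation predictor.
residue_conservation_share <- function(cons_atomic) {
  e <- cons_atomic$edges
  if (length(e) == 0 || nrow(e) == 0)
    return(data.frame(res_uid = character(), conserved_weight = numeric(),
                      total_weight = numeric(), share = numeric()))
  touch <- rbind(data.frame(res_uid = e$uid_a, w = e$weight, s = e$status),
                 data.frame(res_uid = e$uid_b, w = e$weight, s = e$status))
  tot <- tapply(touch$w, touch$res_uid, sum)
  con <- tapply(touch$w * (touch$s == "conserved"), touch$res_uid, sum)
  data.frame(res_uid = names(tot), conserved_weight = as.numeric(con),
             total_weight = as.numeric(tot),
             share = as.numeric(con) / as.numeric(tot),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare two interologous complexes
#'
#' Runs the full pairwise analysis: interface models for both complexes,
#' residue correspondence, weighted-Jaccard conservation per contact type,
#' apolar conservation split by patch membership, patch-bundle conservation
#' after cross-interolog patch merging, switching-out, charge exchange,
#' charge-fate scenarios and minimum interface sequence identity.
#'
#' @param xa,xb `complex_structure` objects (chain k of A pairs with chain k
#'   of B), or prebuilt [interface_model()] objects.
#' @param alignments Optional per-chain alignments for
#'   [chain_correspondence()].
#' @param map Optional precomputed correspondence (e.g. the ground truth of a
#'   synthetic pair); overrides `alignments`.
#' @param config A [contact_config()].
#' @return An object of class `conservation_report`: list with `conservation`
#'   (per contact type: `ratio`, conserved/non-conserved weights),
#'   `switching`, `charge_exchange`, `charge_fate`, `identity`,
#'   `residue_conservation`, `correspondence`, `patches_merged`, `im_a`,
#'   `im_b`, `config`.
#' @export
compare_interologs <- function(xa, xb, alignments = NULL, map = NULL,
                               config = contact_config()) {
  im_a <- if (inherits(xa, "interface_model")) xa else interface_model(xa, config)
  im_b <- if (inherits(xb, "interface_model")) xb else interface_model(xb, config)
  sa <- im_a$structure; sb <- im_b$structure
  corr <- if (is.null(map))
    chain_correspondence(sa, sb, alignments = alignments)
  else map
  mvec <- if (inherits(corr, "correspondence_map")) corr$map else corr

  cons <- list(
    atomic = contact_conservation(im_a$contacts$graph, im_b$contacts$graph,
                                  mvec, weighted = TRUE),
    charged = contact_conservation(im_a$contacts$charged,
                                   im_b$contacts$charged, mvec,
                                   weighted = FALSE),
    salt_bridges = contact_conservation(im_a$contacts$salt_bridges,
                                        im_b$contacts$salt_bridges, mvec,
                                        weighted = FALSE),
    hbonds = contact_conservation(im_a$contacts$hbonds, im_b$contacts$hbonds,
                                  mvec, weighted = FALSE),
    apolar = contact_conservation(im_a$contacts$apolar, im_b$contacts$apolar,
                                  mvec, weighted = TRUE)
  )
  mem_a <- apolar_by_membership(im_a$contacts$apolar, im_a$patches, sa$chains)
  mem_b <- apolar_by_membership(im_b$contacts$apolar, im_b$patches, sb$chains)
  for (cat in c("both", "one", "none"))
    cons[[paste0("apolar_patch_", cat)]] <-
      contact_conservation(mem_a[[cat]], mem_b[[cat]], mvec, weighted = TRUE)

  merged <- merge_patches_across_interologs(im_a$patches, im_b$patches, mvec)
  cons$patch_bundles <- patch_bundle_conservation(
    merged, im_a$contacts$apolar, im_b$contacts$apolar, sa$chains, sb$chains)

  sw <- switching_out(im_a, im_b, mvec)
  ce <- charge_exchange(sa, sb, im_a$contacts$salt_bridges,
                        im_b$contacts$salt_bridges, mvec)
  cf <- charge_fate(sa, sb, im_b, im_a$contacts$salt_bridges,
                    im_b$contacts$salt_bridges, mvec, config)
  ident <- tryCatch(
    min_interface_identity(im_a, im_b,
                           if (inherits(corr, "correspondence_map")) corr
                           else list(pairs = data.frame(
                             uid_a = names(mvec), uid_b = unname(mvec),
                             aa_a = residue_aa(sa, names(mvec)),
                             aa_b = residue_aa(sb, unname(mvec)),
                             chain_a = sub(":.*", "", names(mvec)),
                             stringsAsFactors = FALSE))),
    error = function(e) list(identity = NA_real_, bin = NA_character_,
                             per_chain = NULL))

  structure(list(conservation = cons, switching = sw, charge_exchange = ce,
                 charge_fate = cf, identity = ident,
                 residue_conservation = residue_conservation_share(cons$atomic),
                 correspondence = corr, patches_merged = merged,
                 im_a = im_a, im_b = im_b, config = config),
            class = "conservation_report")
}

# one-letter codes for a uid vector
residue_aa <- function(x, uids) {
  res <- residue_table(x)
  stats::setNames(res$aa, res$res_uid)[uids]
}

#' @export
print.conservation_report <- function(x, ...) {
  cat("Interolog conservation report:", x$im_a$structure$id, "vs",
      x$im_b$structure$id, "\n")
  if (!is.na(x$identity$identity))
    cat(sprintf("  min interface identity: %.1f%% %s\n",
                x$identity$identity, x$identity$bin))
  for (nm in names(x$conservation)) {
    r <- x$conservation[[nm]]$ratio
    cat(sprintf("  %-20s %s\n", nm,
                if (is.na(r)) "(no contacts)" else sprintf("%.3f", r)))
  }
  cat(sprintf("  switching out: %.1f%% of %d mapped interface residues\n",
              100 * x$switching$fraction, x$switching$n))
  if (x$charge_exchange$n_conserved > 0)
    cat(sprintf("  charge exchanges: %d of %d conserved salt bridges\n",
                x$charge_exchange$n_exchange, x$charge_exchange$n_conserved))
  invisible(x)
}

#' @export
summary.conservation_report <- function(object, ...) {
  ratios <- vapply(object$conservation, `[[`, numeric(1), "ratio")
  data.frame(contact_type = names(ratios), conservation = unname(ratios))
}
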