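# Interolog comparison: residue correspondence, weighted-Jaccard contact
# conservation, switching-out, charge exchange and charge-fate scenarios.

#' Residue correspondence between two homologous complexes
#'
#' Maps residues of complex A onto residues of complex B, chain by chain,
#' either from user-supplied pairwise alignments (aligned FASTA, two sequences
#' per chain pair) or from a global Needleman-Wunsch alignment (BLOSUM62, gap
#' opening 11, extension 1, via Biostrings). Only non-gap aligned columns are
#' mapped; the map is one-to-one on its domain.
#'
#' @param xa,xb `complex_structure` objects; chain k of `xa` is paired with
#'   chain k of `xb`.
#' @param alignments Optional list (length 2) of either paths to aligned FASTA
#'   files or character vectors of two aligned sequences, one per chain pair.
#' @return An object of class `correspondence_map`: list with `pairs` (data
#'   frame `uid_a`, `uid_b`, `aa_a`, `aa_b`, `chain_a`, `chain_b`), `map`
#'   (named vector uid_a -> uid_b), `rmap` (inverse), `chain_identity`
#'   (percent identity per chain pair), `source`.
#' @export
chain_correspondence <- function(xa, xb, alignments = NULL) {
  res_a <- residue_table(xa); res_b <- residue_table(xb)
  rows <- list(); ident <- numeric(2)
  for (k in 1:2) {
    ra <- res_a[res_a$chain == xa$chains[k], , drop = FALSE]
    rb <- res_b[res_b$chain == xb$chains[k], , drop = FALSE]
    seq_a <- paste(ra$aa, collapse = ""); seq_b <- paste(rb$aa, collapse = "")
    if (!is.null(alignments)) {
      aln <- alignments[[k]]
      if (length(aln) == 1 && file.exists(aln)) {
        ss <- Biostrings::readBStringSet(aln)
        if (length(ss) != 2) stop("aligned FASTA must hold exactly 2 sequences")
        aln <- as.character(ss)
      }
      ga <- strsplit(aln[1], "")[[1]]; gb <- strsplit(aln[2], "")[[1]]
      if (length(ga) != length(gb))
        stop("aligned sequences have different lengths")
      da <- gsub("-", "", aln[1]); db <- gsub("-", "", aln[2])
      if (da != seq_a)
        stop("alignment/structure mismatch for chain ", xa$chains[k],
             " of A (first discrepancy at position ",
             which(strsplit(da, "")[[1]] != strsplit(seq_a, "")[[1]])[1], ")")
      if (db != seq_b)
        stop("alignment/structure mismatch for chain ", xb$chains[k],
             " of B (first discrepancy at position ",
             which(strsplit(db, "")[[1]] != strsplit(seq_b, "")[[1]])[1], ")")
      src <- "provided-alignment"
    } else {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
        substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
        type = "global")
      ga <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
      gb <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
      src <- "computed"
    }
    ia <- cumsum(ga != "-"); ib <- cumsum(gb != "-")
    aligned <- ga != "-" & gb != "-"
    pairs <- data.frame(
      uid_a = ra$res_uid[ia[aligned]], uid_b = rb$res_uid[ib[aligned]],
      aa_a = ga[aligned], aa_b = gb[aligned],
      chain_a = xa$chains[k], chain_b = xb$chains[k],
      stringsAsFactors = FALSE)
    ident[k] <- if (nrow(pairs) > 0)
      100 * mean(pairs$aa_a == pairs$aa_b) else NA_real_
    rows[[k]] <- pairs
  }
  pairs <- do.call(rbind, rows)
  structure(list(pairs = pairs,
                 map = stats::setNames(pairs$uid_b, pairs$uid_a),
                 rmap = stats::setNames(pairs$uid_a, pairs$uid_b),
                 chain_identity = stats::setNames(ident, xa$chains),
                 source = src),
            class = "correspondence_map")
}

#' @export
print.correspondence_map <- function(x, ...) {
  cat("Residue correspondence (", x$source, "): ", nrow(x$pairs),
      " mapped pairs\n", sep = "")
  for (ch in names(x$chain_identity))
    cat(sprintf("  chain %s: %.1f%% identity\n", ch, x$chain_identity[ch]))
  invisible(x)
}

#' Restrict contact edges to slowly evolving residues
#'
#' Keeps the edges whose two residues both have a per-residue evolutionary
#' conservation score (normalized 0-100, e.g. from a rate-estimation tool)
#' above a threshold. Used to compute conservation statistics over the most
#' conserved interface positions only.
#'
#' @param edges Residue-pair edge table (`uid_a`, `uid_b`, ...).
#' @param scores Named numeric vector of scores per `res_uid`, or a data
#'   frame with columns `res_uid` and `score` (or `chain`, `resnum`,
#'   optionally `icode`, and `score`).
#' @param min_score Threshold; edges are kept when both endpoints score
#'   strictly above it (default 80).
#' @return The filtered edge table.
#' @export
filter_edges_by_rate <- function(edges, scores, min_score = 80) {
  if (is.data.frame(scores)) {
    if (!"res_uid" %in% names(scores)) {
      ic <- if ("icode" %in% names(scores)) scores$icode else ""
      ic[is.na(ic)] <- ""
      scores$res_uid <- paste(scores$chain, scores$resnum, ic, sep = ":")
    }
    scores <- stats::setNames(scores$score, scores$res_uid)
  }
  keep <- !is.na(scores[edges$uid_a]) & !is.na(scores[edges$uid_b]) &
    scores[edges$uid_a] > min_score & scores[edges$uid_b] > min_score
  edges[keep, , drop = FALSE]
}

# Restrict a residue-pair edge table to edges whose endpoints are both mapped,
# and rekey B-side edges into A-side uids.
restrict_edges <- function(edges, keep_a, keep_b = NULL) {
  if (is.null(keep_b)) keep_b <- keep_a
  edges[edges$uid_a %in% keep_a & edges$uid_b %in% keep_b, , drop = FALSE]
}

#' Weighted-Jaccard contact conservation between two interologs
#'
#' Both contact graphs are restricted to residues with a mapped equivalent;
#' an edge present in both interologs contributes the average of its two
#' atomic-contact weights to the conserved mass, an edge present in only one
#' contributes its own weight to the non-conserved mass; the conservation
#' ratio is conserved / (conserved + non-conserved). For polar contact types
#' (salt bridges, charged, hydrogen bonds) the convention is unweighted:
#' every residue-pair edge counts 1 (`weighted = FALSE`).
#'
#' @param edges_a,edges_b Residue-pair edge tables (`uid_a`, `uid_b`,
#'   `weight`) of the two interologs.
#' @param map Correspondence from [chain_correspondence()] (or any named
#'   uid_a -> uid_b vector).
#' @param weighted Use atomic-contact weights (`TRUE`) or count each edge as
#'   1 (`FALSE`).
#' @return List with `ratio` (in \[0, 1\], or NA when both restricted graphs
#'   are empty), `conserved`, `nonconserved`, `n_conserved`, `n_a_only`,
#'   `n_b_only`, and `edges` (the merged edge table with per-edge status).
#' @export
contact_conservation <- function(edges_a, edges_b, map, weighted = TRUE) {
  if (inherits(map, "correspondence_map")) map <- map$map
  rmap <- stats::setNames(names(map), map)
  ea <- restrict_edges(edges_a, names(map))
  eb <- restrict_edges(edges_b, unname(map))
  # rekey B edges into A uid space
  if (nrow(eb) > 0) {
    eb$uid_a <- unname(rmap[eb$uid_a]); eb$uid_b <- unname(rmap[eb$uid_b])
  }
  wa <- if (weighted) ea$weight else rep(1, nrow(ea))
  wb <- if (weighted) eb$weight else rep(1, nrow(eb))
  ka <- paste(ea$uid_a, ea$uid_b, sep = "|")
  kb <- paste(eb$uid_a, eb$uid_b, sep = "|")
  keys <- union(ka, kb)
  if (length(keys) == 0)
    return(list(ratio = NA_real_, conserved = 0, nonconserved = 0,
                n_conserved = 0, n_a_only = 0, n_b_only = 0,
                edges = data.frame()))
  ma <- match(keys, ka); mb <- match(keys, kb)
  in_a <- !is.na(ma); in_b <- !is.na(mb)
  w <- ifelse(in_a & in_b, (wa[ma] + wb[mb]) / 2,
              ifelse(in_a, wa[ma], wb[mb]))
  status <- ifelse(in_a & in_b, "conserved", ifelse(in_a, "a_only", "b_only"))
  conserved <- sum(w[status == "conserved"])
  nonconserved <- sum(w[status != "conserved"])
  parts <- strsplit(keys, "|", fixed = TRUE)
  edges <- data.frame(uid_a = vapply(parts, `[`, "", 1),
                      uid_b = vapply(parts, `[`, "", 2),
                      weight = w, status = status, stringsAsFactors = FALSE)
  list(ratio = conserved / (conserved + nonconserved),
       conserved = conserved, nonconserved = nonconserved,
       n_conserved = sum(status == "conserved"),
       n_a_only = sum(status == "a_only"), n_b_only = sum(status == "b_only"),
       edges = edges)
}

#' Residues switching out of the interface
#'
#' A mapped residue switches out when it is at the interface in one interolog
#' and its structural equivalent is not at the interface in the other.
#' Unmapped residues are excluded. The overall fraction is taken over mapped
#' residues at the interface of either interolog; per-sub-region fractions
#' pool each side's interface residues with that side's labels.
#'
#' @param im_a,im_b [interface_model()] objects.
#' @param map A `correspondence_map` (or named uid_a -> uid_b vector).
#' @return List with `flags` (named logical over mapped interface residues of
#'   either side, keyed by A-side uid), `fraction`, `by_region` (named
#'   fractions for core/support/rim), `n`.
#' @export
switching_out <- function(im_a, im_b, map) {
  if (inherits(map, "correspondence_map")) map <- map$map
  ia <- im_a$interface; ib <- im_b$interface
  uid_a <- names(map)[names(map) %in% ia | unname(map) %in% ib]
  in_a <- uid_a %in% ia
  in_b <- unname(map[uid_a]) %in% ib
  flags <- stats::setNames(xor(in_a, in_b), uid_a)
  reg_a <- stats::setNames(im_a$residues$region, im_a$residues$res_uid)
  reg_b <- stats::setNames(im_b$residues$region, im_b$residues$res_uid)
  by_region <- c(core = NA_real_, support = NA_real_, rim = NA_real_)
  cnt <- c(core = 0, support = 0, rim = 0); sw <- cnt
  for (i in seq_along(uid_a)) {
    if (in_a[i]) {
      r <- reg_a[uid_a[i]]
      cnt[r] <- cnt[r] + 1; sw[r] <- sw[r] + flags[i]
    }
    if (in_b[i]) {
      r <- reg_b[unname(map[uid_a[i]])]
      cnt[r] <- cnt[r] + 1; sw[r] <- sw[r] + flags[i]
    }
  }
  by_region[cnt > 0] <- sw[cnt > 0] / cnt[cnt > 0]
  list(flags = flags,
       fraction = if (length(flags) > 0) mean(flags) else NA_real_,
       by_region = by_region, n = length(flags))
}

# amino-acid charge sign of a residue uid in a structure ("+", "-", or NA)
charge_sign <- function(x, uids) {
  res <- residue_table(x)
  aa <- stats::setNames(res$resid, res$res_uid)[uids]
  ifelse(aa %in% names(.CHARGED_POS), "+",
         ifelse(aa %in% names(.CHARGED_NEG), "-", NA_character_))
}

#' Charge exchange among conserved salt bridges
#'
#' A conserved salt-bridge position pair whose positive and negative charges
#' are swapped between the two interologs (e.g. Lys-Glu becoming Asp-Arg at
#' the mapped positions) is a charge exchange; such pairs count as conserved.
#'
#' @param xa,xb `complex_structure` objects.
#' @param sb_a,sb_b Salt-bridge edge tables from [salt_bridges()].
#' @param map A `correspondence_map` or named uid vector.
#' @return List with `n_conserved`, `n_exchange` and `edges` (conserved
#'   salt-bridge edges with an `exchange` flag).
#' @export
charge_exchange <- function(xa, xb, sb_a, sb_b, map) {
  if (inherits(map, "correspondence_map")) map <- map$map
  cons <- contact_conservation(sb_a, sb_b, map, weighted = FALSE)
  if (length(cons$edges) == 0 || nrow(cons$edges) == 0)
    return(list(n_conserved = 0, n_exchange = 0, edges = data.frame()))
  e <- cons$edges[cons$edges$status == "conserved", , drop = FALSE]
  if (nrow(e) == 0)
    return(list(n_conserved = 0, n_exchange = 0, edges = e))
  sign_a <- charge_sign(xa, e$uid_a)
  sign_b <- charge_sign(xb, unname(map[e$uid_a]))
  e$exchange <- !is.na(sign_a) & !is.na(sign_b) & sign_a != sign_b
  list(n_conserved = nrow(e), n_exchange = sum(e$exchange), edges = e)
}

#' Fate of charged residues losing a salt bridge
#'
#' For every salt bridge of interolog A absent in B, examines each endpoint
#' whose mapped equivalent remains charged (same sign) while the partner
#' position no longer provides the bridge, and classifies its situation in B.
#' Categories, in priority order: `switch_out` (the residue is no longer at
#' interface), `SB_inter` (another inter-chain salt bridge), `SB_intra`
#' (intra-chain salt bridge), `CH_inter` (longer-range inter-chain charged
#' contact), `CH_intra`, `other`.
#'
#' @param xa,xb `complex_structure` objects.
#' @param im_b The [interface_model()] of B (for its interface set).
#' @param sb_a,sb_b Inter-chain salt-bridge tables of A and B.
#' @param map A `correspondence_map` or named uid vector.
#' @param config A [contact_config()].
#' @return Data frame with one row per examined residue: `uid_a`, `uid_b`,
#'   `category`.
#' @export
charge_fate <- function(xa, xb, im_b, sb_a, sb_b, map,
                        config = contact_config()) {
  if (inherits(map, "correspondence_map")) map <- map$map
  out <- data.frame(uid_a = character(), uid_b = character(),
                    category = character(), stringsAsFactors = FALSE)
  if (nrow(sb_a) == 0) return(out)
  cons <- contact_conservation(sb_a, sb_b, map, weighted = FALSE)
  lost <- cons$edges[cons$edges$status == "a_only", , drop = FALSE]
  if (nrow(lost) == 0) return(out)
  # contact tables of B evaluated once
  sb_inter <- sb_b
  sb_intra <- charged_contacts(xb, cutoff = config$salt_bridge_cutoff,
                               inter_chain = FALSE)
  ch_inter <- charged_contacts(xb, cutoff = config$charged_cutoff)
  ch_intra <- charged_contacts(xb, cutoff = config$charged_cutoff,
                               inter_chain = FALSE)
  involved <- function(tab, uid)
    nrow(tab) > 0 && any(tab$uid_a == uid | tab$uid_b == uid)
  rows <- list()
  for (i in seq_len(nrow(lost))) {
    ends <- c(lost$uid_a[i], lost$uid_b[i])
    sa <- charge_sign(xa, ends)
    for (k in 1:2) {
      me <- ends[k]; partner <- ends[3 - k]
      me_b <- unname(map[me]); partner_b <- unname(map[partner])
      if (is.na(me_b)) next
      # the residue of interest must remain charged with the same sign in B
      if (is.na(charge_sign(xb, me_b)) || charge_sign(xb, me_b) != sa[k]) next
      # and the bridge must be lost because the partner no longer supplies it:
      # partner uncharged/mutated or switched out
      partner_lost <- is.na(partner_b) ||
        is.na(charge_sign(xb, partner_b)) ||
        charge_sign(xb, partner_b) != sa[3 - k] ||
        !(partner_b %in% im_b$interface)
      if (!partner_lost) next
      cat_b <- if (!(me_b %in% im_b$interface)) "switch_out"
      else if (involved(sb_inter, me_b)) "SB_inter"
      else if (involved(sb_intra, me_b)) "SB_intra"
      else if (involved(ch_inter, me_b)) "CH_inter"
      else if (involved(ch_intra, me_b)) "CH_intra"
      else "other"
      rows[[length(rows) + 1]] <- data.frame(uid_a = me, uid_b = me_b,
                                             category = cat_b,
                                             stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(out)
  do.call(rbind, rows)
}

#' Minimum interface sequence identity of an interolog pair
#'
#' Per chain pair, the percent identity over mapped positions at the
#' interface of both interologs (intersection); the minimum over the two
#' chain pairs is returned and binned into the divergence classes
#' \[0,30), \[30,50), \[50,70), \[70,100\].
#'
#' @param im_a,im_b [interface_model()] objects.
#' @param corr A `correspondence_map`.
#' @return List with `identity` (percent), `bin` (label), `per_chain`.
#' @export
min_interface_identity <- function(im_a, im_b, corr) {
  p <- corr$pairs
  sel <- p$uid_a %in% im_a$interface & p$uid_b %in% im_b$interface
  if (!any(sel)) stop("no mapped interface residues between the interologs")
  per_chain <- vapply(split(p[sel, ], p$chain_a[sel]),
                      function(d) 100 * mean(d$aa_a == d$aa_b), numeric(1))
  ident <- min(per_chain)
  bin <- cut(ident, breaks = c(0, 30, 50, 70, 100.000001),
             labels = c("[0,30)", "[30,50)", "[50,70)", "[70,100]"),
             right = FALSE, include.lowest = TRUE)
  list(identity = ident, bin = as.character(bin), per_chain = per_chain)
}
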