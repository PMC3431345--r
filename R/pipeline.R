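# Pipeline orchestration: per-complex analysis, pairwise comparison and batch
# aggregation with JSON/TSV report writing.

.SCHEMA_VERSION <- "1.0"

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# interface residue table in the export layout
interface_tsv_table <- function(im) {
  r <- im$residues[im$residues$interface, ]
  data.frame(chain = r$chain, resnum = r$resno, icode = r$insert, aa = r$aa,
             region = r$region, delta_rasa = round(r$delta_rasa, 2),
             n_contacts = r$n_contacts, dist_center = round(r$dist_center, 4),
             is_anchor = r$is_anchor, stringsAsFactors = FALSE)
}

patch_report <- function(patches) {
  lapply(unlist(patches, recursive = FALSE), function(p)
    list(id = p$id, side = p$chain, n_atoms = p$n_atoms, atoms = p$atoms,
         residues = p$residues, composition = as.list(p$composition)))
}

#' Analyze one complex and write its interface report
#'
#' Builds the [interface_model()] and, if `out_dir` is given, writes a JSON
#' report (interface, sub-regions, contacts, patches, anchors) plus a TSV
#' residue table and a TSV contact table. Outputs are deterministic: the same
#' input and configuration produce byte-identical files.
#'
#' @param x A `complex_structure`, or a path to a PDB/mmCIF file.
#' @param chains Chain pair (required when `x` is a path).
#' @param config A [contact_config()].
#' @param out_dir Optional output directory.
#' @return The `interface_model`, invisibly when writing files.
#' @export
run_analyze <- function(x, chains = NULL, config = contact_config(),
                        out_dir = NULL) {
  if (is.character(x)) x <- read_structure(x, chains)
  im <- interface_model(x, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    rep <- list(schema_version = .SCHEMA_VERSION, id = x$id,
                chains = x$chains,
                n_interface = length(im$interface),
                regions = as.list(table(im$residues$region[im$residues$interface])),
                anchors = im$anchors,
                center = as.numeric(im$center),
                n_contacts = list(
                  atomic = nrow(im$contacts$atomic),
                  residue_pairs = nrow(im$contacts$graph),
                  charged = nrow(im$contacts$charged),
                  salt_bridges = nrow(im$contacts$salt_bridges),
                  hbonds = nrow(im$contacts$hbonds),
                  apolar = nrow(im$contacts$apolar)),
                patches = patch_report(im$patches))
    jsonlite::write_json(rep, file.path(out_dir, "interface.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_tsv(interface_tsv_table(im), file.path(out_dir, "residues.tsv"))
    write_tsv(im$contacts$atomic, file.path(out_dir, "contacts.tsv"))
    return(invisible(im))
  }
  im
}

#' Compare two complexes and write the conservation report
#'
#' Runs [compare_interologs()] and optionally writes the conservation report
#' (JSON) and the per-residue feature table with predictor scores (TSV).
#'
#' @param xa,xb `complex_structure` objects or file paths.
#' @param chains_a,chains_b Chain pairs (when paths are given).
#' @param alignments,map,config Passed to [compare_interologs()].
#' @param out_dir Optional output directory.
#' @return The `conservation_report`, invisibly when writing files.
#' @export
run_compare <- function(xa, xb, chains_a = NULL, chains_b = NULL,
                        alignments = NULL, map = NULL,
                        config = contact_config(), out_dir = NULL) {
  if (is.character(xa)) xa <- read_structure(xa, chains_a)
  if (is.character(xb)) xb <- read_structure(xb, chains_b)
  rep <- compare_interologs(xa, xb, alignments = alignments, map = map,
                            config = config)
  feats <- suppressWarnings(residue_features(rep))
  if (nrow(feats) > 0) {
    feats$p_switch_out <- logistic_score(feats, switching_out_model())
    feats$p_conserved <- logistic_score(feats, contact_conservation_model())
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ratios <- lapply(rep$conservation, function(cc)
      list(ratio = cc$ratio, conserved = cc$conserved,
           nonconserved = cc$nonconserved))
    out <- list(schema_version = .SCHEMA_VERSION,
                id_a = rep$im_a$structure$id, id_b = rep$im_b$structure$id,
                min_interface_identity = rep$identity$identity,
                identity_bin = rep$identity$bin,
                conservation = ratios,
                switching_out = list(fraction = rep$switching$fraction,
                                     n = rep$switching$n,
                                     by_region = as.list(rep$switching$by_region)),
                charge_exchange = rep$charge_exchange[c("n_conserved",
                                                        "n_exchange")],
                charge_fate = if (nrow(rep$charge_fate) > 0)
                  as.list(table(rep$charge_fate$category)) else list())
    jsonlite::write_json(out, file.path(out_dir, "conservation.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (nrow(feats) > 0)
      write_tsv(feats, file.path(out_dir, "features.tsv"))
    return(invisible(rep))
  }
  rep
}

#' Batch comparison of interolog couples with bootstrap summaries
#'
#' Processes a manifest of interolog couples, pooling per-couple conservation
#' ratios by contact type and attaching bootstrap confidence intervals for
#' each pooled mean. Per-couple failures are recorded and skipped.
#'
#' @param manifest Data frame (or TSV path) with columns `path_a`, `chains_a`
#'   (e.g. `"A:B"`), `path_b`, `chains_b`, and optionally `aln_1`, `aln_2`
#'   (alignment paths) and `rates_a`, `rates_b` (per-residue conservation
#'   score TSVs, see [filter_edges_by_rate()]).
#' @param config A [contact_config()].
#' @param n_resamples,fraction,seed Bootstrap parameters (see
#'   [bootstrap_mean_ci()]).
#' @param min_rate_score When rate-score files are supplied, atomic contact
#'   conservation is additionally pooled over the residues scoring above this
#'   threshold (default 80).
#' @return List with `reports` (per-couple `conservation_report`s), `pooled`
#'   (data frame: contact type, n, mean, CI), `failures` (data frame of
#'   failed couples with messages).
#' @export
run_batch <- function(manifest, config = contact_config(), n_resamples = 1000,
                      fraction = 0.5, seed = 1, min_rate_score = 80) {
  if (is.character(manifest))
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  reports <- list(); failures <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      aln <- if (!is.null(row$aln_1) && !is.na(row$aln_1) && nzchar(row$aln_1))
        list(row$aln_1, row$aln_2) else NULL
      run_compare(row$path_a, row$path_b,
                  chains_a = strsplit(row$chains_a, ":")[[1]],
                  chains_b = strsplit(row$chains_b, ":")[[1]],
                  alignments = aln, config = config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        data.frame(couple = i, message = conditionMessage(res))
    } else {
      # optional restriction to slowly evolving residues
      if (!is.null(row$rates_a) && !is.na(row$rates_a) &&
          nzchar(row$rates_a)) {
        ra <- utils::read.delim(row$rates_a, stringsAsFactors = FALSE)
        rb <- utils::read.delim(row$rates_b, stringsAsFactors = FALSE)
        mvec <- if (inherits(res$correspondence, "correspondence_map"))
          res$correspondence$map else res$correspondence
        ga <- filter_edges_by_rate(res$im_a$contacts$graph, ra,
                                   min_rate_score)
        gb <- filter_edges_by_rate(res$im_b$contacts$graph, rb,
                                   min_rate_score)
        res$conservation$atomic_rate_filtered <-
          contact_conservation(ga, gb, mvec, weighted = TRUE)
      }
      reports[[length(reports) + 1]] <- res
    }
  }
  types <- c("atomic", "charged", "salt_bridges", "hbonds", "apolar",
             "patch_bundles")
  if (any(vapply(reports, function(r)
    !is.null(r$conservation$atomic_rate_filtered), logical(1))))
    types <- c(types, "atomic_rate_filtered")
  pooled <- list()
  for (k in seq_along(types)) {
    vals <- vapply(reports, function(r) {
      cc <- r$conservation[[types[k]]]
      if (is.null(cc)) NA_real_ else cc$ratio
    }, numeric(1))
    vals <- vals[!is.na(vals)]
    if (length(vals) >= 4) {
      bs <- bootstrap_mean_ci(vals, n_resamples, fraction, seed = seed + k)
      pooled[[k]] <- data.frame(contact_type = types[k], n = length(vals),
                                mean = bs$estimate, ci_low = bs$ci_low,
                                ci_high = bs$ci_high)
    } else if (length(vals) > 0) {
      pooled[[k]] <- data.frame(contact_type = types[k], n = length(vals),
                                mean = mean(vals), ci_low = NA_real_,
                                ci_high = NA_real_)
    }
  }
  list(reports = reports, pooled = do.call(rbind, pooled),
       failures = if (length(failures)) do.call(rbind, failures) else
         data.frame(couple = integer(), message = character()))
}
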