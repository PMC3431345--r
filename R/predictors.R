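# Logistic-regression predictors of residue switching-out and contact
# conservation: the six per-residue features, published coefficient presets,
# maximum-likelihood fitting, ROC/AUC and deviance-drop ranking.

.FEATURE_NAMES <- c("sim_res", "sim_env", "seq_id", "support", "rim",
                    "n_contacts", "dist_center")

#' Construct a logistic model with named coefficients
#'
#' @param intercept Numeric intercept.
#' @param coef Named numeric vector over the features `sim_res`, `sim_env`,
#'   `seq_id`, `support`, `rim` (dummies, core is the reference category),
#'   `n_contacts`, `dist_center`.
#' @param se Optional named standard errors (same names plus `intercept`).
#' @param deviance,n Optional fit statistics.
#' @param label Descriptive model name.
#' @return An object of class `logistic_model`.
#' @export
logistic_model <- function(intercept, coef, se = NULL, deviance = NULL,
                           n = NULL, label = "custom") {
  miss <- setdiff(.FEATURE_NAMES, names(coef))
  if (length(miss) > 0)
    stop("missing coefficient(s): ", paste(miss, collapse = ", "))
  structure(list(intercept = intercept, coef = coef[.FEATURE_NAMES], se = se,
                 deviance = deviance, n = n, label = label),
            class = "logistic_model")
}

#' Published switching-out predictor
#'
#' Logistic model scoring the probability that an interface residue switches
#' out of the interface in the interolog, with the published coefficients:
#' intercept -1.99; BLOSUM62 residue similarity -0.054; environment
#' similarity -0.128; overall minimum sequence identity (percent) -0.0096;
#' support +0.96 and rim +1.06 (core is the reference); atomic contacts per
#' residue -0.122; normalized distance to the interface center +1.40.
#'
#' @return A `logistic_model`.
#' @export
switching_out_model <- function() {
  logistic_model(-1.99,
                 c(sim_res = -0.054, sim_env = -0.128, seq_id = -0.0096,
                   support = 0.96, rim = 1.06, n_contacts = -0.122,
                   dist_center = 1.40),
                 label = "switching-out (published)")
}

#' Published contact-conservation predictor
#'
#' Logistic model scoring the probability that an interface residue retains
#' most of its contacts in the interolog: intercept -1.32; residue similarity
#' +0.112; environment similarity +0.224; sequence identity +0.0066; support
#' +0.23; rim -0.21; atomic contacts +0.075; distance to center -0.69.
#'
#' @return A `logistic_model`.
#' @export
contact_conservation_model <- function() {
  logistic_model(-1.32,
                 c(sim_res = 0.112, sim_env = 0.224, seq_id = 0.0066,
                   support = 0.23, rim = -0.21, n_contacts = 0.075,
                   dist_center = -0.69),
                 label = "contact conservation (published)")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("Logistic model:", x$label, "\n")
  cat(sprintf("  intercept: %.4g\n", x$intercept))
  for (nm in names(x$coef)) {
    if (!is.null(x$se) && nm %in% names(x$se))
      cat(sprintf("  %-12s %9.4g  (se %.3g)\n", nm, x$coef[nm], x$se[nm]))
    else
      cat(sprintf("  %-12s %9.4g\n", nm, x$coef[nm]))
  }
  if (!is.null(x$deviance))
    cat(sprintf("  deviance: %.2f on n = %d\n", x$deviance, x$n))
  invisible(x)
}

# Build the numeric design matrix from a feature table (region dummy-coded,
# core = reference).
feature_matrix <- function(data) {
  need <- c("sim_res", "sim_env", "seq_id", "region", "n_contacts",
            "dist_center")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("missing feature(s): ", paste(miss, collapse = ", "))
  region <- as.character(data$region)
  if (!all(region %in% c("core", "support", "rim")))
    stop("region must be core, support or rim")
  cbind(sim_res = data$sim_res, sim_env = data$sim_env, seq_id = data$seq_id,
        support = as.numeric(region == "support"),
        rim = as.numeric(region == "rim"),
        n_contacts = data$n_contacts, dist_center = data$dist_center)
}

#' Score residues with a logistic model
#'
#' @param features Data frame with columns `sim_res`, `sim_env`, `seq_id`,
#'   `region` (core/support/rim), `n_contacts`, `dist_center`.
#' @param model A `logistic_model`.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
logistic_score <- function(features, model) {
  X <- feature_matrix(features)
  if (anyNA(X)) stop("missing feature values")
  eta <- model$intercept + drop(X %*% model$coef[colnames(X)])
  stats::plogis(eta)
}

#' Per-residue features for the predictors
#'
#' Extracts the six features for every mapped interface residue of the
#' reference interolog: `sim_res` (BLOSUM62 score of the residue against its
#' structural equivalent), `sim_env` (mean BLOSUM62 score over the residues
#' it contacts, both chains), `seq_id` (overall minimum percent identity with
#' the interolog), `region`, `n_contacts` (atomic contacts of the residue)
#' and `dist_center`. Residues with no atomic contact are excluded with a
#' warning (their environment score is undefined). Labels for both predictors
#' are attached: `switch_out` and `conserved` (share of the residue's
#' atomic-contact weight conserved at least `conserved_threshold`).
#'
#' @param report A [compare_interologs()] result.
#' @param conserved_threshold Binarization threshold for the
#'   contact-conservation label (default 0.5).
#' @return Data frame of features and labels keyed by `res_uid` (A-side).
#' @export
residue_features <- function(report, conserved_threshold = 0.5) {
  im <- report$im_a
  corr <- report$correspondence
  mvec <- if (inherits(corr, "correspondence_map")) corr$map else corr
  res <- im$residues
  aa_a <- stats::setNames(res$aa, res$res_uid)
  aa_b <- residue_aa(report$im_b$structure, unname(mvec))
  names(aa_b) <- names(mvec)
  B62 <- blosum62()

  seq_id <- if (inherits(corr, "correspondence_map"))
    min(corr$chain_identity) else {
      p <- data.frame(a = aa_a[names(mvec)], b = aa_b[names(mvec)],
                      ch = sub(":.*", "", names(mvec)))
      min(vapply(split(p, p$ch), function(d) 100 * mean(d$a == d$b),
                 numeric(1)))
    }

  graph <- im$contacts$graph
  uids <- res$res_uid[res$interface & res$res_uid %in% names(mvec)]
  sim_of <- function(u) {
    if (is.na(aa_b[u])) return(NA_real_)
    B62[aa_a[u], aa_b[u]]
  }
  rows <- list()
  excluded <- character()
  for (u in uids) {
    partners <- c(graph$uid_b[graph$uid_a == u], graph$uid_a[graph$uid_b == u])
    env <- vapply(partners[partners %in% names(mvec)], sim_of, numeric(1))
    env <- env[!is.na(env)]
    if (length(env) == 0) { excluded <- c(excluded, u); next }
    rows[[u]] <- data.frame(
      res_uid = u, sim_res = sim_of(u), sim_env = mean(env), seq_id = seq_id,
      region = res$region[res$res_uid == u],
      n_contacts = res$n_contacts[res$res_uid == u],
      dist_center = res$dist_center[res$res_uid == u],
      stringsAsFactors = FALSE)
  }
  if (length(excluded) > 0)
    warning(length(excluded),
            " residue(s) without contacts excluded from features")
  if (length(rows) == 0) return(data.frame())
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out$switch_out <- as.logical(report$switching$flags[out$res_uid])
  shares <- stats::setNames(report$residue_conservation$share,
                            report$residue_conservation$res_uid)
  out$conserved <- !is.na(shares[out$res_uid]) &
    shares[out$res_uid] >= conserved_threshold
  out
}

#' Fit a logistic regression on a feature table
#'
#' Maximum-likelihood fit (via `glm`, iteratively reweighted least squares)
#' of a binary label on the six features.
#'
#' @param data Feature data frame (columns as in [logistic_score()]) plus the
#'   label column.
#' @param label Name of the logical/0-1 label column (default `"label"`).
#' @return A `logistic_model` with fitted coefficients, standard errors,
#'   deviance and sample size. Warns on suspected perfect separation.
#' @export
fit_logistic <- function(data, label = "label") {
  y <- as.numeric(data[[label]])
  if (length(unique(y)) < 2)
    stop("need at least one positive and one negative label")
  X <- feature_matrix(data)
  df <- data.frame(y = y, X)
  fit <- stats::glm(y ~ ., data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (!fit$converged || any(abs(co) > 15, na.rm = TRUE))
    warning("possible perfect separation: coefficients ",
            paste(sprintf("%s=%.3g", names(co), co), collapse = ", "))
  m <- logistic_model(unname(co["(Intercept)"]),
                      stats::setNames(co[.FEATURE_NAMES], .FEATURE_NAMES),
                      se = stats::setNames(c(se["(Intercept)"],
                                             se[.FEATURE_NAMES]),
                                           c("intercept", .FEATURE_NAMES)),
                      deviance = stats::deviance(fit), n = length(y),
                      label = "fitted")
  m$null_deviance <- fit$null.deviance
  m
}

#' ROC area under the curve
#'
#' AUC as the Mann-Whitney concordance probability (midranks give half credit
#' to ties), plus the points of the ROC curve obtained by progressively
#' including residues from the best score down.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Logical or 0/1 labels; both classes must be present.
#' @return List with `auc` and `curve` (data frame `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  y <- as.logical(labels)
  if (!any(y) || all(y)) stop("both classes must be present")
  r <- rank(scores)
  npos <- sum(y); nneg <- sum(!y)
  auc <- (sum(r[y]) - npos * (npos + 1) / 2) / (npos * nneg)
  ord <- order(scores, decreasing = TRUE)
  curve <- data.frame(fpr = c(0, cumsum(!y[ord]) / nneg),
                      tpr = c(0, cumsum(y[ord]) / npos))
  list(auc = auc, curve = curve)
}

#' Rank features by deviance reduction
#'
#' Drops each feature in turn from the full logistic model, refits, and ranks
#' features by the resulting deviance increase (rank 1 = largest increase =
#' most important). The two sub-region dummies are dropped together as one
#' `region` feature.
#'
#' @param data Feature + label data frame as for [fit_logistic()].
#' @param label Label column name.
#' @return Data frame `feature`, `deviance_increase`, `rank`.
#' @export
deviance_ranking <- function(data, label = "label") {
  full <- fit_logistic(data, label)
  groups <- list(sim_res = "sim_res", sim_env = "sim_env", seq_id = "seq_id",
                 region = c("support", "rim"), n_contacts = "n_contacts",
                 dist_center = "dist_center")
  y <- as.numeric(data[[label]])
  X <- feature_matrix(data)
  inc <- vapply(groups, function(drop_cols) {
    Xr <- X[, setdiff(colnames(X), drop_cols), drop = FALSE]
    fit <- stats::glm(y ~ ., data = data.frame(y = y, Xr),
                      family = stats::binomial())
    stats::deviance(fit) - full$deviance
  }, numeric(1))
  out <- data.frame(feature = names(groups), deviance_increase = unname(inc))
  out$rank <- rank(-out$deviance_increase, ties.method = "min")
  out[order(out$rank), ]
}

#' Split interolog couples into train/test partitions
#'
#' Partitions at the couple level (all residues of a couple stay together):
#' a random `train_fraction` of the couples forms the training set, the rest
#' the test set, repeated `repeats` times. Reproducible by seed.
#'
#' @param couples Character or integer vector of couple identifiers (>= 3).
#' @param train_fraction Fraction of couples used for training (default 1/3).
#' @param repeats Number of random partitions (default 10).
#' @param seed Integer seed.
#' @return List of `repeats` lists, each with `train` and `test` id vectors.
#' @export
split_train_test <- function(couples, train_fraction = 1/3, repeats = 10,
                             seed = 1) {
  couples <- unique(couples)
  if (length(couples) < 3) stop("need at least 3 couples")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n_train <- max(1, round(length(couples) * train_fraction))
  lapply(seq_len(repeats), function(i) {
    train <- sample(couples, n_train)
    list(train = train, test = setdiff(couples, train))
  })
}
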