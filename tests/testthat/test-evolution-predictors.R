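# Feature extraction, logistic scoring/fitting, ROC and deviance ranking.

zero_row <- function(region = "core") {
  data.frame(sim_res = 0, sim_env = 0, seq_id = 0, region = region,
             n_contacts = 0, dist_center = 0)
}

test_that("published presets score the logistic equation exactly", {
  expect_equal(logistic_score(zero_row(), switching_out_model()),
               1 / (1 + exp(1.99)), tolerance = 1e-12)
  expect_equal(logistic_score(zero_row("support"), switching_out_model()),
               stats::plogis(-1.99 + 0.96), tolerance = 1e-12)
  expect_equal(logistic_score(zero_row(), contact_conservation_model()),
               1 / (1 + exp(1.32)), tolerance = 1e-12)
  # rough numeric anchors
  expect_equal(round(logistic_score(zero_row(), switching_out_model()), 3),
               0.120)
  expect_equal(round(logistic_score(zero_row("support"),
                                    switching_out_model()), 3), 0.263)
  expect_equal(round(logistic_score(zero_row(), contact_conservation_model()),
                     3), 0.211)
})

test_that("scores live in (0,1), flip under sign reversal, follow coefficients", {
  m <- switching_out_model()
  d <- simulate_logistic_dataset(500, m, seed = 3)
  p <- logistic_score(d, m)
  expect_true(all(p > 0 & p < 1))
  m_neg <- logistic_model(-m$intercept, -m$coef)
  expect_equal(logistic_score(d, m_neg), 1 - p, tolerance = 1e-12)

  # monotone in n_contacts per the conservation model's positive coefficient
  lo <- zero_row(); hi <- zero_row(); hi$n_contacts <- 10
  expect_gt(logistic_score(hi, contact_conservation_model()),
            logistic_score(lo, contact_conservation_model()))

  bad <- zero_row(); bad$sim_env <- NULL
  expect_error(logistic_score(bad, m), "sim_env")
  expect_error(logistic_model(0, c(sim_res = 1)), "missing coefficient")
})

test_that("residue features are assembled from correspondence and contacts", {
  toy <- default_toy()
  im <- default_im()
  rep <- compare_interologs(im, im, map = identity_map(toy$structure))
  feats <- suppressWarnings(residue_features(rep))
  expect_true(all(c("sim_res", "sim_env", "seq_id", "region", "n_contacts",
                    "dist_center", "switch_out", "conserved") %in%
                    names(feats)))
  # self-comparison: sim_res is the BLOSUM62 diagonal, identity 100
  B <- blosum62()
  res <- im$residues
  aa <- stats::setNames(res$aa, res$res_uid)
  expect_equal(feats$sim_res, unname(B[cbind(aa[feats$res_uid],
                                             aa[feats$res_uid])]))
  expect_true(all(feats$seq_id == 100))
  expect_true(all(!feats$switch_out))
  expect_true(all(feats$conserved))

  # hand-assembled environment score for one residue
  u <- feats$res_uid[1]
  g <- im$contacts$graph
  partners <- c(g$uid_b[g$uid_a == u], g$uid_a[g$uid_b == u])
  expect_equal(feats$sim_env[feats$res_uid == u],
               mean(B[cbind(aa[partners], aa[partners])]))
  # region, contacts and distances come straight from the interface model
  expect_equal(feats$n_contacts,
               res$n_contacts[match(feats$res_uid, res$res_uid)])
  expect_equal(feats$region, res$region[match(feats$res_uid, res$res_uid)])
})

test_that("null-model fits recover a flat intercept and the 2x2 log odds ratio", {
  set.seed(4)
  d <- simulate_logistic_dataset(20000, logistic_model(
    stats::qlogis(0.3), c(sim_res = 0, sim_env = 0, seq_id = 0, support = 0,
                          rim = 0, n_contacts = 0, dist_center = 0)),
    seed = 4)
  fit <- fit_logistic(d)
  expect_equal(fit$intercept, stats::qlogis(0.3), tolerance = 0.15)
  z <- abs(fit$coef[c("sim_res", "sim_env", "seq_id", "n_contacts",
                      "dist_center")]) /
    fit$se[c("sim_res", "sim_env", "seq_id", "n_contacts", "dist_center")]
  expect_true(all(z < 4))

  # a single binary feature: the slope is the table's log odds ratio
  d2 <- data.frame(sim_res = 0, sim_env = 0, seq_id = 0,
                   region = rep(c("core", "support"), c(100, 100)),
                   n_contacts = 0, dist_center = 0,
                   label = c(rep(1, 30), rep(0, 70), rep(1, 60), rep(0, 40)))
  fit2 <- suppressWarnings(fit_logistic(d2))
  expect_equal(unname(fit2$coef["support"]),
               log((60 / 40) / (30 / 70)), tolerance = 1e-6)
  expect_equal(fit2$intercept, log(30 / 70), tolerance = 1e-6)

  expect_error(fit_logistic(transform(d2, label = 1)), "positive and one")
})

test_that("ROC AUC equals the Mann-Whitney concordance with tie half-credit", {
  r <- roc_auc(c(0.9, 0.8, 0.7, 0.2, 0.1), c(1, 1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.3), c(1, 0, 1))$auc, 0.5)
  s <- runif(50); y <- rbinom(50, 1, 0.5)
  if (length(unique(y)) == 2) {
    expect_equal(roc_auc(s, y)$auc + roc_auc(-s, y)$auc, 1)
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                            direction = "<")))
      expect_equal(roc_auc(s, y)$auc, ref, tolerance = 1e-12)
    }
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("deviance ranking puts the informative feature first", {
  m <- logistic_model(-2, c(sim_res = 0, sim_env = 0, seq_id = 0, support = 0,
                            rim = 0, n_contacts = 0.35, dist_center = 0))
  d <- simulate_logistic_dataset(8000, m, seed = 6)
  rk <- deviance_ranking(d)
  expect_identical(rk$feature[rk$rank == 1], "n_contacts")
  # dropping a zero-coefficient feature barely moves the deviance
  expect_lt(rk$deviance_increase[rk$feature == "sim_res"], 10)
  expect_gt(rk$deviance_increase[rk$feature == "n_contacts"], 100)
})

test_that("train/test splits partition couples reproducibly", {
  sp <- split_train_test(paste0("c", 1:9), seed = 2)
  expect_length(sp, 10)
  expect_length(sp[[1]]$train, 3)
  expect_length(sp[[1]]$test, 6)
  sp2 <- split_train_test(paste0("c", 1:9), seed = 2)
  expect_identical(sp, sp2)
  for (s in sp) {
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), paste0("c", 1:9))
  }
  expect_error(split_train_test(c("a", "b")), "at least 3")
})
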