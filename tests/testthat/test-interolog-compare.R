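# Residue correspondence and conservation statistics between interologs.

test_that("identical chains map by the identity with 100% identity", {
  x <- seq_structure("ACDEFGHIKL", "MNPQRSTVWY")
  corr <- chain_correspondence(x, x)
  expect_equal(unname(corr$chain_identity), c(100, 100))
  expect_identical(unname(corr$map[corr$pairs$uid_a]), corr$pairs$uid_b)
  expect_identical(names(corr$map), unname(corr$map))
})

test_that("provided alignments drive the map and gaps stay unmapped", {
  xa <- seq_structure("ACDEFGHIKL", "MNPQRSTVWY")
  xb <- seq_structure("ACDGHIKL", "MNPQRSTVWY")  # EF deleted in chain A
  aln <- list(c("ACDEFGHIKL", "ACD--GHIKL"), c("MNPQRSTVWY", "MNPQRSTVWY"))
  corr <- chain_correspondence(xa, xb, alignments = aln)
  expect_false(any(c("A:4:", "A:5:") %in% names(corr$map)))  # E, F unmapped
  expect_identical(unname(corr$map["A:6:"]), "A:4:")         # G realigned
  expect_equal(unname(corr$chain_identity[1]), 100 * 8 / 8)

  bad <- list(c("ACDEFGHIKW", "ACD--GHIKL"), c("MNPQRSTVWY", "MNPQRSTVWY"))
  expect_error(chain_correspondence(xa, xb, alignments = bad), "mismatch")
})

test_that("computed alignment matches an independent Gotoh oracle", {
  s1a <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  s1b <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIE"
  s2a <- "APNTWWKVGDHVITAGRK"
  s2b <- "APNTWVGDHVITAGRK"
  xa <- seq_structure(s1a, s2a)
  xb <- seq_structure(s1b, s2b)
  corr <- chain_correspondence(xa, xb)
  for (k in 1:2) {
    ora <- oracle_nw(c(s1a, s2a)[k], c(s1b, s2b)[k])
    got <- corr$pairs[corr$pairs$chain_a == c("A", "B")[k], ]
    expect_equal(as.integer(sub(".*?:(\\d+):.*", "\\1", got$uid_a)),
                 unname(ora[, 1]))
    expect_equal(as.integer(sub(".*?:(\\d+):.*", "\\1", got$uid_b)),
                 unname(ora[, 2]))
  }
})

test_that("weighted Jaccard conservation implements the published edge rule", {
  map <- c("1" = "1b", "2" = "2b", "3" = "3b")
  ea <- data.frame(uid_a = c("1", "2"), uid_b = c("1", "2"),
                   weight = c(2, 4))
  # edge (1,1) shared (B weight 6), edge (2,2) only in A
  eb <- data.frame(uid_a = "1b", uid_b = "1b", weight = 6)
  cc <- contact_conservation(ea, eb, map)
  expect_equal(cc$conserved, 4)       # avg(2, 6)
  expect_equal(cc$nonconserved, 4)    # the one-sided edge keeps its weight
  expect_equal(cc$ratio, 0.5)

  # identical graphs conserve everything; disjoint graphs conserve nothing
  same <- contact_conservation(ea, data.frame(
    uid_a = c("1b", "2b"), uid_b = c("1b", "2b"), weight = c(2, 4)), map)
  expect_equal(same$ratio, 1)
  disj <- contact_conservation(ea, data.frame(
    uid_a = "3b", uid_b = "3b", weight = 1), map)
  expect_equal(disj$ratio, 0)

  # empty-vs-empty is missing, not zero
  none <- contact_conservation(ea[0, ], eb[0, ], map)
  expect_true(is.na(none$ratio))

  # unmapped endpoints never enter the statistic
  ea2 <- rbind(ea, data.frame(uid_a = "9", uid_b = "9", weight = 50))
  cc2 <- contact_conservation(ea2, eb, map)
  expect_equal(cc2$ratio, 0.5)
})

test_that("conservation ratios are symmetric under interolog swap", {
  set.seed(8)
  for (rep in 1:5) {
    uids <- as.character(1:12)
    map <- stats::setNames(paste0(uids, "b"), uids)
    mk <- function(suffix) {
      n <- sample(3:8, 1)
      data.frame(uid_a = paste0(sample(uids, n, TRUE), suffix),
                 uid_b = paste0(sample(uids, n, TRUE), suffix),
                 weight = sample(1:5, n, TRUE))
    }
    ea <- mk(""); eb <- mk("b")
    fwd <- contact_conservation(ea, eb, map)
    rev <- contact_conservation(eb, ea, stats::setNames(names(map), map))
    expect_equal(fwd$ratio, rev$ratio)
    expect_equal(fwd$conserved, rev$conserved)
  }
})

test_that("switching out flags interface loss and tracks the planted rate", {
  toy <- default_toy()
  im <- default_im()
  # self comparison: nothing switches
  self <- switching_out(im, im, identity_map(toy$structure))
  expect_equal(self$fraction, 0)

  # a larger lattice at a planted rate: fraction within the binomial band
  big <- build_toy_complex(toy_spec(nx = 11, ny = 11, seed = 2))
  der <- derive_interolog(big, perturbation_spec(switch_rate = 0.2, seed = 5))
  rep <- compare_interologs(big$structure, der$structure, map = der$map)
  n <- der$expected$n_eligible_switch
  band <- 1.96 * sqrt(0.2 * 0.8 / n)
  expect_gt(rep$switching$fraction, 0.2 - band)
  expect_lt(rep$switching$fraction, 0.2 + band)
  # every displaced residue is flagged; the rare extras are residues whose
  # whole cross-chain neighborhood was displaced alongside them
  flagged <- names(rep$switching$flags)[rep$switching$flags]
  expect_true(all(der$events$switched %in% flagged))
  expect_lt(length(setdiff(flagged, der$events$switched)) /
              length(flagged), 0.1)
})

test_that("charge exchange distinguishes polarity swaps among conserved bridges", {
  mk_sb <- function(aa_a, tip_a, aa_b, tip_b) {
    mini_structure(list(tip_res("A", 1, aa_a, tip_a),
                        tip_res("B", 1, aa_b, tip_b, base_z = 9.4, dirn = -1)))
  }
  map <- c("A:1:" = "A:1:", "B:1:" = "B:1:")
  xa <- mk_sb("LYS", c(NZ = 3.2), "GLU", c(OE1 = 3.2))   # K-E at 3.0
  # same polarity at the mapped positions: conserved, no exchange
  xb1 <- mk_sb("ARG", c(NH1 = 3.2), "ASP", c(OD1 = 3.2))
  ce1 <- charge_exchange(xa, xb1, salt_bridges(xa), salt_bridges(xb1), map)
  expect_equal(ce1$n_conserved, 1L)
  expect_equal(ce1$n_exchange, 0L)

  # swapped charges: conserved AND an exchange
  xb2 <- mk_sb("ASP", c(OD1 = 3.2), "ARG", c(NH1 = 3.2))
  ce2 <- charge_exchange(xa, xb2, salt_bridges(xa), salt_bridges(xb2), map)
  expect_equal(ce2$n_conserved, 1L)
  expect_equal(ce2$n_exchange, 1L)

  # partner mutated to Ser: bridge not conserved
  xb3 <- mk_sb("SER", c(OG = 3.2), "GLU", c(OE1 = 3.2))
  ce3 <- charge_exchange(xa, xb3, salt_bridges(xa), salt_bridges(xb3), map)
  expect_equal(ce3$n_conserved, 0L)
})

test_that("charge fate classifies the remaining charged residue by priority", {
  map <- c("A:1:" = "A:1:", "B:1:" = "B:1:", "A:2:" = "A:2:")
  # A: Lys(A:1)-Glu(B:1) salt bridge
  xa <- mini_structure(list(tip_res("A", 1, "LYS", c(NZ = 3.2)),
                            tip_res("A", 2, "ALA", c(), x = 7),
                            tip_res("B", 1, "GLU", c(OE1 = 3.2),
                                    base_z = 9.4, dirn = -1)))
  # B: partner mutated to Ser; Lys keeps an intra-chain bridge to Asp
  xb_intra <- mini_structure(list(
    tip_res("A", 1, "LYS", c(NZ = 3.2)),
    tip_res("A", 2, "ASP", c(OD1 = 3.2), x = 3),  # OD1 ~3 A from NZ
    tip_res("B", 1, "SER", c(OG = 3.2), base_z = 9.4, dirn = -1)))
  cf <- charge_fate(xa, xb_intra, interface_model(xb_intra),
                    salt_bridges(xa), salt_bridges(xb_intra), map)
  expect_equal(nrow(cf), 1L)
  expect_identical(cf$category, "SB_intra")
  expect_identical(cf$uid_a, "A:1:")

  # B: partner mutated to Ser; Lys ~4.8 A from another partner-chain Asp:
  # a longer-range inter-chain charged contact
  xb_ch <- mini_structure(list(
    tip_res("A", 1, "LYS", c(NZ = 3.2)),
    tip_res("A", 2, "ALA", c(), x = 7),
    tip_res("B", 1, "SER", c(OG = 3.2), base_z = 9.4, dirn = -1),
    tip_res("B", 2, "ASP", c(OD1 = 2.45), x = 3, base_z = 9.4, dirn = -1)))
  cf2 <- charge_fate(xa, xb_ch, interface_model(xb_ch),
                     salt_bridges(xa), salt_bridges(xb_ch), map)
  expect_identical(cf2$category, "CH_inter")

  # B: Lys displaced out of the interface entirely
  xb_sw <- mini_structure(list(
    tip_res("A", 1, "LYS", c(NZ = 3.2), x = 40),
    tip_res("A", 2, "VAL", c(CG1 = 3.0)),
    tip_res("B", 1, "SER", c(OG = 3.2), base_z = 9.4, dirn = -1)))
  cf3 <- charge_fate(xa, xb_sw, interface_model(xb_sw),
                     salt_bridges(xa), salt_bridges(xb_sw), map)
  expect_identical(cf3$category, "switch_out")
})

test_that("minimum interface identity takes the lower chain and bins half-open", {
  fake_im <- function(iface) structure(list(interface = iface),
                                       class = "interface_model")
  mk_corr <- function(n1, k1, n2, k2) {
    pairs <- data.frame(
      uid_a = c(paste0("A:", 1:n1, ":"), paste0("B:", 1:n2, ":")),
      uid_b = c(paste0("A:", 1:n1, ":"), paste0("B:", 1:n2, ":")),
      aa_a = c(rep("A", n1), rep("G", n2)),
      aa_b = c(rep("A", k1), rep("V", n1 - k1), rep("G", k2),
               rep("L", n2 - k2)),
      chain_a = c(rep("A", n1), rep("B", n2)), chain_b = "x")
    structure(list(pairs = pairs), class = "correspondence_map")
  }
  # chains at 40% and 60% identity over 10 interface positions each
  corr <- mk_corr(10, 4, 10, 6)
  iface <- c(paste0("A:", 1:10, ":"), paste0("B:", 1:10, ":"))
  r <- min_interface_identity(fake_im(iface), fake_im(iface), corr)
  expect_equal(r$identity, 40)
  expect_identical(r$bin, "[30,50)")

  # 3 of 10 identical: 30% lands in the upper bin by the half-open rule
  r2 <- min_interface_identity(fake_im(iface), fake_im(iface),
                               mk_corr(10, 3, 10, 10))
  expect_equal(r2$identity, 30)
  expect_identical(r2$bin, "[30,50)")

  # identical complexes
  r3 <- min_interface_identity(fake_im(iface), fake_im(iface),
                               mk_corr(10, 10, 10, 10))
  expect_equal(r3$identity, 100)
  expect_identical(r3$bin, "[70,100]")

  # no mapped interface residues is an error
  expect_error(min_interface_identity(fake_im("Z:1:"), fake_im(iface), corr),
               "no mapped interface")
})

test_that("self-comparison is the fixed point of every statistic", {
  toy <- default_toy()
  im <- default_im()
  rep <- compare_interologs(im, im, map = identity_map(toy$structure))
  for (nm in c("atomic", "charged", "salt_bridges", "hbonds", "apolar")) {
    expect_equal(rep$conservation[[nm]]$ratio, 1,
                 info = nm, tolerance = 1e-12)
  }
  expect_equal(rep$conservation$patch_bundles$ratio, 1)
  expect_equal(rep$switching$fraction, 0)
  expect_equal(rep$identity$identity, 100)
})
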