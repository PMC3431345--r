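# Apolar patch detection, cross-interolog merging, bundles, random patches.

# minimal hand-built patch object for merging tests
mk_patch <- function(id, chain, residues) {
  list(id = id, chain = chain, atoms = paste0(residues, "/CB"),
       residues = sort(residues), n_atoms = length(residues),
       composition = c(core = length(residues), support = 0, rim = 0),
       provenance = id)
}

test_that("patch detection applies the 4-atom/2-residue and adjacency rules", {
  # 5 C atoms from 2 residues chained at 4 A: one patch
  x <- mini_structure(list(
    tip_res("A", 1, "LEU", c(CG = 2.0, CD1 = 3.0)),
    tip_res("A", 2, "VAL", c(CG1 = 2.0), x = 4),
    cb_res("B", 1, 0, 0, 60)))
  p <- detect_patches(x, interface = c("A:1:", "A:2:"))
  expect_equal(length(p$A), 1L)
  expect_setequal(p$A[[1]]$residues, c("A:1:", "A:2:"))
  expect_gte(p$A[[1]]$n_atoms, 4L)

  # 3 C atoms from 2 residues: below the size rule
  x2 <- mini_structure(list(
    tip_res("A", 1, "SER", c(OG = 2.0)),       # CB only
    tip_res("A", 2, "VAL", c(CG1 = 2.0), x = 4),
    cb_res("B", 1, 0, 0, 60)))
  p2 <- detect_patches(x2, interface = c("A:1:", "A:2:"))
  expect_equal(length(p2$A), 0L)
})

test_that("two distant clusters are two patches unless an atom bridges them", {
  far <- 10
  base <- list(
    tip_res("A", 1, "LEU", c(CG = 2.0, CD1 = 3.0)),
    tip_res("A", 2, "LEU", c(CG = 2.0, CD1 = 3.0), x = 3),
    tip_res("A", 3, "LEU", c(CG = 2.0, CD1 = 3.0), x = far),
    tip_res("A", 4, "LEU", c(CG = 2.0, CD1 = 3.0), x = far + 3),
    cb_res("B", 1, 0, 0, 60))
  x <- mini_structure(base)
  iface <- paste0("A:", 1:5, ":")
  p <- detect_patches(x, interface = iface)
  expect_equal(length(p$A), 2L)

  bridged <- append(base, list(tip_res("A", 5, "VAL", c(CG1 = 2.0),
                                       x = 6.5)), after = 4)
  x2 <- mini_structure(bridged)
  p2 <- detect_patches(x2, interface = paste0("A:", 1:6, ":"))
  expect_equal(length(p2$A), 1L)

  # connected components agree with a union-find oracle
  a <- x$atoms[x$atoms$is_apolar & x$atoms$chain == "A", ]
  comp <- oracle_components(as.matrix(a[, c("x", "y", "z")]), 4.5)
  expect_equal(length(unique(comp)), 2L)
})

test_that("toy-complex patches match the union-find oracle atom for atom", {
  im <- default_im()
  x <- im$structure
  sa <- x$atoms[x$atoms$is_apolar & x$atoms$res_uid %in% im$interface, ]
  msasa <- im$sasa_monomer$atoms
  key <- paste(sa$res_uid, sa$elety)
  sa <- sa[msasa$area[match(key, paste(msasa$res_uid, msasa$elety))] > 0, ]
  for (ch in x$chains) {
    a <- sa[sa$chain == ch, ]
    comp <- oracle_components(as.matrix(a[, c("x", "y", "z")]),
                              im$config$patch_adjacency_cutoff)
    keep <- table(comp)
    oracle_patches <- lapply(names(keep), function(cid) {
      sel <- comp == as.integer(cid)
      if (sum(sel) >= 4 && length(unique(a$res_uid[sel])) >= 2)
        sort(paste(a$res_uid[sel], a$elety[sel], sep = "/"))
    })
    oracle_patches <- Filter(Negate(is.null), oracle_patches)
    got <- lapply(im$patches[[ch]], function(p) sort(p$atoms))
    expect_setequal(got, oracle_patches)
  }
})

test_that("every emitted patch satisfies the size and membership rules", {
  im <- default_im()
  for (ch in names(im$patches)) for (p in im$patches[[ch]]) {
    expect_gte(p$n_atoms, 4L)
    expect_gte(length(p$residues), 2L)
    expect_true(all(p$residues %in% im$interface))
  }
})

test_that("cross-interolog patch merging reaches an injective fixpoint", {
  map <- stats::setNames(paste0("A:", 1:10, ":"), paste0("A:", 1:10, ":"))
  # one A patch overlapping two B patches: the B patches merge
  pa <- list(A = list(mk_patch("A-1", "A", paste0("A:", 1:4, ":"))))
  pb <- list(A = list(mk_patch("A-1", "A", paste0("A:", 1:2, ":")),
                      mk_patch("A-2", "A", paste0("A:", 3:4, ":"))))
  m <- merge_patches_across_interologs(pa, pb, map)
  expect_equal(length(m$b$A), 1L)
  expect_setequal(m$b$A[[1]]$residues, paste0("A:", 1:4, ":"))
  expect_equal(nrow(m$mapping), 1L)

  # disjoint patches stay unmapped and unmerged
  pb2 <- list(A = list(mk_patch("A-1", "A", paste0("A:", 7:9, ":"))))
  m2 <- merge_patches_across_interologs(pa, pb2, map)
  expect_equal(length(m2$a$A), 1L)
  expect_equal(length(m2$b$A), 1L)
  expect_true(any(is.na(m2$mapping$patch_a) | is.na(m2$mapping$patch_b)))

  # overlap chain a1-b1, a2-b1, a2-b2 collapses to one patch per side
  pa3 <- list(A = list(mk_patch("A-1", "A", paste0("A:", 1:2, ":")),
                       mk_patch("A-2", "A", paste0("A:", 3:5, ":"))))
  pb3 <- list(A = list(mk_patch("A-1", "A", paste0("A:", 2:3, ":")),
                       mk_patch("A-2", "A", paste0("A:", 5:6, ":"))))
  m3 <- merge_patches_across_interologs(pa3, pb3, map)
  expect_equal(length(m3$a$A), 1L)
  expect_equal(length(m3$b$A), 1L)
  # final mapping is 1:1 in both directions
  expect_false(any(duplicated(stats::na.omit(m3$mapping$patch_a))))
  expect_false(any(duplicated(stats::na.omit(m3$mapping$patch_b))))
})

test_that("patch bundles require an apolar contact and report participation", {
  patches <- list(A = list(mk_patch("A-1", "A", paste0("A:", 1:4, ":"))),
                  B = list(mk_patch("B-1", "B", paste0("B:", 1:4, ":"))))
  ap <- data.frame(uid_a = c("A:1:", "A:2:"), uid_b = c("B:1:", "B:1:"),
                   weight = c(2, 1))
  b <- patch_contact_bundles(patches, ap)
  expect_equal(nrow(b), 1L)
  expect_equal(b$weight, 3)
  expect_equal(b$participation_1, 0.5)   # 2 of 4 patch residues contact
  expect_equal(b$participation_2, 0.25)

  none <- patch_contact_bundles(patches, ap[0, ])
  expect_equal(nrow(none), 0L)
})

test_that("random patches are reproducible, connected, and size-matched", {
  im <- default_im()
  r1 <- random_patches(im, seed = 21)
  r2 <- random_patches(im, seed = 21)
  expect_identical(r1, r2)

  nb <- structural_neighbors(im$structure, 8, "monomer")
  for (ch in names(r1)) {
    real <- im$patches[[ch]]
    for (k in seq_along(r1[[ch]])) {
      rp <- r1[[ch]][[k]]
      expect_gte(rp$n_atoms, real[[k]]$n_atoms)
      # connectivity over the residue-adjacency graph (union-find oracle)
      uids <- rp$residues
      if (length(uids) > 1) {
        res <- residue_table(im$structure)
        xyz <- as.matrix(res[match(uids, res$res_uid), c("rx", "ry", "rz")])
        comp <- oracle_components(xyz, 8)
        expect_equal(length(unique(comp)), 1L)
      }
      # members are interface residues of the right chain
      expect_true(all(uids %in% im$interface))
      expect_true(all(sub(":.*", "", uids) == ch))
    }
  }
})
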