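# Typed inter-chain contact detection.

test_that("atomic contacts respect the distance cutoff", {
  x <- mini_structure(list(cb_res("A", 1, 0, 0, 0), cb_res("B", 1, 0, 0, 4.9)))
  ac <- atomic_contacts(x)
  expect_true(any(ac$elety_a == "CB" & ac$elety_b == "CB"))

  x2 <- mini_structure(list(ca_res("A", 1, 0), ca_res("B", 1, 5.1)))
  expect_equal(nrow(atomic_contacts(x2)), 0L)
})

test_that("contacts equal an all-pairs brute-force oracle on a random fixture", {
  set.seed(5)
  res <- list()
  for (k in 1:40)
    res[[k]] <- ca_res("A", k, runif(1, 0, 25), runif(1, 0, 25),
                       runif(1, 0, 6))
  for (k in 1:40)
    res[[40 + k]] <- ca_res("B", k, runif(1, 0, 25), runif(1, 0, 25),
                            runif(1, 5, 11))
  x <- mini_structure(res)
  got <- atomic_contacts(x)
  ref <- oracle_contacts(x, 5.0)
  key <- function(d) sort(paste(d$uid_a, d$elety_a, d$uid_b, d$elety_b))
  expect_identical(key(got), key(ref))

  # residue graph conserves total contact mass
  g <- residue_contact_graph(got)
  expect_equal(sum(g$weight), nrow(got))
})

test_that("residue contact graph groups atomic contacts per residue pair", {
  ac <- data.frame(uid_a = c("A:1:", "A:1:", "A:1:"), uid_b = rep("B:2:", 3))
  g <- residue_contact_graph(ac)
  expect_equal(nrow(g), 1L)
  expect_equal(g$weight, 3)
  expect_equal(nrow(residue_contact_graph(ac[0, ])), 0L)
})

test_that("charged contacts and salt bridges follow residue/atom typing", {
  # Lys NZ 3.4 A from Glu OE1: salt bridge and charged contact
  x <- mini_structure(list(
    tip_res("A", 1, "LYS", c(NZ = 3.0)),
    tip_res("B", 1, "GLU", c(OE1 = 1.6), base_z = 8.0, dirn = -1)))
  expect_equal(nrow(salt_bridges(x)), 1L)       # NZ at 3.0, OE1 at 6.4
  expect_equal(nrow(charged_contacts(x)), 1L)
  expect_identical(charged_contacts(x)$sign_a, "+")

  # 4.8 A apart: charged at 5.5 but not a salt bridge
  x2 <- mini_structure(list(
    tip_res("A", 1, "LYS", c(NZ = 3.0)),
    tip_res("B", 1, "ASP", c(OD2 = 1.6), base_z = 9.4, dirn = -1)))
  expect_equal(nrow(salt_bridges(x2)), 0L)
  expect_equal(nrow(charged_contacts(x2)), 1L)

  # Ser OG near Asp OD1: not a charged contact (Ser is not charged)
  x3 <- mini_structure(list(
    tip_res("A", 1, "SER", c(OG = 3.0)),
    tip_res("B", 1, "ASP", c(OD1 = 1.6), base_z = 7.6, dirn = -1)))
  expect_equal(nrow(charged_contacts(x3)), 0L)
})

test_that("salt bridges are nested within charged contacts", {
  x <- default_toy()$structure
  sb <- salt_bridges(x)
  ch <- charged_contacts(x)
  expect_true(all(paste(sb$uid_a, sb$uid_b) %in% paste(ch$uid_a, ch$uid_b)))
  expect_error(contact_config(salt_bridge_cutoff = 6, charged_cutoff = 5.5),
               "must not exceed")
})

test_that("hydrogen bonds use distance, angle, and the backbone-backbone rule", {
  # Ser OG donor 3.0 A from a backbone O, antecedent angle ~180: a bond
  x <- mini_structure(list(
    tip_res("A", 1, "SER", c(OG = 3.0)),
    list(chain = "B", resno = 1, resid = "GLY",
         atoms = data.frame(elety = c("N", "CA", "C", "O"),
                            x = c(-1.4, 0, 1.4, 0), y = 0,
                            z = c(7, 7, 7, 6)))))
  hb <- hydrogen_bonds(x)
  expect_equal(nrow(hb), 1L)

  # backbone N to backbone O at 2.9 A: excluded
  x2 <- mini_structure(list(
    list(chain = "A", resno = 1, resid = "GLY",
         atoms = data.frame(elety = c("N", "CA", "C", "O"),
                            x = c(0, 1.4, 2.8, 2.8), y = 0, z = c(0, 0, 0, 1))),
    list(chain = "B", resno = 1, resid = "GLY",
         atoms = data.frame(elety = c("N", "CA", "C", "O"),
                            x = c(0, 1.4, 2.8, 2.8), y = 0,
                            z = c(2.9, 4, 4, 5)))))
  expect_equal(nrow(hydrogen_bonds(x2)), 0L)

  # D-A distance fine but antecedent angle acute: rejected
  x3 <- mini_structure(list(
    list(chain = "A", resno = 1, resid = "SER",
         atoms = data.frame(elety = c("N", "CA", "C", "O", "CB", "OG"),
                            x = c(-1.4, 0, 1.4, 1.9, 0, 1.5),
                            y = 0, z = c(0, 0, 0, 1, 1.5, 4.1))),
    list(chain = "B", resno = 1, resid = "GLY",
         atoms = data.frame(elety = c("N", "CA", "C", "O"),
                            x = c(-1.4, 0, 1.4, -1.0), y = 0,
                            z = c(7.5, 7.5, 7.5, 2.0)))))
  # the acceptor O sits back toward the donor's antecedent: CB-OG-O is acute
  ang <- {
    v1 <- c(0, 0, 1.5) - c(1.5, 0, 4.1)
    v2 <- c(-1.0, 0, 2.0) - c(1.5, 0, 4.1)
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  }
  expect_lt(ang, 90)
  expect_lt(sqrt(sum((c(-1, 0, 2) - c(1.5, 0, 4.1))^2)), 3.5)
  expect_equal(nrow(hydrogen_bonds(x3)), 0L)
})

test_that("apolar contacts use side-chain C/S surface atoms of any residue", {
  # Leu CD1 4.2 A from Ile CG2
  x <- mini_structure(list(
    tip_res("A", 1, "LEU", c(CG = 2.0, CD1 = 3.0)),
    tip_res("B", 1, "ILE", c(CG1 = 2.0, CG2 = 3.0), base_z = 10.2, dirn = -1)))
  ap <- apolar_contacts(x, interface = c("A:1:", "B:1:"))
  expect_equal(nrow(ap), 1L)

  # Lys side-chain carbon counts despite the charged residue type
  x2 <- mini_structure(list(
    tip_res("A", 1, "LYS", c(CG = 2.0, CD = 3.0)),
    tip_res("B", 1, "VAL", c(CG1 = 3.0), base_z = 10.0, dirn = -1)))
  ap2 <- apolar_contacts(x2, interface = c("A:1:", "B:1:"))
  expect_gte(nrow(ap2), 1L)

  # atoms with zero monomer SASA are excluded
  fake_sasa <- compute_sasa(x, "monomer")
  fake_sasa$atoms$area[] <- 0
  ap3 <- apolar_contacts(x, interface = c("A:1:", "B:1:"),
                         sasa_monomer = fake_sasa)
  expect_equal(nrow(ap3), 0L)

  # non-interface residues are excluded
  ap4 <- apolar_contacts(x, interface = character())
  expect_equal(nrow(ap4), 0L)
})

test_that("contact sets are invariant under chain order", {
  x <- default_toy()$structure
  xr <- as_complex_structure(x$atoms[, c("elety", "resid", "chain", "resno",
                                         "insert", "x", "y", "z", "o",
                                         "element")],
                             chains = rev(x$chains), id = x$id)
  key <- function(d) sort(paste(pmin(d$uid_a, d$uid_b),
                                pmax(d$uid_a, d$uid_b)))
  expect_identical(key(atomic_contacts(x)), key(atomic_contacts(xr)))
  expect_identical(key(salt_bridges(x)), key(salt_bridges(xr)))
  expect_identical(key(hydrogen_bonds(x)), key(hydrogen_bonds(xr)))
})
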