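# Shared fixtures and independent oracles for the test suite.

# ---- cached default toy complex (built once per test run) -------------------
.fixture_env <- new.env()

default_toy <- function() {
  if (is.null(.fixture_env$toy))
    .fixture_env$toy <- build_toy_complex(toy_spec())
  .fixture_env$toy
}

default_im <- function() {
  if (is.null(.fixture_env$im))
    .fixture_env$im <- interface_model(default_toy()$structure)
  .fixture_env$im
}

identity_map <- function(x) {
  uids <- residue_table(x)$res_uid
  stats::setNames(uids, uids)
}

# ---- minimal structure builders ---------------------------------------------

# Build a complex_structure from a compact residue description:
# list(list(chain=, resno=, resid=, atoms=data.frame(elety,x,y,z)), ...)
mini_structure <- function(residues, chains = c("A", "B"), id = "mini") {
  rows <- lapply(residues, function(r) {
    a <- r$atoms
    a$resid <- r$resid; a$chain <- r$chain; a$resno <- r$resno
    a
  })
  as_complex_structure(do.call(rbind, rows), chains = chains, id = id)
}

# One residue with a lone CA reference atom.
ca_res <- function(chain, resno, x, y = 0, z = 0, resid = "GLY") {
  list(chain = chain, resno = resno, resid = resid,
       atoms = data.frame(elety = "CA", x = x, y = y, z = z))
}

# One residue with CA + CB (CB at the given coordinates).
cb_res <- function(chain, resno, cbx, cby = 0, cbz = 0, resid = "ALA") {
  list(chain = chain, resno = resno, resid = resid,
       atoms = data.frame(elety = c("CA", "CB"),
                          x = c(cbx, cbx), y = c(cby, cby),
                          z = c(cbz - 1.5, cbz)))
}

# Two facing single-residue chains with arbitrary side-chain atoms; `tips`
# is a named numeric: atom name -> z of the tip atom on its chain's axis.
tip_res <- function(chain, resno, resid, tips, x = 0, y = 0, base_z = 0,
                    dirn = 1) {
  elety <- c("N", "CA", "C", "O", "CB", names(tips))
  zs <- c(base_z, base_z, base_z, base_z + 1, base_z + dirn * 1.5,
          base_z + dirn * unname(tips))
  xs <- c(x - 1.4, x, x + 1.4, x + 1.9, rep(x, 1 + length(tips)))
  list(chain = chain, resno = resno, resid = resid,
       atoms = data.frame(elety = elety, x = xs, y = y, z = zs))
}

# ---- independent oracles -----------------------------------------------------

# Brute-force O(n^2) inter-chain atomic contact oracle.
oracle_contacts <- function(x, cutoff) {
  a <- x$atoms[!x$atoms$is_hydrogen & !x$atoms$is_water, ]
  a1 <- a[a$chain == x$chains[1], ]; a2 <- a[a$chain == x$chains[2], ]
  out <- list()
  for (i in seq_len(nrow(a1))) for (j in seq_len(nrow(a2))) {
    d <- sqrt((a1$x[i] - a2$x[j])^2 + (a1$y[i] - a2$y[j])^2 +
                (a1$z[i] - a2$z[j])^2)
    if (d <= cutoff)
      out[[length(out) + 1]] <- data.frame(
        uid_a = a1$res_uid[i], uid_b = a2$res_uid[j],
        elety_a = a1$elety[i], elety_b = a2$elety[j], distance = d)
  }
  if (length(out) == 0) return(data.frame())
  do.call(rbind, out)
}

# Union-find connected components over points with a distance cutoff.
oracle_components <- function(xyz, cutoff) {
  n <- nrow(xyz)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Monte-Carlo SASA oracle for a set of spheres (random surface points).
oracle_sasa_mc <- function(xyz, radii, probe = 1.4, n_mc = 20000, seed = 99) {
  set.seed(seed)
  r <- radii + probe
  vapply(seq_len(nrow(xyz)), function(k) {
    z <- stats::runif(n_mc, -1, 1)
    phi <- stats::runif(n_mc, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    p <- cbind(s * cos(phi), s * sin(phi), z) * r[k]
    p <- sweep(p, 2, xyz[k, ], "+")
    free <- rep(TRUE, n_mc)
    for (j in seq_len(nrow(xyz))[-k]) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & d2 >= r[j]^2
    }
    4 * pi * r[k]^2 * mean(free)
  }, numeric(1))
}

# Affine-gap Needleman-Wunsch (Gotoh) oracle returning aligned index pairs.
oracle_nw <- function(s1, s2, gap_open = 11, gap_ext = 1) {
  B <- ppievol::blosum62()
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -gap_open - (i - 2) * gap_ext
  for (j in 2:(m + 1)) Iy[1, j] <- -gap_open - (j - 2) * gap_ext
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- B[a[i - 1], b[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
    Ix[i, j] <- max(M[i - 1, j] - gap_open, Ix[i - 1, j] - gap_ext)
    Iy[i, j] <- max(M[i, j - 1] - gap_open, Iy[i, j - 1] - gap_ext)
  }
  # traceback
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], Ix[i, j], Iy[i, j]))
  pairs <- list()
  while (i > 1 || j > 1) {
    if (state == 1) {
      pairs[[length(pairs) + 1]] <- c(i - 1, j - 1)
      s <- B[a[i - 1], b[j - 1]]
      prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      if (abs(Ix[i, j] - (M[i - 1, j] - gap_open)) < 1e-9) state <- 1
      i <- i - 1
    } else {
      if (abs(Iy[i, j] - (M[i, j - 1] - gap_open)) < 1e-9) state <- 1
      j <- j - 1
    }
  }
  do.call(rbind, rev(pairs))
}

# Build a two-chain structure whose chains carry given sequences (CA-only
# lattice geometry; used for alignment tests where coordinates are irrelevant).
seq_structure <- function(seq1, seq2, id = "seqs") {
  aa3 <- stats::setNames(
    c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
      "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL"),
    c("A","R","N","D","C","Q","E","G","H","I",
      "L","K","M","F","P","S","T","W","Y","V"))
  res <- list()
  for (k in seq_along(strsplit(seq1, "")[[1]]))
    res[[length(res) + 1]] <- ca_res("A", k, x = 3.8 * k,
                                     resid = aa3[substr(seq1, k, k)])
  for (k in seq_along(strsplit(seq2, "")[[1]]))
    res[[length(res) + 1]] <- ca_res("B", k, x = 3.8 * k, y = 100,
                                     resid = aa3[substr(seq2, k, k)])
  mini_structure(res, id = id)
}
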