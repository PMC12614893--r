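random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
}

test_that("PDB writing and reading round-trips the toy dimer", {
  toy <- synth_dimer(toy_dimer_spec("open", "closed"))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(toy$model, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atoms), nrow(toy$model$atoms))
  ord <- function(a) a[order(a$chain, a$resno, a$atom), c("x", "y", "z")]
  expect_equal(unname(as.matrix(ord(back$atoms))),
               unname(as.matrix(ord(toy$model$atoms))), tolerance = 1e-3)
  expect_setequal(unique(back$atoms$chain), c("A", "B"))
})

test_that("altloc and water policy is applied deterministically", {
  atoms <- data.frame(
    chain = "A", resno = c(1, 1, 1, 2), resid = c("ALA", "ALA", "ALA", "HOH"),
    atom = c("CA", "CB", "CB", "O"),
    x = 1:4, y = 1:4, z = 1:4,
    altloc = c("", "A", "B", ""), stringsAsFactors = FALSE)
  m <- structure_model(atoms)
  expect_equal(nrow(m$atoms), 2)              # altloc B dropped, water dropped
  expect_true(all(m$atoms$altloc %in% c("", "A")))
  m2 <- structure_model(atoms, keep_waters = TRUE)
  expect_equal(nrow(m2$atoms), 3)
})

test_that("Kabsch superposition is exact, symmetric, and matches the quaternion oracle", {
  toy <- synth_dimer(toy_dimer_spec("open", "open"))$model

  self <- superpose(toy, toy)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)

  # a rigidly moved copy superposes back exactly
  set.seed(4)
  R <- random_rotation()
  moved <- toy
  xyz <- as.matrix(moved$atoms[, c("x", "y", "z")])
  moved$atoms[, c("x", "y", "z")] <- xyz %*% t(R) +
    matrix(c(5, -3, 11), nrow(xyz), 3, byrow = TRUE)
  fit <- superpose(moved, toy)
  expect_lt(fit$rmsd, 1e-9)

  # symmetry of the RMSD under swapping mobile and reference
  noisy <- toy
  noisy$atoms$x <- noisy$atoms$x + rnorm(nrow(noisy$atoms), sd = 0.3)
  f1 <- superpose(noisy, toy); f2 <- superpose(toy, noisy)
  expect_equal(f1$rmsd, f2$rmsd, tolerance = 1e-9)

  # independent quaternion oracle on random point sets
  for (i in 1:50) {
    X <- matrix(rnorm(30), 10, 3)
    Y <- X %*% t(random_rotation()) +
      matrix(rnorm(3), 10, 3, byrow = TRUE) + matrix(rnorm(30, sd = 0.2), 10, 3)
    expect_equal(deerens:::kabsch_rmsd(X, Y), quaternion_rmsd(X, Y),
                 tolerance = 1e-9)
  }

  degenerate <- structure_model(data.frame(
    chain = "A", resno = 1:4, resid = "GLY", atom = "CA",
    x = 1:4, y = 2 * (1:4), z = 3 * (1:4), stringsAsFactors = FALSE))
  expect_error(superpose(degenerate, degenerate), "collinear")
})

test_that("per-C-alpha RMSD compares chains after superposition", {
  toy <- synth_dimer(toy_dimer_spec("open", "open"))$model
  a <- extract_chain(toy, "A")
  expect_equal(rmsd_per_ca(a, a, min_shared = 20)$rmsd, 0, tolerance = 1e-9)

  b <- a
  b$atoms$x <- b$atoms$x + rnorm(nrow(b$atoms), sd = 0.5)
  r <- rmsd_per_ca(a, b, min_shared = 20)
  expect_gt(r$rmsd, 0)
  expect_gte(r$n_paired, 20)
  expect_error(rmsd_per_ca(a, b, min_shared = 100), "shared")
})

test_that("hybrid assembly is exact for an identity spec and interpolates states", {
  open_d <- synth_dimer(toy_dimer_spec("open", "open"))
  closed_d <- synth_dimer(toy_dimer_spec("closed", "closed"))

  # hybrid of a structure's own two chains reproduces that structure
  idem <- build_hybrid(
    hybrid_spec(chain_a = list(structure = "x", chain = "A"),
                chain_b = list(structure = "x", chain = "B"),
                reference = "x"),
    sources = list(x = open_d$model))
  ord <- function(a) a[order(a$chain, a$resno, a$atom), c("x", "y", "z")]
  expect_equal(unname(as.matrix(ord(idem$atoms))),
               unname(as.matrix(ord(open_d$model$atoms))), tolerance = 1e-6)

  hy <- build_hybrid(
    hybrid_spec(chain_a = list(structure = "closed", chain = "A"),
                chain_b = list(structure = "open", chain = "B"),
                reference = "open"),
    sources = list(open = open_d$model, closed = closed_d$model))
  expect_setequal(unique(hy$atoms$chain), c("A", "B"))

  sep <- function(m, resno) {
    cb <- m$atoms[m$atoms$resno == resno & m$atoms$atom == "CB", ]
    sqrt(sum((cb[cb$chain == "A", c("x", "y", "z")] -
                cb[cb$chain == "B", c("x", "y", "z")])^2)) / 10
  }
  for (resno in c(25, 26)) {
    lo <- min(sep(open_d$model, resno), sep(closed_d$model, resno))
    hi <- max(sep(open_d$model, resno), sep(closed_d$model, resno))
    s <- sep(hy, resno)
    expect_gt(s, lo); expect_lt(s, hi)
  }

  expect_error(build_hybrid(
    hybrid_spec(chain_a = list(structure = "closed", chain = "Q"),
                chain_b = list(structure = "open", chain = "B"),
                reference = "open"),
    sources = list(open = open_d$model, closed = closed_d$model)),
    "chain 'Q'")
})
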