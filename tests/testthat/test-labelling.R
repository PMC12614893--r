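single_residue_model <- function() {
  structure_model(data.frame(
    chain = "A", resno = 1, resid = "CYS",
    atom = c("N", "CA", "CB", "C"),
    x = c(1.2, 0, 0, -1.2), y = c(-0.8, 0, 1.53, -0.8),
    z = c(0, 0, 0, 0.4), stringsAsFactors = FALSE))
}

test_that("rotamer clouds are reproducible and respect steric clashes", {
  # isolated residue: nothing to clash with, full retention
  iso <- single_residue_model()
  cl <- label_site(iso, "A", 1, seed = 3)
  expect_equal(cl$n_retained, cl$n_sampled)
  expect_equal(sum(cl$weights), 1, tolerance = 1e-9)
  expect_true(all(cl$weights >= 0))

  # identical seed, identical cloud; different seed, different cloud
  expect_identical(label_site(iso, "A", 1, seed = 3), cl)
  expect_false(identical(label_site(iso, "A", 1, seed = 4)$points, cl$points))

  # a residue fully enclosed in a double-shelled cage retains nothing
  set.seed(1)
  shell <- function(radius, n) {
    cz <- runif(n, -1, 1); ph <- runif(n, -pi, pi)
    data.frame(chain = "B", resno = seq_len(n) + 1000L * radius,
               resid = "CAG", atom = "C1",
               x = radius * sqrt(1 - cz^2) * cos(ph),
               y = radius * sqrt(1 - cz^2) * sin(ph),
               z = radius * cz, stringsAsFactors = FALSE)
  }
  cage <- rbind(shell(3.5, 300), shell(5.0, 300))
  caged <- structure_model(rbind(iso$atoms[, names(cage)], cage))
  expect_error(label_site(caged, "A", 1, seed = 1), "loose")

  # retention is monotone non-increasing in the clash cutoff (zero retained
  # counts as zero, not as an error, for the comparison)
  toy <- synth_dimer(toy_dimer_spec("open", "open"))$model
  ret <- vapply(c(1.5, 2.5, 3.5), function(cut)
    tryCatch(label_site(toy, "A", 27, seed = 1, n_sampled = 500,
                        clash_cutoff = cut)$n_retained,
             error = function(e) 0L), numeric(1))
  expect_true(all(diff(ret) <= 0))
  expect_gt(ret[1], 0)

  # surface sites retain strictly more rotamers than the caged site
  surf <- label_site(toy, "A", 25, seed = 1, n_sampled = 500)
  bur <- label_site(toy, "A", 27, seed = 1, n_sampled = 500)
  expect_gt(surf$n_retained, bur$n_retained)

  # loose mode retains at least as many conformers as tight
  expect_gte(label_site(toy, "A", 27, seed = 1, n_sampled = 500,
                        mode = "loose")$n_retained, bur$n_retained)

  expect_error(label_site(toy, "A", 999), "absent")
})

test_that("CB is built from backbone geometry when missing", {
  gly <- structure_model(data.frame(
    chain = "A", resno = 1, resid = "GLY", atom = c("N", "CA", "C"),
    x = c(1.46, 0, -0.55), y = c(0, 0, 1.4), z = c(0, 0, 0),
    stringsAsFactors = FALSE))
  cl <- label_site(gly, "A", 1, seed = 1, n_sampled = 200)
  expect_equal(cl$n_retained, 200)
  # reporter points sit within the physical reach of the label arm
  d <- sqrt(rowSums(cl$points^2))
  expect_true(all(d < 12))
})

test_that("predicted distributions are symmetric and correctly located", {
  # two single-point clouds 4.0 nm apart concentrate at 4.0 nm
  mk_point <- function(x) structure(list(
    site = list(chain = "A", resno = 1),
    points = matrix(c(x, 0, 0), 1, 3), weights = 1,
    n_sampled = 1, n_retained = 1), class = "rotamer_cloud")
  a <- mk_point(0); b <- mk_point(40)
  d <- predict_distribution(a, b, smooth_sd = 0.001)
  expect_equal(distribution_stats(d)$modal, 4.0, tolerance = 0.011)

  # swapping the clouds changes nothing
  toy <- synth_dimer(toy_dimer_spec("open", "open"))$model
  ca <- label_site(toy, "A", 26, seed = 1, n_sampled = 400)
  cb <- label_site(toy, "B", 26, seed = 2, n_sampled = 400)
  expect_equal(predict_distribution(ca, cb)$p, predict_distribution(cb, ca)$p)

  # the distribution honours the container invariants
  pd <- predict_distribution(ca, cb)
  dr <- pd$r[2] - pd$r[1]
  expect_true(all(pd$p >= 0))
  expect_equal(sum(pd$p) * dr, 1, tolerance = 1e-9)

  # pairs falling outside the grid are an error
  expect_error(predict_distribution(mk_point(0), mk_point(900)), "outside")
})

test_that("cloud export writes one model per reporter point", {
  iso <- single_residue_model()
  cl <- label_site(iso, "A", 1, seed = 1, n_sampled = 25)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_cloud_pdb(cl, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^MODEL", lines)), cl$n_retained)
  expect_equal(sum(grepl("^HETATM", lines)), cl$n_retained)
})
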