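# Place an atom from three reference atoms by internal coordinates
# (bond length Angstrom, bond angle and dihedral in radians): the standard
# natural-extension reference frame construction.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma::cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma::cross(n, bc)
  d <- c(-bond * cos(angle),
         bond * sin(angle) * cos(dihedral),
         bond * sin(angle) * sin(dihedral))
  as.vector(c + cbind(bc, m, n) %*% d)
}

# idealised CB from backbone N/CA/C (tetrahedral geometry, 1.53 Angstrom)
build_cb <- function(N, CA, C) {
  u <- N - CA; u <- u / sqrt(sum(u^2))
  v <- C - CA; v <- v / sqrt(sum(v^2))
  bis <- u + v; bis <- bis / sqrt(sum(bis^2))
  perp <- pracma::cross(u, v); perp <- perp / sqrt(sum(perp^2))
  CA + 1.53 * (-0.5774 * bis + 0.8165 * perp)
}

# internal geometry of the reduced R1 side chain: five rotatable bonds
# (chi1-chi5) carrying SG, SD, CE (methylene), C3 (ring attachment), and the
# nitroxide N1/O1 whose midpoint is the reporter point
R1_GEOMETRY <- list(
  SG = list(bond = 1.81, angle = 114),
  SD = list(bond = 2.04, angle = 104),
  CE = list(bond = 1.81, angle = 104),
  C3 = list(bond = 1.51, angle = 114),
  N1 = list(bond = 2.33, angle = 122),   # C3...N1 across the pyrroline ring
  O1 = list(bond = 1.29, angle = 140))   # N-O bond, fixed in the ring plane

build_rotamer <- function(N, CA, CB, chi) {
  deg <- pi / 180
  g <- R1_GEOMETRY
  SG <- place_atom(N, CA, CB, g$SG$bond, g$SG$angle * deg, chi[1])
  SD <- place_atom(CA, CB, SG, g$SD$bond, g$SD$angle * deg, chi[2])
  CE <- place_atom(CB, SG, SD, g$CE$bond, g$CE$angle * deg, chi[3])
  C3 <- place_atom(SG, SD, CE, g$C3$bond, g$C3$angle * deg, chi[4])
  N1 <- place_atom(SD, CE, C3, g$N1$bond, g$N1$angle * deg, chi[5])
  O1 <- place_atom(CE, C3, N1, g$O1$bond, g$O1$angle * deg, pi)
  rbind(SG = as.vector(SG), SD = as.vector(SD), CE = as.vector(CE),
        C3 = as.vector(C3), N1 = as.vector(N1), O1 = as.vector(O1))
}

#' Accessible-volume rotamer cloud of an R1 spin label
#'
#' Attaches a reduced-representation methanethiosulphonate (R1) side chain
#' at a site and samples its five side-chain dihedrals uniformly at random
#' from an idealised internal geometry. A conformer is retained if its heavy
#' atoms make no steric clash with the structure; in `"tight"` mode zero
#' contacts below the cutoff are allowed, in `"loose"` mode up to
#' `max_clashes`. The labelled residue itself (and any of its native
#' side-chain atoms) is excluded from the clash environment. The reporter
#' point of each retained conformer is the midpoint of the nitroxide N-O
#' bond; weights are uniform.
#'
#' @param model A `structure_model`.
#' @param chain Chain id of the site.
#' @param resno Residue number of the site; must have backbone N and CA (CB
#'   is built from backbone geometry when absent).
#' @param mode `"tight"` (zero clashes) or `"loose"` (up to `max_clashes`).
#' @param seed Integer seed; clouds are fully reproducible.
#' @param n_sampled Number of dihedral draws.
#' @param clash_cutoff Heavy-atom contact distance (Angstrom).
#' @param max_clashes Contacts tolerated per conformer in loose mode.
#' @return An object of class `rotamer_cloud`: `site`, `points` (n x 3
#'   matrix of reporter coordinates, Angstrom), `weights`, `n_sampled`,
#'   `n_retained`.
#' @export
label_site <- function(model, chain, resno, mode = c("tight", "loose"),
                       seed = 1L, n_sampled = 2000, clash_cutoff = 2.5,
                       max_clashes = 5L) {
  stopifnot(inherits(model, "structure_model"))
  mode <- match.arg(mode)
  allowed <- if (mode == "tight") 0L else as.integer(max_clashes)
  res <- model$atoms[model$atoms$chain == chain &
                       model$atoms$resno == resno & !model$atoms$hetatm, ]
  if (nrow(res) == 0)
    stop(sprintf("residue %s:%d absent from %s", chain, resno, model$id))
  gx <- function(name) {
    row <- res[res$atom == name, , drop = FALSE]
    if (nrow(row) == 0) return(NULL)
    as.numeric(row[1, c("x", "y", "z")])
  }
  N <- gx("N"); CA <- gx("CA"); CB <- gx("CB")
  if (is.null(N) || is.null(CA))
    stop(sprintf("residue %s:%d lacks backbone N/CA", chain, resno))
  if (is.null(CB)) {
    C <- gx("C")
    if (is.null(C))
      stop(sprintf("residue %s:%d lacks CB and C; cannot build CB",
                   chain, resno))
    CB <- build_cb(N, CA, C)
  }
  # clash environment: heavy atoms of everything except the labelled residue
  env <- model$atoms[!(model$atoms$chain == chain &
                         model$atoms$resno == resno &
                         !model$atoms$hetatm), , drop = FALSE]
  env <- env[!(toupper(env$element) %in% c("H", "D")), , drop = FALSE]
  # prefilter to the label's reach around CB
  reach <- 9 + clash_cutoff
  if (nrow(env) > 0) {
    d2 <- (env$x - CB[1])^2 + (env$y - CB[2])^2 + (env$z - CB[3])^2
    env <- env[d2 <= reach^2, , drop = FALSE]
  }
  E <- as.matrix(env[, c("x", "y", "z"), drop = FALSE])

  set.seed(as.integer(seed))
  chis <- matrix(stats::runif(5 * n_sampled, -pi, pi), ncol = 5)
  pts <- matrix(NA_real_, n_sampled, 3)
  keep <- logical(n_sampled)
  cut2 <- clash_cutoff^2
  for (i in seq_len(n_sampled)) {
    at <- build_rotamer(N, CA, CB, chis[i, ])
    if (nrow(E) > 0) {
      n_clash <- 0L
      for (j in seq_len(nrow(at))) {
        n_clash <- n_clash + sum((E[, 1] - at[j, 1])^2 +
                                   (E[, 2] - at[j, 2])^2 +
                                   (E[, 3] - at[j, 3])^2 < cut2)
        if (n_clash > allowed) break
      }
      if (n_clash > allowed) next
    }
    keep[i] <- TRUE
    pts[i, ] <- (at["N1", ] + at["O1", ]) / 2
  }
  n_ret <- sum(keep)
  if (n_ret == 0L)
    stop(sprintf(
      "no rotamers retained at %s:%d in '%s' mode; try mode = 'loose' (clash tolerance > 0)",
      chain, resno, mode))
  structure(list(site = list(chain = chain, resno = resno),
                 points = pts[keep, , drop = FALSE],
                 weights = rep(1 / n_ret, n_ret),
                 n_sampled = n_sampled, n_retained = n_ret),
            class = "rotamer_cloud")
}

#' @export
print.rotamer_cloud <- function(x, ...) {
  cat(sprintf(
    "<rotamer_cloud> site %s:%d, %d/%d rotamers retained (%.0f%%)\n",
    x$site$chain, x$site$resno, x$n_retained, x$n_sampled,
    100 * x$n_retained / x$n_sampled))
  invisible(x)
}

#' Predicted inter-label distance distribution
#'
#' Weighted histogram of all pairwise reporter-point distances between two
#' rotamer clouds, convolved with a Gaussian of width `smooth_sd` and
#' normalised on the distance grid.
#'
#' @param cloud_a,cloud_b [label_site()] results.
#' @param r_grid Distance grid (nm).
#' @param smooth_sd Gaussian smoothing width (nm).
#' @return A [distance_distribution()].
#' @export
predict_distribution <- function(cloud_a, cloud_b,
                                 r_grid = default_r_grid(),
                                 smooth_sd = 0.05) {
  stopifnot(inherits(cloud_a, "rotamer_cloud"),
            inherits(cloud_b, "rotamer_cloud"))
  A <- cloud_a$points; B <- cloud_b$points
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d_nm <- sqrt(pmax(d2, 0)) / 10
  w <- outer(cloud_a$weights, cloud_b$weights)
  dr <- r_grid[2] - r_grid[1]
  lo <- r_grid[1] - dr / 2
  inside <- d_nm >= lo & d_nm < max(r_grid) + dr / 2
  if (!any(inside))
    stop("all pairwise label distances fall outside the distance grid")
  bin <- pmin(pmax(floor((d_nm[inside] - lo) / dr) + 1L, 1L),
              length(r_grid))
  h <- numeric(length(r_grid))
  agg <- tapply(w[inside], bin, sum)
  h[as.integer(names(agg))] <- agg
  if (smooth_sd > 0) {
    half <- max(1L, ceiling(5 * smooth_sd / dr))
    kern <- stats::dnorm(seq(-half, half) * dr, sd = smooth_sd)
    kern <- kern / sum(kern)
    padded <- c(numeric(half), h, numeric(half))
    h <- vapply(seq_along(h), function(i)
      sum(padded[i:(i + 2 * half)] * kern), numeric(1))
  }
  distance_distribution(r_grid, h / dr)
}

#' Export a rotamer cloud as a multi-model PDB of reporter points
#'
#' @param cloud A `rotamer_cloud`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cloud_pdb <- function(cloud, path) {
  stopifnot(inherits(cloud, "rotamer_cloud"))
  lines <- character(0)
  for (i in seq_len(nrow(cloud$points))) {
    lines <- c(lines,
               sprintf("MODEL     %4d", i),
               sprintf(
                 "HETATM%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           N",
                 1L, " NO", "R1X", substr(cloud$site$chain, 1, 1),
                 cloud$site$resno %% 10000,
                 cloud$points[i, 1], cloud$points[i, 2], cloud$points[i, 3],
                 cloud$weights[i] * nrow(cloud$points), 0),
               "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
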