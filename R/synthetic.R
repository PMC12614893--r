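#' Specification of one synthetic measurement condition
#'
#' Bundles everything needed to simulate a condition of the study design:
#' the ground-truth distance distribution (Gaussian mixture), acquisition
#' settings, background parameters, noise level and seed.
#'
#' @param label Condition tag (e.g. `"S525_apo"`); must be unique within a
#'   study table.
#' @param site Labelling-site family, `"S525"` (periplasmic-like) or
#'   `"C599"` (cytoplasmic-like).
#' @param components Data frame with `modal` (nm), `sigma` (nm), `weight`.
#' @param acq [acquisition_params()].
#' @param t_cut Truncation time applied during processing (ns), or `NA`.
#' @param noise_sd Additive white-noise SD as a fraction of V(0).
#' @param background [background_fit()] parameters used for simulation.
#' @param seed Integer seed for the noise realisation.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(label, site, components,
                           acq = acquisition_params(),
                           t_cut = NA_real_, noise_sd = 0.01,
                           background = background_fit(dim = 3, k = 5e-5,
                                                       lambda_mod = 0.30),
                           seed = 1L) {
  components <- as.data.frame(components)
  if (abs(sum(components$weight) - 1) > 1e-8)
    stop("component weights must sum to 1")
  structure(list(label = label, site = site, components = components,
                 acq = acq, t_cut = t_cut, noise_sd = noise_sd,
                 background = background, seed = as.integer(seed)),
            class = "condition_spec")
}

# acquisition families used by the study design
acq_s525 <- function() acquisition_params(tau1 = 380, tau2 = 5000, dt = 4,
                                          t_max = 5000, shots_per_point = 16,
                                          srt = 3060, freq_offset = 65)
acq_s525_alt <- function() acquisition_params(tau1 = 380, tau2 = 4000,
                                              dt = 12, t_max = 4000,
                                              shots_per_point = 10,
                                              srt = 2000, freq_offset = 65)
acq_c599 <- function() acquisition_params(tau1 = 380, tau2 = 5000, dt = 12,
                                          t_max = 5000, shots_per_point = 10,
                                          srt = 2000, freq_offset = 80)

#' Default synthetic study table
#'
#' The sixteen conditions of the study design: eight ligand conditions at
#' each of two labelling sites, with ground-truth modal distances and widths
#' set to the reported per-condition values. Periplasmic-site traces use a
#' 4 ns increment over a 5000 ns window (truncated to 4000 ns in
#' processing), except the `+PAM`/`+ALE` conditions which emulate a second
#' instrument (12 ns increment, 4000 ns window). Cytoplasmic-site traces use
#' a 12 ns increment over 5000 ns. The `+IDP` and `+ETD` cytoplasmic
#' conditions carry a 20% minor component at 5.0 nm representing the
#' fully-closed subpopulation.
#'
#' @param seed Study master seed; per-condition seeds are derived from it.
#' @param noise_sd Noise level passed to every condition.
#' @return A list of [condition_spec()] objects, length 16.
#' @export
default_conditions <- function(seed = 1L, noise_sd = 0.01) {
  g1 <- function(m, s) data.frame(modal = m, sigma = s, weight = 1)
  g2 <- function(m1, s1, m2, s2, w2)
    data.frame(modal = c(m1, m2), sigma = c(s1, s2), weight = c(1 - w2, w2))
  tab <- list(
    list("S525_apo",    "S525", g1(3.8, 0.60), acq_s525(),     4000),
    list("S525_Ca",     "S525", g1(3.6, 0.43), acq_s525(),     4000),
    list("S525_CaETD",  "S525", g1(3.7, 0.51), acq_s525(),     4000),
    list("S525_ETD",    "S525", g1(3.9, 0.60), acq_s525(),     4000),
    list("S525_IDP",    "S525", g1(4.0, 0.60), acq_s525(),     4000),
    list("S525_ZLD",    "S525", g1(3.4, 0.51), acq_s525(),     4000),
    list("S525_PAM",    "S525", g1(4.1, 0.51), acq_s525_alt(), NA),
    list("S525_ALE",    "S525", g1(4.3, 0.55), acq_s525_alt(), NA),
    list("C599_apo",    "C599", g1(5.8, 0.34), acq_c599(),     NA),
    list("C599_Ca",     "C599", g1(6.0, 0.34), acq_c599(),     NA),
    list("C599_IDP",    "C599", g2(5.8, 0.51, 5.0, 0.30, 0.2), acq_c599(), NA),
    list("C599_ZLD",    "C599", g1(5.9, 0.34), acq_c599(),     NA),
    list("C599_ETD",    "C599", g2(5.9, 0.30, 5.0, 0.30, 0.2), acq_c599(), NA),
    list("C599_ETDCa",  "C599", g1(5.9, 0.34), acq_c599(),     NA),
    list("C599_PAM",    "C599", g1(5.9, 0.30), acq_c599(),     NA),
    list("C599_ALE",    "C599", g1(6.0, 0.30), acq_c599(),     NA))
  lapply(seq_along(tab), function(i) {
    z <- tab[[i]]
    condition_spec(label = z[[1]], site = z[[2]], components = z[[3]],
                   acq = z[[4]], t_cut = z[[5]], noise_sd = noise_sd,
                   seed = (as.integer(seed) * 131L + i) %% 2000000000L)
  })
}

#' Simulate one condition
#'
#' @param spec A [condition_spec()].
#' @param r_grid Distance grid for the ground truth.
#' @return A list (`condition_bundle`): `trace` ([dipolar_trace()]), `truth`
#'   ([distance_distribution()]), `spec`. Deterministic for a given spec.
#' @export
synth_condition <- function(spec, r_grid = default_r_grid()) {
  stopifnot(inherits(spec, "condition_spec"))
  truth <- gaussian_mixture(spec$components, r_grid)
  trace <- simulate_trace(truth, spec$background, spec$acq,
                          noise_sd = spec$noise_sd, seed = spec$seed,
                          label = spec$label)
  structure(list(trace = trace, truth = truth, spec = spec),
            class = "condition_bundle")
}

#' Generate a full synthetic study
#'
#' Simulates every condition in a study table and, when `out_dir` is given,
#' writes one bundle per condition (ASCII trace with JSON sidecar plus truth
#' CSV) and a `manifest.json` recording labels, seeds and truth statistics.
#'
#' @param conditions List of [condition_spec()]s; defaults to
#'   [default_conditions()].
#' @param out_dir Optional output directory.
#' @param r_grid Distance grid for ground truths.
#' @return Named list of bundles (see [synth_condition()]), invisibly when
#'   writing to disk.
#' @export
synth_study <- function(conditions = default_conditions(), out_dir = NULL,
                        r_grid = default_r_grid()) {
  labels <- vapply(conditions, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate condition labels")
  bundles <- lapply(conditions, synth_condition, r_grid = r_grid)
  names(bundles) <- labels
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list()
    for (b in bundles) {
      stem <- file.path(out_dir, b$spec$label)
      write_trace(b$trace, paste0(stem, ".dat"))
      write_distribution(b$truth, paste0(stem, "_truth.csv"))
      st <- distribution_stats(b$truth)
      manifest[[b$spec$label]] <- list(
        site = b$spec$site, seed = b$spec$seed, t_cut = b$spec$t_cut,
        noise_sd = b$spec$noise_sd,
        truth = list(modal = st$modal, fwhm = st$fwhm, sigma = st$sigma),
        components = b$spec$components)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    return(invisible(bundles))
  }
  bundles
}

#' Specification of a toy labelled homodimer
#'
#' A small (~200 atom) two-chain structure with idealised helical backbone
#' scaffolds, labelable residues carrying backbone N/CA/CB at a
#' periplasmic-like site (residue 25) and a cytoplasmic-like site (residue
#' 26), a partially buried site (residue 27, chain A, surrounded by
#' decoration atoms), and per-state inter-chain site separations fixed by
#' construction. Open and closed states move the site residues; the
#' scaffold is state-independent so that state models superpose cleanly.
#'
#' @param state_a,state_b Conformational state of each monomer, `"open"` or
#'   `"closed"`.
#' @param sep_peri Named inter-chain CB separations (nm) of the
#'   periplasmic-like site per state; the open/closed values must differ by
#'   at least 0.5 nm.
#' @param sep_cyto As `sep_peri` for the cytoplasmic-like site.
#' @param n_decoration Decoration atoms caging the buried site.
#' @param seed Seed for decoration placement.
#' @return An object of class `toy_dimer_spec`.
#' @export
toy_dimer_spec <- function(state_a = "open", state_b = "open",
                           sep_peri = c(open = 4.0, closed = 3.4),
                           sep_cyto = c(open = 6.8, closed = 4.8),
                           n_decoration = 40, seed = 1L) {
  stopifnot(state_a %in% c("open", "closed"),
            state_b %in% c("open", "closed"))
  if (abs(sep_peri["open"] - sep_peri["closed"]) < 0.5)
    stop("open/closed periplasmic-site separations must differ by >= 0.5 nm")
  structure(list(state_a = state_a, state_b = state_b,
                 sep_peri = sep_peri, sep_cyto = sep_cyto,
                 n_decoration = n_decoration, seed = as.integer(seed)),
            class = "toy_dimer_spec")
}

# one site residue: CB at `cb`, CA displaced along -y (so the label grows
# along +y, perpendicular to the inter-chain axis), N and C completing the
# backbone frame
toy_site_residue <- function(chain, resno, cb) {
  ca <- cb - c(0, 1.53, 0)
  data.frame(chain = chain, resno = resno,
             resid = "CYS", atom = c("N", "CA", "CB", "C"),
             element = c("N", "C", "C", "C"),
             x = c(ca[1] + 1.20, ca[1], cb[1], ca[1] - 1.20),
             y = c(ca[2] - 0.80, ca[2], cb[2], ca[2] - 0.80),
             z = c(ca[3], ca[3], cb[3], ca[3] + 0.40),
             stringsAsFactors = FALSE)
}

#' Generate a toy labelled dimer
#'
#' @param spec A [toy_dimer_spec()].
#' @return A list: `model` (`structure_model`), `separations` (named vector,
#'   nm: realised CB-CB distances `peri` and `cyto`), `spec`.
#' @export
synth_dimer <- function(spec = toy_dimer_spec()) {
  stopifnot(inherits(spec, "toy_dimer_spec"))
  # scaffolds sit at y = -8 A, displaced away from the +y direction the
  # labels grow in, so site residues never clash with them in any state
  scaffold <- function(chain, x0, y0 = -8) {
    i <- 0:23
    ca <- cbind(x0 + 2.3 * cos(i * 100 * pi / 180),
                y0 + 2.3 * sin(i * 100 * pi / 180),
                1.5 * i)
    do.call(rbind, lapply(seq_along(i), function(j) {
      data.frame(chain = chain, resno = j, resid = "ALA",
                 atom = c("N", "CA", "C"), element = c("N", "C", "C"),
                 x = ca[j, 1] + c(0.6, 0, -0.6),
                 y = ca[j, 2] + c(0.9, 0, -0.9),
                 z = ca[j, 3] + c(-0.8, 0, 0.8),
                 stringsAsFactors = FALSE)
    }))
  }
  half <- function(state, sign_x, sep) 10 * sign_x * sep[state] / 2
  atoms <- rbind(
    scaffold("A", -24), scaffold("B", 24),
    toy_site_residue("A", 25, c(half(spec$state_a, -1, spec$sep_peri), 0, 5)),
    toy_site_residue("B", 25, c(half(spec$state_b, +1, spec$sep_peri), 0, 5)),
    toy_site_residue("A", 26, c(half(spec$state_a, -1, spec$sep_cyto), 0, 30)),
    toy_site_residue("B", 26, c(half(spec$state_b, +1, spec$sep_cyto), 0, 30)))
  # partially buried site on chain A: CB close to the scaffold, caged from
  # the -y hemisphere by decoration atoms
  buried_cb <- c(-24, -3.5, 18)
  atoms <- rbind(atoms, toy_site_residue("A", 27, buried_cb))
  set.seed(spec$seed)
  n_dec <- spec$n_decoration
  if (n_dec > 0) {
    phi <- stats::runif(n_dec, 0, pi)         # +y hemisphere: the label side
    cz <- stats::runif(n_dec, -1, 1)
    rad <- stats::runif(n_dec, 4.0, 6.5)
    dirs <- cbind(sqrt(1 - cz^2) * cos(phi), sqrt(1 - cz^2) * sin(phi), cz)
    dec <- sweep(dirs * rad, 2, buried_cb + c(0, 3.5, 0), `+`)
    atoms <- rbind(atoms, data.frame(
      chain = "A", resno = 100 + seq_len(n_dec), resid = "DEC",
      atom = "C1", element = "C",
      x = dec[, 1], y = dec[, 2], z = dec[, 3],
      stringsAsFactors = FALSE))
  }
  model <- structure_model(atoms,
                           id = sprintf("toy_%s_%s", spec$state_a,
                                        spec$state_b))
  cb_sep <- function(resno) {
    a <- atoms[atoms$chain == "A" & atoms$resno == resno &
                 atoms$atom == "CB", c("x", "y", "z")]
    b <- atoms[atoms$chain == "B" & atoms$resno == resno &
                 atoms$atom == "CB", c("x", "y", "z")]
    sqrt(sum((a - b)^2)) / 10
  }
  list(model = model,
       separations = c(peri = cb_sep(25), cyto = cb_sep(26)),
       spec = spec)
}
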