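#' Parse an atomic structure from PDB or mmCIF
#'
#' Reads ATOM/HETATM records into a flat atom table. Alternate locations are
#' resolved deterministically by keeping blank or 'A' altlocs and dropping
#' the rest; waters are dropped unless requested.
#'
#' @param path File path (`.pdb` or `.cif`); format guessed from the
#'   extension when not given.
#' @param format `"pdb"` or `"mmcif"`.
#' @param keep_waters Retain water (HOH) records.
#' @param id Structure tag; defaults to the file base name.
#' @return An object of class `structure_model`: list with `atoms` (data
#'   frame: `chain`, `resno`, `insert`, `resid`, `atom`, `element`, `x`,
#'   `y`, `z` in Angstrom, `altloc`, `occupancy`, `hetatm`) and `id`.
#' @export
read_structure <- function(path, format = NULL, keep_waters = FALSE,
                           id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  format <- match.arg(format, c("pdb", "mmcif"))
  pdb <- if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
         else bio3d::read.cif(path, verbose = FALSE)
  a <- pdb$atom
  if (nrow(a) == 0) stop("empty model: no atoms parsed")
  atoms <- data.frame(
    chain = as.character(a$chain),
    resno = as.integer(a$resno),
    insert = ifelse(is.na(a$insert), "", as.character(a$insert)),
    resid = as.character(a$resid),
    atom = as.character(a$elety),
    element = as.character(a$elesy),
    x = a$x, y = a$y, z = a$z,
    altloc = ifelse(is.na(a$alt), "", as.character(a$alt)),
    occupancy = a$o,
    hetatm = a$type == "HETATM",
    stringsAsFactors = FALSE)
  structure_model(atoms, id = id %||% sub("\\.[^.]+(\\.gz)?$", "",
                                          basename(path)))
}

#' Construct a structure model from an atom table
#'
#' @param atoms Atom data frame (see [read_structure()] for columns).
#' @param id Free-text structure tag.
#' @param keep_waters Retain water records.
#' @return A `structure_model`.
#' @export
structure_model <- function(atoms, id = "model", keep_waters = FALSE) {
  need <- c("chain", "resno", "resid", "atom", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atom table lacks columns: ",
         paste(setdiff(need, names(atoms)), collapse = ", "))
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  if (!"altloc" %in% names(atoms)) atoms$altloc <- ""
  if (!"element" %in% names(atoms))
    atoms$element <- substr(trimws(atoms$atom), 1, 1)
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  if (!"hetatm" %in% names(atoms)) atoms$hetatm <- FALSE
  atoms <- atoms[atoms$altloc %in% c("", "A"), , drop = FALSE]
  if (!keep_waters) atoms <- atoms[atoms$resid != "HOH", , drop = FALSE]
  if (nrow(atoms) == 0) stop("empty model: no atoms retained")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$atom,
               atoms$altloc)
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, id = id), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- protein_chains(x)
  cat(sprintf("<structure_model> '%s': %d atoms, %d protein chain(s) [%s]\n",
              x$id, nrow(x$atoms), length(ch), paste(ch, collapse = ", ")))
  invisible(x)
}

#' Protein chain identifiers of a model
#'
#' Chains possessing at least `min_ca` C-alpha atoms, i.e. polypeptide
#' chains as opposed to ligand/ion-only chains.
#'
#' @param model A `structure_model`.
#' @param min_ca Minimum number of CA atoms for a chain to count as protein.
#' @return Character vector of chain ids.
#' @export
protein_chains <- function(model, min_ca = 20) {
  ca <- model$atoms[model$atoms$atom == "CA" & !model$atoms$hetatm, ]
  tab <- table(ca$chain)
  names(tab)[tab >= min_ca]
}

#' Write a structure model as PDB
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  rec <- sprintf(
    "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$hetatm, "HETATM", "ATOM"),
    seq_len(nrow(a)) %% 100000,
    ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom),
    "", substr(a$resid, 1, 3), substr(a$chain, 1, 1), a$resno %% 10000,
    substr(a$insert, 1, 1), a$x, a$y, a$z, a$occupancy, 0, a$element)
  writeLines(c(rec, "END"), path)
  invisible(path)
}

coords_matrix <- function(model, sel = TRUE) {
  as.matrix(model$atoms[sel, c("x", "y", "z"), drop = FALSE])
}

# pair atoms of two models by (mapped chain, residue number, atom name)
pair_atoms <- function(mobile, reference, chain_map, atom = "CA") {
  ma <- mobile$atoms[mobile$atoms$atom %in% atom & !mobile$atoms$hetatm, ]
  ra <- reference$atoms[reference$atoms$atom %in% atom &
                          !reference$atoms$hetatm, ]
  ma <- ma[ma$chain %in% names(chain_map), ]
  ma$rchain <- unname(chain_map[ma$chain])
  mkey <- paste(ma$rchain, ma$resno, ma$insert, ma$atom)
  rkey <- paste(ra$chain, ra$resno, ra$insert, ra$atom)
  hit <- match(mkey, rkey)
  ok <- !is.na(hit)
  list(mobile = as.matrix(ma[ok, c("x", "y", "z")]),
       reference = as.matrix(ra[hit[ok], c("x", "y", "z")]),
       n = sum(ok))
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired atoms of two models, pairing by mapped chain id, residue number
#' and atom name over the selected atom names.
#'
#' @param mobile,reference `structure_model` objects.
#' @param chain_map Named character vector mapping mobile chain ids to
#'   reference chain ids; defaults to identity over shared chains.
#' @param selection Atom names used for the fit (default `"CA"`).
#' @return A list: `rotation` (3x3, det +1), `translation` (length 3; the
#'   transform is `x %*% t(R) + translation`), `rmsd` (Angstrom), `n_paired`.
#' @export
superpose <- function(mobile, reference, chain_map = NULL,
                      selection = "CA") {
  stopifnot(inherits(mobile, "structure_model"),
            inherits(reference, "structure_model"))
  if (is.null(chain_map)) {
    shared <- intersect(unique(mobile$atoms$chain),
                        unique(reference$atoms$chain))
    chain_map <- stats::setNames(shared, shared)
  }
  pr <- pair_atoms(mobile, reference, chain_map, atom = selection)
  if (pr$n < 3) stop("selection yields fewer than 3 paired atoms")
  fit <- kabsch(pr$mobile, pr$reference)
  moved <- sweep(pr$mobile, 2, fit$center_mobile) %*% t(fit$rotation)
  moved <- sweep(moved, 2, fit$center_reference, `+`)
  fit$rmsd <- sqrt(mean(rowSums((moved - pr$reference)^2)))
  fit$n_paired <- pr$n
  fit
}

# RMSD between two paired point sets after optimal rigid superposition
kabsch_rmsd <- function(X, Y) {
  fit <- kabsch(X, Y)
  moved <- sweep(X, 2, fit$center_mobile) %*% t(fit$rotation)
  moved <- sweep(moved, 2, fit$center_reference, `+`)
  sqrt(mean(rowSums((moved - Y)^2)))
}

# Kabsch algorithm via SVD with reflection guard
kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  if (qr(Xc)$rank < 2) stop("degenerate (collinear) selection")
  list(rotation = R,
       translation = as.vector(cy - R %*% cx),
       center_mobile = cx, center_reference = cy)
}

#' Apply a rigid transform to a structure model
#'
#' @param model A `structure_model`.
#' @param fit Result of [superpose()] (or a list with `rotation` and
#'   `translation`).
#' @return The transformed `structure_model`.
#' @export
transform_structure <- function(model, fit) {
  xyz <- coords_matrix(model)
  moved <- xyz %*% t(fit$rotation)
  moved <- sweep(moved, 2, fit$translation, `+`)
  model$atoms[, c("x", "y", "z")] <- moved
  model
}

#' Per-C-alpha RMSD between two chains or models
#'
#' Superposes on the shared C-alpha atoms and reports the C-alpha RMSD after
#' the fit, the standard whole-fold comparison for conformational states.
#'
#' @param a,b `structure_model` objects (may be single chains extracted with
#'   [extract_chain()]).
#' @param chain_map Named map from chains of `a` to chains of `b`; identity
#'   over shared chains by default.
#' @param min_shared Minimum number of shared residues required.
#' @return List: `rmsd` (Angstrom), `n_paired` residues.
#' @export
rmsd_per_ca <- function(a, b, chain_map = NULL, min_shared = 50) {
  if (is.null(chain_map)) {
    ca <- unique(a$atoms$chain); cb <- unique(b$atoms$chain)
    shared <- intersect(ca, cb)
    if (!length(shared) && length(ca) == 1 && length(cb) == 1)
      chain_map <- stats::setNames(cb, ca)
    else chain_map <- stats::setNames(shared, shared)
  }
  fit <- superpose(a, b, chain_map = chain_map, selection = "CA")
  if (fit$n_paired < min_shared)
    stop(sprintf("only %d shared C-alpha residues (need >= %d)",
                 fit$n_paired, min_shared))
  list(rmsd = fit$rmsd, n_paired = fit$n_paired)
}

#' Extract one chain as a standalone model
#'
#' @param model A `structure_model`.
#' @param chain Chain id.
#' @param rename Optional new chain id.
#' @param keep_het Keep HETATM records belonging to the chain.
#' @return A `structure_model` containing the single chain.
#' @export
extract_chain <- function(model, chain, rename = NULL, keep_het = TRUE) {
  sel <- model$atoms$chain == chain
  if (!keep_het) sel <- sel & !model$atoms$hetatm
  if (!any(sel)) stop(sprintf("chain '%s' absent from %s", chain, model$id))
  atoms <- model$atoms[sel, , drop = FALSE]
  if (!is.null(rename)) atoms$chain <- rename
  structure_model(atoms, id = paste0(model$id, ":", chain))
}

#' Specification of an asymmetric hybrid dimer
#'
#' Describes a homodimer assembled from one chain of each of two (possibly
#' identical) source structures, after superposing each source onto a
#' reference dimer.
#'
#' @param chain_a,chain_b Lists `list(structure = <id>, chain = <id>)`
#'   naming the source structure and chain for the first and second monomer.
#' @param reference Structure id of the reference dimer.
#' @param ref_chains Chain ids of the reference dimer onto which the two
#'   monomers are aligned (length 2).
#' @param selection Atom names used for the alignment (default `"CA"`).
#' @return An object of class `hybrid_spec`.
#' @export
hybrid_spec <- function(chain_a, chain_b, reference,
                        ref_chains = c("A", "B"), selection = "CA") {
  stopifnot(length(ref_chains) == 2)
  structure(list(chain_a = chain_a, chain_b = chain_b,
                 reference = reference, ref_chains = ref_chains,
                 selection = selection),
            class = "hybrid_spec")
}

#' Assemble an asymmetric hybrid dimer
#'
#' Superposes each source dimer onto the reference via the shared C-alpha
#' atoms of the whole dimer, then extracts the assigned chain of each source
#' post-transform. The output contains exactly two chains, renamed A and B.
#'
#' @param spec A [hybrid_spec()].
#' @param sources Named list of `structure_model` objects containing the
#'   reference and both sources (keys are structure ids).
#' @param rmsd_warn Alignment RMSD (Angstrom) above which a warning is
#'   emitted.
#' @return A `structure_model` with chains A and B.
#' @export
build_hybrid <- function(spec, sources, rmsd_warn = 10) {
  stopifnot(inherits(spec, "hybrid_spec"))
  ref <- sources[[spec$reference]]
  if (is.null(ref)) stop("reference structure missing from sources")
  place <- function(assign, new_chain) {
    src <- sources[[assign$structure]]
    if (is.null(src))
      stop("source structure missing: ", assign$structure)
    if (!assign$chain %in% unique(src$atoms$chain))
      stop(sprintf("chain '%s' absent from %s", assign$chain,
                   assign$structure))
    fit <- superpose(src, ref, selection = spec$selection)
    if (fit$rmsd > rmsd_warn)
      warning(sprintf("alignment RMSD %.2f A above %.1f A sanity threshold",
                      fit$rmsd, rmsd_warn))
    extract_chain(transform_structure(src, fit), assign$chain,
                  rename = new_chain)
  }
  ma <- place(spec$chain_a, "A")
  mb <- place(spec$chain_b, "B")
  structure_model(rbind(ma$atoms, mb$atoms),
                  id = sprintf("%s(%s)_%s(%s)",
                               spec$chain_a$structure, spec$chain_a$chain,
                               spec$chain_b$structure, spec$chain_b$chain))
}
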