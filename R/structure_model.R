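#' Coarse-grained scattering structure
#'
#' A `coarse_structure` is an ordered set of scattering centers: positions in
#' Angstrom, excess scattering lengths `b` (relative units; the overall
#' intensity scale is always fitted), and chain/residue annotation carried
#' over from the source coordinates.  All protein atoms share one average
#' excess scattering length, which is the coarse-graining this package's
#' forward model is built on; hydration-shell dummy atoms are a second kind
#' of center whose `b` may take any sign (solvent contrast).
#'
#' @param xyz numeric n x 3 matrix of positions (Angstrom).
#' @param b numeric vector of excess scattering lengths (relative units).
#' @param kind character vector, `"protein_atom"` or `"hydration_dummy"`.
#' @param chain,resno,resid,elety annotation vectors (chain id, residue
#'   number, 3-letter residue name, atom name); recycled if length 1.
#' @param provenance free-text description of where the centers came from.
#' @return An object of class `coarse_structure`.
#' @export
coarse_structure <- function(xyz, b = 1, kind = "protein_atom",
                             chain = "A", resno = seq_len(nrow(xyz)),
                             resid = "ALA", elety = "CA",
                             provenance = "constructed") {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns")
  n <- nrow(xyz)
  if (n < 1L) stop("a coarse_structure must contain at least one center")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  rec <- function(x) if (length(x) == 1L) rep(x, n) else x
  b <- rec(b); kind <- rec(kind); chain <- rec(chain)
  resno <- rec(resno); resid <- rec(resid); elety <- rec(elety)
  stopifnot(length(b) == n, length(kind) == n, length(chain) == n,
            length(resno) == n, length(resid) == n, length(elety) == n)
  if (!all(kind %in% c("protein_atom", "hydration_dummy")))
    stop("kind must be 'protein_atom' or 'hydration_dummy'")
  if (any(b[kind == "protein_atom"] <= 0))
    stop("protein_atom centers must have b > 0")
  if (sum(b) <= 0) stop("total scattering length must be positive")
  structure(list(xyz = unname(xyz), b = as.numeric(b), kind = kind,
                 chain = as.character(chain), resno = as.integer(resno),
                 resid = as.character(resid), elety = as.character(elety),
                 provenance = provenance),
            class = "coarse_structure")
}

#' @export
print.coarse_structure <- function(x, ...) {
  cat("coarse_structure:", n_centers(x), "centers,",
      sum(x$kind == "hydration_dummy"), "hydration dummies\n")
  cat("  chains:", paste(unique(x$chain), collapse = " "), "\n")
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @rdname coarse_structure
#' @param x a `coarse_structure`.
#' @export
n_centers <- function(x) nrow(x$xyz)

## internal: subset a coarse_structure by integer index, preserving order
cs_subset <- function(x, idx, provenance = x$provenance) {
  if (length(idx) == 0L) stop("selection is empty")
  coarse_structure(x$xyz[idx, , drop = FALSE], x$b[idx], x$kind[idx],
                   x$chain[idx], x$resno[idx], x$resid[idx], x$elety[idx],
                   provenance = provenance)
}

## internal: concatenate coarse structures
cs_bind <- function(a, b, provenance = a$provenance) {
  coarse_structure(rbind(a$xyz, b$xyz), c(a$b, b$b), c(a$kind, b$kind),
                   c(a$chain, b$chain), c(a$resno, b$resno),
                   c(a$resid, b$resid), c(a$elety, b$elety),
                   provenance = provenance)
}

#' Read a structure from PDB coordinates as scattering centers
#'
#' Parses standard PDB ATOM records (via [bio3d::read.pdb]) and coarse-grains
#' them to scattering centers: every non-hydrogen protein atom becomes one
#' center with the same average excess scattering length.  Waters and hetero
#' ligands are excluded; hydrogens are excluded unless requested.
#'
#' @param pdb path to a PDB file, or a character vector of PDB-format lines,
#'   or a `bio3d` `pdb` object.
#' @param include_hydrogens keep hydrogen atoms (default `FALSE`).
#' @param b average excess scattering length assigned to every atom
#'   (relative units, default 1; the intensity scale is fitted downstream).
#' @return A [coarse_structure].
#' @export
read_structure <- function(pdb, include_hydrogens = FALSE, b = 1.0) {
  if (inherits(pdb, "pdb")) {
    obj <- pdb
    src <- "pdb object"
  } else if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    obj <- bio3d::read.pdb(pdb, verbose = FALSE)
    src <- pdb
  } else {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf))
    writeLines(unlist(strsplit(paste(pdb, collapse = "\n"), "\n")), tf)
    obj <- tryCatch(bio3d::read.pdb(tf, verbose = FALSE),
                    error = function(e) stop("PDB parse error: ",
                                             conditionMessage(e)))
    src <- "PDB text"
  }
  at <- obj$atom
  keep <- at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD"))
  if (!include_hydrogens) {
    elem <- at$elesy
    if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
      elem <- ifelse(grepl("^[0-9]*H", trimws(at$elety)), "H", "X")
    }
    keep <- keep & !(trimws(elem) %in% c("H", "D"))
  }
  if (!any(keep)) stop("no atoms selected from PDB input")
  at <- at[keep, , drop = FALSE]
  ch <- at$chain
  ch[is.na(ch) | ch == ""] <- "A"
  coarse_structure(cbind(at$x, at$y, at$z), b = b, kind = "protein_atom",
                   chain = ch, resno = at$resno, resid = at$resid,
                   elety = trimws(at$elety),
                   provenance = paste0("read_structure(", src, ")"))
}

#' Write scattering centers as a PDB file
#'
#' Protein centers are written as ATOM records and hydration dummies as
#' HETATM `DUM` records, to PDB fixed-column precision (3 decimals).
#'
#' @param structure a [coarse_structure].
#' @param file output path.
#' @export
write_structure <- function(structure, file) {
  x <- structure
  n <- n_centers(x)
  type <- ifelse(x$kind == "hydration_dummy", "HETATM", "ATOM  ")
  resid <- ifelse(x$kind == "hydration_dummy", "DUM", x$resid)
  elety <- ifelse(x$kind == "hydration_dummy", "O", x$elety)
  lines <- sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                   type, pmin(seq_len(n), 99999L), substr(elety, 1, 4),
                   substr(resid, 1, 3), substr(x$chain, 1, 1),
                   x$resno %% 10000L, x$xyz[, 1], x$xyz[, 2], x$xyz[, 3],
                   1.0, 0.0)
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' Fetch a PDB entry from the RCSB (network required)
#'
#' @param id 4-character PDB accession, e.g. `"7AB5"`.
#' @param destfile optional path to keep the downloaded file.
#' @return A [coarse_structure], or `NULL` if the download fails (no
#'   network); callers decide how to handle the offline case.
#' @export
fetch_pdb <- function(id, destfile = tempfile(fileext = ".pdb")) {
  url <- paste0("https://files.rcsb.org/download/", toupper(id), ".pdb")
  old <- options(timeout = 20)
  on.exit(options(old), add = TRUE)
  ok <- tryCatch({
    suppressWarnings(utils::download.file(url, destfile, quiet = TRUE,
                                          method = "libcurl"))
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(destfile) || file.info(destfile)$size < 1000)
    return(NULL)
  read_structure(destfile)
}

#' Remove whole chains from a structure
#'
#' Used, e.g., to build a model of the complex with one component left out
#' (the "domain-omitted" topology) for model discrimination against SAXS
#' data.
#'
#' @param structure a [coarse_structure].
#' @param chains character vector of chain identifiers to drop; may be empty.
#' @return A [coarse_structure] without the named chains, order preserved.
#' @export
omit_chains <- function(structure, chains) {
  if (length(chains) == 0L) return(structure)
  avail <- unique(structure$chain)
  bad <- setdiff(chains, avail)
  if (length(bad))
    stop("unknown chain(s) ", paste(bad, collapse = ", "),
         "; available: ", paste(avail, collapse = ", "))
  keep <- !(structure$chain %in% chains)
  if (!any(keep))
    stop("omitting all chains would leave an empty structure")
  cs_subset(structure, which(keep),
            provenance = paste0(structure$provenance, " minus chains ",
                                paste(chains, collapse = "")))
}

## canonical helix frame: axis +z through the origin, CA of residue 1 at
## angle 0.  5 pseudo-centers per residue (N, CA, C, O backbone + CB), 4 for
## glycine -- the documented coarse-graining constant.
helix_canonical <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(aa %in% valid))
    stop("invalid residue letter(s): ",
         paste(unique(aa[!aa %in% valid]), collapse = ", "))
  rise <- 1.5            # Angstrom per residue
  twist <- 100 * pi / 180  # radians per residue
  r_ca <- 2.3            # CA helix radius
  out <- list()
  for (k in seq_along(aa)) {
    ang <- (k - 1) * twist
    z <- (k - 1) * rise
    radial <- c(cos(ang), sin(ang), 0)
    tangential <- c(-sin(ang), cos(ang), 0)
    ca <- r_ca * radial + c(0, 0, z)
    # backbone satellites: fixed offsets in the local (radial, tangential,
    # axial) frame, chosen to give realistic ~1.5 A bond-scale spread
    off <- list(N  = -0.8 * tangential + c(0, 0, -0.9),
                C  = 0.9 * tangential + c(0, 0, 0.7),
                O  = 0.8 * tangential + 0.9 * radial + c(0, 0, 1.3),
                CB = 1.5 * radial + c(0, 0, 0.4))
    names_k <- c("N", "CA", "C", "O", if (aa[k] != "G") "CB")
    pos <- rbind(ca + off$N, ca, ca + off$C, ca + off$O,
                 if (aa[k] != "G") ca + off$CB)
    out[[k]] <- list(pos = pos, elety = names_k, aa = aa[k])
  }
  out
}

aa1to3 <- function(a) {
  tab <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
           P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
           W = "TRP", Y = "TYR")
  unname(tab[a])
}

#' Build an ideal alpha-helix stand-in for a disordered segment
#'
#' Places an ideal alpha helix (rise 1.5 Angstrom/residue, twist 100
#' degrees/residue) along a given direction, as a stand-in for a segment not
#' resolved in the crystal (e.g. a disordered N-terminal helix predicted to
#' be helical).  Each residue contributes 5 pseudo-centers (N, CA, C, O, CB;
#' glycine 4) so the mass per residue matches the all-atom coarse-graining
#' within a few percent.
#'
#' @param sequence 1-letter amino-acid string.
#' @param start_residue residue number assigned to the first residue.
#' @param attach_point 3-vector; the CA of the first residue is placed here.
#' @param direction 3-vector, helix axis direction (need not be normalized).
#' @param chain chain identifier for the fragment.
#' @return A [coarse_structure] fragment.
#' @export
build_helix_standin <- function(sequence, start_residue = 1L,
                                attach_point = c(0, 0, 0),
                                direction = c(0, 0, 1), chain = "A") {
  if (nchar(sequence) < 1L) stop("sequence must be non-empty")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be non-zero")
  u <- direction / nrm
  # orthonormal frame (e1, e2, u), right-handed, deterministic
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  R <- cbind(e1, e2, u)  # maps canonical frame -> world
  can <- helix_canonical(sequence)
  pos <- do.call(rbind, lapply(can, `[[`, "pos"))
  elety <- unlist(lapply(can, `[[`, "elety"))
  nres <- vapply(can, function(r) nrow(r$pos), integer(1))
  resno <- rep(start_residue + seq_along(can) - 1L, nres)
  resid <- rep(aa1to3(vapply(can, `[[`, "", "aa")), nres)
  world <- pos %*% t(R)
  # anchor: CA of residue 1 (the first center of the fragment's CA set)
  ca1 <- world[which(elety == "CA")[1], ]
  world <- sweep(world, 2, ca1 - attach_point)
  coarse_structure(world, b = 1, kind = "protein_atom", chain = chain,
                   resno = resno, resid = resid, elety = elety,
                   provenance = sprintf("helix stand-in (%d residues)",
                                        length(can)))
}

## Fibonacci directions on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Add a hydration dummy-atom shell
#'
#' Solvation water around proteins has excess electron density relative to
#' bulk; the forward model represents it by dummy scattering centers on a
#' shell outside the protein envelope.  Dummies are placed on a Fibonacci
#' lattice over the convex offset envelope at `shell_distance` from the
#' protein surface, with `grid_spacing` the nominal lattice pitch (one dummy
#' per `grid_spacing^2` of shell area).  With `dummy_b = 0` the forward
#' intensity is identical to the unhydrated structure.
#'
#' @param structure a [coarse_structure] of protein centers.
#' @param shell_distance shell offset from the envelope, Angstrom.
#' @param grid_spacing nominal lattice pitch, Angstrom (> 0).
#' @param dummy_b excess scattering length per dummy (relative units; any
#'   sign; default 0).
#' @return A [coarse_structure] with the dummies appended.
#' @export
add_hydration_layer <- function(structure, shell_distance = 3.0,
                                grid_spacing = 3.5, dummy_b = 0) {
  if (grid_spacing <= 0) stop("grid_spacing must be positive")
  if (shell_distance < 0) stop("shell_distance must be non-negative")
  prot <- which(structure$kind == "protein_atom")
  xyz <- structure$xyz[prot, , drop = FALSE]
  ctr <- colMeans(xyz)
  # estimate shell radius in a pilot set of directions -> target count
  pilot <- fibonacci_sphere(256)
  rad <- apply(pilot, 1, function(u)
    max((xyz[, 1] - ctr[1]) * u[1] + (xyz[, 2] - ctr[2]) * u[2] +
          (xyz[, 3] - ctr[3]) * u[3]) + shell_distance)
  area <- 4 * pi * mean(rad^2)
  nd <- max(12L, round(area / grid_spacing^2))
  dirs <- fibonacci_sphere(nd)
  t_support <- apply(dirs, 1, function(u)
    max((xyz[, 1] - ctr[1]) * u[1] + (xyz[, 2] - ctr[2]) * u[2] +
          (xyz[, 3] - ctr[3]) * u[3]) + shell_distance)
  pts <- sweep(dirs * t_support, 2, ctr, `+`)
  # never inside the envelope: push out any point closer than the shell
  dmin <- cpp_min_dist(pts, xyz)
  short <- dmin < shell_distance - 1e-9
  if (any(short)) {
    pts[short, ] <- pts[short, , drop = FALSE] +
      dirs[short, , drop = FALSE] * (shell_distance - dmin[short])
  }
  dummies <- coarse_structure(pts, b = if (dummy_b == 0) 1 else dummy_b,
                              kind = "hydration_dummy", chain = "W",
                              resno = seq_len(nrow(pts)), resid = "DUM",
                              elety = "O",
                              provenance = "hydration shell")
  dummies$b[] <- dummy_b   # allow b = 0 after validation
  cs_bind(structure, dummies,
          provenance = paste0(structure$provenance, " + hydration shell"))
}

#' Rigid-body partition scheme
#'
#' Defines how a structure is split into rigid bodies for refinement: a list
#' of (label, chain, inclusive residue range) entries, an optional C2
#' symmetry flag, and distance restraints between residue anchors.
#'
#' @param bodies data.frame with columns `label`, `chain`, `first`, `last`
#'   (inclusive residue ranges).
#' @param symmetry `"none"` or `"C2"`.
#' @param restraints data.frame with columns `chain_a`, `resno_a`,
#'   `chain_b`, `resno_b`, `weight` and optionally `resid_a`, `resid_b`,
#'   `target` (Angstrom; `NA` = measure from the reference structure).
#' @return An object of class `body_scheme`.
#' @export
body_scheme <- function(bodies, symmetry = c("none", "C2"),
                        restraints = NULL) {
  symmetry <- match.arg(symmetry)
  bodies <- as.data.frame(bodies)
  stopifnot(all(c("label", "chain", "first", "last") %in% names(bodies)))
  if (any(bodies$last < bodies$first)) stop("ranges must satisfy first <= last")
  # disjointness within chains
  for (ch in unique(bodies$chain)) {
    bd <- bodies[bodies$chain == ch, , drop = FALSE]
    if (nrow(bd) > 1) {
      o <- order(bd$first)
      if (any(bd$first[o][-1] <= bd$last[o][-nrow(bd)]))
        stop("overlapping residue ranges in chain ", ch)
    }
  }
  if (!is.null(restraints)) {
    restraints <- as.data.frame(restraints)
    stopifnot(all(c("chain_a", "resno_a", "chain_b", "resno_b") %in%
                    names(restraints)))
    if (is.null(restraints$weight)) restraints$weight <- 1
    if (is.null(restraints$target)) restraints$target <- NA_real_
    if (any(restraints$weight < 0)) stop("restraint weights must be >= 0")
  }
  structure(list(bodies = bodies, symmetry = symmetry,
                 restraints = restraints), class = "body_scheme")
}

#' @export
print.body_scheme <- function(x, ...) {
  cat("body_scheme:", nrow(x$bodies), "bodies, symmetry", x$symmetry, "\n")
  print(x$bodies, row.names = FALSE)
  if (!is.null(x$restraints))
    cat(nrow(x$restraints), "distance restraints\n")
  invisible(x)
}

#' The HipBST rigid-body scheme
#'
#' The default partition used for the HipBST heterohexamer half: three
#' bodies for HipB (residues 1-31, 32-43, 44-107), one body for HipS, and
#' three bodies for HipT (residues 2-59, 60-169, 170-331), with C2 symmetry
#' and six inter-domain distance restraints at the domain boundaries
#' (Glu A107-Val D101, Pro B55-Gly C154, Trp B65-Gly C60, Gly D100-Asp F188,
#' Leu D6-Arg F291, Val C147-Gly B94).  Chains A/E are HipB, B/D HipS, C/F
#' HipT; the asymmetric half is A+B+C.
#'
#' @param hips_range inclusive residue range used for the single HipS body.
#' @return A [body_scheme].
#' @export
hipbst_scheme <- function(hips_range = c(1L, 110L)) {
  bodies <- data.frame(
    label = c("HipB-N", "HipB-mid", "HipB-C", "HipS",
              "HipT-N", "HipT-core", "HipT-C"),
    chain = c("A", "A", "A", "B", "C", "C", "C"),
    first = c(1L, 32L, 44L, hips_range[1], 2L, 60L, 170L),
    last  = c(31L, 43L, 107L, hips_range[2], 59L, 169L, 331L))
  restraints <- data.frame(
    chain_a = c("A", "B", "B", "D", "D", "C"),
    resno_a = c(107L, 55L, 65L, 100L, 6L, 147L),
    resid_a = c("GLU", "PRO", "TRP", "GLY", "LEU", "VAL"),
    chain_b = c("D", "C", "C", "F", "F", "B"),
    resno_b = c(101L, 154L, 60L, 188L, 291L, 94L),
    resid_b = c("VAL", "GLY", "GLY", "ASP", "ARG", "GLY"),
    weight = 1, target = NA_real_)
  add_boundary_restraints(
    body_scheme(bodies, symmetry = "C2", restraints = restraints))
}

#' Add chain-continuity restraints at rigid-body boundaries
#'
#' For every pair of sequential bodies within a chain, adds a distance
#' restraint between the last residue of one body and the first residue of
#' the next, preserving the covalent chain connectivity that rigid-body
#' moves would otherwise break.  Targets are measured from the reference
#' structure at setup, like all other restraints.
#'
#' @param scheme a [body_scheme].
#' @param weight restraint weight (default 1).
#' @return The scheme with the boundary restraints appended.
#' @export
add_boundary_restraints <- function(scheme, weight = 1) {
  bodies <- scheme$bodies
  extra <- NULL
  for (ch in unique(bodies$chain)) {
    bd <- bodies[bodies$chain == ch, , drop = FALSE]
    bd <- bd[order(bd$first), , drop = FALSE]
    if (nrow(bd) < 2) next
    for (k in seq_len(nrow(bd) - 1)) {
      extra <- rbind(extra, data.frame(
        chain_a = ch, resno_a = bd$last[k], resid_a = NA_character_,
        chain_b = ch, resno_b = bd$first[k + 1], resid_b = NA_character_,
        weight = weight, target = NA_real_))
    }
  }
  if (is.null(extra)) return(scheme)
  body_scheme(bodies, symmetry = scheme$symmetry,
              restraints = rbind(scheme$restraints, extra))
}

#' Read / write a body scheme as YAML
#'
#' The on-disk format is a mapping with keys `symmetry`, `bodies` (list of
#' `{label, chain, first, last}`) and optional `restraints` (list of
#' `{chain_a, resno_a, chain_b, resno_b, weight, target}`).
#'
#' @param file path to a YAML file.
#' @return A [body_scheme].
#' @export
read_body_scheme <- function(file) {
  y <- yaml::read_yaml(file)
  bodies <- do.call(rbind, lapply(y$bodies, as.data.frame))
  restraints <- if (!is.null(y$restraints))
    do.call(rbind, lapply(y$restraints, as.data.frame)) else NULL
  body_scheme(bodies, symmetry = if (is.null(y$symmetry)) "none" else
    y$symmetry, restraints = restraints)
}

#' @rdname read_body_scheme
#' @param scheme a [body_scheme].
#' @export
write_body_scheme <- function(scheme, file) {
  y <- list(symmetry = scheme$symmetry,
            bodies = lapply(seq_len(nrow(scheme$bodies)), function(i)
              as.list(scheme$bodies[i, ])),
            restraints = if (!is.null(scheme$restraints))
              lapply(seq_len(nrow(scheme$restraints)), function(i)
                as.list(scheme$restraints[i, ])))
  yaml::write_yaml(y, file)
  invisible(file)
}

#' Partition a structure into rigid-body index sets
#'
#' Resolves a [body_scheme] against a structure.  Every protein center of a
#' chain named in the scheme is assigned to exactly one body; centers whose
#' residue number falls outside all ranges of their chain are assigned to
#' the nearest-in-sequence body with a warning.  Hydration dummies are never
#' assigned to bodies.
#'
#' @param structure a [coarse_structure].
#' @param scheme a [body_scheme].
#' @return Named list of integer index vectors, one per body.
#' @export
partition_bodies <- function(structure, scheme) {
  bodies <- scheme$bodies
  out <- vector("list", nrow(bodies))
  names(out) <- bodies$label
  assigned <- integer(0)
  for (i in seq_len(nrow(bodies))) {
    idx <- which(structure$kind == "protein_atom" &
                   structure$chain == bodies$chain[i] &
                   structure$resno >= bodies$first[i] &
                   structure$resno <= bodies$last[i])
    if (length(idx) == 0L)
      stop("body '", bodies$label[i], "' selects zero centers")
    out[[i]] <- idx
    assigned <- c(assigned, idx)
  }
  # orphans: centers in scheme chains but outside every range
  orphan <- which(structure$kind == "protein_atom" &
                    structure$chain %in% bodies$chain)
  orphan <- setdiff(orphan, assigned)
  if (length(orphan)) {
    warning(length(orphan),
            " center(s) outside all body ranges; assigned to the ",
            "nearest-in-sequence body of their chain")
    for (k in orphan) {
      cand <- which(bodies$chain == structure$chain[k])
      gap <- pmax(bodies$first[cand] - structure$resno[k],
                  structure$resno[k] - bodies$last[cand], 0)
      out[[cand[which.min(gap)]]] <- sort(c(out[[cand[which.min(gap)]]], k))
    }
  }
  out
}

## Rodrigues rotation of points about an axis (point p0, unit direction u)
rotate_about_axis <- function(xyz, p0, u, angle) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  sweep(sweep(xyz, 2, p0) %*% t(R), 2, p0, `+`)
}

#' Apply a C2 (two-fold) symmetry operation
#'
#' Returns the half structure together with its 180-degree rotated image
#' about the given axis.  The image chains are renamed by the `chain_map`
#' so the two halves remain distinguishable.
#'
#' @param half_structure a [coarse_structure] (the asymmetric half).
#' @param axis_point a point on the symmetry axis.
#' @param axis_direction axis direction (non-zero).
#' @param chain_map named character vector mapping half chains to mate
#'   chains; defaults to the HipBST convention `c(A = "E", B = "D", C = "F")`
#'   extended alphabetically for other chains.
#' @return A [coarse_structure] with twice the number of centers.
#' @export
apply_c2 <- function(half_structure, axis_point, axis_direction,
                     chain_map = c(A = "E", B = "D", C = "F")) {
  if (sqrt(sum(axis_direction^2)) == 0) stop("axis direction must be non-zero")
  mate <- half_structure
  mate$xyz <- rotate_about_axis(half_structure$xyz, axis_point,
                                axis_direction, pi)
  ch <- unique(half_structure$chain)
  map <- chain_map
  missing <- setdiff(ch, names(map))
  if (length(missing)) {
    pool <- setdiff(LETTERS, c(ch, map))
    extra <- pool[seq_along(missing)]
    names(extra) <- missing
    map <- c(map, extra)
  }
  mate$chain <- unname(map[mate$chain])
  cs_bind(half_structure, mate,
          provenance = paste0(half_structure$provenance, " (C2 expanded)"))
}

#' Fit the two-fold symmetry axis of a C2 dimeric structure
#'
#' Coordinate files do not annotate the molecular symmetry axis.  For a
#' structure whose two halves are related by (approximate) C2, this
#' estimates the axis from one pair of equivalent chains: the rotation
#' superposing the first chain onto the second (Kabsch/SVD) has the
#' symmetry axis as its rotation axis, and the midpoint of the two chain
#' centroids lies on it.  By default the two central (HipB-like) chains A
#' and E are used.
#'
#' @param structure a [coarse_structure] containing both chains.
#' @param chains length-2 character vector of equivalent chains.
#' @return `list(point =, direction =)` usable with [apply_c2].
#' @export
fit_c2_axis <- function(structure, chains = c("A", "E")) {
  ia <- which(structure$chain == chains[1] &
                structure$kind == "protein_atom")
  ib <- which(structure$chain == chains[2] &
                structure$kind == "protein_atom")
  if (length(ia) == 0L || length(ib) == 0L)
    stop("chains not found: ", paste(chains, collapse = ", "))
  if (length(ia) != length(ib))
    stop("chains ", chains[1], " and ", chains[2],
         " have different center counts; cannot superpose")
  A <- structure$xyz[ia, , drop = FALSE]
  B <- structure$xyz[ib, , drop = FALSE]
  cA <- colMeans(A); cB <- colMeans(B)
  H <- t(sweep(A, 2, cA)) %*% sweep(B, 2, cB)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  aa <- axis_angle_from_matrix(R)
  th <- sqrt(sum(aa^2))
  if (th < 1e-6)
    stop("the two chains are related by a translation, not a rotation")
  list(point = (cA + cB) / 2, direction = aa / th)
}

#' Maximum intramolecular distance
#'
#' The largest pairwise distance between scattering centers, the model-side
#' counterpart of the Dmax read off a p(r) curve.  Hydration dummies are
#' excluded by default.
#'
#' @param structure a [coarse_structure].
#' @param include_dummies include hydration dummies (default `FALSE`).
#' @return Length in Angstrom.
#' @export
max_diameter <- function(structure, include_dummies = FALSE) {
  idx <- if (include_dummies) seq_len(n_centers(structure)) else
    which(structure$kind == "protein_atom")
  if (length(idx) < 2L) stop("need at least 2 centers")
  cpp_max_pair_dist(structure$xyz[idx, , drop = FALSE])
}

#' Scattering-weighted radius of gyration of a model
#'
#' Rg^2 = sum b_i |r_i - r_cm|^2 / sum b_i with r_cm the b-weighted
#' centroid; the model-side quantity a Guinier fit of the simulated curve
#' should recover.
#'
#' @param structure a [coarse_structure].
#' @return Rg in Angstrom.
#' @export
model_rg <- function(structure) {
  bsum <- sum(structure$b)
  if (bsum <= 0) stop("total scattering length must be positive")
  cm <- colSums(structure$xyz * structure$b) / bsum
  d2 <- rowSums(sweep(structure$xyz, 2, cm)^2)
  sqrt(sum(structure$b * d2) / bsum)
}
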