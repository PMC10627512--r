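#' Noise model for simulated SAXS curves
#'
#' Multiplicative Gaussian noise with an additive error floor:
#' I_obs = I_model (1 + eps), eps ~ N(0, rel_sigma), and the reported error
#' column is sigma = rel_sigma * I_model + floor_fraction * I_model(0).
#'
#' @param rel_sigma relative noise level (default 0.02, i.e. 2 percent).
#' @param floor_fraction error floor as a fraction of I(0) (default 1e-4).
#' @param seed integer seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(rel_sigma = 0.02, floor_fraction = 1e-4,
                        seed = 1L) {
  stopifnot(rel_sigma >= 0, floor_fraction >= 0)
  structure(list(rel_sigma = rel_sigma, floor_fraction = floor_fraction,
                 seed = as.integer(seed)), class = "noise_model")
}

#' Scenario specification for the synthetic-data generator
#'
#' Bundles everything needed to generate a reproducible test scenario:
#' the bead topology, the true oligomer parameters, the body perturbations
#' used as a refinement start, the noise model and the q grid.  The default
#' oligomer truth (N = 1.8, D = 80 Angstrom) and 2 percent noise are the
#' partial-dimerization conditions the analysis is designed around.
#'
#' @param topology `"full_hexamer_like"`, `"domain_omitted"`, `"sphere"` or
#'   `"dumbbell"`.
#' @param N,D true oligomer parameters.
#' @param noise a [noise_model].
#' @param qgrid q values (default [qgrid_default]).
#' @param seed integer seed for structure generation.
#' @param perturb_trans,perturb_rot start-state perturbation magnitudes
#'   (Angstrom, degrees).
#' @param sphere_radius,sphere_n sphere topology parameters.
#' @param dumbbell_sep,dumbbell_radius dumbbell topology parameters.
#' @param sigma_smear forward-model smearing width (A).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(topology = c("full_hexamer_like",
                                       "domain_omitted", "sphere",
                                       "dumbbell"),
                          N = 1.8, D = 80, noise = noise_model(),
                          qgrid = qgrid_default(), seed = 1L,
                          perturb_trans = 8, perturb_rot = 10,
                          perturb_body = NULL,
                          sphere_radius = 30, sphere_n = 2000,
                          dumbbell_sep = 60, dumbbell_radius = 15,
                          sigma_smear = 1.0) {
  topology <- match.arg(topology)
  structure(list(topology = topology, N = N, D = D, noise = noise,
                 qgrid = qgrid, seed = as.integer(seed),
                 perturb_trans = perturb_trans, perturb_rot = perturb_rot,
                 perturb_body = perturb_body,
                 sphere_radius = sphere_radius, sphere_n = sphere_n,
                 dumbbell_sep = dumbbell_sep,
                 dumbbell_radius = dumbbell_radius,
                 sigma_smear = sigma_smear),
            class = "scenario_spec")
}

## uniform rejection sampling in a sphere (deterministic given the RNG
## state); beads get CA-like labels so restraint anchors resolve
sample_globule <- function(n, radius, center, chain, resno_start = 1L) {
  pts <- matrix(NA_real_, n, 3)
  got <- 0L
  while (got < n) {
    cand <- matrix(stats::runif(3 * 2 * (n - got), -radius, radius),
                   ncol = 3)
    keep <- rowSums(cand^2) <= radius^2
    cand <- cand[keep, , drop = FALSE]
    take <- min(nrow(cand), n - got)
    if (take > 0) {
      pts[(got + 1):(got + take), ] <- cand[seq_len(take), , drop = FALSE]
      got <- got + take
    }
  }
  sweep(pts, 2, center, `+`)
}

## radius giving ~135 A^3 of volume per residue (typical protein density)
globule_radius <- function(n_res) (3 * n_res * 135 / (4 * pi))^(1 / 3)

## deterministic repulsion relaxation: push domain spheres apart (including
## their C2 mates about the z axis) until every pair clears `gap`
pack_domains <- function(centers, radii, gap = 4.5, max_iter = 2000L) {
  n <- nrow(centers)
  for (it in seq_len(max_iter)) {
    moved <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      v <- centers[j, ] - centers[i, ]
      d <- sqrt(sum(v^2))
      need <- radii[i] + radii[j] + gap
      if (d < need) {
        shift <- (need - d + 1e-6) / 2
        u <- if (d > 1e-9) v / d else c(1, 0, 0)
        centers[i, ] <- centers[i, ] - u * shift
        centers[j, ] <- centers[j, ] + u * shift
        moved <- TRUE
      }
    }
    # clear the C2 mate images: mate of (x, y, z) is (-x, -y, z)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      mate <- c(-centers[j, 1], -centers[j, 2], centers[j, 3])
      v <- centers[i, ] - mate
      d <- sqrt(sum(v^2))
      need <- radii[i] + radii[j] + gap
      if (d < need) {
        u <- if (d > 1e-9) v / d else c(1, 0, 0)
        # move only in-plane (away from the axis) so the fix is symmetric
        centers[i, ] <- centers[i, ] + u * (need - d + 1e-6) / 2
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  centers
}

#' Generate a coarse bead model of a test complex
#'
#' Builds the deterministic (per seed) bead structures used throughout the
#' test suite: a heterohexamer-like complex of six globular chains arranged
#' with C2 symmetry (outer small chain, large kinase-sized chain, central
#' dimerization chain, mirrored: the S-T-B | B-T-S layout), the same with
#' the outer chains omitted, a uniform sphere, or a two-globule dumbbell.
#' Beads are one per residue (CA-like, 135 Angstrom^3 per residue globules)
#' with unit scattering length.
#'
#' For the hexamer-like topologies the returned structure carries
#' attributes `half` (the asymmetric half, chains A/B/C), `axis` (the C2
#' axis as `list(point, direction)`) and `chains_omitted`.
#'
#' @param spec a [scenario_spec].
#' @return A [coarse_structure].
#' @export
make_bead_complex <- function(spec) {
  set.seed(spec$seed)
  if (spec$topology == "sphere") {
    xyz <- sample_globule(spec$sphere_n, spec$sphere_radius, c(0, 0, 0), "A")
    return(coarse_structure(xyz, chain = "A",
                            resno = seq_len(nrow(xyz)), elety = "CA",
                            provenance = sprintf(
                              "synthetic sphere R=%g n=%d seed=%d",
                              spec$sphere_radius, spec$sphere_n, spec$seed)))
  }
  if (spec$topology == "dumbbell") {
    n_half <- 500L
    a <- sample_globule(n_half, spec$dumbbell_radius,
                        c(-spec$dumbbell_sep / 2, 0, 0), "A")
    b <- sample_globule(n_half, spec$dumbbell_radius,
                        c(spec$dumbbell_sep / 2, 0, 0), "B")
    return(coarse_structure(rbind(a, b),
                            chain = rep(c("A", "B"), each = n_half),
                            resno = c(seq_len(n_half), seq_len(n_half)),
                            elety = "CA",
                            provenance = sprintf(
                              "synthetic dumbbell sep=%g R=%g seed=%d",
                              spec$dumbbell_sep, spec$dumbbell_radius,
                              spec$seed)))
  }
  # hexamer-like: half = HipB-like (A, 107 res), HipS-like (B, 110 res),
  # HipT-like (C, 331 res); mate = E/D/F by C2 about the z axis.  Each
  # rigid-body range is its own compact globule (domains are spatially
  # compact in real structures) and domains are packed with a clearance
  # gap so the truth state is clash-free under the default excluded-volume
  # cutoff.
  dom <- data.frame(
    chain = c("A", "A", "A", "B", "C", "C", "C"),
    first = c(1L, 32L, 44L, 1L, 2L, 60L, 170L),
    last  = c(31L, 43L, 107L, 110L, 59L, 169L, 331L))
  dom$n <- dom$last - dom$first + 1L
  dom$r <- globule_radius(dom$n)
  start <- rbind(c(12, 8, -6), c(10, 0, 8), c(18, -6, 4),   # HipB domains
                 c(64, -4, 6),                              # HipS
                 c(32, 6, 10), c(36, -8, -8), c(48, 6, -2)) # HipT domains
  ctr <- pack_domains(start, dom$r, gap = 4.5)
  parts <- lapply(seq_len(nrow(dom)), function(i)
    sample_globule(dom$n[i], dom$r[i], ctr[i, ], dom$chain[i]))
  xyz <- do.call(rbind, parts)
  # place restraint anchor residues at the domain surface facing their
  # partner (contact restraints come from interface analysis, so the
  # anchors of real structures sit at domain-domain contacts)
  resno_all <- unlist(mapply(seq, dom$first, dom$last, SIMPLIFY = FALSE),
                      use.names = FALSE)
  chain_all <- rep(dom$chain, dom$n)
  dom_of <- rep(seq_len(nrow(dom)), dom$n)
  mate_map <- c(D = "B", E = "A", F = "C")
  c2_img <- function(p) c(-p[1], -p[2], p[3])   # 180 deg about z
  sch <- hipbst_scheme()
  rr <- sch$restraints
  # named contact restraints first, then chain-continuity boundary pairs
  moved <- character(0)
  for (k in seq_len(nrow(rr))) for (side in c("a", "b")) {
    ch <- rr[[paste0("chain_", side)]][k]
    rn <- rr[[paste0("resno_", side)]][k]
    och <- rr[[paste0("chain_", setdiff(c("a", "b"), side))]][k]
    orn <- rr[[paste0("resno_", setdiff(c("a", "b"), side))]][k]
    h_ch <- if (ch %in% names(mate_map)) mate_map[[ch]] else ch
    key <- paste0(h_ch, rn)
    if (key %in% moved) next
    i <- which(chain_all == h_ch & resno_all == rn)
    oh_ch <- if (och %in% names(mate_map)) mate_map[[och]] else och
    j <- which(chain_all == oh_ch & resno_all == orn)
    if (length(i) != 1L || length(j) != 1L) next
    # partner position in the full-model frame ...
    pj <- if (och %in% names(mate_map)) c2_img(xyz[j, ]) else xyz[j, ]
    # ... pulled back to this endpoint's half frame (C2 is an involution)
    q <- if (ch %in% names(mate_map)) c2_img(pj) else pj
    g <- dom_of[i]
    cg <- ctr[g, ]
    u <- q - cg
    nu <- sqrt(sum(u^2))
    if (nu < 1e-9) next
    xyz[i, ] <- cg + dom$r[g] * u / nu
    moved <- c(moved, key)
  }
  half <- coarse_structure(xyz,
                           chain = rep(dom$chain, dom$n),
                           resno = unlist(mapply(seq, dom$first, dom$last,
                                                 SIMPLIFY = FALSE),
                                          use.names = FALSE),
                           elety = "CA",
                           provenance = sprintf(
                             "synthetic hexamer half seed=%d", spec$seed))
  axis <- list(point = c(0, 0, 0), direction = c(0, 0, 1))
  omitted <- character(0)
  if (spec$topology == "domain_omitted") {
    half <- omit_chains(half, "B")
    omitted <- c("B", "D")
  }
  full <- apply_c2(half, axis$point, axis$direction)
  attr(full, "half") <- half
  attr(full, "axis") <- axis
  attr(full, "chains_omitted") <- omitted
  full
}

#' Simulate a noisy SAXS curve from a model
#'
#' Computes the decoupled model intensity I = P + <A>^2 (S - 1) on the q
#' grid and applies the noise model: multiplicative Gaussian noise and an
#' error column sigma = rel_sigma * I_model + floor * I(0).  Seeded and
#' exactly reproducible.
#'
#' @param structure a [coarse_structure] (the oligomer repeat unit).
#' @param oligomer an [oligomer_model].
#' @param noise a [noise_model].
#' @param qgrid q values.
#' @param sigma_smear forward-model smearing width (A).
#' @return A [saxs_curve].
#' @export
simulate_curve <- function(structure, oligomer, noise = noise_model(),
                           qgrid = qgrid_default(), sigma_smear = 1.0) {
  ic <- intensity_decoupled(structure, oligomer, qgrid, sigma_smear,
                            method = "histogram")
  I_model <- ic$I
  sg <- noise$rel_sigma * I_model + noise$floor_fraction * I_model[1]
  if (any(sg <= 0)) sg <- pmax(sg, 1e-12 * max(I_model))
  set.seed(noise$seed)
  eps <- stats::rnorm(length(I_model), 0, 1)
  I_obs <- I_model * (1 + noise$rel_sigma * eps)
  saxs_curve(qgrid, I_obs, sg)
}

## uniform random unit vector
runif_dir <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-9) return(v / n)
  }
}

#' Randomly perturb a body state
#'
#' Gives each body a seeded random rotation (angle uniform in (0,
#' `max_rot`] degrees about a random axis) and translation (length uniform
#' in (0, `max_trans`] Angstrom, random direction).  Used to create
#' refinement start points away from the truth.
#'
#' @param state a `body_state` (see [body_state_identity]).
#' @param max_trans,max_rot maximum shift (Angstrom) and angle (degrees);
#'   scalars or per-body vectors (a zero leaves that body untouched).
#' @param seed integer seed.
#' @return The perturbed `body_state`.
#' @export
perturb_bodies <- function(state, max_trans = 8, max_rot = 10, seed = 1L) {
  stopifnot(all(max_trans >= 0), all(max_rot >= 0))
  max_trans <- rep_len(max_trans, length(state))
  max_rot <- rep_len(max_rot, length(state))
  set.seed(seed)
  out <- state
  for (k in seq_along(state)) {
    if (max_rot[k] > 0)
      out[[k]]$rot <- state[[k]]$rot +
        runif_dir() * stats::runif(1, 0, max_rot[k] * pi / 180)
    if (max_trans[k] > 0)
      out[[k]]$trans <- state[[k]]$trans +
        runif_dir() * stats::runif(1, 0, max_trans[k])
  }
  out
}

#' Package a complete recovery test scenario
#'
#' Generates the truth structure, the perturbed start state, the noisy
#' curve and the matching [body_scheme], and (optionally) writes them to a
#' directory as plain-text files (PDB half, three-column curve, YAML
#' scheme, JSON truth record).
#'
#' @param spec a [scenario_spec].
#' @param dir optional output directory.
#' @return A list: `spec`, `structure` (full), `half`, `axis`, `scheme`,
#'   `body_indices`, `start_state`, `truth` (N, D, body centroids), and
#'   `curve`.
#' @export
recovery_suite <- function(spec = scenario_spec(), dir = NULL) {
  full <- make_bead_complex(spec)
  half <- attr(full, "half")
  axis <- attr(full, "axis")
  if (is.null(half)) {        # sphere / dumbbell: refine the whole model
    half <- full
    axis <- NULL
  }
  scheme <- if (spec$topology %in% c("full_hexamer_like")) {
    hipbst_scheme()
  } else if (spec$topology == "domain_omitted") {
    s <- hipbst_scheme()
    keep <- s$bodies$chain != "B"
    rkeep <- !(s$restraints$chain_a %in% c("B", "D") |
                 s$restraints$chain_b %in% c("B", "D"))
    body_scheme(s$bodies[keep, ], symmetry = "C2",
                restraints = s$restraints[rkeep, ])
  } else {
    body_scheme(data.frame(label = unique(half$chain),
                           chain = unique(half$chain), first = 1L,
                           last = max(half$resno)), symmetry = "none")
  }
  body_indices <- partition_bodies(half, scheme)
  olig <- oligomer_model(spec$N, spec$D)
  curve <- simulate_curve(full, olig, spec$noise, spec$qgrid,
                          spec$sigma_smear)
  # perturb one designated body (default HipS, else the kinase core): the
  # standard recovery scenario displaces a single domain from the truth
  labels <- names(body_indices)
  target <- if (!is.null(spec$perturb_body) &&
                spec$perturb_body %in% labels) {
    spec$perturb_body
  } else if ("HipS" %in% labels) "HipS"
  else if ("HipT-core" %in% labels) "HipT-core"
  else labels[1]
  tr <- ifelse(labels == target, spec$perturb_trans, 0)
  ro <- ifelse(labels == target, spec$perturb_rot, 0)
  start_state <- perturb_bodies(body_state_identity(body_indices),
                                tr, ro, seed = spec$seed + 1000L)
  truth_centroids <- lapply(body_indices, function(i)
    colMeans(half$xyz[i, , drop = FALSE]))
  out <- list(spec = spec, structure = full, half = half, axis = axis,
              scheme = scheme, body_indices = body_indices,
              start_state = start_state,
              truth = list(N = spec$N, D = spec$D,
                           centroids = truth_centroids),
              curve = curve)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_structure(half, file.path(dir, "half.pdb"))
    write_saxs(curve, file.path(dir, "curve.dat"))
    write_body_scheme(scheme, file.path(dir, "scheme.yaml"))
    jsonlite::write_json(list(topology = spec$topology, N = spec$N,
                              D = spec$D, seed = spec$seed,
                              rel_sigma = spec$noise$rel_sigma),
                         file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
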