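# Shared fixtures, all generated in code.

# cubic-lattice-filled sphere: deterministic stand-in for the continuum
# uniform sphere (the closed-form oracle geometry)
lattice_sphere <- function(R = 30, h = 1.5) {
  g <- seq(-R, R, by = h)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[rowSums(pts^2) <= R^2, ]
  coarse_structure(pts, chain = "A", resno = seq_len(nrow(pts)),
                   provenance = sprintf("lattice sphere R=%g h=%g", R, h))
}

# analytic uniform-sphere form factor [3(sin x - x cos x)/x^3]^2
sphere_ff <- function(x) (3 * (sin(x) - x * cos(x)) / x^3)^2

# analytic uniform-sphere p(r) (unnormalized), Dmax = 2R
sphere_pr <- function(r, R) {
  D <- 2 * R
  ifelse(r >= 0 & r <= D,
         r^2 * (1 - 1.5 * (r / D) + 0.5 * (r / D)^3), 0)
}

# minimal hand-built PDB text: n_res poly-Ala residues, 5 atoms each
# (N, CA, C, O, CB), plus one hydrogen to exercise the H filter
poly_ala_pdb <- function(n_res = 10, chain = "A", with_h = TRUE) {
  lines <- character(0)
  k <- 0
  for (i in seq_len(n_res)) {
    for (at in c("N", "CA", "C", "O", "CB")) {
      k <- k + 1
      x <- i * 3.8 + k * 0.01
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        k, at, chain, i, x, 0.5 * i, -0.2 * i, substr(at, 1, 1)))
    }
    if (with_h) {
      k <- k + 1
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           H",
        k, "HA", chain, i, i * 3.8, 0.5 * i + 0.5, -0.2 * i))
    }
  }
  c(lines, "END")
}

# random rigid transform applied to a coarse structure
random_rigid <- function(structure, seed = 1) {
  set.seed(seed)
  v <- stats::rnorm(3)
  ang <- stats::runif(1, 0, pi)
  R <- saxsrb:::axis_angle_matrix(v / sqrt(sum(v^2)) * ang)
  out <- structure
  out$xyz <- sweep(structure$xyz %*% t(R), 2, stats::rnorm(3, 0, 20), `+`)
  out
}

# small but realistic hexamer recovery bundle (cached per session)
.hex_cache <- new.env()
hexamer_bundle <- function(seed = 11, noise_seed = 42, rel_sigma = 0.02,
                           topology = "full_hexamer_like") {
  key <- paste(seed, noise_seed, rel_sigma, topology, sep = "_")
  if (is.null(.hex_cache[[key]])) {
    .hex_cache[[key]] <- recovery_suite(scenario_spec(
      topology = topology, seed = seed,
      noise = noise_model(rel_sigma, 1e-4, noise_seed)))
  }
  .hex_cache[[key]]
}

body_centroid_errors <- function(bundle, fit) {
  bi <- bundle$body_indices
  half_t <- apply_body_state(bundle$half, bi, fit$state)
  errs <- vapply(seq_along(bi), function(k)
    sqrt(sum((colMeans(half_t$xyz[bi[[k]], , drop = FALSE]) -
                bundle$truth$centroids[[k]])^2)), numeric(1))
  names(errs) <- names(bi)
  errs
}

# 48-sequence loop FASTA with a fixed group composition (30 SPsiS members)
motif_fixture_fasta <- function(path) {
  set.seed(7)
  psi <- c("I", "L", "V")
  triplets <- c(
    paste0("S", sample(psi, 30, TRUE), "S"),            # SPsiS x 30
    paste0(sample(c("S", "T"), 6, TRUE), sample(psi, 6, TRUE), "T"),
    paste0(sample(c("S", "T"), 4, TRUE), sample(psi, 4, TRUE), "P"),
    paste0("S", sample(psi, 4, TRUE), "Q"),
    paste0(sample(psi, 3, TRUE), sample(psi, 3, TRUE), "T"),
    "GAA")                                              # one 'other'
  stopifnot(length(triplets) == 48)
  seqs <- paste0("MGKEQ", triplets, "GKGND")
  ids <- sprintf("hip%02d", seq_along(seqs))
  writeLines(paste0(">", ids, "\n", seqs), path)
  list(ids = ids, triplets = triplets,
       groups = classify_motif(triplets))
}
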