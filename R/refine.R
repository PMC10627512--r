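#' Reduced chi-square with analytic optimal scale
#'
#' The error-weighted model-to-data discrepancy used for model selection.
#' The overall scale is profiled out in closed form,
#' s* = sum(Im Ie / sigma^2) / sum(Im^2 / sigma^2), and
#' chi2_red = sum(((s* Im - Ie)/sigma)^2) / (n_points - n_free_params).
#'
#' @param model_I model intensities evaluated on the curve's q grid.
#' @param curve a [saxs_curve].
#' @param n_free_params number of fitted parameters (including the scale).
#' @return List with `chi2_reduced` and `scale`.
#' @export
chi2_reduced <- function(model_I, curve, n_free_params = 1L) {
  if (inherits(model_I, "intensity_curve")) model_I <- model_I$I
  y <- curve$I; sg <- curve$sigma
  n <- length(y)
  stopifnot(length(model_I) == n)
  if (n <= n_free_params) stop("need more points than free parameters")
  s <- sum(model_I * y / sg^2) / sum(model_I^2 / sg^2)
  chi2 <- sum(((s * model_I - y) / sg)^2) / (n - n_free_params)
  list(chi2_reduced = chi2, scale = s)
}

#' Resolve distance-restraint anchors to representative centers
#'
#' Each anchor (chain, residue number) is represented by the residue's CA
#' center when present, otherwise by its first center.  Target distances
#' that are `NA` are measured from the reference structure (the usual
#' setup: restraints preserve crystal-contact distances during refinement).
#'
#' @param structure the reference [coarse_structure].
#' @param restraints restraint data.frame (see [body_scheme]).
#' @return The restraints with columns `idx_a`, `idx_b` and `target` filled.
#' @export
resolve_restraints <- function(structure, restraints) {
  find_anchor <- function(ch, rn) {
    idx <- which(structure$chain == ch & structure$resno == rn &
                   structure$kind == "protein_atom")
    if (length(idx) == 0L)
      stop("restraint anchor ", ch, rn, " not found in structure")
    ca <- idx[structure$elety[idx] == "CA"]
    if (length(ca) >= 1L) ca[1] else idx[1]
  }
  restraints$idx_a <- mapply(find_anchor, restraints$chain_a,
                             restraints$resno_a)
  restraints$idx_b <- mapply(find_anchor, restraints$chain_b,
                             restraints$resno_b)
  d <- sqrt(rowSums((structure$xyz[restraints$idx_a, , drop = FALSE] -
                       structure$xyz[restraints$idx_b, , drop = FALSE])^2))
  restraints$target <- ifelse(is.na(restraints$target), d,
                              restraints$target)
  if (any(restraints$target <= 0)) stop("restraint targets must be > 0")
  restraints
}

#' Harmonic distance-restraint penalty
#'
#' Sum over restraints of w_i (d_i - d_i,target)^2, with d_i the current
#' anchor-anchor distance.
#'
#' @param structure current [coarse_structure].
#' @param restraints resolved restraints (see [resolve_restraints]); if the
#'   `idx_a`/`target` columns are absent they are resolved against
#'   `structure` first (giving a zero penalty by construction).
#' @return Penalty value (>= 0).
#' @export
restraint_penalty <- function(structure, restraints) {
  if (is.null(restraints) || nrow(restraints) == 0L) return(0)
  if (is.null(restraints$idx_a) || any(is.na(restraints$target)))
    restraints <- resolve_restraints(structure, restraints)
  d <- sqrt(rowSums((structure$xyz[restraints$idx_a, , drop = FALSE] -
                       structure$xyz[restraints$idx_b, , drop = FALSE])^2))
  sum(restraints$weight * (d - restraints$target)^2)
}

#' Soft excluded-volume penalty between rigid bodies
#'
#' weight * sum over inter-body center pairs closer than `cutoff` of
#' (cutoff - d)^2; intra-body pairs are ignored.  Continuous in value and
#' slope at d = cutoff.
#'
#' @param structure current [coarse_structure].
#' @param body_indices list of integer index vectors (one per body); centers
#'   not in any body are ignored.
#' @param cutoff clash distance, Angstrom.
#' @param weight penalty weight per Angstrom^-2.
#' @return Penalty value (>= 0).
#' @export
excluded_volume_penalty <- function(structure, body_indices, cutoff = 4.0,
                                    weight = 1.0) {
  idx <- unlist(body_indices, use.names = FALSE)
  body <- rep.int(seq_along(body_indices),
                  vapply(body_indices, length, integer(1)))
  weight * cpp_clash_penalty(structure$xyz[idx, , drop = FALSE],
                             as.integer(body), cutoff)
}

#' Refinement configuration
#'
#' Parameters of the multi-start simulated-annealing search: number of
#' independent runs (best-of-n by reduced chi-square), iteration budget,
#' Gaussian move sizes, geometric cooling, penalty weights, and box bounds
#' for the oligomer parameters N (mean copies) and D (inter-particle
#' distance).
#'
#' @param n_runs independent annealing runs (default 10).
#' @param seed integer seed; run k uses `seed + k - 1`.
#' @param max_iter iterations per run.
#' @param step_trans,step_rot proposal s.d. (Angstrom, degrees).
#' @param t0,cool initial temperature and geometric cooling factor.
#' @param restraint_weight weight multiplying the distance-restraint term.
#' @param ev_weight,ev_cutoff excluded-volume weight and clash cutoff (A).
#' @param n_bounds,d_bounds allowed ranges for N and D.
#' @param polish run a deterministic Nelder-Mead local polish on the
#'   selected best run (default TRUE).
#' @param polish_maxit iteration cap for the polish phase.
#' @param sigma_smear Gaussian smearing width of the forward model (A).
#' @param bin_width Debye histogram bin width (A).
#' @param refine_oligomer also refine N and D (default TRUE).
#' @param hydrate add a hydration dummy shell to the model (default FALSE);
#'   when on, the shell is regenerated every `hydrate_every` accepted moves
#'   and exactly for the final model.
#' @param hydrate_every accepted-move interval for shell regeneration.
#' @param dummy_b hydration dummy contrast (relative units).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_runs = 10L, seed = 1L, max_iter = 600L,
                       step_trans = 2.0, step_rot = 5.0, t0 = 1.0,
                       cool = 0.97, restraint_weight = 10,
                       ev_weight = 0.1, ev_cutoff = 4.0,
                       n_bounds = c(1, 4), d_bounds = c(20, 300),
                       sigma_smear = 1.0, bin_width = 0.5,
                       refine_oligomer = TRUE,
                       polish = TRUE, polish_maxit = 1500L,
                       hydrate = FALSE, hydrate_every = 25L,
                       dummy_b = 0.05) {
  stopifnot(n_runs >= 1, max_iter >= 1, n_bounds[1] < n_bounds[2],
            d_bounds[1] < d_bounds[2], cool > 0, cool <= 1)
  structure(list(n_runs = as.integer(n_runs), seed = as.integer(seed),
                 max_iter = as.integer(max_iter), step_trans = step_trans,
                 step_rot = step_rot, t0 = t0, cool = cool,
                 restraint_weight = restraint_weight,
                 ev_weight = ev_weight, ev_cutoff = ev_cutoff,
                 n_bounds = n_bounds, d_bounds = d_bounds,
                 sigma_smear = sigma_smear, bin_width = bin_width,
                 refine_oligomer = refine_oligomer, polish = polish,
                 polish_maxit = as.integer(polish_maxit),
                 hydrate = hydrate,
                 hydrate_every = as.integer(hydrate_every),
                 dummy_b = dummy_b),
            class = "fit_config")
}

## rotation matrix back to a 3-vector axis-angle (inverse of
## axis_angle_matrix); robust at 0 and pi
axis_angle_from_matrix <- function(R) {
  tr <- sum(diag(R))
  ct <- max(-1, min(1, (tr - 1) / 2))
  th <- acos(ct)
  if (th < 1e-10) return(c(0, 0, 0))
  if (abs(pi - th) > 1e-6) {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(th))
  } else {
    # near pi: axis from the symmetric part B = (R + I)/2 = I - (1-c) +
    # uu^T ... u u^T = B up to O(pi - th)
    B <- (R + diag(3)) / 2
    i <- which.max(diag(B))
    ax <- B[i, ] / sqrt(max(B[i, i], 1e-12))
    ax <- ax / sqrt(sum(ax^2))
  }
  ax * th
}

## compose a collective rigid move (rotation R0 about point g, then
## translation t0) onto the per-body transforms of the given bodies
compose_collective <- function(state, body_indices, half, which_bodies,
                               R0, g, t0) {
  for (k in which_bodies) {
    ck <- colMeans(half$xyz[body_indices[[k]], , drop = FALSE])
    Rk <- axis_angle_matrix(state[[k]]$rot)
    tk <- state[[k]]$trans
    Rn <- R0 %*% Rk
    tn <- as.numeric(R0 %*% (ck + tk - g)) + g + t0 - ck
    state[[k]]$rot <- axis_angle_from_matrix(Rn)
    state[[k]]$trans <- tn
  }
  state
}

## axis-angle (3-vector, radians) to rotation matrix
axis_angle_matrix <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  u <- v / th
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Identity body state for a partitioned half structure
#'
#' A body state stores one rigid transform per body of the asymmetric half:
#' an axis-angle rotation (3-vector, radians, about the body centroid) and a
#' translation (3-vector, Angstrom).  The identity state reproduces the
#' input structure exactly.
#'
#' @param body_indices list of per-body index vectors into the half
#'   structure (from [partition_bodies]).
#' @return An object of class `body_state`: list of `list(rot, trans)`.
#' @export
body_state_identity <- function(body_indices) {
  structure(lapply(body_indices, function(i)
    list(rot = c(0, 0, 0), trans = c(0, 0, 0))), class = "body_state")
}

#' Apply a body state to the asymmetric half
#'
#' Rotates each body about its (reference) centroid and translates it; the
#' C2 symmetry mate is regenerated from the transformed half.
#'
#' @param half the reference half [coarse_structure].
#' @param body_indices per-body index vectors into `half`.
#' @param state a `body_state`.
#' @return The transformed half structure.
#' @export
apply_body_state <- function(half, body_indices, state) {
  out <- half
  for (k in seq_along(body_indices)) {
    # identity transforms reproduce the input bit-exactly
    if (all(state[[k]]$rot == 0) && all(state[[k]]$trans == 0)) next
    idx <- body_indices[[k]]
    ctr <- colMeans(half$xyz[idx, , drop = FALSE])
    R <- axis_angle_matrix(state[[k]]$rot)
    out$xyz[idx, ] <- sweep(sweep(half$xyz[idx, , drop = FALSE], 2, ctr) %*%
                              t(R), 2, ctr + state[[k]]$trans, `+`)
  }
  out
}

## assemble the full model from a transformed half
assemble_model <- function(half_t, symmetry, axis) {
  if (symmetry == "C2") apply_c2(half_t, axis$point, axis$direction)
  else half_t
}

## forward intensity of a model on the curve's q grid
model_intensity <- function(model, oligomer, q, config) {
  P <- form_factor_debye(model, q, config$sigma_smear,
                         method = "histogram", bin_width = config$bin_width)
  A <- amplitude_cm(model, q, config$sigma_smear)
  S <- structure_factor(q, N = oligomer$N, D = oligomer$D)
  P + A^2 * (S - 1)
}

#' Combined refinement objective
#'
#' chi2_red (with analytic scale) + restraint penalty + excluded-volume
#' penalty for one candidate state; the components are returned separately.
#'
#' @param half reference half structure.
#' @param body_indices per-body index vectors.
#' @param state a `body_state`.
#' @param oligomer an [oligomer_model].
#' @param curve a [saxs_curve].
#' @param scheme the [body_scheme] (symmetry + restraints).
#' @param axis C2 axis, `list(point, direction)`.
#' @param restraints resolved restraints (on the full model's indexing).
#' @param config a [fit_config].
#' @param n_free number of free parameters for the chi2 denominator.
#' @return List with `objective`, `chi2_reduced`, `scale`, `restraint`,
#'   `excluded_volume`, and the assembled `model`.
#' @export
refine_objective <- function(half, body_indices, state, oligomer, curve,
                             scheme, axis, restraints, config, n_free) {
  half_t <- apply_body_state(half, body_indices, state)
  model <- assemble_model(half_t, scheme$symmetry, axis)
  if (config$hydrate)
    model <- add_hydration_layer(model, dummy_b = config$dummy_b)
  Im <- model_intensity(model, oligomer, curve$q, config)
  cf <- chi2_reduced(Im, curve, n_free)
  rp <- config$restraint_weight *
    restraint_penalty(model, restraints)
  # bodies in the full model: half bodies + their C2 mates
  nb <- length(body_indices)
  nh <- n_centers(half)
  full_idx <- body_indices
  if (scheme$symmetry == "C2")
    full_idx <- c(body_indices, lapply(body_indices, function(i) i + nh))
  ev <- excluded_volume_penalty(model, full_idx, config$ev_cutoff,
                                config$ev_weight)
  list(objective = cf$chi2_reduced + rp + ev,
       chi2_reduced = cf$chi2_reduced, scale = cf$scale,
       restraint = rp, excluded_volume = ev, model = model)
}

#' Restrained C2-symmetric rigid-body refinement against a SAXS curve
#'
#' Multi-start simulated annealing over per-body rigid transforms of the
#' asymmetric half (the symmetry mate is regenerated at every evaluation,
#' so every candidate model is exactly C2-symmetric) and, simultaneously,
#' over the oligomerization parameters N and D of the structure factor.
#' The objective is reduced chi-square (analytic scale) plus harmonic
#' distance restraints and a soft excluded-volume term.  The run with the
#' lowest final reduced chi-square out of `config$n_runs` is returned as
#' the representative model; results are deterministic given the seed.
#'
#' @param half the asymmetric half [coarse_structure] (for
#'   `symmetry = "none"` schemes, the whole model).
#' @param scheme a [body_scheme].
#' @param curve a [saxs_curve].
#' @param config a [fit_config].
#' @param axis C2 axis as `list(point =, direction =)`; required when the
#'   scheme has C2 symmetry.
#' @param oligomer_start starting [oligomer_model] (default N = 1.5, D =
#'   the model Rg times 2, clipped to bounds).
#' @param start_state optional `body_state` start (default identity).
#' @return An object of class `saxs_fit`.
#' @export
refine_rigid_body <- function(half, scheme, curve, config = fit_config(),
                              axis = NULL, oligomer_start = NULL,
                              start_state = NULL) {
  if (scheme$symmetry == "C2" && is.null(axis))
    stop("a C2 scheme needs an axis (list(point, direction))")
  body_indices <- partition_bodies(half, scheme)
  nb <- length(body_indices)
  n_free <- 1L + 6L * nb + if (config$refine_oligomer) 2L else 0L
  # resolve restraints on the reference full model
  ref_model <- assemble_model(half, scheme$symmetry, axis)
  restraints <- if (!is.null(scheme$restraints))
    resolve_restraints(ref_model, scheme$restraints) else NULL
  if (is.null(oligomer_start)) {
    d0 <- min(max(2 * model_rg(ref_model), config$d_bounds[1]),
              config$d_bounds[2])
    oligomer_start <- oligomer_model(N = min(max(1.5, config$n_bounds[1]),
                                             config$n_bounds[2]), D = d0)
  }
  if (is.null(start_state)) start_state <- body_state_identity(body_indices)

  reflect <- function(x, lo, hi) {
    for (it in 1:10) {
      if (x < lo) x <- lo + (lo - x) else if (x > hi) x <- hi - (x - hi)
      if (x >= lo && x <= hi) break
    }
    min(max(x, lo), hi)
  }
  eval_state <- function(state, olig) {
    refine_objective(half, body_indices, state, olig, curve, scheme, axis,
                     restraints, config, n_free)
  }

  body_chain <- vapply(body_indices, function(i)
    half$chain[i[1]], character(1))
  chains <- unique(body_chain)

  one_run <- function(run_seed) {
    set.seed(run_seed)
    state <- start_state
    olig <- oligomer_start
    cur <- eval_state(state, olig)
    best <- list(state = state, olig = olig, eval = cur)
    temp <- config$t0
    for (iter in seq_len(config$max_iter)) {
      prop_state <- state
      prop_olig <- olig
      # proposal sizes shrink with the temperature for a fine final search
      sc <- max(0.1, sqrt(temp / config$t0))
      u <- stats::runif(1)
      if (config$refine_oligomer && u < 0.15) {
        prop_olig$N <- reflect(olig$N * exp(stats::rnorm(1, 0, sc * 0.05)),
                               config$n_bounds[1], config$n_bounds[2])
        prop_olig$D <- reflect(olig$D * exp(stats::rnorm(1, 0, sc * 0.05)),
                               config$d_bounds[1], config$d_bounds[2])
      } else {
        # hierarchical rigid moves: one body, one whole chain, or the
        # whole half -- collective modes are essential because domain
        # clusters move coherently while keeping their contacts
        v <- stats::runif(1)
        grp <- if (v < 0.6 || nb == 1L) {
          sample.int(nb, 1L)
        } else if (v < 0.85) {
          which(body_chain == chains[sample.int(length(chains), 1L)])
        } else seq_len(nb)
        rot <- stats::rnorm(3, 0, sc * config$step_rot * pi / 180)
        trans <- stats::rnorm(3, 0, sc * config$step_trans)
        if (length(grp) == 1L) {
          prop_state[[grp]]$rot <- state[[grp]]$rot + rot
          prop_state[[grp]]$trans <- state[[grp]]$trans + trans
        } else {
          half_t <- apply_body_state(half, body_indices, state)
          g <- colMeans(half_t$xyz[unlist(body_indices[grp]), ,
                                   drop = FALSE])
          prop_state <- compose_collective(state, body_indices, half, grp,
                                           axis_angle_matrix(rot), g, trans)
        }
      }
      prop <- eval_state(prop_state, prop_olig)
      accept <- prop$objective <= cur$objective ||
        stats::runif(1) < exp((cur$objective - prop$objective) / temp)
      if (accept) {
        state <- prop_state; olig <- prop_olig; cur <- prop
        if (cur$objective < best$eval$objective)
          best <- list(state = state, olig = olig, eval = cur)
      }
      temp <- temp * config$cool
    }
    best$seed <- run_seed
    best
  }

  runs <- lapply(seq_len(config$n_runs), function(k) one_run(config$seed + k - 1L))
  per_run <- data.frame(
    run = seq_len(config$n_runs),
    seed = vapply(runs, `[[`, numeric(1), "seed"),
    chi2_reduced = vapply(runs, function(r) r$eval$chi2_reduced, numeric(1)),
    objective = vapply(runs, function(r) r$eval$objective, numeric(1)),
    N = vapply(runs, function(r) r$olig$N, numeric(1)),
    D = vapply(runs, function(r) r$olig$D, numeric(1)))
  ibest <- which.min(per_run$chi2_reduced)
  best <- runs[[ibest]]
  if (config$polish) {
    # derivative-free local polish of the selected run (deterministic)
    with_olig <- config$refine_oligomer
    pack <- function(state, olig) {
      v <- unlist(lapply(state, function(s) c(s$rot, s$trans)))
      if (with_olig) v <- c(v, log(max(olig$N - 1, 1e-8)), log(olig$D))
      v
    }
    unpack <- function(v) {
      st <- vector("list", nb)
      for (k in seq_len(nb))
        st[[k]] <- list(rot = v[(k - 1) * 6 + 1:3],
                        trans = v[(k - 1) * 6 + 4:6])
      class(st) <- "body_state"
      olig <- if (with_olig) {
        oligomer_model(
          min(max(1 + exp(v[nb * 6 + 1]), config$n_bounds[1]),
              config$n_bounds[2]),
          min(max(exp(v[nb * 6 + 2]), config$d_bounds[1]),
              config$d_bounds[2]))
      } else best$olig
      list(state = st, olig = olig)
    }
    op <- stats::optim(pack(best$state, best$olig), function(v) {
      u <- unpack(v)
      eval_state(u$state, u$olig)$objective
    }, method = "Nelder-Mead",
    control = list(maxit = config$polish_maxit))
    u <- unpack(op$par)
    cand <- eval_state(u$state, u$olig)
    if (cand$objective <= best$eval$objective) {
      best <- list(state = u$state, olig = u$olig, eval = cand,
                   seed = best$seed)
      # the polished endpoint is the selected run's final result
      per_run$chi2_reduced[ibest] <- cand$chi2_reduced
      per_run$objective[ibest] <- cand$objective
      per_run$N[ibest] <- u$olig$N
      per_run$D[ibest] <- u$olig$D
    }
  }
  # final model, with exact hydration regeneration if enabled
  final <- eval_state(best$state, best$olig)
  structure(list(state = best$state, oligomer = best$olig,
                 scale = final$scale, chi2_reduced = final$chi2_reduced,
                 restraint = final$restraint,
                 excluded_volume = final$excluded_volume,
                 objective = final$objective, model = final$model,
                 per_run = per_run, best_run = ibest,
                 n_free_params = n_free,
                 converged = final$chi2_reduced <= 10,
                 config = config),
            class = "saxs_fit")
}

#' @export
print.saxs_fit <- function(x, ...) {
  cat(sprintf(
    "saxs_fit: chi2_red = %.3f (best of %d runs), N = %.3f, D = %.1f A\n",
    x$chi2_reduced, nrow(x$per_run), x$oligomer$N, x$oligomer$D))
  cat(sprintf("  restraint = %.4g, excluded volume = %.4g, scale = %.4g\n",
              x$restraint, x$excluded_volume, x$scale))
  if (!x$converged) cat("  WARNING: flagged non-converged\n")
  invisible(x)
}

#' Write a fit report as JSON (with per-run table)
#'
#' @param fit a `saxs_fit`.
#' @param file output path.
#' @export
write_fit_report <- function(fit, file) {
  jsonlite::write_json(
    list(chi2_reduced = fit$chi2_reduced, N = fit$oligomer$N,
         D = fit$oligomer$D, scale = fit$scale,
         restraint_penalty = fit$restraint,
         excluded_volume_penalty = fit$excluded_volume,
         best_run = fit$best_run, n_free_params = fit$n_free_params,
         converged = fit$converged, per_run = fit$per_run),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
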