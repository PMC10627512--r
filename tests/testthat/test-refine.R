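test_that("reduced chi-square profiles the scale analytically", {
  q <- qgrid_default(100)
  I <- exp(-q^2 * 120)
  cv <- saxs_curve(q, I, 0.05 * I)
  # model == data: perfect fit at unit scale
  cf <- chi2_reduced(I, cv, 1)
  expect_equal(cf$scale, 1, tolerance = 1e-12)
  expect_equal(cf$chi2_reduced, 0, tolerance = 1e-12)
  # data = 2 x model: scale absorbs it exactly
  cf2 <- chi2_reduced(I / 2, cv, 1)
  expect_equal(cf2$scale, 2, tolerance = 1e-12)
  expect_equal(cf2$chi2_reduced, 0, tolerance = 1e-12)
  # unit-sigma Gaussian residuals: chi2_red ~ 1
  set.seed(99)
  n <- 200
  y <- rep(100, n)
  cvn <- saxs_curve(seq_len(n) / 1000, y + stats::rnorm(n), rep(1, n))
  expect_lt(abs(chi2_reduced(y, cvn, 1)$chi2_reduced - 1), 0.2)
  expect_error(chi2_reduced(I[1:3], saxs_curve(q[1:3], I[1:3],
                                               0.1 * I[1:3]), 5),
               "more points")
})

test_that("restraint penalty is harmonic about reference distances", {
  bundle <- hexamer_bundle()
  restr <- resolve_restraints(bundle$structure, bundle$scheme$restraints)
  expect_equal(restraint_penalty(bundle$structure, restr), 0)
  # displace one anchor 2 A along the inter-anchor axis: penalty = w * 4
  moved <- bundle$structure
  ia <- restr$idx_a[1]; ib <- restr$idx_b[1]
  u <- moved$xyz[ib, ] - moved$xyz[ia, ]
  u <- u / sqrt(sum(u^2))
  moved$xyz[ia, ] <- moved$xyz[ia, ] - 2 * u
  expect_equal(restraint_penalty(moved, restr), restr$weight[1] * 4,
               tolerance = 1e-9)
  # unresolvable anchor names the culprit
  bad <- data.frame(chain_a = "A", resno_a = 9999L, chain_b = "B",
                    resno_b = 1L, weight = 1, target = NA_real_)
  expect_error(resolve_restraints(bundle$structure, bad), "A9999")
})

test_that("excluded-volume penalty is a continuous soft-core clash term", {
  # two single-center bodies 2 A apart, cutoff 4: (4 - 2)^2 = 4
  two <- coarse_structure(rbind(c(0, 0, 0), c(2, 0, 0)), chain = c("A", "B"),
                          resno = c(1L, 1L))
  expect_equal(excluded_volume_penalty(two, list(1L, 2L), 4, 1), 4)
  # separated bodies: zero
  far <- coarse_structure(rbind(c(0, 0, 0), c(10, 0, 0)),
                          chain = c("A", "B"), resno = c(1L, 1L))
  expect_equal(excluded_volume_penalty(far, list(1L, 2L), 4, 1), 0)
  # continuous at the cutoff
  eps <- 1e-6
  near <- coarse_structure(rbind(c(0, 0, 0), c(4 - eps, 0, 0)),
                           chain = c("A", "B"), resno = c(1L, 1L))
  expect_lt(excluded_volume_penalty(near, list(1L, 2L), 4, 1), 1e-10)
  # intra-body pairs ignored
  intra <- coarse_structure(rbind(c(0, 0, 0), c(1, 0, 0), c(50, 0, 0)),
                            chain = "A", resno = 1:3)
  expect_equal(excluded_volume_penalty(intra, list(1:2, 3L), 4, 1), 0)
  # compiled cell-list kernel agrees with a brute-force R oracle
  set.seed(31)
  xyz <- matrix(stats::runif(300, 0, 25), ncol = 3)
  body <- rep(1:4, each = 25)
  d <- as.matrix(stats::dist(xyz))
  pen_r <- 0
  for (i in 1:99) for (j in (i + 1):100)
    if (body[i] != body[j] && d[i, j] < 4) pen_r <- pen_r + (4 - d[i, j])^2
  cs <- coarse_structure(xyz, chain = "A", resno = 1:100)
  expect_equal(excluded_volume_penalty(cs, split(1:100, body), 4, 1), pen_r,
               tolerance = 1e-9)
})

test_that("objective is chi2 plus non-negative penalties, zero at truth", {
  bundle <- hexamer_bundle(rel_sigma = 0)      # noiseless self-simulation
  bi <- bundle$body_indices
  restr <- resolve_restraints(bundle$structure, bundle$scheme$restraints)
  cfg <- fit_config()
  ev <- refine_objective(bundle$half, bi, body_state_identity(bi),
                         oligomer_model(1.8, 80), bundle$curve,
                         bundle$scheme, bundle$axis, restr, cfg, 45L)
  expect_lt(ev$objective, 1e-6)
  expect_equal(ev$scale, 1, tolerance = 1e-6)
  # any state: objective >= chi2 component
  st <- perturb_bodies(body_state_identity(bi), 5, 5, seed = 3)
  ev2 <- refine_objective(bundle$half, bi, st, oligomer_model(1.8, 80),
                          bundle$curve, bundle$scheme, bundle$axis, restr,
                          cfg, 45L)
  expect_gte(ev2$objective, ev2$chi2_reduced)
  expect_gte(ev2$restraint, 0)
  expect_gte(ev2$excluded_volume, 0)
  # pushing one body into another monotonically raises the clash term
  # (bodies start ~46 A apart with radii ~15 A: contact begins near 16 A)
  pens <- vapply(c(0, 18, 26, 34), function(s) {
    st <- body_state_identity(bi)
    ctr_b <- colMeans(bundle$half$xyz[bi$HipS, ])
    ctr_c <- colMeans(bundle$half$xyz[bi$`HipT-core`, ])
    st$HipS$trans <- (ctr_c - ctr_b) / sqrt(sum((ctr_c - ctr_b)^2)) * s
    refine_objective(bundle$half, bi, st, oligomer_model(1.8, 80),
                     bundle$curve, bundle$scheme, bundle$axis, restr,
                     cfg, 45L)$excluded_volume
  }, numeric(1))
  expect_equal(pens[1], 0)
  expect_gt(pens[2], 0)
  expect_true(all(diff(pens[2:4]) > 0))
})

test_that("body states transform rigidly and identity is exact", {
  bundle <- hexamer_bundle()
  bi <- bundle$body_indices
  id <- body_state_identity(bi)
  expect_identical(apply_body_state(bundle$half, bi, id)$xyz,
                   bundle$half$xyz)
  # a transform moves only its own body, preserving internal distances
  st <- id
  st[[2]]$rot <- c(0.1, -0.2, 0.3)
  st[[2]]$trans <- c(3, -1, 2)
  moved <- apply_body_state(bundle$half, bi, st)
  others <- setdiff(seq_len(n_centers(bundle$half)), bi[[2]])
  expect_identical(moved$xyz[others, ], bundle$half$xyz[others, ])
  d0 <- as.numeric(stats::dist(bundle$half$xyz[bi[[2]][1:50], ]))
  d1 <- as.numeric(stats::dist(moved$xyz[bi[[2]][1:50], ]))
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("refinement from the truth state stays at the truth", {
  bundle <- hexamer_bundle(rel_sigma = 0)
  cfg <- fit_config(n_runs = 1, seed = 2, max_iter = 60, polish = FALSE)
  fit <- refine_rigid_body(bundle$half, bundle$scheme, bundle$curve, cfg,
                           axis = bundle$axis,
                           oligomer_start = oligomer_model(1.8, 80))
  expect_lt(fit$chi2_reduced, 1e-6)
  errs <- body_centroid_errors(bundle, fit)
  expect_lt(max(errs), 0.1)
})

test_that("every refined model is exactly C2 symmetric", {
  bundle <- hexamer_bundle()
  cfg <- fit_config(n_runs = 1, seed = 3, max_iter = 25, polish = FALSE)
  fit <- refine_rigid_body(bundle$half, bundle$scheme, bundle$curve, cfg,
                           axis = bundle$axis,
                           start_state = bundle$start_state)
  m <- fit$model
  n2 <- n_centers(m) / 2
  img <- saxsrb:::rotate_about_axis(m$xyz[seq_len(n2), ],
                                    bundle$axis$point,
                                    bundle$axis$direction, pi)
  expect_lt(max(abs(img - m$xyz[n2 + seq_len(n2), ])), 1e-9)
})

test_that("refinement is deterministic and selects the best run", {
  bundle <- hexamer_bundle()
  cfg <- fit_config(n_runs = 3, seed = 7, max_iter = 30, polish = FALSE)
  f1 <- refine_rigid_body(bundle$half, bundle$scheme, bundle$curve, cfg,
                          axis = bundle$axis,
                          start_state = bundle$start_state)
  f2 <- refine_rigid_body(bundle$half, bundle$scheme, bundle$curve, cfg,
                          axis = bundle$axis,
                          start_state = bundle$start_state)
  expect_identical(f1$per_run, f2$per_run)
  expect_identical(f1$state, f2$state)
  expect_identical(f1$oligomer, f2$oligomer)
  # reported chi2 equals the per-run minimum
  expect_equal(f1$chi2_reduced, min(f1$per_run$chi2_reduced),
               tolerance = 1e-12)
  expect_equal(f1$best_run, which.min(f1$per_run$chi2_reduced))
})

test_that("fit report serializes to JSON", {
  bundle <- hexamer_bundle()
  cfg <- fit_config(n_runs = 2, seed = 5, max_iter = 10, polish = FALSE)
  fit <- refine_rigid_body(bundle$half, bundle$scheme, bundle$curve, cfg,
                           axis = bundle$axis)
  tf <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, tf)
  rep <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_equal(rep$chi2_reduced, fit$chi2_reduced)
  expect_equal(nrow(rep$per_run), 2)
})
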