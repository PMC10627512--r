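test_that("Debye form factor reproduces closed-form limits", {
  q <- qgrid_default(60)
  # single center: only the smearing Gaussian survives
  one <- coarse_structure(matrix(c(5, 5, 5), 1), chain = "A", resno = 1)
  expect_equal(form_factor_debye(one, q, sigma_smear = 1), exp(-q^2),
               tolerance = 1e-12)
  # two equal centers 50 A apart at q = pi/50: sinc vanishes -> P = 1/2
  two <- coarse_structure(rbind(c(0, 0, 0), c(50, 0, 0)), chain = "A",
                          resno = 1:2)
  expect_equal(form_factor_debye(two, pi / 50, sigma_smear = 0), 0.5,
               tolerance = 1e-12)
  # P(0) = 1 exactly
  expect_equal(form_factor_debye(two, c(0, 0.01), sigma_smear = 0)[1], 1)
  # lattice sphere vs analytic sphere form factor (at the lattice's own
  # effective radius; the relative error is ill-conditioned only at the
  # analytic zero x = 4.493)
  sph <- lattice_sphere(30, 1.5)
  Reff <- sqrt(5 / 3) * model_rg(sph)
  P <- form_factor_debye(sph, q, sigma_smear = 0, method = "histogram",
                         bin_width = 0.25)
  x <- q * Reff
  sel <- x <= 4.4 & x > 0
  expect_lt(max(abs(P[sel] - sphere_ff(x[sel])) / sphere_ff(x[sel])), 0.01)
})

test_that("form factor is invariant under rigid motion", {
  set.seed(21)
  cs <- coarse_structure(matrix(stats::rnorm(600, 0, 12), ncol = 3),
                         chain = "A", resno = 1:200)
  q <- qgrid_default(40)
  P0 <- form_factor_debye(cs, q)
  A0 <- amplitude_cm(cs, q)
  for (s in 1:3) {
    rr <- random_rigid(cs, seed = s)
    expect_lt(max(abs(form_factor_debye(rr, q) - P0) / P0), 1e-10)
    expect_lt(max(abs(amplitude_cm(rr, q) - A0)), 1e-10)
  }
})

test_that("histogram-accelerated Debye sum matches the direct sum", {
  set.seed(8)
  spec <- scenario_spec("sphere", sphere_n = 2000, sphere_radius = 30,
                        seed = 8)
  sph <- make_bead_complex(spec)
  q <- qgrid_default(120)
  Pd <- form_factor_debye(sph, q, sigma_smear = 0, method = "direct")
  Ph <- form_factor_debye(sph, q, sigma_smear = 0, method = "histogram",
                          bin_width = 0.5)
  expect_lt(max(abs(Ph - Pd) / Pd), 1e-3)
  # two-center structure: binning error bounded by construction
  two <- coarse_structure(rbind(c(0, 0, 0), c(37.3, 0, 0)), chain = "A",
                          resno = 1:2)
  expect_equal(histogram_debye(two, q, sigma_smear = 0),
               form_factor_debye(two, q, sigma_smear = 0),
               tolerance = 1e-6)
  # refining the bins converges monotonically (within noise) to the oracle
  errs <- vapply(c(2, 1, 0.5, 0.25), function(bw)
    max(abs(form_factor_debye(sph, q, 0, "histogram", bw) - Pd) / Pd),
    numeric(1))
  expect_true(all(diff(errs) < 1e-6))
  expect_lt(errs[4], 1e-4)
})

test_that("CM amplitude obeys normalization, symmetry and Cauchy-Schwarz", {
  q <- qgrid_default(80)
  # single center at its own CM: pure Gaussian
  one <- coarse_structure(matrix(0, 1, 3), chain = "A", resno = 1)
  expect_equal(amplitude_cm(one, q, sigma_smear = 1), exp(-q^2 / 2),
               tolerance = 1e-12)
  # <A(0)> = 1 for any structure
  set.seed(4)
  cs <- coarse_structure(matrix(stats::rnorm(300, 0, 9), ncol = 3),
                         b = stats::runif(100, 0.5, 2), chain = "A",
                         resno = 1:100)
  expect_equal(amplitude_cm(cs, c(0, 0.05), 0)[1], 1)
  # spherical symmetry: <A>^2 ~ P for the sphere at low q
  sph <- lattice_sphere(30, 1.5)
  A <- amplitude_cm(sph, q, 0)
  P <- form_factor_debye(sph, q, 0, "histogram", 0.25)
  sel <- q * 30 <= 4 & q > 0
  expect_lt(max(abs(A[sel]^2 - P[sel]) / P[sel]), 0.01)
  # Cauchy-Schwarz: <A>^2 <= P at every q, also for asymmetric structures
  Pa <- form_factor_debye(cs, q, 1.0)
  Aa <- amplitude_cm(cs, q, 1.0)
  expect_true(all(Aa^2 <= Pa + 1e-12))
})

test_that("structure factor has exact limits and values", {
  q <- qgrid_default(100)
  # N = 1: no interference, S identically 1
  expect_equal(structure_factor(q, N = 1, D = 80), rep(1, length(q)))
  # S(0) -> N
  expect_equal(structure_factor(c(0, 1e-9, 0.01), N = 1.8, D = 80)[1], 1.8)
  # direct formula value at the partial-dimer anchor point
  expect_equal(structure_factor(0.01, N = 1.8, D = 80),
               1 + 0.8 * sin(0.8) / 0.8, tolerance = 1e-12)
  # decay to 1 at large qD
  expect_lt(abs(structure_factor(2, N = 1.8, D = 80) - 1), 0.01)
  expect_error(structure_factor(q, N = 0.5, D = 80), "N must be")
  expect_error(structure_factor(q, N = 2, D = -1), "D must be")
})

test_that("decoupling approximation combines components correctly", {
  set.seed(12)
  cs <- coarse_structure(matrix(stats::rnorm(450, 0, 10), ncol = 3),
                         chain = "A", resno = 1:150)
  q <- qgrid_default(60)
  # monomer limit: identical to the bare form factor
  mono <- intensity_decoupled(cs, oligomer_model(1, 80), q)
  expect_equal(mono$I, form_factor_debye(cs, q), tolerance = 1e-12)
  # forward scattering reports the oligomer mass: I(0)/scale = N
  ic <- intensity_decoupled(cs, oligomer_model(1.8, 80), c(0, q),
                            scale = 2.5)
  expect_equal(ic$I[1] / 2.5, 1.8, tolerance = 1e-12)
  # single point particle: decoupling is exact, I = scale e^{-q^2 s^2} S(q)
  one <- coarse_structure(matrix(c(1, 1, 1), 1), chain = "A", resno = 1)
  ic1 <- intensity_decoupled(one, oligomer_model(1.7, 60), q,
                             sigma_smear = 1, scale = 3)
  expect_equal(ic1$I, 3 * exp(-q^2) * structure_factor(q, N = 1.7, D = 60),
               tolerance = 1e-12)
})

test_that("low-q Guinier expansion of the model matches its Rg", {
  sph <- make_bead_complex(scenario_spec("sphere", sphere_n = 1500,
                                         sphere_radius = 25, seed = 13))
  rg <- model_rg(sph)
  q <- seq(0.001, 0.012, length.out = 30)
  P <- form_factor_debye(sph, q, sigma_smear = 0)
  slope <- unname(stats::coef(stats::lm(log(P) ~ I(q^2)))[2])
  expect_equal(sqrt(-3 * slope), rg, tolerance = 0.01)
})

test_that("model curves write as readable three-column text", {
  cs <- coarse_structure(matrix(stats::rnorm(90, 0, 8), ncol = 3),
                         chain = "A", resno = 1:30)
  ic <- intensity_decoupled(cs, oligomer_model(1.8, 80), qgrid_default(40))
  tf <- withr::local_tempfile(fileext = ".dat")
  write_intensity(ic, tf, sidecar = TRUE)
  expect_warning(back <- read_saxs(tf), "sigma")  # zero errors replaced
  expect_equal(back$q, ic$q, tolerance = 1e-6)
  expect_equal(back$I, ic$I, tolerance = 1e-6)
  side <- jsonlite::read_json(paste0(tf, ".json"), simplifyVector = TRUE)
  expect_equal(unname(side$S[1]), ic$S[1], tolerance = 1e-9)
})
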