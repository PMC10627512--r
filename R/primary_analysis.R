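#' SAXS curve container
#'
#' A measured (or simulated) 1-D SAXS curve: q in inverse Angstrom,
#' intensity I (absolute cm^-1 or relative units) and 1-sigma errors in the
#' same units as I.
#'
#' @param q,I,sigma equal-length numeric vectors; q ascending and >= 0,
#'   sigma > 0.  If `sigma` is `NULL` it is set to 1 percent of I with a
#'   warning.
#' @return A data.frame of class `saxs_curve`.
#' @export
saxs_curve <- function(q, I, sigma = NULL) {
  if (is.null(sigma)) {
    warning("no errors supplied; sigma set to 1% of I")
    sigma <- 0.01 * abs(I)
  }
  stopifnot(length(q) == length(I), length(I) == length(sigma))
  if (any(!is.finite(q)) || any(q < 0)) stop("q must be finite and >= 0")
  if (is.unsorted(q, strictly = TRUE)) stop("q must be strictly ascending")
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  structure(data.frame(q = q, I = I, sigma = sigma),
            class = c("saxs_curve", "data.frame"))
}

#' Read a three-column SAXS data file
#'
#' Whitespace-delimited `q I sigma` text with '#' comments ignored; a
#' missing third column is replaced by 1 percent errors with a warning.
#'
#' @param file path.
#' @param q_unit `"A"` for inverse Angstrom (default) or `"nm"` for inverse
#'   nanometre (converted to inverse Angstrom on read).
#' @return A [saxs_curve].
#' @export
read_saxs <- function(file, q_unit = c("A", "nm")) {
  q_unit <- match.arg(q_unit)
  dat <- utils::read.table(file, comment.char = "#",
                           col.names = c("q", "I", "sigma")[1:3],
                           fill = TRUE, header = FALSE)
  q <- dat[[1]]
  if (q_unit == "nm") q <- q / 10
  sigma <- if (ncol(dat) >= 3 && !all(is.na(dat[[3]])) &&
                 any(dat[[3]] > 0)) dat[[3]] else NULL
  saxs_curve(q, dat[[2]], sigma)
}

#' @rdname read_saxs
#' @param curve a [saxs_curve].
#' @export
write_saxs <- function(curve, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# q(1/A)  I  sigma", con)
  utils::write.table(format(as.data.frame(curve)[c("q", "I", "sigma")],
                            digits = 8, scientific = TRUE),
                     con, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}

#' Guinier analysis
#'
#' Weighted linear regression of ln I against q^2 over the largest low-q
#' window satisfying q * Rg <= `qrg_max`, iterated to self-consistency
#' (the fitted Rg defines the window that must reproduce it).  Returns
#' Rg = sqrt(-3 * slope) and I0 = exp(intercept).
#'
#' @param curve a [saxs_curve].
#' @param qrg_max Guinier window limit (default 1.3, the usual convention
#'   for globular particles).
#' @param qmin optional lower q cutoff (drop beamstop-contaminated points).
#' @return An object of class `guinier_result` with fields `rg`, `i0`,
#'   `fit_range`, `n_points`, `r_squared`.
#' @export
guinier_fit <- function(curve, qrg_max = 1.3, qmin = NULL) {
  dat <- as.data.frame(curve)
  if (!is.null(qmin)) dat <- dat[dat$q >= qmin, , drop = FALSE]
  if (nrow(dat) < 5L) stop("need at least 5 points")
  fit_window <- function(n) {
    w <- dat[seq_len(n), ]
    if (any(w$I <= 0))
      stop("non-positive intensities in the Guinier window")
    wt <- (w$I / w$sigma)^2           # var(ln I) = (sigma/I)^2
    fm <- stats::lm(log(I) ~ I(q^2), data = w, weights = wt)
    slope <- stats::coef(fm)[2]
    if (slope >= 0) return(NULL)      # not Guinier-like at this window
    list(rg = sqrt(-3 * slope), i0 = exp(stats::coef(fm)[1]),
         r2 = summary(fm)$r.squared, n = n)
  }
  n <- nrow(dat)
  last_n <- -1L
  res <- NULL
  for (iter in 1:100) {
    res <- fit_window(n)
    if (is.null(res)) {
      n <- max(5L, n - max(1L, n %/% 5L))
      if (n == last_n) break
      last_n <- n
      next
    }
    n_new <- max(5L, sum(dat$q * res$rg <= qrg_max))
    if (n_new == n) break
    if (n_new == last_n) { n <- min(n, n_new); last_n <- -2L; next }
    last_n <- n
    n <- n_new
  }
  if (is.null(res)) stop("no self-consistent Guinier window found")
  structure(list(rg = unname(res$rg), i0 = unname(res$i0),
                 fit_range = c(dat$q[1], dat$q[res$n]),
                 n_points = res$n, r_squared = res$r2,
                 qrg_max = qrg_max),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf(
    "Guinier fit: Rg = %.2f A, I0 = %.4g (%d pts, q in [%.4f, %.4f], R^2 = %.4f)\n",
    x$rg, x$i0, x$n_points, x$fit_range[1], x$fit_range[2], x$r_squared))
  invisible(x)
}

#' Molar mass from forward scattering
#'
#' M = I0 * N_A / (c * delta_rho_m^2), with I0 the forward scattering on
#' absolute scale (cm^-1), c the mass concentration (g cm^-3), and
#' delta_rho_m the excess scattering length per unit mass (default
#' 2.00e10 cm g^-1, the typical value for proteins).
#'
#' @param I0 forward scattering, cm^-1.
#' @param c mass concentration, g cm^-3.
#' @param delta_rho_m excess scattering length per mass, cm g^-1.
#' @return An object of class `mass_estimate` with `M` in g mol^-1.
#' @export
molar_mass_from_i0 <- function(I0, c, delta_rho_m = 2.00e10) {
  if (I0 <= 0 || c <= 0 || delta_rho_m <= 0)
    stop("I0, c and delta_rho_m must all be positive")
  NA_const <- 6.02214076e23
  structure(list(M = I0 * NA_const / (c * delta_rho_m^2),
                 I0 = I0, c = c, delta_rho_m = delta_rho_m,
                 N_A = NA_const),
            class = "mass_estimate")
}

#' @export
print.mass_estimate <- function(x, ...) {
  cat(sprintf("molar mass: %.4g g/mol (I0 = %.4g 1/cm, c = %.3g g/cm^3)\n",
              x$M, x$I0, x$c))
  invisible(x)
}

## IFT design matrix: I(q) = 4*pi * sum_j p(r_j) sinc(q r_j) dr
ift_design <- function(q, r, dr) {
  A <- outer(q, r, function(qq, rr) {
    x <- qq * rr
    ifelse(x < 1e-12, 1, sin(x) / ifelse(x == 0, 1, x))
  })
  4 * pi * A * dr
}

## returns NULL when the active-set solver fails to converge at this alpha
ift_solve <- function(Aw, yw, L, alpha, nonneg) {
  M <- rbind(Aw, sqrt(alpha) * L)
  y <- c(yw, rep(0, nrow(L)))
  if (nonneg) {
    tryCatch(as.numeric(pracma::lsqnonneg(M, y)$x),
             error = function(e) NULL)
  } else {
    tryCatch(as.numeric(qr.solve(M, y)), error = function(e) NULL)
  }
}

#' Indirect Fourier transform to the pair distance distribution p(r)
#'
#' Fits a histogram representation of p(r) on `[0, dmax]` to the measured
#' curve by regularized least squares: the back-transform
#' I_fit(q) = 4 pi sum_j p(r_j) sinc(q r_j) dr is matched to the data in the
#' error-weighted chi-square sense, with a second-difference (Tikhonov)
#' smoothness penalty `alpha` and boundary conditions p(0) = p(Dmax) = 0
#' (enforced through zero-padded differences), optionally with p(r) >= 0.
#' `dmax = "auto"` scans candidates and takes the smallest whose reduced
#' chi-square is within 5 percent of the minimum; `alpha = "auto"` picks the
#' L-curve corner (maximum curvature) on a log grid.
#'
#' @param curve a [saxs_curve].
#' @param dmax maximum particle dimension, Angstrom, or `"auto"`.
#' @param n_bins number of p(r) bins.
#' @param alpha smoothness weight, or `"auto"`.
#' @param nonneg constrain p(r) >= 0 (default `TRUE`).
#' @return An object of class `pofr`: `r`, `p` (with explicit zeros at the
#'   end points), `dmax`, `rg`, `i0`, `alpha`, `chi2_reduced`, `I_fit`.
#' @export
ift <- function(curve, dmax = "auto", n_bins = 100, alpha = "auto",
                nonneg = TRUE) {
  dat <- as.data.frame(curve)
  q <- dat$q; y <- dat$I; sg <- dat$sigma
  qmax <- max(q)
  solve_for <- function(dm, al) {
    r <- (seq_len(n_bins) - 0.5) * dm / n_bins
    dr <- dm / n_bins
    A <- ift_design(q, r, dr)
    Aw <- A / sg
    yw <- y / sg
    # second differences over (0, p, 0): boundary rows pull ends to zero
    L <- matrix(0, n_bins + 2, n_bins)
    for (i in seq_len(n_bins + 2)) {
      for (j in (i - 2):i) if (j >= 1 && j <= n_bins)
        L[i, j] <- c(1, -2, 1)[j - i + 3]
    }
    p <- ift_solve(Aw, yw, L, al, nonneg)
    if (is.null(p))
      stop("IFT system is singular or too ill-conditioned at alpha = ",
           signif(al, 3), "; increase alpha")
    If <- as.numeric(A %*% p)
    chi2 <- sum(((If - y) / sg)^2) / max(1, length(q) - n_bins / 2)
    list(r = r, p = p, dr = dr, I_fit = If, chi2 = chi2, A = A)
  }
  pick_alpha <- function(dm) {
    r <- (seq_len(n_bins) - 0.5) * dm / n_bins
    A <- ift_design(q, r, dm / n_bins)
    scale0 <- sum((A / sg)^2) / n_bins
    grid <- scale0 * 10^seq(-7, 1, length.out = 12)
    rho <- eta <- rep(NA_real_, length(grid))
    for (i in seq_along(grid)) {
      s <- tryCatch(solve_for(dm, grid[i]), error = function(e) NULL)
      if (is.null(s)) next
      rho[i] <- log(sum(((s$I_fit - y) / sg)^2))
      eta[i] <- log(sum(diff(diff(c(0, s$p, 0)))^2) + 1e-300)
    }
    keep <- which(!is.na(rho))
    if (length(keep) < 3) stop("IFT failed over the whole alpha grid")
    grid <- grid[keep]; rho <- rho[keep]; eta <- eta[keep]
    # discrete curvature of the L-curve (rho, eta)
    k <- rep(-Inf, length(grid))
    for (i in 2:(length(grid) - 1)) {
      x1 <- rho[i] - rho[i - 1]; y1 <- eta[i] - eta[i - 1]
      x2 <- rho[i + 1] - rho[i]; y2 <- eta[i + 1] - eta[i]
      cross <- x1 * y2 - y1 * x2
      denom <- (x1^2 + y1^2) * (x2^2 + y2^2)
      if (denom > 0) k[i] <- cross / sqrt(denom)
    }
    grid[which.max(k)]
  }
  auto_dmax <- is.character(dmax) && dmax == "auto"
  if (auto_dmax) {
    g <- tryCatch(guinier_fit(curve), error = function(e) NULL)
    rg0 <- if (is.null(g)) pi / qmax else g$rg
    cand <- seq(2.0 * rg0, 4.5 * rg0, length.out = 14)
    al0 <- if (is.character(alpha)) pick_alpha(stats::median(cand)) else alpha
    chis <- vapply(cand, function(dm) solve_for(dm, al0)$chi2, numeric(1))
    ok <- which(chis <= min(chis) * 1.05)
    dmax <- cand[min(ok)]       # parsimonious support
  } else {
    if (dmax <= 0) stop("dmax must be positive")
    if (dmax < pi / qmax)
      warning("dmax below the data resolution limit pi/qmax")
  }
  if (is.character(alpha)) alpha <- pick_alpha(dmax)
  s <- solve_for(dmax, alpha)
  psum <- sum(s$p) * s$dr
  if (psum <= 0) stop("degenerate p(r); increase alpha or check the data")
  rg <- sqrt(sum(s$p * s$r^2) * s$dr / (2 * psum))
  i0 <- 4 * pi * psum
  structure(list(r = c(0, s$r, dmax), p = c(0, s$p, 0), dmax = dmax,
                 rg = rg, i0 = i0, alpha = alpha,
                 chi2_reduced = s$chi2, I_fit = s$I_fit, q = q,
                 nonneg = nonneg, n_bins = n_bins),
            class = "pofr")
}

#' @export
print.pofr <- function(x, ...) {
  cat(sprintf(
    "p(r): Dmax = %.1f A, Rg = %.2f A, I0 = %.4g, chi2_red = %.3f (alpha = %.3g)\n",
    x$dmax, x$rg, x$i0, x$chi2_reduced, x$alpha))
  invisible(x)
}

#' Write p(r) as two-column text
#'
#' @param pofr a `pofr` object from [ift].
#' @param file output path.
#' @export
write_pofr <- function(pofr, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# p(r): Dmax = %.2f A, Rg = %.3f A", pofr$dmax,
                     pofr$rg), con)
  utils::write.table(data.frame(r = pofr$r, p = pofr$p), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Normalized (dimensionless) Kratky transform
#'
#' Pointwise transform x = q Rg, y = (q Rg)^2 I(q)/I0 used to assess
#' compactness: a globular particle peaks at (sqrt(3), 3/e), a random coil
#' rises to a plateau.
#'
#' @param curve a [saxs_curve].
#' @param guinier a `guinier_result` supplying Rg and I0.
#' @return data.frame with columns `x` (= q Rg) and `y`.
#' @export
normalized_kratky <- function(curve, guinier) {
  stopifnot(inherits(guinier, "guinier_result"))
  x <- curve$q * guinier$rg
  data.frame(x = x, y = x^2 * curve$I / guinier$i0)
}
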