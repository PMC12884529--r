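# Closed-form route for the surface excess energy.
#
# The azimuthal field problems are linear, and the unit-mean cap weight has
# an explicit cosine expansion
#   Theta~(phi) = 1 + sum_n t_n cos(n phi),  t_n = 2 sin(n phi0) / (pi sbar n),
# with sbar = phi0 / pi the cap fraction. Solving the balances harmonic by
# harmonic yields the analytic structure of each excess-energy term: every
# contribution is proportional to the mean substrate concentration <C_M> =
# beta^2/(alpha^2 + beta^2) C0 in the weak-exchange limit, except the
# electrostatic one, which picks up a second field factor and scales with
# <C_M>^2. The leading-order coefficients (half-cap, phi0 = pi/2) are
#   G[Chat_N] = -G[Chat_M] = (2/pi) alpha^2 <Chat_M> / (1 + beta^2),
#   G[That]   = (2/pi) lambda^2 <Chat_M> / (1 + omega^2).
# The implementation below evaluates the harmonic algebra exactly (cosine-
# Galerkin solve with the analytic cap coefficients, convolution products,
# exact projection rules) instead of truncating at first order, so that
# terms whose leading order cancels -- the entropic term at alpha = beta,
# the electrostatic term, whose first-order harmonics are parity-blocked --
# are still produced correctly. This is the package's re-derivation of the
# closed forms; it is validated term-by-term against the quadrature route
# in the small-alpha, small-beta regime by the test suite.

cap_cosine_coeffs <- function(phi0, N) {
  sbar <- phi0 / pi
  n <- seq_len(N)
  c(1, 2 * sin(n * phi0) / (pi * sbar * n))
}

# Cosine-series product: a, b are coefficient vectors indexed 0..N
# (f = a[1] + sum a[k+1] cos(k phi)). Returns coefficients of f*g, 0..N.
cos_mult <- function(a, b) {
  N <- length(a) - 1L
  out <- numeric(N + 1L)
  ka <- 0:N
  for (k in 0:N) {
    # f0 g_k + g0 f_k (k >= 1) / f0 g0 + half sum f_n g_n (k == 0)
    if (k == 0L) {
      out[1] <- a[1] * b[1] + 0.5 * sum(a[-1] * b[-1])
    } else {
      s <- a[1] * b[k + 1] + b[1] * a[k + 1]
      n <- 1:N
      m1 <- k + n     # |n - m| = k with m = n + k
      ok <- m1 <= N
      s <- s + 0.5 * sum(a[n[ok] + 1] * b[m1[ok] + 1]) +
        0.5 * sum(b[n[ok] + 1] * a[m1[ok] + 1])
      if (k >= 2L) {
        n2 <- 1:(k - 1L)     # n + m = k
        s <- s + 0.5 * sum(a[n2 + 1] * b[k - n2 + 1])
      }
      out[k + 1] <- s
    }
  }
  out
}

# Axial projection P[f g'] of two cosine series (see energy.R for the
# grid-based analogue): P = -(1/4) sum_m m g_m (ftil_{m-1} - ftil_{m+1}),
# ftil_0 = 2 f_0.
cos_axial_projection <- function(a, b) {
  N <- length(a) - 1L
  ftil <- c(2 * a[1], a[-1])
  m <- 1:N
  fm1 <- ftil[m]                       # ftil_{m-1}
  fp1 <- c(ftil[-(1:2)], 0)            # ftil_{m+1} (0 beyond truncation)
  -0.25 * sum(m * b[m + 1] * (fm1 - fp1))
}

cos_gradient_mean <- function(a) -a[2] / 2

# ln(series) for a strictly positive series written as c0 (1 + s), |s| small:
# returns cosine coefficients of log(c0) + s - s^2/2 + s^3/3.
cos_log <- function(a) {
  c0 <- a[1]
  if (c0 <= 0) stop("cos_log requires a positive mean", call. = FALSE)
  s <- a / c0
  s[1] <- 0
  s2 <- cos_mult(s, s)
  s3 <- cos_mult(s2, s)
  out <- s - s2 / 2 + s3 / 3
  out[1] <- out[1] + log(c0)
  out
}

# Galerkin solve of u'' - q(phi) u = rhs(phi) in cosine space, where q is
# mu0 + mu1 * Theta~ (cap-modulated absorption). Dense (N+1)^2 solve.
cos_galerkin_solve <- function(tcap, mu0, mu1, rhs, gauge_mean = NULL) {
  N <- length(tcap) - 1L
  if (mu0 == 0 && mu1 == 0) {
    # pure Poisson problem: mean decouples; fix the gauge explicitly
    k <- 1:N
    out <- c(if (is.null(gauge_mean)) 0 else gauge_mean,
             -rhs[k + 1] / k^2)
    return(out)
  }
  M <- matrix(0, N + 1L, N + 1L)
  # second-derivative diagonal
  diag(M) <- -(0:N)^2
  # -mu0 * I
  diag(M) <- diag(M) - mu0
  if (mu1 != 0) {
    # -(mu1 Theta~ u): convolution matrix T[k, m]
    Tm <- matrix(0, N + 1L, N + 1L)
    Tm[1, 1] <- tcap[1]
    if (N >= 1) {
      Tm[1, 2:(N + 1)] <- tcap[2:(N + 1)] / 2
      Tm[2:(N + 1), 1] <- tcap[2:(N + 1)]
      for (k in 1:N) for (m in 1:N) {
        tp <- if (k + m <= N) tcap[k + m + 1] else 0
        td <- if (k == m) 2 * tcap[1] else tcap[abs(k - m) + 1]
        Tm[k + 1, m + 1] <- 0.5 * (tp + td)
      }
    }
    M <- M - mu1 * Tm
  }
  as.numeric(solve(M, rhs))
}

# Harmonic solution of the four field problems; returns cosine series.
closed_form_fields <- function(g, N = 96L) {
  tcap <- cap_cosine_coeffs(g$phi0, N)
  rhsM <- c(-g$beta2 * g$Chat_Mb, numeric(N))
  CM <- cos_galerkin_solve(tcap, g$beta2, g$alpha2, rhsM)
  src <- cos_mult(tcap, CM)            # Theta~ * Chat_M
  CN <- cos_galerkin_solve(tcap, g$beta2, 0, -g$alpha2 * src)
  That <- cos_galerkin_solve(tcap, g$omega2, 0,
                             -g$lambda2 * src - c(g$omega2 * g$That_b,
                                                  numeric(N)),
                             gauge_mean = g$That_b)
  charge <- g$z_M * CM + g$z_N * CN
  psi <- numeric(N + 1L)
  if (g$xi2 > 0 && any(charge[-1] != 0)) {
    k <- 1:N
    psi[k + 1] <- g$xi2 * charge[k + 1] / k^2
  }
  list(CM = CM, CN = CN, That = That, psi = psi, tcap = tcap)
}

#' Closed-form surface excess energy (weak reaction-exchange limit)
#'
#' Analytic-route evaluation of the nondissipative excess-energy terms from
#' the harmonic solution of the interfacial balances, valid for
#' `alpha2, beta2` well below one. Each term reproduces the proportionality
#' to the mean substrate concentration (the electrostatic one to its
#' square); see the package vignette for the leading-order algebra.
#'
#' @param p A [physical_params()] object.
#' @param g Optional `dimensionless_groups`; computed from `p` when absent.
#' @param validity_threshold Upper bound on `alpha2` and `beta2` for the
#'   closed forms to be trusted (default 0.1).
#' @param override Set `TRUE` to evaluate beyond the validity threshold;
#'   otherwise a warning is attached to the result.
#' @param n_harmonics Truncation order of the harmonic algebra.
#' @return An `energy_breakdown` with the nondissipative terms populated.
#' @export
energy_closed_form <- function(p, g = compute_dimensionless_groups(p),
                               validity_threshold = 0.1, override = FALSE,
                               n_harmonics = 96L) {
  p <- validate_physical_params(p)
  b <- new_energy_breakdown()
  if (g$alpha2 == 0) return(b)
  if ((g$alpha2 > validity_threshold || g$beta2 > validity_threshold) &&
      !override)
    warning("closed forms evaluated outside their validity range ",
            "(alpha2 or beta2 > ", validity_threshold,
            "); pass override = TRUE to silence", call. = FALSE)

  cf <- closed_form_fields(g, N = as.integer(n_harmonics))
  A <- 4 * pi * p$R^2
  eps <- p$eps_thick
  RgT0 <- phys_constants$R_g * p$T0

  GN <- cos_gradient_mean(cf$CN)
  GM <- cos_gradient_mean(cf$CM)
  GT <- cos_gradient_mean(cf$That)

  b$e_reaction <- -A * eps * p$C0 * (p$dH_r + p$dmu_r0) * GN
  b$e_diffusio <- -A * p$C0 * (p$gamma_CM * GM + p$gamma_CN * GN)
  b$e_thermo <- -A * p$gamma_T * p$T0 * GT

  scale_x <- p$C0 / c_ref(p)    # x_i = scale_x * Chat_i
  lnxM <- cos_log(scale_x * cf$CM)
  lnxN <- cos_log(scale_x * cf$CN)
  b$e_entropic <- A * eps * p$C0 * RgT0 *
    (cos_axial_projection(cos_mult(cf$That, lnxM), cf$CM) +
     cos_axial_projection(cos_mult(cf$That, lnxN), cf$CN))

  b$e_electro <- A * eps * p$C0 * RgT0 *
    (p$z_M * cos_axial_projection(cf$psi, cf$CM) +
     p$z_N * cos_axial_projection(cf$psi, cf$CN))

  b$total_nd <- b$e_reaction + b$e_entropic + b$e_electro +
    b$e_diffusio + b$e_thermo
  b
}

#' Closed-form mean substrate concentration
#'
#' Weak-reaction, weak-exchange limit of the surface-mean dimensionless
#' substrate concentration: `beta2 / (alpha2 + beta2)`.
#'
#' @param g A `dimensionless_groups` object.
#' @return Dimensionless mean in (0, 1].
#' @export
mean_substrate_closed_form <- function(g) {
  if (g$alpha2 == 0 && g$beta2 == 0)
    stop("alpha2 = beta2 = 0 is degenerate", call. = FALSE)
  g$beta2 / (g$alpha2 + g$beta2)
}
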