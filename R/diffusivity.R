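#' Active diffusivity from the surface excess energy
#'
#' The long-time diffusivity of a chemically active particle exceeds its
#' passive value in proportion to the interfacial energy available beyond
#' the thermal bath:
#' \deqn{D = D_0 \left(1 + \frac{|E_s|}{k_B T^{(b)}}\right).}
#'
#' @param D0 Passive diffusivity (any unit; the result shares it).
#' @param E_abs Magnitude of the surface excess energy, J (>= 0).
#' @param T_b Bath temperature, K (> 0).
#' @return Active diffusivity in the unit of `D0`.
#' @export
#' @examples
#' active_diffusivity(7.75, 3 * 1.380649e-23 * 298.15, 298.15)  # 31.0
active_diffusivity <- function(D0, E_abs, T_b) {
  if (!is.numeric(T_b) || any(T_b <= 0))
    stop("T_b must be positive", call. = FALSE)
  if (any(D0 < 0)) stop("D0 must be nonnegative", call. = FALSE)
  if (any(E_abs < 0)) stop("E_abs must be nonnegative", call. = FALSE)
  D0 * (1 + E_abs / (phys_constants$k_B * T_b))
}

# One point of the activity pipeline at bulk concentration C0 (mol/m^3).
# The nominal parameter set supplies everything but C0; the mole-fraction
# composition scale stays pinned at the nominal C0.
pipeline_point <- function(p, C0, grid, route = "both") {
  p_at <- unclass(p)
  if (is.null(p_at$C0_ref)) p_at$C0_ref <- p$C0
  p_at$C0 <- C0
  p_at <- validate_physical_params(p_at)
  g <- compute_dimensionless_groups(p_at)
  f <- solve_surface_fields(g, grid)
  rdot <- mean_reaction_rate(p_at, f)
  nd <- if (route %in% c("nd", "both"))
    energy_from_fields(p_at, g, f) else NULL
  d <- if (route %in% c("d", "both"))
    dissipative_energy(p_at, g, f) else NULL
  kT <- phys_constants$k_B * p_at$T0
  list(
    params = p_at, groups = g, fields = f, rdot = rdot,
    E_nd = if (!is.null(nd)) nd$total_nd else NA_real_,
    E_d = if (!is.null(d)) d$total_d else NA_real_,
    D_nd = if (!is.null(nd)) active_diffusivity(p$D0, abs(nd$total_nd),
                                                p_at$T0) else NA_real_,
    D_d = if (!is.null(d)) active_diffusivity(p$D0, abs(d$total_d),
                                              p_at$T0) else NA_real_,
    breakdown_nd = nd, breakdown_d = d, kT = kT
  )
}

#' Bulk-concentration grid for a target reaction-rate window
#'
#' The mean reaction rate is linear in the bulk substrate concentration
#' (`rdot = k_r C0 <Chat_M>` with a C0-independent `<Chat_M>`), so a target
#' `rdot` window maps directly onto a `C0` window. Points are spaced
#' logarithmically.
#'
#' @param p A [physical_params()] object.
#' @param rdot_range Length-2 vector, target reaction-rate window in nM/s.
#' @param n Number of points.
#' @param grid Azimuthal grid used to evaluate `<Chat_M>`.
#' @return Increasing vector of bulk concentrations in mol/m^3.
#' @export
c0_grid_for_rdot <- function(p, rdot_range = c(1, 100), n = 25L,
                             grid = azimuthal_grid(256L)) {
  p <- validate_physical_params(p)
  if (p$k_r <= 0) stop("k_r must be positive to target a rdot window",
                       call. = FALSE)
  g <- compute_dimensionless_groups(p)
  f <- solve_surface_fields(g, grid)
  mC <- f$mean_Chat_M
  # rdot [nM/s] = 1e6 * k_r * C0 [mol/m^3] * <Chat_M>
  c0 <- rdot_range * 1e-6 / (p$k_r * mC)
  exp(seq(log(c0[1]), log(c0[2]), length.out = n))
}

#' Default sweep grid of a packaged preset
#'
#' Each preset ships the sweep window its group prefactors were calibrated
#' on: a direct `C0` window, or a reaction-rate window that is converted to
#' `C0` through the (linear) rate-concentration map.
#'
#' @param name Preset identifier (see [load_preset()]).
#' @param n Number of points (log-spaced).
#' @param grid Azimuthal grid used when converting a rate window.
#' @return Increasing vector of bulk concentrations in mol/m^3, with the
#'   corresponding [load_preset()] object attached as attribute `params`.
#' @export
preset_sweep_grid <- function(name, n = 25L, grid = azimuthal_grid(256L)) {
  p <- load_preset(name)
  path <- system.file("extdata", paste0(name, ".yaml"),
                      package = "activejanus", mustWork = TRUE)
  sw <- yaml::read_yaml(path)$sweep
  if (!is.null(sw$c0_min)) {
    c0 <- exp(seq(log(sw$c0_min), log(sw$c0_max), length.out = n))
  } else {
    c0 <- c0_grid_for_rdot(p, c(sw$rdot_min_nMps, sw$rdot_max_nMps),
                           n = n, grid = grid)
  }
  attr(c0, "params") <- p
  c0
}

#' Sweep the bulk concentration and assemble an activity curve
#'
#' For each bulk concentration the pipeline recomputes the concentration-
#' dependent dimensionless groups (`lambda2` and `xi2` are proportional to
#' `C0`), solves the four interfacial fields, evaluates the surface excess
#' energy by the requested route(s) and maps it to the active diffusivity.
#'
#' @param p A [physical_params()] object (nominal parameter set).
#' @param C0_grid Increasing positive bulk concentrations, mol/m^3.
#' @param route `"nd"`, `"d"` or `"both"`.
#' @param grid Azimuthal grid for the field solves.
#' @return An object of class `activity_curve`: a data frame with columns
#'   `C0` (mol/m^3), `rdot_nMps`, `E_nd_J`, `E_nd_kT`, `E_d_J`, `E_d_kT`,
#'   `D_nd_um2ps`, `D_d_um2ps`, plus attributes `params` and `route`.
#' @export
#' @examples
#' p <- load_preset("case2_vesicle")
#' curve <- sweep_activity(p, c0_grid_for_rdot(p, c(1, 100), n = 9))
#' head(curve)
sweep_activity <- function(p, C0_grid, route = c("both", "nd", "d"),
                           grid = azimuthal_grid(256L)) {
  route <- match.arg(route)
  p <- validate_physical_params(p)
  if (any(C0_grid <= 0) || is.unsorted(C0_grid, strictly = TRUE))
    stop("C0_grid must be strictly increasing and positive", call. = FALSE)
  rows <- lapply(C0_grid, function(c0) {
    pt <- tryCatch(pipeline_point(p, c0, grid, route),
                   error = function(e)
                     stop("activity sweep failed at C0 = ", signif(c0, 6),
                          " mol/m^3: ", conditionMessage(e), call. = FALSE))
    data.frame(
      C0 = c0,
      rdot_nMps = pt$rdot * 1e6,
      E_nd_J = pt$E_nd, E_nd_kT = pt$E_nd / pt$kT,
      E_d_J = pt$E_d, E_d_kT = pt$E_d / pt$kT,
      D_nd_um2ps = pt$D_nd * 1e12, D_d_um2ps = pt$D_d * 1e12,
      mean_Chat_M = pt$fields$mean_Chat_M
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "params") <- p
  attr(out, "route") <- route
  attr(out, "grid_n") <- grid$n
  class(out) <- c("activity_curve", "data.frame")
  out
}

#' Locate extrema of the active diffusivity and zero crossings of the
#' signed excess energy
#'
#' Scans an activity curve for interior local minima/maxima of `D` and for
#' sign changes of the signed total excess energy, then refines each
#' candidate against the continuous pipeline: extrema by golden-section
#' search, zero crossings by bisection, both to a relative tolerance of
#' 1e-3 in the reaction rate. A strictly monotone curve yields an empty
#' result.
#'
#' @param curve An [sweep_activity()] result (>= 5 points).
#' @param route `"nd"` or `"d"`.
#' @param refine Re-solve the pipeline to polish locations (default TRUE).
#'   With `refine = FALSE` the discrete grid locations are returned.
#' @return A data frame with columns `rdot_nMps`, `kind` (`"min"`, `"max"`
#'   or `"zero_crossing_of_E"`) and `value` (D in um^2/s, or E in J at the
#'   crossing).
#' @export
find_extrema <- function(curve, route = c("nd", "d"), refine = TRUE) {
  route <- match.arg(route)
  stopifnot(inherits(curve, "activity_curve"))
  if (nrow(curve) < 5) stop("need at least 5 sweep points", call. = FALSE)
  p <- attr(curve, "params")
  grid <- azimuthal_grid(attr(curve, "grid_n"))
  Dcol <- if (route == "nd") curve$D_nd_um2ps else curve$D_d_um2ps
  Ecol <- if (route == "nd") curve$E_nd_J else curve$E_d_J
  if (anyNA(Dcol)) stop("route '", route, "' was not swept", call. = FALSE)
  out <- list()

  D_of_c0 <- function(c0) {
    pt <- pipeline_point(p, c0, grid, route)
    if (route == "nd") pt$D_nd * 1e12 else pt$D_d * 1e12
  }
  E_of_c0 <- function(c0) {
    pt <- pipeline_point(p, c0, grid, route)
    if (route == "nd") pt$E_nd else pt$E_d
  }
  rdot_of_c0 <- function(c0) {
    pt <- pipeline_point(p, c0, grid, route)
    pt$rdot * 1e6
  }

  golden <- function(f, lo, hi, minimize, tol) {
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- f(x1); f2 <- f(x2)
    sgn <- if (minimize) 1 else -1
    while ((b - a) > tol * b) {
      if (sgn * f1 < sgn * f2) {
        b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - gr * (b - a); f1 <- f(x1)
      } else {
        a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + gr * (b - a); f2 <- f(x2)
      }
    }
    (a + b) / 2
  }

  n <- nrow(curve)
  for (i in 2:(n - 1)) {
    is_min <- Dcol[i] < Dcol[i - 1] && Dcol[i] < Dcol[i + 1]
    is_max <- Dcol[i] > Dcol[i - 1] && Dcol[i] > Dcol[i + 1]
    if (!is_min && !is_max) next
    lo <- curve$C0[i - 1]; hi <- curve$C0[i + 1]
    c0_star <- if (refine)
      golden(D_of_c0, lo, hi, minimize = is_min, tol = 2e-4)
    else curve$C0[i]
    out[[length(out) + 1]] <- data.frame(
      rdot_nMps = if (refine) rdot_of_c0(c0_star) else curve$rdot_nMps[i],
      kind = if (is_min) "min" else "max",
      value = D_of_c0(c0_star))
  }
  for (i in 1:(n - 1)) {
    if (is.na(Ecol[i]) || is.na(Ecol[i + 1])) next
    if (sign(Ecol[i]) == 0 || sign(Ecol[i]) * sign(Ecol[i + 1]) >= 0) next
    lo <- curve$C0[i]; hi <- curve$C0[i + 1]
    c0_star <- if (refine) {
      stats::uniroot(E_of_c0, c(lo, hi), tol = lo * 1e-4)$root
    } else sqrt(lo * hi)
    out[[length(out) + 1]] <- data.frame(
      rdot_nMps = if (refine) rdot_of_c0(c0_star)
                  else sqrt(curve$rdot_nMps[i] * curve$rdot_nMps[i + 1]),
      kind = "zero_crossing_of_E",
      value = if (refine) E_of_c0(c0_star) else NA_real_)
  }
  if (length(out) == 0)
    return(data.frame(rdot_nMps = numeric(0), kind = character(0),
                      value = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$rdot_nMps), , drop = FALSE]
}

#' Export an activity curve as CSV
#'
#' @param curve An [sweep_activity()] result.
#' @param path Output CSV path.
#' @return The curve, invisibly.
#' @export
export_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "activity_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(curve)
}
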