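#' Construct and validate a physical parameter set
#'
#' Bundles the dimensional description of a catalytic particle-fluid
#' interface: kinetics, transport coefficients, thermochemistry, charges and
#' surface-tension sensitivities. All downstream computations (surface-field
#' solves, excess-energy evaluation, activity sweeps) start from this object.
#'
#' Units are fixed per field and are not inferred:
#' \describe{
#'   \item{C0}{bulk substrate concentration, mol/m^3}
#'   \item{T0}{bulk temperature, K}
#'   \item{k_r}{first-order surface kinetic constant, 1/s}
#'   \item{D_s}{interface diffusivity, m^2/s}
#'   \item{eta_s}{interface viscosity, Pa s}
#'   \item{U}{mass-transfer coefficient, 1/s}
#'   \item{dH_r}{reaction enthalpy, J/mol (signed, exothermic negative)}
#'   \item{dmu_r0}{standard reaction free energy, J/mol (signed)}
#'   \item{kappa}{thermal conductivity, W/(K m)}
#'   \item{U_q}{heat-transfer coefficient, W/(K m^2)}
#'   \item{eps_thick}{interface thickness, m}
#'   \item{z_M, z_N}{substrate/product valences (signed integers)}
#'   \item{gamma_CM, gamma_CN}{surface-tension derivatives w.r.t.
#'     concentration, (J/m^2)/(mol/m^3) = J m/mol}
#'   \item{gamma_T}{surface-tension derivative w.r.t. temperature, J/(m^2 K)}
#'   \item{D0}{passive particle diffusivity, m^2/s}
#'   \item{R}{particle radius, m}
#'   \item{w0}{dimensionless interfacial composition constant in (0, 1);
#'     sets the mole-fraction scale x_i = w0 C_i / C0}
#'   \item{phi0}{catalytic-cap half-angle, rad (cap is |phi| <= phi0)}
#'   \item{eps_r}{relative permittivity of the medium (default water, 78.5)}
#'   \item{xi2_prefactor}{multiplicative prefactor applied to the raw
#'     electrostatic coupling number xi^2 (see
#'     [compute_dimensionless_groups()])}
#'   \item{lambda2_prefactor}{multiplicative prefactor applied to the raw
#'     heat-generation number lambda^2}
#'   \item{tau_mode}{characteristic-time convention for the dissipative
#'     route: "kr_beta2" gives tau = 1/(k_r beta^2), "kr" gives tau = 1/k_r}
#' }
#'
#' @param C0,T0,k_r,D_s,eta_s,U,dH_r,dmu_r0,kappa,U_q,eps_thick,z_M,z_N
#'   See description.
#' @param gamma_CM,gamma_CN,gamma_T,D0,R,w0,phi0,eps_r See description.
#' @param xi2_prefactor,lambda2_prefactor,tau_mode See description.
#' @param C0_ref Reference bulk concentration (mol/m^3) fixing the
#'   mole-fraction composition scale `C_ref = C0_ref / w0`; `NULL` (default)
#'   uses `C0`. Activity sweeps pin this at the nominal concentration while
#'   `C0` is varied.
#' @return An object of class `physical_params` (a validated named list).
#' @seealso [load_preset()], [compute_dimensionless_groups()]
#' @export
#' @examples
#' p <- load_preset("case1_janus_nano")
#' p$D0 * 1e12  # passive diffusivity in um^2/s
physical_params <- function(C0, T0, k_r, D_s, eta_s, U, dH_r, dmu_r0,
                            kappa, U_q, eps_thick, z_M, z_N,
                            gamma_CM, gamma_CN, gamma_T, D0, R,
                            w0 = 0.5, phi0 = pi / 2, eps_r = 78.5,
                            xi2_prefactor = 1, lambda2_prefactor = 1,
                            tau_mode = c("kr_beta2", "kr"),
                            C0_ref = NULL) {
  tau_mode <- match.arg(tau_mode)
  if (!is.null(C0_ref) &&
      (!is.numeric(C0_ref) || length(C0_ref) != 1L || C0_ref <= 0))
    stop("C0_ref must be NULL or a single positive number", call. = FALSE)
  p <- list(
    C0_ref = C0_ref,
    C0 = C0, T0 = T0, k_r = k_r, D_s = D_s, eta_s = eta_s, U = U,
    dH_r = dH_r, dmu_r0 = dmu_r0, kappa = kappa, U_q = U_q,
    eps_thick = eps_thick, z_M = z_M, z_N = z_N,
    gamma_CM = gamma_CM, gamma_CN = gamma_CN, gamma_T = gamma_T,
    D0 = D0, R = R, w0 = w0, phi0 = phi0, eps_r = eps_r,
    xi2_prefactor = xi2_prefactor, lambda2_prefactor = lambda2_prefactor,
    tau_mode = tau_mode
  )
  validate_physical_params(p)
}

validate_physical_params <- function(p) {
  strictly_positive <- c("C0", "T0", "D_s", "eta_s", "kappa",
                         "eps_thick", "R", "eps_r", "xi2_prefactor",
                         "lambda2_prefactor")
  nonnegative <- c("k_r", "U", "U_q", "D0")
  for (nm in strictly_positive) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single strictly positive number",
           call. = FALSE)
  }
  for (nm in nonnegative) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("parameter '", nm, "' must be a single nonnegative number",
           call. = FALSE)
  }
  for (nm in c("dH_r", "dmu_r0", "gamma_CM", "gamma_CN", "gamma_T")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  for (nm in c("z_M", "z_N")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v != round(v))
      stop("parameter '", nm, "' must be a single (signed) integer",
           call. = FALSE)
  }
  if (!(p$w0 > 0 && p$w0 < 1))
    stop("parameter 'w0' must lie strictly in (0, 1)", call. = FALSE)
  if (!(p$phi0 > 0 && p$phi0 <= pi))
    stop("parameter 'phi0' must lie in (0, pi]", call. = FALSE)
  if (!p$tau_mode %in% c("kr_beta2", "kr"))
    stop("tau_mode must be 'kr_beta2' or 'kr'", call. = FALSE)
  structure(p, class = "physical_params")
}

#' @export
print.physical_params <- function(x, ...) {
  cat("<physical_params>\n")
  cat(sprintf("  R = %.3g m, k_r = %.3g 1/s, C0 = %.3g mol/m^3, T0 = %.2f K\n",
              x$R, x$k_r, x$C0, x$T0))
  g <- compute_dimensionless_groups(x)
  cat(sprintf("  alpha^2 = %.3g, beta^2 = %.3g, lambda^2 = %.3g,",
              g$alpha2, g$beta2, g$lambda2))
  cat(sprintf(" omega^2 = %.3g, xi^2 = %.3g\n", g$omega2, g$xi2))
  invisible(x)
}

#' Map a physical parameter set to its dimensionless groups
#'
#' The azimuthal boundary-value problems for the interfacial fields are
#' governed by five nonnegative groups:
#' \itemize{
#'   \item `alpha2 = k_r R^2 / D_s` -- reaction vs interface diffusion,
#'   \item `beta2 = U R^2 / D_s` -- bulk exchange (adsorption) vs diffusion,
#'   \item `lambda2 = R^2 |dH_r| k_r C0 / (kappa T0)` -- heat generation vs
#'     conduction (times `lambda2_prefactor`),
#'   \item `omega2 = U_q R / kappa` -- interfacial cooling vs conduction,
#'   \item `xi2 = R^2 C0 N_A q0^2 / (k_B T0 eps0 eps_r)` -- electrostatic
#'     coupling (times `xi2_prefactor`).
#' }
#' `lambda2` and `xi2` are proportional to the bulk concentration `C0`, so
#' they vary along an activity sweep while `alpha2` and `beta2` stay fixed.
#'
#' @param p A [physical_params()] object.
#' @return An object of class `dimensionless_groups`: a list with fields
#'   `alpha2`, `beta2`, `lambda2`, `omega2`, `xi2`, `phi0`, `w0`, `That_b`
#'   (= 1) and `Chat_Mb` (= 1).
#' @export
#' @examples
#' g <- compute_dimensionless_groups(load_preset("case2_vesicle"))
#' g$alpha2  # about 3.06 for the vesicle preset
compute_dimensionless_groups <- function(p) {
  p <- validate_physical_params(p)
  k <- phys_constants
  g <- list(
    alpha2 = p$k_r * p$R^2 / p$D_s,
    beta2  = p$U * p$R^2 / p$D_s,
    lambda2 = p$lambda2_prefactor *
      p$R^2 * abs(p$dH_r) * p$k_r * p$C0 / (p$kappa * p$T0),
    omega2 = p$U_q * p$R / p$kappa,
    xi2 = p$xi2_prefactor *
      p$R^2 * p$C0 * k$N_A * k$q0^2 / (k$k_B * p$T0 * k$eps0 * p$eps_r),
    phi0 = p$phi0,
    w0 = p$w0,
    z_M = p$z_M,
    z_N = p$z_N,
    That_b = 1,
    Chat_Mb = 1
  )
  stopifnot(all(vapply(g[1:5], is.finite, logical(1))))
  structure(g, class = "dimensionless_groups")
}

#' @export
print.dimensionless_groups <- function(x, ...) {
  cat("<dimensionless_groups>\n")
  cat(sprintf("  alpha^2 = %.6g   beta^2 = %.6g\n", x$alpha2, x$beta2))
  cat(sprintf("  lambda^2 = %.6g  omega^2 = %.6g  xi^2 = %.6g\n",
              x$lambda2, x$omega2, x$xi2))
  cat(sprintf("  phi0 = %.4g rad, w0 = %.3g, z_M = %d, z_N = %d\n",
              x$phi0, x$w0, as.integer(x$z_M), as.integer(x$z_N)))
  invisible(x)
}

#' Characteristic time of the dissipative route
#'
#' Two conventions are supported, selected by `tau_mode` in the parameter
#' set: `tau = 1/(k_r beta^2)` couples reaction kinetics to interfacial
#' exchange (appropriate for nanometric particles), while `tau = 1/k_r` is
#' the bare kinetic time (appropriate for the vesicle case).
#'
#' @param p A [physical_params()] object.
#' @return Characteristic time in seconds.
#' @export
characteristic_time <- function(p) {
  p <- validate_physical_params(p)
  if (p$k_r <= 0)
    stop("characteristic time undefined for k_r = 0", call. = FALSE)
  if (p$tau_mode == "kr") return(1 / p$k_r)
  g <- compute_dimensionless_groups(p)
  if (g$beta2 <= 0)
    stop("tau_mode 'kr_beta2' requires beta^2 > 0", call. = FALSE)
  1 / (p$k_r * g$beta2)
}

#' Load a packaged parameter preset
#'
#' Two presets ship with the package, corresponding to the two case studies
#' the model was built around:
#' \describe{
#'   \item{`case1_janus_nano`}{nanometric catalytic Janus particles
#'     (R = 9 nm) converting a charged salt substrate (z_M = -3 to
#'     z_N = -4).}
#'   \item{`case2_vesicle`}{phospholipid vesicles (R = 2.1 um) with
#'     membrane-embedded enzymes hydrolyzing a neutral substrate into a
#'     charged product (z_M = 0, z_N = -1).}
#' }
#'
#' @param name Preset identifier, one of `"case1_janus_nano"`,
#'   `"case2_vesicle"`.
#' @return A [physical_params()] object.
#' @export
#' @examples
#' load_preset("case1_janus_nano")$R  # 9e-9 m
load_preset <- function(name) {
  available <- c("case1_janus_nano", "case2_vesicle")
  if (!is.character(name) || length(name) != 1L || !name %in% available)
    stop("unknown preset; available presets: ",
         paste(available, collapse = ", "), call. = FALSE)
  path <- system.file("extdata", paste0(name, ".yaml"),
                      package = "activejanus", mustWork = TRUE)
  read_params(path)
}

#' Read a physical parameter set from a YAML configuration file
#'
#' The file must contain a top-level `params` mapping whose keys are the
#' fields of [physical_params()]. Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A [physical_params()] object.
#' @export
read_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$params))
    stop("configuration file must contain a top-level 'params' section",
         call. = FALSE)
  fields <- cfg$params
  known <- names(formals(physical_params))
  unknown <- setdiff(names(fields), known)
  if (length(unknown) > 0)
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(physical_params, fields)
}

#' Write a physical parameter set to a YAML configuration file
#'
#' The written file round-trips through [read_params()] to an identical
#' parameter set.
#'
#' @param p A [physical_params()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  p <- validate_physical_params(p)
  yaml::write_yaml(list(params = unclass(p)), path, precision = 17L)
  invisible(path)
}

#' Export the dimensionless groups of one or more parameter sets as CSV
#'
#' @param params A [physical_params()] object or a named list of them.
#' @param path Output CSV path.
#' @return The exported data frame, invisibly.
#' @export
export_groups_csv <- function(params, path) {
  if (inherits(params, "physical_params")) params <- list(params)
  if (is.null(names(params))) names(params) <- paste0("set", seq_along(params))
  rows <- lapply(names(params), function(nm) {
    g <- compute_dimensionless_groups(params[[nm]])
    data.frame(name = nm, alpha2 = g$alpha2, beta2 = g$beta2,
               lambda2 = g$lambda2, omega2 = g$omega2, xi2 = g$xi2,
               phi0 = g$phi0, w0 = g$w0)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
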