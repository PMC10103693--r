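#' Stokes-Einstein free diffusion coefficient of a sphere
#'
#' `D0 = kB * T / (3 * pi * eta * d)` for a sphere of diameter `d` in a
#' Newtonian fluid of viscosity `eta` — the free-water reference against
#' which hindered diffusion in mucus is measured.
#'
#' @param diameter_nm Particle diameter in nm.
#' @param temperature Absolute temperature in K (default 298.15, room
#'   temperature).
#' @param viscosity Dynamic viscosity in Pa s (default 8.9e-4, water).
#' @return Diffusion coefficient in um^2/s.
#' @export
stokes_einstein_d0 <- function(diameter_nm, temperature = 298.15,
                               viscosity = 8.9e-4) {
  if (any(diameter_nm <= 0) || temperature <= 0 || viscosity <= 0)
    stop("diameter, temperature and viscosity must all be > 0")
  d_m <- diameter_nm * 1e-9
  (.kB * temperature / (3 * pi * viscosity * d_m)) * 1e12
}

#' Effective diffusivity from a 2-D MSD
#'
#' `D_eff = MSD(tau) / (4 * tau)` for two-dimensional tracking.
#'
#' @param msd MSD at lag `tau`, um^2 (>= 0).
#' @param tau Lag time, s (> 0).
#' @return Effective diffusivity, um^2/s.
#' @export
effective_diffusivity <- function(msd, tau) {
  if (any(msd < 0)) stop("'msd' must be >= 0")
  stop_if_not_scalar_pos(tau, "tau")
  msd / (4 * tau)
}

#' Forward obstruction-scaling model
#'
#' Hindrance ratio of a probe of diameter `d` in a fibre network of pore
#' size `xi` and fibre diameter `d_f`:
#' `D_eff / D0 = exp(-(pi/4) * ((d + d_f) / (xi + d_f))^2)`.
#'
#' @param xi_nm Pore size, nm.
#' @param diameter_nm Probe diameter, nm.
#' @param d_fiber_nm Fibre diameter, nm (default 7, mucin fibres).
#' @return Hindrance ratio in (0, 1).
#' @export
obstruction_hindrance <- function(xi_nm, diameter_nm, d_fiber_nm = 7) {
  exp(-(pi / 4) * ((diameter_nm + d_fiber_nm) / (xi_nm + d_fiber_nm))^2)
}

#' Invert the obstruction model: pore size from a hindrance ratio
#'
#' Solves the forward model for the pore size:
#' `xi = (d + d_f) * sqrt(pi / (4 * ln(D0 / D_eff))) - d_f`.
#' A hindrance at or above 1 (free diffusion) carries no information about
#' confinement and returns `Inf`, reported downstream as "unbounded".
#' A negative root (extreme hindrance) is clamped to 0 with attribute
#' `clamped = TRUE`.
#'
#' @param hindrance `D_eff / D0`, must be finite and > 0.
#' @param diameter_nm Probe diameter, nm.
#' @param d_fiber_nm Fibre diameter, nm (default 7).
#' @return Pore size in nm (`Inf` = unbounded).
#' @export
invert_obstruction_model <- function(hindrance, diameter_nm, d_fiber_nm = 7) {
  if (any(!is.finite(hindrance)) || any(hindrance <= 0))
    stop("'hindrance' must be finite and > 0")
  n <- max(length(hindrance), length(diameter_nm))
  h <- rep_len(hindrance, n)
  d <- rep_len(diameter_nm, n)
  out <- ifelse(h >= 1, Inf,
                (d + d_fiber_nm) * sqrt(pi / (4 * log(1 / pmin(h, 1 - 1e-15))))
                - d_fiber_nm)
  clamped <- is.finite(out) & out < 0
  out[clamped] <- 0
  attr(out, "clamped") <- clamped
  out
}

#' Effective pore size of one sample from multi-probe MSDs
#'
#' Chains ensemble-average MSD at tau = 1 s per mucus-penetrating probe
#' (100/200/500 nm at defaults) through effective diffusivity, the
#' Stokes-Einstein free-water reference and the inverted obstruction model
#' to a per-probe pore size; the sample estimate is the arithmetic mean of
#' the defined (bounded) per-probe values. Probes whose effective
#' diffusivity reaches the free value are "unbounded" and excluded from
#' the mean; if all probes are unbounded the estimate is undefined (NA).
#'
#' @param msd_by_probe Named numeric vector of ensemble-average MSDs
#'   (um^2) at lag `tau`; names are probe diameters in nm (e.g.
#'   `c("100" = 0.9, "200" = 0.6, "500" = 0.2)`).
#' @param tau Lag time, s (default 1).
#' @param temperature,viscosity,d_fiber_nm Model constants; see
#'   [stokes_einstein_d0()] and [invert_obstruction_model()].
#' @param sample_id Optional identifier carried into the result.
#'
#' @return Object of class `poresize_estimate`: list with `sample_id`,
#'   `per_probe_xi` (named vector, nm, `Inf` = unbounded), `xi_mean`
#'   (nm or NA), `d_fiber`, `temperature`, `viscosity`, `flags`.
#' @export
sample_pore_size <- function(msd_by_probe, tau = 1, temperature = 298.15,
                             viscosity = 8.9e-4, d_fiber_nm = 7,
                             sample_id = NA_character_) {
  if (length(msd_by_probe) < 1) stop("at least one probe is required")
  diam <- as.numeric(names(msd_by_probe))
  if (any(is.na(diam)))
    stop("'msd_by_probe' names must be probe diameters in nm")
  d_eff <- effective_diffusivity(unname(msd_by_probe), tau)
  d0 <- stokes_einstein_d0(diam, temperature, viscosity)
  h <- d_eff / d0
  xi <- rep(NA_real_, length(h))
  pos <- h > 0
  xi[pos] <- invert_obstruction_model(h[pos], diam[pos], d_fiber_nm)
  xi[!pos] <- 0   # zero MSD: complete confinement at this probe scale
  names(xi) <- names(msd_by_probe)
  defined <- is.finite(xi)
  flags <- character(0)
  if (any(!defined)) flags <- c(flags, "unbounded_probe")
  if (!any(defined)) flags <- c(flags, "undefined")
  structure(list(sample_id = sample_id, per_probe_xi = xi,
                 xi_mean = if (any(defined)) mean(xi[defined]) else NA_real_,
                 d_fiber = d_fiber_nm, temperature = temperature,
                 viscosity = viscosity, flags = flags),
            class = "poresize_estimate")
}

#' @export
print.poresize_estimate <- function(x, ...) {
  cat(sprintf("poresize_estimate%s: xi_mean = %s nm [%s]\n",
              if (is.na(x$sample_id)) "" else paste0(" ", x$sample_id),
              if (is.na(x$xi_mean)) "undefined" else sprintf("%.1f", x$xi_mean),
              paste(sprintf("%s nm: %s", names(x$per_probe_xi),
                            ifelse(is.finite(x$per_probe_xi),
                                   sprintf("%.1f", x$per_probe_xi),
                                   "unbounded")), collapse = ", ")))
  invisible(x)
}
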