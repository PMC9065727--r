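# 15N relaxation: exponential decay fitting, R2 from R1rho, tumbling model.

#' Default relaxation delay schedules (seconds)
#'
#' Standard constant-series schedules for backbone amide 15N relaxation:
#' eight R1 delays from 0 to 840 ms and nine R1rho delays from 0.2 to 20 ms.
#'
#' @return numeric vector of delays in seconds.
#' @export
r1_delay_schedule <- function() {
  c(0, 80, 200, 320, 440, 560, 720, 840) / 1000
}

#' @rdname r1_delay_schedule
#' @export
r1rho_delay_schedule <- function() {
  c(0.2, 1.4, 2.4, 5.0, 7.8, 10.8, 14.0, 17.4, 20) / 1000
}

#' Fit a mono-exponential relaxation decay
#'
#' Least-squares fit of I(t) = A exp(-R t) with the rate bounded below at
#' zero. Starting values come from a log-linear regression; the
#' Levenberg-Marquardt refinement reports the rate standard error from the
#' parameter covariance.
#'
#' @param delays delay durations (seconds), >= 3 distinct values.
#' @param intensities peak intensities (arbitrary units).
#' @return list(rate, amplitude, rate_err, clipped) with rate in 1/s;
#'   \code{clipped} flags a fit pinned at the R >= 0 bound.
#' @export
fit_exponential <- function(delays, intensities) {
  if (length(unique(delays)) < 3L) stop("need >= 3 distinct delays")
  if (any(!is.finite(intensities))) stop("non-finite intensities")
  pos <- intensities > 0
  r_unbounded <- NA_real_
  if (sum(pos) >= 2L) {
    lf <- stats::lm(log(intensities[pos]) ~ delays[pos])
    r_unbounded <- -stats::coef(lf)[[2]]
    r0 <- max(0, r_unbounded)
    a0 <- exp(stats::coef(lf)[[1]])
  } else {
    r0 <- 1
    a0 <- max(abs(intensities))
  }
  resid_fn <- function(p) p[1] * exp(-p[2] * delays) - intensities
  fit <- minpack.lm::nls.lm(par = c(a0, r0), fn = resid_fn,
                            lower = c(-Inf, 0),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  dof <- length(delays) - 2L
  rate_err <- NA_real_
  if (dof > 0) {
    s2 <- fit$deviance / dof
    hin <- try(solve(fit$hessian), silent = TRUE)
    if (!inherits(hin, "try-error") && hin[2, 2] >= 0) {
      rate_err <- sqrt(s2 * hin[2, 2])
    }
  }
  clipped <- p[2] < 1e-12 && is.finite(r_unbounded) && r_unbounded < -1e-12
  if (clipped) warning("negative-rate best fit clipped to R = 0")
  list(rate = p[2], amplitude = p[1], rate_err = rate_err, clipped = clipped)
}

#' R2 from R1rho with off-resonance correction
#'
#' R2 = (R1rho - R1 cos^2 beta) / sin^2 beta with tan(beta) =
#' spin_lock / offset. The default zero offset gives beta = 90 degrees and
#' R2 = R1rho (on-resonance).
#'
#' @param r1rho rotating-frame rate (1/s).
#' @param r1 longitudinal rate (1/s).
#' @param spin_lock spin-lock field strength (Hz).
#' @param offset resonance offset from the spin-lock carrier (Hz).
#' @return R2 in 1/s.
#' @export
r2_from_r1rho <- function(r1rho, r1, spin_lock = 1000, offset = 0) {
  beta <- atan2(spin_lock, offset)
  s2 <- sin(beta)^2
  if (any(s2 < 1e-12)) stop("tilt angle beta is zero: R2 undefined")
  (r1rho - r1 * cos(beta)^2) / s2
}

# water viscosities (cP) printed for the supported temperatures
.VISCOSITY_CP <- c("25" = 0.8903, "30" = 0.7973)

#' Rotational correlation time from molecular weight
#'
#' Empirical linear calibration for globular proteins,
#' tau_c(25 C) = 0.0005998 MW + 0.1674 (ns, MW in Da), rescaled to 30 C by
#' the Stokes-Einstein-Debye temperature/viscosity ratio
#' (298/303) x (0.7973/0.8903 cP).
#'
#' @param mw molecular weight in Dalton.
#' @param temperature 25 or 30 (degrees C).
#' @return tau_c in nanoseconds.
#' @export
tauc_from_mw <- function(mw, temperature = 30) {
  if (any(mw <= 0)) stop("MW must be positive")
  if (!temperature %in% c(25, 30)) {
    stop("supported temperatures: 25 or 30 C")
  }
  tc25 <- 0.0005998 * mw + 0.1674
  if (temperature == 25) return(tc25)
  unname(tc25 * (298 / 303) * (.VISCOSITY_CP[["30"]] / .VISCOSITY_CP[["25"]]))
}

#' Rigid-limit 15N R2/R1 ratio
#'
#' R2/R1 ~ ((4 pi nuN tau_c)^2 + 7) / 6 for a rigid isotropic tumbler; the
#' ratio grows quadratically with the correlation time and approaches 7/6 as
#' tumbling becomes fast.
#'
#' @param tau_c rotational correlation time in seconds.
#' @param nu_n 15N resonance frequency in Hz (e.g. 81.1e6 at an 800 MHz
#'   spectrometer; the default scales the 1H field by the 15N/1H
#'   gyromagnetic ratio 0.1013756).
#' @param field_h1 1H spectrometer frequency in Hz, used only when
#'   \code{nu_n} is missing.
#' @return dimensionless expected R2/R1.
#' @export
expected_r2r1 <- function(tau_c, nu_n = NULL, field_h1 = 800e6) {
  if (any(tau_c <= 0)) stop("tau_c must be positive")
  if (is.null(nu_n)) nu_n <- 0.1013756 * field_h1
  ((4 * pi * nu_n * tau_c)^2 + 7) / 6
}

#' Fit a full relaxation profile from decay tables
#'
#' @param decays long data.frame with columns residue, experiment ("R1" or
#'   "R1rho"), delay_s, intensity.
#' @param spin_lock spin-lock field (Hz) for the R2 extraction.
#' @param offsets optional data.frame (residue, offset_hz); default
#'   on-resonance.
#' @return \code{relaxation_profile} data.frame: residue, r1, r1_err, r1rho,
#'   r1rho_err, r2, ratio.
#' @export
fit_relaxation_profile <- function(decays, spin_lock = 1000, offsets = NULL) {
  need <- c("residue", "experiment", "delay_s", "intensity")
  if (!all(need %in% names(decays))) {
    stop("decay table needs columns: ", paste(need, collapse = ", "))
  }
  resnos <- sort(unique(decays$residue))
  rows <- lapply(resnos, function(r) {
    out <- data.frame(residue = r, r1 = NA_real_, r1_err = NA_real_,
                      r1rho = NA_real_, r1rho_err = NA_real_,
                      r2 = NA_real_, ratio = NA_real_)
    for (exp_name in c("R1", "R1rho")) {
      d <- decays[decays$residue == r & decays$experiment == exp_name, ]
      if (nrow(d) >= 3L) {
        f <- fit_exponential(d$delay_s, d$intensity)
        if (exp_name == "R1") {
          out$r1 <- f$rate; out$r1_err <- f$rate_err
        } else {
          out$r1rho <- f$rate; out$r1rho_err <- f$rate_err
        }
      }
    }
    if (is.finite(out$r1) && is.finite(out$r1rho) && out$r1 > 0) {
      off <- 0
      if (!is.null(offsets)) {
        i <- match(r, offsets$residue)
        if (!is.na(i)) off <- offsets$offset_hz[i]
      }
      out$r2 <- r2_from_r1rho(out$r1rho, out$r1, spin_lock, off)
      out$ratio <- out$r2 / out$r1
    }
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("relaxation_profile", "data.frame")
  res
}

#' Flag residues with depressed R2/R1 (enhanced flexibility)
#'
#' Residues whose R2/R1 ratio falls more than \code{n_sigma} spreads below
#' the profile average are flagged as flexible. The center/spread are the
#' mean/SD by default, or median/MAD (x 1.4826) with \code{robust = TRUE}.
#'
#' @param profile \code{relaxation_profile} (needs residue, ratio).
#' @param n_sigma threshold in spread units (default 1).
#' @param robust use median/MAD instead of mean/SD.
#' @return integer vector of flagged residue numbers.
#' @export
flag_flexible_residues <- function(profile, n_sigma = 1, robust = FALSE) {
  ok <- is.finite(profile$ratio)
  if (sum(ok) < 5L) stop("need >= 5 residues with R2/R1 ratios")
  x <- profile$ratio[ok]
  if (robust) {
    center <- stats::median(x)
    spread <- stats::mad(x) # constant = 1.4826 by default
  } else {
    center <- mean(x)
    spread <- stats::sd(x)
  }
  thr <- center - n_sigma * spread
  sort(profile$residue[ok][x < thr])
}

#' Read a relaxation decay table from TSV
#' @param path TSV with columns residue, experiment, delay_s, intensity.
#' @return data.frame.
#' @export
read_decay_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "experiment", "delay_s", "intensity")
  if (!all(need %in% names(d))) {
    stop("decay table needs columns: ", paste(need, collapse = ", "))
  }
  d
}
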