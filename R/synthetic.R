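# Synthetic-data generation with known ground truth for every pipeline stage.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  force(code)
}

# internal coordinate placement: position D with |CD| = bond, angle(BCD) =
# theta, torsion(ABCD) = tau (standard chain-extension construction)
.place_atom <- function(a, b, c, bond, theta, tau) {
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a; ab <- ab / sqrt(sum(ab^2))
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- bond * c(-cos(theta), sin(theta) * cos(tau), sin(theta) * sin(tau))
  c + d[1] * bc + d[2] * m + d[3] * n
}

#' Build an idealized peptide backbone from phi/psi angles
#'
#' Places N, CA, C, O and amide H atoms with ideal bond lengths and angles
#' (N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 A; omega = 180 degrees);
#' H sits 1.02 A from N on the external bisector of C(i-1)-N-CA.
#'
#' @param phi,psi backbone dihedrals in degrees, one per residue (phi of the
#'   first and psi of the last are unused).
#' @param resnames residue names (default "ALA").
#' @return \code{structure_model}.
#' @export
build_backbone <- function(phi, psi, resnames = NULL) {
  n <- length(phi)
  if (length(psi) != n) stop("phi and psi must have equal length")
  if (is.null(resnames)) resnames <- rep("ALA", n)
  d2r <- pi / 180
  ang_NCAC <- 111.2 * d2r; ang_CACN <- 116.2 * d2r
  ang_CNCA <- 121.7 * d2r; ang_CACO <- 120.8 * d2r
  N <- CA <- C <- O <- H <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(ang_NCAC), sin(ang_NCAC), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- .place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                            1.329, ang_CACN, psi[i - 1] * d2r)
      CA[i, ] <- .place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                             1.458, ang_CNCA, pi) # omega = 180
      C[i, ] <- .place_atom(C[i - 1, ], N[i, ], CA[i, ],
                            1.525, ang_NCAC, phi[i] * d2r)
      # amide H on the external bisector of C(i-1)-N-CA
      u1 <- N[i, ] - C[i - 1, ]; u1 <- u1 / sqrt(sum(u1^2))
      u2 <- N[i, ] - CA[i, ]; u2 <- u2 / sqrt(sum(u2^2))
      hb <- u1 + u2
      H[i, ] <- N[i, ] + 1.02 * hb / sqrt(sum(hb^2))
    }
    psi_i <- if (i < n) psi[i] else -47
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ],
                          1.231, ang_CACO, (psi_i + 180) * d2r)
  }
  rows <- list()
  for (i in seq_len(n)) {
    at <- rbind(N = N[i, ], CA = CA[i, ], C = C[i, ], O = O[i, ])
    if (i > 1 && resnames[i] != "PRO") at <- rbind(at, H = H[i, ])
    rows[[i]] <- data.frame(resno = i, resname = resnames[i],
                            atom = rownames(at),
                            x = at[, 1], y = at[, 2], z = at[, 3])
  }
  structure_model(do.call(rbind, rows))
}

.random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# rotate v about unit axis by angle (Rodrigues)
.rotate_about <- function(xyz, origin, axis, angle) {
  x <- sweep(xyz, 2, origin)
  k <- axis / sqrt(sum(axis^2))
  kx <- x %*% k
  cross <- cbind(k[2] * x[, 3] - k[3] * x[, 2],
                 k[3] * x[, 1] - k[1] * x[, 3],
                 k[1] * x[, 2] - k[2] * x[, 1])
  rot <- x * cos(angle) + cross * sin(angle) +
    outer(as.numeric(kx), k) * (1 - cos(angle))
  sweep(rot, 2, origin, "+")
}

# rigid hinge rotation of the loop segment (changes both positions and bond
# orientations, as a real loop excursion does) plus optional all-atom jitter
.displace_model <- function(model, loop_res, axis, amplitude, jitter_sigma) {
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  in_loop <- a$resno %in% loop_res
  if (!is.null(axis) && amplitude > 0 && any(in_loop)) {
    hinge <- xyz[which(in_loop)[1], ] # N of the first loop residue
    loop_xyz <- xyz[in_loop, , drop = FALSE]
    k <- axis / sqrt(sum(axis^2))
    rel <- sweep(loop_xyz, 2, hinge)
    rho <- sqrt(rowSums((rel - outer(as.numeric(rel %*% k), k))^2))
    rho_max <- max(rho)
    # chord displacement of a point at distance rho from the axis is
    # 2 sin(theta/2) rho; pick theta so the farthest loop atom moves by
    # `amplitude` (or the geometric maximum)
    theta <- 2 * asin(min(1, amplitude / (2 * rho_max)))
    xyz[in_loop, ] <- .rotate_about(loop_xyz, hinge, k, theta)
  }
  if (jitter_sigma > 0) {
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, jitter_sigma), ncol = 3)
  }
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

#' Generate a toy helix-loop-helix conformer ensemble
#'
#' Builds an idealized helix-loop-helix backbone (helical phi/psi -57/-47,
#' extended loop -75/+145) and derives ensemble members by a rigid hinge
#' rotation of the loop segment (random axis per member, rotation angle set
#' so the farthest loop atom moves by \code{loop_disp}) plus isotropic
#' Gaussian jitter on every atom. A hinge rotation displaces the loop and
#' reorients its N-H bonds, as a real loop excursion does. The displaced
#' segment is the planted flexible region; everything else is rigid up to
#' the jitter.
#'
#' @param n_residues total chain length (>= 6).
#' @param n_members ensemble size.
#' @param loop integer range of loop residues (default 10:15).
#' @param loop_disp rigid loop displacement amplitude (A); member 1 keeps
#'   the reference geometry.
#' @param jitter_sigma per-atom Gaussian jitter SD (A).
#' @param seed integer seed (reproducible; global RNG state untouched).
#' @return \code{conformer_ensemble} with attribute \code{flexible_residues}.
#' @export
make_toy_ensemble <- function(n_residues = 36, n_members = 5,
                              loop = 10:15, loop_disp = 5,
                              jitter_sigma = 0, seed = NULL) {
  if (n_residues < 6L) stop("need >= 6 residues")
  helix <- c(-57, -47); loopang <- c(-75, 145)
  phi <- rep(helix[1], n_residues); psi <- rep(helix[2], n_residues)
  phi[loop] <- loopang[1]; psi[loop] <- loopang[2]
  base <- build_backbone(phi, psi)
  members <- .with_seed(seed, {
    lapply(seq_len(n_members), function(k) {
      axis <- if (k == 1L || loop_disp == 0) NULL else .random_unit_vector()
      m <- .displace_model(base, loop, axis, loop_disp, jitter_sigma)
      m$model_id <- k
      m
    })
  })
  e <- conformer_ensemble(members)
  attr(e, "flexible_residues") <- as.integer(loop)
  e
}

#' Generate a conformer pool with planted conformers plus decoys
#'
#' Builds \code{n_planted} well-separated conformers (loop displacements
#' along orthogonal directions) and surrounds each with
#' \code{decoys_per} small-jitter copies, emulating a clustered trajectory
#' in which the planted structures are the natural cluster centers.
#'
#' @inheritParams make_toy_ensemble
#' @param n_planted number of distinct planted conformers (<= 3 orthogonal
#'   displacement directions plus the reference).
#' @param decoys_per jittered decoys per planted conformer.
#' @param decoy_jitter decoy jitter SD (A).
#' @return list(pool = \code{conformer_ensemble}, planted = indices of the
#'   planted members within the pool).
#' @export
make_conformer_pool <- function(n_planted = 3, decoys_per = 3,
                                n_residues = 36, loop = 10:15, loop_disp = 6,
                                decoy_jitter = 0.3, seed = NULL) {
  if (n_planted > 4L) stop("at most 4 planted conformers supported")
  helix <- c(-57, -47); loopang <- c(-75, 145)
  phi <- rep(helix[1], n_residues); psi <- rep(helix[2], n_residues)
  phi[loop] <- loopang[1]; psi[loop] <- loopang[2]
  base <- build_backbone(phi, psi)
  axes <- list(NULL, c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))[seq_len(n_planted)]
  .with_seed(seed, {
    members <- list()
    planted <- integer(n_planted)
    for (k in seq_len(n_planted)) {
      pk <- .displace_model(base, loop, axes[[k]], loop_disp, 0)
      planted[k] <- length(members) + 1L
      members[[length(members) + 1L]] <- pk
      for (d in seq_len(decoys_per)) {
        members[[length(members) + 1L]] <-
          .displace_model(pk, loop, NULL, 0, decoy_jitter)
      }
    }
    for (k in seq_along(members)) members[[k]]$model_id <- k
    list(pool = conformer_ensemble(members), planted = planted)
  })
}

#' Simulate RDCs from an ensemble under known member tensors
#'
#' Forward back-calculation plus i.i.d. Gaussian noise; the error column of
#' the returned set is the noise SD (floored at 0.1 Hz).
#'
#' @param e \code{conformer_ensemble}.
#' @param tensors list of \code{alignment_tensor}, one per member
#'   (population scaling folded into the magnitudes).
#' @param noise_sigma Gaussian noise SD in Hz; the default 1.5 Hz sits under
#'   the sub-2 Hz error typical of intensity-based coupling measurement.
#' @param seed integer seed.
#' @return \code{rdc_set}.
#' @export
simulate_rdcs <- function(e, tensors, noise_sigma = 1.5, seed = NULL) {
  pred <- back_calc_rdc(tensors, lapply(e$members, identity))
  .with_seed(seed, {
    noisy <- pred$rdc_calc + stats::rnorm(nrow(pred), 0, noise_sigma)
    rdc_set(pred$resno, noisy, rep(max(noise_sigma, 0.1), nrow(pred)))
  })
}

#' Simulate mono-exponential relaxation decays
#'
#' I(t) = 100 exp(-R t) (1 + eps), eps ~ N(0, noise_frac).
#'
#' @param rates data.frame with columns residue, rate (1/s) and experiment
#'   ("R1"/"R1rho"), or a named numeric vector for a single experiment.
#' @param schedule delays in seconds; defaults to the standard schedule for
#'   each experiment.
#' @param noise_frac fractional intensity noise SD.
#' @param seed integer seed.
#' @return long data.frame residue, experiment, delay_s, intensity.
#' @export
simulate_relaxation_decays <- function(rates, schedule = NULL,
                                       noise_frac = 0.02, seed = NULL) {
  if (is.numeric(rates)) {
    rates <- data.frame(residue = seq_along(rates), rate = rates,
                        experiment = "R1")
  }
  .with_seed(seed, {
    out <- lapply(seq_len(nrow(rates)), function(i) {
      ex <- rates$experiment[i]
      del <- if (!is.null(schedule)) schedule else
        if (ex == "R1rho") r1rho_delay_schedule() else r1_delay_schedule()
      ideal <- 100 * exp(-rates$rate[i] * del)
      data.frame(residue = rates$residue[i], experiment = ex, delay_s = del,
                 intensity = ideal * (1 + stats::rnorm(length(del), 0,
                                                       noise_frac)))
    })
    do.call(rbind, out)
  })
}

#' Simulate CPMG dispersion curves from a two-site exchange model
#'
#' Forward Carver-Richards evaluation with Gaussian noise added either to
#' R2,eff directly or to the underlying constant-time intensities (the way
#' real data arise; default).
#'
#' @param m \code{exchange_model}.
#' @param fields CPMG fields (Hz).
#' @param tcp constant-time delay (s).
#' @param noise_sigma noise SD in 1/s (both modes express noise on the
#'   R2,eff scale; intensity mode converts through the exponential).
#' @param mode "intensity" or "r2eff".
#' @param seed integer seed.
#' @return data.frame residue, temperature, nu_cpmg, r2eff, err.
#' @export
simulate_dispersion <- function(m, fields = cpmg_field_schedule(),
                                tcp = cpmg_tcp_default(), noise_sigma = 0.3,
                                mode = c("intensity", "r2eff"), seed = NULL) {
  mode <- match.arg(mode)
  ideal <- carver_richards_model(m, fields)
  .with_seed(seed, {
    n <- nrow(ideal)
    if (noise_sigma == 0) {
      r2 <- ideal$r2eff
    } else if (mode == "r2eff") {
      r2 <- ideal$r2eff + stats::rnorm(n, 0, noise_sigma)
    } else {
      # perturb intensities so that the induced R2eff noise SD ~ noise_sigma
      i_ideal <- exp(-ideal$r2eff * tcp)
      i_noisy <- i_ideal * exp(-stats::rnorm(n, 0, noise_sigma * tcp))
      r2 <- r2eff_from_intensities(i_noisy, 1, tcp)
    }
    data.frame(residue = ideal$residue, temperature = m$temperature,
               nu_cpmg = ideal$nu_cpmg, r2eff = r2,
               err = max(noise_sigma, 1e-3))
  })
}

#' Materialize a complete demo dataset on disk
#'
#' Writes every input file the pipeline drivers consume, generated with
#' known ground truth: a multi-model PDB conformer pool (3 planted
#' conformers + decoys), a matching RDC table simulated from known member
#' tensors, R1/R1rho decay tables with a planted low-R2 segment, a CPMG
#' dispersion table from a known exchange model, and a short synthetic
#' energy trace for aMD parameter calculation.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed controlling all randomness.
#' @return named list of file paths plus the ground-truth objects,
#'   invisibly.
#' @export
materialize_demo_dataset <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pool <- make_conformer_pool(n_planted = 3, decoys_per = 3, seed = seed)
  tensors <- lapply(1:3, function(k) {
    alignment_tensor(c(9, -11, 13)[k], c(0.2, 0.4, 0.6)[k],
                     c(0.3 * k, 0.5 * k, -0.2 * k))
  })
  obs <- simulate_rdcs(conformer_ensemble(pool$pool$members[pool$planted]),
                       tensors, noise_sigma = 0, seed = seed + 1L)
  pdb <- file.path(dir, "pool.pdb")
  write_structure(pool$pool, pdb)
  rdc <- file.path(dir, "rdc.tsv")
  write_rdc_table(obs, rdc)

  rates <- rbind(
    data.frame(residue = 1:20, rate = 1.1, experiment = "R1"),
    data.frame(residue = 1:20, rate = c(rep(120, 6), rep(60, 5),
                                        rep(120, 9)), experiment = "R1rho"))
  decay <- file.path(dir, "decays.tsv")
  utils::write.table(simulate_relaxation_decays(rates, noise_frac = 0.005,
                                                seed = seed + 2L),
                     decay, sep = "\t", quote = FALSE, row.names = FALSE)

  ex <- exchange_model(0.03, 500, dw = dw_ppm_to_rads(c(1.8, 2.6)),
                       r2_0 = c(20, 26), temperature = 30)
  cur <- simulate_dispersion(ex, noise_sigma = 0.2, seed = seed + 3L)
  cpmg <- file.path(dir, "cpmg.tsv")
  utils::write.table(data.frame(residue = cur$residue, temperature_C = 30,
                                nu_cpmg_hz = cur$nu_cpmg,
                                r2eff_s = cur$r2eff, err_s = cur$err),
                     cpmg, sep = "\t", quote = FALSE, row.names = FALSE)

  energy <- file.path(dir, "energy.tsv")
  tr <- .with_seed(seed + 4L, data.frame(
    time = seq_len(200),
    dihedral_energy = stats::rnorm(200, 8000, 50),
    potential_energy = stats::rnorm(200, -195000, 300)))
  utils::write.table(tr, energy, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(pdb = pdb, rdc = rdc, decay = decay, cpmg = cpmg,
                 energy = energy, pool = pool, tensors = tensors,
                 exchange = ex, flexible = 7:11))
}
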