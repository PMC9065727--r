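# Dual-boost accelerated-MD acceleration parameters from short-MD statistics.

#' Collect energy statistics from a short conventional MD trace
#'
#' @param table data.frame (or TSV path) with columns time, dihedral_energy,
#'   potential_energy (kcal/mol).
#' @return \code{energy_stats}: list(e_d_prime, e_p_prime, n_frames), the
#'   mean dihedral and total potential energies.
#' @export
collect_energy_stats <- function(table) {
  if (is.character(table)) table <- utils::read.delim(table)
  need <- c("dihedral_energy", "potential_energy")
  if (!all(need %in% names(table))) {
    stop("energy trace needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(table) < 1L) stop("empty energy trace")
  structure(list(e_d_prime = mean(table$dihedral_energy),
                 e_p_prime = mean(table$potential_energy),
                 n_frames = nrow(table)),
            class = "energy_stats")
}

#' Dual-boost aMD acceleration parameters
#'
#' Threshold energies and smoothing factors for dual-boost accelerated MD:
#' \deqn{E_D = E_D' + \alpha_1 N_{res} / 5, \quad
#'       \alpha_D = \alpha_1 N_{res} / 5,}
#' \deqn{E_P = E_P' + \alpha_2 N_{atom}, \quad
#'       \alpha_P = \alpha_2 N_{atom},}
#' with \eqn{\alpha_1} = 3.5 kcal/mol per residue and \eqn{\alpha_2} = 0.2
#' kcal/mol per atom, the approximate energy contribution per degree of
#' freedom. E_D'/E_P' are the mean dihedral/total potential energies from a
#' short conventional MD run.
#'
#' @param stats \code{energy_stats} (see \code{\link{collect_energy_stats}}),
#'   or a list with e_d_prime and e_p_prime.
#' @param n_res number of residues in the simulated system.
#' @param n_atom number of atoms in the simulated system (including solvent).
#' @param alpha1,alpha2 per-residue / per-atom energy contributions
#'   (kcal/mol).
#' @return \code{amd_params}: list(e_d, alpha_d, e_p, alpha_p, n_res,
#'   n_atom), energies in kcal/mol.
#' @export
amd_parameters <- function(stats, n_res, n_atom, alpha1 = 3.5, alpha2 = 0.2) {
  if (n_res <= 0 || n_atom <= 0) stop("n_res and n_atom must be positive")
  alpha_d <- alpha1 * n_res / 5
  alpha_p <- alpha2 * n_atom
  structure(list(e_d = stats$e_d_prime + alpha_d,
                 alpha_d = alpha_d,
                 e_p = stats$e_p_prime + alpha_p,
                 alpha_p = alpha_p,
                 n_res = n_res, n_atom = n_atom),
            class = "amd_params")
}

#' @export
print.amd_params <- function(x, ...) {
  cat(format_amd_params(x), sep = "\n")
  invisible(x)
}

#' Format aMD parameters as a structured text block
#'
#' Suitable for manual transfer into an MD engine's input file.
#'
#' @param x \code{amd_params}.
#' @return character vector of lines.
#' @export
format_amd_params <- function(x) {
  c("# dual-boost aMD acceleration parameters (kcal/mol)",
    sprintf("E_D     = %.4f", x$e_d),
    sprintf("alpha_D = %.4f", x$alpha_d),
    sprintf("E_P     = %.4f", x$e_p),
    sprintf("alpha_P = %.4f", x$alpha_p),
    sprintf("N_res   = %d", as.integer(x$n_res)),
    sprintf("N_atom  = %d", as.integer(x$n_atom)))
}
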