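# Per-atom fluctuations, B-factors, displacement profiles over an ensemble.

#' Per-atom mean-square fluctuations over a conformer ensemble
#'
#' Members are superposed onto an iteratively refined mean structure
#' (\code{rounds} rounds: superpose on current mean, recompute mean), then
#' the mean-square displacement of each selected atom from its mean position
#' is reported together with the B-factor 8 pi^2 <u^2>.
#'
#' @param e \code{conformer_ensemble} (>= 2 members for non-trivial output;
#'   a single member yields a zero profile with a warning).
#' @param selection atoms to report (default "CA").
#' @param fit_selection atoms used for the superposition (default
#'   "backbone").
#' @param fit_residues optional residue numbers restricting the
#'   superposition anchor to one domain (fit the domain, measure
#'   everywhere).
#' @param rounds iterative mean-refinement rounds.
#' @return \code{fluctuation_profile} data.frame: resno, atom, msd (A^2),
#'   bfactor (A^2).
#' @export
atomic_fluctuations <- function(e, selection = "CA",
                                fit_selection = "backbone",
                                fit_residues = NULL, rounds = 2L) {
  members <- e$members
  n <- length(members)
  a1 <- members[[1]]$atoms
  if (n < 2L) {
    warning("single-member ensemble: fluctuations are identically zero")
    sel <- resolve_selection(selection)
    keep <- if (is.null(sel)) rep(TRUE, nrow(a1)) else a1$atom %in% sel
    out <- data.frame(resno = a1$resno[keep], atom = a1$atom[keep],
                      msd = 0, bfactor = 0)
    class(out) <- c("fluctuation_profile", "data.frame")
    return(out)
  }
  coords <- lapply(members, function(m) as.matrix(m$atoms[, c("x", "y", "z")]))
  fit_sel <- resolve_selection(fit_selection)
  keep_fit <- if (is.null(fit_sel)) rep(TRUE, nrow(a1)) else
    a1$atom %in% fit_sel
  if (!is.null(fit_residues)) keep_fit <- keep_fit & a1$resno %in% fit_residues
  fit_idx <- which(keep_fit)
  if (length(fit_idx) < 3L) stop("fit selection has < 3 atoms")

  ref <- coords[[1]][fit_idx, , drop = FALSE]
  for (round in seq_len(rounds)) {
    for (k in seq_len(n)) {
      f <- kabsch(coords[[k]][fit_idx, , drop = FALSE], ref)
      coords[[k]] <- sweep(coords[[k]] %*% t(f$rotation), 2, f$translation, "+")
    }
    ref <- Reduce(`+`, lapply(coords, function(x) x[fit_idx, , drop = FALSE])) / n
  }
  mean_all <- Reduce(`+`, coords) / n
  msd <- Reduce(`+`, lapply(coords, function(x) rowSums((x - mean_all)^2))) / n

  sel <- resolve_selection(selection)
  keep <- if (is.null(sel)) rep(TRUE, nrow(a1)) else a1$atom %in% sel
  out <- data.frame(resno = a1$resno[keep], atom = a1$atom[keep],
                    msd = msd[keep], bfactor = bfactor_from_msd(msd[keep]))
  rownames(out) <- NULL
  class(out) <- c("fluctuation_profile", "data.frame")
  out
}

#' B-factor from mean-square displacement
#'
#' The crystallographic temperature-factor convention B = 8 pi^2 <u^2>.
#'
#' @param msd mean-square displacement (A^2), non-negative.
#' @return B-factor (A^2).
#' @export
bfactor_from_msd <- function(msd) {
  if (any(msd < 0)) stop("mean-square displacement must be >= 0")
  8 * pi^2 * msd
}

#' Per-residue C-alpha displacement between two structures
#'
#' Superposes \code{member} onto \code{reference} over the fit selection and
#' reports the distance between paired C-alpha atoms per residue. Because a
#' least-squares superposition precedes the measurement, the profile is
#' invariant to any rigid motion of either input.
#'
#' @param member,reference \code{structure_model} objects sharing residues
#'   with CA atoms.
#' @param fit_selection atoms anchoring the superposition (default "CA").
#' @param fit_residues optional residue numbers restricting the anchor to
#'   one domain (fit the domain, measure everywhere).
#' @return data.frame resno, displacement (A).
#' @export
displacement_profile <- function(member, reference, fit_selection = "CA",
                                 fit_residues = NULL) {
  if (!is.null(fit_residues)) {
    # derive the transform from the domain anchor, apply it everywhere
    anchor <- member
    anchor$atoms <- anchor$atoms[anchor$atoms$resno %in% fit_residues, ]
    sp0 <- superpose(anchor, reference, fit_selection)
    xyz <- as.matrix(member$atoms[, c("x", "y", "z")])
    moved <- sweep(xyz %*% t(sp0$rotation), 2, sp0$translation, "+")
    tm <- member
    tm$atoms$x <- moved[, 1]; tm$atoms$y <- moved[, 2]
    tm$atoms$z <- moved[, 3]
    sp <- list(transformed = tm)
  } else {
    sp <- superpose(member, reference, fit_selection)
  }
  m <- .coords(sp$transformed, "CA")
  r <- .coords(reference, "CA")
  shared <- intersect(rownames(m), rownames(r))
  if (length(shared) == 0L) stop("no shared CA atoms")
  d <- sqrt(rowSums((m[shared, , drop = FALSE] - r[shared, , drop = FALSE])^2))
  resno <- as.integer(sub(" .*", "", shared))
  out <- data.frame(resno = resno, displacement = as.numeric(d))
  out[order(out$resno), , drop = FALSE]
}
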