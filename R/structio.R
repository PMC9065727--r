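# Structure input/output, superposition, clustering.

.BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Resolve an atom-selection keyword to atom names
#'
#' The selection mini-language accepts the keywords \code{"backbone"}
#' (N, CA, C, O), \code{"CA"}, \code{"all"}, or a comma-separated list of
#' atom names such as \code{"N,H"}.
#'
#' @param selection character scalar.
#' @return character vector of atom names, or \code{NULL} meaning all atoms.
#' @keywords internal
resolve_selection <- function(selection) {
  if (is.null(selection) || identical(selection, "all")) return(NULL)
  if (identical(selection, "backbone")) return(.BACKBONE_ATOMS)
  trimws(strsplit(selection, ",", fixed = TRUE)[[1]])
}

#' Construct a structure model
#'
#' A \code{structure_model} is a plain atom table (one row per atom) with the
#' columns \code{resno}, \code{resname}, \code{atom}, \code{x}, \code{y},
#' \code{z}. Residue numbers are 1-based PDB numbering and must be
#' non-decreasing down the table.
#'
#' @param atoms data.frame with columns resno, resname, atom, x, y, z.
#' @param model_id integer model identifier (MODEL block number).
#' @return object of class \code{structure_model}.
#' @export
structure_model <- function(atoms, model_id = 1L) {
  need <- c("resno", "resname", "atom", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("atom table must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("empty model")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates")
  }
  if (is.unsorted(atoms$resno)) stop("residue numbers must be non-decreasing")
  atoms <- atoms[, need]
  rownames(atoms) <- NULL
  structure(list(model_id = as.integer(model_id), atoms = atoms),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> model %d: %d atoms, %d residues\n",
              x$model_id, nrow(x$atoms), length(unique(x$atoms$resno))))
  invisible(x)
}

#' Construct a conformer ensemble
#'
#' @param members list of \code{structure_model} objects sharing an identical
#'   (resno, atom) roster.
#' @param weights fractional populations; default uniform. Must be
#'   non-negative and sum to 1 (within 1e-9).
#' @return object of class \code{conformer_ensemble}.
#' @export
conformer_ensemble <- function(members, weights = NULL) {
  if (length(members) == 0L) stop("empty ensemble")
  roster <- paste(members[[1]]$atoms$resno, members[[1]]$atoms$atom)
  for (m in members[-1]) {
    if (!identical(paste(m$atoms$resno, m$atoms$atom), roster)) {
      stop("ensemble members have incongruent atom rosters")
    }
  }
  if (is.null(weights)) weights <- rep(1 / length(members), length(members))
  if (length(weights) != length(members)) stop("one weight per member")
  if (any(weights < 0)) stop("weights must be >= 0")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  structure(list(members = members, weights = weights),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> %d members, %d atoms each\n",
              length(x$members), nrow(x$members[[1]]$atoms)))
  invisible(x)
}

#' @export
length.conformer_ensemble <- function(x) length(x$members)

.model_from_bio3d <- function(atom, xyz, model_id) {
  structure_model(data.frame(resno = atom$resno,
                             resname = atom$resid,
                             atom = atom$elety,
                             x = xyz[seq(1, length(xyz), 3)],
                             y = xyz[seq(2, length(xyz), 3)],
                             z = xyz[seq(3, length(xyz), 3)],
                             stringsAsFactors = FALSE),
                  model_id = model_id)
}

#' Read a structure (or multi-model ensemble) from a PDB file
#'
#' Parses ATOM records with \pkg{bio3d}. Alternate locations are resolved by
#' keeping the highest-occupancy altloc per atom (ties go to altloc "A");
#' a message reports how many atoms were resolved this way. When the file
#' holds several MODEL blocks and \code{model_index} is \code{NULL}, all
#' models are returned as a \code{conformer_ensemble} with uniform weights.
#'
#' @param path PDB file path.
#' @param model_index 1-based model to extract, or \code{NULL} for all.
#' @return A \code{structure_model}, or a \code{conformer_ensemble} when the
#'   file is multi-model and \code{model_index} is \code{NULL}.
#' @export
read_structure <- function(path, model_index = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  atom <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atom) == 0L) stop("no ATOM records in ", path)

  # altloc resolution: highest occupancy wins, tie -> 'A' (alphabetical)
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  occ <- atom$o
  occ[is.na(occ)] <- 1
  key <- paste(atom$chain, atom$resno, atom$elety)
  keep <- rep(TRUE, nrow(atom))
  dup_keys <- unique(key[duplicated(key)])
  if (length(dup_keys)) {
    for (k in dup_keys) {
      idx <- which(key == k)
      ord <- order(-occ[idx], alt[idx])
      keep[idx[-ord[1]]] <- FALSE
    }
    message(sprintf("resolved %d altloc atoms (kept highest occupancy)",
                    length(dup_keys)))
  }
  rows <- which(pdb$atom$type == "ATOM")[keep]
  atom <- atom[keep, , drop = FALSE]
  xyz_cols <- as.vector(rbind(3 * rows - 2, 3 * rows - 1, 3 * rows))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)

  if (!is.null(model_index)) {
    if (model_index < 1 || model_index > n_models) {
      stop("model_index ", model_index, " out of range (", n_models, " models)")
    }
    return(.model_from_bio3d(atom, xyz[model_index, xyz_cols], model_index))
  }
  if (n_models == 1L) return(.model_from_bio3d(atom, xyz[1, xyz_cols], 1L))
  conformer_ensemble(lapply(seq_len(n_models), function(m) {
    .model_from_bio3d(atom, xyz[m, xyz_cols], m)
  }))
}

#' Write a structure or ensemble to a (multi-model) PDB file
#'
#' @param x \code{structure_model} or \code{conformer_ensemble}.
#' @param path output file path.
#' @param bfactor optional numeric vector (one per atom) written into the
#'   B-factor column; recycled across models.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(x, path, bfactor = NULL) {
  members <- if (inherits(x, "conformer_ensemble")) x$members else list(x)
  a <- members[[1]]$atoms
  xyz <- do.call(rbind, lapply(members, function(m) {
    as.vector(t(as.matrix(m$atoms[, c("x", "y", "z")])))
  }))
  if (is.null(bfactor)) bfactor <- rep(0, nrow(a))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, resid = a$resname,
                   elety = a$atom, b = bfactor)
  invisible(path)
}

.coords <- function(model, sel_atoms = NULL, resno = NULL) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel_atoms)) keep <- keep & a$atom %in% sel_atoms
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  m <- as.matrix(a[keep, c("x", "y", "z")])
  rownames(m) <- paste(a$resno[keep], a$atom[keep])
  m
}

.atom_xyz <- function(model, resno, atom) {
  a <- model$atoms
  i <- which(a$resno == resno & a$atom == atom)
  if (length(i) == 0L) return(NULL)
  as.numeric(a[i[1], c("x", "y", "z")])
}

#' Extract unit amide N-H bond vectors
#'
#' Returns the unit vector from the backbone amide nitrogen to its hydrogen
#' for every non-proline residue. Prolines carry no amide proton and are
#' always skipped. When the hydrogen is absent and \code{build_missing_h} is
#' set, H is placed 1.02 Angstrom from N along the in-plane external bisector
#' of the C(i-1)-N-CA angle (the standard idealized amide geometry); the
#' first residue cannot be built for lack of a preceding carbonyl carbon.
#'
#' @param s \code{structure_model}.
#' @param build_missing_h logical; construct H where missing.
#' @return \code{nh_vectors}: data.frame with columns resno, x, y, z
#'   (unit norm).
#' @export
extract_nh_vectors <- function(s, build_missing_h = FALSE) {
  a <- s$atoms
  resnos <- unique(a$resno)
  out <- vector("list", length(resnos))
  for (i in seq_along(resnos)) {
    r <- resnos[i]
    rn <- a$resname[a$resno == r][1]
    if (identical(rn, "PRO")) next
    n <- .atom_xyz(s, r, "N")
    if (is.null(n)) next
    h <- .atom_xyz(s, r, "H")
    if (is.null(h)) h <- .atom_xyz(s, r, "HN")
    if (is.null(h) && build_missing_h) {
      cprev <- .atom_xyz(s, r - 1L, "C")
      ca <- .atom_xyz(s, r, "CA")
      if (!is.null(cprev) && !is.null(ca)) {
        u1 <- (n - cprev) / sqrt(sum((n - cprev)^2))
        u2 <- (n - ca) / sqrt(sum((n - ca)^2))
        d <- u1 + u2
        h <- n + 1.02 * d / sqrt(sum(d^2))
      }
    }
    if (is.null(h)) {
      # the chain's first residue has no amide proton to build; skip quietly
      if (r != min(resnos)) warning("residue ", r, ": no amide H; skipped")
      next
    }
    v <- h - n
    v <- v / sqrt(sum(v^2))
    out[[i]] <- data.frame(resno = r, x = v[1], y = v[2], z = v[3])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(resno = integer(), x = numeric(),
                                      y = numeric(), z = numeric())
  rownames(res) <- NULL
  class(res) <- c("nh_vectors", "data.frame")
  res
}

#' Kabsch least-squares rigid-body superposition
#'
#' Finds the proper rotation (determinant +1, no reflection) and translation
#' minimizing the RMSD between paired atoms of \code{mobile} and
#' \code{reference}. Atoms are paired on (resno, atom) within the selection.
#'
#' @param mobile,reference \code{structure_model} objects.
#' @param selection atom selection (see \code{\link{resolve_selection}});
#'   default "backbone".
#' @return list with \code{rotation} (3x3), \code{translation} (length 3;
#'   transformed x = R x + t), \code{rmsd} over the selection, and
#'   \code{transformed}, the mobile model with all atoms moved.
#' @export
superpose <- function(mobile, reference, selection = "backbone") {
  sel <- resolve_selection(selection)
  P <- .coords(mobile, sel)
  Q <- .coords(reference, sel)
  shared <- intersect(rownames(P), rownames(Q))
  if (length(shared) < 3L) stop("need >= 3 paired atoms, got ", length(shared))
  P <- P[shared, , drop = FALSE]
  Q <- Q[shared, , drop = FALSE]
  fit <- kabsch(P, Q)
  all_xyz <- as.matrix(mobile$atoms[, c("x", "y", "z")])
  moved <- sweep(all_xyz %*% t(fit$rotation), 2, fit$translation, "+")
  transformed <- mobile
  transformed$atoms$x <- moved[, 1]
  transformed$atoms$y <- moved[, 2]
  transformed$atoms$z <- moved[, 3]
  list(rotation = fit$rotation, translation = fit$translation,
       rmsd = fit$rmsd, transformed = transformed)
}

#' Kabsch algorithm on raw coordinate matrices
#'
#' @param P mobile n x 3 coordinates; Q reference n x 3.
#' @param Q reference coordinates.
#' @return list(rotation, translation, rmsd); transformed P is
#'   \code{P \%*\% t(rotation) + translation}.
#' @export
kabsch <- function(P, Q) {
  if (nrow(P) < 3L) stop("need >= 3 atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  # collinearity guard: rank of centered cloud must be >= 2
  if (sum(svd(Pc)$d > 1e-8 * max(1, max(abs(Pc)))) < 2L) {
    stop("selection atoms are collinear; superposition is degenerate")
  }
  s <- svd(t(Pc) %*% Qc)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  list(rotation = R, translation = as.numeric(cq - R %*% cp), rmsd = rmsd)
}

#' Pairwise superposed RMSD matrix over an ensemble
#'
#' @param e \code{conformer_ensemble} with >= 2 members.
#' @param selection atom selection; default "CA".
#' @return symmetric matrix of superposed RMSDs (Angstrom), zero diagonal.
#' @export
pairwise_rmsd_matrix <- function(e, selection = "CA") {
  n <- length(e$members)
  if (n < 2L) stop("need >= 2 members")
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- superpose(e$members[[i]], e$members[[j]], selection)$rmsd
      M[i, j] <- M[j, i] <- r
    }
  }
  M
}

#' Cluster ensemble frames by K-medoids
#'
#' Partitions frames with PAM (partitioning around medoids) on a precomputed
#' RMSD matrix. PAM's build + swap phases are deterministic, so the result is
#' reproducible without a seed. The medoids serve as cluster-representative
#' structures.
#'
#' @param rmsd_matrix symmetric distance matrix from
#'   \code{\link{pairwise_rmsd_matrix}}.
#' @param K number of clusters, 1 <= K <= nrow(rmsd_matrix).
#' @return list(medoids = integer frame indices, assignments = integer vector,
#'   objective = total within-cluster distance to medoid).
#' @export
cluster_frames <- function(rmsd_matrix, K) {
  n <- nrow(rmsd_matrix)
  if (K <= 0L) stop("K must be positive")
  if (K > n) stop("K exceeds number of frames")
  if (K == n) {
    return(list(medoids = seq_len(n), assignments = seq_len(n), objective = 0))
  }
  p <- cluster::pam(stats::as.dist(rmsd_matrix), k = K, diss = TRUE,
                    variant = "original")
  med <- as.integer(p$id.med)
  assign <- as.integer(p$clustering)
  obj <- sum(rmsd_matrix[cbind(seq_len(n), med[assign])])
  list(medoids = med, assignments = assign, objective = obj)
}

#' Select the representative ensemble member
#'
#' All members are superposed onto the first member (backbone atoms), the
#' mean structure is computed, and the member with the lowest backbone RMSD
#' from that mean is returned. Ties go to the lowest index.
#'
#' @param e \code{conformer_ensemble}.
#' @return integer index of the representative member.
#' @export
representative_member <- function(e) {
  n <- length(e$members)
  if (n == 1L) return(1L)
  aligned <- lapply(e$members, function(m) {
    superpose(m, e$members[[1]], "backbone")$transformed
  })
  bb <- lapply(aligned, .coords, sel_atoms = .BACKBONE_ATOMS)
  avg <- Reduce(`+`, bb) / n
  dev <- vapply(bb, function(x) sqrt(mean(rowSums((x - avg)^2))), numeric(1))
  which.min(dev) # which.min takes the first (lowest-index) minimum
}
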