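# RDC back-calculation, SVD tensor fitting, R-factor, ensemble-size selection.

#' Construct an RDC set
#'
#' @param resno residue numbers (unique).
#' @param rdc_hz observed couplings (Hz).
#' @param err_hz positive per-residue errors (Hz).
#' @param medium optional alignment-medium label.
#' @return \code{rdc_set} data.frame (resno, rdc_hz, err_hz).
#' @export
rdc_set <- function(resno, rdc_hz, err_hz = rep(1, length(resno)),
                    medium = NULL) {
  if (anyDuplicated(resno)) stop("duplicate residue numbers")
  if (any(err_hz <= 0)) stop("errors must be positive")
  if (any(!is.finite(rdc_hz)) || any(!is.finite(err_hz))) {
    stop("couplings and errors must be finite")
  }
  d <- data.frame(resno = as.integer(resno), rdc_hz = rdc_hz, err_hz = err_hz)
  d <- d[order(d$resno), ]
  rownames(d) <- NULL
  attr(d, "medium") <- medium
  class(d) <- c("rdc_set", "data.frame")
  d
}

#' RDCs from aligned and isotropic scalar couplings
#'
#' The residual dipolar coupling is the difference between the one-bond
#' splitting measured in the aligned and isotropic medium,
#' D = J_aligned - J_iso; errors combine in quadrature.
#'
#' @param j_aligned,j_isotropic data.frames with columns resno, j_hz and
#'   optionally err_hz.
#' @return \code{rdc_set} over the shared residues.
#' @export
rdc_from_couplings <- function(j_aligned, j_isotropic) {
  shared <- intersect(j_aligned$resno, j_isotropic$resno)
  if (length(shared) == 0L) stop("no shared residues between coupling tables")
  ia <- match(shared, j_aligned$resno)
  ii <- match(shared, j_isotropic$resno)
  ea <- if ("err_hz" %in% names(j_aligned)) j_aligned$err_hz[ia] else 0
  ei <- if ("err_hz" %in% names(j_isotropic)) j_isotropic$err_hz[ii] else 0
  err <- sqrt(ea^2 + ei^2)
  err[err == 0] <- 1
  rdc_set(shared, j_aligned$j_hz[ia] - j_isotropic$j_hz[ii], err)
}

.as_nh_vectors <- function(x) {
  if (inherits(x, "nh_vectors")) return(x)
  if (inherits(x, "structure_model")) {
    return(extract_nh_vectors(x, build_missing_h = TRUE))
  }
  stop("expected a structure_model or nh_vectors object")
}

#' Back-calculate RDCs from member tensors and bond vectors
#'
#' Each ensemble member contributes v' A_k v (its Saupe matrix applied to its
#' own N-H unit vector); the prediction is the sum over members, with the
#' fractional population absorbed into the tensor magnitude. With
#' \code{form = "printed"} the axial/rhombic angular expression is evaluated
#' with the rhombic coefficient fixed at 3/2 (rhombicity factor 1) instead of
#' (3/2) R.
#'
#' @param tensors list of \code{alignment_tensor} (one per member).
#' @param vector_sets list of \code{nh_vectors} (or \code{structure_model}),
#'   one per member.
#' @param form "saupe" (general rhombic tensor, default) or "printed".
#' @return data.frame (resno, rdc_calc) over residues present in all members.
#' @export
back_calc_rdc <- function(tensors, vector_sets, form = c("saupe", "printed")) {
  form <- match.arg(form)
  if (inherits(tensors, "alignment_tensor")) tensors <- list(tensors)
  if (!is.list(vector_sets) || inherits(vector_sets, c("nh_vectors", "structure_model"))) {
    vector_sets <- list(vector_sets)
  }
  if (length(tensors) != length(vector_sets)) {
    stop("need one vector set per tensor")
  }
  vector_sets <- lapply(vector_sets, .as_nh_vectors)
  shared <- Reduce(intersect, lapply(vector_sets, function(v) v$resno))
  if (length(shared) == 0L) stop("no residues shared by all members")
  pred <- numeric(length(shared))
  for (k in seq_along(tensors)) {
    v <- vector_sets[[k]]
    v <- v[match(shared, v$resno), ]
    if (form == "saupe") {
      pred <- pred + as.numeric(direction_cosines(v) %*%
                                  saupe_to_svec(tensors[[k]]$saupe))
    } else {
      tk <- tensors[[k]]
      Rk <- euler_zyz(tk$euler[1], tk$euler[2], tk$euler[3])
      w <- as.matrix(v[, c("x", "y", "z")]) %*% Rk # PAS coordinates
      ct2 <- w[, 3]^2
      st2 <- 1 - ct2
      cos2phi <- ifelse(st2 > 1e-12, (w[, 1]^2 - w[, 2]^2) / st2, 1)
      pred <- pred + tk$da * ((3 * ct2 - 1) + 1.5 * st2 * cos2phi)
    }
  }
  data.frame(resno = shared, rdc_calc = pred)
}

#' RDC R-factor
#'
#' R = sqrt( sum (D_obs - D_calc)^2 / (2 sum D_obs^2) ). Zero for perfect
#' agreement; approximately 1/sqrt(2) for uncorrelated predictions.
#'
#' @param obs \code{rdc_set} (or data.frame with resno, rdc_hz).
#' @param calc data.frame with resno, rdc_calc (or numeric vector aligned
#'   with \code{obs}).
#' @return dimensionless R-factor.
#' @export
r_factor <- function(obs, calc) {
  if (is.numeric(calc)) {
    d_obs <- obs$rdc_hz
    d_calc <- calc
  } else {
    shared <- intersect(obs$resno, calc$resno)
    if (length(shared) == 0L) stop("no shared residues")
    d_obs <- obs$rdc_hz[match(shared, obs$resno)]
    d_calc <- calc$rdc_calc[match(shared, calc$resno)]
  }
  denom <- 2 * sum(d_obs^2)
  if (denom == 0) stop("all observed couplings are zero: R-factor undefined")
  sqrt(sum((d_obs - d_calc)^2) / denom)
}

.fit_svec <- function(A, d) {
  s <- svd(A)
  tol <- max(dim(A)) * max(s$d) * .Machine$double.eps
  rank <- sum(s$d > tol)
  dinv <- ifelse(s$d > tol, 1 / s$d, 0)
  coef <- s$v %*% (dinv * (t(s$u) %*% d))
  list(coef = as.numeric(coef), rank = rank)
}

#' Fit a single alignment tensor to observed RDCs by SVD
#'
#' Solves the linear system (direction-cosine rows) x (5 Saupe elements) =
#' (observed couplings) in the least-squares sense via singular value
#' decomposition. Rank deficiency triggers a warning and the minimum-norm
#' pseudo-inverse solution is returned.
#'
#' @param obs \code{rdc_set}.
#' @param s \code{structure_model} or \code{nh_vectors}.
#' @return \code{ensemble_fit_result} with a single member tensor.
#' @export
svd_fit_tensor <- function(obs, s) {
  ensemble_fit(obs, list(.as_nh_vectors(s)))
}

#' Joint linear least-squares tensor fit over ensemble members
#'
#' Stacks one 5-column direction-cosine block per member (each member's own
#' bond-vector geometry); the fitted Saupe elements carry the fractional
#' populations inside the magnitudes, so per-member weights are never claimed
#' separately.
#'
#' @param obs \code{rdc_set}.
#' @param members \code{conformer_ensemble}, or list of
#'   \code{structure_model}/\code{nh_vectors}.
#' @return \code{ensemble_fit_result}: list(tensors, r_factor, predicted
#'   (data.frame resno, rdc_obs, rdc_calc, residual), n_params, n_data, rank).
#' @export
ensemble_fit <- function(obs, members) {
  if (inherits(members, "conformer_ensemble")) members <- members$members
  vsets <- lapply(members, .as_nh_vectors)
  K <- length(vsets)
  shared <- Reduce(intersect, c(list(obs$resno),
                                lapply(vsets, function(v) v$resno)))
  n <- length(shared)
  if (n < 5L * K) {
    stop(sprintf("underdetermined: %d RDCs for %d tensor parameters",
                 n, 5L * K))
  }
  d <- obs$rdc_hz[match(shared, obs$resno)]
  A <- do.call(cbind, lapply(vsets, function(v) {
    direction_cosines(v[match(shared, v$resno), ])
  }))
  fit <- .fit_svec(A, d)
  if (fit$rank < 5L * K) {
    warning(sprintf("ill-conditioned fit (rank %d < %d); pseudo-inverse used",
                    fit$rank, 5L * K))
  }
  tensors <- lapply(seq_len(K), function(k) {
    tensor_from_saupe(svec_to_saupe(fit$coef[(5 * k - 4):(5 * k)]))
  })
  pred <- as.numeric(A %*% fit$coef)
  # all-zero observations legitimately yield the zero tensor; the R-factor
  # is undefined there and reported as NA
  rf <- if (sum(d^2) == 0) NA_real_ else
    r_factor(rdc_set(shared, d, obs$err_hz[match(shared, obs$resno)]), pred)
  res <- list(
    tensors = tensors,
    r_factor = rf,
    predicted = data.frame(resno = shared, rdc_obs = d, rdc_calc = pred,
                           residual = d - pred),
    n_params = 5L * K, n_data = n, rank = fit$rank)
  class(res) <- "ensemble_fit_result"
  res
}

#' @export
print.ensemble_fit_result <- function(x, ...) {
  cat(sprintf(
    "<ensemble_fit_result> %d member(s), %d RDCs, R-factor = %.4f\n",
    length(x$tensors), x$n_data, x$r_factor))
  invisible(x)
}

#' Iterative ensemble-size selection against RDC data
#'
#' For K = 1..k_max the conformer pool is clustered into K groups
#' (K-medoids on the pairwise C-alpha RMSD matrix), the K medoid structures
#' are fitted jointly to the observed RDCs, and the R-factor is recorded.
#' To keep the curve non-increasing, each K also considers the previous
#' best member set augmented by the single best new medoid (a nested model,
#' hence never worse); the better of the two candidate sets is kept.
#' The loop stops early at the smallest K whose R-factor improvement is
#' below \code{stability_tol} (relative) for two consecutive steps; an
#' absolute floor of 1e-8 counts as converged outright.
#'
#' @param pool \code{conformer_ensemble} of candidate conformers.
#' @param obs \code{rdc_set}.
#' @param k_max largest ensemble size to try.
#' @param stability_tol relative R-factor improvement below which the curve
#'   is considered stable (default 0.01).
#' @param selection atom selection for the clustering metric (default "CA").
#' @return list(k_star, curve = data.frame(K, r_factor), members = indices of
#'   the selected conformers, fit = final \code{ensemble_fit_result}).
#' @export
select_ensemble_size <- function(pool, obs, k_max = 10L, stability_tol = 0.01,
                                 selection = "CA") {
  n_pool <- length(pool$members)
  k_max <- min(k_max, n_pool)
  vsets <- lapply(pool$members, .as_nh_vectors)
  n_data <- length(Reduce(intersect, c(list(obs$resno),
                                       lapply(vsets, function(v) v$resno))))
  if (5L * k_max > n_data) {
    k_max_new <- max(1L, n_data %/% 5L)
    warning(sprintf("k_max truncated from %d to %d (only %d RDCs)",
                    k_max, k_max_new, n_data))
    k_max <- k_max_new
  }
  D <- if (n_pool > 1L) pairwise_rmsd_matrix(pool, selection) else
    matrix(0, 1, 1)
  # members sharing rigid-core bond geometry make the stacked blocks rank
  # deficient; the minimum-norm pseudo-inverse resolves this, so the scan
  # silences the per-fit conditioning warnings
  fit_members <- function(idx) suppressWarnings(ensemble_fit(obs, vsets[idx]))

  curve_r <- numeric(0)
  sets <- list()
  fits <- list()
  prev_idx <- integer(0)
  stable_run <- 0L
  for (K in seq_len(k_max)) {
    med <- cluster_frames(D, K)$medoids
    fit <- fit_members(med)
    idx <- med
    if (K > 1L) {
      # nested candidate: previous set plus the best new medoid
      extra <- setdiff(med, prev_idx)
      if (length(prev_idx) == K - 1L && length(extra) > 0L) {
        for (e in extra) {
          f2 <- fit_members(c(prev_idx, e))
          if (f2$r_factor < fit$r_factor) {
            fit <- f2
            idx <- c(prev_idx, e)
          }
        }
      }
      if (fit$r_factor > curve_r[K - 1L]) { # numerical guard
        fit <- fits[[K - 1L]]
        idx <- prev_idx
      }
    }
    curve_r[K] <- fit$r_factor
    sets[[K]] <- idx
    fits[[K]] <- fit
    prev_idx <- idx
    if (K > 1L) {
      rel <- (curve_r[K - 1L] - curve_r[K]) / max(curve_r[K - 1L], 1e-12)
      # once the previous K already fits to numerical zero, further relative
      # improvement is meaningless: count the step as stable
      stable <- rel < stability_tol || curve_r[K - 1L] < 1e-8
      stable_run <- if (stable) stable_run + 1L else 0L
      if (stable_run >= 2L) break
    }
  }
  k_star <- if (stable_run >= 2L) length(curve_r) - 2L else length(curve_r)
  k_star <- max(1L, k_star)
  list(k_star = k_star,
       curve = data.frame(K = seq_along(curve_r), r_factor = curve_r),
       members = sets[[k_star]],
       fit = fits[[k_star]])
}

#' Restrict an RDC set to a residue subset
#'
#' Convenience for per-domain tensor fits: subset the observations to one
#' domain's residues and refit (all fitting functions operate on whatever
#' residues the set contains).
#'
#' @param x \code{rdc_set}.
#' @param residues residue numbers to keep.
#' @return \code{rdc_set} restricted to \code{residues}.
#' @export
subset_rdc_set <- function(x, residues) {
  keep <- x$resno %in% residues
  if (!any(keep)) stop("no residues of the set fall in the requested subset")
  rdc_set(x$resno[keep], x$rdc_hz[keep], x$err_hz[keep],
          medium = attr(x, "medium"))
}

#' Read an RDC table from TSV
#'
#' Expected columns: residue, atom_pair, rdc_hz, err_hz.
#' @param path TSV path.
#' @return \code{rdc_set}.
#' @export
read_rdc_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "rdc_hz", "err_hz")
  if (!all(need %in% names(d))) {
    stop("RDC table needs columns: ", paste(need, collapse = ", "))
  }
  rdc_set(d$residue, d$rdc_hz, d$err_hz)
}

#' Write an RDC table to TSV
#' @param x \code{rdc_set}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_rdc_table <- function(x, path) {
  utils::write.table(
    data.frame(residue = x$resno, atom_pair = "N-H",
               rdc_hz = x$rdc_hz, err_hz = x$err_hz),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a fitted-tensor text report
#'
#' Emits each member tensor's Saupe elements, magnitude Da, rhombicity and
#' Euler angles plus the fit R-factor, and (next to it) a per-residue
#' observed/calculated TSV.
#'
#' @param fit \code{ensemble_fit_result}.
#' @param path report path; the per-residue table goes to
#'   \code{paste0(path, ".obs_vs_calc.tsv")}.
#' @return \code{path}, invisibly.
#' @export
write_tensor_report <- function(fit, path) {
  lines <- c(sprintf("members: %d", length(fit$tensors)),
             sprintf("n_data: %d", fit$n_data),
             sprintf("r_factor: %.6f", fit$r_factor))
  for (k in seq_along(fit$tensors)) {
    tk <- fit$tensors[[k]]
    s <- saupe_to_svec(tk$saupe)
    lines <- c(lines,
               sprintf("member %d:", k),
               sprintf("  saupe_Ayy_Azz_Axy_Axz_Ayz_hz: %s",
                       paste(sprintf("%.6g", s), collapse = " ")),
               sprintf("  Da_hz: %.6g", tk$da),
               sprintf("  rhombicity: %.6g", tk$rhombicity),
               sprintf("  euler_rad: %s",
                       paste(sprintf("%.6g", tk$euler), collapse = " ")))
  }
  writeLines(lines, path)
  utils::write.table(fit$predicted, paste0(path, ".obs_vs_calc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
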