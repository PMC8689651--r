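# Rigid-body superposition (Kabsch, SVD closed form with determinant
# correction) and iterative average-structure alignment.

#' Optimal rigid-body superposition of two coordinate sets
#'
#' Kabsch algorithm: the least-squares proper rotation and translation
#' mapping `mobile` onto `reference` over the atoms in `fit_sel`, via SVD
#' of the cross-covariance with a determinant sign correction. The
#' transformation found on the fit selection is applied to all atoms.
#'
#' @param mobile n x 3 coordinate matrix, Angstrom
#' @param reference n x 3 coordinate matrix
#' @param fit_sel indices of atoms used to determine the fit (default:
#'   all); at least 3 non-collinear atoms
#' @return list of class `superposition` with `rotation` (3x3, det +1),
#'   `translation` (length-3), `rmsd` (over the fit selection, Angstrom)
#'   and `transformed` (all atoms moved)
#' @export
kabsch_superpose <- function(mobile, reference, fit_sel = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3)
  if (is.null(fit_sel)) fit_sel <- seq_len(nrow(mobile))
  if (length(fit_sel) < 3) .stopf("need at least 3 fit atoms")
  A <- mobile[fit_sel, , drop = FALSE]
  B <- reference[fit_sel, , drop = FALSE]
  if (nrow(A) != nrow(B)) .stopf("fit selections have unequal length")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  H <- crossprod(Ac, Bc)
  sv <- svd(H)
  if (min(sv$d) < 1e-12 && sum(sv$d > 1e-12) < 2)
    .stopf("degenerate geometry in fit selection")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  rot <- sv$v %*% D %*% t(sv$u)        # maps centred mobile rows: x %*% t(rot)
  fitted <- Ac %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - Bc)^2)))
  transformed <- sweep(sweep(mobile, 2, ca) %*% t(rot), 2, cb, "+")
  translation <- cb - drop(rot %*% ca)
  structure(list(rotation = rot, translation = translation, rmsd = rmsd,
                 transformed = transformed),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition: RMSD %.4f A over fit selection\n", x$rmsd))
  invisible(x)
}

#' Iterative average structure of a coordinate ensemble
#'
#' Aligns every frame to the current mean structure (over `fit_sel`),
#' recomputes the mean, and repeats until the mean moves less than `tol`
#' or `max_iter` is reached. Returns the converged mean and the aligned
#' ensemble (flagged `aligned` for the downstream fluctuation statistics).
#'
#' @param x a `coord_ensemble` (at least 2 frames)
#' @param fit_sel atom indices used for the alignment (default: all)
#' @param max_iter maximum alignment iterations
#' @param tol convergence threshold on the mean coordinate shift, Angstrom
#' @return list with `average` (atoms x 3), `ensemble` (aligned
#'   `coord_ensemble`), `n_iter`, `shifts` (mean shift per iteration)
#' @export
average_structure <- function(x, fit_sel = NULL, max_iter = 10, tol = 1e-6) {
  stopifnot(inherits(x, "coord_ensemble"))
  d <- dim(x$coords)
  if (d[1] < 2) .stopf("need at least 2 frames")
  coords <- x$coords
  avg <- apply(coords, c(2, 3), mean)
  shifts <- numeric(0)
  for (it in seq_len(max_iter)) {
    for (f in seq_len(d[1])) {
      coords[f, , ] <- kabsch_superpose(coords[f, , ], avg, fit_sel)$transformed
    }
    new_avg <- apply(coords, c(2, 3), mean)
    shift <- sqrt(mean(rowSums((new_avg - avg)^2)))
    shifts <- c(shifts, shift)
    avg <- new_avg
    if (shift < tol) break
  }
  ens <- coord_ensemble(coords, x$atom_names, x$residue_ids,
                        x$residue_names, x$chain_ids, x$frame_times)
  attr(ens, "aligned") <- TRUE
  list(average = avg, ensemble = ens, n_iter = it, shifts = shifts)
}
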