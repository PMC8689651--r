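# RMSD-based hierarchical clustering of substrate orientations.
# Frames are first aligned on a shared fit selection (active-site CA
# atoms); pairwise RMSD is then computed over the substrate atoms with
# no per-pair re-fitting, so the RMSD reports orientation differences in
# the active-site frame.

#' Cluster substrate orientations by pairwise RMSD
#'
#' Hierarchical agglomerative clustering (average linkage) of frames on
#' the pairwise RMSD of the substrate selection after alignment on the
#' fit selection. Merging stops when the smallest inter-cluster distance
#' exceeds `epsilon` (i.e. the tree is cut at height `epsilon`). Clusters
#' are numbered 1, 2, ... by decreasing population; each cluster reports
#' its medoid frame (smallest summed RMSD to its members).
#'
#' @param x a `coord_ensemble`
#' @param substrate_sel atom indices of the (non-hydrogen) substrate atoms
#' @param fit_sel atom indices used for the shared alignment (e.g.
#'   active-site CA atoms)
#' @param epsilon minimum distance between clusters, Angstrom
#' @return object of class `cluster_result` with `labels` (per frame),
#'   `fractions` (per cluster, decreasing, summing to 1), `medoids`
#'   (representative frame per cluster), `epsilon`, `merge_heights`
#' @export
cluster_orientations <- function(x, substrate_sel, fit_sel, epsilon = 1.5) {
  stopifnot(inherits(x, "coord_ensemble"), epsilon > 0)
  nf <- n_frames(x)
  if (length(substrate_sel) == 0 || length(fit_sel) == 0)
    .stopf("empty selection")
  if (nf == 1) {
    return(structure(list(labels = 1L, fractions = 1, medoids = 1L,
                          epsilon = epsilon, merge_heights = numeric(0)),
                     class = "cluster_result"))
  }
  aligned <- average_structure(x, fit_sel = fit_sel)$ensemble
  sub <- aligned$coords[, substrate_sel, , drop = FALSE]
  # pairwise RMSD without re-fitting
  flat <- matrix(sub, nrow = nf)  # frames x (atoms*3)
  dmat <- as.matrix(stats::dist(flat)) / sqrt(length(substrate_sel))
  hc <- stats::hclust(stats::as.dist(dmat), method = "average")
  raw <- stats::cutree(hc, h = epsilon)
  # relabel by decreasing population; ties by first occurrence
  tab <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(tab), names(tab))
  labels <- unname(relabel[as.character(raw)])
  fractions <- as.numeric(tab) / nf
  medoids <- vapply(seq_along(tab), function(cl) {
    members <- which(labels == cl)
    if (length(members) == 1) return(members)
    members[which.min(rowSums(dmat[members, members, drop = FALSE]))]
  }, integer(1))
  structure(list(labels = labels, fractions = fractions, medoids = medoids,
                 epsilon = epsilon, merge_heights = hc$height,
                 hclust = hc),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Orientation clustering (epsilon %.2f A): %d cluster(s)\n",
              x$epsilon, length(x$fractions)))
  for (i in seq_along(x$fractions))
    cat(sprintf("  cluster %d: %.1f%% (medoid frame %d)\n",
                i, 100 * x$fractions[i], x$medoids[i]))
  invisible(x)
}
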