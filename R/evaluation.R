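#' Split spatially discontiguous clusters
#'
#' Decomposes every cluster into its 26-connected components and relabels
#' each component uniquely.  The increase in label count is the spatial
#' discontiguity index: 0 means every cluster was already one contiguous
#' region.
#'
#' @param parc a [parcellation()].
#' @return A list with elements `parcellation` (relabeled, compacted) and
#'   `index` (nonnegative integer).
#' @export
split_discontiguous <- function(parc) {
  stopifnot(inherits(parc, "parcellation"))
  p <- neighbor_pairs(parc$mask)
  same <- parc$labels[p$i] == parc$labels[p$j]
  g <- igraph::make_empty_graph(n = parc$mask$n, directed = FALSE)
  if (any(same))
    g <- igraph::add_edges(g, rbind(p$i[same], p$j[same]))
  memb <- igraph::components(g)$membership
  # relabel by first occurrence in mask row order
  new_labels <- match(memb, unique(memb))
  out <- parcellation(parc$mask, new_labels, k_init = parc$k_init)
  list(parcellation = out, index = out$k_actual - parc$k_actual)
}

#' Functional homogeneity of a parcellation on held-out data
#'
#' For each cluster with at least two voxels the mean pairwise Pearson
#' correlation a(k) is computed on the held-out time series, and the
#' homogeneity is the unweighted mean of a(k) over those clusters
#' (singleton clusters are omitted).  Evaluating on data not used to build
#' the atlas avoids circularity.
#'
#' @param parc a [parcellation()].
#' @param ts_norm_heldout normalized [masked_ts()] on the same mask.
#' @return Homogeneity in \[-1, 1\].
#' @export
homogeneity <- function(parc, ts_norm_heldout) {
  stopifnot(inherits(parc, "parcellation"),
            inherits(ts_norm_heldout, "masked_ts"))
  if (!ts_norm_heldout$normalized)
    stop("held-out time courses must be normalized first")
  if (!same_mask(parc$mask, ts_norm_heldout$mask))
    stop("parcellation and held-out data are on different masks")
  V <- ts_norm_heldout$data
  rows_by_label <- split(seq_len(parc$mask$n), parc$labels)
  aks <- vapply(rows_by_label, function(idx) {
    nk <- length(idx)
    if (nk < 2L) return(NA_real_)
    s <- colSums(V[idx, , drop = FALSE])
    # sum_{i != j} v_i . v_j = ||sum v||^2 - sum ||v||^2, unit-norm rows
    (sum(s * s) - nk) / (nk * (nk - 1))
  }, numeric(1))
  aks <- aks[!is.na(aks)]
  if (!length(aks))
    stop("no cluster has two or more voxels; homogeneity is undefined")
  mean(aks)
}

#' Adjacency-matrix Dice coefficient between two parcellations
#'
#' `Dice = 2 |A & B| / (|A| + |B|)` where A and B are the same-cluster
#' adjacency matrices of the two parcellations and |.| counts their ones.
#' Computed from the label contingency table (never from dense N x N
#' matrices): |A| = sum_a n_a (n_a - 1), |A & B| = sum_ab m_ab (m_ab - 1).
#' Diagonals are excluded from all counts; when both adjacencies are empty
#' (all-singleton parcellations) the Dice is defined as 1.
#'
#' @param parcA,parcB [parcellation()]s on the same mask.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_adjacency <- function(parcA, parcB) {
  stopifnot(inherits(parcA, "parcellation"), inherits(parcB, "parcellation"))
  if (!same_mask(parcA$mask, parcB$mask))
    stop("parcellations are on different masks")
  na <- tabulate(parcA$labels)
  nb <- tabulate(parcB$labels)
  sizeA <- sum(na * (na - 1))
  sizeB <- sum(nb * (nb - 1))
  if (sizeA + sizeB == 0) return(1)
  m <- table(parcA$labels, parcB$labels)
  inter <- sum(m * (m - 1))
  2 * inter / (sizeA + sizeB)
}

#' Mean group-to-subject adjacency Dice
#'
#' The reproducibility of a group atlas against the individual atlases it
#' was built from: the mean of [dice_adjacency()] between the group
#' parcellation and each subject parcellation.
#'
#' @param group_parc group-level [parcellation()].
#' @param subject_parcs list of subject [parcellation()]s on the same mask.
#' @return Mean Dice in \[0, 1\].
#' @export
group_to_subject <- function(group_parc, subject_parcs) {
  if (length(subject_parcs) == 0L) stop("empty subject list")
  mean(vapply(subject_parcs, dice_adjacency, numeric(1),
              parcA = group_parc))
}

#' Evaluate a parcellation and build a report row set
#'
#' Convenience wrapper computing the actual-vs-initialized cluster-number
#' difference, the spatial discontiguity index, and optionally held-out
#' homogeneity and Dice against a second parcellation.
#'
#' @param parc a [parcellation()].
#' @param heldout optional normalized [masked_ts()] for homogeneity.
#' @param reference optional second [parcellation()] for Dice.
#' @param approach,scheme descriptors recorded in the report.
#' @return A data.frame with columns approach, scheme, K, metric, value.
#' @export
evaluation_report <- function(parc, heldout = NULL, reference = NULL,
                              approach = "subject", scheme = "ss1") {
  rows <- list(
    data.frame(approach = approach, scheme = scheme, K = parc$k_init,
               metric = "k_actual", value = parc$k_actual),
    data.frame(approach = approach, scheme = scheme, K = parc$k_init,
               metric = "k_difference", value = parc$k_difference),
    data.frame(approach = approach, scheme = scheme, K = parc$k_init,
               metric = "discontiguity_index",
               value = split_discontiguous(parc)$index))
  if (!is.null(heldout))
    rows <- c(rows, list(
      data.frame(approach = approach, scheme = scheme, K = parc$k_init,
                 metric = "homogeneity",
                 value = homogeneity(parc, heldout))))
  if (!is.null(reference))
    rows <- c(rows, list(
      data.frame(approach = approach, scheme = scheme, K = parc$k_init,
                 metric = "dice",
                 value = dice_adjacency(parc, reference))))
  do.call(rbind, rows)
}

#' Write an evaluation report as TSV
#'
#' One row per (approach, scheme, K, metric) combination.
#'
#' @param report data.frame from [evaluation_report()] (or rbind of them).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
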