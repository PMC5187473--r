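#' Mean SLIC group parcellation
#'
#' Per-subject weight matrices are Fisher r-to-z averaged into a group
#' weight matrix ([fisher_mean()]), which is then parcellated with the
#' Ncut + SLIC pipeline ([parcellate_subject()]).
#'
#' @param Ws list of per-subject `sparse_w` on a common mask.
#' @param mask the shared [gm_mask()].
#' @param K group-level cluster number.
#' @param control a [slic_control()].
#' @return A group-level [parcellation()].
#' @export
mean_slic <- function(Ws, mask, K, control = slic_control()) {
  if (length(Ws) == 0L) stop("need at least one subject")
  Wg <- fisher_mean(Ws)
  parcellate_subject(Wg, mask, K, control)
}

#' Two-level SLIC group parcellation
#'
#' Each subject is parcellated separately; the same-cluster adjacency
#' matrices of the subject parcellations are averaged
#' ([average_adjacency()]) into a second-level weight matrix, which is
#' parcellated again with Ncut + SLIC.  Setting `K_subject > K` is the
#' overclustering variant.
#'
#' @param Ws list of per-subject `sparse_w` on a common mask.
#' @param mask the shared [gm_mask()].
#' @param K group-level cluster number.
#' @param K_subject subject-level cluster number (defaults to `K`).
#' @param control a [slic_control()] shared by all subjects and the group
#'   stage.
#' @param group_coupling uniform-affinity regularization for the group
#'   stage only (see [ncut_embedding()]).  Averaged adjacency matrices are
#'   consensus graphs: a cluster on which all subjects agree perfectly is a
#'   disconnected clique whose indicator vector would otherwise be
#'   discarded with the trivial eigenvalues.
#' @return A group-level [parcellation()]; the per-subject parcellations
#'   are attached as field `subject_parcellations`.
#' @export
twolevel_slic <- function(Ws, mask, K, K_subject = K,
                          control = slic_control(), group_coupling = 0.01) {
  if (length(Ws) == 0L) stop("need at least one subject")
  subject_parcs <- lapply(Ws, parcellate_subject, mask = mask,
                          K = K_subject, control = control)
  As <- lapply(subject_parcs, adjacency_from_parcellation)
  Ab <- average_adjacency(As)
  group_control <- control
  group_control$coupling <- max(control$coupling, group_coupling)
  out <- parcellate_subject(Ab, mask, K, group_control)
  out$subject_parcellations <- subject_parcs
  out$K_subject <- as.integer(K_subject)
  out
}
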