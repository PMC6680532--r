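# Ligand-Cluster construction: Butina leader clustering on the Tanimoto
# similarity matrix (primary), hierarchical Ward as an optional alternative,
# and selection of the representative ligand of each cluster.

#' Cluster ligands by fingerprint similarity
#'
#' Butina leader clustering (default): ligands are ranked by their number of
#' neighbours at `threshold` (ties broken by `ligand_id`); the densest
#' unassigned ligand becomes a centroid and all unassigned neighbours with
#' Tanimoto >= `threshold` join it; the sweep repeats until everything is
#' assigned (singletons become singleton clusters). Every member is
#' guaranteed Tanimoto >= `threshold` to its centroid; member-member pairs
#' may fall below it. The result is always a partition.
#'
#' `method = "ward"` offers hierarchical clustering (Ward linkage on the
#' Tanimoto distance `1 - s`, cut at height `1 - threshold`) for comparison.
#'
#' @param fps logical fingerprint matrix (rows = ligands) from
#'   [fingerprint_ligands()], or a precomputed similarity matrix via
#'   `similarity`.
#' @param threshold Tanimoto threshold (default 0.8, boundary inclusive).
#' @param method `"butina"` (default) or `"ward"`.
#' @param similarity optional precomputed symmetric similarity matrix.
#' @return tibble `ligand_id`, `ligand_cluster` (id string), `is_centroid`.
#' @export
cluster_ligands <- function(fps = NULL, threshold = 0.8,
                            method = c("butina", "ward"),
                            similarity = NULL) {
  method <- match.arg(method)
  sim <- if (is.null(similarity)) tanimoto_matrix(fps) else similarity
  ids <- rownames(sim)
  if (is.null(ids)) stop("similarity matrix needs ligand ids as rownames")
  n <- length(ids)
  if (n == 0) {
    return(tibble::tibble(ligand_id = character(),
                          ligand_cluster = character(),
                          is_centroid = logical()))
  }

  if (method == "ward") {
    if (n == 1) {
      cl <- 1L
    } else {
      hc <- stats::hclust(stats::as.dist(1 - sim), method = "ward.D2")
      cl <- stats::cutree(hc, h = 1 - threshold)
    }
    centroid <- rep(FALSE, n)
  } else {
    nbr <- sim >= threshold
    diag(nbr) <- FALSE
    n_nbr <- rowSums(nbr)
    order_idx <- order(-n_nbr, ids)
    cl <- rep(NA_integer_, n)
    centroid <- rep(FALSE, n)
    next_cl <- 0L
    for (i in order_idx) {
      if (!is.na(cl[i])) next
      next_cl <- next_cl + 1L
      cl[i] <- next_cl
      centroid[i] <- TRUE
      join <- which(is.na(cl) & nbr[i, ])
      cl[join] <- next_cl
    }
  }
  ## stable cluster ids ordered by smallest member ligand_id
  first_id <- vapply(sort(unique(cl)), function(k) min(ids[cl == k]),
                     character(1))
  relabel <- match(cl, sort(unique(cl))[order(first_id)])
  tibble::tibble(
    ligand_id = ids,
    ligand_cluster = sprintf("LC%04d", relabel),
    is_centroid = centroid
  )
}

#' Representative ligand of a cluster
#'
#' The member closest to the cluster's mean descriptor vector under a
#' weighted Euclidean distance, with weights `1 / variance` computed per
#' descriptor over the WHOLE dataset (so scales are comparable across
#' clusters); zero-variance or incomputable descriptors get weight 0. Ties
#' break deterministically by `ligand_id`; a singleton returns its only
#' member.
#'
#' @param member_ids ligand ids of the cluster members.
#' @param descriptors full-dataset descriptor table (`ligand_id` + numeric
#'   descriptor columns).
#' @param descriptor_cols descriptor columns to use; defaults to the 21-slot
#'   panel intersected with what is present.
#' @return the representative `ligand_id`.
#' @export
representative_ligand <- function(member_ids, descriptors,
                                  descriptor_cols = NULL) {
  if (length(member_ids) == 1) return(member_ids)
  if (is.null(descriptor_cols)) {
    descriptor_cols <- intersect(ligand_descriptor_slots()$descriptor,
                                 names(descriptors))
  }
  X <- as.matrix(descriptors[, descriptor_cols])
  rownames(X) <- descriptors$ligand_id
  v <- apply(X, 2, stats::var, na.rm = TRUE)
  w <- ifelse(is.na(v) | v <= 0, 0, 1 / v)
  M <- X[member_ids, , drop = FALSE]
  mu <- colMeans(M, na.rm = TRUE)
  d <- apply(M, 1, function(r) {
    dd <- (r - mu)^2 * w
    sum(dd[!is.na(dd)])
  })
  member_ids[order(d, member_ids)][1]
}

#' Summarise Ligand-Clusters
#'
#' @param clusters membership tibble from [cluster_ligands()].
#' @param fps fingerprint matrix (for mean pairwise Tanimoto per cluster).
#' @param descriptors optional descriptor table; when given, the
#'   representative ligand is selected per cluster.
#' @return tibble `ligand_cluster`, `size`, `members` (list-column),
#'   `mean_pairwise_tanimoto`, and `representative` when descriptors are
#'   supplied.
#' @export
ligand_cluster_summary <- function(clusters, fps, descriptors = NULL) {
  sim <- tanimoto_matrix(fps)
  out <- dplyr::summarise(
    dplyr::group_by(clusters, .data$ligand_cluster),
    size = dplyr::n(),
    members = list(sort(.data$ligand_id)),
    .groups = "drop")
  out$mean_pairwise_tanimoto <- vapply(out$members, function(m) {
    if (length(m) == 1) return(1)
    s <- sim[m, m]
    mean(s[upper.tri(s)])
  }, numeric(1))
  if (!is.null(descriptors)) {
    out$representative <- vapply(out$members, representative_ligand,
                                 character(1), descriptors = descriptors)
  }
  out
}
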