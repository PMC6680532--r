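# Druggable-binding-site (DBS) identification: the adaptive barycenter
# cutoff C = D - k*sigma over the observed pocket radii, transitive pocket
# clustering within each homologous chain cluster, the score of overlap
# validation, promiscuity labelling and the minimum-occurrence filter.

#' Barycenter clustering cutoff from the observed pocket radii
#'
#' For the `p` pockets of one homologous chain cluster, let `dmax(i)` be the
#' largest barycenter-to-atom distance of pocket `i`. The cutoff is
#' `C = D - k * sigma` where `D` is the mean and `sigma` the standard
#' deviation of the `p` observed `dmax` values. `sigma` uses the population
#' divisor `p` by default (a single pocket gives `sigma = 0`, `C = dmax`).
#' `C <= 0` is possible when the radii are very dispersed and is handled
#' downstream (every pocket becomes a singleton).
#'
#' @param dmax_values numeric vector of pocket radii (Angstrom), all >= 0.
#' @param k constant multiplier (default 2).
#' @param sigma `"population"` (divisor p, default) or `"sample"` (p - 1).
#' @return list with `D`, `sigma`, `k`, `C`, `p`.
#' @export
compute_cutoff <- function(dmax_values, k = 2,
                           sigma = c("population", "sample")) {
  sigma <- match.arg(sigma)
  if (length(dmax_values) == 0) stop("no dmax values")
  if (any(dmax_values < 0)) stop("dmax values must be >= 0")
  p <- length(dmax_values)
  D <- mean(dmax_values)
  s <- if (p == 1) 0 else {
    if (sigma == "population") sqrt(mean((dmax_values - D)^2)) else
      stats::sd(dmax_values)
  }
  list(D = D, sigma = s, k = k, C = D - k * s, p = p)
}

#' Cluster pockets into binding sites by the barycenter cutoff
#'
#' Two pockets fall in the same Pocket-Cluster when the distance between
#' their barycenters is strictly below the cutoff `C`; clusters are the
#' connected components of the resulting graph, which enforces transitivity
#' regardless of `k`. Pairs joined only through intermediates (transitive
#' joins whose direct distance is >= C) are counted per cluster. With
#' `C <= 0` every pocket becomes a singleton (with a warning).
#'
#' @param pockets pockets tibble (from [extract_pockets()]) for ONE chain
#'   cluster: needs `pocket_id`, `bx`, `by`, `bz`.
#' @param params cutoff as from [compute_cutoff()] on these pockets' `dmax`.
#' @return tibble `pocket_id`, `dbs_ordinal`, `n_transitive_joins` (per
#'   cluster); ordinals are assigned by the smallest member `pocket_id`.
#' @export
cluster_pockets <- function(pockets, params) {
  stopifnot(all(c("pocket_id", "bx", "by", "bz") %in% names(pockets)))
  n <- nrow(pockets)
  if (n == 0) return(tibble::tibble(pocket_id = character(),
                                    dbs_ordinal = integer(),
                                    n_transitive_joins = integer()))
  C <- params$C
  if (C <= 0) {
    warning("cutoff C <= 0 (D < k*sigma): all pockets become singletons")
    comp <- seq_len(n)
    adj <- matrix(FALSE, n, n)
  } else {
    d <- as.matrix(stats::dist(pockets[, c("bx", "by", "bz")]))
    adj <- d < C
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
  }
  ## deterministic ordinals: order components by their smallest pocket_id
  comps <- sort(unique(comp))
  first_id <- vapply(comps, function(cmp) min(pockets$pocket_id[comp == cmp]),
                     character(1))
  ordered_comps <- comps[order(first_id)]
  ordinal <- match(comp, ordered_comps)
  ## transitive joins: within-cluster pairs with no direct edge
  n_trans <- vapply(comps, function(cmp) {
    idx <- which(comp == cmp)
    as.integer(choose(length(idx), 2) -
                 sum(adj[idx, idx, drop = FALSE]) / 2)
  }, integer(1))
  tibble::tibble(
    pocket_id = pockets$pocket_id,
    dbs_ordinal = as.integer(ordinal),
    n_transitive_joins = n_trans[match(comp, comps)]
  )
}

#' Score of overlap between two pockets
#'
#' The proportion of atoms common to two pockets:
#' `SO = n_common / (n1 + n2 - n_common)`, in \[0, 1\]; 1 means maximum
#' overlap. Across homologous chains, two atoms correspond when they share
#' the aligned reference residue position and the atom name (keys computed
#' at extraction time from the cluster superposition); for pockets on the
#' same chain the correspondence is atom identity.
#'
#' @param keys_a,keys_b character vectors of atom correspondence keys (the
#'   `atom_keys` list-column of the pockets table); `NA` keys (atoms at
#'   unaligned positions) never match.
#' @return overlap fraction in \[0, 1\]; symmetric.
#' @export
score_of_overlap <- function(keys_a, keys_b) {
  n_a <- length(keys_a); n_b <- length(keys_b)
  if (n_a == 0 || n_b == 0) stop("empty pocket")
  common <- length(intersect(keys_a[!is.na(keys_a)], keys_b[!is.na(keys_b)]))
  common / (n_a + n_b - common)
}

## pairwise SO summary for the pockets of one DBS
overlap_stats <- function(atom_keys) {
  p <- length(atom_keys)
  if (p < 2) {
    return(tibble::tibble(so_mean = NA_real_, so_min = NA_real_,
                          so_max = NA_real_))
  }
  so <- utils::combn(p, 2, function(ij) {
    score_of_overlap(atom_keys[[ij[1]]], atom_keys[[ij[2]]])
  })
  tibble::tibble(so_mean = mean(so), so_min = min(so), so_max = max(so))
}

#' Identify DBS: cluster pockets within every chain cluster
#'
#' Applies [compute_cutoff()] and [cluster_pockets()] per homologous chain
#' cluster and summarises each resulting Pocket-Cluster (= one DBS) with its
#' size and pairwise score-of-overlap statistics.
#'
#' @param pockets pockets tibble from [extract_pockets()] run with a
#'   superposition (needs `cluster_id`).
#' @param k cutoff multiplier (default 2).
#' @param sigma divisor convention, see [compute_cutoff()].
#' @return list with `membership` (tibble `pocket_id`, `cluster_id`,
#'   `dbs_id`), `dbs` (tibble `dbs_id`, `cluster_id`, `p`, `so_mean`,
#'   `so_min`, `so_max`, `C`, `D`, `sigma`, `n_transitive_joins`).
#' @export
identify_dbs <- function(pockets, k = 2, sigma = "population") {
  stopifnot(!any(is.na(pockets$cluster_id)))
  membership <- list(); dbs <- list()
  for (cl in sort(unique(pockets$cluster_id))) {
    pk <- pockets[pockets$cluster_id == cl, ]
    params <- compute_cutoff(pk$dmax, k = k, sigma = sigma)
    mem <- cluster_pockets(pk, params)
    mem$cluster_id <- cl
    mem$dbs_id <- sprintf("%s_DBS%02d", cl, mem$dbs_ordinal)
    membership[[cl]] <- mem[, c("pocket_id", "cluster_id", "dbs_id")]
    for (d in sort(unique(mem$dbs_id))) {
      ids <- mem$pocket_id[mem$dbs_id == d]
      keys <- pk$atom_keys[match(ids, pk$pocket_id)]
      st <- overlap_stats(keys)
      dbs[[d]] <- dplyr::bind_cols(
        tibble::tibble(dbs_id = d, cluster_id = cl, p = length(ids)), st,
        tibble::tibble(C = params$C, D = params$D, sigma = params$sigma,
                       n_transitive_joins =
                         mem$n_transitive_joins[mem$dbs_id == d][1]))
    }
  }
  list(membership = dplyr::bind_rows(membership),
       dbs = dplyr::bind_rows(dbs))
}

#' Label DBS promiscuity from bound ligand chemotypes
#'
#' The promiscuity of a DBS is the number `L` of distinct Ligand-Clusters
#' its pockets bind: `L = 1` selective (S), `L` of 2-3 moderately
#' promiscuous (MP), `L >= 4` highly promiscuous (HP). A DBS described by a
#' single pocket cannot be characterized and is labelled `UNDETERMINED`,
#' reported separately from S.
#'
#' @param dbs_membership tibble `pocket_id`, `dbs_id` (from
#'   [identify_dbs()]).
#' @param pocket_ligand_clusters tibble `pocket_id`, `ligand_cluster`; every
#'   pocket must appear exactly once.
#' @return tibble `dbs_id`, `p`, `n_ligand_clusters`, `promiscuity`.
#' @export
classify_promiscuity <- function(dbs_membership, pocket_ligand_clusters) {
  miss <- setdiff(dbs_membership$pocket_id, pocket_ligand_clusters$pocket_id)
  if (length(miss) > 0) {
    stop("pocket(s) without ligand-cluster assignment: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  joined <- dplyr::left_join(dbs_membership, pocket_ligand_clusters,
                             by = "pocket_id")
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$dbs_id),
    p = dplyr::n(),
    n_ligand_clusters = dplyr::n_distinct(.data$ligand_cluster),
    .groups = "drop")
  out$promiscuity <- dplyr::case_when(
    out$p == 1 ~ "UNDETERMINED",
    out$n_ligand_clusters == 1 ~ "S",
    out$n_ligand_clusters <= 3 ~ "MP",
    TRUE ~ "HP")
  out
}

#' Keep DBS observed at least `min_pockets` times
#'
#' Promiscuity statistics are computed on sites seen often enough that a
#' "selective" call is not an artefact of sparse observation; the default
#' keeps DBS described by four or more pockets (the DBS4 convention).
#'
#' @param dbs tibble with a `p` column (pockets per DBS).
#' @param min_pockets minimum Pocket-Cluster size (default 4).
#' @return the filtered tibble, with attributes `n_kept` and `n_dropped`.
#' @export
dbs4_filter <- function(dbs, min_pockets = 4) {
  keep <- dbs$p >= min_pockets
  out <- dbs[keep, ]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}
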