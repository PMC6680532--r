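# Bipartite DBS / Ligand-Cluster interaction network and its summary tables.

#' Build the DBS-ligand interaction network
#'
#' Nodes are DBS and Ligand-Clusters; an (unweighted) edge joins a DBS to a
#' Ligand-Cluster when at least one pocket of the DBS binds at least one
#' ligand of the cluster — multiple pocket-ligand contacts collapse to one
#' edge. A ligand node of degree 1 is selective, degree >= 2 promiscuous.
#'
#' @param dbs tibble with `dbs_id`, `promiscuity` and optionally
#'   `protein_class`.
#' @param ligand_clusters tibble with `ligand_cluster` (ids).
#' @param interactions tibble with `dbs_id`, `ligand_cluster` (one row per
#'   observed pocket-ligand contact; duplicates allowed). Ids absent from
#'   the node tables are an error naming the offending rows.
#' @return object of class `promisite_network`: list with `graph` (igraph),
#'   `dbs_nodes`, `ligand_nodes`, `edges` tibbles.
#' @export
build_network <- function(dbs, ligand_clusters, interactions) {
  bad_d <- setdiff(interactions$dbs_id, dbs$dbs_id)
  bad_l <- setdiff(interactions$ligand_cluster,
                   ligand_clusters$ligand_cluster)
  if (length(bad_d) || length(bad_l)) {
    stop("dangling id(s) in interactions: ",
         paste(utils::head(c(bad_d, bad_l), 5), collapse = ", "))
  }
  edges <- dplyr::distinct(interactions, .data$dbs_id, .data$ligand_cluster)
  deg_l <- dplyr::count(edges, .data$ligand_cluster, name = "degree")
  ligand_nodes <- dplyr::left_join(ligand_clusters, deg_l,
                                   by = "ligand_cluster")
  ligand_nodes$degree[is.na(ligand_nodes$degree)] <- 0L
  ligand_nodes$promiscuity <- ifelse(ligand_nodes$degree >= 2,
                                     "promiscuous", "selective")
  dbs_nodes <- dbs
  if (!"protein_class" %in% names(dbs_nodes)) {
    dbs_nodes$protein_class <- NA_character_
  }

  verts <- dplyr::bind_rows(
    tibble::tibble(name = dbs_nodes$dbs_id, kind = "dbs",
                   promiscuity = dbs_nodes$promiscuity,
                   protein_class = dbs_nodes$protein_class),
    tibble::tibble(name = ligand_nodes$ligand_cluster, kind = "ligand",
                   promiscuity = ligand_nodes$promiscuity,
                   protein_class = NA_character_))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE, vertices = verts)
  igraph::V(g)$type <- igraph::V(g)$kind == "ligand"  # bipartite convention
  stopifnot(igraph::is_bipartite(g))
  structure(list(graph = g, dbs_nodes = dbs_nodes,
                 ligand_nodes = ligand_nodes, edges = edges),
            class = "promisite_network")
}

#' @export
print.promisite_network <- function(x, ...) {
  cat("<promisite_network> ", nrow(x$dbs_nodes), " DBS, ",
      nrow(x$ligand_nodes), " ligand clusters, ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

#' Percentage column of a count vector, rounded to one decimal
#'
#' The tabulation arithmetic shared by all network summary tables: each
#' count as a percentage of `total` (default: the vector sum), rounded to
#' one decimal place — the precision the summary tables print.
#'
#' @param n vector of counts.
#' @param total denominator (defaults to `sum(n)`).
#' @return numeric vector of percentages.
#' @export
percentages <- function(n, total = sum(n)) round(100 * n / total, 1)

pct1 <- percentages

#' Promiscuity summary tables of an interaction network
#'
#' Three tables. `dbs_classes`: DBS and pocket counts (and percentages) per
#' promiscuity level. `ligand_dedication`: Ligand-Clusters dedicated to one
#' promiscuity level versus mixed (bound DBS span more than one level), with
#' the mixed breakdown and member-ligand counts when cluster sizes are
#' supplied. `ligand_promiscuity`: for each DBS level, how many of the
#' Ligand-Clusters touching at least one such DBS are selective versus
#' promiscuous, with the mean number of DBS (and protein classes) bound by
#' the promiscuous ones; the `ALL` row uses distinct counts over all
#' Ligand-Clusters and is deliberately NOT the sum of the level rows (a
#' cluster can touch several levels). Percentages are rounded to one
#' decimal.
#'
#' @param network a `promisite_network`.
#' @param pockets_per_dbs optional tibble `dbs_id`, `p` for the pocket
#'   columns of `dbs_classes`.
#' @param cluster_sizes optional tibble `ligand_cluster`, `size` (member
#'   ligands) for the dedication table.
#' @return list of three tibbles.
#' @export
tabulate_network <- function(network, pockets_per_dbs = NULL,
                             cluster_sizes = NULL) {
  dbs <- network$dbs_nodes
  edges <- network$edges
  lev <- c("S", "MP", "HP")

  d1 <- dplyr::count(dbs[dbs$promiscuity %in% lev, ], .data$promiscuity,
                     name = "n_dbs")
  d1 <- d1[match(lev, d1$promiscuity), ]
  d1$promiscuity <- lev
  d1$n_dbs[is.na(d1$n_dbs)] <- 0L
  d1$pct_dbs <- pct1(d1$n_dbs, sum(d1$n_dbs))
  if (!is.null(pockets_per_dbs)) {
    pp <- dplyr::left_join(dbs, pockets_per_dbs, by = "dbs_id")
    pk <- tapply(pp$p, pp$promiscuity, sum)
    d1$n_pockets <- as.integer(pk[lev])
    d1$pct_pockets <- pct1(d1$n_pockets, sum(d1$n_pockets))
  }

  ## dedication: which promiscuity levels does each ligand cluster touch
  lvl_of <- stats::setNames(dbs$promiscuity, dbs$dbs_id)
  touched <- tapply(lvl_of[edges$dbs_id], edges$ligand_cluster,
                    function(v) sort(unique(v[v %in% lev])))
  dedication <- vapply(touched, function(v) {
    if (length(v) == 0) return(NA_character_)
    if (length(v) == 1) v else "mixed"
  }, character(1))
  mixed_combo <- vapply(touched, function(v) {
    if (length(v) <= 1) NA_character_ else paste(v, collapse = "+")
  }, character(1))
  ded_tbl <- tibble::tibble(ligand_cluster = names(dedication),
                            dedication = dedication,
                            mixed_combo = mixed_combo)
  rows <- c(lev, "mixed")
  d2 <- tibble::tibble(
    dedication = rows,
    n_clusters = vapply(rows, function(r) sum(ded_tbl$dedication == r,
                                              na.rm = TRUE), integer(1),
                        USE.NAMES = FALSE))
  d2 <- dplyr::bind_rows(d2, tibble::tibble(
    dedication = "ALL", n_clusters = sum(d2$n_clusters)))
  d2$pct_clusters <- pct1(d2$n_clusters, sum(!is.na(ded_tbl$dedication)))
  if (!is.null(cluster_sizes)) {
    sz <- stats::setNames(cluster_sizes$size, cluster_sizes$ligand_cluster)
    n_lig <- vapply(rows, function(r) {
      sum(sz[ded_tbl$ligand_cluster[ded_tbl$dedication %in% r]])
    }, numeric(1), USE.NAMES = FALSE)
    d2$n_ligands <- c(n_lig, sum(n_lig))
    d2$pct_ligands <- pct1(d2$n_ligands, sum(n_lig))
  }

  ## ligand promiscuity per DBS level (distinct-count semantics for ALL)
  lig_deg <- stats::setNames(network$ligand_nodes$degree,
                             network$ligand_nodes$ligand_cluster)
  classes_of <- stats::setNames(dbs$protein_class, dbs$dbs_id)
  row3 <- function(label, clusters) {
    prom <- clusters[lig_deg[clusters] >= 2]
    n_classes <- vapply(prom, function(lc) {
      length(unique(stats::na.omit(
        classes_of[edges$dbs_id[edges$ligand_cluster == lc]])))
    }, numeric(1))
    tibble::tibble(
      dbs_level = label,
      total = length(clusters),
      selective = length(clusters) - length(prom),
      promiscuous = length(prom),
      pct_selective = pct1(length(clusters) - length(prom),
                           length(clusters)),
      mean_dbs_bound = if (length(prom)) mean(lig_deg[prom]) else NA_real_,
      mean_classes_bound = if (length(prom) && any(n_classes > 0))
        mean(n_classes) else NA_real_)
  }
  d3 <- dplyr::bind_rows(
    lapply(lev, function(l) {
      cl <- unique(edges$ligand_cluster[lvl_of[edges$dbs_id] == l])
      row3(paste0(l, " DBS"), cl)
    }),
    row3("All DBS", unique(edges$ligand_cluster)))

  list(dbs_classes = d1, ligand_dedication = d2, ligand_promiscuity = d3,
       dedication_detail = ded_tbl)
}

#' Two-step ego expansion around a set of seed DBS
#'
#' Expands exactly two steps: the seed DBS, every Ligand-Cluster they bind,
#' and every DBS bound by those Ligand-Clusters. Re-running the expansion on
#' its own result adds nothing (the operation is idempotent at two steps).
#'
#' @param network a `promisite_network`.
#' @param seed_dbs character vector of DBS ids, or
#' @param protein_class select all DBS of one protein class as seeds.
#' @return a `promisite_network` induced on the expanded node set.
#' @export
subnetwork <- function(network, seed_dbs = NULL, protein_class = NULL) {
  dbs <- network$dbs_nodes
  if (is.null(seed_dbs)) {
    if (is.null(protein_class)) stop("give seed_dbs or protein_class")
    if (!protein_class %in% dbs$protein_class) {
      stop("unknown protein class: ", protein_class)
    }
    seed_dbs <- dbs$dbs_id[dbs$protein_class %in% protein_class]
  }
  if (!all(seed_dbs %in% dbs$dbs_id)) {
    stop("unknown DBS id(s): ",
         paste(setdiff(seed_dbs, dbs$dbs_id), collapse = ", "))
  }
  e <- network$edges
  ligs <- unique(e$ligand_cluster[e$dbs_id %in% seed_dbs])
  dbs_all <- unique(e$dbs_id[e$ligand_cluster %in% ligs])
  keep_d <- dbs[dbs$dbs_id %in% union(seed_dbs, dbs_all), ]
  keep_l <- network$ligand_nodes[
    network$ligand_nodes$ligand_cluster %in% ligs, ]
  keep_e <- e[e$dbs_id %in% keep_d$dbs_id & e$ligand_cluster %in% ligs, ]
  build_network(keep_d, keep_l[, "ligand_cluster", drop = FALSE], keep_e)
}

#' Export a network as GraphML plus an edge-list CSV
#'
#' @param network a `promisite_network`.
#' @param graphml_path,edges_path output file paths (either may be NULL).
#' @return invisibly, the paths written.
#' @export
write_network <- function(network, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path)) {
    g <- network$graph
    ## GraphML writers reject NA attributes
    pc <- igraph::V(g)$protein_class
    igraph::V(g)$protein_class <- ifelse(is.na(pc), "", pc)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    utils::write.csv(network$edges, edges_path, row.names = FALSE)
  }
  invisible(c(graphml_path, edges_path))
}

#' Plot a bipartite interaction network
#'
#' DBS on the left (coloured by promiscuity), Ligand-Clusters on the right;
#' a simple two-column layout rendered with ggplot2.
#'
#' @param object a `promisite_network`.
#' @param ... unused.
#' @export
autoplot.promisite_network <- function(object, ...) {
  dbs <- object$dbs_nodes
  lig <- object$ligand_nodes
  nd <- tibble::tibble(name = dbs$dbs_id, kind = "DBS",
                       promiscuity = dbs$promiscuity, x = 0,
                       y = seq_len(nrow(dbs)) / max(1, nrow(dbs)))
  nl <- tibble::tibble(name = lig$ligand_cluster, kind = "Ligand-Cluster",
                       promiscuity = lig$promiscuity, x = 1,
                       y = seq_len(nrow(lig)) / max(1, nrow(lig)))
  nodes <- dplyr::bind_rows(nd, nl)
  seg <- dplyr::left_join(
    dplyr::left_join(object$edges,
                     stats::setNames(nd[, c("name", "y")], c("dbs_id", "y0")),
                     by = "dbs_id"),
    stats::setNames(nl[, c("name", "y")], c("ligand_cluster", "y1")),
    by = "ligand_cluster")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = 0, xend = 1, y = .data$y0,
                                       yend = .data$y1),
                          alpha = 0.3, colour = "grey50") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$promiscuity,
                                     shape = .data$kind), size = 2) +
    ggplot2::scale_x_continuous(breaks = c(0, 1),
                                labels = c("DBS", "Ligand-Cluster"),
                                limits = c(-0.1, 1.1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
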