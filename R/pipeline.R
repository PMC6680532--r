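# End-to-end orchestration: ligand space -> chain space -> pockets -> DBS ->
# statistics -> interaction network, with a funnel manifest and full
# determinism under the configured seed.

#' Pipeline configuration
#'
#' Every default is the protocol's standard value: 5.5 A pocket proximity,
#' 0.8 Tanimoto ligand clustering, 90%/80% two-step chain identity
#' clustering, cutoff constant k = 2 and a minimum of 4 pockets per DBS.
#'
#' @param proximity_threshold pocket contact distance (Angstrom).
#' @param tanimoto_threshold ligand clustering threshold.
#' @param identity_t1,identity_t2 chain clustering identity thresholds.
#' @param k barycenter cutoff constant.
#' @param min_pockets minimum pockets per DBS (DBS4 convention).
#' @param seed master seed for the stochastic stages (CV, balancing).
#' @param run_stats run the descriptor statistics and CART stage.
#' @param cart_repeats CART balance/split repeats when stats run.
#' @return list of class `promisite_config`.
#' @export
pipeline_config <- function(proximity_threshold = 5.5,
                            tanimoto_threshold = 0.8,
                            identity_t1 = 0.90, identity_t2 = 0.80,
                            k = 2, min_pockets = 4, seed = 1,
                            run_stats = TRUE, cart_repeats = 20) {
  structure(list(proximity_threshold = proximity_threshold,
                 tanimoto_threshold = tanimoto_threshold,
                 identity_t1 = identity_t1, identity_t2 = identity_t2,
                 k = k, min_pockets = min_pockets, seed = as.integer(seed),
                 run_stats = run_stats, cart_repeats = cart_repeats),
            class = "promisite_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are an error; missing keys keep their defaults.
#'
#' @param path YAML file of `pipeline_config()` keys.
#' @return a `promisite_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full promiscuity analysis
#'
#' Executes the protocol end to end on a directory of complexes plus a
#' ligand SMILES table: ligand validity/drug-likeness filtering,
#' fingerprinting and Ligand-Cluster construction; chain clustering and
#' superposition; pocket extraction with interface filtering; DBS
#' identification and promiscuity labelling; (optionally) descriptor
#' statistics and the S-vs-HP CART; and the bipartite interaction network.
#' The returned manifest mirrors the protocol funnel (ligands in / valid /
#' drug-like, chains, chain clusters, pockets, DBS, DBS >= min_pockets,
#' interactions) and is identical across reruns with the same inputs and
#' config.
#'
#' @param complexes_dir directory of PDB complexes (or vector of paths).
#' @param ligand_table data frame (or CSV path) with `ligand_id`, `smiles`.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory: stage tables, the manifest JSON and
#'   the serialized config are written there.
#' @return object of class `promisite_run`: list with `manifest`, `ligands`,
#'   `ligand_clusters`, `chain_clusters`, `superposition`, `pockets`,
#'   `pocket_descriptors`, `dbs`, `promiscuity`, `stats`, `network`,
#'   `config`.
#' @export
run_pipeline <- function(complexes_dir, ligand_table,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "promisite_config"))
  if (is.character(ligand_table) && length(ligand_table) == 1) {
    ligand_table <- utils::read.csv(ligand_table, stringsAsFactors = FALSE)
  }
  ligand_table <- tibble::as_tibble(ligand_table)
  atoms <- read_complexes(complexes_dir)
  manifest <- list(n_complexes = length(unique(atoms$complex_id)))

  ## ---- ligand space
  used_ids <- unique(stats::na.omit(atoms$ligand_id))
  ligands <- ligand_table[ligand_table$ligand_id %in% used_ids, ]
  manifest$n_ligands_parsed <- nrow(ligands)
  ligands <- validity_filter(ligands)
  manifest$n_ligands_valid <- sum(ligands$valid)
  valid <- ligands[ligands$valid, ]
  empty_run <- function(reason) {
    manifest$stopped <- reason
    structure(list(manifest = manifest, config = config),
              class = "promisite_run")
  }
  if (nrow(valid) == 0) return(empty_run("no valid ligands"))

  desc <- ligand_descriptors(valid)
  desc <- druglike_filter(desc)
  manifest$n_ligands_druglike <- sum(desc$drug_like %in% TRUE)
  druglike <- desc[desc$drug_like %in% TRUE, ]
  if (nrow(druglike) == 0) return(empty_run("no drug-like ligands"))

  fps <- fingerprint_ligands(valid[valid$ligand_id %in% druglike$ligand_id, ])
  lig_clusters <- cluster_ligands(fps,
                                  threshold = config$tanimoto_threshold)
  lc_summary <- ligand_cluster_summary(lig_clusters, fps,
                                       descriptors = druglike)
  manifest$n_ligand_clusters <- nrow(lc_summary)

  ## ---- chain space
  seqs <- chain_sequences(atoms)
  manifest$n_chains <- nrow(seqs)
  cc <- cluster_chains(seqs, t1 = config$identity_t1,
                       t2 = config$identity_t2)
  manifest$n_chain_clusters <- length(unique(cc$cluster_id))
  sup <- superpose_chains(atoms, cc)

  ## ---- pockets (only for drug-like ligands)
  keep_atoms <- atoms[atoms$record == "ATOM" |
                        atoms$ligand_id %in% druglike$ligand_id, ]
  pk <- extract_pockets(keep_atoms, threshold = config$proximity_threshold,
                        superposition = sup)
  manifest$n_pockets <- nrow(pk$pockets)
  manifest$n_pockets_rejected <- nrow(pk$rejected)
  if (nrow(pk$pockets) == 0) return(empty_run("no pockets"))
  pdesc <- pocket_descriptors(pk)

  ## ---- DBS
  dbs_res <- identify_dbs(pk$pockets, k = config$k)
  cluster_of_ligand <- stats::setNames(lig_clusters$ligand_cluster,
                                       lig_clusters$ligand_id)
  plc <- tibble::tibble(
    pocket_id = pk$pockets$pocket_id,
    ligand_cluster = unname(cluster_of_ligand[pk$pockets$ligand_id]))
  prom <- classify_promiscuity(dbs_res$membership, plc)
  manifest$n_dbs <- nrow(prom)
  dbs_tbl <- dplyr::left_join(dbs_res$dbs,
                              prom[, c("dbs_id", "n_ligand_clusters",
                                       "promiscuity")],
                              by = "dbs_id")
  dbs4 <- dbs4_filter(dbs_tbl, min_pockets = config$min_pockets)
  manifest$n_dbs4 <- nrow(dbs4)
  manifest$promiscuity_counts <- as.list(
    table(factor(dbs4$promiscuity, levels = c("S", "MP", "HP",
                                              "UNDETERMINED"))))

  ## ---- statistics (S vs HP CART on pocket descriptors)
  stats_out <- NULL
  if (isTRUE(config$run_stats)) {
    rows <- dplyr::inner_join(
      dplyr::inner_join(pdesc, dbs_res$membership, by = "pocket_id"),
      dbs4[, c("dbs_id", "promiscuity")], by = "dbs_id")
    rows <- rows[rows$promiscuity %in% c("S", "MP", "HP"), ]
    slot_names <- pocket_descriptor_slots()$descriptor
    usable <- slot_names[vapply(slot_names, function(s)
      is.numeric(rows[[s]]) && sum(!is.na(rows[[s]])) > 0, logical(1))]
    comparison <- NULL
    if (length(unique(rows$promiscuity)) >= 2 && nrow(rows) >= 4) {
      comparison <- class_comparison(rows, usable,
                                     class_col = "promiscuity",
                                     bonferroni_n = length(slot_names))
    }
    cart <- NULL
    shp <- rows[rows$promiscuity %in% c("S", "HP"), ]
    n_groups <- table(dplyr::distinct(shp, .data$dbs_id,
                                      .data$promiscuity)$promiscuity)
    if (length(n_groups) == 2 && all(n_groups >= 5)) {
      cart <- cart_train_eval(shp, usable, class_col = "promiscuity",
                              group_col = "dbs_id", positive = "HP",
                              repeats = config$cart_repeats,
                              seed = config$seed)
    }
    stats_out <- list(comparison = comparison, cart = cart)
  }

  ## ---- network
  interactions <- dplyr::inner_join(
    dbs_res$membership[, c("pocket_id", "dbs_id")], plc, by = "pocket_id")
  net_dbs <- dbs_tbl[dbs_tbl$dbs_id %in% interactions$dbs_id,
                     c("dbs_id", "promiscuity")]
  net <- build_network(
    net_dbs,
    dplyr::distinct(interactions, .data$ligand_cluster),
    interactions[, c("dbs_id", "ligand_cluster")])
  manifest$n_interactions <- nrow(net$edges)
  manifest$n_ligand_clusters_selective <-
    sum(net$ligand_nodes$promiscuity == "selective")

  run <- structure(list(
    manifest = manifest, ligands = ligands, ligand_descriptors = desc,
    ligand_clusters = lc_summary, ligand_membership = lig_clusters,
    chain_clusters = cc, superposition = sup, pockets = pk,
    pocket_descriptors = pdesc, dbs = dbs_tbl, dbs4 = dbs4,
    dbs_membership = dbs_res$membership,
    promiscuity = prom, stats = stats_out, network = net,
    config = config), class = "promisite_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    utils::write.csv(dbs_tbl, file.path(out_dir, "dbs.csv"),
                     row.names = FALSE)
    utils::write.csv(dbs_res$membership,
                     file.path(out_dir, "pocket_membership.csv"),
                     row.names = FALSE)
    utils::write.csv(pdesc, file.path(out_dir, "pocket_descriptors.csv"),
                     row.names = FALSE)
    write_network(net, file.path(out_dir, "network.graphml"),
                  file.path(out_dir, "network_edges.csv"))
  }
  run
}

#' @export
print.promisite_run <- function(x, ...) {
  cat("<promisite_run>\n")
  m <- x$manifest
  for (nm in setdiff(names(m), "promiscuity_counts")) {
    cat(sprintf("  %-28s %s\n", nm, as.character(m[[nm]])))
  }
  if (!is.null(m$promiscuity_counts)) {
    cat("  promiscuity (>= min_pockets):",
        paste(names(m$promiscuity_counts), unlist(m$promiscuity_counts),
              sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' One-row summary of a pipeline run
#' @param x a `promisite_run`.
#' @param ... unused.
#' @export
glance.promisite_run <- function(x, ...) {
  m <- x$manifest
  tibble::as_tibble(m[vapply(m, function(v) length(v) == 1 &&
                               !is.list(v), logical(1))])
}

#' DBS table of a pipeline run in tidy form
#' @param x a `promisite_run`.
#' @param ... unused.
#' @export
tidy.promisite_run <- function(x, ...) x$dbs
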