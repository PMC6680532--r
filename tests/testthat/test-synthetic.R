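# Synthetic complex generator: planted structure, determinism, noise model.

test_that("scenario validation rejects impossible designs", {
  expect_error(synthetic_scenario(n_chain_families = 0), "counts")
  expect_error(synthetic_scenario(within_family_identity = 0.5), "identity")
  expect_error(synthetic_scenario(site_separation = -2), "site_separation")
  expect_error(synthetic_scenario(planted_promiscuity = 9,
                                  ligand_families = 4),
               "exceeds the number of ligand families")
  expect_error(synthetic_scenario(planted_promiscuity = 4,
                                  pockets_per_site = 2),
               "pockets_per_site")
  ## sites that cannot fit on the chain fail fast
  expect_error(synthetic_scenario(sites_per_family = 30,
                                  site_separation = 25),
               "unsatisfiable")
})

test_that("generated counts equal the scenario by construction", {
  sc <- small_scenario_dir()
  gt <- sc$gt; scn <- sc$scenario
  n_complex <- scn$n_chain_families * scn$pockets_per_site
  expect_length(list.files(file.path(sc$dir, "complexes")), n_complex)
  expect_equal(nrow(gt$chains), n_complex)
  expect_equal(nrow(gt$sites),
               scn$n_chain_families * scn$sites_per_family)
  expect_equal(nrow(gt$pockets),
               n_complex * scn$sites_per_family)
  expect_equal(nrow(gt$ligands),
               scn$ligand_families * scn$ligands_per_family)
  ## every pocket maps to exactly one site, every site has its quota
  expect_equal(unname(table(gt$pockets$site_id)),
               rep(scn$pockets_per_site, nrow(gt$sites)),
               ignore_attr = TRUE)
  ## planted labels match the promiscuity counts
  expect_equal(gt$sites$label,
               ifelse(gt$sites$n_ligand_families == 1, "S",
                      ifelse(gt$sites$n_ligand_families <= 3, "MP", "HP")))
})

test_that("regeneration with the same seed is byte-identical", {
  scn <- synthetic_scenario(seed = 5, n_chain_families = 1,
                            sites_per_family = 1, ligand_families = 2,
                            ligands_per_family = 2,
                            planted_promiscuity = 2)
  d1 <- tempfile(); d2 <- tempfile()
  generate_scenario(scn, d1)
  generate_scenario(scn, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_equal(f1, sort(list.files(d2, recursive = TRUE)))
  sum1 <- tools::md5sum(file.path(d1, f1))
  sum2 <- tools::md5sum(file.path(d2, f1))
  expect_equal(unname(sum1), unname(sum2))
  ## a different seed changes the output
  scn2 <- synthetic_scenario(seed = 6, n_chain_families = 1,
                             sites_per_family = 1, ligand_families = 2,
                             ligands_per_family = 2,
                             planted_promiscuity = 2)
  d3 <- tempfile(); generate_scenario(scn2, d3)
  sum3 <- tools::md5sum(file.path(d3, sort(list.files(d3,
                                                      recursive = TRUE))))
  expect_false(all(unname(sum1) == unname(sum3)))
})

test_that("realized within-family identity respects the target", {
  scn <- synthetic_scenario(seed = 2, n_chain_families = 3,
                            within_family_identity = 0.92,
                            sites_per_family = 1,
                            planted_promiscuity = c(1, 2, 4))
  dir <- tempfile()
  generate_scenario(scn, dir)
  atoms <- read_complexes(file.path(dir, "complexes"))
  seqs <- chain_sequences(atoms)
  gt <- read.csv(file.path(dir, "ground_truth_chains.csv"))
  seqs <- merge(seqs, gt, by = "chain_uid")
  for (fam in unique(seqs$family)) {
    s <- seqs[seqs$family == fam, ]
    s <- s[!duplicated(s$sequence), ]
    if (nrow(s) < 2) next
    ids <- combn(nrow(s), 2, function(ij) {
      sequence_identity(s$sequence[ij[1]], s$sequence[ij[2]])
    })
    expect_true(all(ids >= 0.90))
  }
})

test_that("planted sites are separated as requested", {
  sc <- small_scenario_dir()
  atoms <- read_complexes(file.path(sc$dir, "complexes"))
  lig <- atoms[atoms$record == "HETATM", ]
  truth <- sc$gt$pockets
  centers <- dplyr::summarise(
    dplyr::group_by(merge(lig, truth), site_id, complex_id),
    x = mean(x), y = mean(y), z = mean(z), .groups = "drop")
  for (cid in unique(centers$complex_id)) {
    cc <- centers[centers$complex_id == cid, ]
    if (nrow(cc) < 2) next
    d <- dist(as.matrix(cc[, c("x", "y", "z")]))
    ## anchors are >= site_separation apart; ligand-cloud centroids may
    ## wobble by the cloud radius plus coordinate noise
    expect_true(all(d >= sc$scenario$site_separation - 2))
  }
})

test_that("ligand families are cohesive under the fingerprint recomputation", {
  sc <- small_scenario_dir()
  fps <- fingerprint_ligands(sc$gt$ligand_table)
  fam <- merge(sc$gt$ligand_table, sc$gt$ligands)
  for (f in unique(fam$family)) {
    ids <- fam$ligand_id[fam$family == f]
    if (length(ids) < 2) next
    sim <- tanimoto_matrix(fps[ids, ])
    expect_true(min(sim) >= sc$scenario$within_family_tanimoto)
  }
  ## cross-family similarity stays below the clustering threshold
  sim <- tanimoto_matrix(fps)
  for (f in unique(fam$family)) {
    ids <- fam$ligand_id[fam$family == f]
    other <- setdiff(rownames(sim), ids)
    expect_lt(max(sim[ids, other]), 0.8)
  }
})

test_that("coordinate noise has the requested per-axis spread", {
  sc <- small_scenario_dir()
  atoms <- read_complexes(file.path(sc$dir, "complexes"))
  big <- dplyr::bind_rows(replicate(8, atoms, simplify = FALSE))
  big <- big[seq_len(12000), ]
  out0 <- perturb_coordinates(big, sd = 0)
  expect_identical(out0$x, big$x)
  out1 <- perturb_coordinates(big, sd = 0.3, seed = 4)
  out2 <- perturb_coordinates(big, sd = 0.3, seed = 4)
  expect_identical(out1$x, out2$x)
  disp <- c(out1$x - big$x, out1$y - big$y, out1$z - big$z)
  expect_lt(abs(sd(disp) - 0.3) / 0.3, 0.05)
  expect_error(perturb_coordinates(big, sd = -1), ">= 0")
})
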