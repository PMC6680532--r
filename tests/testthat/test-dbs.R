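# Barycenter cutoff, pocket clustering, score of overlap, promiscuity.

fake_pockets <- function(xyz, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(nrow(xyz)))
  tibble::tibble(pocket_id = ids, bx = xyz[, 1], by = xyz[, 2],
                 bz = xyz[, 3])
}

test_that("cutoff follows C = D - k*sigma with population sigma", {
  p <- compute_cutoff(c(6, 8), k = 2)
  expect_equal(p$D, 7)
  expect_equal(p$sigma, 1)       # population divisor
  expect_equal(p$C, 5)

  z <- compute_cutoff(rep(7, 5), k = 2)
  expect_equal(z$C, 7)           # zero variance
  expect_equal(compute_cutoff(c(6, 8), k = 0)$C, 7)
  expect_equal(compute_cutoff(4)$C, 4)   # single pocket: sigma = 0
  s <- compute_cutoff(c(6, 8), k = 2, sigma = "sample")
  expect_equal(s$sigma, sd(c(6, 8)))
  expect_error(compute_cutoff(numeric(0)), "no dmax")
  expect_error(compute_cutoff(c(3, -1)), ">= 0")
})

test_that("pocket clustering equals brute-force connected components", {
  set.seed(17)
  for (rep in 1:30) {
    n <- sample(5:40, 1)
    xyz <- matrix(rnorm(3 * n, sd = sample(5:20, 1)), ncol = 3)
    C <- runif(1, 2, 15)
    mem <- cluster_pockets(fake_pockets(xyz), params = list(C = C))
    want <- oracle_components(xyz, C)
    ## identical partitions up to relabeling
    expect_equal(anyDuplicated(mem$pocket_id), 0)
    got_part <- split(mem$pocket_id, mem$dbs_ordinal)
    want_part <- split(sprintf("P%03d", seq_len(n)), want)
    norm <- function(p) unname(lapply(p[order(vapply(p, min, ""))], sort))
    expect_equal(norm(got_part), norm(want_part))
  }
})

test_that("clustering edge cases behave as specified", {
  one <- cluster_pockets(fake_pockets(rbind(c(0, 0, 0))),
                         params = list(C = 5))
  expect_equal(nrow(one), 1)
  expect_equal(one$dbs_ordinal, 1L)

  same <- cluster_pockets(fake_pockets(rbind(c(1, 1, 1), c(1, 1, 1))),
                          params = list(C = 3))
  expect_equal(length(unique(same$dbs_ordinal)), 1)

  ## C <= 0: all singletons, with a warning
  expect_warning(
    sing <- cluster_pockets(fake_pockets(rbind(c(0, 0, 0), c(0, 0, 0))),
                            params = list(C = -1)),
    "singleton")
  expect_equal(length(unique(sing$dbs_ordinal)), 2)

  ## strict inequality at the boundary: distance == C is NOT joined
  apart <- fake_pockets(rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_equal(length(unique(
    cluster_pockets(apart, params = list(C = 5))$dbs_ordinal)), 2)
  expect_equal(length(unique(
    cluster_pockets(apart, params = list(C = 5.001))$dbs_ordinal)), 1)
})

test_that("score of overlap follows the shared-atom formula", {
  keys <- paste0(1:25, "|CA")
  expect_equal(score_of_overlap(keys, keys), 1)
  expect_equal(score_of_overlap(keys[1:10], keys[11:20]), 0)
  ## n1 = 10, n2 = 10, n_common = 5 -> 5 / 15
  expect_equal(score_of_overlap(keys[1:10], keys[6:15]), 1 / 3)
  ## symmetry
  a <- keys[1:12]; b <- keys[7:25]
  expect_equal(score_of_overlap(a, b), score_of_overlap(b, a))
  ## NA keys (unaligned atoms) never match but still count in the union
  expect_equal(score_of_overlap(c(keys[1:5], NA), c(keys[1:5], NA)),
               5 / 7)
  expect_error(score_of_overlap(character(0), keys), "empty")
})

test_that("promiscuity labels follow the ligand-cluster counts", {
  mem <- tibble::tibble(
    pocket_id = sprintf("P%02d", 1:13),
    dbs_id = rep(c("D1", "D2", "D3", "D4"), c(4, 4, 4, 1)))
  plc <- tibble::tibble(
    pocket_id = sprintf("P%02d", 1:13),
    ligand_cluster = c("L1", "L1", "L1", "L1",      # D1: 1 cluster -> S
                       "L1", "L2", "L3", "L1",      # D2: 3 clusters -> MP
                       "L1", "L2", "L3", "L4",      # D3: 4 clusters -> HP
                       "L5"))                       # D4: single pocket
  out <- classify_promiscuity(mem, plc)
  lab <- setNames(out$promiscuity, out$dbs_id)
  expect_equal(lab[["D1"]], "S")
  expect_equal(lab[["D2"]], "MP")
  expect_equal(lab[["D3"]], "HP")
  expect_equal(lab[["D4"]], "UNDETERMINED")
  expect_error(classify_promiscuity(mem, plc[-1, ]), "without ligand-cluster")
})

test_that("the minimum-occurrence filter keeps p >= 4 inclusively", {
  dbs <- tibble::tibble(dbs_id = c("a", "b", "c", "d"), p = c(3, 4, 5, 1))
  kept <- dbs4_filter(dbs)
  expect_setequal(kept$dbs_id, c("b", "c"))
  expect_equal(attr(kept, "n_kept"), 2)
  expect_equal(attr(kept, "n_dropped"), 2)
  ## tally oracle on a random p distribution
  set.seed(2)
  tbl <- tibble::tibble(dbs_id = as.character(1:50),
                        p = sample(1:10, 50, replace = TRUE))
  expect_equal(nrow(dbs4_filter(tbl)), sum(tbl$p >= 4))
  expect_equal(nrow(dbs4_filter(tbl, min_pockets = 2)), sum(tbl$p >= 2))
})

test_that("identify_dbs splits planted sites and validates overlap", {
  sc <- small_scenario_dir()
  run_atoms <- read_complexes(file.path(sc$dir, "complexes"))
  seqs <- chain_sequences(run_atoms)
  cl <- cluster_chains(seqs)
  sup <- superpose_chains(run_atoms, cl)
  pk <- extract_pockets(run_atoms, superposition = sup)
  res <- identify_dbs(pk$pockets)
  ## one DBS per planted site; within-DBS overlap strictly positive
  expect_equal(nrow(res$dbs), nrow(sc$gt$sites))
  expect_true(all(res$dbs$so_min > 0))
  expect_true(all(res$dbs$so_max <= 1))
  ## every pocket in exactly one DBS
  expect_setequal(res$membership$pocket_id, pk$pockets$pocket_id)
  expect_equal(anyDuplicated(res$membership$pocket_id), 0)
  ## pockets of one DBS map to one planted site
  truth <- sc$gt$pockets
  joined <- merge(res$membership,
                  data.frame(pocket_id = paste0(truth$ligand_instance,
                                                "__A"),
                             site_id = truth$site_id))
  expect_equal(nrow(joined), nrow(res$membership))
  tab <- table(joined$dbs_id, joined$site_id)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
})
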