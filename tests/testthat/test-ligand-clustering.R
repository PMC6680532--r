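# Butina clustering and representative selection.

## block-structured fingerprints: one 46-member family of near-duplicates
## plus 10 mutually dissimilar singletons
family_plus_singletons <- function() {
  n_fam <- 46; n_sing <- 10; bits <- 200
  m <- matrix(FALSE, n_fam + n_sing, bits)
  m[seq_len(n_fam), 1:40] <- TRUE
  for (i in seq_len(n_fam)) m[i, 40 + i %% 8 + 1] <- TRUE
  for (k in seq_len(n_sing)) {
    m[n_fam + k, (60 + 10 * k):(60 + 10 * k + 6)] <- TRUE
  }
  rownames(m) <- sprintf("L%02d", seq_len(n_fam + n_sing))
  m
}

test_that("butina clustering recovers a separable family structure", {
  fps <- family_plus_singletons()
  ## independent check that the instance is separable at 0.8
  sim <- tanimoto_matrix(fps)
  fam <- sim[1:46, 1:46]
  expect_true(min(fam) >= 0.8)
  expect_true(max(sim[1:46, 47:56]) < 0.8)

  cl <- cluster_ligands(fps, threshold = 0.8)
  sizes <- sort(table(cl$ligand_cluster), decreasing = TRUE)
  expect_equal(length(sizes), 11)
  expect_equal(unname(sizes[1]), 46)

  ## brute-force connected components at the threshold agree on this
  ## separable instance
  n <- nrow(sim)
  comp <- rep(NA_integer_, n); k <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1; queue <- s; comp[s] <- k
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- which(is.na(comp) & sim[i, ] >= 0.8)
      comp[nb] <- k; queue <- c(queue, nb)
    }
  }
  butina_part <- split(cl$ligand_id, cl$ligand_cluster)
  cc_part <- split(rownames(sim), comp)
  norm <- function(p) unname(lapply(p[order(vapply(p, min, ""))], sort))
  expect_equal(norm(butina_part), norm(cc_part))
})

test_that("butina output is a partition with the centroid guarantee", {
  fps <- random_fps(60, bits = 48, density = 0.45, seed = 12)
  cl <- cluster_ligands(fps, threshold = 0.8)
  expect_setequal(cl$ligand_id, rownames(fps))
  expect_equal(anyDuplicated(cl$ligand_id), 0)
  sim <- tanimoto_matrix(fps)
  for (k in unique(cl$ligand_cluster)) {
    mem <- cl$ligand_id[cl$ligand_cluster == k]
    cen <- cl$ligand_id[cl$ligand_cluster == k & cl$is_centroid]
    expect_length(cen, 1)
    expect_true(all(sim[cen, mem] >= 0.8 | mem == cen))
  }
})

test_that("lowering the threshold never increases the cluster count", {
  fps <- random_fps(50, bits = 48, density = 0.4, seed = 5)
  counts <- vapply(c(0.9, 0.8, 0.6, 0.4, 0.2), function(t) {
    length(unique(cluster_ligands(fps, threshold = t)$ligand_cluster))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("small clustering contracts hold", {
  one <- random_fps(1, seed = 2)
  cl1 <- cluster_ligands(one)
  expect_equal(nrow(cl1), 1)
  expect_true(cl1$is_centroid)

  two <- matrix(FALSE, 2, 40, dimnames = list(c("a", "b"), NULL))
  two[1, 1:20] <- TRUE
  two[2, c(1:17, 21:23)] <- TRUE   # tanimoto 17/23 = 0.739
  expect_equal(length(unique(cluster_ligands(two, 0.8)$ligand_cluster)), 2)
  two[2, ] <- FALSE; two[2, 1:19] <- TRUE; two[2, 21] <- TRUE # 19/21 = 0.905
  expect_equal(length(unique(cluster_ligands(two, 0.8)$ligand_cluster)), 1)
})

test_that("ward alternative also yields a partition", {
  fps <- random_fps(25, bits = 48, density = 0.4, seed = 9)
  cl <- cluster_ligands(fps, threshold = 0.8, method = "ward")
  expect_setequal(cl$ligand_id, rownames(fps))
  expect_equal(anyDuplicated(cl$ligand_id), 0)
})

test_that("representative ligand minimises the weighted distance to the mean", {
  desc <- tibble::tibble(
    ligand_id = c("a", "b", "c", "d", "e"),
    mw = c(100, 110, 300, 105, 500),
    logp = c(1, 2, 9, 1.5, -3),
    hbd = c(1, 1, 4, 1, 6))
  ## oracle: explicit arithmetic over the stated weights
  X <- as.matrix(desc[, c("mw", "logp", "hbd")])
  w <- 1 / apply(X, 2, var)
  members <- c("a", "b", "d")
  mu <- colMeans(X[c(1, 2, 4), ])
  dists <- apply(X[c(1, 2, 4), ], 1, function(r) sum(w * (r - mu)^2))
  want <- members[which.min(dists)]
  expect_equal(
    representative_ligand(members, desc,
                          descriptor_cols = c("mw", "logp", "hbd")),
    want)
  ## singleton and tie-break contracts
  expect_equal(representative_ligand("c", desc), "c")
  tie <- tibble::tibble(ligand_id = c("z", "y", "x"), mw = c(1, 1, 1),
                        logp = c(2, 2, 2))
  expect_equal(
    representative_ligand(c("z", "y", "x"), tie,
                          descriptor_cols = c("mw", "logp")), "x")
})

test_that("cluster summary reports sizes, cohesion and representatives", {
  fps <- family_plus_singletons()
  cl <- cluster_ligands(fps, threshold = 0.8)
  desc <- tibble::tibble(ligand_id = rownames(fps),
                         mw = seq_len(nrow(fps)) * 10,
                         logp = rev(seq_len(nrow(fps))))
  s <- ligand_cluster_summary(cl, fps, descriptors = desc)
  expect_equal(sum(s$size), nrow(fps))
  expect_true(all(s$mean_pairwise_tanimoto >= 0 &
                    s$mean_pairwise_tanimoto <= 1))
  big <- s[s$size == 46, ]
  expect_true(big$representative %in% big$members[[1]])
})
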