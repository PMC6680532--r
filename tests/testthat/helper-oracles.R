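# Independent brute-force oracles used to validate the package's
# implementations. These deliberately avoid the code paths they check.

## all protein atom indices within `threshold` of any ligand atom, by a
## plain O(n*m) double loop
oracle_pocket_scan <- function(prot_xyz, lig_xyz, threshold) {
  hit <- logical(nrow(prot_xyz))
  for (i in seq_len(nrow(prot_xyz))) {
    for (j in seq_len(nrow(lig_xyz))) {
      if (sqrt(sum((prot_xyz[i, ] - lig_xyz[j, ])^2)) <= threshold) {
        hit[i] <- TRUE
        break
      }
    }
  }
  which(hit)
}

## connected components under "distance < C" by breadth-first search
oracle_components <- function(xyz, C) {
  n <- nrow(xyz)
  comp <- rep(NA_integer_, n)
  k <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1
    queue <- s
    comp[s] <- k
    while (length(queue) > 0) {
      i <- queue[1]; queue <- queue[-1]
      for (j in seq_len(n)) {
        if (is.na(comp[j]) &&
            sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < C) {
          comp[j] <- k
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

## exhaustive global alignment (affine gaps) by plain recursion with
## memoisation; returns the best score and the matches achieved by a
## score-optimal alignment (match 1, mismatch 0, gap open 10, extend 0.5)
oracle_alignment_matches <- function(a, b, open = 10, ext = 0.5) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  memo <- new.env(hash = TRUE)
  ## state: position i in a, j in b, mode (0 diag, 1 gap-in-b, 2 gap-in-a)
  rec <- function(i, j, mode) {
    key <- paste(i, j, mode)
    if (exists(key, envir = memo, inherits = FALSE)) {
      return(get(key, envir = memo))
    }
    if (i > length(a) && j > length(b)) return(c(0, 0))
    best <- c(-Inf, 0)
    cand <- list()
    if (i <= length(a) && j <= length(b)) {
      sub <- rec(i + 1, j + 1, 0)
      m <- as.numeric(a[i] == b[j])
      cand[[length(cand) + 1]] <- c(sub[1] + m, sub[2] + m)
    }
    if (i <= length(a)) {    # a[i] against a gap
      sub <- rec(i + 1, j, 1)
      pen <- if (mode == 1) ext else open + ext
      cand[[length(cand) + 1]] <- c(sub[1] - pen, sub[2])
    }
    if (j <= length(b)) {    # gap against b[j]
      sub <- rec(i, j + 1, 2)
      pen <- if (mode == 2) ext else open + ext
      cand[[length(cand) + 1]] <- c(sub[1] - pen, sub[2])
    }
    for (cc in cand) {
      if (cc[1] > best[1] || (cc[1] == best[1] && cc[2] > best[2])) {
        best <- cc
      }
    }
    assign(key, best, envir = memo)
    best
  }
  res <- rec(1, 1, 0)
  list(score = res[1], matches = res[2])
}

## random fingerprint matrix with no empty rows
random_fps <- function(n, bits = 64, density = 0.3, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::runif(n * bits) < density, n, bits)
  empty <- rowSums(m) == 0
  m[empty, 1] <- TRUE
  rownames(m) <- sprintf("L%03d", seq_len(n))
  m
}

## small cached synthetic scenario shared across test files
small_scenario_dir <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      scn <- synthetic_scenario(seed = 11, n_chain_families = 2,
                                sites_per_family = 2,
                                planted_promiscuity = c(1, 2, 4, 1))
      dir <- file.path(tempdir(), "promisite-small-scenario")
      gt <- generate_scenario(scn, dir)
      cache <<- list(dir = dir, gt = gt, scenario = scn)
    }
    cache
  }
})
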