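# Class comparisons, grouped CV, balancing, CART, metrics.

## planted three-class dataset: `shifted` descriptors differ across classes
make_grouped_data <- function(n_groups_per_class = 10, rows_per_group = 4,
                              shift = 0, seed = 1, classes = c("S", "HP")) {
  set.seed(seed)
  rows <- list()
  g <- 0
  for (ci in seq_along(classes)) {
    for (k in seq_len(n_groups_per_class)) {
      g <- g + 1
      mu <- (ci - 1) * shift
      rows[[g]] <- tibble::tibble(
        group = sprintf("G%03d", g),
        promiscuity = classes[ci],
        volume = rnorm(rows_per_group, 500 + mu, 50),
        hydro = rnorm(rows_per_group, 0, 1),
        noise1 = rnorm(rows_per_group),
        noise2 = rnorm(rows_per_group))
    }
  }
  dplyr::bind_rows(rows)
}

test_that("performance metrics follow their defining ratios", {
  m <- performance_metrics(tp = 75, tn = 0, fp = 0, fn = 25)
  expect_equal(m$sensitivity, 0.75)
  m2 <- performance_metrics(tp = 0, tn = 67, fp = 33, fn = 0)
  expect_equal(m2$specificity, 0.67)
  m3 <- performance_metrics(tp = 68, tn = 0, fp = 32, fn = 0)
  expect_equal(m3$precision_eq5, 0.68)
  m4 <- performance_metrics(tp = 40, tn = 40, fp = 10, fn = 10)
  expect_equal(m4$accuracy, 0.8)
  ## sensitivity + miss rate = 1
  expect_equal(m$sensitivity + 25 / (75 + 25), 1)
  ## zero denominators yield NA
  expect_true(is.na(performance_metrics(0, 5, 0, 0)$sensitivity))
})

test_that("grouped folds are balanced, leak-free and deterministic", {
  groups <- rep(sprintf("g%02d", 1:10), each = 3)
  f <- cv_split(groups, n_folds = 5, seed = 42)
  expect_equal(as.integer(table(f$fold)), rep(2L, 5))
  expect_equal(anyDuplicated(f$group), 0)       # a group sits in one fold
  expect_equal(f, cv_split(groups, n_folds = 5, seed = 42))
  f2 <- cv_split(groups, n_folds = 5, seed = 43)
  expect_false(identical(f, f2))
  expect_error(cv_split(sprintf("g%d", 1:4), n_folds = 5), "fewer groups")
})

test_that("class balancing undersamples the majority at group level", {
  d <- make_grouped_data(n_groups_per_class = 10)
  d_maj <- dplyr::bind_rows(d, dplyr::mutate(
    make_grouped_data(40, seed = 2, classes = "HP"),
    group = paste0("X", .data$group)))
  bal <- balance_classes(d_maj, "promiscuity", "group", seed = 3)
  tab <- table(dplyr::distinct(bal, .data$promiscuity, .data$group)$promiscuity)
  expect_equal(unname(tab["S"]), unname(tab["HP"]))
  ## retained groups are a subset of the originals
  expect_true(all(bal$group %in% d_maj$group))
  ## already balanced input is unchanged (as a set of groups)
  bal0 <- balance_classes(d, "promiscuity", "group", seed = 1)
  expect_setequal(unique(bal0$group), unique(d$group))
})

test_that("ANOVA detects a planted shift and skips degenerate input", {
  d <- make_grouped_data(n_groups_per_class = 17, rows_per_group = 3,
                         shift = 150, seed = 7,
                         classes = c("S", "MP", "HP"))
  out <- class_comparison(d, c("volume", "hydro"),
                          class_col = "promiscuity", bonferroni_n = 2)
  av <- out$tests[out$tests$descriptor == "volume" &
                    out$tests$test == "anova", ]
  expect_lt(av$p_value, 1e-3)
  expect_false(av$skipped)
  expect_equal(nrow(out$class_summary[out$class_summary$descriptor ==
                                        "volume", ]), 3)

  ## all-identical values: skipped with a reason, not an error
  d$flat <- 1
  out2 <- class_comparison(d, "flat", class_col = "promiscuity")
  expect_true(all(out2$tests$skipped))
  expect_match(out2$tests$reason[1], "variance")
})

test_that("categorical descriptors go through the chi-squared path", {
  d <- make_grouped_data(n_groups_per_class = 20, seed = 3)
  d$cat <- ifelse(d$promiscuity == "HP" & runif(nrow(d)) < 0.8, "yes", "no")
  out <- class_comparison(d, "cat", class_col = "promiscuity")
  expect_equal(out$tests$test, "chisq")
  expect_false(out$tests$skipped)
})

test_that("CART separates a planted contrast perfectly", {
  d <- make_grouped_data(n_groups_per_class = 10, shift = 400, seed = 11)
  fit <- cart_train_eval(d, c("volume", "hydro", "noise1", "noise2"),
                         class_col = "promiscuity", group_col = "group",
                         positive = "HP", repeats = 3, seed = 5)
  expect_equal(fit$summary$mean[fit$summary$metric == "sensitivity"], 1)
  expect_equal(fit$summary$mean[fit$summary$metric == "specificity"], 1)
  ## the root split uses the planted descriptor
  expect_equal(as.character(fit$tree$frame$var[1]), "volume")
  ## tidiers
  expect_true(all(c("rep", "fold", "accuracy") %in% names(tidy(fit))))
  expect_equal(nrow(glance(fit)), 1)
})

test_that("constant features are dropped with a warning", {
  d <- make_grouped_data(n_groups_per_class = 8, shift = 400)
  d$const <- 3
  expect_warning(
    fit <- cart_train_eval(d, c("volume", "const"),
                           class_col = "promiscuity", group_col = "group",
                           positive = "HP", repeats = 2, seed = 1),
    "constant")
  expect_false("const" %in% fit$features)
})

test_that("train/test folds never share a group inside CART", {
  ## instrumented check on the same splitting primitives CART uses
  d <- make_grouped_data(n_groups_per_class = 10, shift = 100, seed = 13)
  bal <- balance_classes(d, "promiscuity", "group", seed = 99)
  folds <- cv_split(bal$group, n_folds = 5, seed = 99)
  fold_of <- setNames(folds$fold, folds$group)
  for (f in 1:5) {
    train_g <- unique(bal$group[fold_of[bal$group] != f])
    test_g <- unique(bal$group[fold_of[bal$group] == f])
    expect_length(intersect(train_g, test_g), 0)
  }
})
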