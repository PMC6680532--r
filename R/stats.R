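# Descriptor statistics across promiscuity classes and the grouped,
# balanced, cross-validated CART discrimination of selective vs highly
# promiscuous entities.

#' Compare descriptors across promiscuity classes
#'
#' For every numeric descriptor: one-way ANOVA across the classes plus all
#' pairwise t-tests with a Bonferroni correction whose denominator is the
#' number of descriptors tested in the family (not the number of pairs), so
#' family-wise error is controlled across the descriptor panel. Character or
#' factor descriptors are compared with a chi-squared test. Descriptors with
#' zero within-class variance everywhere are skipped with a reason rather
#' than reported with an undefined statistic.
#'
#' @param data data frame of rows (pockets or ligands) with a class column.
#' @param descriptors descriptor column names to test.
#' @param class_col name of the class column (e.g. promiscuity label).
#' @param bonferroni_n Bonferroni denominator; defaults to
#'   `length(descriptors)`.
#' @param welch use Welch's unequal-variance ANOVA/t-tests instead of the
#'   classic pooled-variance forms.
#' @return list with `tests` (tibble: descriptor, test, statistic, p_value,
#'   p_bonferroni, skipped, reason) and `class_summary` (tibble: descriptor,
#'   class, mean, sd, n).
#' @export
class_comparison <- function(data, descriptors, class_col = "promiscuity",
                             bonferroni_n = length(descriptors),
                             welch = FALSE) {
  cls <- as.character(data[[class_col]])
  classes <- sort(unique(cls))
  if (length(classes) < 2) stop("need >= 2 classes")
  tests <- list(); summaries <- list()
  for (d in descriptors) {
    x <- data[[d]]
    if (is.numeric(x)) {
      summaries[[d]] <- dplyr::summarise(
        dplyr::group_by(tibble::tibble(x = x, class = cls), .data$class),
        mean = mean(.data$x, na.rm = TRUE),
        sd = stats::sd(.data$x, na.rm = TRUE),
        n = sum(!is.na(.data$x)), .groups = "drop")
      summaries[[d]]$descriptor <- d
      wv <- tapply(x, cls, stats::var, na.rm = TRUE)
      if (all(is.na(wv) | wv == 0)) {
        tests[[length(tests) + 1]] <- tibble::tibble(
          descriptor = d, test = "anova", comparison = "all",
          statistic = NA_real_, p_value = NA_real_, p_bonferroni = NA_real_,
          skipped = TRUE, reason = "zero within-class variance")
        next
      }
      av <- stats::oneway.test(x ~ cls, var.equal = !welch)
      tests[[length(tests) + 1]] <- tibble::tibble(
        descriptor = d, test = "anova", comparison = "all",
        statistic = unname(av$statistic), p_value = av$p.value,
        p_bonferroni = min(1, av$p.value * bonferroni_n),
        skipped = FALSE, reason = "")
      for (pair in utils::combn(classes, 2, simplify = FALSE)) {
        xa <- x[cls == pair[1]]; xb <- x[cls == pair[2]]
        if (sum(!is.na(xa)) < 2 || sum(!is.na(xb)) < 2 ||
            (stats::var(xa, na.rm = TRUE) == 0 &&
             stats::var(xb, na.rm = TRUE) == 0)) {
          tests[[length(tests) + 1]] <- tibble::tibble(
            descriptor = d, test = "t",
            comparison = paste(pair, collapse = " vs "),
            statistic = NA_real_, p_value = NA_real_,
            p_bonferroni = NA_real_, skipped = TRUE,
            reason = "insufficient data or zero variance")
          next
        }
        tt <- stats::t.test(xa, xb, var.equal = !welch)
        tests[[length(tests) + 1]] <- tibble::tibble(
          descriptor = d, test = "t",
          comparison = paste(pair, collapse = " vs "),
          statistic = unname(tt$statistic), p_value = tt$p.value,
          p_bonferroni = min(1, tt$p.value * bonferroni_n),
          skipped = FALSE, reason = "")
      }
    } else {
      tab <- table(x, cls)
      if (nrow(tab) < 2) {
        tests[[length(tests) + 1]] <- tibble::tibble(
          descriptor = d, test = "chisq", comparison = "all",
          statistic = NA_real_, p_value = NA_real_, p_bonferroni = NA_real_,
          skipped = TRUE, reason = "single level")
        next
      }
      ch <- suppressWarnings(stats::chisq.test(tab))
      tests[[length(tests) + 1]] <- tibble::tibble(
        descriptor = d, test = "chisq", comparison = "all",
        statistic = unname(ch$statistic), p_value = ch$p.value,
        p_bonferroni = min(1, ch$p.value * bonferroni_n),
        skipped = FALSE, reason = "")
    }
  }
  list(tests = dplyr::bind_rows(tests),
       class_summary = dplyr::bind_rows(summaries))
}

#' Group-aware cross-validation folds
#'
#' Whole groups (e.g. all pockets of one Pocket-Cluster) are assigned to
#' folds, so rows of one group never straddle the train/test boundary; folds
#' are balanced by group count and deterministic under `seed`.
#'
#' @param groups group label per row.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed.
#' @return tibble `group`, `fold`.
#' @export
cv_split <- function(groups, n_folds = 5, seed = 1) {
  g <- sort(unique(as.character(groups)))
  if (length(g) < n_folds) {
    stop("fewer groups (", length(g), ") than folds (", n_folds, ")")
  }
  perm <- with_seed(seed, sample(g))
  tibble::tibble(group = perm,
                 fold = rep_len(seq_len(n_folds), length(perm)))
}

#' Balance two classes by group-level undersampling
#'
#' Randomly drops groups of the majority class until both classes have the
#' same number of groups. Deterministic under `seed`; the retained majority
#' groups are always a subset of the original ones.
#'
#' @param data data frame with class and group columns.
#' @param class_col,group_col column names.
#' @param seed integer seed.
#' @return the balanced data frame (row order: retained groups).
#' @export
balance_classes <- function(data, class_col, group_col, seed = 1) {
  cls_of_group <- dplyr::distinct(data, .data[[class_col]],
                                  .data[[group_col]])
  if (anyDuplicated(cls_of_group[[group_col]])) {
    stop("a group maps to several classes")
  }
  counts <- table(cls_of_group[[class_col]])
  if (length(counts) != 2) stop("need exactly 2 classes")
  if (any(counts == 0)) stop("a class has zero groups")
  n_min <- min(counts)
  keep <- unlist(lapply(names(counts), function(cl) {
    g <- sort(cls_of_group[[group_col]][cls_of_group[[class_col]] == cl])
    if (length(g) > n_min) {
      with_seed(seed + match(cl, names(counts)), sample(g, n_min))
    } else g
  }))
  data[data[[group_col]] %in% keep, ]
}

#' Classification performance metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, standard accuracy
#' `(TP+TN)/total`, and `precision_eq5 = TP/(TP+FP)` (precision; reported
#' alongside because some published "accuracy" figures use this form).
#' Metrics with a zero denominator are `NA`.
#'
#' @param tp,tn,fp,fn confusion counts.
#' @return tibble with the four metrics.
#' @export
performance_metrics <- function(tp, tn, fp, fn) {
  safe_div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  tibble::tibble(
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    accuracy = safe_div(tp + tn, tp + tn + fp + fn),
    precision_eq5 = safe_div(tp, tp + fp)
  )
}

#' Balanced, grouped, cross-validated CART
#'
#' Discriminates two classes (e.g. selective vs highly promiscuous) with a
#' binary classification tree (Gini impurity, cost-complexity pruning at the
#' minimum internal cross-validation error). Every repeat rebalances the
#' classes by group undersampling and redraws group-aware folds; per-fold
#' confusion counts on the held-out groups give the performance
#' distribution. Constant features are dropped with a warning; unsplittable
#' data yields a majority-class stump.
#'
#' @param data data frame with descriptors, a two-level class column and a
#'   group column.
#' @param descriptors feature column names.
#' @param class_col,group_col column names.
#' @param positive class treated as positive (default: last level
#'   alphabetically).
#' @param n_folds folds per repeat (default 5).
#' @param repeats number of balance/split repeats (default 20; published
#'   protocols often use 500).
#' @param seed integer seed.
#' @param minbucket minimum rows per leaf (default 5).
#' @return object of class `promisite_cart`: list with `fold_metrics`
#'   (tibble: repeat, fold + metrics), `summary` (mean and sd per metric),
#'   `tree` (an `rpart` fit on the full balanced data), `positive`.
#' @export
cart_train_eval <- function(data, descriptors, class_col, group_col,
                            positive = NULL, n_folds = 5, repeats = 20,
                            seed = 1, minbucket = 5) {
  cls <- as.character(data[[class_col]])
  lv <- sort(unique(cls))
  if (length(lv) != 2) stop("CART discrimination needs exactly 2 classes")
  if (is.null(positive)) positive <- lv[2]
  stopifnot(positive %in% lv)

  keep <- vapply(descriptors, function(d) {
    x <- data[[d]]
    is.numeric(x) && stats::var(x, na.rm = TRUE) > 0
  }, logical(1))
  if (any(!keep)) {
    warning("dropping constant/non-numeric feature(s): ",
            paste(descriptors[!keep], collapse = ", "))
  }
  feats <- descriptors[keep]
  if (length(feats) == 0) stop("no usable features")

  fit_tree <- function(df) {
    df <- df[, c(feats, ".class")]
    fit <- rpart::rpart(
      .class ~ ., data = df, method = "class",
      control = rpart::rpart.control(minbucket = minbucket, cp = 0.001,
                                     xval = 10))
    cp_tab <- fit$cptable
    best <- cp_tab[which.min(cp_tab[, "xerror"]), "CP"]
    rpart::prune(fit, cp = best)
  }

  d0 <- data
  d0$.class <- factor(cls, levels = c(setdiff(lv, positive), positive))
  fold_metrics <- list()
  for (r in seq_len(repeats)) {
    bal <- balance_classes(d0, class_col, group_col, seed = seed * 1000 + r)
    folds <- cv_split(bal[[group_col]], n_folds = n_folds,
                      seed = seed * 1000 + r)
    fold_of <- stats::setNames(folds$fold, folds$group)
    bal$.fold <- fold_of[as.character(bal[[group_col]])]
    for (f in seq_len(n_folds)) {
      train <- bal[bal$.fold != f, ]
      test <- bal[bal$.fold == f, ]
      if (nrow(test) == 0 || length(unique(train$.class)) < 2) next
      fit <- with_seed(seed * 1000 + r,
                       tryCatch(fit_tree(train), error = function(e) NULL))
      pred <- if (is.null(fit)) {
        ## unsplittable: majority-class stump
        rep(names(which.max(table(train$.class))), nrow(test))
      } else {
        as.character(predict(fit, test, type = "class"))
      }
      truth <- as.character(test$.class)
      tp <- sum(pred == positive & truth == positive)
      tn <- sum(pred != positive & truth != positive)
      fp <- sum(pred == positive & truth != positive)
      fn <- sum(pred != positive & truth == positive)
      fold_metrics[[length(fold_metrics) + 1]] <- dplyr::bind_cols(
        tibble::tibble(rep = r, fold = f, tp = tp, tn = tn, fp = fp,
                       fn = fn),
        performance_metrics(tp, tn, fp, fn))
    }
  }
  fm <- dplyr::bind_rows(fold_metrics)
  metric_cols <- c("sensitivity", "specificity", "accuracy", "precision_eq5")
  summ <- tibble::tibble(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(fm[[m]], na.rm = TRUE),
                  numeric(1), USE.NAMES = FALSE),
    sd = vapply(metric_cols, function(m) stats::sd(fm[[m]], na.rm = TRUE),
                numeric(1), USE.NAMES = FALSE))

  bal_full <- balance_classes(d0, class_col, group_col, seed = seed)
  tree <- with_seed(seed, tryCatch(fit_tree(bal_full),
                                   error = function(e) NULL))
  structure(list(fold_metrics = fm, summary = summ, tree = tree,
                 positive = positive, features = feats),
            class = "promisite_cart")
}

#' @export
print.promisite_cart <- function(x, ...) {
  cat("<promisite_cart> positive class:", x$positive, "\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-14s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-fold CART metrics in tidy form
#' @param x a `promisite_cart`.
#' @param ... unused.
#' @export
tidy.promisite_cart <- function(x, ...) x$fold_metrics

#' One-row CART performance summary
#' @param x a `promisite_cart`.
#' @param ... unused.
#' @export
glance.promisite_cart <- function(x, ...) {
  s <- x$summary
  out <- as.list(c(stats::setNames(s$mean, s$metric),
                   stats::setNames(s$sd, paste0(s$metric, "_sd"))))
  tibble::as_tibble(out)
}

#' Distribution of held-out CART metrics across folds and repeats
#' @param object a `promisite_cart`.
#' @param ... unused.
#' @export
autoplot.promisite_cart <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$fold_metrics,
    cols = c("sensitivity", "specificity", "accuracy"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "held-out value") +
    ggplot2::ylim(0, 1)
}

## run code with a temporary RNG state; restores any prior state after
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
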