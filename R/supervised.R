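#' Configure the Monte-Carlo random-forest runs
#'
#' Hyperparameters of the supervised arm: in each of `n_runs` Monte-Carlo
#' cross-validation runs a random forest of `n_trees` trees (at most
#' `max_nodes` terminal nodes each, `round(0.5 * sqrt(n_features))`
#' candidate features per split) is trained on a stratified `train_fraction`
#' of subjects and evaluated on the held-out remainder.  The defaults are
#' the study conditions: 1000 runs, 1000 trees, 2/3 training fraction,
#' seven-node trees; with 280 features mtry is 8.
#'
#' @param n_runs Number of Monte-Carlo cross-validation runs.
#' @param train_fraction Fraction of each stratum used for training.
#' @param n_trees Trees per forest.
#' @param mtry_factor Multiplier of `sqrt(n_features)` giving the number of
#'   candidate features per split.
#' @param max_nodes Maximum terminal nodes per tree.
#' @param block_mode How the sparse block-diagonal matrix is fed to the
#'   forest: `"sentinel"` (default) trains one forest on all 280 columns
#'   with out-of-block cells encoded as a constant 0 outside the grade
#'   scale, making them uninformative to splits; `"per_set"` trains one
#'   forest per odor set on its own subjects and 70 columns.
#' @param balance `"balanced"` (default) draws the same number of training
#'   subjects -- `round(train_fraction * smallest stratum)` -- from every
#'   diagnosis-by-odor-set stratum, so no set or diagnosis dominates
#'   training and the classifier cannot score subjects by the cohort's
#'   uneven per-set hyposmic prevalence; `"proportional"` samples each
#'   stratum at `train_fraction` of its own size.
#' @param seed Master seed; spawns one sub-seed per run so runs are
#'   reproducible.
#' @return A `run_config` list.
#' @export
run_config <- function(n_runs = 1000L,
                       train_fraction = 2 / 3,
                       n_trees = 1000L,
                       mtry_factor = 0.5,
                       max_nodes = 7L,
                       block_mode = c("sentinel", "per_set"),
                       balance = c("balanced", "proportional"),
                       seed = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly between 0 and 1 (an empty test set is not allowed)",
          class = "odordisc_config_error")
  }
  stopifnot(n_runs >= 1L, n_trees >= 1L, max_nodes >= 2L, mtry_factor > 0)
  structure(
    list(
      n_runs = as.integer(n_runs),
      train_fraction = train_fraction,
      n_trees = as.integer(n_trees),
      mtry_factor = mtry_factor,
      max_nodes = as.integer(max_nodes),
      block_mode = match.arg(block_mode),
      balance = match.arg(balance),
      seed = if (!is.null(seed)) as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Number of candidate features per split
#'
#' @param cfg A [run_config()].
#' @param n_features Number of feature columns.
#' @return `max(1, round(mtry_factor * sqrt(n_features)))`.
#' @export
config_mtry <- function(cfg, n_features) {
  max(1L, as.integer(round(cfg$mtry_factor * sqrt(n_features))))
}

#' Stratified Monte-Carlo train/test split
#'
#' Samples training subjects without replacement within each
#' diagnosis-by-odor-set stratum.  With `balance = "proportional"` (the
#' default of this standalone function), `round(fraction * n)` subjects of
#' each stratum (clamped so that neither side is empty) go to training,
#' preserving every stratum's own proportions.  With
#' `balance = "balanced"` -- what [run_relevance()] uses by default -- the
#' same number of training subjects, `round(fraction * smallest stratum)`,
#' is drawn from every stratum, so unequal stratum sizes (and hence the
#' cohort's uneven per-set diagnosis prevalence) cannot steer the
#' classifier.
#'
#' @param matrix A feature-matrix tibble from [build_feature_matrix()].
#' @param fraction Training fraction in (0, 1).
#' @param balance Stratum sizing rule, see above.
#' @return A list with character vectors `train` and `test` whose union is
#'   all subjects.
#' @export
stratified_split <- function(matrix, fraction = 2 / 3,
                             balance = c("proportional", "balanced")) {
  balance <- match.arg(balance)
  if (fraction <= 0 || fraction >= 1) {
    abort("`fraction` must lie strictly between 0 and 1",
          class = "odordisc_config_error")
  }
  strata <- split(matrix$subject_id,
                  paste(matrix$diagnosis, matrix$odor_set, sep = "/"))
  small <- names(strata)[lengths(strata) < 2L]
  if (length(small)) {
    abort(paste("stratum too small to split (need >= 2 subjects):",
                paste(small, collapse = ", ")),
          class = "odordisc_config_error")
  }
  n_balanced <- max(1L, round(fraction * min(lengths(strata))))
  train <- unlist(lapply(strata, function(ids) {
    n_train <- if (balance == "balanced") n_balanced else
      max(1L, round(fraction * length(ids)))
    sample(ids, min(length(ids) - 1L, n_train))
  }), use.names = FALSE)
  list(train = sort(train),
       test = sort(setdiff(matrix$subject_id, train)))
}

# Encode the block-diagonal feature tibble as a plain numeric matrix.
# Sentinel 0 sits outside the 1..5 grade scale, so splits on out-of-block
# cells separate odor sets, which carry no diagnosis information.
feature_encode <- function(matrix, sentinel = 0) {
  info <- attr(matrix, "feature_info")
  x <- as.matrix(matrix[, info$column])
  rownames(x) <- matrix$subject_id
  x[is.na(x)] <- sentinel
  x
}

relevance_one_run <- function(matrix, info, cfg) {
  split <- stratified_split(matrix, cfg$train_fraction, cfg$balance)
  train <- matrix[matrix$subject_id %in% split$train, ]
  test <- matrix[matrix$subject_id %in% split$test, ]
  y_train <- factor(train$diagnosis, levels = c("normosmic", "hyposmic"))
  y_test <- factor(test$diagnosis, levels = c("normosmic", "hyposmic"))
  p <- nrow(info)

  importance <- numeric(p)
  names(importance) <- info$column
  if (cfg$block_mode == "sentinel") {
    x_train <- feature_encode(train)
    x_test <- feature_encode(test)
    rf <- randomForest::randomForest(
      x_train, y_train, ntree = cfg$n_trees,
      mtry = config_mtry(cfg, p), maxnodes = cfg$max_nodes
    )
    importance[] <- rf$importance[, "MeanDecreaseGini"]
    score <- predict(rf, x_test, type = "prob")[, "hyposmic"]
  } else {
    score <- setNames(numeric(nrow(test)), test$subject_id)
    for (s in unique(info$odor_set)) {
      cols <- info$column[info$odor_set == s]
      tr <- train[train$odor_set == s, ]
      te <- test[test$odor_set == s, ]
      x_tr <- as.matrix(tr[, cols])
      rf <- randomForest::randomForest(
        x_tr, factor(tr$diagnosis, levels = c("normosmic", "hyposmic")),
        ntree = cfg$n_trees, mtry = config_mtry(cfg, length(cols)),
        maxnodes = cfg$max_nodes
      )
      importance[cols] <- rf$importance[, "MeanDecreaseGini"]
      score[te$subject_id] <- predict(rf, as.matrix(te[, cols]),
                                      type = "prob")[, "hyposmic"]
    }
    score <- score[test$subject_id]
  }

  # per-feature Wilcoxon on the training subjects of the feature's own block
  neglogp <- setNames(numeric(p), info$column)
  for (s in unique(info$odor_set)) {
    cols <- info$column[info$odor_set == s]
    tr <- train[train$odor_set == s, ]
    hypo <- tr$diagnosis == "hyposmic"
    for (colname in cols) {
      v <- tr[[colname]]
      if (length(unique(v)) < 2L) {
        neglogp[colname] <- 0  # zero variance: p = 1
        next
      }
      pval <- suppressWarnings(
        wilcox.test(v[hypo], v[!hypo], exact = FALSE, correct = TRUE)$p.value
      )
      neglogp[colname] <- -log(max(pval, .Machine$double.xmin))
    }
  }

  auc <- as.numeric(pROC::auc(
    response = y_test, predictor = score,
    levels = c("normosmic", "hyposmic"), direction = "<", quiet = TRUE
  ))
  list(importance = importance, neglogp = neglogp, auc = auc)
}

#' Monte-Carlo random-forest relevance of odor-property ratings
#'
#' The supervised arm.  Over `cfg$n_runs` stratified Monte-Carlo
#' cross-validation runs it (i) trains a random forest to classify the
#' olfactory diagnosis from the subject-by-rating matrix and records each
#' feature's mean decrease in Gini impurity, (ii) computes per-feature
#' two-sided Wilcoxon-Mann-Whitney tests between diagnoses on the training
#' subjects of the feature's own odor-set block, keeping `-log(p)`, and
#' (iii) scores the held-out subjects by AUC-ROC.  Importance and `-log(p)`
#' are averaged over runs and reshaped to odor-by-property matrices.
#'
#' @param matrix A feature-matrix tibble from [build_feature_matrix()].
#' @param cfg A [run_config()].
#' @param permute_labels If `TRUE`, diagnosis labels are permuted
#'   independently in every run before training -- the negative control,
#'   expected to classify no better than guessing.
#' @param progress Emit a message every 100 runs.
#' @return An object of class `relevance_result`: `relevance` (tibble
#'   odor_set, odor, property, importance_mean, neglogp_mean), `auc`
#'   (tibble run, auc), the config, and `permuted` flag.
#' @export
run_relevance <- function(matrix, cfg = run_config(), permute_labels = FALSE,
                          progress = FALSE) {
  info <- attr(matrix, "feature_info")
  if (is.null(info)) {
    abort("`matrix` must come from build_feature_matrix()",
          class = "odordisc_data_error")
  }
  run_seeds <- spawn_seeds(cfg$seed, cfg$n_runs)
  imp_sum <- nlp_sum <- numeric(nrow(info))
  aucs <- numeric(cfg$n_runs)
  for (r in seq_len(cfg$n_runs)) {
    res <- withr::with_seed(run_seeds[r], {
      m <- matrix
      if (permute_labels) m$diagnosis <- sample(m$diagnosis)
      relevance_one_run(m, info, cfg)
    })
    imp_sum <- imp_sum + res$importance
    nlp_sum <- nlp_sum + res$neglogp
    aucs[r] <- res$auc
    if (progress && r %% 100 == 0) inform(sprintf("run %d/%d", r, cfg$n_runs))
  }
  relevance <- info |>
    mutate(importance_mean = unname(imp_sum) / cfg$n_runs,
           neglogp_mean = unname(nlp_sum) / cfg$n_runs) |>
    select("odor_set", "odor", "property", "importance_mean", "neglogp_mean")
  structure(
    list(relevance = relevance,
         auc = tibble(run = seq_len(cfg$n_runs), auc = aucs),
         config = cfg, permuted = permute_labels),
    class = "relevance_result"
  )
}

#' Permuted-label negative control
#'
#' Re-runs the supervised arm with diagnosis labels shuffled independently
#' before every training run.  If the real analysis were only overfitting,
#' its AUC would look like this control's, which is expected to sit near
#' 0.5 (guessing).
#'
#' @inheritParams run_relevance
#' @return A `relevance_result` with `permuted = TRUE`.
#' @export
permuted_control <- function(matrix, cfg = run_config(), progress = FALSE) {
  run_relevance(matrix, cfg, permute_labels = TRUE, progress = progress)
}

#' @export
print.relevance_result <- function(x, ...) {
  cat(sprintf("<relevance_result>%s %d runs; median held-out AUC %.3f\n",
              if (x$permuted) " [permuted labels]" else "",
              nrow(x$auc), median(x$auc$auc)))
  invisible(x)
}

#' @rdname run_relevance
#' @param x,object A `relevance_result`.
#' @param ... Unused.
#' @method tidy relevance_result
#' @export
tidy.relevance_result <- function(x, ...) x$relevance

#' @rdname run_relevance
#' @method glance relevance_result
#' @export
glance.relevance_result <- function(x, ...) {
  ci <- quantile(x$auc$auc, c(0.025, 0.975), names = FALSE)
  tibble(
    n_runs = nrow(x$auc),
    auc_median = median(x$auc$auc),
    auc_ci95_low = ci[1],
    auc_ci95_high = ci[2],
    permuted = x$permuted
  )
}

#' @rdname run_relevance
#' @method autoplot relevance_result
#' @export
autoplot.relevance_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$property, y = .data$odor,
                               fill = .data$importance_mean)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~odor_set, scales = "free_y") +
    ggplot2::scale_fill_viridis_c(name = "mean Gini\nimportance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Fuse importance and effect size by rank products and select cells
#'
#' Rank-transforms the mean Gini importance and the mean Wilcoxon `-log(p)`
#' matrices (ascending: the largest value gets the largest rank; ties get
#' average ranks) and multiplies them elementwise.  Multiplication of ranks
#' acts as a logical AND: a cell scores high only if it is important to the
#' forest AND shows a large statistical group difference.  Computed ABC
#' analysis of the descending rank products yields set A, the most
#' diagnosis-relevant (odor, property) cells; repeating with inverted ranks
#' yields the least relevant cells.  Cells selected in both directions are
#' dropped from both (with a message).
#'
#' @param rel A `relevance_result`.
#' @return An object of class `selection_result`: `most_relevant` and
#'   `least_relevant` cell tibbles (odor_set, odor, property,
#'   rank_product), the per-direction odor and property occurrence tallies,
#'   and the AUC summary of the underlying runs.
#' @export
rank_product_select <- function(rel) {
  stopifnot(inherits(rel, "relevance_result"))
  cells <- rel$relevance
  if (any(!is.finite(cells$importance_mean)) ||
      any(!is.finite(cells$neglogp_mean))) {
    abort("non-finite relevance entries", class = "odordisc_domain_error")
  }
  rp_most <- rank(cells$importance_mean) * rank(cells$neglogp_mean)
  rp_least <- rank(-cells$importance_mean) * rank(-cells$neglogp_mean)
  label <- paste(cells$odor, cells$property, sep = ".")
  most <- abc_set(abc_partition(rp_most, labels = label), "A", "item")
  least <- abc_set(abc_partition(rp_least, labels = label), "A", "item")
  both <- intersect(most, least)
  if (length(both)) {
    inform(sprintf("%d cell(s) selected in both directions were dropped: %s",
                   length(both), paste(label[both], collapse = ", ")))
    most <- setdiff(most, both)
    least <- setdiff(least, both)
  }
  cell_tbl <- function(idx, rp) {
    cells[idx, c("odor_set", "odor", "property")] |>
      mutate(rank_product = rp[idx]) |>
      arrange(dplyr::desc(.data$rank_product))
  }
  tally <- function(tbl, col) {
    tbl |> count(.data[[col]], sort = TRUE, name = "n_cells")
  }
  most_tbl <- cell_tbl(most, rp_most)
  least_tbl <- cell_tbl(least, rp_least)
  structure(
    list(
      most_relevant = most_tbl,
      least_relevant = least_tbl,
      odor_tally = list(most = tally(most_tbl, "odor"),
                        least = tally(least_tbl, "odor")),
      property_tally = list(most = tally(most_tbl, "property"),
                            least = tally(least_tbl, "property")),
      auc = glance(rel)
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d most- and %d least-relevant cells (%d / %d odors)\n",
              nrow(x$most_relevant), nrow(x$least_relevant),
              nrow(x$odor_tally$most), nrow(x$odor_tally$least)))
  cat(sprintf("  median held-out AUC %.3f [%.3f, %.3f]\n",
              x$auc$auc_median, x$auc$auc_ci95_low, x$auc$auc_ci95_high))
  invisible(x)
}

#' @rdname rank_product_select
#' @param x A `selection_result`.
#' @param ... Unused.
#' @method tidy selection_result
#' @export
tidy.selection_result <- function(x, ...) {
  bind_rows(
    mutate(x$most_relevant, direction = "most_relevant"),
    mutate(x$least_relevant, direction = "least_relevant")
  )
}

spawn_seeds <- function(seed, n) {
  if (is.null(seed)) {
    return(sample.int(.Machine$integer.max, n))
  }
  withr::with_seed(seed, sample.int(.Machine$integer.max, n))
}
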