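# The iterated 1-vs-rest gradient-boosted classification engine.
#
# Per iteration: stratified 70/30 split -> CSS normalization fit separately
# within each split (no leakage of scaling factors) -> restriction to the
# core-union feature universe -> minority up-sampling -> grid-searched
# stochastic gradient boosting (2-fold CV, interaction depth 1-3, 50-150
# trees, learning rate 0.1, minimum 3 observations per node) -> AUROC/AUPR
# on the untouched test split. Iterations differ only in their derived seed.

#' Hyperparameter and protocol settings for the boosted tissue models
#'
#' @param learning_rate boosting shrinkage (eta).
#' @param interaction_depth_grid tree depths searched.
#' @param n_trees_grid boosting-round counts searched.
#' @param min_node_obs minimum observations per terminal node.
#' @param cv_folds cross-validation folds for the grid search (2 for tissue
#'   models; 4 for categorical-trait models; 5 for continuous-trait models).
#' @param train_fraction training share of the stratified split.
#' @param upsample resample the minority class to balance training.
#' @param upsample_within_folds if `TRUE`, up-sample inside each CV training
#'   fold instead of once before CV (the default applies it once to the full
#'   training split).
#' @param subsample row subsample fraction per boosting round (the
#'   "stochastic" in stochastic gradient boosting).
#' @param iterations number of train/test iterations per model.
#' @param master_seed base seed; iteration i uses `master_seed + i`.
#' @return a `model_spec` list.
#' @export
model_spec <- function(learning_rate = 0.1,
                       interaction_depth_grid = 1:3,
                       n_trees_grid = c(50L, 100L, 150L),
                       min_node_obs = 3,
                       cv_folds = 2L,
                       train_fraction = 0.7,
                       upsample = TRUE,
                       upsample_within_folds = FALSE,
                       subsample = 0.5,
                       iterations = 100L,
                       master_seed = 1L) {
  if (length(interaction_depth_grid) == 0L || length(n_trees_grid) == 0L)
    stop_config("interaction_depth_grid/n_trees_grid", "must be non-empty")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_config("train_fraction", "must lie in (0,1)")
  if (cv_folds < 2) stop_config("cv_folds", "must be >= 2")
  if (iterations < 1) stop_config("iterations", "must be >= 1")
  structure(list(learning_rate = learning_rate,
                 interaction_depth_grid = sort(as.integer(interaction_depth_grid)),
                 n_trees_grid = sort(as.integer(n_trees_grid)),
                 min_node_obs = min_node_obs,
                 cv_folds = as.integer(cv_folds),
                 train_fraction = train_fraction,
                 upsample = upsample,
                 upsample_within_folds = upsample_within_folds,
                 subsample = subsample,
                 iterations = as.integer(iterations),
                 master_seed = as.integer(master_seed)),
            class = "model_spec")
}

#' Stratified train/test split
#'
#' Allocates `round(n_class * train_fraction)` members of each class to the
#' training set, the remainder to the test set; the two sets partition the
#' input.
#'
#' @param labels class label per sample (any type coercible to factor).
#' @param train_fraction training share.
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 1L) {
  f <- as.factor(labels)
  if (any(table(f) < 2L))
    stop("every class needs at least 2 members to split", call. = FALSE)
  with_seed(seed, {
    train <- integer(0)
    for (lev in levels(f)) {
      idx <- which(f == lev)
      n_train <- round(length(idx) * train_fraction)
      n_train <- max(1L, min(length(idx) - 1L, n_train))
      train <- c(train, sample(idx, n_train))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Up-sample the minority class to parity
#'
#' The minority class is resampled with replacement until both classes have
#' equal counts; every original index is kept and the majority class is
#' untouched.
#'
#' @param idx integer indices of the training samples.
#' @param labels binary labels aligned with `idx` (i.e. `labels[idx]` is the
#'   training labeling).
#' @param seed RNG seed.
#' @return expanded index multiset.
#' @export
upsample_minority <- function(idx, labels, seed = 1L) {
  y <- as.factor(labels[idx])
  tab <- table(y)
  if (length(tab) != 2L || any(tab == 0L))
    stop("up-sampling requires exactly two non-empty classes", call. = FALSE)
  if (tab[1] == tab[2]) return(idx)
  minority <- names(tab)[which.min(tab)]
  min_idx <- idx[y == minority]
  deficit <- max(tab) - min(tab)
  with_seed(seed, c(idx, sample(min_idx, deficit, replace = TRUE)))
}

# Stratified k-fold assignment (classification) or plain shuffled folds
# (regression).
make_folds <- function(y, k, seed, stratify = TRUE) {
  with_seed(seed, {
    fold <- integer(length(y))
    if (stratify) {
      f <- as.factor(y)
      for (lev in levels(f)) {
        idx <- sample(which(f == lev))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold[sample(seq_along(y))] <- rep_len(seq_len(k), length(y))
    }
    fold
  })
}

xgb_params <- function(spec, depth, task, seed) {
  list(objective = if (task == "classification") "binary:logistic"
       else "reg:squarederror",
       eta = spec$learning_rate,
       max_depth = depth,
       min_child_weight = spec$min_node_obs,
       subsample = spec$subsample,
       colsample_bytree = 1,
       lambda = 0,
       nthread = 1,
       seed = as.integer(seed %% .Machine$integer.max))
}

#' Train a grid-searched gradient-boosted model
#'
#' Cross-validated grid search over interaction depth and number of trees
#' (learning rate and minimum node size held fixed), selecting by mean CV
#' AUROC for classification or lowest CV RMSE for regression; ties prefer
#' the simpler model (smallest depth, then fewest trees). The winning
#' configuration is refit on the full training matrix. Backed by xgboost,
#' whose tree booster implements the stochastic gradient boosting
#' hyperparameters used here (shrinkage, depth, rounds, minimum node size,
#' row subsampling).
#'
#' @param X training matrix, samples x features.
#' @param y binary (0/1 or logical) labels, or numeric response for
#'   `task = "regression"`.
#' @param spec a [model_spec()].
#' @param seed RNG seed controlling folds and the booster's subsampling.
#' @param task `"classification"` or `"regression"`.
#' @return a `boosted_model`: the refit booster plus selected
#'   hyperparameters, CV table, and normalized feature-importance shares
#'   (total split-gain attribution, summing to 1).
#' @export
train_boosted_model <- function(X, y, spec, seed = 1L,
                                task = c("classification", "regression")) {
  task <- match.arg(task)
  if (task == "classification") y <- as.numeric(as.logical(y))
  if (length(unique(y)) < 2L)
    stop("response is constant; cannot train", call. = FALSE)
  if (is.null(colnames(X)))
    stop("X needs feature column names", call. = FALSE)
  k <- spec$cv_folds
  fold <- make_folds(y, k, seed, stratify = task == "classification")
  max_trees <- max(spec$n_trees_grid)

  # one booster per (depth, fold), scored at every tree count on the grid
  cv <- expand.grid(n_trees = spec$n_trees_grid,
                    interaction_depth = spec$interaction_depth_grid)
  cv$score <- NA_real_
  for (d in spec$interaction_depth_grid) {
    fold_scores <- matrix(NA_real_, nrow = k, ncol = length(spec$n_trees_grid))
    for (fi in seq_len(k)) {
      tr <- fold != fi
      ytr <- y[tr]
      if (task == "classification" && length(unique(ytr)) < 2L) next
      if (task == "classification" && spec$upsample_within_folds) {
        up <- upsample_minority(which(tr), y, seed = seed + 131L * fi)
        dtr <- xgboost::xgb.DMatrix(X[up, , drop = FALSE], label = y[up])
      } else {
        dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = ytr)
      }
      booster <- xgboost::xgb.train(
        params = xgb_params(spec, d, task, seed + fi),
        data = dtr, nrounds = max_trees, verbose = 0)
      dte <- xgboost::xgb.DMatrix(X[!tr, , drop = FALSE])
      yte <- y[!tr]
      for (ti in seq_along(spec$n_trees_grid)) {
        p <- predict(booster, dte,
                     iterationrange = c(1, spec$n_trees_grid[ti]))
        fold_scores[fi, ti] <-
          if (task == "classification") {
            if (length(unique(yte)) < 2L) NA_real_ else auroc(p, yte)
          } else {
            sqrt(mean((p - yte)^2))
          }
      }
    }
    cv$score[cv$interaction_depth == d] <- colMeans(fold_scores, na.rm = TRUE)
  }

  # tie-break toward the simpler model: grid is ordered by (depth, trees)
  ord <- order(cv$interaction_depth, cv$n_trees)
  cv <- cv[ord, , drop = FALSE]
  better <- if (task == "classification") `>` else `<`
  best <- NA_integer_
  for (i in seq_len(nrow(cv))) {
    if (is.na(cv$score[i])) next
    if (is.na(best) || better(cv$score[i], cv$score[best])) best <- i
  }
  if (is.na(best)) best <- 1L
  best_depth <- cv$interaction_depth[best]
  best_trees <- cv$n_trees[best]

  dall <- xgboost::xgb.DMatrix(X, label = y)
  booster <- xgboost::xgb.train(
    params = xgb_params(spec, best_depth, task, seed),
    data = dall, nrounds = best_trees, verbose = 0)

  imp <- xgboost::xgb.importance(model = booster)
  shares <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (!is.null(imp) && nrow(imp) > 0)
    shares[imp$Feature] <- imp$Gain / sum(imp$Gain)
  structure(list(booster = booster, task = task,
                 best_interaction_depth = best_depth,
                 best_n_trees = best_trees,
                 cv_results = cv, importance_shares = shares,
                 features = colnames(X), seed = seed),
            class = "boosted_model")
}

#' @export
predict.boosted_model <- function(object, newdata, ...) {
  if (!identical(colnames(newdata), object$features))
    newdata <- t(align_features(t(newdata), object$features)$matrix)
  stats::predict(object$booster, xgboost::xgb.DMatrix(newdata))
}

#' Evaluate a fitted model on a test set
#'
#' @param model a `boosted_model`.
#' @param X_test samples x features test matrix.
#' @param y_test binary test labels (both classes required).
#' @return a [metrics_record()].
#' @export
evaluate <- function(model, X_test, y_test) {
  metrics_record(predict(model, X_test), y_test)
}

# One train/test iteration of the 1-vs-rest pipeline; the workhorse shared
# by the signature, contamination and null experiments. `mutate_nm` lets the
# contamination module modify each split's normalized matrix post-CSS.
run_iteration <- function(counts, labels, feature_universe, spec, seed,
                          quantile = 0.5, scale_constant = 1000,
                          mutate_nm = NULL) {
  sp <- stratified_split(labels, spec$train_fraction, seed)
  nm_train <- css_normalize(counts[, sp$train, drop = FALSE],
                            quantile, scale_constant)
  nm_test <- css_normalize(counts[, sp$test, drop = FALSE],
                           quantile, scale_constant)
  if (!is.null(mutate_nm)) {
    nm_train <- mutate_nm(nm_train, seed)
    nm_test <- mutate_nm(nm_test, seed)
  }
  X_train <- t(align_features(nm_train$values, feature_universe)$matrix)
  X_test <- t(align_features(nm_test$values, feature_universe)$matrix)
  y <- as.numeric(labels)
  train_rows <- seq_len(nrow(X_train))
  if (spec$upsample && !spec$upsample_within_folds)
    train_rows <- upsample_minority(train_rows, y[sp$train], seed = seed)
  model <- train_boosted_model(X_train[train_rows, , drop = FALSE],
                               y[sp$train][train_rows], spec, seed = seed)
  rec <- evaluate(model, X_test, y[sp$test])
  list(model = model, metrics = rec, split = sp)
}

summarize_iterations <- function(iters) {
  data.frame(
    iteration = seq_along(iters),
    seed = vapply(iters, function(x) x$model$seed, numeric(1)),
    auroc = vapply(iters, function(x) x$metrics$auroc, numeric(1)),
    aupr = vapply(iters, function(x) x$metrics$aupr, numeric(1)),
    aupr_random = vapply(iters, function(x) x$metrics$aupr_random, numeric(1)),
    relative_aupr = vapply(iters, function(x) x$metrics$relative_aupr, numeric(1)),
    best_interaction_depth = vapply(iters, function(x)
      x$model$best_interaction_depth, numeric(1)),
    best_n_trees = vapply(iters, function(x) x$model$best_n_trees, numeric(1)))
}

#' Run the iterated 1-vs-rest signature experiment for one tissue
#'
#' Repeats the full split / per-split CSS normalization / core-feature
#' restriction / up-sampled grid-searched boosting / test evaluation loop
#' `spec$iterations` times with derived seeds, and aggregates mean AUROC,
#' AUPR and relative AUPR with normal-approximation 95% CI margins.
#' Feature-importance shares are taken from the first iteration's model
#' (the convention used for reporting signature features); the mean share
#' across iterations is also returned.
#'
#' @param counts raw count matrix (all features; normalization precedes the
#'   feature restriction).
#' @param metadata sample metadata aligned with `counts` columns.
#' @param target_tissue the positive-class tissue label.
#' @param feature_universe character vector of model features (typically the
#'   core-microbiome union from [core_union_and_intersections()]).
#' @param spec a [model_spec()].
#' @param quantile,scale_constant CSS parameters.
#' @param store_models keep each iteration's fitted model (needed for
#'   [transfer_test()]).
#' @return a `signature_result`.
#' @export
run_signature_experiment <- function(counts, metadata, target_tissue,
                                     feature_universe, spec = model_spec(),
                                     quantile = 0.5, scale_constant = 1000,
                                     store_models = FALSE) {
  validate_metadata(metadata, counts)
  if (!target_tissue %in% metadata$tissue)
    stop("unknown tissue: ", target_tissue, call. = FALSE)
  labels <- metadata$tissue == target_tissue
  iters <- lapply(seq_len(spec$iterations), function(i)
    run_iteration(counts, labels, feature_universe, spec,
                  seed = spec$master_seed + i,
                  quantile = quantile, scale_constant = scale_constant))
  tab <- summarize_iterations(iters)
  imp_mat <- vapply(iters, function(x) x$model$importance_shares,
                    numeric(length(feature_universe)))
  res <- list(tissue = target_tissue,
              iterations = tab,
              mean_auroc = mean(tab$auroc),
              mean_aupr = mean(tab$aupr),
              mean_relative_aupr = mean(tab$relative_aupr),
              ci_margin = list(auroc = ci_margin(tab$auroc),
                               aupr = ci_margin(tab$aupr),
                               relative_aupr = ci_margin(tab$relative_aupr)),
              importance_shares = iters[[1]]$model$importance_shares,
              mean_importance_shares = rowMeans(imp_mat),
              feature_universe = feature_universe,
              quantile = quantile, scale_constant = scale_constant,
              spec = spec)
  if (store_models) res$models <- lapply(iters, `[[`, "model")
  class(res) <- "signature_result"
  res
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("1-vs-rest signature model for %s (%d iterations)\n",
              x$tissue, nrow(x$iterations)))
  cat(sprintf("  mean AUROC %.3f +/- %.3f | mean relative AUPR %.2f +/- %.2f\n",
              x$mean_auroc, x$ci_margin$auroc,
              x$mean_relative_aupr, x$ci_margin$relative_aupr))
  invisible(x)
}

#' Signature verdict for a tissue model
#'
#' A tissue is called signature-positive when mean AUROC >= `auroc_min` and
#' mean relative AUPR >= `rel_aupr_min`, both boundaries inclusive.
#'
#' @param result a `signature_result` (or any list with `mean_auroc` and
#'   `mean_relative_aupr`).
#' @param auroc_min,rel_aupr_min detection thresholds.
#' @return logical verdict.
#' @export
signature_verdict <- function(result, auroc_min = 0.70, rel_aupr_min = 1.4) {
  result$mean_auroc >= auroc_min && result$mean_relative_aupr >= rel_aupr_min
}

#' Spearman rank correlation between per-tissue sample sizes and performance
#'
#' Used to check that signature detection is not driven by tissue sample
#' size.
#'
#' @param sample_sizes per-tissue sample counts.
#' @param performances per-tissue mean metric values.
#' @return list with `rho` and two-sided `p`.
#' @export
rank_correlation <- function(sample_sizes, performances) {
  if (length(sample_sizes) < 3L)
    stop("need at least 3 tissues", call. = FALSE)
  if (stats::sd(sample_sizes) == 0 || stats::sd(performances) == 0) {
    warning("constant input; rank correlation undefined", call. = FALSE)
    return(list(rho = NaN, p = NaN))
  }
  ct <- suppressWarnings(
    stats::cor.test(sample_sizes, performances, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Trait and disease-history models within one tissue
#'
#' Trains boosted models to predict a metadata trait from the microbial
#' profile of a single tissue. Continuous traits (e.g. age, BMI) use
#' regression with 5-fold CV grid search and report mean RMSE, MAE and
#' R-squared over iterations; categorical traits and disease flags use
#' classification with 4-fold CV and report mean AUROC/AUPR. Ancestry-like
#' multi-level traits are restricted to their two largest categories. Any
#' group with fewer than `min_group` samples makes the tissue/trait
#' combination ineligible: a skipped record is returned and no model is
#' trained (for continuous traits the rule applies to the tissue's total
#' sample count).
#'
#' @param counts raw count matrix.
#' @param metadata sample metadata aligned with `counts`.
#' @param tissue tissue whose samples are modeled.
#' @param trait metadata column to predict.
#' @param feature_universe model features (default: the tissue's own
#'   features, i.e. all rows).
#' @param spec a [model_spec()]; its `cv_folds` is overridden to 5
#'   (continuous) or 4 (categorical) unless `override_cv_folds = FALSE`.
#' @param min_group minimum group size.
#' @param quantile,scale_constant CSS parameters.
#' @param override_cv_folds see `spec`.
#' @return a `trait_result` list; `status` is `"ok"` or `"skipped"`.
#' @export
trait_experiment <- function(counts, metadata, tissue, trait,
                             feature_universe = rownames(counts),
                             spec = model_spec(), min_group = 20,
                             quantile = 0.5, scale_constant = 1000,
                             override_cv_folds = TRUE) {
  validate_metadata(metadata, counts)
  if (!trait %in% names(metadata))
    stop("unknown trait: ", trait, call. = FALSE)
  if (!tissue %in% metadata$tissue)
    stop("unknown tissue: ", tissue, call. = FALSE)
  keep <- metadata$tissue == tissue
  meta_t <- metadata[keep, , drop = FALSE]
  counts_t <- counts[, keep, drop = FALSE]
  val <- meta_t[[trait]]
  continuous <- is.numeric(val) && length(unique(val)) > 5L

  skipped <- function(reason, sizes = NULL)
    structure(list(status = "skipped", tissue = tissue, trait = trait,
                   reason = reason, group_sizes = sizes),
              class = "trait_result")

  if (continuous) {
    if (nrow(meta_t) < min_group)
      return(skipped("insufficient samples", nrow(meta_t)))
    spec2 <- spec
    if (override_cv_folds) spec2$cv_folds <- 5L
    rmse <- mae <- r2 <- numeric(spec2$iterations)
    for (i in seq_len(spec2$iterations)) {
      seed <- spec2$master_seed + i
      n <- nrow(meta_t)
      tr <- with_seed(seed, sort(sample(n, round(spec2$train_fraction * n))))
      te <- setdiff(seq_len(n), tr)
      nm_tr <- css_normalize(counts_t[, tr, drop = FALSE], quantile, scale_constant)
      nm_te <- css_normalize(counts_t[, te, drop = FALSE], quantile, scale_constant)
      X_tr <- t(align_features(nm_tr$values, feature_universe)$matrix)
      X_te <- t(align_features(nm_te$values, feature_universe)$matrix)
      fit <- train_boosted_model(X_tr, val[tr], spec2, seed = seed,
                                 task = "regression")
      p <- predict(fit, X_te)
      rmse[i] <- sqrt(mean((p - val[te])^2))
      mae[i] <- mean(abs(p - val[te]))
      r2[i] <- if (stats::sd(p) == 0) 0 else stats::cor(p, val[te])^2
    }
    return(structure(list(status = "ok", tissue = tissue, trait = trait,
                          type = "continuous", n = nrow(meta_t),
                          mean_rmse = mean(rmse), mean_mae = mean(mae),
                          mean_r2 = mean(r2),
                          iterations = data.frame(rmse = rmse, mae = mae,
                                                  r2 = r2)),
                     class = "trait_result"))
  }

  # categorical: keep the two largest categories
  tab <- sort(table(as.character(val)), decreasing = TRUE)
  if (length(tab) < 2L)
    return(skipped("trait has a single category", tab))
  lv <- names(tab)[1:2]
  sizes <- tab[1:2]
  if (any(sizes < min_group))
    return(skipped("insufficient samples", sizes))
  keep2 <- as.character(val) %in% lv
  meta_2 <- meta_t[keep2, , drop = FALSE]
  counts_2 <- counts_t[, keep2, drop = FALSE]
  labels <- as.character(meta_2[[trait]]) == names(tab)[2]  # minority positive
  spec2 <- spec
  if (override_cv_folds) spec2$cv_folds <- 4L
  iters <- lapply(seq_len(spec2$iterations), function(i)
    run_iteration(counts_2, labels, feature_universe, spec2,
                  seed = spec2$master_seed + i,
                  quantile = quantile, scale_constant = scale_constant))
  it <- summarize_iterations(iters)
  structure(list(status = "ok", tissue = tissue, trait = trait,
                 type = "categorical", groups = lv,
                 group_sizes = as.integer(sizes),
                 mean_auroc = mean(it$auroc), mean_aupr = mean(it$aupr),
                 mean_relative_aupr = mean(it$relative_aupr),
                 iterations = it),
            class = "trait_result")
}
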