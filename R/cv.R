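## Component standardization, SVM training and the repeated stratified
## two-fold cross-validation protocol.

#' Standardize a component vector to zero mean and unit variance
#'
#' Standardization is applied across the features of each extracted component
#' (i.e. per sample/component, not per feature), using the population
#' standard deviation. A constant vector standardizes to the zero vector with
#' a warning.
#'
#' @param v numeric vector, length >= 2.
#' @return Standardized vector of the same length.
#' @export
standardize_component <- function(v) {
  if (length(v) < 2L) stop("standardize_component: need length >= 2")
  mu <- mean(v)
  s <- sqrt(mean((v - mu)^2))
  if (s == 0) {
    warning("standardize_component: constant vector; returning zeros")
    return(rep(0, length(v)))
  }
  (v - mu) / s
}

standardize_rows <- function(mat) {
  mu <- rowMeans(mat)
  centred <- mat - mu
  s <- sqrt(rowMeans(centred^2))
  s[s == 0] <- Inf                      # constant rows become zero rows
  centred / s
}

#' Sensitivity, specificity and accuracy from labelled predictions
#'
#' Sensitivity is the true-positive rate on the disease class (y = 1),
#' specificity the true-negative rate on the control class (y = -1).
#'
#' @param y_true,y_pred numeric vectors with values in \{1, -1\}; `y_true`
#'   must contain both classes.
#' @return Named numeric vector `(sensitivity, specificity, accuracy)`.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred),
            all(y_true %in% c(1, -1)), all(y_pred %in% c(1, -1)))
  if (length(unique(y_true)) < 2L)
    stop("confusion_metrics: y_true contains a single class")
  tp <- sum(y_true == 1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == -1)
  tn <- sum(y_true == -1 & y_pred == -1)
  fp <- sum(y_true == -1 & y_pred == 1)
  c(sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(y_true))
}

#' Hyper-parameter grid for the repeated two-fold cross-validation
#'
#' Defaults are the cross-validated grids of the protocol: M in \{2..5\},
#' delta_theta in \{1, 3, 5\} degrees, lambda in \{1e-2, 1e-4, 1e-6\} times
#' lambda_max, SVM cost fixed at C = 1 with only kernel hyper-parameters
#' searched (RBF variance grid 500..1500 by 100; polynomial degree 2-4).
#'
#' @param M_values subset of 2:5.
#' @param delta_theta_values subset of c(1, 3, 5) (degrees).
#' @param lambda_multipliers subset of c(1e-2, 1e-4, 1e-6).
#' @param kernels subset of c("linear", "rbf", "polynomial").
#' @param rbf_sigma2 RBF kernel variance grid (gamma = 1 / (2 sigma^2)).
#' @param poly_degree polynomial degree grid.
#' @param n_repetitions number of independent two-fold cross-validations.
#' @param mode `"nested"` selects the configuration by an inner two-fold
#'   split on each training half; `"sweep"` evaluates every configuration on
#'   every fold and reports the best cell.
#' @return An object of class `cv_grid`.
#' @export
cv_grid <- function(M_values = 2:5, delta_theta_values = c(1, 3, 5),
                    lambda_multipliers = c(1e-2, 1e-4, 1e-6),
                    kernels = "linear",
                    rbf_sigma2 = seq(500, 1500, by = 100),
                    poly_degree = 2:4,
                    n_repetitions = 100L,
                    mode = c("nested", "sweep")) {
  mode <- match.arg(mode)
  stopifnot(length(M_values) >= 1L, all(M_values %in% 2:5),
            length(delta_theta_values) >= 1L,
            length(lambda_multipliers) >= 1L,
            all(lambda_multipliers > 0 & lambda_multipliers <= 1),
            all(kernels %in% c("linear", "rbf", "polynomial")),
            n_repetitions >= 1L)
  structure(list(M_values = as.integer(M_values),
                 delta_theta_values = delta_theta_values,
                 lambda_multipliers = lambda_multipliers,
                 kernels = kernels, rbf_sigma2 = rbf_sigma2,
                 poly_degree = as.integer(poly_degree),
                 n_repetitions = as.integer(n_repetitions),
                 mode = mode),
            class = "cv_grid")
}

classifier_configs <- function(grid) {
  out <- list()
  for (k in grid$kernels) {
    if (k == "linear") {
      out[[length(out) + 1L]] <- list(kernel = "linear", param = NA_real_)
    } else if (k == "rbf") {
      for (s2 in grid$rbf_sigma2)
        out[[length(out) + 1L]] <- list(kernel = "rbf", param = s2)
    } else {
      for (d in grid$poly_degree)
        out[[length(out) + 1L]] <- list(kernel = "polynomial", param = d)
    }
  }
  out
}

svm_fit <- function(x, y, clf) {
  args <- list(x = x, y = factor(y, levels = c(-1, 1)), scale = FALSE,
               cost = 1, type = "C-classification")
  if (clf$kernel == "linear") {
    args$kernel <- "linear"
  } else if (clf$kernel == "rbf") {
    args$kernel <- "radial"
    args$gamma <- 1 / (2 * clf$param)
  } else {
    args$kernel <- "polynomial"
    args$degree <- clf$param
    args$gamma <- 1
    args$coef0 <- 1
  }
  do.call(e1071::svm, args)
}

svm_predict <- function(model, x) {
  as.numeric(as.character(predict(model, x)))
}

#' Stratified 50/50 fold assignment
#'
#' Each class is shuffled and split as evenly as possible between two folds,
#' so the class ratio of either fold deviates from the dataset's by at most
#' one sample.
#'
#' @param labels vector in \{1, -1\}.
#' @return Integer vector of fold memberships (1 or 2).
#' @export
stratified_twofold <- function(labels) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    half <- ceiling(length(idx) / 2)
    fold[idx[seq_len(half)]] <- 1L
    fold[idx[-seq_len(half)]] <- 2L
  }
  fold
}

## Evaluate every (classifier, component-set) cell on one train/test split
## of pre-standardized component sets. Returns a data.frame of metrics.
eval_cells <- function(std_sets, labels, train_idx, test_idx, clfs) {
  rows <- list()
  for (set_name in names(std_sets)) {
    xtr <- std_sets[[set_name]][train_idx, , drop = FALSE]
    xte <- std_sets[[set_name]][test_idx, , drop = FALSE]
    for (ci in seq_along(clfs)) {
      model <- svm_fit(xtr, labels[train_idx], clfs[[ci]])
      m <- confusion_metrics(labels[test_idx], svm_predict(model, xte))
      rows[[length(rows) + 1L]] <-
        data.frame(set = set_name, kernel = clfs[[ci]]$kernel,
                   kernel_param = clfs[[ci]]$param,
                   sensitivity = m[["sensitivity"]],
                   specificity = m[["specificity"]],
                   accuracy = m[["accuracy"]])
    }
  }
  do.call(rbind, rows)
}

extract_std_sets <- function(dataset, M, dtheta, lambda, nonneg,
                             reference_policy, train_ids, max_scps) {
  solver <- solver_config(lambda_multiplier = lambda, nonnegative = nonneg)
  cs <- extract_feature_sets(dataset, M = M, delta_theta = dtheta,
                             solver = solver,
                             reference_policy = reference_policy,
                             train_ids = train_ids, max_scps = max_scps)
  lapply(cs$sets, standardize_rows)
}

#' Repeated stratified two-fold cross-validation of the full pipeline
#'
#' For each repetition the dataset is split 50/50 with stratification; each
#' half serves once as training and once as test set. In `"nested"` mode an
#' inner two-fold split of the training half selects the configuration
#' (M, delta_theta, lambda multiplier, classifier, component set) with the
#' highest inner accuracy; the winning pipeline is refit on the whole
#' training half (references rebuilt under the reference policy) and
#' evaluated on the held-out half. In `"sweep"` mode every configuration is
#' evaluated on every fold and the best cell is reported. Sensitivity,
#' specificity and accuracy are summarized by their mean and standard
#' deviation over all 2 x n_repetitions evaluations.
#'
#' @param dataset an [expression_dataset()].
#' @param grid a [cv_grid()].
#' @param nonnegative impose S >= 0 in the decompositions (gene-expression
#'   modality).
#' @param reference_policy `"train_only"` (default; leakage-free) or `"all"`.
#' @param seed integer seed; the repetition streams are derived from it so
#'   identical seeds give identical reports.
#' @param max_scps cap on clustered SCP vectors per decomposition.
#' @return An object of class `cv_report` with mean/sd sensitivity,
#'   specificity and accuracy, `n_repetitions`, `winning_config`,
#'   `per_evaluation` (a data.frame of every outer evaluation) and, in sweep
#'   mode, `grid_table`.
#' @export
repeated_two_fold_cv <- function(dataset, grid = cv_grid(),
                                 nonnegative = FALSE,
                                 reference_policy = c("train_only", "all"),
                                 seed = NULL, max_scps = 500L) {
  stopifnot(inherits(dataset, "expression_dataset"), inherits(grid, "cv_grid"))
  reference_policy <- match.arg(reference_policy)
  labels <- dataset$labels
  if (sum(labels == 1) < 2L || sum(labels == -1) < 2L)
    stop("repeated_two_fold_cv: both classes need at least 2 samples")
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, grid$n_repetitions)
  clfs <- classifier_configs(grid)
  ext_grid <- expand.grid(M = grid$M_values,
                          delta_theta = grid$delta_theta_values,
                          lambda = grid$lambda_multipliers,
                          KEEP.OUT.ATTRS = FALSE)
  evaluations <- list()
  winners <- list()

  for (r in seq_len(grid$n_repetitions)) {
    set.seed(rep_seeds[r])
    fold <- stratified_twofold(labels)
    for (test_fold in 1:2) {
      train_idx <- which(fold != test_fold)
      test_idx <- which(fold == test_fold)
      train_ids <- dataset$sample_ids[train_idx]

      if (grid$mode == "nested") {
        if (min(table(labels[train_idx])) < 2L)
          stop("repeated_two_fold_cv: inner split impossible ",
               "(a class has a single training sample)")
        inner_fold <- stratified_twofold(labels[train_idx])
        best <- NULL
        for (g in seq_len(nrow(ext_grid))) {
          inner_acc <- NULL
          for (inner_test in 1:2) {
            it <- train_idx[inner_fold != inner_test]
            ie <- train_idx[inner_fold == inner_test]
            sub <- subset_dataset(dataset, c(it, ie))
            n_it <- length(it)
            std <- extract_std_sets(sub, ext_grid$M[g],
                                    ext_grid$delta_theta[g],
                                    ext_grid$lambda[g], nonnegative,
                                    reference_policy,
                                    dataset$sample_ids[it], max_scps)
            cells <- eval_cells(std, sub$labels, seq_len(n_it),
                                n_it + seq_along(ie), clfs)
            inner_acc <- if (is.null(inner_acc)) cells$accuracy
                         else inner_acc + cells$accuracy
          }
          cells$inner_accuracy <- inner_acc / 2
          cells$g <- g
          best <- if (is.null(best)) cells else rbind(best, cells)
        }
        w <- best[which.max(best$inner_accuracy), ]
        winner_clf <- Filter(function(cf) cf$kernel == w$kernel &&
                               (is.na(w$kernel_param) || cf$param == w$kernel_param),
                             clfs)[[1L]]
        std <- extract_std_sets(dataset, ext_grid$M[w$g],
                                ext_grid$delta_theta[w$g],
                                ext_grid$lambda[w$g], nonnegative,
                                reference_policy, train_ids, max_scps)
        cell <- eval_cells(std[w$set], labels, train_idx, test_idx,
                           list(winner_clf))
        cell$M <- ext_grid$M[w$g]
        cell$delta_theta <- ext_grid$delta_theta[w$g]
        cell$lambda <- ext_grid$lambda[w$g]
        cell$repetition <- r
        cell$fold <- test_fold
        evaluations[[length(evaluations) + 1L]] <- cell
        winners[[length(winners) + 1L]] <-
          paste(ext_grid$M[w$g], ext_grid$delta_theta[w$g],
                ext_grid$lambda[w$g], w$kernel, w$kernel_param, w$set,
                sep = "|")
      } else {                         # sweep: evaluate every cell
        for (g in seq_len(nrow(ext_grid))) {
          std <- extract_std_sets(dataset, ext_grid$M[g],
                                  ext_grid$delta_theta[g],
                                  ext_grid$lambda[g], nonnegative,
                                  reference_policy, train_ids, max_scps)
          cells <- eval_cells(std, labels, train_idx, test_idx, clfs)
          cells$M <- ext_grid$M[g]
          cells$delta_theta <- ext_grid$delta_theta[g]
          cells$lambda <- ext_grid$lambda[g]
          cells$repetition <- r
          cells$fold <- test_fold
          evaluations[[length(evaluations) + 1L]] <- cells
        }
      }
    }
  }

  per_eval <- do.call(rbind, evaluations)
  rownames(per_eval) <- NULL

  if (grid$mode == "sweep") {
    tab <- grid_report_table(per_eval)
    wrow <- tab[which.max(tab$mean_accuracy), ]
    sel <- per_eval$M == wrow$M & per_eval$delta_theta == wrow$delta_theta &
      per_eval$lambda == wrow$lambda & per_eval$kernel == wrow$kernel &
      per_eval$set == wrow$set &
      (is.na(wrow$kernel_param) | per_eval$kernel_param %in% wrow$kernel_param)
    chosen <- per_eval[sel, ]
    winning <- list(M = wrow$M, delta_theta = wrow$delta_theta,
                    lambda_multiplier = wrow$lambda, kernel = wrow$kernel,
                    kernel_param = wrow$kernel_param, component_set = wrow$set)
  } else {
    tab <- NULL
    chosen <- per_eval
    mode_w <- names(sort(table(unlist(winners)), decreasing = TRUE))[1L]
    parts <- strsplit(mode_w, "|", fixed = TRUE)[[1L]]
    winning <- list(M = as.integer(parts[1L]),
                    delta_theta = as.numeric(parts[2L]),
                    lambda_multiplier = as.numeric(parts[3L]),
                    kernel = parts[4L],
                    kernel_param = suppressWarnings(as.numeric(parts[5L])),
                    component_set = parts[6L])
  }

  structure(list(mean_sensitivity = mean(chosen$sensitivity),
                 sd_sensitivity = sd(chosen$sensitivity),
                 mean_specificity = mean(chosen$specificity),
                 sd_specificity = sd(chosen$specificity),
                 mean_accuracy = mean(chosen$accuracy),
                 sd_accuracy = sd(chosen$accuracy),
                 n_repetitions = grid$n_repetitions,
                 mode = grid$mode,
                 winning_config = winning,
                 per_evaluation = per_eval,
                 grid_table = tab),
            class = "cv_report")
}

grid_report_table <- function(per_eval) {
  key <- paste(per_eval$M, per_eval$delta_theta, per_eval$lambda,
               per_eval$kernel,
               ifelse(is.na(per_eval$kernel_param), "none", per_eval$kernel_param),
               per_eval$set, sep = "|")
  agg <- lapply(split(per_eval, key), function(d)
    data.frame(M = d$M[1L], delta_theta = d$delta_theta[1L],
               lambda = d$lambda[1L], kernel = d$kernel[1L],
               kernel_param = d$kernel_param[1L], set = d$set[1L],
               mean_sensitivity = mean(d$sensitivity),
               sd_sensitivity = sd(d$sensitivity),
               mean_specificity = mean(d$specificity),
               sd_specificity = sd(d$specificity),
               mean_accuracy = mean(d$accuracy),
               sd_accuracy = sd(d$accuracy)))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(-out$mean_accuracy), ]
}

#' Per-configuration performance table
#'
#' Aggregates a cross-validation report into one row of mean/sd sensitivity,
#' specificity and accuracy per (M, delta_theta, lambda, kernel, component
#' set) cell — the analogue of a full parameter-sweep supplementary table.
#'
#' @param report a `cv_report` from [repeated_two_fold_cv()].
#' @return A data.frame sorted by decreasing mean accuracy.
#' @export
grid_report <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  grid_report_table(report$per_evaluation)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Repeated two-fold cross-validation (%d repetitions, %s mode)\n",
              x$n_repetitions, x$mode))
  cat(sprintf("  sensitivity: %.1f%% (sd %.1f%%)\n",
              100 * x$mean_sensitivity, 100 * x$sd_sensitivity))
  cat(sprintf("  specificity: %.1f%% (sd %.1f%%)\n",
              100 * x$mean_specificity, 100 * x$sd_specificity))
  cat(sprintf("  accuracy:    %.1f%%\n", 100 * x$mean_accuracy))
  w <- x$winning_config
  cat(sprintf("  winning configuration: M = %s, delta_theta = %s deg, lambda = %s * lambda_max,\n    %s kernel%s, component set %s\n",
              w$M, w$delta_theta, w$lambda_multiplier, w$kernel,
              if (is.na(w$kernel_param)) "" else paste0(" (", w$kernel_param, ")"),
              w$component_set))
  invisible(x)
}
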