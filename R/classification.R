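#' Default SVM configuration
#'
#' A radial-basis LIBSVM C-classifier with `C = 1` and
#' `gamma = 1 / n_features` on per-fold standardized inputs.  Fixed defaults
#' keep every subset evaluation comparable and the whole search
#' reproducible; no per-subset tuning is attempted.
#'
#' @param kernel,cost,gamma,degree,coef0 passed through to [e1071::svm()];
#'   `gamma = NULL` means `1 / n_features`.
#' @return list of class `svm_config`.
#' @export
svm_defaults <- function(kernel = "radial", cost = 1, gamma = NULL,
                         degree = 3, coef0 = 0) {
  structure(list(kernel = kernel, cost = cost, gamma = gamma,
                 degree = degree, coef0 = coef0),
            class = "svm_config")
}

#' MANOVA gate for class separability
#'
#' Reports the Wilks'-lambda MANOVA p-value for species differences on the
#' chosen feature columns.  The gate is informational: a non-significant
#' result raises a warning but never blocks the pipeline.  If the
#' within-class covariance is singular, the Wilks statistic is recomputed
#' with a small ridge (1e-8) on the pooled within-class SSCP diagonal,
#' using Rao's F approximation.
#'
#' @param table feature table with a `species` column.
#' @param columns feature columns to test.
#' @return the p-value (numeric scalar).
#' @export
manova_gate <- function(table, columns) {
  check_feature_columns(table, columns)
  g <- factor(table$species)
  k <- nlevels(g)
  if (k < 2L) stop("MANOVA needs at least 2 classes")
  n <- nrow(table)
  if (n <= length(columns) + k) {
    stop("MANOVA needs n > n_columns + n_classes")
  }
  Y <- as.matrix(table[columns])
  # a column with (near-)zero pooled within-class variance makes the raw
  # within SSCP singular; go straight to the ridge-regularized statistic
  wvar <- vapply(seq_len(ncol(Y)), function(j) {
    sum(tapply(Y[, j], g, function(x) sum((x - mean(x))^2))) / (n - k)
  }, 0)
  singularish <- any(wvar <= 1e-10 * max(wvar, 1e-300))
  p <- if (singularish) {
    warning("within-class covariance is singular; ",
            "using the ridge-regularized Wilks statistic", call. = FALSE)
    wilks_ridge_p(Y, g, ridge = 1e-8)
  } else {
    tryCatch({
      fit <- stats::manova(Y ~ g)
      s <- summary(fit, test = "Wilks")$stats
      pv <- s[1, "Pr(>F)"]
      if (!is.finite(pv)) stop("non-finite p")
      pv
    }, error = function(e) {
      warning("MANOVA failed on the raw SSCP (", conditionMessage(e),
              "); retrying with ridge-regularized Wilks statistic",
              call. = FALSE)
      wilks_ridge_p(Y, g, ridge = 1e-8)
    })
  }
  if (p >= 0.05) {
    warning(sprintf(
      "MANOVA gate: classes are not significantly separated (p = %.3g)", p),
      call. = FALSE)
  }
  p
}

# Wilks' lambda with ridge-regularized within SSCP and Rao's F approximation
wilks_ridge_p <- function(Y, g, ridge = 1e-8) {
  n <- nrow(Y); p <- ncol(Y); k <- nlevels(g)
  grand <- colMeans(Y)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (lev in levels(g)) {
    Yi <- Y[g == lev, , drop = FALSE]
    mi <- colMeans(Yi)
    ci <- sweep(Yi, 2, mi)
    W <- W + crossprod(ci)
    B <- B + nrow(Yi) * tcrossprod(mi - grand)
  }
  W <- W + diag(ridge, p)
  lambda <- det(W) / det(W + B)
  q <- k - 1
  t <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  df1 <- p * q
  df2 <- (n - 1 - (p + q + 1) / 2) * t - (p * q - 2) / 2
  Fstat <- (1 - lambda^(1 / t)) / lambda^(1 / t) * df2 / df1
  stats::pf(Fstat, df1, df2, lower.tail = FALSE)
}

#' Cohen's kappa from a confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = trace / n` and chance agreement
#' `p_e = sum_k row_k * col_k / n^2`.  Returns 1 for the degenerate
#' `p_e = 1` case (which implies perfect agreement).
#'
#' @param confusion square nonnegative matrix, true classes in rows,
#'   predicted in columns.
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(confusion) {
  m <- as.matrix(confusion)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  if (any(m < 0)) stop("confusion matrix entries must be nonnegative")
  n <- sum(m)
  if (n <= 0) stop("confusion matrix total must be positive")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - pe) < 1e-15) return(1)
  (po - pe) / (1 - pe)
}

#' Leave-one-out cross-validated SVM species classification
#'
#' For every tree, the feature columns are z-score standardized using the
#' statistics of the other `n - 1` trees only (no leakage), a LIBSVM
#' classifier is trained on those trees and the held-out tree is predicted.
#' The procedure is deterministic for a fixed configuration and invariant
#' to the row order of the table (training rows are sorted by `tree_id`
#' internally).
#'
#' @param table feature table with `tree_id`, `species` and feature columns.
#' @param columns feature columns to use.
#' @param svm_config an [svm_defaults()] list.
#' @return object of class `classification_report`: list with `confusion`
#'   (true x predicted), `recall`, `precision`, `accuracy`, `kappa`,
#'   `predictions` (named by `tree_id`, in the input row order), `columns`,
#'   `svm_config`, `n`.
#' @export
loocv_svm <- function(table, columns, svm_config = svm_defaults()) {
  check_feature_columns(table, columns)
  if (anyNA(table$species)) stop("supervised LOOCV needs species labels for every tree")
  classes <- sort(unique(as.character(table$species)))
  if (length(classes) < 2L) stop("LOOCV needs at least 2 classes")
  sizes <- table(table$species)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    stop("class with a single member cannot be cross-validated: ",
         paste(small, collapse = ", "))
  }
  gamma <- if (is.null(svm_config$gamma)) 1 / length(columns) else svm_config$gamma

  ord <- order(table$tree_id)
  tab <- table[ord, , drop = FALSE]
  X <- as.matrix(tab[columns])
  y <- factor(as.character(tab$species), levels = classes)
  n <- nrow(tab)

  pred <- character(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv < 1e-12] <- 1
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
    Xte <- (X[i, ] - mu) / sdv
    fit <- e1071::svm(Xtr, y[-i], type = "C-classification",
                      kernel = svm_config$kernel, cost = svm_config$cost,
                      gamma = gamma, degree = svm_config$degree,
                      coef0 = svm_config$coef0, scale = FALSE)
    pred[i] <- as.character(stats::predict(fit, matrix(Xte, nrow = 1)))
  }

  confusion <- table(true = factor(as.character(y), levels = classes),
                     predicted = factor(pred, levels = classes))
  confusion <- unclass(confusion)
  recall <- diag(confusion) / rowSums(confusion)
  precision <- diag(confusion) / colSums(confusion)
  predictions <- pred[order(ord)]          # back to the input row order
  names(predictions) <- table$tree_id
  structure(
    list(confusion = confusion, recall = recall, precision = precision,
         accuracy = sum(diag(confusion)) / n, kappa = cohens_kappa(confusion),
         predictions = predictions, columns = columns,
         svm_config = c(svm_config, list(gamma_effective = gamma)), n = n),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> n = %d, accuracy = %.3f, kappa = %.3f\n",
              x$n, x$accuracy, x$kappa))
  cat("features:", paste(x$columns, collapse = ", "), "\n")
  print(x$confusion)
  invisible(x)
}

#' Exhaustive feature-subset search
#'
#' Evaluates every unordered subset of the feature pool at each requested
#' size with [loocv_svm()] and records, per size, the number of cases
#' (exactly `choose(|pool|, k)`) and the best-performing subset.  Ties are
#' broken toward the smaller subset first and then toward the
#' lexicographically earlier column combination.
#'
#' @param table feature table.
#' @param pool candidate feature columns.
#' @param sizes subset sizes to evaluate (default all `1:|pool|`).
#' @param svm_config an [svm_defaults()] list.
#' @param count_only if TRUE, only enumerate and count the cases without
#'   fitting any classifier (useful to audit the combinatorial case counts).
#' @param evaluator optional function(columns) -> accuracy overriding the
#'   LOOCV evaluation (e.g. for stubbing in tests).
#' @return object of class `subset_search`: list with `per_size` (data
#'   frame: size, n_cases, best_accuracy, best_subset), `best_subset`,
#'   `best_accuracy` and `best_report` (NULL when `count_only`).
#' @export
subset_search <- function(table, pool, sizes = NULL,
                          svm_config = svm_defaults(), count_only = FALSE,
                          evaluator = NULL) {
  pool <- sort(unique(pool))
  if (is.null(sizes)) sizes <- seq_along(pool)
  sizes <- as.integer(sizes)
  if (any(sizes < 1L) || any(sizes > length(pool))) {
    stop(sprintf("requested subset size outside 1..%d", length(pool)))
  }
  if (!count_only) {
    check_feature_columns(table, pool)
    if (is.null(evaluator)) {
      evaluator <- function(cols) loocv_svm(table, cols, svm_config)$accuracy
    }
  }

  best_acc <- -Inf
  best_sub <- NULL
  per_size <- data.frame(size = integer(0), n_cases = integer(0),
                         best_accuracy = numeric(0),
                         best_subset = character(0),
                         stringsAsFactors = FALSE)
  for (k in sort(sizes)) {
    cmb <- utils::combn(pool, k)
    n_cases <- ncol(cmb)
    if (count_only) {
      per_size <- rbind(per_size, data.frame(
        size = k, n_cases = n_cases, best_accuracy = NA_real_,
        best_subset = NA_character_, stringsAsFactors = FALSE))
      next
    }
    acc <- vapply(seq_len(n_cases), function(j) evaluator(cmb[, j]), 0)
    jbest <- which.max(acc)            # first max = lexicographically earliest
    per_size <- rbind(per_size, data.frame(
      size = k, n_cases = n_cases, best_accuracy = acc[jbest],
      best_subset = paste(cmb[, jbest], collapse = "+"),
      stringsAsFactors = FALSE))
    if (acc[jbest] > best_acc) {       # strict: smaller size wins ties
      best_acc <- acc[jbest]
      best_sub <- cmb[, jbest]
    }
  }
  best_report <- NULL
  if (!count_only && !is.null(best_sub) && is.null(evaluator_is_stub(evaluator))) {
    best_report <- tryCatch(loocv_svm(table, best_sub, svm_config),
                            error = function(e) NULL)
  }
  structure(list(per_size = per_size,
                 best_subset = best_sub,
                 best_accuracy = if (count_only) NA_real_ else best_acc,
                 best_report = best_report),
            class = "subset_search")
}

# internal marker so stubbed evaluators skip the final report refit
evaluator_is_stub <- function(evaluator) attr(evaluator, "stub")

#' @export
print.subset_search <- function(x, ...) {
  cat("<subset_search>\n")
  print(x$per_size, row.names = FALSE)
  if (!is.null(x$best_subset)) {
    cat(sprintf("best: {%s} accuracy %.3f\n",
                paste(x$best_subset, collapse = ", "), x$best_accuracy))
  }
  invisible(x)
}

#' Agreement statistics between estimated and reference values
#'
#' `RMSE = sqrt(sum((d_i - d_i^R)^2) / n)`.  The coefficient of
#' determination is computed against the fitted values of the ordinary
#' least-squares regression of the estimates on the references:
#' `R^2 = 1 - sum((d_i - dhat_i)^2) / sum((d_i - dbar)^2)` with `dbar` the
#' mean of the estimates.
#'
#' @param estimates estimated values `d_i`.
#' @param references reference values `d_i^R`.
#' @return list with `r_squared` (NA with a warning when the estimates have
#'   zero variance) and `rmse`.
#' @export
r2_rmse <- function(estimates, references) {
  if (length(estimates) != length(references)) {
    stop("'estimates' and 'references' must have equal length")
  }
  if (length(estimates) < 2L) stop("need at least 2 value pairs")
  rmse <- sqrt(mean((estimates - references)^2))
  ss_tot <- sum((estimates - mean(estimates))^2)
  if (ss_tot < 1e-24) {
    warning("estimates have zero variance; R^2 is undefined", call. = FALSE)
    return(list(r_squared = NA_real_, rmse = rmse))
  }
  dhat <- stats::fitted(stats::lm(estimates ~ references))
  list(r_squared = 1 - sum((estimates - dhat)^2) / ss_tot, rmse = rmse)
}
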