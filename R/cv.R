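#' Random k-fold assignments, repeated
#'
#' Each repeat partitions the individuals uniformly at random into `k` folds
#' whose sizes differ by at most one; the assignment is reproducible from
#' `seed`.
#'
#' @param ids individual identifiers.
#' @param k number of folds (>= 2).
#' @param repeats number of independent repetitions of the partition.
#' @param seed integer seed.
#' @return data.frame with columns `individual_id`, `rep`, `fold`.
#' @export
make_folds <- function(ids, k = 5L, repeats = 2L, seed = 1L) {
  n <- length(ids)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k (", k, ") exceeds the number of individuals (", n, ")")
  folds <- withr::with_seed(seed, {
    lapply(seq_len(repeats), function(r) sample(rep_len(seq_len(k), n)))
  })
  data.frame(individual_id = rep(as.character(ids), repeats),
             rep = rep(seq_len(repeats), each = n),
             fold = unlist(folds))
}

#' Predict genetic values for masked individuals
#'
#' Re-estimates the variance components on the training records only, then
#' propagates BLUPs to every individual through the genomic relationships:
#' `u_hat = sigma2_k K[, train] P y_train`, the mixed-model-equation solution
#' when the validation phenotypes are unobserved. Fixed-effect columns that
#' are empty or aliased within the training set are merged into the
#' reference level (dropped) with a warning.
#'
#' @param y phenotypes for all individuals (validation values are ignored).
#' @param X fixed-effect design for all individuals.
#' @param kinships named list of kinship matrices over ALL individuals.
#' @param validation integer or logical index of the held-out individuals.
#' @param ... passed to [fit_gblup()].
#' @return List: `fit` (training `reml_fit`), `pred` (matrix, one column per
#'   genetic component plus `total`, rows = all individuals), `fixed_part`
#'   (X b_hat for all individuals), `kept_columns`.
#' @export
predict_masked <- function(y, X, kinships, validation, ...) {
  n <- length(y)
  X <- as.matrix(X)
  val <- if (is.logical(validation)) which(validation) else as.integer(validation)
  train <- setdiff(seq_len(n), val)
  if (!length(train)) stop("no training records left")
  kin <- lapply(kinships, .kin_values)

  Xt <- X[train, , drop = FALSE]
  qrX <- qr(Xt)
  keep <- sort(qrX$pivot[seq_len(qrX$rank)])
  if (length(keep) < ncol(X)) {
    warning("fixed-effect column(s) ",
            paste(colnames(X)[-keep], collapse = ", "),
            " unidentifiable in training set; merged into reference level")
  }
  fit <- fit_gblup(y[train], Xt[, keep, drop = FALSE],
                   lapply(kin, function(k) k[train, train, drop = FALSE]), ...)
  train_used <- train[fit$used]

  pred <- sapply(names(kin), function(nm) {
    drop(fit$sigma2[[nm]] * kin[[nm]][, train_used, drop = FALSE] %*% fit$Py)
  })
  pred <- cbind(pred, total = rowSums(pred))
  rownames(pred) <- rownames(X)
  fixed_part <- drop(X[, keep, drop = FALSE] %*% fit$beta)
  list(fit = fit, pred = pred, fixed_part = fixed_part, kept_columns = keep,
       validation = val)
}

#' Prediction accuracy of genomic values
#'
#' Pearson correlation between predicted genetic values and phenotypes
#' adjusted for the fixed effects estimated in training
#' (`y - X b_hat`); pass `fixed_part = 0` for raw-phenotype accuracy.
#'
#' @param predicted predicted genetic values.
#' @param observed phenotypes (NA allowed; such records are dropped).
#' @param fixed_part fixed-effect part to subtract from `observed`.
#' @return Pearson correlation, or `NA` (with a warning) when either vector
#'   is constant.
#' @export
accuracy <- function(predicted, observed, fixed_part = 0) {
  adj <- observed - fixed_part
  ok <- !is.na(adj) & !is.na(predicted)
  if (sum(ok) < 3L) {
    stop("at least 3 validation records with non-missing phenotype required")
  }
  if (stats::sd(predicted[ok]) == 0 || stats::sd(adj[ok]) == 0) {
    warning("zero variance in predictions or adjusted phenotypes; ",
            "accuracy undefined")
    return(NA_real_)
  }
  stats::cor(predicted[ok], adj[ok])
}

#' Repeated k-fold cross-validation of genomic prediction
#'
#' For every (repeat, fold) cell: mask the fold, re-estimate variance
#' components on the remaining records, predict the masked individuals'
#' genetic values through the genomic relationship matrices, and score the
#' Pearson correlation against their (fixed-effect-adjusted) phenotypes.
#' The summary is the mean and the standard error of the mean over the
#' `k * repeats` cell accuracies. A cell whose training fit pins the scored
#' genetic variance at zero yields constant (prior-mean) predictions; such a
#' cell is scored 0, since an uninformative predictor has no predictive
#' correlation with any phenotype.
#'
#' @inheritParams predict_masked
#' @inheritParams make_folds
#' @param accuracy_def `"adjusted"` (correlate with `y - X b_hat`, default)
#'   or `"raw"` (correlate with `y`).
#' @param score which predicted genetic value to correlate: `"breeding"`
#'   (the additive BLUP `u_hat`, default) or `"total"` (sum of all genetic
#'   components, `u_hat + v_hat` under the dominance model).
#' @param ... passed to [fit_gblup()].
#' @return An object of class `cv_result`: list with `cells` (data.frame
#'   `rep`, `fold`, `n_validation`, `accuracy`, `converged`), `mean`, `se`,
#'   and the design parameters.
#' @export
cross_validate <- function(y, X, kinships, k = 5L, repeats = 2L, seed = 1L,
                           accuracy_def = c("adjusted", "raw"),
                           score = c("breeding", "total"), ...) {
  accuracy_def <- match.arg(accuracy_def)
  score <- match.arg(score)
  X <- as.matrix(X)
  ids <- rownames(X) %||% as.character(seq_along(y))
  folds <- make_folds(ids, k = k, repeats = repeats, seed = seed)
  score_col <- if (score == "breeding") 1L else "total"

  cells <- expand.grid(fold = seq_len(k), rep = seq_len(repeats))[, 2:1]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    r <- cells$rep[i]; f <- cells$fold[i]
    val <- which(folds$fold[folds$rep == r] == f)
    out <- data.frame(rep = r, fold = f, n_validation = length(val),
                      accuracy = NA_real_, converged = FALSE)
    pm <- tryCatch(
      suppressWarnings(predict_masked(y, X, kinships, val, ...)),
      error = function(e) {
        warning("fold ", f, " of repeat ", r, " failed: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(pm)) return(out)
    out$converged <- pm$fit$converged
    if (!pm$fit$converged) {
      warning("fold ", f, " of repeat ", r,
              " did not converge; cell recorded as missing")
      return(out)
    }
    fp <- if (accuracy_def == "adjusted") pm$fixed_part[val] else 0
    pred <- pm$pred[val, score_col]
    if (stats::sd(pred) == 0) {
      # the training fit pinned the genetic variance at zero, so every
      # prediction is the prior mean: an uninformative predictor has zero
      # predictive correlation by convention
      out$accuracy <- 0
    } else {
      out$accuracy <- accuracy(pred, y[val], fp)
    }
    out
  })
  cells <- do.call(rbind, res)
  acc <- cells$accuracy[!is.na(cells$accuracy)]
  structure(list(cells = cells,
                 mean = mean(acc),
                 se = stats::sd(acc) / sqrt(length(acc)),
                 k = k, repeats = repeats, seed = seed,
                 accuracy_def = accuracy_def, score = score),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "%d-fold cross-validation, %d repeat(s) (%d cells, %s phenotypes, %s values)\n",
    x$k, x$repeats, nrow(x$cells), x$accuracy_def, x$score))
  cat(sprintf("mean accuracy %.3f (SE %.3f)\n", x$mean, x$se))
  invisible(x)
}
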