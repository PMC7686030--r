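#' Fixed-effect design matrix for sex and herd
#'
#' Intercept plus treatment-coded factor columns; the reference level of each
#' factor is the lexicographically first observed level. Factors with a
#' single observed level contribute no column (with a warning).
#'
#' @param samples data.frame holding the factor columns (e.g. `sex`, `herd`),
#'   one row per record, with an `individual_id` column used for row names
#'   when present.
#' @param factors character vector of factor column names.
#' @return Numeric full-rank design matrix with attribute
#'   `reference_levels`.
#' @export
build_fixed_design <- function(samples, factors = c("sex", "herd")) {
  missing_cols <- setdiff(factors, names(samples))
  if (length(missing_cols)) {
    stop("fixed-effect column(s) not found: ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(samples)
  blocks <- list(`(Intercept)` = matrix(1, n, 1,
                                        dimnames = list(NULL, "(Intercept)")))
  refs <- character(0)
  for (f in factors) {
    v <- samples[[f]]
    if (anyNA(v)) stop("missing values in fixed effect '", f, "'")
    v <- factor(as.character(v))        # lexicographic level order
    if (nlevels(v) < 2L) {
      warning("fixed effect '", f, "' has a single observed level; ",
              "column dropped")
      next
    }
    refs[f] <- levels(v)[1L]
    mm <- stats::model.matrix(~v)[, -1L, drop = FALSE]
    colnames(mm) <- paste0(f, levels(v)[-1L])
    blocks[[f]] <- mm
  }
  X <- do.call(cbind, blocks)
  if (qr(X)$rank < ncol(X)) {
    stop("fixed-effect design is rank deficient (confounded factors)")
  }
  if (!is.null(samples$individual_id)) {
    rownames(X) <- as.character(samples$individual_id)
  }
  attr(X, "reference_levels") <- refs
  X
}

.kin_values <- function(k) if (inherits(k, "kinship")) k$values else as.matrix(k)

# Dense mixed-model workspace at a given set of variance components.
# V = sum_k sigma2_k K_k + sigma2_e I; P = Vinv - Vinv X (X'Vinv X)^-1 X'Vinv.
.mm_workspace <- function(y, X, kin, sigma2) {
  n <- length(y)
  V <- diag(rep(sigma2[["e"]], n))
  for (nm in names(kin)) V <- V + sigma2[[nm]] * kin[[nm]]
  cv <- tryCatch(chol(V), error = function(e) {
    stop("phenotypic covariance not positive definite at sigma2 = (",
         paste(sprintf("%s=%.4g", names(sigma2), sigma2), collapse = ", "),
         ")")
  })
  Vinv <- chol2inv(cv)
  VinvX <- Vinv %*% X
  XtVinvX <- crossprod(X, VinvX)
  cx <- chol(XtVinvX)
  XtVinvX_inv <- chol2inv(cx)
  P <- Vinv - VinvX %*% tcrossprod(XtVinvX_inv, VinvX)
  Py <- drop(P %*% y)
  loglik <- -0.5 * (2 * sum(log(diag(cv))) + 2 * sum(log(diag(cx))) +
                      sum(y * Py) + (n - ncol(X)) * log(2 * pi))
  beta <- drop(XtVinvX_inv %*% crossprod(VinvX, y))
  names(beta) <- colnames(X)
  list(P = P, Py = Py, loglik = loglik, beta = beta,
       XtVinvX_inv = XtVinvX_inv)
}

# Score, average-information matrix and EM ingredients at a workspace.
# Component order: genetic terms then the residual ("e", K = I).
.reml_derivs <- function(ws, kin) {
  comp <- c(names(kin), "e")
  n <- length(ws$Py)
  KPy <- matrix(0, n, length(comp), dimnames = list(NULL, comp))
  trPK <- yPKPy <- stats::setNames(numeric(length(comp)), comp)
  for (nm in names(kin)) {
    KPy[, nm] <- kin[[nm]] %*% ws$Py
    trPK[nm] <- sum(ws$P * kin[[nm]])   # tr(P K), K symmetric
    yPKPy[nm] <- sum(ws$Py * KPy[, nm])
  }
  KPy[, "e"] <- ws$Py
  trPK["e"] <- sum(diag(ws$P))
  yPKPy["e"] <- sum(ws$Py^2)
  score <- -0.5 * (trPK - yPKPy)
  ai <- 0.5 * crossprod(KPy, ws$P %*% KPy)
  list(score = score, ai = ai, trPK = trPK, yPKPy = yPKPy)
}

#' Restricted log-likelihood of a multi-kinship mixed model
#'
#' For `y = X b + sum_k u_k + e` with `Var(u_k) = sigma2_k K_k` and
#' `Var(e) = sigma2_e I`, returns the restricted log-likelihood
#' `-0.5 * (log|V| + log|X' V^-1 X| + y' P y + (n - p) log 2 pi)`.
#'
#' @param y numeric response (no missing values).
#' @param X full-rank fixed-effect design matrix.
#' @param kinships named list of kinship matrices (or `kinship` objects).
#' @param sigma2 named variance components: one per kinship plus `"e"`.
#' @return Scalar restricted log-likelihood.
#' @export
restricted_loglik <- function(y, X, kinships, sigma2) {
  kin <- lapply(kinships, .kin_values)
  if (!all(c(names(kin), "e") %in% names(sigma2))) {
    stop("sigma2 must be named: one entry per kinship plus 'e'")
  }
  .mm_workspace(y, X, kin, sigma2)$loglik
}

#' Fit a GBLUP mixed model by REML
#'
#' Average-information REML with EM-REML fallback. An AI update proposing a
#' negative component is replaced by the EM update for that component;
#' components driven to the boundary are pinned at zero and the remaining
#' components re-optimized. Standard errors come from the inverse
#' average-information matrix evaluated at convergence over all components
#' (pinned ones included, at their boundary value). BLUPs are
#' `sigma2_k * K_k %*% P y`, the solution of Henderson's mixed-model
#' equations at the final components.
#'
#' @param y numeric response; records with missing `y` are dropped.
#' @param X fixed-effect design matrix (rows matching `y`).
#' @param kinships named list of genetic covariance structures, e.g.
#'   `list(a = G)` or `list(a = G, d = D)`; `kinship` objects or plain
#'   matrices.
#' @param method `"ai"` (default) or `"em"` (pure EM-REML, slower but
#'   monotone).
#' @param max_iter iteration cap.
#' @param tol_loglik absolute restricted log-likelihood change declaring
#'   convergence.
#' @param tol_sigma2 maximum relative component change declaring convergence.
#' @param verbose print the iteration trace.
#' @return An object of class `reml_fit`.
#' @export
fit_gblup <- function(y, X, kinships, method = c("ai", "em"),
                      max_iter = 200L, tol_loglik = 1e-8, tol_sigma2 = 1e-6,
                      verbose = FALSE) {
  method <- match.arg(method)
  X <- as.matrix(X)
  used <- !is.na(y)
  if (!all(used)) {
    y <- y[used]
    X <- X[used, , drop = FALSE]
  }
  kin <- lapply(kinships, function(k) .kin_values(k)[used, used, drop = FALSE])
  n <- length(y)
  p <- ncol(X)
  if (is.null(names(kin)) || any(names(kin) == "")) {
    stop("kinships must be a named list")
  }
  if (n < p + length(kin) + 1L) stop("too few records for the model")

  vary <- stats::var(y)
  comp <- c(names(kin), "e")
  theta <- stats::setNames(c(rep(vary / 2 / length(kin), length(kin)),
                             vary / 2), comp)
  pinned <- stats::setNames(rep(FALSE, length(comp)), comp)
  floor_hard <- 1e-8 * vary             # always pin genetic terms below this
  floor_soft <- 1e-6 * vary             # restart value for released terms
  # boundary values: genetic variances are pinned at 0; the residual is
  # bounded at a small positive floor so V stays positive definite
  bound <- stats::setNames(c(rep(0, length(kin)), 1e-4 * vary), comp)
  trace <- vector("list", max_iter)
  ll_prev <- -Inf
  theta_prev <- theta
  converged <- FALSE
  it <- 0L

  ll_at <- function(theta_all, active) {
    tryCatch(.mm_workspace(y, X, kin[active],
                           theta_all[c(active, "e")])$loglik,
             error = function(e) -Inf)
  }

  repeat {
    it <- it + 1L
    active <- names(kin)[!pinned[names(kin)]]
    ws <- .mm_workspace(y, X, kin[active], theta[c(active, "e")])
    dv <- .reml_derivs(ws, kin[active])  # scores/AI for active terms + "e"
    free <- c(active, if (!pinned[["e"]]) "e")
    if (!length(free)) {                # everything on a bound: nothing to fit
      converged <- TRUE
      trace[[it]] <- data.frame(iter = it, loglik = ws$loglik,
                                t(theta)[1, , drop = FALSE])
      break
    }
    em_step <- theta[free] +
      theta[free]^2 * (dv$yPKPy[free] - dv$trPK[free]) / n
    em_step <- pmax(em_step, bound[free] + floor_hard)
    trace[[it]] <- data.frame(iter = it, loglik = ws$loglik,
                              t(theta)[1, , drop = FALSE])
    if (verbose) {
      message(sprintf("iter %3d  logLik %.6f  %s", it, ws$loglik,
                      paste(sprintf("%s=%.4g", comp, theta), collapse = " ")))
    }

    rel_change <- abs(theta - theta_prev) / pmax(theta_prev, floor_hard)
    if (it > 1L && abs(ws$loglik - ll_prev) < tol_loglik &&
        max(rel_change) < tol_sigma2) {
      # before declaring convergence, check that no boundary component
      # wants back into the interior (positive score at the bound)
      release <- character(0)
      if (any(pinned)) {
        pin_gen <- names(which(pinned[names(kin)]))
        sc_pin <- c(if (length(pin_gen)) {
          .reml_derivs(ws, kin[pin_gen])$score[pin_gen]
        }, if (pinned[["e"]]) dv$score["e"])
        release <- names(sc_pin)[sc_pin > sqrt(tol_loglik)]
      }
      if (length(release) && it < max_iter) {
        pinned[release] <- FALSE
        theta[release] <- bound[release] + floor_soft
      } else {
        converged <- TRUE
        break
      }
      ll_prev <- ws$loglik
      theta_prev <- theta
      next
    }
    if (it >= max_iter) break

    # monotone step: halve toward the current point until the restricted
    # log-likelihood does not decrease; components in `fix` sit exactly on
    # their bound. NULL if no admissible step is found.
    damped <- function(target, fix = character(0)) {
      step <- 1
      while (step >= 1 / 64) {
        cand <- (1 - step) * theta[free] + step * target
        cand[fix] <- bound[fix]
        full_theta <- theta
        full_theta[free] <- cand
        if (all(cand[setdiff(free, fix)] > bound[setdiff(free, fix)]) &&
            ll_at(full_theta, active) >= ws$loglik - 1e-10) {
          return(cand)
        }
        step <- step / 2
      }
      NULL
    }

    prop <- NULL
    newly_pinned <- character(0)
    if (method == "em" || it == 1L) {
      prop <- em_step
    } else {
      delta <- tryCatch(solve(dv$ai[free, free, drop = FALSE],
                              dv$score[free]),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        full <- theta[free] + delta
        viol <- free[full <= bound[free]]
        if (length(viol) && length(viol) < length(free)) {
          # active-set move: project the offending components onto their
          # bound and re-solve the Newton step for the rest
          others <- setdiff(free, viol)
          delta_r <- tryCatch(solve(dv$ai[others, others, drop = FALSE],
                                    dv$score[others]),
                              error = function(e) NULL)
          if (!is.null(delta_r)) {
            target <- theta[free]
            target[viol] <- bound[viol]
            target[others] <- theta[others] + delta_r
            prop <- damped(target, fix = viol)
            if (!is.null(prop)) newly_pinned <- viol
          }
        }
        if (is.null(prop)) {            # boundary move rejected: stay inside
          full <- pmax(full, bound[free] + floor_soft)
          prop <- damped(full)
        }
      }
      if (is.null(prop)) {
        prop <- em_step                 # fallback: monotone EM step
      }
    }
    genetic_free <- setdiff(free, "e")
    hard <- genetic_free[prop[genetic_free] < floor_hard &
                           !genetic_free %in% newly_pinned]
    newly_pinned <- union(newly_pinned, hard)
    prop[hard] <- 0
    if ("e" %in% free) prop["e"] <- max(prop["e"], bound[["e"]])
    if (length(newly_pinned)) pinned[newly_pinned] <- TRUE

    ll_prev <- ws$loglik
    theta_prev <- theta
    theta[free] <- prop
    theta[names(which(pinned[names(kin)]))] <- 0
    if (pinned[["e"]]) theta[["e"]] <- bound[["e"]]
  }

  # final quantities at the converged components, all kinships included so
  # the AI matrix (hence the SEs) covers boundary components too
  ws <- .mm_workspace(y, X, kin[!pinned[names(kin)]],
                      theta[c(names(kin)[!pinned[names(kin)]], "e")])
  dv_full <- .reml_derivs(ws, kin)
  ai_inv <- tryCatch(solve(dv_full$ai), error = function(e) NULL)
  se <- if (is.null(ai_inv)) {
    warning("average-information matrix is singular; SEs unavailable")
    stats::setNames(rep(NA_real_, length(comp)), comp)
  } else {
    stats::setNames(sqrt(pmax(diag(ai_inv), 0)), comp)
  }
  blup <- lapply(stats::setNames(names(kin), names(kin)), function(nm) {
    u <- drop(theta[nm] * kin[[nm]] %*% ws$Py)
    names(u) <- rownames(X)
    u
  })
  structure(list(
    sigma2 = theta, se = se, beta = ws$beta, blup = blup,
    loglik = ws$loglik, iterations = it, converged = converged,
    pinned = pinned, ai = dv_full$ai, ai_inv = ai_inv,
    Py = ws$Py, used = used, n = n, method = method,
    trace = do.call(rbind, trace[seq_len(it)])),
    class = "reml_fit")
}

#' Additive-only GBLUP model (MAG)
#'
#' `y = X b + u + e` with `Var(u) = sigma2_a G`.
#'
#' @inheritParams fit_gblup
#' @param G additive genomic relationship matrix (`kinship` or matrix).
#' @param ... passed to [fit_gblup()].
#' @return A `reml_fit` with `model = "MAG"`.
#' @export
fit_mag <- function(y, X, G, ...) {
  fit <- fit_gblup(y, X, list(a = G), ...)
  fit$model <- "MAG"
  fit
}

#' Additive plus dominance GBLUP model (MADG)
#'
#' `y = X b + u + v + e` with `Var(u) = sigma2_a G`, `Var(v) = sigma2_d D`.
#'
#' @inheritParams fit_mag
#' @param D dominance genomic relationship matrix.
#' @return A `reml_fit` with `model = "MADG"`.
#' @export
fit_madg <- function(y, X, G, D, ...) {
  fit <- fit_gblup(y, X, list(a = G, d = D), ...)
  fit$model <- "MADG"
  fit
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("%s REML fit: n = %d, %s after %d iterations\n",
              x$model %||% "GBLUP", x$n,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  comp <- data.frame(component = names(x$sigma2),
                     estimate = unname(x$sigma2),
                     se = unname(x$se),
                     boundary = unname(x$pinned[names(x$sigma2)]))
  print(comp, row.names = FALSE, digits = 4)
  cat(sprintf("restricted logLik: %.4f\n", x$loglik))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Variance ratios (heritability and dominance proportion)
#'
#' Each genetic component's share of the total phenotypic variance
#' `sigma2_a (+ sigma2_d) + sigma2_e`: for the additive-only model
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)`; with dominance,
#' `h2 = sigma2_a / (sigma2_a + sigma2_d + sigma2_e)` and
#' `d2 = sigma2_d / (sigma2_a + sigma2_d + sigma2_e)`. Ratio standard errors
#' use the delta method on the inverse average-information matrix.
#'
#' @param fit a `reml_fit`, or a named numeric vector of variance components
#'   (one per genetic term plus `"e"`) for desk arithmetic on published
#'   component tables (SEs are then unavailable).
#' @return data.frame with one row per genetic component: `component`,
#'   `variance`, `se_variance`, `ratio`, `se_ratio`.
#' @export
variance_ratios <- function(fit) {
  if (is.numeric(fit)) {
    sigma2 <- fit
    if (!"e" %in% names(sigma2)) stop("components must include 'e'")
    ai_inv <- NULL
    se <- stats::setNames(rep(NA_real_, length(sigma2)), names(sigma2))
  } else {
    stopifnot(inherits(fit, "reml_fit"))
    sigma2 <- fit$sigma2
    ai_inv <- fit$ai_inv
    se <- fit$se
  }
  total <- sum(sigma2)
  if (total <= 0) stop("total phenotypic variance is not positive")
  genetic <- setdiff(names(sigma2), "e")
  out <- lapply(genetic, function(nm) {
    ratio <- sigma2[[nm]] / total
    se_ratio <- NA_real_
    if (!is.null(ai_inv)) {
      grad <- -sigma2[[nm]] / total^2 + (names(sigma2) == nm) / total
      se_ratio <- sqrt(max(0, drop(grad %*% ai_inv %*% grad)))
    }
    data.frame(component = nm, variance = sigma2[[nm]],
               se_variance = se[[nm]], ratio = ratio, se_ratio = se_ratio)
  })
  out <- do.call(rbind, out)
  attr(out, "total_variance") <- total
  out
}
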