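test_that("fixed design has treatment coding with lexicographic references", {
  samples <- data.frame(
    individual_id = sprintf("A%02d", 1:14),
    sex = rep(c("F", "M"), 7),
    herd = rep(paste0("H", 1:7), each = 2))
  X <- build_fixed_design(samples)
  expect_equal(ncol(X), 1 + 1 + 6)      # intercept + sex + 6 herd contrasts
  expect_equal(attr(X, "reference_levels"), c(sex = "F", herd = "H1"))
  expect_equal(qr(X)$rank, ncol(X))
  # a (female, H3) row: intercept + herdH3 only
  row <- X[samples$sex == "F" & samples$herd == "H3", ]
  expect_lte(sum(row != 0), 3)
  expect_equal(unname(row[c("(Intercept)", "herdH3")]), c(1, 1))
  expect_equal(unname(row["sexM"]), 0)

  # single-level factor dropped with warning
  samples$herd <- "H1"
  expect_warning(X1 <- build_fixed_design(samples), "single observed level")
  expect_equal(ncol(X1), 2)
  # missing level entries are an error
  samples$sex[3] <- NA
  expect_error(suppressWarnings(build_fixed_design(samples)), "missing values")
})

test_that("restricted log-likelihood matches the naive dense-inverse oracle", {
  withr::with_seed(41, {
    for (rep in 1:5) {
      n <- sample(8:20, 1)
      K <- crossprod(matrix(rnorm(n * n), n)) / n
      K2 <- crossprod(matrix(rnorm(n * n), n)) / n
      X <- cbind(1, rnorm(n))
      y <- rnorm(n, sd = 2)
      th1 <- c(a = runif(1, 0.2, 3), e = runif(1, 0.2, 3))
      expect_equal(restricted_loglik(y, X, list(a = K), th1),
                   naive_restricted_loglik(y, X, list(a = K), th1),
                   tolerance = 1e-8)
      th2 <- c(a = runif(1, 0.2, 3), d = runif(1, 0.2, 3),
               e = runif(1, 0.2, 3))
      expect_equal(restricted_loglik(y, X, list(a = K, d = K2), th2),
                   naive_restricted_loglik(y, X, list(a = K, d = K2), th2),
                   tolerance = 1e-8)
    }
  })
})

test_that("restricted log-likelihood limits and equivariances hold", {
  withr::with_seed(42, {
    n <- 12
    K <- crossprod(matrix(rnorm(n * n), n)) / n
    X <- cbind(1, rbinom(n, 1, 0.5))
    y <- rnorm(n)
  })
  # sigma2_a -> 0 recovers the fixed-effects-only model
  ols <- naive_restricted_loglik(y, X, list(), c(e = 1.7))
  expect_equal(restricted_loglik(y, X, list(a = K), c(a = 0, e = 1.7)), ols)
  # scaling y by c scales the optimal variance by c^2, leaving ratios alone
  pop <- small_pop()
  f1 <- fit_mag(pop$pheno$y, pop$X, pop$G)
  f2 <- fit_mag(pop$pheno$y * 3, pop$X, pop$G)
  expect_equal(f2$sigma2 / f1$sigma2, c(a = 9, e = 9), tolerance = 1e-3)
  expect_equal(variance_ratios(f2)$ratio, variance_ratios(f1)$ratio,
               tolerance = 1e-4)
})

test_that("AI-REML and EM-REML reach the same optimum", {
  pop <- small_pop()
  sub <- 1:120
  y <- pop$pheno$y[sub]; X <- pop$X[sub, ]
  K <- pop$G$values[sub, sub]
  ai <- fit_gblup(y, X, list(a = K), tol_loglik = 1e-12, tol_sigma2 = 1e-8)
  em <- fit_gblup(y, X, list(a = K), method = "em", max_iter = 5000,
                  tol_loglik = 1e-13, tol_sigma2 = 1e-9)
  expect_true(ai$converged)
  expect_true(em$converged)
  expect_equal(ai$sigma2, em$sigma2, tolerance = 1e-5)
  expect_equal(ai$loglik, em$loglik, tolerance = 1e-7)
})

test_that("the fitted optimum beats random neighbourhood perturbations", {
  pop <- small_pop()
  sub <- 1:100
  y <- pop$pheno$y[sub]; X <- pop$X[sub, ]
  kin <- list(a = pop$G$values[sub, sub])
  fit <- fit_gblup(y, X, kin)
  withr::with_seed(44, {
    for (i in 1:100) {
      th <- fit$sigma2 * exp(runif(2, -0.2, 0.2))
      expect_lte(restricted_loglik(y, X, kin, th), fit$loglik + 1e-8)
    }
  })
})

test_that("grouped-data REML matches lme4 as an independent oracle", {
  skip_if_not_installed("lme4")
  withr::with_seed(45, {
    g <- 30; r <- 4
    grp <- factor(rep(seq_len(g), each = r))
    x <- rnorm(g * r)
    u <- rnorm(g, sd = sqrt(2))
    y <- 1 + 0.5 * x + u[grp] + rnorm(g * r, sd = 1)
  })
  Z <- stats::model.matrix(~ grp - 1)
  K <- tcrossprod(Z)                    # block-diagonal group kinship
  X <- cbind(1, x)
  ours <- fit_gblup(y, X, list(a = K), tol_loglik = 1e-12,
                    tol_sigma2 = 1e-9)
  lmm <- lme4::lmer(y ~ x + (1 | grp), REML = TRUE,
                    control = lme4::lmerControl(
                      optCtrl = list(xtol_abs = 1e-12, ftol_abs = 1e-12)))
  vc <- as.data.frame(lme4::VarCorr(lmm))
  expect_equal(unname(ours$sigma2[["a"]]), vc$vcov[1], tolerance = 1e-6)
  expect_equal(unname(ours$sigma2[["e"]]), vc$vcov[2], tolerance = 1e-6)
  expect_equal(unname(ours$beta), unname(lme4::fixef(lmm)), tolerance = 1e-6)
  # BLUPs of the group effects agree too
  uhat <- drop(crossprod(Z, ours$blup$a)) / r
  expect_equal(unname(uhat), unname(lme4::ranef(lmm)$grp[, 1]),
               tolerance = 1e-4)
})

test_that("BLUPs satisfy Henderson's mixed-model equations", {
  pop <- small_pop()
  sub <- 1:80
  y <- pop$pheno$y[sub]; X <- unname(pop$X[sub, ])
  G <- pop$G$values[sub, sub] + diag(1e-4, 80)
  fit <- fit_gblup(y, X, list(a = G))
  s2a <- fit$sigma2[["a"]]; s2e <- fit$sigma2[["e"]]
  Ginv <- solve(G)
  n <- length(y); p <- ncol(X)
  lhs <- rbind(cbind(crossprod(X) / s2e, t(X) / s2e),
               cbind(X / s2e, diag(n) / s2e + Ginv / s2a))
  rhs <- c(crossprod(X, y) / s2e, y / s2e)
  sol <- c(fit$beta, fit$blup$a)
  expect_lt(sqrt(sum((lhs %*% sol - rhs)^2)) / sqrt(sum(rhs^2)), 1e-8)
})

test_that("fits are invariant to reordering individuals", {
  pop <- small_pop()
  sub <- 1:90
  y <- pop$pheno$y[sub]; X <- pop$X[sub, ]; K <- pop$G$values[sub, sub]
  withr::with_seed(46, perm <- sample(90))
  f1 <- fit_gblup(y, X, list(a = K))
  f2 <- fit_gblup(y[perm], X[perm, ], list(a = K[perm, perm]))
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-6)
  expect_equal(f1$blup$a[perm], f2$blup$a, tolerance = 1e-5)
})

test_that("records with missing phenotypes are dropped from the fit", {
  pop <- small_pop()
  y <- pop$pheno$y
  y[c(5, 20, 33)] <- NA
  fit <- fit_gblup(y, pop$X, list(a = pop$G))
  expect_equal(fit$n, length(y) - 3)
  expect_equal(length(fit$blup$a), length(y) - 3)
  ref <- fit_gblup(y[-c(5, 20, 33)], pop$X[-c(5, 20, 33), ],
                   list(a = pop$G$values[-c(5, 20, 33), -c(5, 20, 33)]))
  expect_equal(fit$sigma2, ref$sigma2, tolerance = 1e-10)
})

test_that("variance ratios and their boundary cases are correct", {
  # desk arithmetic on published-style component values; recomputing from
  # components printed at 2 dp carries up to one unit in the last digit
  vr <- variance_ratios(c(a = 40.96, e = 41.79))
  expect_equal(vr$ratio, 0.50, tolerance = 0.011)
  vr2 <- variance_ratios(c(a = 0, d = 22.29, e = 8.07))
  expect_equal(round(vr2$ratio[vr2$component == "d"], 2), 0.73)
  expect_equal(vr2$ratio[vr2$component == "a"], 0)
  expect_error(variance_ratios(c(a = 0, e = 0)), "not positive")
  # delta-method SEs come out of a fit
  pop <- small_pop()
  fit <- fit_mag(pop$pheno$y, pop$X, pop$G)
  vr3 <- variance_ratios(fit)
  expect_true(is.finite(vr3$se_ratio))
  expect_true(vr3$ratio >= 0 && vr3$ratio <= 1)
})

test_that("a zero-variance genetic term sits at the boundary in most replicates", {
  pop <- small_pop()                    # additive-only truth: sigma2_d = 0
  at_zero <- 0
  for (s in 101:107) {
    ph <- simulate_phenotypes(pop$pop, seed = s)
    fit <- fit_madg(ph$pheno$y, pop$X, pop$G, pop$D)
    expect_true(fit$converged)
    if (fit$sigma2[["d"]] == 0) {
      at_zero <- at_zero + 1
      expect_true(fit$pinned[["d"]])
      expect_true(is.finite(fit$se[["d"]]))  # SE reported, AI convention
      # with d on the boundary the additive estimates coincide with MAG
      mag <- fit_mag(ph$pheno$y, pop$X, pop$G)
      expect_equal(fit$sigma2[["a"]], mag$sigma2[["a"]], tolerance = 1e-3)
    }
  }
  expect_gte(at_zero, 4)                # the majority of 7 replicates
})
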