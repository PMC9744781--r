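# Independent oracles: stats::aov (classical univariate RM decomposition),
# an explicit design-matrix GLM projection, and numerical quadrature for the
# studentized-range distribution.

rand_design <- function(n, levels, seed) {
  set.seed(seed)
  fac_names <- paste0("f", seq_along(levels))
  grid <- do.call(expand.grid, c(
    list(subject = factor(seq_len(n))),
    stats::setNames(lapply(levels, function(k) factor(seq_len(k))),
                    fac_names)
  ))
  grid$y <- rnorm(nrow(grid)) +
    rowSums(vapply(fac_names, function(f) as.numeric(grid[[f]]),
                   numeric(nrow(grid)))) * 0.4
  grid
}

test_that("rm_anova matches the aov error-stratum decomposition", {
  cases <- list(list(n = 8, levels = 3, seed = 1),
                list(n = 10, levels = c(3, 2), seed = 2),
                list(n = 6, levels = c(2, 2, 2), seed = 3),
                list(n = 12, levels = c(4, 3), seed = 4))
  for (cs in cases) {
    d <- rand_design(cs$n, cs$levels, cs$seed)
    within <- grep("^f", names(d), value = TRUE)
    mine <- tidy(rm_anova(d, "y", within))
    form <- stats::as.formula(paste(
      "y ~", paste(within, collapse = "*"),
      "+ Error(subject/(", paste(within, collapse = "*"), "))"
    ))
    ref <- summary(stats::aov(form, data = d))
    for (i in seq_len(nrow(mine))) {
      eff <- mine$effect[i]
      stratum <- ref[[paste0("Error: subject:", eff)]][[1]]
      expect_equal(mine$F[i], stratum$`F value`[1], tolerance = 1e-8)
      expect_equal(mine$df_num[i], stratum$Df[1])
      expect_equal(mine$df_den[i], stratum$Df[2])
      expect_equal(mine$ss_num[i], stratum$`Sum Sq`[1], tolerance = 1e-8)
      expect_equal(mine$ss_den[i], stratum$`Sum Sq`[2], tolerance = 1e-8)
      expect_equal(mine$p[i], stratum$`Pr(>F)`[1], tolerance = 1e-8)
    }
  }
})

test_that("rm_anova matches a brute-force GLM projection", {
  d <- rand_design(10, 4, seed = 11)
  mine <- tidy(rm_anova(d, "y", "f1"))
  rss <- function(X, y) {
    H <- X %*% solve(crossprod(X), t(X))
    sum((y - H %*% y)^2)
  }
  X_full <- stats::model.matrix(~ subject * f1, d)
  X_nofx <- stats::model.matrix(~ subject, d)
  X_add <- stats::model.matrix(~ subject + f1, d)
  ss_eff <- rss(X_nofx, d$y) - rss(X_add, d$y)
  ss_err <- rss(X_add, d$y) - rss(X_full, d$y)  # subject x f1 interaction
  Fo <- (ss_eff / 3) / (ss_err / 27)
  expect_equal(mine$F, Fo, tolerance = 1e-8)
  expect_equal(mine$ss_num, ss_eff, tolerance = 1e-8)
  expect_equal(mine$ss_den, ss_err, tolerance = 1e-8)
  expect_equal(mine$partial_eta_sq, ss_eff / (ss_eff + ss_err),
               tolerance = 1e-10)
})

test_that("degenerate and invalid designs are handled explicitly", {
  d <- expand.grid(subject = factor(1:6), cond = factor(1:2))
  d$y <- rep(c(1, 2, 3, 1, 2, 3), 2)   # identical across conditions
  res <- tidy(rm_anova(d, "y", "cond"))
  expect_equal(res$F, 0)
  expect_equal(res$partial_eta_sq, 0)
  expect_equal(res$epsilon, 1)          # 2 levels force epsilon = 1
  expect_error(rm_anova(d[-1, ], "y", "cond"), "balanced")
  expect_error(rm_anova(d, "y", "nope"), "not found")
  d1 <- d[d$subject == 1, ]
  expect_error(rm_anova(d1, "y", "cond"), "2 subjects")
})

test_that("Greenhouse-Geisser epsilon hits its closed-form bounds", {
  # compound symmetry -> 1
  S_cs <- matrix(0.3, 4, 4) + diag(0.7, 4)
  expect_equal(gg_epsilon(S_cs), 1)
  # any 2 x 2 covariance -> 1
  expect_equal(gg_epsilon(matrix(c(2, 0.5, 0.5, 1), 2)), 1)
  # rank-1 covariance with k = 3 -> lower bound 1/(k-1) = 0.5
  v <- c(1, -2, 0.5)
  expect_equal(gg_epsilon(v %o% v), 0.5, tolerance = 1e-10)
  expect_error(gg_epsilon(matrix(c(1, 2, 3, 4), 2)), "symmetric")
  # for F >= 1 (the reportable regime), shrinking the dfs by epsilon < 1
  # can only make the p-value more conservative
  d <- rand_design(9, 4, seed = 21)
  tab <- tidy(rm_anova(d, "y", "f1"))
  expect_true(tab$epsilon >= 1 / 3 && tab$epsilon <= 1)
  expect_true(tab$F < 1 || tab$p_adjusted >= tab$p)
  d2 <- rand_design(9, 4, seed = 22)
  d2$y <- d2$y + 0.8 * as.numeric(d2$f1)   # strong effect -> F > 1
  tab2 <- tidy(rm_anova(d2, "y", "f1"))
  expect_gt(tab2$F, 1)
  expect_gte(tab2$p_adjusted, tab2$p)
})

test_that("Tukey HSD agrees with quadrature of the studentized range", {
  # oracle: P(Q >= q) by numerical double integration
  q_surv <- function(q, k, df) {
    inner <- function(s) {
      vapply(s, function(si) {
        f <- function(z) {
          stats::dnorm(z) *
            (stats::pnorm(z) - stats::pnorm(z - q * si))^(k - 1)
        }
        k * stats::integrate(f, -8, 8, rel.tol = 1e-10)$value
      }, numeric(1))
    }
    dens <- function(s) 2 * df * s * stats::dchisq(df * s^2, df)
    1 - stats::integrate(function(s) inner(s) * dens(s), 0, 10,
                         rel.tol = 1e-8)$value
  }
  means <- c(a = 0, b = 0.8, c = 2.1)
  hsd <- tukey_hsd(means, ms_error = 1.3, df_error = 18, n_per_level = 9)
  se <- sqrt(1.3 / 9)
  for (i in seq_len(nrow(hsd))) {
    q <- abs(hsd$difference[i]) / se
    expect_equal(hsd$p_adjusted[i], q_surv(q, 3, 18), tolerance = 1e-4)
  }
})

test_that("Tukey HSD matches TukeyHSD on a balanced one-way design", {
  set.seed(33)
  d <- data.frame(g = factor(rep(letters[1:4], each = 8)),
                  y = rnorm(32) + rep(c(0, 0.5, 1, 1.2), each = 8))
  fit <- stats::aov(y ~ g, data = d)
  ref <- stats::TukeyHSD(fit)$g
  ms <- summary(fit)[[1]]$`Mean Sq`[2]
  mine <- tukey_hsd(tapply(d$y, d$g, mean), ms, df_error = 28,
                    n_per_level = 8)
  key_mine <- paste(mine$level_2, mine$level_1, sep = "-")
  expect_equal(mine$p_adjusted[match(rownames(ref), key_mine)],
               unname(ref[, "p adj"]), tolerance = 1e-8)
})

test_that("Tukey HSD behaves at the edges", {
  means <- c(a = 1, b = 1, c = 1)
  hsd <- tukey_hsd(means, 1, 10, 5)
  expect_true(all(hsd$p_adjusted > 0.999))
  # p decreases monotonically with |difference| at fixed error
  means2 <- c(a = 0, b = 0.5, c = 2, d = 5)
  hsd2 <- tukey_hsd(means2, 1, 20, 6)
  ord <- order(abs(hsd2$difference))
  expect_true(all(diff(hsd2$p_adjusted[ord]) <= 1e-12))
  expect_error(tukey_hsd(means, 1, 0, 5), "df_error")
  expect_error(tukey_hsd(means["a"], 1, 10, 5), "2 levels")
})
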