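# Repeated-measures ANOVA (univariate, fully within-subject), implemented via
# orthonormal effect contrasts: for effect S over factors with levels k_f,
# project each subject's cell vector onto M = kron over factors of
# (orthonormal contrasts C_f if f in S, else the averaging vector 1/k_f).
# Then SS_effect = r * n * sum(colMeans(Z)^2) and SS_error (the effect x
# subject interaction) = r * sum((Z - colMeans)^2), with r the product of the
# levels of the factors averaged over. The Greenhouse-Geisser epsilon of the
# effect comes from the covariance of the same projected scores.

# Orthonormal basis of the centered subspace for a k-level factor.
.orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), `/`)
}

.effect_projection <- function(levels_per_factor, in_effect) {
  mats <- mapply(function(k, inc) {
    if (inc) .orthonormal_contrasts(k) else matrix(1 / k, k, 1)
  }, levels_per_factor, in_effect, SIMPLIFY = FALSE)
  # cells are ordered with the FIRST factor varying fastest
  Reduce(function(a, b) kronecker(b, a), mats)
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity-violation correction factor from the covariance of the
#' condition measures: with `S~` the double-centered covariance (or, when a
#' `contrast` basis is supplied, the contrast-projected covariance `C'SC`),
#' `epsilon = tr(S~)^2 / (d * tr(S~ %*% S~))`, clipped to the theoretical
#' range `[1/(k-1), 1]`. Equals 1 under compound symmetry and for any
#' 2-level factor; reaches the lower bound for a rank-1 covariance.
#'
#' @param condition_covariance symmetric `k x k` covariance matrix of the
#'   within-factor condition measures.
#' @param contrast optional `k x d` orthonormal contrast basis; defaults to
#'   the full centered subspace (`d = k - 1`).
#' @return epsilon in `[1/d, 1]`.
#' @export
gg_epsilon <- function(condition_covariance, contrast = NULL) {
  S <- as.matrix(condition_covariance)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S)))) {
    abort("condition covariance must be a symmetric square matrix")
  }
  k <- nrow(S)
  if (k < 2) abort("need at least 2 conditions")
  if (is.null(contrast)) contrast <- .orthonormal_contrasts(k)
  Sc <- t(contrast) %*% S %*% contrast
  d <- ncol(contrast)
  tr1 <- sum(diag(Sc))
  tr2 <- sum(Sc * Sc)
  if (tr2 <= 0) return(1)
  eps <- tr1^2 / (d * tr2)
  min(1, max(1 / d, eps))
}

#' Repeated-measures ANOVA
#'
#' Univariate repeated-measures analysis of variance for a balanced, fully
#' crossed within-subject design with one observation per subject x cell
#' (subject is the random blocking factor; each effect is tested against its
#' effect-by-subject interaction). For every within effect the result
#' carries F, degrees of freedom, the uncorrected p, the Greenhouse-Geisser
#' epsilon with the epsilon-adjusted p, and partial eta squared
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data long-format data frame / tibble.
#' @param dv name of the dependent-variable column (character).
#' @param within character vector of within-subject factor columns.
#' @param subject name of the subject id column.
#' @return An `erp_anova` object; `tidy()` returns the per-effect tibble
#'   (`effect`, `df_num`, `df_den`, `ss_num`, `ss_den`, `F`, `p`, `epsilon`,
#'   `p_adjusted`, `partial_eta_sq`).
#' @examples
#' d <- expand.grid(subject = factor(1:8), cond = factor(c("a", "b", "c")))
#' d$y <- rnorm(nrow(d)) + as.numeric(d$cond)
#' tidy(rm_anova(d, "y", "cond"))
#' @export
rm_anova <- function(data, dv, within, subject = "subject") {
  data <- as.data.frame(data)
  for (col in c(dv, within, subject)) {
    if (!col %in% names(data)) abort(paste0("column '", col, "' not found"))
  }
  subj <- factor(data[[subject]])
  facs <- lapply(data[within], factor)
  levs <- lapply(facs, levels)
  k <- vapply(levs, length, integer(1))
  n <- nlevels(subj)
  if (n < 2) abort("need at least 2 subjects")
  n_cells <- prod(k)
  # cell index with the first factor varying fastest
  cell <- Reduce(`+`, mapply(function(f, mult) (as.integer(f) - 1L) * mult,
                             facs, cumprod(c(1, utils::head(k, -1))),
                             SIMPLIFY = FALSE)) + 1L
  counts <- table(factor(as.integer(subj), levels = seq_len(n)),
                  factor(cell, levels = seq_len(n_cells)))
  if (any(counts != 1)) {
    abort("design must be balanced and fully crossed: exactly one observation per subject x cell")
  }
  Y <- matrix(NA_real_, n, n_cells)
  Y[cbind(as.integer(subj), cell)] <- data[[dv]]
  effects <- unlist(lapply(seq_along(within), function(m) {
    utils::combn(within, m, simplify = FALSE)
  }), recursive = FALSE)
  rows <- lapply(effects, function(eff) {
    in_eff <- within %in% eff
    M <- .effect_projection(k, in_eff)
    r <- prod(k[!in_eff])
    Z <- Y %*% M
    zbar <- colMeans(Z)
    d1 <- ncol(M)
    ss_num <- r * n * sum(zbar^2)
    ss_den <- r * sum(sweep(Z, 2, zbar)^2)
    d2 <- (n - 1) * d1
    Fv <- if (ss_den > 0) (ss_num / d1) / (ss_den / d2) else 0
    eps <- if (d1 == 1) 1 else {
      Sc <- stats::cov(Z)
      tr2 <- sum(Sc * Sc)
      if (tr2 <= 0) 1 else min(1, max(1 / d1, sum(diag(Sc))^2 / (d1 * tr2)))
    }
    tibble::tibble(
      effect = paste(eff, collapse = ":"),
      df_num = d1, df_den = d2, ss_num = ss_num, ss_den = ss_den,
      F = Fv,
      p = stats::pf(Fv, d1, d2, lower.tail = FALSE),
      epsilon = eps,
      p_adjusted = stats::pf(Fv, eps * d1, eps * d2, lower.tail = FALSE),
      partial_eta_sq = if (ss_num + ss_den > 0) ss_num / (ss_num + ss_den)
                       else 0
    )
  })
  structure(
    list(table = dplyr::bind_rows(rows), dv = dv, within = within,
         n_subjects = n, levels = levs),
    class = "erp_anova"
  )
}

#' @export
print.erp_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA on '", x$dv, "' (n = ", x$n_subjects,
      " subjects)\n", sep = "")
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %s: F(%g, %g) = %.2f, p = %.4g; eps = %.2f, adj p = %.4g; pes = %.2f\n",
                tab$effect[i], tab$df_num[i], tab$df_den[i], tab$F[i],
                tab$p[i], tab$epsilon[i], tab$p_adjusted[i],
                tab$partial_eta_sq[i]))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.erp_anova <- function(x, ...) x$table

#' @export
glance.erp_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects,
                 n_effects = nrow(x$table),
                 dv = x$dv)
}

#' Tukey HSD post hoc comparisons
#'
#' All-pairs comparisons of level means using the studentized-range
#' distribution: `q = |m_i - m_j| / sqrt(ms_error / n_per_level)`, adjusted
#' `p = P(Q(k, df) >= q)`. When used after [rm_anova()], `ms_error` and
#' `df_error` are the error term of the factor under test (its
#' subject-interaction mean square).
#'
#' @param level_means named numeric vector of level means.
#' @param ms_error error mean square.
#' @param df_error error degrees of freedom.
#' @param n_per_level observations per level mean.
#' @return A tibble `level_1, level_2, difference, p_adjusted` (difference =
#'   mean(level_1) - mean(level_2)).
#' @export
tukey_hsd <- function(level_means, ms_error, df_error, n_per_level) {
  if (df_error <= 0) abort("df_error must be positive")
  if (ms_error <= 0) abort("ms_error must be positive")
  k <- length(level_means)
  if (k < 2) abort("need at least 2 levels")
  nm <- names(level_means) %||% as.character(seq_len(k))
  level_means <- as.numeric(level_means)  # tapply results are 1-d arrays
  se <- sqrt(ms_error / n_per_level)
  pairs <- utils::combn(k, 2)
  diffs <- level_means[pairs[1, ]] - level_means[pairs[2, ]]
  q <- abs(diffs) / se
  tibble::tibble(
    level_1 = nm[pairs[1, ]],
    level_2 = nm[pairs[2, ]],
    difference = unname(diffs),
    p_adjusted = unname(stats::ptukey(q, nmeans = k, df = df_error,
                                      lower.tail = FALSE))
  )
}
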