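#' Statistical test report
#'
#' Lightweight container for one test: statistic, degrees of freedom,
#' p-value, an effect size with its name, and a confidence interval where one
#' is defined.
#' @param test,statistic,df,p.value,effect,effect_name,conf.int,note fields.
#' @return class `stat_report`.
#' @keywords internal
stat_report <- function(test, statistic = NA_real_, df = NA_real_,
                        p.value = NA_real_, effect = NA_real_,
                        effect_name = NA_character_, conf.int = NULL,
                        note = NULL) {
  structure(list(test = test, statistic = statistic, df = df,
                 p.value = p.value, effect = effect,
                 effect_name = effect_name, conf.int = conf.int, note = note),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat("<stat_report>", x$test, "\n")
  cat(sprintf("  statistic = %.4f%s, p = %.4g\n", x$statistic,
              if (is.finite(x$df)) paste0(", df = ", x$df) else "", x$p.value))
  if (is.finite(x$effect))
    cat(sprintf("  %s = %.4f\n", x$effect_name, x$effect))
  if (!is.null(x$conf.int))
    cat(sprintf("  95%% CI: %.4f to %.4f\n", x$conf.int[1], x$conf.int[2]))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Cochran's Q test for k matched binary outcomes
#'
#' Tests marginal homogeneity of k related proportions (here: lesion status
#' under the Liberal, Traditional and Restrictive definitions). With column
#' totals Cj, row totals Ri and N the grand total,
#' `Q = (k-1) * (k * sum(Cj^2) - N^2) / (k * sum(Ri) - sum(Ri^2))`,
#' referred to chi-square with k-1 df. Rows with all-equal responses
#' contribute nothing; if every row is constant, Q is defined as 0 with
#' p = 1. At k = 2 the statistic equals the uncorrected McNemar statistic.
#'
#' @param m n x k binary (0/1 or logical) matrix, subjects in rows.
#' @return a `stat_report` (effect: Kendall's W-style `Q/(n(k-1))`).
#' @export
cochran_q <- function(m) {
  m <- as.matrix(m) * 1
  if (!all(m %in% c(0, 1))) stop("cochran_q: matrix must be binary")
  n <- nrow(m); k <- ncol(m)
  if (k < 2L) stop("cochran_q: need k >= 2 conditions")
  if (n < 1L) stop("cochran_q: need at least one subject")
  Cj <- colSums(m); Ri <- rowSums(m); N <- sum(Cj)
  den <- k * sum(Ri) - sum(Ri^2)
  if (den == 0) {
    return(stat_report("Cochran's Q", statistic = 0, df = k - 1, p.value = 1,
                       effect = 0, effect_name = "Q/(n(k-1))",
                       note = "all rows constant"))
  }
  Q <- (k - 1) * (k * sum(Cj^2) - N^2) / den
  stat_report("Cochran's Q", statistic = Q, df = k - 1,
              p.value = pchisq(Q, k - 1, lower.tail = FALSE),
              effect = Q / (n * (k - 1)), effect_name = "Q/(n(k-1))")
}

#' Friedman test with Kendall's W
#'
#' Friedman rank test for k related samples with average-rank tie handling
#' and the standard tie correction; Kendall's coefficient of concordance is
#' derived as `W = Q / (n * (k - 1))`.
#'
#' @param m n x k numeric matrix (subjects x conditions).
#' @return a `stat_report` with Kendall's W as the effect size.
#' @export
friedman_kendall <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (k < 2L) stop("friedman_kendall: need k >= 2 conditions")
  if (n < 2L) stop("friedman_kendall: need n >= 2 subjects")
  rk <- t(apply(m, 1, rank))
  Rj <- colSums(rk)
  Q0 <- 12 * sum((Rj - n * (k + 1) / 2)^2) / (n * k * (k + 1))
  tie_sum <- sum(apply(m, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  }))
  corr <- 1 - tie_sum / (n * k * (k^2 - 1))
  if (corr <= 0) {
    return(stat_report("Friedman", statistic = 0, df = k - 1, p.value = 1,
                       effect = 0, effect_name = "Kendall's W",
                       note = "all rows fully tied"))
  }
  Q <- Q0 / corr
  stat_report("Friedman", statistic = Q, df = k - 1,
              p.value = pchisq(Q, k - 1, lower.tail = FALSE),
              effect = Q / (n * (k - 1)), effect_name = "Kendall's W")
}

#' Kendall's W from a Friedman statistic
#'
#' `W = Q / (n * (k - 1))`, the concordance effect size paired with the
#' Friedman test.
#' @param Q Friedman chi-square statistic.
#' @param n number of subjects.
#' @param k number of conditions.
#' @return numeric W in \[0, 1\].
#' @export
kendall_w <- function(Q, n, k = 3) Q / (n * (k - 1))

#' 2x2 chi-square test with Cramer's phi
#'
#' Pearson chi-square on a 2x2 table, with the Yates continuity correction by
#' default, and `phi = sqrt(X^2 / N)`.
#'
#' @param table 2x2 non-negative integer matrix.
#' @param yates apply the continuity correction (default TRUE).
#' @return a `stat_report` with phi as the effect size.
#' @export
chi2_2x2 <- function(table, yates = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("chi2_2x2: need a 2x2 table")
  if (any(table < 0)) stop("chi2_2x2: negative cell counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi2_2x2: degenerate table (zero margin)")
  res <- suppressWarnings(chisq.test(table, correct = yates))
  N <- sum(table)
  stat_report(paste0("Chi-squared (2x2", if (yates) ", Yates", ")"),
              statistic = unname(res$statistic), df = unname(res$parameter),
              p.value = res$p.value,
              effect = sqrt(unname(res$statistic) / N),
              effect_name = "Cramer's phi")
}

#' Cramer's phi from a chi-square statistic
#' @param x2 chi-square statistic.
#' @param n total sample size.
#' @return `sqrt(x2 / n)`.
#' @export
cramers_phi <- function(x2, n) sqrt(x2 / n)

# conditional noncentral hypergeometric machinery for a 2x2 table
# [[a, b], [c, d]] conditioned on both margins; x = top-left cell
.cnh_support <- function(r1, r2, c1) max(0L, c1 - r2):min(r1, c1)
.cnh_logw <- function(x, r1, r2, c1, log_psi) {
  lchoose(r1, x) + lchoose(r2, c1 - x) + x * log_psi
}
.cnh_mean <- function(r1, r2, c1, log_psi) {
  x <- .cnh_support(r1, r2, c1)
  lw <- .cnh_logw(x, r1, r2, c1, log_psi)
  w <- exp(lw - max(lw))
  sum(x * w) / sum(w)
}

#' Fisher's exact test with conditional-MLE odds ratio
#'
#' Two-sided exact p-value by summing hypergeometric probabilities no larger
#' than that of the observed table, and the odds ratio estimated as the
#' conditional maximum-likelihood value: the psi maximizing the noncentral
#' hypergeometric likelihood given both margins, found by solving
#' `E[X | psi] = a`. When the observed cell sits on the boundary of its
#' support (a zero cell that makes the estimate 0 or unbounded) the odds
#' ratio is reported as `NA` with a note.
#'
#' @param table 2x2 non-negative integer matrix.
#' @return a `stat_report`; `effect` is the conditional-MLE odds ratio.
#' @export
fisher_exact <- function(table) {
  table <- round(as.matrix(table))
  if (!all(dim(table) == 2L)) stop("fisher_exact: need a 2x2 table")
  if (any(table < 0)) stop("fisher_exact: negative cell counts")
  a <- table[1, 1]
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ]); c1 <- sum(table[, 1])
  supp <- .cnh_support(r1, r2, c1)
  d <- stats::dhyper(supp, c1, r1 + r2 - c1, r1)
  p <- sum(d[d <= d[match(a, supp)] * (1 + 1e-7)])
  p <- min(1, p)
  if (length(supp) == 1L) {
    return(stat_report("Fisher's exact", p.value = 1, effect = NA_real_,
                       effect_name = "conditional MLE odds ratio",
                       note = "degenerate margins"))
  }
  if (a == min(supp) || a == max(supp)) {
    return(stat_report("Fisher's exact", p.value = p, effect = NA_real_,
                       effect_name = "conditional MLE odds ratio",
                       note = "odds ratio unbounded (observed cell on support boundary)"))
  }
  root <- uniroot(function(lp) .cnh_mean(r1, r2, c1, lp) - a,
                  lower = -35, upper = 35, tol = 1e-10)
  stat_report("Fisher's exact", p.value = p, effect = exp(root$root),
              effect_name = "conditional MLE odds ratio")
}

# exact Mann-Whitney U null distribution (no ties): number of ways to choose
# n1 of the ranks 1..N with each rank-sum, by subset-sum dynamic programming;
# U = rank-sum - n1(n1+1)/2
.mwu_exact_counts <- function(n1, n2) {
  N <- n1 + n2
  smax <- sum((N - n1 + 1):N)
  f <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  f[1L, 1L] <- 1
  for (r in seq_len(N)) {
    for (j in rev(seq_len(min(r, n1)))) {
      idx <- (r + 1L):(smax + 1L)
      f[j + 1L, idx] <- f[j + 1L, idx] + f[j, idx - r]
    }
  }
  smin <- n1 * (n1 + 1) / 2
  f[n1 + 1L, (smin + 1L):(smax + 1L)]   # counts for U = 0 .. n1*n2
}

#' Mann-Whitney U test with r effect size
#'
#' Rank-sum test with a tie-corrected normal approximation for the p-value
#' (continuity-corrected by default, matching common software) and the
#' effect size `r = |Z| / sqrt(n1 + n2)` computed from the uncorrected Z.
#' With `exact = TRUE` (tie-free data only) the p-value is instead taken
#' from the exact permutation null distribution of U.
#'
#' @param x,y non-empty numeric samples.
#' @param continuity apply the 0.5 continuity correction (default TRUE).
#' @param exact use the exact null distribution of U (requires no ties).
#' @return a `stat_report`; `statistic` is U for the first sample.
#' @export
mann_whitney_r <- function(x, y, continuity = TRUE, exact = FALSE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 < 1L || n2 < 1L) stop("mann_whitney_r: both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
  if (exact) {
    if (any(ties > 1)) stop("exact p-value requires tie-free data")
    cnt <- .mwu_exact_counts(n1, n2)
    u_all <- 0:(n1 * n2)
    pr <- cnt / sum(cnt)
    p <- sum(pr[abs(u_all - mu) >= abs(U - mu) - 1e-9])
  } else {
    zc <- if (sigma2 > 0)
      (U - mu - sign(U - mu) * if (continuity) 0.5 else 0) / sqrt(sigma2) else 0
    p <- min(1, 2 * pnorm(-abs(zc)))
  }
  stat_report(paste0("Mann-Whitney U", if (exact) " (exact)"),
              statistic = U, p.value = p,
              effect = abs(z) / sqrt(N), effect_name = "r = |Z|/sqrt(N)")
}

#' Spearman correlation screen
#'
#' Zero-order Spearman rank correlations (average-rank ties) over all pairs
#' of the requested variables on pairwise-complete observations, with
#' per-pair uncorrected p-values and significance flags at `alpha` (no
#' multiple-comparison correction, by design). Pairs with a constant
#' variable or fewer than 3 complete observations are flagged `NA`.
#'
#' @param table data.frame.
#' @param variables character vector of numeric column names.
#' @param alpha flag threshold (default 0.05).
#' @return class `spearman_screen`: list of matrices `rho`, `p`, `n`,
#'   `significant`.
#' @export
spearman_screen <- function(table, variables, alpha = 0.05) {
  v <- length(variables)
  rho <- p <- nmat <- matrix(NA_real_, v, v, dimnames = list(variables, variables))
  for (i in seq_len(v)) {
    rho[i, i] <- 1
    for (j in seq_len(v)) {
      if (j <= i) next
      xi <- table[[variables[i]]]; xj <- table[[variables[j]]]
      ok <- complete.cases(xi, xj)
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 3L || sd(xi[ok]) == 0 || sd(xj[ok]) == 0) next
      ct <- suppressWarnings(cor.test(xi[ok], xj[ok], method = "spearman",
                                      exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(rho = rho, p = p, n = nmat,
                 significant = !is.na(p) & p < alpha, alpha = alpha),
            class = "spearman_screen")
}

#' @export
print.spearman_screen <- function(x, digits = 2, ...) {
  cat("<spearman_screen> rho (", sum(x$significant, na.rm = TRUE) / 2,
      " pairs flagged at p < ", x$alpha, ", uncorrected)\n", sep = "")
  print(round(x$rho, digits))
  invisible(x)
}

#' Impute group means for missing values
#'
#' Replaces missing entries of `variable` with the mean of the observed
#' values in the same group.
#'
#' @param table data.frame.
#' @param variable column to impute.
#' @param group_var grouping column (default `"group"`).
#' @param groups restrict imputation to these group levels (default: all).
#' @return the table with imputations applied; the number imputed per group
#'   is recorded in `attr(, "n_imputed")`.
#' @export
impute_group_mean <- function(table, variable, group_var = "group",
                              groups = NULL) {
  if (is.null(groups)) groups <- unique(table[[group_var]])
  counts <- integer(0)
  for (g in groups) {
    sel <- table[[group_var]] == g
    miss <- sel & is.na(table[[variable]])
    if (!any(miss)) { counts[as.character(g)] <- 0L; next }
    obs <- table[[variable]][sel & !is.na(table[[variable]])]
    if (!length(obs))
      stop("impute_group_mean: group '", g, "' has no observed values for ",
           variable)
    table[[variable]][miss] <- mean(obs)
    counts[as.character(g)] <- sum(miss)
  }
  attr(table, "n_imputed") <- counts
  table
}

#' Group comparison summary (demographics and cognition)
#'
#' Per-variable descriptives and the matching between-group test: chi-square
#' with phi for sex, Mann-Whitney with `r = |Z|/sqrt(N)` for ordinal or
#' skewed variables (age, education decile, SpO2), Welch t-tests with
#' pooled-SD Cohen's d for the cognitive indices, and Fisher's exact test
#' with conditional-MLE odds ratio for impairment.
#'
#' @param table an `sci_cohort`-style data.frame (columns `group`, `sex`,
#'   `age_years`, `education_decile`, `spo2`, `iq`, `wmi`, `psi`,
#'   `impaired`).
#' @param group_levels the two group labels; the first is the patient group.
#' @return data.frame with one row per comparison.
#' @export
group_summary <- function(table, group_levels = c("SCA", "control")) {
  g1 <- table[table$group == group_levels[1], , drop = FALSE]
  g2 <- table[table$group == group_levels[2], , drop = FALSE]
  if (!nrow(g1) || !nrow(g2)) stop("group_summary: both groups must be non-empty")
  rows <- list()
  add <- function(variable, test, statistic, p, effect_name, effect,
                  sum1, sum2) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, test = test, statistic = statistic, p.value = p,
      effect_name = effect_name, effect = effect,
      group1 = sum1, group2 = sum2, stringsAsFactors = FALSE)
  }
  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  if ("sex" %in% names(table)) {
    tab <- table(table$group == group_levels[1], table$sex)
    r <- safe(chi2_2x2(tab))
    if (!is.null(r))
      add("sex", r$test, r$statistic, r$p.value, r$effect_name, r$effect,
          sprintf("%d M (%.1f%%)", sum(g1$sex == "M"), 100 * mean(g1$sex == "M")),
          sprintf("%d M (%.1f%%)", sum(g2$sex == "M"), 100 * mean(g2$sex == "M")))
  }
  for (v in intersect(c("age_years", "education_decile", "spo2"), names(table))) {
    r <- safe(mann_whitney_r(g1[[v]], g2[[v]]))
    if (is.null(r)) next
    add(v, r$test, r$statistic, r$p.value, r$effect_name, r$effect,
        sprintf("%.2f (%.0f-%.0f)", median(g1[[v]], na.rm = TRUE),
                min(g1[[v]], na.rm = TRUE), max(g1[[v]], na.rm = TRUE)),
        sprintf("%.2f (%.0f-%.0f)", median(g2[[v]], na.rm = TRUE),
                min(g2[[v]], na.rm = TRUE), max(g2[[v]], na.rm = TRUE)))
  }
  for (v in intersect(c("iq", "wmi", "psi"), names(table))) {
    x1 <- g1[[v]]; x2 <- g2[[v]]
    tt <- safe(t.test(x2, x1))            # Welch; positive t = controls higher
    if (is.null(tt)) next
    sp <- sqrt(((length(x1) - 1) * stats::var(x1) +
                  (length(x2) - 1) * stats::var(x2)) /
                 (length(x1) + length(x2) - 2))
    d <- (mean(x2) - mean(x1)) / sp
    add(v, "Welch t", unname(tt$statistic), tt$p.value, "Cohen's d", d,
        sprintf("%.2f (%.2f)", mean(x1), sd(x1)),
        sprintf("%.2f (%.2f)", mean(x2), sd(x2)))
  }
  if ("impaired" %in% names(table)) {
    tab <- matrix(c(sum(g1$impaired), sum(!g1$impaired),
                    sum(g2$impaired), sum(!g2$impaired)), 2, byrow = TRUE)
    r <- safe(fisher_exact(tab))
    if (!is.null(r))
      add("impaired", r$test, NA_real_, r$p.value, r$effect_name, r$effect,
          sprintf("%d (%.1f%%)", sum(g1$impaired), 100 * mean(g1$impaired)),
          sprintf("%d (%.1f%%)", sum(g2$impaired), 100 * mean(g2$impaired)))
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "group1"] <- group_levels[1]
  names(out)[names(out) == "group2"] <- group_levels[2]
  out
}
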