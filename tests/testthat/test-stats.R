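# the statistics battery: formulas checked against independent derivations

test_that("Cochran's Q matches the nested matrices implied by printed counts", {
  q_sca <- cochran_q(nested_matrix(106, c(45, 42, 25)))
  expect_equal(round(q_sca$statistic, 2), 34.90)
  expect_equal(q_sca$df, 2)
  q_hc <- cochran_q(nested_matrix(48, c(11, 5, 2)))
  expect_equal(round(q_hc$statistic, 2), 14.00)
  # all-constant rows: Q defined as 0, p = 1
  q0 <- cochran_q(rbind(matrix(1, 5, 3), matrix(0, 4, 3)))
  expect_equal(q0$statistic, 0)
  expect_equal(q0$p.value, 1)
})

test_that("Cochran's Q is row-order invariant and equals an independent derivation", {
  # independent route: Q = k(k-1) * sum((Cj - Nbar)^2) / sum(Ri * (k - Ri))
  q_alt <- function(m) {
    k <- ncol(m); Cj <- colSums(m); Ri <- rowSums(m)
    k * (k - 1) * sum((Cj - mean(Cj))^2) / sum(Ri * (k - Ri))
  }
  set.seed(53)
  for (rep in 1:20) {
    m <- matrix(rbinom(30, 1, 0.5), 10, 3)
    if (all(rowSums(m) %in% c(0, 3))) m[1, ] <- c(1, 0, 0)
    expect_equal(cochran_q(m)$statistic, q_alt(m))
    expect_equal(cochran_q(m[sample(10), ])$statistic, cochran_q(m)$statistic)
  }
  # k = 2: Q equals the uncorrected McNemar statistic on discordant pairs
  for (rep in 1:10) {
    m <- matrix(rbinom(24, 1, 0.5), 12, 2)
    disc <- m[m[, 1] != m[, 2], , drop = FALSE]
    if (!nrow(disc)) next
    b <- sum(disc[, 1] == 1); c <- sum(disc[, 2] == 1)
    expect_equal(cochran_q(m)$statistic, (b - c)^2 / (b + c))
  }
})

test_that("Kendall's W reproduces the printed Friedman effect sizes", {
  expect_equal(round(kendall_w(76.80, 106), 2), 0.36)
  expect_equal(round(kendall_w(19.50, 48), 2), 0.20)
  # perfectly concordant untied rankings give W = 1
  m <- matrix(rep(c(3, 2, 1), each = 8), 8, 3) + matrix(rnorm(24, 0, 1e-6), 8, 3)
  f <- friedman_kendall(m)
  expect_equal(f$effect, 1, tolerance = 1e-9)
  # tie-free data agree with the base Friedman test
  set.seed(5)
  m2 <- matrix(rnorm(30), 10, 3)
  expect_equal(friedman_kendall(m2)$statistic,
               unname(stats::friedman.test(m2)$statistic))
})

test_that("Yates chi-square and phi reproduce the printed between-group tests", {
  r <- chi2_2x2(rbind(c(45, 61), c(11, 37)))
  expect_equal(round(r$statistic, 2), 4.64)
  expect_equal(round(r$effect, 2), 0.17)
  expect_equal(round(cramers_phi(11.90, 154), 2), 0.28)
  # identical row proportions: statistic 0 (uncorrected)
  expect_equal(chi2_2x2(rbind(c(20, 40), c(10, 20)), yates = FALSE)$statistic, 0)
  expect_error(chi2_2x2(rbind(c(0, 0), c(1, 2))), "zero margin")
})

test_that("Fisher conditional-MLE odds ratio matches the printed value and flags zeros", {
  r <- fisher_exact(rbind(c(25, 81), c(2, 46)))
  expect_equal(round(r$effect, 2), 7.03)
  # cross-check against the reference conditional estimator
  ft <- stats::fisher.test(rbind(c(25, 81), c(2, 46)))
  expect_equal(r$effect, unname(ft$estimate), tolerance = 1e-4)
  expect_equal(r$p.value, ft$p.value, tolerance = 1e-8)
  # zero cell: OR unbounded, reported NA
  rz <- fisher_exact(rbind(c(12, 94), c(0, 48)))
  expect_true(is.na(rz$effect))
  expect_match(rz$note, "unbounded")
  # identical rows: OR 1, p 1
  ri <- fisher_exact(rbind(c(7, 13), c(7, 13)))
  expect_equal(ri$effect, 1, tolerance = 1e-8)
  expect_equal(ri$p.value, 1)
})

test_that("the conditional MLE maximizes the noncentral hypergeometric likelihood", {
  loglik <- function(psi, tab) {
    a <- tab[1, 1]; r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
    x <- max(0, c1 - r2):min(r1, c1)
    lw <- lchoose(r1, x) + lchoose(r2, c1 - x) + x * log(psi)
    (lchoose(r1, a) + lchoose(r2, c1 - a) + a * log(psi)) -
      (max(lw) + log(sum(exp(lw - max(lw)))))
  }
  set.seed(71)
  for (rep in 1:10) {
    tab <- matrix(rpois(4, 8) + 1, 2)
    est <- fisher_exact(tab)$effect
    grid <- exp(seq(log(est) - 2, log(est) + 2, length.out = 801))
    ll <- vapply(grid, loglik, numeric(1), tab = tab)
    expect_lt(abs(log(grid[which.max(ll)]) - log(est)), 0.01)
  }
})

test_that("Mann-Whitney U behaves at the extremes and matches full enumeration", {
  set.seed(3)
  x <- rnorm(2000); y <- rnorm(2000)
  expect_lt(mann_whitney_r(x, y)$effect, 0.05)  # null: r near 0
  # complete separation: U = n1 * n2
  expect_equal(mann_whitney_r(11:16, 1:5)$statistic, 30)
  # exact p equals brute-force enumeration over all assignments
  for (n in c(5, 6, 7)) {
    x <- rnorm(n); y <- rnorm(n)
    got <- mann_whitney_r(x, y, exact = TRUE)$p.value
    pool <- c(x, y); N <- 2 * n
    u_obs <- mann_whitney_r(x, y)$statistic
    mu <- n * n / 2
    combs <- utils::combn(N, n)
    us <- apply(combs, 2, function(ix)
      sum(rank(pool)[ix]) - n * (n + 1) / 2)
    p_brute <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
    expect_equal(got, p_brute)
    # and the reference implementation agrees
    expect_equal(got, stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("Spearman screen matches the direct rank formula and flags nulls", {
  set.seed(9)
  df <- data.frame(a = 1:20, b = (1:20)^2, c = rnorm(20))
  sc <- spearman_screen(df, c("a", "b", "c"))
  expect_equal(sc$rho["a", "b"], 1)       # perfectly monotone
  # direct computation with average ranks
  brute_rho <- cor(rank(df$a), rank(df$c))
  expect_equal(sc$rho["a", "c"], brute_rho)
  # independent large-sample pairs: near-zero correlation
  big <- data.frame(x = rnorm(1e4), y = rnorm(1e4))
  expect_lt(abs(spearman_screen(big, c("x", "y"))$rho["x", "y"]), 0.03)
  # constant variable flagged undefined
  dfc <- data.frame(u = rep(1, 10), v = rnorm(10))
  expect_true(is.na(spearman_screen(dfc, c("u", "v"))$rho["u", "v"]))
})

test_that("group-mean imputation fills each group's missing values with its own mean", {
  df <- data.frame(group = c("A", "A", "A", "B", "B"),
                   hb = c(90, 100, NA, 50, NA))
  out <- impute_group_mean(df, "hb")
  expect_equal(out$hb, c(90, 100, 95, 50, 50))
  expect_equal(unname(attr(out, "n_imputed")), c(1L, 1L))
  # no missing values: identity
  df2 <- data.frame(group = "A", hb = c(1, 2))
  expect_equal(impute_group_mean(df2, "hb")$hb, c(1, 2))
  expect_error(impute_group_mean(data.frame(group = "A", hb = NA_real_), "hb"),
               "no observed values")
})

test_that("group summary recovers the configured cognitive effect sizes", {
  # identical groups: d = 0 and p near 1
  set.seed(77)
  base <- data.frame(group = rep(c("SCA", "control"), each = 40),
                     iq = rep(rnorm(40, 95, 12), 2),
                     wmi = rep(rnorm(40, 95, 12), 2),
                     psi = rep(rnorm(40, 95, 12), 2))
  gs <- group_summary(base)
  expect_true(all(abs(gs$effect[gs$variable %in% c("iq", "wmi", "psi")]) < 1e-12))
  # pooled-SD Cohen's d from the configured means/SDs at large n
  spec <- cohort_spec(n_sca = 4e4L, n_control = 4e4L, seed = 31L)
  tab <- generate_cohort(spec)
  gs2 <- group_summary(tab)
  d_iq <- gs2$effect[gs2$variable == "iq"]
  expect_equal(d_iq, 0.33, tolerance = 0.03)
  # Welch statistic agrees with the closed form on unequal variances
  x1 <- tab$iq[tab$group == "SCA"]; x2 <- tab$iq[tab$group == "control"]
  tw <- (mean(x2) - mean(x1)) /
    sqrt(var(x1) / length(x1) + var(x2) / length(x2))
  expect_equal(gs2$statistic[gs2$variable == "iq"], tw, tolerance = 1e-9)
})
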