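log2_mat <- function(m) {
  dimnames(m) <- list(sprintf("g%d", seq_len(nrow(m))),
                      sprintf("s%d", seq_len(ncol(m))))
  expression_matrix(m, "log2")
}

test_that("two-group ANOVA reduces to the squared t statistic", {
  set.seed(1)
  m <- log2_mat(matrix(rnorm(20 * 24), 20, 24))
  g <- rep(1:2, each = 12)
  an <- stage_anova(m, g)
  for (i in c(1, 7, 20)) {
    tt <- t.test(unclass(m)[i, g == 2], unclass(m)[i, g == 1],
                 var.equal = TRUE)
    expect_equal(an$f[i], unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(an$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("a constant gene yields a null ANOVA record", {
  m <- log2_mat(rbind(rep(1, 12), rnorm(12)))
  an <- stage_anova(m, rep(1:3, each = 4))
  expect_true(is.na(an$p[1]))
  expect_false(is.na(an$p[2]))
})

test_that("ANOVA matches aov and Tukey matches TukeyHSD", {
  set.seed(3)
  g <- factor(rep(1:4, times = c(10, 8, 7, 5)))
  m <- log2_mat(matrix(rnorm(3 * 30), 3, 30))
  an <- stage_anova(m, g)
  tk <- tukey_pairwise(m, g)
  for (i in 1:3) {
    df <- data.frame(y = unclass(m)[i, ], g = g)
    fit <- aov(y ~ g, df)
    expect_equal(an$p[i], summary(fit)[[1]][["Pr(>F)"]][1],
                 tolerance = 1e-10)
    th <- TukeyHSD(fit)$g
    expect_equal(tk[["1-2"]]$p_adj[i], th["2-1", "p adj"], tolerance = 1e-8)
    expect_equal(tk[["3-4"]]$p_adj[i], th["4-3", "p adj"], tolerance = 1e-8)
  }
})

test_that("balanced two-group Tukey equals the pooled t-test", {
  set.seed(4)
  m <- log2_mat(matrix(rnorm(5 * 20), 5, 20))
  g <- rep(1:2, each = 10)
  tk <- tukey_pairwise(m, g)[["1-2"]]
  for (i in 1:5) {
    tt <- t.test(unclass(m)[i, g == 2], unclass(m)[i, g == 1],
                 var.equal = TRUE)
    expect_equal(tk$p_adj[i], tt$p.value, tolerance = 1e-8)
  }
})

test_that("Tukey-adjusted p is never below the unadjusted pairwise p", {
  set.seed(5)
  m <- log2_mat(matrix(rnorm(10 * 30), 10, 30))
  g <- rep(1:3, each = 10)
  tk <- tukey_pairwise(m, g)[["1-2"]]
  for (i in 1:10) {
    tt <- t.test(unclass(m)[i, g == 2], unclass(m)[i, g == 1],
                 var.equal = TRUE)
    expect_gte(tk$p_adj[i] + 1e-12, tt$p.value)
  }
})

test_that("a planted shift in one group lands on the affected pairs", {
  hits <- 0
  for (s in 1:50) {
    set.seed(s)
    y <- c(rnorm(10), rnorm(10, mean = 1), rnorm(10))
    m <- log2_mat(matrix(y, 1))
    tk <- tukey_pairwise(m, rep(1:3, each = 10))
    ps <- vapply(tk, function(d) d$p_adj[1], numeric(1))
    # the null (1,3) pair must not carry the smallest adjusted p
    if (names(which.min(ps)) != "1-3") hits <- hits + 1
  }
  expect_gte(hits, 47)
})

test_that("Welch t behaves under identity, swap, and power", {
  x <- rnorm(30)
  same <- group_ttest(rbind(c(x, x)), rep(0:1, each = 30))
  expect_lt(abs(same$t), 1e-10)
  expect_equal(same$p, 1, tolerance = 1e-10)
  set.seed(6)
  y <- matrix(rnorm(60), 1)
  a <- group_ttest(y, rep(0:1, each = 30))
  b <- group_ttest(y, rep(1:0, each = 30))
  expect_equal(a$t, -b$t, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  # 2-sd shift at n = 50/50 is essentially always detected
  hits <- sum(replicate(50, {
    v <- matrix(c(rnorm(50), rnorm(50, 2)), 1)
    group_ttest(v, rep(0:1, each = 50))$p < 1e-6
  }))
  expect_gte(hits, 49)
  # matches t.test's Welch p
  v <- matrix(rnorm(40), 1)
  g <- rep(0:1, each = 20)
  expect_equal(group_ttest(v, g)$p,
               t.test(v[1, g == 1], v[1, g == 0])$p.value,
               tolerance = 1e-12)
})

test_that("BH adjustment is the classical step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG calling applies strict thresholds on both axes", {
  rec <- call_degs(c("a", "b", "c"), l2fc = c(0.6, 0.5, -0.7),
                   p = c(1e-6, 1e-6, 0.2))
  expect_true(rec$is_deg[1])
  expect_identical(rec$direction[1], "up")
  expect_false(rec$is_deg[2])    # |l2fc| must strictly exceed 0.5
  expect_false(rec$is_deg[3])
  expect_identical(rec$direction[3], "down")
})

test_that("DEG calling is invariant to gene order", {
  set.seed(7)
  l2fc <- rnorm(50); p <- runif(50)
  rec <- call_degs(sprintf("g%02d", 1:50), l2fc, p)
  perm <- sample(50)
  rec2 <- call_degs(sprintf("g%02d", 1:50)[perm], l2fc[perm], p[perm])
  expect_identical(rec$is_deg[perm], rec2$is_deg)
})

test_that("stage contrasts share one code path", {
  set.seed(8)
  m <- log2_mat(matrix(rnorm(20 * 30), 20, 30))
  stages <- rep(1:2, each = 15)
  a <- stage_de(m, stages, "stage1_vs_2")
  b <- stage_de(m, stages, "stage1_vs_rest")
  expect_equal(a$l2fc, b$l2fc, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_identical(a$is_deg, b$is_deg)
})
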