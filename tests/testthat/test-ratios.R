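norm_mat <- function(m) {
  dimnames(m) <- list(sprintf("g%d", seq_len(nrow(m))),
                      sprintf("s%d", seq_len(ncol(m))))
  expression_matrix(m, "normalized")
}

test_that("three-step normalization centres samples and is idempotent", {
  set.seed(1)
  raw <- matrix(rexp(50 * 10, 0.1), 50, 10)
  dimnames(raw) <- list(sprintf("g%d", 1:50), sprintf("s%d", 1:10))
  nm <- cluster3_normalize(expression_matrix(raw, "raw"))
  x <- unclass(nm)
  expect_lt(max(abs(apply(x, 2, median))), 1e-9)
  expect_equal(unname(sqrt(colMeans(x^2))), rep(1, 10), tolerance = 1e-9)
  # steps 2-3 are idempotent: feeding the result back (as log2) changes nothing
  again <- cluster3_normalize(expression_matrix(x, "log2"))
  expect_equal(unclass(again), x, tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(attr(nm, "recipe")[1], "log2(x+1)")
})

test_that("hand-checked normalization of a two-gene toy", {
  raw <- matrix(c(0, 3, 15,
                  1, 7, 31), 2, 3, byrow = TRUE)
  dimnames(raw) <- list(c("gA", "gB"), c("s1", "s2", "s3"))
  # log2(x+1): gA -> (0,2,4), gB -> (1,3,5); sample medians (0.5,2.5,4.5)
  # centred: gA (-0.5,-0.5,-0.5), gB (0.5,0.5,0.5); sample RMS all 0.5
  nm <- cluster3_normalize(expression_matrix(raw, "raw"))
  expect_equal(unname(unclass(nm)["gA", ]), rep(-1, 3), tolerance = 1e-12)
  expect_equal(unname(unclass(nm)["gB", ]), rep(1, 3), tolerance = 1e-12)
})

test_that("ratio scores divide sums with a denominator guard", {
  m <- norm_mat(matrix(c(1, 1, 0.5, 0.5,
                         2, 0, 1, -1), 4, 2))
  sig <- signature_def("s", c("g1", "g2"), c("g3", "g4"))
  sc <- ratio_score(m, sig)
  expect_equal(unname(sc["s1"]), (1 + 1) / (0.5 + 0.5))
  expect_true(is.na(sc["s2"]))   # denominator sums to 0
  inv <- signature_def("si", c("g1", "g2"), c("g3", "g4"), invert = TRUE)
  expect_equal(unname(ratio_score(m, inv)["s1"]), -unname(sc["s1"]))
  expect_error(ratio_score(m, signature_def("x", "g9", "g1")), "g9")
})

test_that("fixed-horizon binarization follows the censoring rule", {
  time <- c(300, 400, 200, 365)
  event <- c(1, 0, 0, 1)
  o <- binarize_outcome(time, event, 365)
  expect_equal(o, c(1L, 0L, NA, 1L))
  expect_error(binarize_outcome(time, event, 0), "> 0")
})

test_that("logistic fitted probabilities preserve the AUC orientation", {
  set.seed(2)
  score <- rnorm(100)
  out <- rbinom(100, 1, plogis(-1.2 * score))   # negatively oriented
  lf <- fit_logistic(score, out)
  a_raw <- roc_auc(score, out)
  expect_equal(roc_auc(lf$fitted, out), max(a_raw, 1 - a_raw),
               tolerance = 1e-12)
  expect_lt(lf$coef[2], 0)
  # coefficient agrees with a direct likelihood maximization oracle
  nll <- function(b) -sum(dbinom(out, 1, plogis(b[1] + b[2] * score),
                                 log = TRUE))
  opt <- optim(c(0, 0), nll)$par
  expect_equal(lf$coef[2], opt[2], tolerance = 1e-3)
})

test_that("AUC is the Mann-Whitney concordance", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(1, 10), rep(0:1, 5)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "positive")
})

test_that("AUC is invariant under strictly increasing transforms", {
  for (s in 1:10) {
    set.seed(s)
    sc <- rnorm(60)
    out <- rbinom(60, 1, plogis(sc))
    if (length(unique(out)) < 2) next
    a <- roc_auc(sc, out)
    expect_equal(roc_auc(exp(sc), out), a, tolerance = 1e-12)
    expect_equal(roc_auc(rank(sc), out), a, tolerance = 1e-12)
  }
})

test_that("DeLong CI matches pROC and narrows with n", {
  skip_if_not_installed("pROC")
  set.seed(3)
  score <- c(rnorm(60, 1), rnorm(60))
  out <- rep(1:0, each = 60)
  ci <- auc_ci(score, out)
  proc <- pROC::ci.auc(pROC::roc(out, score, direction = "<",
                                 levels = c(0, 1), quiet = TRUE),
                       method = "delong")
  expect_equal(ci$auc, as.numeric(proc[2]), tolerance = 1e-10)
  expect_equal(ci$ci_low, as.numeric(proc[1]), tolerance = 1e-8)
  expect_equal(ci$ci_high, as.numeric(proc[3]), tolerance = 1e-8)
  # width shrinks as n doubles
  widths <- vapply(c(50, 100, 200, 400), function(n) {
    set.seed(n)
    s <- c(rnorm(n, 1), rnorm(n)); y <- rep(1:0, each = n)
    ci <- auc_ci(s, y)
    ci$ci_high - ci$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # symmetric null: p near 1
  set.seed(4)
  s0 <- rnorm(200); y0 <- rep(0:1, 100)
  expect_gt(auc_ci(s0, y0)$p, 0.05)
})

test_that("combination enumeration matches the closed form", {
  num <- sprintf("N%d", 1:6); den <- sprintf("D%d", 1:5)
  for (k_max in 1:4) {
    combos <- enumerate_combinations(num, den, k_max)
    closed <- sum(choose(6, 1:k_max) * choose(5, 1:k_max))
    expect_equal(nrow(combos), closed)
  }
  expect_equal(nrow(enumerate_combinations("a", "b", 4)), 1L)
  expect_error(enumerate_combinations(c("a", "b"), c("b", "c"), 2),
               "disjoint")
  # deterministic lexical order
  c1 <- enumerate_combinations(num, den, 2)
  c2 <- enumerate_combinations(rev(num), rev(den), 2)
  expect_identical(c1, c2)
})

test_that("ratio evaluation is deterministic and null combos sit near 0.5", {
  set.seed(5)
  m <- norm_mat(matrix(rnorm(12 * 300), 12, 300) + 5)
  time <- rexp(300, 1e-3)
  event <- rbinom(300, 1, 0.7)
  num <- sprintf("g%d", 1:4); den <- sprintf("g%d", 5:8)
  e1 <- evaluate_all_ratios(m, time, event, num, den)
  e2 <- evaluate_all_ratios(m, time, event, num, den)
  expect_identical(e1, e2)
  expect_lt(abs(mean(e1$mean_all) - 0.5), 0.1)
  expect_true(all(e1$mean_all >= 0.5 - 1e-12))   # orientation-free AUC
})

test_that("the AUC fast path agrees with the full logistic evaluation", {
  set.seed(6)
  m <- norm_mat(matrix(rnorm(8 * 150), 8, 150) + 5)
  truth <- colSums(unclass(m)[1:2, ])
  time <- rexp(150, 1e-3 * exp(0.8 * scale(truth)[, 1]))
  event <- rep(1L, 150)
  ev <- evaluate_all_ratios(m, time, event, c("g1", "g2"), c("g3", "g4"),
                            metrics = "full")
  sig <- signature_def(ev$name[1],
                       strsplit(ev$num[1], "+", fixed = TRUE)[[1]],
                       strsplit(ev$den[1], "+", fixed = TRUE)[[1]])
  full <- evaluate_signature(m, sig, time, event)
  expect_equal(ev$auc_1095[1], full$table$auc[full$table$t_days == 1095],
               tolerance = 1e-10)
  expect_true(all(c("ci_low_365", "p_1095", "sensitivity_548",
                    "n_used_1825") %in% colnames(ev)))
})

test_that("ranking sorts by the requested subset with stable ties", {
  ev <- data.frame(k = 2, num = c("a+b", "a+c", "b+c"),
                   den = c("x+y", "x+z", "y+z"),
                   auc_365 = c(0.9, 0.6, 0.7), auc_548 = c(0.5, 0.8, 0.7),
                   name = c("r1", "r2", "r3"),
                   mean_all = c(0.70, 0.70, 0.70),
                   mean_no10y = c(0.70, 0.70, 0.70),
                   mean_no5y10y = c(0.9, 0.6, 0.7))
  class(ev) <- c("ratio_evaluation", "data.frame")
  r <- rank_by_mean_auc(ev, "no5y10y")
  expect_identical(r$name, c("r1", "r3", "r2"))
  # full-subset tie falls back to lexical name
  r2 <- rank_by_mean_auc(ev, "all")
  expect_identical(r2$name, c("r1", "r2", "r3"))
  shuffled <- ev[c(3, 1, 2), ]
  expect_identical(rank_by_mean_auc(shuffled, "no5y10y")$name, r$name)
  expect_error(rank_by_mean_auc(ev, "bogus"), "unknown")
})

test_that("top-gene frequency counts per side", {
  ev <- data.frame(k = 1, num = c("a", "a", "b", "a", "c"),
                   den = c("x", "y", "x", "x", "x"),
                   name = sprintf("r%d", 1:5),
                   mean_all = seq(0.9, 0.5, by = -0.1),
                   mean_no10y = 0.5, mean_no5y10y = 0.5)
  class(ev) <- c("ratio_evaluation", "data.frame")
  cfg <- ratio_config(top_k_for_frequency = 5, frequency_threshold = 0.2)
  fr <- top_gene_frequency(ev, cfg)
  expect_equal(fr$frequency[fr$gene == "a" & fr$side == "num"], 0.6)
  expect_equal(fr$frequency[fr$gene == "x" & fr$side == "den"], 0.8)
  expect_equal(fr$frequency[fr$gene == "c" & fr$side == "num"], 0.2)
  expect_false(fr$flagged[fr$gene == "c" & fr$side == "num"])
  small <- ev[1:3, ]
  class(small) <- class(ev)
  expect_warning(top_gene_frequency(small, ratio_config()), "using all")
})

test_that("survival-time correlation nominates the right directions", {
  set.seed(7)
  n <- 100
  time <- rexp(n, 1e-3)
  m <- rbind(time, -time, matrix(rnorm(4 * n), 4, n))
  dimnames(m) <- list(sprintf("g%d", 1:6), sprintf("s%d", 1:n))
  nm <- expression_matrix(m, "normalized")
  sel <- select_survival_correlated(nm, time, rep(1L, n), top_n = 1)
  expect_identical(sel$numerator, "g1")
  expect_identical(sel$denominator, "g2")
  expect_equal(unname(sel$cor["g1"]), 1, tolerance = 1e-6)
  expect_error(select_survival_correlated(nm, time, rep(1L, n), top_n = 10),
               "top_n")
})
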