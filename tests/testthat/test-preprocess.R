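toy_expr <- function(m, scale = "raw") {
  dimnames(m) <- list(sprintf("g%d", seq_len(nrow(m))),
                      sprintf("s%d", seq_len(ncol(m))))
  expression_matrix(m, scale)
}

test_that("zero-fraction filter removes at >= 50% and is idempotent", {
  m <- rbind(c(rep(0, 5), rep(2, 5)),   # 5/10 zeros -> removed
             c(rep(0, 4), rep(2, 6)),   # 4/10 zeros -> kept
             rep(3, 10))
  expr <- toy_expr(m)
  out <- filter_missing_transcripts(expr)
  expect_identical(rownames(out), c("g2", "g3"))
  expect_identical(unclass(filter_missing_transcripts(out)), unclass(out))
  all_pos <- toy_expr(matrix(1:12, 3, 4))
  expect_identical(unclass(filter_missing_transcripts(all_pos)),
                   unclass(all_pos))
})

test_that("log2 transform applies the pseudocount", {
  expr <- toy_expr(matrix(c(1, 0, 3, 7), 2, 2))
  lg <- log2_transform(expr)
  expect_equal(unname(unclass(lg)[1, 1]), 1)
  expect_equal(unname(unclass(lg)[2, 1]), 0)
  expect_equal(unname(unclass(lg)[1, 2]), 2)
  expect_identical(expr_scale(lg), "log2")
  expect_error(log2_transform(lg), "raw")
})

test_that("connectivity outliers are flagged in one pass", {
  set.seed(2)
  base <- rnorm(50)
  m <- sapply(1:20, function(i) base + rnorm(50, sd = 0.3))
  m <- cbind(m, -base + rnorm(50, sd = 0.3))   # constructed anti-correlated
  expr <- toy_expr(m, "log2")
  out <- remove_outlier_samples(expr, z_thresh = 3)
  expect_identical(out$removed, "s21")
  # z computed directly on the construction agrees
  cc <- cor(m)
  z <- scale(rowSums(cc) - 1)[, 1]
  expect_true(abs(z[21]) > 3)

  same <- toy_expr(matrix(rep(rnorm(20), 5), 20, 5), "log2")
  expect_warning(res <- remove_outlier_samples(same), "zero variance")
  expect_length(res$removed, 0)
  expect_length(remove_outlier_samples(expr, z_thresh = Inf)$removed, 0)
})

test_that("clinical cleaning drops incomplete and unmatched samples", {
  expr <- toy_expr(matrix(1, 2, 4), "raw")
  cl <- clinical_table(sample_id = c("s1", "s2", "s3", "s9"),
                       stage = c(1, 2, 1, 1),
                       os_time_days = c(10, 20, 30, 40),
                       os_event = c(1, 0, 1, 0),
                       age = c(60, NA, 70, 65),
                       sex = c("male", "female", "male", "male"),
                       t_stage = c(1, 2, 1, 1))
  out <- clean_clinical_samples(expr, cl)
  # s2 misses age, s4 has no clinical row, s9 has no expression column
  expect_identical(colnames(out$expr), c("s1", "s3"))
  expect_identical(out$clinical$sample_id, c("s1", "s3"))
})

test_that("covariate regression removes the effect but keeps gene means", {
  set.seed(7)
  n <- 80
  age <- round(rnorm(n, 65, 8))
  sex <- sample(c("male", "female"), n, TRUE)
  cl <- clinical_table(sample_id = sprintf("s%d", 1:n), stage = 1,
                       os_time_days = 1, os_event = 0, age = age, sex = sex,
                       t_stage = 1)
  m <- rbind(5 + 0.05 * age,                        # exactly linear in age
             rnorm(n),                              # independent of both
             3 + 0.05 * age + rnorm(n, sd = 0.2))   # planted age effect
  expr <- toy_expr(m, "log2")
  colnames(expr) <- cl$sample_id
  adj <- regress_covariates(expr, cl)
  expect_equal(unname(unclass(adj)[1, ]), rep(mean(m[1, ]), n),
               tolerance = 1e-8)
  expect_lt(max(abs(rowMeans(unclass(adj)) - rowMeans(m))), 1e-10)
  expect_lt(abs(cor(unclass(adj)[3, ], age)), 0.05)
  # a gene orthogonal to the design is (numerically) untouched
  resid_gene <- lm(m[2, ] ~ age + factor(sex))$residuals + mean(m[2, ])
  expr2 <- expr
  expr2[2, ] <- resid_gene
  adj2 <- regress_covariates(expr2, cl)
  expect_equal(unname(unclass(adj2)[2, ]), unname(resid_gene),
               tolerance = 1e-10)
})

test_that("trait encoding follows the stage-collapse rules", {
  cl <- clinical_table(sample_id = c("a", "b", "c"), stage = c(4, 1, 3),
                       os_time_days = c(1, 2, 3), os_event = c(1, 0, 1),
                       age = c(60, 61, 62), sex = c("male", "female", NA),
                       t_stage = c(4, 1, 2), n_stage = c(2, 0, 1))
  tr <- encode_traits(cl)
  expect_equal(unname(tr["a", "Stage 3.5"]), 1)
  expect_equal(unname(tr["a", "Pathologic stage 3.5"]), 3.5)
  expect_equal(unname(tr["b", "Stage 1"]), 1)
  expect_equal(unname(tr["b", "Stage 2"]), 0)
  expect_equal(unname(tr["b", "Stage N0"]), 1)
  expect_equal(unname(tr["c", "Stage 3.5"]), 1)
  expect_equal(unname(tr["b", "OS.time"]), 2)
})

test_that("the preprocessing chain logs its removals", {
  sim <- small_sim()
  pre <- preprocess_pipeline(sim$expr, sim$clinical)
  expect_identical(expr_scale(pre$expr), "log2")
  expect_identical(colnames(pre$expr), pre$clinical$sample_id)
  expect_equal(pre$log$genes_in, nrow(sim$expr))
  expect_gte(pre$log$genes_removed_zero_filter, 0)
})
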