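#' Simulation parameters for the planted-structure generator
#'
#' Defines the study conditions the generator emulates: two anti-correlated
#' co-expressed gene blocks (one protective, one adverse) over background
#' genes, ordinal tumour stage shifted along the standardized adverse-minus-
#' protective factor contrast, exponential survival whose log-hazard is
#' linear in the two block factors, independent exponential censoring capped
#' at the follow-up horizon, and an FPKM-like non-negative scale with a
#' zero-inflated low tail.
#'
#' Each block carries a planted core of `planted_per_block` signature genes
#' that load purely on the block's survival-relevant factor with loading
#' `planted_loading`; the remaining block genes load on a mixture
#' `module_purity * factor + sqrt(1 - module_purity^2) * nuisance`, where the
#' nuisance factor is shared within the block (co-expression that is not
#' prognostic). This mirrors cohorts in which a module tracks outcome but
#' only a core of its members carries the outcome signal.
#'
#' @param n_samples number of samples (default 300).
#' @param n_genes number of genes (default 2000).
#' @param module_sizes sizes of the two planted blocks (protective, adverse).
#' @param within_module_cor target mean pairwise correlation inside a block
#'   (default 0.5, typical of real co-expression modules).
#' @param block_anticor target |correlation| between the two planted factors.
#' @param stage_effect shift of the standardized adverse-minus-protective
#'   contrast per stage step, on the cumulative-logit scale (default 1.5).
#' @param hazard_coefs log-hazard weights on (protective, adverse) factors;
#'   default `c(-1, 1)`.
#' @param baseline_hazard exponential baseline hazard per day.
#' @param censor_rate exponential censoring rate per day (0 = none).
#' @param followup_cap_days administrative censoring horizon.
#' @param zero_inflation fraction of the whole FPKM matrix thresholded to 0
#'   from the low tail.
#' @param planted_per_block planted signature genes per block (default 4).
#' @param planted_loading factor loading of planted genes (default 2).
#' @param module_purity fraction of an ordinary block gene's factor variance
#'   carried by the survival-relevant factor (default 0.85).
#' @param loading_range uniform range for ordinary block loadings (default
#'   `c(0.3, 0.6)`).
#' @param seed integer seed fixing all randomness.
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(n_samples = 300, n_genes = 2000,
                       module_sizes = c(150, 150),
                       within_module_cor = 0.5, block_anticor = 0.85,
                       stage_effect = 1.5, hazard_coefs = c(-1, 1),
                       baseline_hazard = 5e-4, censor_rate = 3e-4,
                       followup_cap_days = 3650, zero_inflation = 0.2,
                       planted_per_block = 4, planted_loading = 2,
                       module_purity = 0.85, loading_range = c(0.3, 0.6),
                       seed = 1L) {
  p <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
            module_sizes = as.integer(module_sizes),
            within_module_cor = within_module_cor,
            block_anticor = block_anticor, stage_effect = stage_effect,
            hazard_coefs = as.numeric(hazard_coefs),
            baseline_hazard = baseline_hazard, censor_rate = censor_rate,
            followup_cap_days = followup_cap_days,
            zero_inflation = zero_inflation,
            planted_per_block = as.integer(planted_per_block),
            planted_loading = planted_loading,
            module_purity = module_purity,
            loading_range = as.numeric(loading_range),
            seed = as.integer(seed))
  chk <- function(ok, field, why)
    if (!ok) stop(sprintf("invalid sim_params: field '%s' %s", field, why))
  chk(p$n_samples >= 4, "n_samples", "must be >= 4")
  chk(p$n_genes >= 1, "n_genes", "must be >= 1")
  chk(length(p$module_sizes) >= 2 && all(p$module_sizes >= 1),
      "module_sizes", "needs two positive block sizes")
  chk(sum(p$module_sizes) <= p$n_genes, "module_sizes",
      "must sum to <= n_genes")
  chk(p$within_module_cor > 0 && p$within_module_cor < 1,
      "within_module_cor", "must be in (0,1)")
  chk(p$block_anticor >= 0 && p$block_anticor < 1, "block_anticor",
      "must be in [0,1)")
  chk(length(p$hazard_coefs) == 2, "hazard_coefs", "needs two values")
  chk(p$baseline_hazard > 0, "baseline_hazard", "must be > 0")
  chk(p$censor_rate >= 0, "censor_rate", "must be >= 0")
  chk(p$followup_cap_days > 0, "followup_cap_days", "must be > 0")
  chk(p$zero_inflation >= 0 && p$zero_inflation < 1, "zero_inflation",
      "must be in [0,1)")
  chk(p$planted_per_block >= 1 &&
        all(p$planted_per_block <= p$module_sizes[1:2]),
      "planted_per_block", "must fit inside both blocks")
  chk(p$planted_loading > 0, "planted_loading", "must be > 0")
  chk(p$module_purity > 0 && p$module_purity <= 1, "module_purity",
      "must be in (0,1]")
  chk(length(p$loading_range) == 2 && p$loading_range[1] > 0 &&
        p$loading_range[1] <= p$loading_range[2],
      "loading_range", "must be an increasing positive pair")
  class(p) <- "sim_params"
  p
}

#' Generate a synthetic expression + clinical dataset with ground truth
#'
#' Gene expression on the log2 scale follows a factor model (see
#' [sim_params()]): planted signature genes are
#' `mu_g + planted_loading * f_b + noise`, ordinary block genes load on the
#' purity-mixed factor, and the noise variance is set so mean within-block
#' correlation matches `within_module_cor`. The two block factors are
#' bivariate normal with correlation `-block_anticor`. Planted genes draw
#' high baselines (log2 scale 7-9), other block genes 5-9, and background
#' genes a right-skewed gamma baseline, giving an FPKM-like dynamic range
#' after exponentiation; the lowest `zero_inflation` fraction of entries is
#' set to 0. Stage follows a cumulative-logit model shifted by the
#' standardized `f2 - f1` contrast; survival is exponential with log-hazard
#' `log(baseline_hazard) + h1*f1 + h2*f2`.
#'
#' @param params a [sim_params()] object.
#' @return list of class `sim_dataset` with elements `expr` (raw
#'   [expression_matrix()]), `clinical` ([clinical_table()]) and `truth`
#'   (block labels, latent factors, loadings, true hazard coefficients and
#'   the planted signature with the protective block as numerator).
#' @export
generate_dataset <- function(params = sim_params()) {
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, params)
  p <- params
  set.seed(p$seed)
  n <- p$n_samples
  m1 <- p$module_sizes[1]; m2 <- p$module_sizes[2]
  k <- p$planted_per_block
  n_bg <- p$n_genes - m1 - m2
  genes <- sprintf("gene%05d", seq_len(p$n_genes))
  samples <- sprintf("S%04d", seq_len(n))
  block <- c(rep(1L, m1), rep(2L, m2), rep(0L, n_bg))

  # survival-relevant factors, correlation -block_anticor, plus one shared
  # non-prognostic nuisance factor per block
  z <- matrix(stats::rnorm(2 * n), n, 2)
  a <- -p$block_anticor
  f <- cbind(f1 = z[, 1], f2 = a * z[, 1] + sqrt(1 - a^2) * z[, 2])
  u <- matrix(stats::rnorm(2 * n), n, 2)
  rho <- p$module_purity
  g1 <- rho * f[, 1] + sqrt(1 - rho^2) * u[, 1]
  g2 <- rho * f[, 2] + sqrt(1 - rho^2) * u[, 2]

  lam1 <- c(rep(p$planted_loading, k),
            stats::runif(m1 - k, p$loading_range[1], p$loading_range[2]))
  lam2 <- c(rep(p$planted_loading, k),
            stats::runif(m2 - k, p$loading_range[1], p$loading_range[2]))
  r <- p$within_module_cor
  sig1 <- sqrt(mean(lam1^2) * (1 - r) / r)
  sig2 <- sqrt(mean(lam2^2) * (1 - r) / r)

  mu <- c(stats::runif(k, 7, 9), stats::runif(m1 - k, 5, 9),
          stats::runif(k, 7, 9), stats::runif(m2 - k, 5, 9),
          stats::rgamma(n_bg, shape = 1.5, scale = 1.5))
  fac1 <- rbind(tcrossprod(rep(1, k), f[, 1]),
                tcrossprod(rep(1, m1 - k), g1))
  fac2 <- rbind(tcrossprod(rep(1, k), f[, 2]),
                tcrossprod(rep(1, m2 - k), g2))
  y <- matrix(NA_real_, p$n_genes, n, dimnames = list(genes, samples))
  y[seq_len(m1), ] <- mu[seq_len(m1)] + lam1 * fac1 +
    matrix(stats::rnorm(m1 * n, sd = sig1), m1, n)
  y[m1 + seq_len(m2), ] <- mu[m1 + seq_len(m2)] + lam2 * fac2 +
    matrix(stats::rnorm(m2 * n, sd = sig2), m2, n)
  if (n_bg > 0)
    y[m1 + m2 + seq_len(n_bg), ] <- mu[m1 + m2 + seq_len(n_bg)] +
      matrix(stats::rnorm(n_bg * n, sd = 1), n_bg, n)

  fpkm <- pmax(2^y - 1, 0)
  if (p$zero_inflation > 0) {
    thr <- stats::quantile(fpkm, p$zero_inflation)
    fpkm[fpkm < thr] <- 0
  }

  # ordinal stage: cumulative logit shifted by the standardized disease
  # contrast (adverse minus protective factor); baseline marginals roughly
  # 53/25/17/5% across stages 1-4
  contrast <- (f[, 2] - f[, 1]) / stats::sd(f[, 2] - f[, 1])
  cuts <- stats::qlogis(c(0.53, 0.78, 0.95))
  pl <- stats::plogis(outer(-p$stage_effect * contrast, cuts, "+"))
  stage <- 1L + rowSums(stats::runif(n) > pl)

  # exponential survival + independent exponential censoring, capped
  haz <- p$baseline_hazard * exp(p$hazard_coefs[1] * f[, 1] +
                                 p$hazard_coefs[2] * f[, 2])
  t_death <- stats::rexp(n, rate = haz)
  t_cens <- if (p$censor_rate > 0) stats::rexp(n, rate = p$censor_rate)
            else rep(Inf, n)
  t_cens <- pmin(t_cens, p$followup_cap_days)
  os_time <- pmin(t_death, t_cens)
  os_event <- as.integer(t_death <= t_cens)

  age <- pmin(pmax(round(stats::rnorm(n, 65, 10)), 30), 90)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  t_stage <- pmin(4L, pmax(1L, stage +
    sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = c(0.2, 0.6, 0.2))))
  n_stage <- pmin(2L, pmax(0L, stage - 1L +
    sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = c(0.3, 0.5, 0.2))))
  m_stage <- as.integer(stage == 4L)

  clinical <- clinical_table(sample_id = samples, stage = stage,
                             os_time_days = os_time, os_event = os_event,
                             age = age, sex = sex, t_stage = t_stage,
                             n_stage = n_stage, m_stage = m_stage)

  planted <- signature_def("planted", genes[seq_len(k)],
                           genes[m1 + seq_len(k)])
  truth <- list(gene_block_labels = stats::setNames(block, genes),
                latent_factors = `rownames<-`(f, samples),
                loadings = stats::setNames(c(lam1, lam2, rep(0, n_bg)),
                                           genes),
                true_hazard_coefs = p$hazard_coefs,
                planted_signature = planted)
  structure(list(expr = expression_matrix(fpkm, "raw"),
                 clinical = clinical, truth = truth, params = p),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(paste0("<sim_dataset> %d genes x %d samples ",
                     "(blocks %s, seed %d)\n  events: %d/%d  stages: %s\n"),
              nrow(x$expr), ncol(x$expr),
              paste(x$params$module_sizes, collapse = "+"), x$params$seed,
              sum(x$clinical$os_event), nrow(x$clinical),
              paste(table(x$clinical$stage), collapse = "/")))
  invisible(x)
}
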