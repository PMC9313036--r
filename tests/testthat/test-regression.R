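test_that("extreme-value truncation matches the hand-derived cap", {
  # [1,2,3,4,100]: interpolated Q1 = 2, Q3 = 4, cap = 4 + 8*2 = 20
  out <- truncate_extremes(c(1, 2, 3, 4, 100))
  expect_equal(out$cap, 20)
  expect_equal(out$values, c(1, 2, 3, 4, 20))
  expect_equal(out$truncated_count, 1L)

  # constant vector: IQR 0, cap = Q3, nothing exceeds it
  const <- truncate_extremes(rep(5, 4))
  expect_equal(const$values, rep(5, 4))
  expect_equal(const$truncated_count, 0L)

  # everything below the cap is a no-op
  v <- c(1, 1.2, 1.4, 1.6, 1.8)
  expect_equal(truncate_extremes(v)$values, v)
  expect_equal(truncate_extremes(v)$truncated_count, 0L)

  expect_error(truncate_extremes(c(1, 2, 3)), "at least 4")
  expect_error(truncate_extremes(c(1, 2, 3, 0)), "positive")
})

test_that("truncation is idempotent", {
  set.seed(31)
  for (k in 1:20) {
    v <- exp(rnorm(50, sd = 2))
    once <- truncate_extremes(v)$values
    twice <- truncate_extremes(once)
    expect_equal(twice$values, once)
    expect_equal(twice$truncated_count, 0L)
  }
})

test_that("metabolite preparation standardizes the truncated log scale", {
  # geometric input becomes evenly spaced z-scores
  g <- exp(0:7)
  z <- prepare_metabolite(g)
  expect_equal(diff(z), rep(diff(z)[1], 7), tolerance = 1e-12)
  v <- exp(rnorm(100))
  zv <- prepare_metabolite(v)
  expect_lt(abs(mean(zv)), 1e-12)
  expect_equal(sd(zv), 1, tolerance = 1e-12)
  # positive rescaling is absorbed by log + centering
  expect_equal(prepare_metabolite(v * 37), zv, tolerance = 1e-10)
  expect_error(prepare_metabolite(rep(2, 10)), "zero variance")
})

test_that("a perfectly predictive metabolite has SD-unit beta one", {
  set.seed(5)
  z <- as.numeric(scale(rnorm(50)))
  rec <- fit_association(z, z)
  expect_equal(rec$beta, 1, tolerance = 1e-10)
  expect_lt(rec$p_value, 1e-10)
})

test_that("null effects are estimated near zero at the expected rate", {
  set.seed(77)
  n <- 1000
  hits <- replicate(500, {
    z <- as.numeric(scale(rnorm(n)))
    rec <- fit_association(z, rnorm(n))
    abs(rec$beta) < 3 / sqrt(n)
  })
  expect_gte(mean(hits), 0.99)
})

test_that("planted effects are recovered from the synthetic truth", {
  # one isolated 0.3 SD effect; outcome noise set so the outcome has unit SD
  B <- matrix(0, 8, 2, dimnames = list(NULL, c("BMI", "MAP")))
  B[5, "BMI"] <- 0.3
  cfg <- function(seed) generator_config(
    n_samples = 1000, n_metabolites = 8, within_cluster_corr = 0,
    noise_log_sd = 0, sex_effect = 0, outcome_effects = B,
    sex_outcome_effect = c(BMI = 0, MAP = 0),
    outcome_noise_sd = sqrt(1 - 0.09), seed = seed)
  ch <- generate_cohort(cfg(1))
  target <- ch$truth$marginal_effects[5, "BMI"]
  expect_equal(target, 0.3, tolerance = 1e-12)
  met <- colnames(ch$truth$physiological_matrix)[5]
  rec <- fit_association(ch$truth$physiological_matrix[, met],
                         ch$covariates$BMI, prepare = TRUE)
  expect_lt(abs(rec$beta - 0.3), 3 * rec$se)
})

test_that("collinear designs fail loudly with the offending column", {
  z <- as.numeric(scale(rnorm(30)))
  expect_error(fit_association(z, rnorm(30), covariates = cbind(dup = z)),
               "collinear.*dup")
})

test_that("effective test count tracks the correlation-matrix spectrum", {
  # two exact duplicate pairs: rank 2, all variance in 2 components
  set.seed(8)
  a <- exp(rnorm(50)); b <- exp(rnorm(50))
  dup <- cbind(m1 = a, m2 = a, m3 = b, m4 = b)
  expect_equal(effective_tests(dup, 0.99), 2L)

  # exactly orthogonal standardized columns: eigenvalues all one,
  # 9/10 < 0.99 so all ten components are needed
  q <- qr.Q(qr(cbind(1, matrix(rnorm(200), 20, 10))))[, 2:11]
  orth <- exp(q)  # columns orthogonal to the constant => centered, orthogonal
  colnames(orth) <- paste0("m", 1:10)
  expect_equal(effective_tests(orth, 0.99), 10L)

  expect_equal(effective_tests(dup, 0), 1L)
  expect_error(effective_tests(cbind(m1 = rep(2, 10), m2 = exp(rnorm(10)))),
               "zero-variance")
  expect_error(effective_tests(dup, 1), "variance_cut")
})

test_that("the Bonferroni threshold divides and rounds to two significant digits", {
  th <- bonferroni_threshold(0.05, 39)
  expect_equal(th$threshold, 0.0013)
  expect_equal(bonferroni_threshold(0.05, 1)$threshold, 0.05)
  expect_equal(bonferroni_threshold(0.01, 10)$threshold, 0.001)
  expect_error(bonferroni_threshold(1.5, 10), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "m_eff")
})

test_that("the scan produces one record per scheme, metabolite, outcome and adjustment", {
  ch <- generate_cohort(generator_config(n_samples = 80, seed = 19L))
  tables <- lapply(standard_schemes(), function(sp) apply_scheme(ch$table, sp))
  outcomes <- as.matrix(ch$covariates[, c("BMI", "MAP")])
  th <- bonferroni_threshold(0.05, 39)
  recs <- association_scan(tables, outcomes, sex = ch$covariates$sex,
                           adjust = TRUE, threshold = th)
  # 4 full tables of 44 + 4 IS tables of 43, times 2 outcomes
  n_cells <- sum(vapply(tables, function(t) ncol(t$values), integer(1)))
  expect_equal(nrow(recs), n_cells * 2L)
  expect_equal(nrow(recs), (4L * 44L + 4L * 43L) * 2L)
  expect_identical(recs$robust, recs$p_value < 0.0013)
  expect_true(all(recs$se > 0))
  expect_true(all(recs$p_value > 0 & recs$p_value <= 1))

  # both adjustment strata double the record count
  both <- association_scan(tables["PQN"], outcomes, sex = ch$covariates$sex,
                           adjust = c(FALSE, TRUE), threshold = th)
  expect_equal(nrow(both), 44L * 2L * 2L)

  # mismatched sample sets are refused
  short <- lapply(standard_schemes()[c("ABS", "CS")],
                  function(sp) apply_scheme(ch$table[1:40, ], sp))
  expect_error(association_scan(c(tables["PQN"], short), outcomes,
                                threshold = th),
               "sample set")
})

test_that("SD-unit betas ignore per-metabolite rescaling but differ across schemes", {
  ch <- generate_cohort(generator_config(n_samples = 120, seed = 23L))
  outcomes <- as.matrix(ch$covariates[, c("BMI", "MAP")])
  abs_nt <- normalize_abs(ch$table)
  rescaled <- ch$table
  rescaled[, "lactate"] <- rescaled[, "lactate"] * 1000  # unit change
  recs_a <- association_scan(list(ABS = abs_nt), outcomes, adjust = FALSE)
  recs_b <- association_scan(list(ABS = normalize_abs(rescaled)), outcomes,
                             adjust = FALSE)
  expect_equal(recs_a$beta, recs_b$beta, tolerance = 1e-10)

  pqn <- association_scan(list(PQN = normalize_pqn(ch$table)), outcomes,
                          adjust = FALSE)
  lac <- function(d) d$beta[d$metabolite == "lactate" & d$outcome == "BMI"]
  expect_false(isTRUE(all.equal(lac(recs_a), lac(pqn))))
})

test_that("sex adjustment is inert when sex is unrelated to metabolites and outcome", {
  cfg <- generator_config(n_samples = 2000, sex_effect = 0,
                          sex_outcome_effect = c(BMI = 0, MAP = 0),
                          seed = 29L)
  ch <- generate_cohort(cfg)
  outcomes <- as.matrix(ch$covariates[, c("BMI", "MAP")])
  recs <- association_scan(list(PQN = normalize_pqn(ch$table)), outcomes,
                           sex = ch$covariates$sex, adjust = c(FALSE, TRUE))
  adj <- recs[recs$sex_adjusted, ]
  una <- recs[!recs$sex_adjusted, ]
  key <- paste(adj$metabolite, adj$outcome)
  expect_identical(key, paste(una$metabolite, una$outcome))
  expect_lt(max(abs(adj$beta - una$beta)), 0.05)
})
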