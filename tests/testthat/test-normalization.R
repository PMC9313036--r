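test_that("absolute baseline is the identity with unit scale factors", {
  x <- named_matrix(c(1, 2, 3, 4), c("a", "b"))
  nt <- normalize_abs(x)
  expect_equal(unclass(nt$values), unclass(as_metabolite_table(x)),
               ignore_attr = TRUE)
  expect_equal(unname(nt$scale_factors), c(1, 1))
  # idempotent
  nt2 <- normalize_abs(nt$values)
  expect_equal(unclass(nt2$values), unclass(nt$values))
  expect_error(normalize_abs(matrix(numeric(0), 0, 0)), "empty")
})

test_that("internal-standard normalization divides by and drops the reference", {
  x <- named_matrix(c(4, 8, 2), c("met1", "met2", "crea"))
  nt <- normalize_is(x, "crea")
  expect_equal(unclass(nt$values),
               named_matrix(c(2, 4), c("met1", "met2")),
               ignore_attr = TRUE)
  expect_false("crea" %in% colnames(nt$values))
  expect_identical(nt$excluded, "crea")
  expect_equal(unname(nt$scale_factors), 2)
  expect_error(normalize_is(x, "absent"), "not in table")
  # zero reference values never reach the division: positivity is enforced
  x0 <- named_matrix(c(4, 8, 0), c("met1", "met2", "crea"))
  expect_error(normalize_is(x0, "crea"), "nonpositive")
})

test_that("constant-sum rows sum to one and cancel sample scaling", {
  x <- named_matrix(c(2, 3, 5), c("a", "b", "c"))
  nt <- normalize_cs(x)
  expect_equal(unname(unclass(nt$values)[1, ]), c(0.2, 0.3, 0.5))
  big <- random_table(20, 6, seed = 2)
  cs <- normalize_cs(big)
  expect_lt(max(abs(rowSums(cs$values) - 1)), 1e-12)
  # scaling a row by c > 0 leaves its normalized values unchanged
  scaled <- big
  scaled[7, ] <- big[7, ] * 13
  cs2 <- normalize_cs(scaled)
  expect_equal(cs2$values[7, ], cs$values[7, ], tolerance = 1e-12)
  expect_error(normalize_cs(big, subset = character(0)),
               "non-empty")
})

test_that("PQN reproduces the hand-derived worked example", {
  x <- named_matrix(c(1, 2, 4,
                      2, 4, 8,
                      1, 2, 100), c("a", "b", "c"))
  nt <- normalize_pqn(x, pre_cs = FALSE)
  expect_equal(unname(nt$reference_profile), c(1, 2, 8))
  expect_equal(unname(nt$scale_factors), c(1, 2, 1))
  expect_equal(unname(unclass(nt$values)),
               matrix(c(1, 2, 4, 1, 2, 4, 1, 2, 100), 3, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("PQN collapses pure dilution to identical rows", {
  base <- c(1, 3, 0.5, 2)
  d <- c(0.2, 1, 5, 8, 0.7)
  x <- outer(d, base)
  colnames(x) <- paste0("m", 1:4)
  nt <- normalize_pqn(x, pre_cs = FALSE)
  # quotient scale factors are the dilutions relative to the median sample
  expect_equal(unname(nt$scale_factors), d / median(d), tolerance = 1e-12)
  for (i in 2:5) {
    expect_equal(nt$values[i, ], nt$values[1, ], tolerance = 1e-12)
  }
})

test_that("a single self-referenced sample gets scale factor one", {
  x <- named_matrix(c(3, 7, 11), c("a", "b", "c"))
  nt <- normalize_pqn(x, pre_cs = FALSE)
  expect_equal(unname(nt$scale_factors), 1)
  expect_equal(unclass(nt$values), unclass(as_metabolite_table(x)),
               ignore_attr = TRUE)
})

test_that("geometric-mean reference normalization follows the forced arithmetic", {
  x <- named_matrix(c(1, 2, 4,
                      4, 8, 16), c("a", "b", "c"))
  nt <- normalize_deseq2(x)
  expect_equal(unname(nt$reference_profile), c(2, 4, 8))
  expect_equal(unname(nt$scale_factors), c(0.5, 2))
  expect_equal(unname(unclass(nt$values)),
               matrix(c(2, 4, 8, 2, 4, 8), 2, byrow = TRUE),
               ignore_attr = TRUE)
  x0 <- named_matrix(c(1, 2, 0, 4), c("a", "b"))
  expect_error(normalize_deseq2(x0), "nonpositive")
})

test_that("vectorized PQN and DESeq2 match literal loop oracles", {
  for (k in 1:60) {
    x <- random_table(5, 5, seed = 1000 + k)
    for (pre in c(FALSE, TRUE)) {
      got <- normalize_pqn(x, pre_cs = pre)
      want <- pqn_loop_oracle(x, pre_cs = pre)
      expect_equal(unclass(got$values), want$values, tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_equal(unname(got$reference_profile), want$r, tolerance = 1e-12)
    }
    got <- normalize_deseq2(x)
    want <- deseq2_loop_oracle(x)
    expect_equal(unclass(got$values), want$values, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(unname(got$scale_factors), want$s, tolerance = 1e-12)
  }
})

test_that("reference-cancelling schemes are exactly dilution invariant", {
  # IS, CS and PQN with constant-sum pre-scaling: full recomputation
  for (k in 1:20) {
    x <- random_table(10, 8, seed = 2000 + k)
    colnames(x)[1] <- "creatinine"
    i <- 1 + (k %% 10)
    for (c_fac in c(0.1, 3, 50)) {
      y <- x
      y[i, ] <- x[i, ] * c_fac
      expect_lt(max(abs(normalize_is(y, "creatinine")$values[i, ] -
                          normalize_is(x, "creatinine")$values[i, ])), 1e-10)
      expect_lt(max(abs(normalize_cs(y)$values[i, ] -
                          normalize_cs(x)$values[i, ])), 1e-10)
      expect_lt(max(abs(normalize_pqn(y, pre_cs = TRUE)$values[i, ] -
                          normalize_pqn(x, pre_cs = TRUE)$values[i, ])),
                1e-10)
    }
  }
})

test_that("with a fixed reference profile the quotient scale factor tracks dilution exactly", {
  # out-of-sample semantics: r_j from the unperturbed cohort
  for (k in 1:10) {
    x <- random_table(10, 8, seed = 3000 + k)
    r_pqn <- normalize_pqn(x, pre_cs = FALSE)$reference_profile
    r_gm <- normalize_deseq2(x)$reference_profile
    i <- 1 + (k %% 10)
    for (c_fac in c(0.1, 3, 50)) {
      y <- x
      y[i, ] <- x[i, ] * c_fac
      pq <- normalize_pqn(y, pre_cs = FALSE, reference_profile = r_pqn)
      pq0 <- normalize_pqn(x, pre_cs = FALSE, reference_profile = r_pqn)
      expect_equal(pq$scale_factors[[i]], c_fac * pq0$scale_factors[[i]],
                   tolerance = 1e-10)
      expect_lt(max(abs(pq$values[i, ] - pq0$values[i, ])), 1e-10)
      ds <- normalize_deseq2(y, reference_profile = r_gm)
      ds0 <- normalize_deseq2(x, reference_profile = r_gm)
      expect_equal(ds$scale_factors[[i]], c_fac * ds0$scale_factors[[i]],
                   tolerance = 1e-10)
      expect_lt(max(abs(ds$values[i, ] - ds0$values[i, ])), 1e-10)
    }
  }
})

test_that("scheme dispatch routes to the matching transform", {
  x <- random_table(8, 5, seed = 7)
  colnames(x)[2] <- "creatinine"
  via_spec <- apply_scheme(x, normalization_spec("IS", "creatinine"))
  direct <- normalize_is(x, "creatinine")
  expect_equal(via_spec$values, direct$values)
  expect_equal(scheme_label(via_spec), "IS-CREA")

  abs_nt <- apply_scheme(x, normalization_spec("ABS"))
  expect_equal(unclass(abs_nt$values), unclass(as_metabolite_table(x)),
               ignore_attr = TRUE)
  expect_error(normalization_spec("QUANTILE"), "unknown normalization method")
  expect_error(normalization_spec("IS"), "requires a reference_metabolite")
})

test_that("the eight standard data versions are produced with distinct labels", {
  ch <- generate_cohort(generator_config(n_samples = 30, seed = 8L))
  specs <- standard_schemes()
  expect_length(specs, 8L)
  expect_identical(names(specs),
                   c("ABS", "IS-CREA", "IS-GLUC", "IS-UREA", "IS-PSEURID",
                     "CS", "PQN", "DESEQ2"))
  tables <- lapply(specs, function(sp) apply_scheme(ch$table, sp))
  expect_true(all(vapply(tables, inherits, logical(1), "normalized_table")))
  # IS schemes drop exactly their reference
  expect_identical(tables[["IS-CREA"]]$excluded, "creatinine")
  expect_equal(ncol(tables[["IS-UREA"]]$values), 43L)
  expect_equal(ncol(tables[["CS"]]$values), 44L)
})

test_that("normalized tables and scale factors round-trip as text", {
  x <- random_table(6, 4, seed = 4)
  nt <- normalize_pqn(x)
  dir <- withr::local_tempdir()
  paths <- write_normalized_table(nt, file.path(dir, "pqn.csv"))
  expect_true(all(file.exists(paths)))
  back <- read_metabolite_table(paths[["values"]])
  expect_equal(unclass(back), unclass(nt$values), tolerance = 1e-12,
               ignore_attr = TRUE)
  side <- read.csv(paths[["scale_factors"]])
  expect_equal(side$scale_factor, unname(nt$scale_factors),
               tolerance = 1e-12)
  expect_identical(unique(side$scheme), "PQN")
})
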