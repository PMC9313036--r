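# Literal step-by-step reference implementations and small fixture builders
# used as independent oracles for the vectorized code paths.

# PQN by explicit loops: (1) optional constant-sum pre-scaling, (2) median
# reference per metabolite, (3) quotients, (4) per-sample median quotient,
# (5) divide.
pqn_loop_oracle <- function(x, pre_cs = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  w <- x
  if (pre_cs) {
    for (i in seq_len(n)) w[i, ] <- x[i, ] / sum(x[i, ])
  }
  r <- numeric(p)
  for (j in seq_len(p)) r[j] <- median(w[, j])
  s <- numeric(n)
  for (i in seq_len(n)) {
    q <- numeric(p)
    for (j in seq_len(p)) q[j] <- w[i, j] / r[j]
    s[i] <- median(q)
  }
  out <- w
  for (i in seq_len(n)) out[i, ] <- w[i, ] / s[i]
  list(values = out, s = s, r = r)
}

# geometric-mean-reference normalization by explicit loops
deseq2_loop_oracle <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  r <- numeric(p)
  for (j in seq_len(p)) r[j] <- prod(x[, j])^(1 / n)
  s <- numeric(n)
  for (i in seq_len(n)) {
    q <- numeric(p)
    for (j in seq_len(p)) q[j] <- x[i, j] / r[j]
    s[i] <- median(q)
  }
  out <- x
  for (i in seq_len(n)) out[i, ] <- x[i, ] / s[i]
  list(values = out, s = s, r = r)
}

# random strictly positive table with named columns
random_table <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(exp(rnorm(n * p, sd = 1)), n, p)
  colnames(m) <- paste0("met", seq_len(p))
  m
}

# tiny named matrix helper
named_matrix <- function(values, metabolites, byrow = TRUE) {
  matrix(values, ncol = length(metabolites), byrow = byrow,
         dimnames = list(NULL, metabolites))
}

# cohort with no biology and no noise: observed variation is dilution only
pure_dilution_config <- function(n = 100, seed = 11L) {
  generator_config(n_samples = n, biological_log_sd = 0, noise_log_sd = 0,
                   sex_effect = 0,
                   outcome_effects = matrix(0, 44, 2,
                                            dimnames = list(NULL, c("BMI", "MAP"))),
                   sex_outcome_effect = c(BMI = 0, MAP = 0),
                   seed = seed)
}
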