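# shared fixtures built in code

# small analysis table with full joint-genotype support
toy_data <- function(n = 400, seed = 11, maf1 = 0.5, maf2 = 0.5) {
  set.seed(seed)
  data.frame(V1 = rbinom(n, 2, maf1), V2 = rbinom(n, 2, maf2),
             Y = rnorm(n), S = rbinom(n, 1, 0.5),
             age = runif(n, 40, 70), W1 = rnorm(n))
}

# the simulator's structural conditional mean for a given config
structural_mu <- function(cfg) {
  function(v1, v2, data) {
    W <- as.matrix(data[grep("^W[0-9]+$", names(data))])
    Weff <- if (isTRUE(cfg$nonlinear_w)) W + 0.5 * (W^2 - 1) else W
    cfg$alpha0 + cfg$alpha1 * v1 + cfg$alpha2 * v2 +
      (cfg$gamma + cfg$gamma_sex * data$S) * v1 * v2 +
      drop(Weff %*% cfg$delta)
  }
}

# the simulator's true joint genotype propensity P(V1, V2 | W):
# independent binomial(2, logistic) variants given the first confounder
structural_propensity <- function(cfg) {
  function(data) {
    p1 <- plogis(qlogis(cfg$maf1) + cfg$confound_strength * data$W1)
    p2 <- plogis(qlogis(cfg$maf2) + cfg$confound_strength * data$W1)
    P <- matrix(0, nrow(data), 9)
    for (a in 0:2) for (b in 0:2)
      P[, 3 * a + b + 1] <- dbinom(a, 2, p1) * dbinom(b, 2, p2)
    P
  }
}

# random tabulated mean function over the 9 genotype cells, optionally
# modulated by a covariate stratum
random_tab_mu <- function(seed, w_strata = TRUE) {
  set.seed(seed)
  tab <- matrix(rnorm(9, sd = 2), 3, 3)
  shift <- if (w_strata) rnorm(1) else 0
  function(v1, v2, data) {
    tab[cbind(rep_len(v1, nrow(data)) + 1, rep_len(v2, nrow(data)) + 1)] +
      shift * (data$W1 > 0)
  }
}

# dosage vectors realizing prescribed 3x3 joint cell counts
cells_from_counts <- function(counts) {
  stopifnot(is.matrix(counts), all(dim(counts) == c(3, 3)))
  v1 <- rep(rep(0:2, times = 3), as.vector(counts))
  v2 <- rep(rep(0:2, each = 3), as.vector(counts))
  list(v1 = v1, v2 = v2)
}
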