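#' Fit both nuisance functions for one variant pair and trait
#'
#' Convenience wrapper fitting the outcome regression and the joint
#' genotype propensity with the same learner specification, recording the
#' outcome bounds used to map a continuous trait into \[0, 1\] for the
#' logistic targeting step (the observed range widened by 0.5% on each
#' side; binary traits use \[0, 1\] directly).
#'
#' @param data Analysis data.frame (`Y`, `V1`, `V2`, covariates).
#' @param spec A [nuisance_spec()] used for both fits (pass
#'   `outcome_spec` / `propensity_spec` to differ).
#' @param trait_type `"continuous"` or `"binary"`.
#' @param floor Propensity floor (see [fit_propensity()]).
#' @param seed RNG seed.
#' @param by_sex If `TRUE`, fit separate nuisances within each sex stratum
#'   (required for 3-point components); the outcome bounds stay global.
#' @param outcome_spec,propensity_spec Optional per-function overrides.
#' @return An object of class `"fitted_nuisances"` (or
#'   `"fitted_nuisances_by_sex"` with `$male` / `$female` elements).
#' @export
fit_nuisances <- function(data, spec = nuisance_spec(),
                          trait_type = c("continuous", "binary"),
                          floor = 0.001, seed = 1L, by_sex = FALSE,
                          outcome_spec = spec, propensity_spec = spec) {
  trait_type <- match.arg(trait_type)
  bounds <- if (trait_type == "binary") c(0, 1) else {
    r <- range(data$Y) ; m <- 0.005 * diff(r)
    c(r[1] - m, r[2] + m)
  }
  fit_one <- function(d, s) {
    structure(list(
      outcome = fit_outcome_regression(d, outcome_spec, trait_type,
                                       seed = s),
      propensity = fit_propensity(d, propensity_spec, floor = floor,
                                  seed = s),
      trait_type = trait_type, bounds = bounds),
      class = "fitted_nuisances")
  }
  if (!by_sex) return(fit_one(data, seed))
  stopifnot("S" %in% names(data))
  structure(list(male = fit_one(data[data$S == 1, , drop = FALSE], seed),
                 female = fit_one(data[data$S == 0, , drop = FALSE],
                                  seed + 1L),
                 trait_type = trait_type, bounds = bounds),
            class = "fitted_nuisances_by_sex")
}

#' Assemble nuisances from user-supplied mean and propensity functions
#'
#' Builds a `"fitted_nuisances"` object from an arbitrary conditional-mean
#' function and joint-cell probability function (see [as_outcome_fit()],
#' [as_propensity_fit()]), computing the outcome bounds from `data` as
#' [fit_nuisances()] does. Intended for oracle-nuisance validation and
#' misspecification probes.
#'
#' @param mu Function `(v1, v2, data) -> numeric`.
#' @param g Function `(data) -> n x 9` cell-probability matrix.
#' @param data Analysis data.frame (used for the outcome bounds).
#' @param trait_type `"continuous"` or `"binary"`.
#' @param floor Propensity floor.
#' @return A `"fitted_nuisances"` object.
#' @export
custom_nuisances <- function(mu, g, data,
                             trait_type = c("continuous", "binary"),
                             floor = 0.001) {
  trait_type <- match.arg(trait_type)
  bounds <- if (trait_type == "binary") c(0, 1) else {
    r <- range(data$Y) ; m <- 0.005 * diff(r)
    c(r[1] - m, r[2] + m)
  }
  structure(list(outcome = as_outcome_fit(mu, trait_type),
                 propensity = as_propensity_fit(g, floor),
                 trait_type = trait_type, bounds = bounds),
            class = "fitted_nuisances")
}

# weighted intercept-only logistic fluctuation: solves
# sum_i w_i (y_i - plogis(off_i + eps)) = 0 by Newton's method
solve_fluctuation <- function(y, offset, w, tol = 1e-12, max_iter = 100L) {
  eps <- 0
  for (i in seq_len(max_iter)) {
    p <- stats::plogis(offset + eps)
    score <- sum(w * (y - p))
    info <- sum(w * p * (1 - p))
    if (info <= 0) break
    step <- score / info
    eps <- eps + step
    if (abs(step) < tol) break
  }
  eps
}

# targeted mean for one joint genotype cell; data/nuisances already
# restricted to the relevant (sub)population
tmle_cell <- function(data, nuisances, v1, v2) {
  a <- nuisances$bounds[1] ; b <- nuisances$bounds[2]
  ystar <- (data$Y - a) / (b - a)
  q <- (predict_outcome(nuisances$outcome, v1, v2, data) - a) / (b - a)
  q <- pmin(pmax(q, 1e-6), 1 - 1e-6)
  P <- predict_propensity(nuisances$propensity, data)
  g <- P[, cell_code(v1, v2) + 1L]
  in_cell <- as.numeric(data$V1 == v1 & data$V2 == v2)
  if (sum(in_cell) == 0)
    stop(sprintf("joint genotype cell [%d,%d] has no observed support",
                 v1, v2), call. = FALSE)
  if (any(g <= 0))
    stop("zero propensity after flooring; use a positive floor",
         call. = FALSE)
  h <- in_cell / g
  eps <- solve_fluctuation(ystar, stats::qlogis(q), h)
  qstar <- stats::plogis(stats::qlogis(q) + eps)
  est_s <- mean(qstar)
  eic_s <- h * (ystar - qstar) + qstar - est_s
  list(estimate = a + (b - a) * est_s, eic = (b - a) * eic_s,
       epsilon = eps)
}

#' TMLE of a counterfactual mean E\[Y(v1, v2)\]
#'
#' Targets the machine-learned outcome regression with one weighted
#' intercept-only logistic fluctuation using the clever covariate
#' `1{sample in cell} / P(cell | W)`, on the outcome bounded to \[0, 1\],
#' then back-transforms. The fluctuation solves the efficient-influence-
#' curve score equation exactly, so the empirical mean of the returned EIC
#' is zero up to solver tolerance.
#'
#' @param data Analysis data.frame.
#' @param nuisances A `"fitted_nuisances"` object ([fit_nuisances()]).
#' @param cell Length-2 integer vector `c(v1, v2)` of dosages in 0..2.
#' @return List with `estimate` (trait scale), per-sample `eic`, and the
#'   fluctuation coefficient `epsilon`.
#' @export
tmle_counterfactual_mean <- function(data, nuisances, cell) {
  stopifnot(inherits(nuisances, "fitted_nuisances"), length(cell) == 2L)
  tmle_cell(data, nuisances, cell[1], cell[2])
}

# signed corner cells of a 2-point transition
transition_cells <- function(tr) {
  list(cells = rbind(c(tr$v1[2], tr$v2[2]), c(tr$v1[1], tr$v2[2]),
                     c(tr$v1[2], tr$v2[1]), c(tr$v1[1], tr$v2[1])),
       signs = c(1, -1, -1, 1))
}

# combine targeted cells (from a cache keyed "v1_v2") into one 2-point
# component on the population the cache was computed on
combine_cells <- function(cache, tr, n) {
  tc <- transition_cells(tr)
  est <- 0 ; eic <- numeric(n)
  for (r in seq_len(4)) {
    key <- paste(tc$cells[r, 1], tc$cells[r, 2], sep = "_")
    est <- est + tc$signs[r] * cache[[key]]$estimate
    eic <- eic + tc$signs[r] * cache[[key]]$eic
  }
  list(estimate = est, eic = eic)
}

new_component <- function(tr, estimate, eic) {
  n <- length(eic)
  se <- sqrt(mean((eic - mean(eic))^2) / n)
  p <- if (se > 0) 2 * stats::pnorm(-abs(estimate / se)) else
    as.numeric(estimate == 0)
  structure(list(transition = tr, estimate = estimate, se = se, eic = eic,
                 p_component = p),
            class = "component_estimate")
}

#' @export
format.component_estimate <- function(x, ...) {
  sprintf("%s  estimate %.4g (se %.3g, p %.3g)", format(x$transition),
          x$estimate, x$se, x$p_component)
}

#' @export
print.component_estimate <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' TMLE estimates for a set of interaction components
#'
#' Computes every targeted counterfactual cell mean needed by the supplied
#' transitions once (cells shared between transitions are not re-targeted)
#' and assembles the signed combinations. A 2-point component is the
#' four-corner signed sum of targeted cell means; a 3-point component is
#' the male-stratum 2-point component minus the female-stratum one, with
#' each stratum's EIC inflated by the inverse stratum proportion so the
#' difference's EIC is valid on the full sample.
#'
#' @param data Analysis data.frame.
#' @param nuisances `"fitted_nuisances"` (2-point) or
#'   `"fitted_nuisances_by_sex"` (3-point).
#' @param transitions List of [transition()]s (all 2-point or all 3-point).
#' @return List of `"component_estimate"` objects (estimate, se, EIC
#'   vector on the full sample, two-sided Wald p-value), in the input
#'   order.
#' @export
tmle_components <- function(data, nuisances, transitions) {
  if (length(transitions) == 0L) return(list())
  sex_flags <- vapply(transitions, function(tr) tr$sex, logical(1))
  if (any(sex_flags) && !all(sex_flags))
    stop("mix of 2-point and 3-point transitions; split the calls",
         call. = FALSE)
  n <- nrow(data)
  needed_cells <- unique(do.call(rbind, lapply(transitions, function(tr)
    transition_cells(tr)$cells)))
  build_cache <- function(d, nu) {
    cache <- list()
    for (r in seq_len(nrow(needed_cells))) {
      key <- paste(needed_cells[r, 1], needed_cells[r, 2], sep = "_")
      cache[[key]] <- tmle_cell(d, nu, needed_cells[r, 1],
                                needed_cells[r, 2])
    }
    cache
  }
  if (!any(sex_flags)) {
    stopifnot(inherits(nuisances, "fitted_nuisances"))
    cache <- build_cache(data, nuisances)
    return(lapply(transitions, function(tr) {
      cc <- combine_cells(cache, tr, n)
      new_component(tr, cc$estimate, cc$eic)
    }))
  }
  stopifnot(inherits(nuisances, "fitted_nuisances_by_sex"))
  idx <- list(male = which(data$S == 1), female = which(data$S == 0))
  if (length(idx$male) == 0L || length(idx$female) == 0L)
    stop("both sexes must be present for 3-point components",
         call. = FALSE)
  caches <- list(male = build_cache(data[idx$male, , drop = FALSE],
                                    nuisances$male),
                 female = build_cache(data[idx$female, , drop = FALSE],
                                      nuisances$female))
  pi_s <- vapply(idx, length, integer(1)) / n
  lapply(transitions, function(tr) {
    parts <- lapply(c("male", "female"), function(s)
      combine_cells(caches[[s]], tr, length(idx[[s]])))
    names(parts) <- c("male", "female")
    est <- parts$male$estimate - parts$female$estimate
    eic <- numeric(n)
    eic[idx$male] <- parts$male$eic / pi_s[["male"]]
    eic[idx$female] <- -parts$female$eic / pi_s[["female"]]
    new_component(tr, est, eic)
  })
}

#' TMLE estimate of a single interaction component
#'
#' @inheritParams tmle_components
#' @param tr A single [transition()].
#' @return A `"component_estimate"`.
#' @export
tmle_component <- function(data, nuisances, tr) {
  tmle_components(data, nuisances, list(tr))[[1]]
}

#' Joint covariance of component estimators from their influence curves
#'
#' The (j, l) entry is the empirical covariance of the j-th and l-th
#' per-sample EIC values divided by the sample size — the asymptotic
#' covariance of the estimator vector. Its diagonal equals the squared
#' per-component standard errors, and the matrix is positive semi-definite
#' by construction (a scaled Gram matrix).
#'
#' @param components List of `"component_estimate"`s computed on the same
#'   samples.
#' @return A k x k matrix of class `"component_covariance"` with the
#'   transition labels as dimnames.
#' @export
component_covariance <- function(components) {
  stopifnot(length(components) >= 1L)
  ns <- vapply(components, function(x) length(x$eic), integer(1))
  if (length(unique(ns)) != 1L)
    stop("components were computed on different sample counts",
         call. = FALSE)
  n <- ns[1]
  E <- vapply(components, function(x) x$eic - mean(x$eic), numeric(n))
  sigma <- crossprod(E) / n^2
  labs <- vapply(components, function(x) format(x$transition), character(1))
  dimnames(sigma) <- list(labs, labs)
  class(sigma) <- c("component_covariance", class(sigma))
  sigma
}
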