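#' Nuisance learner specification
#'
#' Controls how the two nuisance functions — the outcome regression
#' `E[Y | V1, V2, S, age, W]` and the joint genotype propensity
#' `P(V1, V2 | W)` — are estimated. The boosted learner cross-validates
#' over tree depth and L2 regularization strength; the generalized-linear
#' learner fits a parametric model with variant(-by-sex) interactions; the
#' constant-mean baseline ignores all covariates and serves as a
#' misspecification probe and a CV sanity floor.
#'
#' @param learner `"xgboost"`, `"glm"` or `"mean"`.
#' @param folds Cross-validation fold count (>= 2).
#' @param depth_grid Candidate tree depths (xgboost).
#' @param lambda_grid Candidate L2 regularization strengths (xgboost).
#' @param nrounds Maximum boosting rounds; early stopping on the CV loss.
#' @param eta Boosting learning rate.
#' @return A list of class `"nuisance_spec"`.
#' @export
nuisance_spec <- function(learner = c("xgboost", "glm", "mean"),
                          folds = 3L, depth_grid = c(2L, 4L),
                          lambda_grid = c(1, 10), nrounds = 100L,
                          eta = 0.3) {
  learner <- match.arg(learner)
  stopifnot(folds >= 2, length(depth_grid) >= 1, length(lambda_grid) >= 1)
  structure(list(learner = learner, folds = as.integer(folds),
                 depth_grid = as.integer(depth_grid),
                 lambda_grid = lambda_grid, nrounds = as.integer(nrounds),
                 eta = eta),
            class = "nuisance_spec")
}

# covariate columns used by the nuisance fits: S/age if present and
# non-constant, plus every W* column
nuisance_covariates <- function(data) {
  covs <- grep("^W[0-9]+$", names(data), value = TRUE)
  for (extra in c("age", "S"))
    if (extra %in% names(data) && length(unique(data[[extra]])) > 1L)
      covs <- c(extra, covs)
  covs
}

cell_code <- function(v1, v2) 3L * v1 + v2   # 0..8, row-major in V1

# deterministic fold assignment
fold_ids <- function(n, k) rep_len(seq_len(k), n)[sample.int(n)]

# grid-search xgboost with k-fold CV on the given objective; returns the
# refit booster, the selected hyperparameters and the winning CV loss
xgb_cv_fit <- function(X, y, spec, objective, num_class = NULL, seed = 1L) {
  set.seed(seed)
  folds <- fold_ids(nrow(X), spec$folds)
  grid <- expand.grid(depth = spec$depth_grid, lambda = spec$lambda_grid)
  metric <- switch(objective, "reg:squarederror" = "rmse",
                   "binary:logistic" = "logloss",
                   "multi:softprob" = "mlogloss")
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    params <- list(objective = objective, max_depth = grid$depth[i],
                   lambda = grid$lambda[i], eta = spec$eta, nthread = 1L,
                   eval_metric = metric)
    if (!is.null(num_class)) params$num_class <- num_class
    cv <- xgboost::xgb.cv(params = params, data = dtrain,
                          nrounds = spec$nrounds,
                          folds = split(seq_len(nrow(X)), folds),
                          early_stopping_rounds = 10L, verbose = 0)
    log <- as.data.frame(cv$evaluation_log)
    loss_col <- paste0("test_", metric, "_mean")
    it <- cv$best_iteration
    if (is.null(it) || length(it) == 0L) it <- which.min(log[[loss_col]])
    loss <- log[[loss_col]][it]
    if (is.null(best) || loss < best$loss)
      best <- list(loss = loss, depth = grid$depth[i],
                   lambda = grid$lambda[i], nrounds = it)
  }
  params <- list(objective = objective, max_depth = best$depth,
                 lambda = best$lambda, eta = spec$eta, nthread = 1L)
  if (!is.null(num_class)) params$num_class <- num_class
  set.seed(seed)
  fit <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = best$nrounds, verbose = 0)
  list(fit = fit, loss = best$loss,
       hyperparameters = best[c("depth", "lambda", "nrounds")])
}

# k-fold CV loss (squared or log loss) of an arbitrary fit/predict pair
cv_loss_generic <- function(data, y, folds_k, fit_fun, pred_fun, loss_fun,
                            seed) {
  set.seed(seed)
  folds <- fold_ids(nrow(data), folds_k)
  losses <- vapply(seq_len(folds_k), function(k) {
    tr <- data[folds != k, , drop = FALSE]
    te <- data[folds == k, , drop = FALSE]
    m <- fit_fun(tr)
    mean(loss_fun(y[folds == k], pred_fun(m, te)))
  }, numeric(1))
  c(mean = mean(losses), se = stats::sd(losses) / sqrt(folds_k))
}

#' Fit the outcome regression E\[Y | V1, V2, S, age, W\]
#'
#' @param data Analysis data.frame with `Y`, dosages `V1`, `V2`, and
#'   covariates (`S`, `age`, `W1`, ...).
#' @param spec A [nuisance_spec()].
#' @param trait_type `"continuous"` or `"binary"`.
#' @param seed RNG seed; the fit (fold split, hyperparameter selection) is
#'   deterministic given the seed.
#' @return An object of class `"outcome_fit"`; evaluate counterfactual
#'   means with [predict_outcome()]. Carries `cv_loss` (mean and fold SE of
#'   the CV loss) and, for the boosted learner, the selected
#'   hyperparameters.
#' @export
fit_outcome_regression <- function(data, spec = nuisance_spec(),
                                   trait_type = c("continuous", "binary"),
                                   seed = 1L) {
  trait_type <- match.arg(trait_type)
  stopifnot(inherits(spec, "nuisance_spec"))
  y <- data$Y
  covs <- nuisance_covariates(data)
  if (length(unique(y)) == 1L) {
    warning("constant outcome; fitting a constant mean")
    spec$learner <- "mean"
  }
  loss_fun <- if (trait_type == "continuous") {
    function(y, p) (y - p)^2
  } else {
    function(y, p) {
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -(y * log(p) + (1 - y) * log(1 - p))
    }
  }
  obj <- switch(spec$learner,
    mean = {
      mu <- mean(y)
      cvl <- cv_loss_generic(data, y, spec$folds,
                             function(tr) mean(tr$Y),
                             function(m, te) rep(m, nrow(te)),
                             loss_fun, seed)
      list(kind = "mean", value = mu, cv_loss = cvl)
    },
    glm = {
      has_sex <- "S" %in% covs
      inter <- if (has_sex) "V1 * V2 * S" else "V1 * V2"
      rhs <- paste(c(inter, setdiff(covs, "S")), collapse = " + ")
      fml <- stats::as.formula(paste("Y ~", rhs))
      fam <- if (trait_type == "binary") stats::binomial() else
        stats::gaussian()
      fit_one <- function(tr) stats::glm(fml, data = tr, family = fam)
      cvl <- cv_loss_generic(data, y, spec$folds, fit_one,
                             function(m, te)
                               stats::predict(m, te, type = "response"),
                             loss_fun, seed)
      set.seed(seed)
      list(kind = "glm", fit = fit_one(data), cv_loss = cvl)
    },
    xgboost = {
      X <- as.matrix(data[c("V1", "V2", covs)])
      objective <- if (trait_type == "binary") "binary:logistic" else
        "reg:squarederror"
      res <- xgb_cv_fit(X, y, spec, objective, seed = seed)
      # fold SE of the CV loss from a light re-evaluation is not needed;
      # xgb.cv already averaged over folds
      list(kind = "xgboost", fit = res$fit,
           cv_loss = c(mean = res$loss, se = NA_real_),
           hyperparameters = res$hyperparameters, features = c("V1", "V2", covs))
    })
  structure(c(obj, list(covariates = covs, trait_type = trait_type)),
            class = "outcome_fit")
}

#' Wrap an arbitrary conditional-mean function as an outcome fit
#'
#' Lets a user-supplied (e.g. oracle or tabulated) mean function
#' `function(v1, v2, data)` stand in for a fitted outcome regression in
#' the targeting step — useful for misspecification probes and for
#' validation against a known data-generating process.
#'
#' @param fun Function `(v1, v2, data) -> numeric(nrow(data))`.
#' @param trait_type `"continuous"` or `"binary"`.
#' @return An `"outcome_fit"`.
#' @export
as_outcome_fit <- function(fun, trait_type = "continuous") {
  structure(list(kind = "function", fun = fun, trait_type = trait_type),
            class = "outcome_fit")
}

#' Wrap an arbitrary cell-probability function as a propensity fit
#'
#' @param fun Function `(data) -> n x 9 matrix` of joint genotype cell
#'   probabilities in cell-code order (`3 * v1 + v2`).
#' @param floor Lower clip applied at prediction time.
#' @return A `"propensity_fit"`.
#' @export
as_propensity_fit <- function(fun, floor = 0.001) {
  structure(list(kind = "function", fun = fun, floor = floor),
            class = "propensity_fit")
}

#' Evaluate a fitted outcome regression at counterfactual genotypes
#'
#' @param fit An `"outcome_fit"`.
#' @param v1,v2 Counterfactual dosages (scalars or vectors of `nrow(data)`).
#' @param data Covariate data.frame (observed `S`, `age`, `W`...).
#' @return Predicted conditional mean (probability for binary traits), one
#'   value per row of `data`.
#' @export
predict_outcome <- function(fit, v1, v2, data) {
  stopifnot(inherits(fit, "outcome_fit"))
  n <- nrow(data)
  nd <- data
  nd$V1 <- rep_len(v1, n) ; nd$V2 <- rep_len(v2, n)
  switch(fit$kind,
         "function" = {
           out <- fit$fun(nd$V1, nd$V2, nd)
           rep_len(out, n)
         },
         mean = rep(fit$value, n),
         glm = as.numeric(stats::predict(fit$fit, nd, type = "response")),
         xgboost = {
           X <- as.matrix(nd[fit$features])
           as.numeric(stats::predict(fit$fit, xgboost::xgb.DMatrix(X)))
         })
}

#' Mean-function view of a fitted outcome regression
#'
#' Wraps an `"outcome_fit"` as a `function(v1, v2, data)` suitable for the
#' plug-in estimands ([plugin_ate()], [plugin_aie2()], ...).
#'
#' @param fit An `"outcome_fit"`.
#' @return A function `(v1, v2, data) -> numeric`.
#' @export
as_mu <- function(fit) {
  force(fit)
  function(v1, v2, data) predict_outcome(fit, v1, v2, data)
}

#' Fit the joint genotype propensity P(V1, V2 | W)
#'
#' Models the nine joint genotype cells of the two variants as a single
#' conditional distribution of the confounders (not two independent
#' per-variant models, since the variants need not be independent given W).
#' Predicted cell probabilities are clipped below at `floor` and
#' renormalized, keeping inverse-propensity weights bounded without masking
#' true positivity violations (which are filtered upstream at a higher
#' threshold).
#'
#' @inheritParams fit_outcome_regression
#' @param floor Lower clip for any predicted cell probability
#'   (default 0.001, an order of magnitude below the default positivity
#'   threshold).
#' @return An object of class `"propensity_fit"`; evaluate with
#'   [predict_propensity()].
#' @export
fit_propensity <- function(data, spec = nuisance_spec(), floor = 0.001,
                           seed = 1L) {
  stopifnot(inherits(spec, "nuisance_spec"), floor >= 0, floor < 1 / 9)
  covs <- setdiff(nuisance_covariates(data), c("S", "age"))
  cls <- cell_code(data$V1, data$V2)
  obj <- switch(spec$learner,
    mean = {
      freq <- tabulate(cls + 1L, nbins = 9L) / length(cls)
      list(kind = "mean", freq = freq)
    },
    glm = {
      df <- data.frame(cell = factor(cls, levels = sort(unique(cls))),
                       data[covs])
      set.seed(seed)
      fit <- nnet::multinom(
        stats::as.formula(paste("cell ~", paste(covs, collapse = " + "))),
        data = df, trace = FALSE, maxit = 200)
      list(kind = "glm", fit = fit, levels = sort(unique(cls)))
    },
    xgboost = {
      X <- as.matrix(data[covs])
      lev <- sort(unique(cls))
      y <- match(cls, lev) - 1L
      res <- xgb_cv_fit(X, y, spec, "multi:softprob",
                        num_class = length(lev), seed = seed)
      list(kind = "xgboost", fit = res$fit, levels = lev,
           hyperparameters = res$hyperparameters)
    })
  structure(c(obj, list(covariates = covs, floor = floor)),
            class = "propensity_fit")
}

#' Predict joint genotype cell probabilities
#'
#' @param fit A `"propensity_fit"`.
#' @param data Covariate data.frame.
#' @return An `nrow(data)` x 9 matrix of probabilities, columns named by
#'   cell code `"v1_v2"` for dosages 0..2; each row sums to 1 and every
#'   entry is at least the fit's floor (before renormalization).
#' @export
predict_propensity <- function(fit, data) {
  stopifnot(inherits(fit, "propensity_fit"))
  n <- nrow(data)
  P <- matrix(0, n, 9L)
  switch(fit$kind,
    "function" = {
      P <- fit$fun(data)
      stopifnot(is.matrix(P), nrow(P) == n, ncol(P) == 9L)
    },
    mean = {
      P <- matrix(rep(fit$freq, each = n), n, 9L)
    },
    glm = {
      pr <- stats::predict(fit$fit, data, type = "probs")
      if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)  # two-level fallback
      P[, fit$levels + 1L] <- pr
    },
    xgboost = {
      X <- as.matrix(data[fit$covariates])
      pr <- matrix(stats::predict(fit$fit, xgboost::xgb.DMatrix(X)),
                   nrow = n, byrow = TRUE)
      P[, fit$levels + 1L] <- pr
    })
  P <- pmax(P, fit$floor)
  P <- P / rowSums(P)
  colnames(P) <- paste(rep(0:2, each = 3), rep(0:2, times = 3), sep = "_")
  P
}
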