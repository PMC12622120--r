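#' Simulation configuration for a synthetic cohort
#'
#' Bundles the parameters of the structural trait model
#' \deqn{Y = \alpha_0 + \alpha_1 V_1 + \alpha_2 V_2 +
#'   (\gamma + \gamma_{sex} S)\, V_1 V_2 + \delta' W + \epsilon}
#' together with the genotype-generating mechanism: both variants are drawn
#' in Hardy-Weinberg proportions at their effect-allele frequencies, with an
#' optional logistic shift of the per-sample allele probability by the first
#' confounder coordinate (making W a genuine common cause of genotype and
#' trait) and optional linkage disequilibrium between the two variants.
#'
#' @param n Sample count.
#' @param maf1,maf2 Effect-allele frequencies of V1 (bQTL) and V2 (fQTL),
#'   in (0, 1) for cohort simulation.
#' @param target_r2 Desired squared dosage correlation between V1 and V2
#'   (0 = independent variants).
#' @param alpha0,alpha1,alpha2,gamma Structural coefficients, trait units
#'   per effect-allele copy (`gamma` per allele-pair product).
#' @param delta Confounder coefficient vector; its length sets the number of
#'   confounder columns W1, W2, ...
#' @param gamma_sex Additive shift of the interaction coefficient in males
#'   (0 disables the 3-point signal).
#' @param confound_strength Slope of the allele log-odds in the first
#'   confounder coordinate; 0 gives genotypes independent of W.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param noise_sd Residual standard deviation of a continuous trait.
#' @param nonlinear_w If `TRUE`, the confounder enters the trait model as
#'   `W + 0.5 * (W^2 - 1)` instead of linearly, to stress model-robustness
#'   of downstream estimators.
#' @param seed RNG seed; identical seeds give bit-identical cohorts.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n = 1000, maf1 = 0.3, maf2 = 0.3, target_r2 = 0,
                       alpha0 = 0, alpha1 = 0, alpha2 = 0, gamma = 0,
                       delta = c(1, 0.5), gamma_sex = 0,
                       confound_strength = 0,
                       trait_type = c("continuous", "binary"),
                       noise_sd = 1, nonlinear_w = FALSE, seed = 1L) {
  trait_type <- match.arg(trait_type)
  stopifnot(n >= 1, noise_sd >= 0,
            maf1 > 0, maf1 < 1, maf2 > 0, maf2 < 1,
            target_r2 >= 0, target_r2 <= 1)
  structure(list(n = as.integer(n), maf1 = maf1, maf2 = maf2,
                 target_r2 = target_r2, alpha0 = alpha0, alpha1 = alpha1,
                 alpha2 = alpha2, gamma = gamma, delta = delta,
                 gamma_sex = gamma_sex, confound_strength = confound_strength,
                 trait_type = trait_type, noise_sd = noise_sd,
                 nonlinear_w = nonlinear_w, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate biallelic genotype dosages under (confounded) Hardy-Weinberg
#'
#' Each dosage is a binomial count of 2 allele draws with per-sample allele
#' probability `plogis(qlogis(maf) + confound_strength * w)`. With
#' `confound_strength = 0` this reduces to i.i.d. Hardy-Weinberg genotypes
#' at frequency `maf`.
#'
#' @param n Sample count.
#' @param maf Effect-allele frequency in \[0, 1\].
#' @param w Optional confounder vector of length `n` shifting the allele
#'   log-odds.
#' @param confound_strength Slope on `w`; ignored when `w` is `NULL`.
#' @param seed Optional RNG seed.
#' @return Integer dosage vector in \{0, 1, 2\}.
#' @export
simulate_genotypes <- function(n, maf, w = NULL, confound_strength = 0,
                               seed = NULL) {
  if (!is.numeric(maf) || length(maf) != 1L || is.na(maf) ||
      maf < 0 || maf > 1)
    stop("`maf` must be a single frequency in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(w) || confound_strength == 0) {
    p <- rep(maf, n)
  } else {
    stopifnot(length(w) == n)
    p <- stats::plogis(stats::qlogis(maf) + confound_strength * w)
  }
  stats::rbinom(n, 2L, p)
}

#' Simulate a second variant in linkage disequilibrium with an existing one
#'
#' Builds the new variant haplotype-copy-wise: each of the two allele copies
#' of `g` is retained with probability `t` and otherwise replaced by an
#' independent Bernoulli draw, with `t` and the replacement frequency solved
#' in closed form so that the dosage correlation converges to
#' `sqrt(target_r2)` and the marginal effect-allele frequency to `maf`.
#' Allele copies of a heterozygote are recovered in random phase, which is
#' immaterial for unphased dosages.
#'
#' @param g Dosage vector in \{0, 1, 2\} of the template variant.
#' @param target_r2 Desired squared dosage correlation, in \[0, 1\].
#' @param maf Desired marginal effect-allele frequency of the new variant;
#'   defaults to the template's empirical frequency.
#' @param seed Optional RNG seed.
#' @return Integer dosage vector; attribute `"achieved_maf"` records the
#'   analytic marginal used.
#' @export
simulate_correlated_variant <- function(g, target_r2, maf = mean(g) / 2,
                                        seed = NULL) {
  stopifnot(target_r2 >= 0, target_r2 <= 1, maf >= 0, maf <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(g)
  p <- mean(g) / 2                    # template allele frequency
  if (p <= 0 || p >= 1)
    stop("template variant is monomorphic; LD is undefined", call. = FALSE)
  if (target_r2 == 0) {
    out <- stats::rbinom(n, 2L, maf)
    attr(out, "achieved_maf") <- maf
    return(out)
  }
  m <- maf
  # copy probability matching corr(dosage) = sqrt(target_r2) at marginal m
  t <- sqrt(target_r2) * sqrt(m * (1 - m) / (p * (1 - p)))
  if (t > 1 + 1e-8) {
    r2max <- p * (1 - p) / (m * (1 - m))
    stop(sprintf(paste0("target_r2 = %.3f infeasible at maf = %.3f given the ",
                        "template frequency %.3f; achievable r2 <= %.3f"),
                 target_r2, maf, p, r2max), call. = FALSE)
  }
  t <- min(t, 1)
  if (t == 1) {
    out <- as.integer(g)
    attr(out, "achieved_maf") <- p
    return(out)
  }
  q <- (m - t * p) / (1 - t)          # replacement allele frequency
  if (q < 0 || q > 1) {
    stop(sprintf(paste0("target_r2 = %.3f infeasible at maf = %.3f given the ",
                        "template frequency %.3f (replacement frequency %.3f ",
                        "outside [0, 1])"), target_r2, maf, p, q),
         call. = FALSE)
  }
  # split each dosage into two exchangeable allele copies
  a1 <- as.integer(g >= 1) ; a2 <- as.integer(g == 2)
  het <- g == 1L
  swap <- stats::runif(n) < 0.5
  tmp <- a1[het & swap] ; a1[het & swap] <- a2[het & swap]
  a2[het & swap] <- tmp
  keep1 <- stats::runif(n) < t ; keep2 <- stats::runif(n) < t
  b1 <- ifelse(keep1, a1, stats::rbinom(n, 1L, q))
  b2 <- ifelse(keep2, a2, stats::rbinom(n, 1L, q))
  out <- as.integer(b1 + b2)
  attr(out, "achieved_maf") <- m
  out
}

#' Simulate a full cohort (genotypes, covariates, trait)
#'
#' Draws confounders W ~ N(0, 1), sex S ~ Bernoulli(0.5), age ~ U(40, 70),
#' genotypes per [simulate_genotypes()] (both variants confounded by the
#' first W coordinate when `confound_strength != 0`, V2 optionally in LD
#' with V1), and the trait from the structural model in [sim_config()].
#' Binary traits pass the linear predictor through the inverse logit.
#'
#' @param config A [sim_config()].
#' @return A list of class `"sim_cohort"` with elements
#'   \describe{
#'     \item{genotypes}{data.frame `sample_id`, `V1`, `V2` (dosages).}
#'     \item{variants}{variant metadata (id, effect and other allele).}
#'     \item{cohort}{data.frame `sample_id`, `Y`, `S`, `age`, `W1`, ...}
#'     \item{data}{the joined analysis table (dosages + cohort columns).}
#'     \item{config}{the input configuration.}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n
  k_w <- length(config$delta)
  W <- matrix(stats::rnorm(n * k_w), n, k_w,
              dimnames = list(NULL, paste0("W", seq_len(k_w))))
  S <- stats::rbinom(n, 1L, 0.5)
  age <- stats::runif(n, 40, 70)
  w1 <- W[, 1L]
  V1 <- simulate_genotypes(n, config$maf1, w = w1,
                           confound_strength = config$confound_strength)
  if (config$target_r2 > 0) {
    V2 <- simulate_correlated_variant(V1, config$target_r2,
                                      maf = config$maf2)
    attributes(V2) <- NULL
  } else {
    V2 <- simulate_genotypes(n, config$maf2, w = w1,
                             confound_strength = config$confound_strength)
  }
  Weff <- if (config$nonlinear_w) W + 0.5 * (W^2 - 1) else W
  lp <- config$alpha0 + config$alpha1 * V1 + config$alpha2 * V2 +
    (config$gamma + config$gamma_sex * S) * V1 * V2 +
    drop(Weff %*% config$delta)
  Y <- if (config$trait_type == "continuous") {
    lp + stats::rnorm(n, 0, config$noise_sd)
  } else {
    stats::rbinom(n, 1L, stats::plogis(lp))
  }
  sample_id <- sprintf("S%06d", seq_len(n))
  cohort <- data.frame(sample_id = sample_id, Y = Y, S = S, age = age, W,
                       stringsAsFactors = FALSE)
  genotypes <- data.frame(sample_id = sample_id, V1 = V1, V2 = V2,
                          stringsAsFactors = FALSE)
  variants <- data.frame(id = c("V1", "V2"),
                         effect_allele = c("B", "F"),
                         other_allele = c("b", "f"),
                         stringsAsFactors = FALSE)
  structure(list(genotypes = genotypes, variants = variants,
                 cohort = cohort,
                 data = cbind(genotypes[c("V1", "V2")],
                              cohort[setdiff(names(cohort), "sample_id")]),
                 config = config),
            class = "sim_cohort")
}

#' Exact ground-truth estimand value under the linear structural model
#'
#' For continuous traits generated by [simulate_cohort()], the
#' model-independent estimands have closed forms: the ATE of one allelic
#' change in V1 is `alpha1 + gamma_eff * E[V2]` with `E[V2] = 2 * maf2` on
#' the dosage scale and `gamma_eff = gamma + 0.5 * gamma_sex` (the
#' sex-marginal interaction coefficient); every 2-point AIE equals
#' `gamma_eff`; every 3-point (sex-difference) AIE equals `gamma_sex`.
#'
#' @param config A continuous-trait [sim_config()].
#' @param estimand One of `"ate_v1"`, `"ate_v2"`, `"aie2"`, `"aie3"`.
#' @return The exact estimand value (trait units).
#' @export
oracle_effects <- function(config,
                           estimand = c("aie2", "ate_v1", "ate_v2", "aie3")) {
  stopifnot(inherits(config, "sim_config"))
  estimand <- match.arg(estimand)
  if (config$trait_type != "continuous")
    stop(paste("no closed form on the risk-difference scale for binary",
               "traits; use a high-n Monte-Carlo oracle"), call. = FALSE)
  g_eff <- config$gamma + 0.5 * config$gamma_sex
  switch(estimand,
         ate_v1 = config$alpha1 + g_eff * 2 * config$maf2,
         ate_v2 = config$alpha2 + g_eff * 2 * config$maf1,
         aie2   = g_eff,
         aie3   = config$gamma_sex)
}

#' Write a simulated cohort to TSV (and optionally a minimal VCF)
#'
#' @param sim A `"sim_cohort"`.
#' @param genotype_path,phenotype_path Output TSV paths (samples as rows).
#' @param vcf_path Optional path for a minimal VCF 4.2 with GT fields; the
#'   counted (ALT) allele is the effect allele.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(sim, genotype_path, phenotype_path,
                         vcf_path = NULL) {
  stopifnot(inherits(sim, "sim_cohort"))
  utils::write.table(sim$genotypes, genotype_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$cohort, phenotype_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(genotype_path, phenotype_path)
  if (!is.null(vcf_path)) {
    ids <- sim$genotypes$sample_id
    gt_code <- c("0/0", "0/1", "1/1")
    header <- c("##fileformat=VCFv4.2",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", ids), collapse = "\t"))
    rows <- vapply(seq_len(nrow(sim$variants)), function(j) {
      v <- sim$variants[j, ]
      d <- sim$genotypes[[v$id]]
      paste(c("1", as.character(1000L * j), v$id, v$other_allele,
              v$effect_allele, ".", "PASS", ".", "GT", gt_code[d + 1L]),
            collapse = "\t")
    }, character(1))
    writeLines(c(header, rows), vcf_path)
    paths <- c(paths, vcf_path)
  }
  invisible(paths)
}
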