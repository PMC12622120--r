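#' Specify one interaction component (a pair of single-allele changes)
#'
#' A component contrasts a single-allele increment toward the effect (B/F)
#' allele in each participating variant, e.g. `bb -> bB` crossed with
#' `fF -> FF`, optionally further contrasted between sexes (female -> male)
#' for 3-point components.
#'
#' @param v1,v2 Length-2 integer vectors `c(from, to)`; must be one of
#'   `c(0, 1)` or `c(1, 2)`.
#' @param sex If `TRUE` the component is the male-minus-female difference of
#'   the 2-point contrast.
#' @return A list of class `"transition"`.
#' @export
transition <- function(v1, v2, sex = FALSE) {
  ok <- function(x) length(x) == 2L && (all(x == c(0, 1)) || all(x == c(1, 2)))
  if (!ok(v1) || !ok(v2))
    stop("each change must be a single-allele increment: c(0,1) or c(1,2)",
         call. = FALSE)
  structure(list(v1 = as.integer(v1), v2 = as.integer(v2),
                 sex = isTRUE(sex)),
            class = "transition")
}

#' @export
format.transition <- function(x, ...) {
  lab <- function(from, to, alleles) {
    geno <- c(paste0(alleles[1], alleles[1]),
              paste0(alleles[1], alleles[2]),
              paste0(alleles[2], alleles[2]))
    paste0(geno[from + 1L], "→", geno[to + 1L])
  }
  out <- paste(lab(x$v1[1], x$v1[2], c("b", "B")),
               lab(x$v2[1], x$v2[2], c("f", "F")), sep = ";")
  if (x$sex) out <- paste0(out, ";F→M")
  out
}

#' @export
print.transition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# the four candidate single-allele transition pairs, in fixed
# lexicographic order (V1 change, then V2 change)
candidate_transitions <- function(with_sex = FALSE) {
  lev <- list(c(0L, 1L), c(1L, 2L))
  out <- list()
  for (a in lev) for (b in lev)
    out[[length(out) + 1L]] <- transition(a, b, sex = with_sex)
  out
}

#' Enumerate transitions passing the positivity criterion
#'
#' Computes the empirical 3 x 3 joint genotype frequency table of the two
#' variants (within each sex stratum for 3-point components) and keeps each
#' candidate single-allele transition pair only if every one of its four
#' implied corner cells has frequency strictly above `threshold`, the
#' minimum-genotype-frequency rule that bounds the number of interpretable
#' components at k <= 4.
#'
#' @param v1,v2 Dosage vectors in \{0, 1, 2\}.
#' @param threshold Positivity threshold on joint genotype frequency
#'   (default 0.01).
#' @param with_sex If `TRUE`, build sex-difference (3-point) candidates and
#'   require positivity within both sex strata.
#' @param sex Sex vector (0 = female, 1 = male); required with `with_sex`.
#' @return A list with `transitions` (list of [transition()], possibly
#'   empty), `k`, and `report` (a `"positivity_report"` data.frame of cell
#'   frequencies plus a per-transition pass table naming the limiting cell).
#' @export
enumerate_transitions <- function(v1, v2, threshold = 0.01,
                                  with_sex = FALSE, sex = NULL) {
  stopifnot(length(v1) == length(v2), threshold > 0, threshold < 1)
  if (with_sex && is.null(sex))
    stop("`sex` is required for 3-point enumeration", call. = FALSE)
  n <- length(v1)
  cell_freq <- function(idx) {
    tab <- table(factor(v1[idx], levels = 0:2),
                 factor(v2[idx], levels = 0:2))
    tab / length(idx)
  }
  strata <- if (with_sex) {
    list(female = which(sex == 0), male = which(sex == 1))
  } else list(all = seq_len(n))
  freqs <- lapply(strata, cell_freq)

  cells <- do.call(rbind, lapply(names(freqs), function(s) {
    f <- freqs[[s]]
    data.frame(stratum = s,
               v1 = rep(0:2, 3), v2 = rep(0:2, each = 3),
               count = as.vector(f) * length(strata[[s]]),
               freq = as.vector(f), stringsAsFactors = FALSE)
  }))

  cand <- candidate_transitions(with_sex)
  checks <- lapply(cand, function(tr) {
    corners <- expand.grid(v1 = tr$v1, v2 = tr$v2)
    worst <- Inf ; worst_cell <- NA_character_
    for (s in names(freqs)) {
      f <- freqs[[s]]
      for (r in seq_len(nrow(corners))) {
        fr <- f[corners$v1[r] + 1L, corners$v2[r] + 1L]
        if (fr < worst) {
          worst <- fr
          worst_cell <- sprintf("[%d,%d]%s", corners$v1[r], corners$v2[r],
                                if (with_sex) paste0("@", s) else "")
        }
      }
    }
    list(pass = worst > threshold, limiting_cell = worst_cell,
         limiting_freq = worst)
  })
  pass_tab <- data.frame(
    transition = vapply(cand, format, character(1)),
    pass = vapply(checks, `[[`, logical(1), "pass"),
    limiting_cell = vapply(checks, `[[`, character(1), "limiting_cell"),
    limiting_freq = vapply(checks, `[[`, numeric(1), "limiting_freq"),
    stringsAsFactors = FALSE)
  keep <- cand[pass_tab$pass]
  report <- structure(list(cells = cells, transitions = pass_tab,
                           threshold = threshold),
                      class = "positivity_report")
  list(transitions = keep, k = length(keep), report = report)
}

#' Serialize a positivity report as TSV
#'
#' @param report A `"positivity_report"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_positivity_report <- function(report, path) {
  stopifnot(inherits(report, "positivity_report"))
  utils::write.table(report$cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# evaluate a conditional-mean function at counterfactual genotype settings;
# mu has signature function(v1, v2, data) -> numeric(nrow(data))
eval_mu <- function(mu, v1, v2, data) {
  out <- mu(v1, v2, data)
  if (any(!is.finite(out)))
    stop(sprintf("mean function returned non-finite values (first at sample %d)",
                 which(!is.finite(out))[1]), call. = FALSE)
  out
}

#' Plug-in (g-computation) average treatment effect of one allelic change
#'
#' The confounder-adjusted effect of changing one variant from its `from`
#' to its `to` genotype: the empirical-W average of
#' `mu(to, W) - mu(from, W)`. The other variant enters `mu` at its observed
#' dosage by default (so that with a linear truth the value equals
#' `alpha1 + gamma * E[V2]` with the empirical `E[V2]`), or at a fixed
#' level via `other`.
#'
#' @param mu Conditional-mean function `function(v1, v2, data)` returning a
#'   prediction per row of `data`.
#' @param data Analysis data.frame with dosage columns `V1`, `V2` and
#'   covariates.
#' @param variant `"V1"` or `"V2"`: which variant is changed.
#' @param tr A [transition()] supplying the (from, to) pair for `variant`.
#' @param other `"observed"` or a fixed dosage (0, 1 or 2) for the other
#'   variant.
#' @return The plug-in ATE (trait units).
#' @export
plugin_ate <- function(mu, data, variant = c("V1", "V2"), tr,
                       other = "observed") {
  variant <- match.arg(variant)
  pair <- if (variant == "V1") tr$v1 else tr$v2
  fix <- function(level, other_level) {
    if (variant == "V1") {
      v2 <- if (identical(other, "observed")) data$V2 else other
      eval_mu(mu, level, v2, data)
    } else {
      v1 <- if (identical(other, "observed")) data$V1 else other
      eval_mu(mu, v1, level, data)
    }
  }
  mean(fix(pair[2]) - fix(pair[1]))
}

#' Plug-in 2-point average interaction effect
#'
#' The four-corner double difference averaged over the empirical confounder
#' distribution:
#' `mean( mu(to1,to2,W) - mu(from1,to2,W) - mu(to1,from2,W) + mu(from1,from2,W) )`.
#' Positive values indicate synergistic, negative antagonistic epistasis.
#'
#' @inheritParams plugin_ate
#' @param tr A 2-point [transition()].
#' @return The plug-in AIE (trait units).
#' @export
plugin_aie2 <- function(mu, data, tr) {
  f1 <- tr$v1[1] ; t1 <- tr$v1[2] ; f2 <- tr$v2[1] ; t2 <- tr$v2[2]
  mean(eval_mu(mu, t1, t2, data) - eval_mu(mu, f1, t2, data) -
       eval_mu(mu, t1, f2, data) + eval_mu(mu, f1, f2, data))
}

#' Plug-in 3-point (sex-difference) average interaction effect
#'
#' The male-stratum 2-point AIE minus the female-stratum 2-point AIE, each
#' averaging confounders over its own stratum; positive when the
#' variant-variant interaction is larger among males.
#'
#' @inheritParams plugin_aie2
#' @param sex_col Name of the sex column in `data` (0 = female, 1 = male).
#' @return The plug-in 3-point AIE (trait units).
#' @export
plugin_aie3 <- function(mu, data, tr, sex_col = "S") {
  s <- data[[sex_col]]
  if (!any(s == 1) || !any(s == 0))
    stop("both sexes must be present for a 3-point estimand", call. = FALSE)
  plugin_aie2(mu, data[s == 1, , drop = FALSE], tr) -
    plugin_aie2(mu, data[s == 0, , drop = FALSE], tr)
}

#' Joint-minus-sum decomposition of the 2-point AIE
#'
#' The AIE equals the effect of changing both variants jointly minus the
#' sum of the two single-variant effects (each with the other variant held
#' at its `from` level) — the algebraic identity behind reading a positive
#' AIE as "the joint change does more than the sum of its parts". Returns
#' both sides for equality testing.
#'
#' @inheritParams plugin_aie2
#' @return List with `lhs` ([plugin_aie2()]) and `rhs` (the decomposition).
#' @export
joint_minus_marginals_identity <- function(mu, data, tr) {
  f1 <- tr$v1[1] ; t1 <- tr$v1[2] ; f2 <- tr$v2[1] ; t2 <- tr$v2[2]
  joint <- mean(eval_mu(mu, t1, t2, data) - eval_mu(mu, f1, f2, data))
  m1 <- mean(eval_mu(mu, t1, f2, data) - eval_mu(mu, f1, f2, data))
  m2 <- mean(eval_mu(mu, f1, t2, data) - eval_mu(mu, f1, f2, data))
  list(lhs = plugin_aie2(mu, data, tr), rhs = joint - m1 - m2)
}

#' Squared dosage correlation (LD R-squared) between two variants
#'
#' @param g1,g2 Equal-length dosage vectors.
#' @return Squared Pearson correlation in \[0, 1\].
#' @export
ld_r2 <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  if (stats::sd(g1) == 0 || stats::sd(g2) == 0)
    stop("LD is undefined for a constant dosage vector", call. = FALSE)
  stats::cor(g1, g2)^2
}
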