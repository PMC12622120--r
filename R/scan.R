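#' Scan configuration
#'
#' @param positivity_threshold Minimum joint genotype frequency for a
#'   transition's corner cells (default 0.01).
#' @param fdr_threshold BH false discovery rate threshold (default 0.05).
#' @param fdr_groups Grouping columns for the BH adjustment (default
#'   trait crossed with TF).
#' @param nuisance A [nuisance_spec()].
#' @param floor Propensity floor.
#' @param reference Hotelling reference distribution, `"F"` or `"chisq"`.
#' @param seed Base RNG seed; each manifest entry is seeded
#'   deterministically from it.
#' @return A list of class `"scan_config"`.
#' @export
scan_config <- function(positivity_threshold = 0.01, fdr_threshold = 0.05,
                        fdr_groups = c("trait", "tf"),
                        nuisance = nuisance_spec(), floor = 0.001,
                        reference = c("F", "chisq"), seed = 1L) {
  reference <- match.arg(reference)
  stopifnot(positivity_threshold > 0, positivity_threshold < 1,
            fdr_threshold > 0, fdr_threshold < 1)
  structure(list(positivity_threshold = positivity_threshold,
                 fdr_threshold = fdr_threshold, fdr_groups = fdr_groups,
                 nuisance = nuisance, floor = floor, reference = reference,
                 seed = as.integer(seed)),
            class = "scan_config")
}

#' Orient a dosage vector to count a manifest's effect allele
#'
#' Genotype files count one of the two alleles; when the manifest's effect
#' (B or F) allele is the file's other allele the dosage is flipped
#' `d -> 2 - d`. Flipping twice restores the input.
#'
#' @param d Dosage vector in \{0, 1, 2\} (NA allowed).
#' @param counted_allele,other_allele Alleles of the file's orientation.
#' @param effect_allele The manifest's effect allele.
#' @return Oriented dosage vector.
#' @export
orient_dosage <- function(d, counted_allele, other_allele, effect_allele) {
  if (effect_allele == counted_allele) return(d)
  if (effect_allele == other_allele) return(2L - d)
  stop(sprintf("effect allele '%s' matches neither allele ('%s'/'%s')",
               effect_allele, counted_allele, other_allele),
       call. = FALSE)
}

# parse a VCF (GT fields only) into a dosage data.frame + allele metadata;
# half-calls and missing GTs become NA
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF input requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- function(g) {
    if (is.na(g)) return(NA_integer_)
    parts <- strsplit(g, "[/|]")[[1]]
    if (any(parts == ".")) return(NA_integer_)
    sum(parts == "1")
  }
  dos <- apply(gt, c(1, 2), alt_count)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste(fix$CHROM, fix$POS, sep = ":"), fix$ID)
  out <- data.frame(sample_id = colnames(gt), t(dos),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("sample_id", ids)
  variants <- data.frame(id = ids, counted_allele = fix$ALT,
                         other_allele = fix$REF, stringsAsFactors = FALSE)
  list(genotypes = out, variants = variants)
}

#' Load genotype, phenotype and manifest inputs
#'
#' Genotypes come from a TSV dosage table (`sample_id` column plus one
#' dosage column per variant; allele orientation supplied via
#' `counted_alleles`) or a VCF 4.2 with GT fields (dosages count the ALT
#' allele). Samples are aligned across files by `sample_id`; the
#' intersection size is reported and non-shared rows are dropped.
#'
#' @param genotype_path Path to the dosage TSV or VCF (`.vcf` suffix).
#' @param phenotype_path Path to the phenotype/covariate TSV
#'   (`sample_id`, trait columns, `S`, `age`, `W1`, ...).
#' @param manifest_path Path to the scan manifest TSV with columns
#'   `tf`, `bqtl`, `bqtl_effect_allele`, `fqtl`, `fqtl_effect_allele`,
#'   `mechanism`, `trait`, `trait_type`, `scope`.
#' @param counted_alleles Optional data.frame (`id`, `counted_allele`,
#'   `other_allele`) for TSV genotype input.
#' @return List of class `"scan_inputs"`: `genotypes`, `variants`,
#'   `cohort`, `manifest`, `n_shared`.
#' @export
load_inputs <- function(genotype_path, phenotype_path, manifest_path,
                        counted_alleles = NULL) {
  read_tsv <- function(p) utils::read.delim(p, sep = "\t",
                                            stringsAsFactors = FALSE,
                                            check.names = FALSE)
  if (grepl("\\.vcf(\\.gz)?$", genotype_path)) {
    gv <- read_vcf_dosages(genotype_path)
    genotypes <- gv$genotypes ; variants <- gv$variants
  } else {
    genotypes <- read_tsv(genotype_path)
    if (!"sample_id" %in% names(genotypes))
      stop("genotype TSV must have a sample_id column", call. = FALSE)
    variants <- counted_alleles
  }
  cohort <- read_tsv(phenotype_path)
  # all-character read: allele columns like "F" must not become logicals
  manifest <- utils::read.delim(manifest_path, sep = "\t",
                                stringsAsFactors = FALSE,
                                check.names = FALSE,
                                colClasses = "character")
  need <- c("tf", "bqtl", "bqtl_effect_allele", "fqtl",
            "fqtl_effect_allele", "trait", "trait_type", "scope")
  missing_cols <- setdiff(need, names(manifest))
  if (length(missing_cols))
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (vcol in unique(c(manifest$bqtl, manifest$fqtl)))
    if (!vcol %in% names(genotypes))
      stop(sprintf("variant '%s' not found in genotype input", vcol),
           call. = FALSE)
  shared <- intersect(genotypes$sample_id, cohort$sample_id)
  if (length(shared) == 0L)
    stop("no shared sample ids between genotype and phenotype inputs",
         call. = FALSE)
  message(sprintf("aligned %d shared samples (%d genotype, %d phenotype)",
                  length(shared), nrow(genotypes), nrow(cohort)))
  genotypes <- genotypes[match(shared, genotypes$sample_id), ,
                         drop = FALSE]
  cohort <- cohort[match(shared, cohort$sample_id), , drop = FALSE]
  structure(list(genotypes = genotypes, variants = variants,
                 cohort = cohort, manifest = manifest,
                 n_shared = length(shared)),
            class = "scan_inputs")
}

#' Estimate and test one bQTL-fQTL interaction on one trait
#'
#' The single-pair pipeline: enumerate transitions passing positivity, fit
#' nuisances, target each component with TMLE, assemble the EIC covariance
#' and run the Hotelling test. With `scope = "3-point-sex"` the components
#' are sex differences of stratified 2-point AIEs; with `"males"` /
#' `"females"` the pipeline runs inside one stratum.
#'
#' @param data Analysis data.frame (`Y`, `V1`, `V2`, `S`, `age`, `W`...).
#' @param trait_type `"continuous"` or `"binary"`.
#' @param config A [scan_config()].
#' @param scope `"all"`, `"males"`, `"females"` or `"3-point-sex"`.
#' @param seed RNG seed (defaults to the config's).
#' @return An object of class `"interaction_result"`: `k`, component
#'   estimates, `theta`, `sigma`, `T2`, `p_H`, the positivity report, and
#'   a `skipped` flag (with reason) when no transition passes positivity.
#' @export
estimate_interaction <- function(data, trait_type, config = scan_config(),
                                 scope = c("all", "males", "females",
                                           "3-point-sex"),
                                 seed = config$seed) {
  scope <- match.arg(scope)
  if (scope == "males") data <- data[data$S == 1, , drop = FALSE]
  if (scope == "females") data <- data[data$S == 0, , drop = FALSE]
  with_sex <- scope == "3-point-sex"
  keep <- stats::complete.cases(data[c("Y", "V1", "V2")])
  data <- data[keep, , drop = FALSE]
  enum <- enumerate_transitions(data$V1, data$V2,
                                threshold = config$positivity_threshold,
                                with_sex = with_sex, sex = data$S)
  base <- list(scope = scope, n = nrow(data), k = enum$k,
               positivity = enum$report, reference = config$reference)
  if (enum$k == 0L)
    return(structure(c(base, list(skipped = TRUE,
                                  reason = "no transition passed positivity")),
                     class = "interaction_result"))
  nus <- fit_nuisances(data, config$nuisance, trait_type,
                       floor = config$floor, seed = seed,
                       by_sex = with_sex)
  comps <- tmle_components(data, nus, enum$transitions)
  theta <- vapply(comps, `[[`, numeric(1), "estimate")
  sigma <- component_covariance(comps)
  ht <- hotelling_test(theta, sigma, n = nrow(data),
                       reference = config$reference)
  structure(c(base, list(skipped = FALSE, transitions = enum$transitions,
                         components = comps, theta = theta, sigma = sigma,
                         T2 = ht$T2, p_H = ht$p_H, p_chisq = ht$p_chisq,
                         k_eff = ht$k)),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("interaction result (scope %s, n = %d, k = %d)\n",
              x$scope, x$n, x$k))
  if (x$skipped) {
    cat("  skipped:", x$reason, "\n")
  } else {
    for (cm in x$components) cat(" ", format(cm), "\n")
    cat(sprintf("  Hotelling T2 = %.4g, p_H = %.4g (%s reference)\n",
                x$T2, x$p_H, x$reference))
  }
  invisible(x)
}

#' Sex-stratified interaction scan for one pair and trait
#'
#' Runs the 2-point pipeline within males and within females and the
#' 3-point sex-difference test on the full sample, mirroring how
#' sex-differential epistasis is reported: per-sex interaction estimates
#' highlighted by a significant male-minus-female difference.
#'
#' @inheritParams estimate_interaction
#' @return List with `males`, `females` and `sex_diff`
#'   `"interaction_result"` elements.
#' @export
sex_stratified_scan <- function(data, trait_type, config = scan_config(),
                                seed = config$seed) {
  if (!any(data$S == 1) || !any(data$S == 0))
    stop("both sexes must be present", call. = FALSE)
  list(males = estimate_interaction(data, trait_type, config, "males",
                                    seed = seed),
       females = estimate_interaction(data, trait_type, config, "females",
                                      seed = seed + 1L),
       sex_diff = estimate_interaction(data, trait_type, config,
                                       "3-point-sex", seed = seed + 2L))
}

# assemble the analysis data.frame for one manifest entry
entry_data <- function(inputs, entry) {
  g <- inputs$genotypes
  cohort <- inputs$cohort
  orient <- function(vid, eff) {
    d <- g[[vid]]
    if (is.null(inputs$variants)) return(d)  # orientation unknown: as-is
    meta <- inputs$variants[inputs$variants$id == vid, , drop = FALSE]
    if (nrow(meta) == 0L) return(d)
    orient_dosage(d, meta$counted_allele[1], meta$other_allele[1], eff)
  }
  if (!entry$trait %in% names(cohort))
    stop(sprintf("trait '%s' not found in phenotype input", entry$trait),
         call. = FALSE)
  covs <- intersect(c("S", "age", grep("^W[0-9]+$", names(cohort),
                                       value = TRUE)), names(cohort))
  out <- data.frame(V1 = orient(entry$bqtl, entry$bqtl_effect_allele),
                    V2 = orient(entry$fqtl, entry$fqtl_effect_allele),
                    Y = cohort[[entry$trait]])
  cbind(out, cohort[covs])
}

#' Run the full interaction scan over a manifest
#'
#' Iterates the manifest entries, running [estimate_interaction()] for
#' each with per-entry deterministic seeding, then applies the grouped BH
#' adjustment across entries. Per-entry failures are isolated: an entry
#' that errors or fails positivity appears in the results with its status
#' and message, never aborting the scan.
#'
#' @param inputs A `"scan_inputs"` object ([load_inputs()]) or a list with
#'   `genotypes`, `variants`, `cohort`, `manifest` in that shape.
#' @param config A [scan_config()].
#' @return List of class `"scan_results"`: `results` (one row per manifest
#'   entry: identifiers, n, k, T2, p_H, q_H, significant, status, error),
#'   `components` (one row per tested component), `details` (the
#'   `"interaction_result"` objects).
#' @export
run_scan <- function(inputs, config = scan_config()) {
  manifest <- inputs$manifest
  details <- vector("list", nrow(manifest))
  rows <- vector("list", nrow(manifest))
  comp_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    entry <- manifest[i, , drop = FALSE]
    scope <- if (entry$scope %in% c("all", "males", "females",
                                    "3-point-sex")) entry$scope else "all"
    res <- tryCatch({
      d <- entry_data(inputs, entry)
      estimate_interaction(d, entry$trait_type, config, scope,
                           seed = config$seed + i)
    }, error = function(e) e)
    row <- data.frame(tf = entry$tf, trait = entry$trait,
                      bqtl = entry$bqtl, fqtl = entry$fqtl,
                      mechanism = if ("mechanism" %in% names(entry))
                        entry$mechanism else NA_character_,
                      scope = scope, n = NA_integer_, k = NA_integer_,
                      T2 = NA_real_, p_H = NA_real_,
                      status = "ok", error = NA_character_,
                      stringsAsFactors = FALSE)
    if (inherits(res, "error")) {
      row$status <- "error" ; row$error <- conditionMessage(res)
    } else {
      details[[i]] <- res
      row$n <- res$n ; row$k <- res$k
      if (res$skipped) {
        row$status <- "skipped_positivity"
      } else {
        row$T2 <- res$T2 ; row$p_H <- res$p_H
        for (cm in res$components) {
          ci <- cm$estimate + c(-1, 1) * stats::qnorm(0.975) * cm$se
          comp_rows[[length(comp_rows) + 1L]] <- data.frame(
            tf = entry$tf, trait = entry$trait, bqtl = entry$bqtl,
            fqtl = entry$fqtl, scope = scope,
            transition = format(cm$transition), estimate = cm$estimate,
            se = cm$se, ci_lower = ci[1], ci_upper = ci[2],
            p_component = cm$p_component, stringsAsFactors = FALSE)
        }
      }
    }
    rows[[i]] <- row
  }
  results <- do.call(rbind, rows)
  results <- bh_adjust(results, group_cols = config$fdr_groups,
                       threshold = config$fdr_threshold)
  structure(list(results = results,
                 components = if (length(comp_rows))
                   do.call(rbind, comp_rows) else NULL,
                 details = details, config = config),
            class = "scan_results")
}

#' Write scan outputs as TSV files plus run metadata
#'
#' @param scan A `"scan_results"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_scan_results <- function(scan, dir) {
  stopifnot(inherits(scan, "scan_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }
  paths <- w(scan$results, "results.tsv")
  if (!is.null(scan$components))
    paths <- c(paths, w(scan$components, "components.tsv"))
  cells <- do.call(rbind, lapply(seq_along(scan$details), function(i) {
    d <- scan$details[[i]]
    if (is.null(d)) return(NULL)
    cbind(entry = i, d$positivity$cells)
  }))
  if (!is.null(cells)) paths <- c(paths, w(cells, "positivity.tsv"))
  meta <- file.path(dir, "run_metadata.txt")
  writeLines(c(sprintf("aiescan %s", as.character(utils::packageVersion("aiescan"))),
               sprintf("seed: %d", scan$config$seed),
               sprintf("positivity_threshold: %g",
                       scan$config$positivity_threshold),
               sprintf("fdr_threshold: %g", scan$config$fdr_threshold),
               sprintf("fdr_groups: %s",
                       paste(scan$config$fdr_groups, collapse = ",")),
               sprintf("nuisance_learner: %s", scan$config$nuisance$learner),
               sprintf("hotelling_reference: %s", scan$config$reference)),
             meta)
  invisible(c(paths, meta))
}
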