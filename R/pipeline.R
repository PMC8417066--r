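#' Block-average correlations of a mixed-worded scale
#'
#' Mean off-diagonal correlation within the positive block, within the
#' negative block, and across blocks. In wording-effects-contaminated data
#' the cross-block average is depressed relative to the within-block
#' averages; successful screening moves it back up.
#'
#' @param R Correlation matrix (or `polychoric` object).
#' @param item_polarity Polarity map covering every item.
#' @return Named vector `c(pos_pos, neg_neg, pos_neg)`.
#' @examples
#' tot <- rses_polychoric("total")
#' round(block_average_correlations(tot$matrix, rses_polarity()), 2)
#' @export
block_average_correlations <- function(R, item_polarity) {
  if (inherits(R, "polychoric")) R <- R$matrix
  p <- ncol(R)
  polarity <- check_polarity(item_polarity, p)
  pos <- polarity == "positive"
  neg <- polarity == "negative"
  pp <- R[pos, pos, drop = FALSE]
  nn <- R[neg, neg, drop = FALSE]
  c(pos_pos = mean(pp[lower.tri(pp)]),
    neg_neg = mean(nn[lower.tri(nn)]),
    pos_neg = mean(R[pos, neg]))
}

#' Profile comparisons between latent classes
#'
#' Compares the flagged (inconsistent) and retained (consistent) respondents
#' on their observed positive-block and negative-block mean scores, and on
#' optional covariates: Welch's t-test with Satterthwaite degrees of freedom
#' and Cohen's d (pooled SD) for numeric covariates, Fisher's exact test for
#' binary ones.
#'
#' @param data Response matrix.
#' @param assignment `fma_classes` (or factor) covering all rows.
#' @param item_polarity Polarity map.
#' @param covariates Optional data frame of per-respondent covariates
#'   (numeric or two-level factors).
#' @return Data frame with one row per comparison: group means/SDs, `t`,
#'   `df`, `p`, `d` (Fisher rows carry only `p`).
#' @export
compare_classes <- function(data, assignment, item_polarity,
                            covariates = NULL) {
  cls <- if (inherits(assignment, "fma_classes")) {
    assignment$class
  } else as.factor(assignment)
  X <- as_response_matrix(data)
  if (length(cls) != nrow(X)) stop("assignment must cover all rows")
  if (min(table(cls)) < 2) stop("each class needs at least 2 respondents")
  polarity <- check_polarity(item_polarity, ncol(X))
  inc <- cls == "inconsistent"
  welch_row <- function(name, x) {
    g1 <- x[inc]; g2 <- x[!inc]
    tt <- stats::t.test(g1, g2)
    sp <- sqrt(((length(g1) - 1) * stats::var(g1) +
                  (length(g2) - 1) * stats::var(g2)) /
                 (length(g1) + length(g2) - 2))
    data.frame(comparison = name, test = "welch_t",
               mean_inconsistent = mean(g1), sd_inconsistent = stats::sd(g1),
               mean_consistent = mean(g2), sd_consistent = stats::sd(g2),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               d = if (sp > 0) abs(mean(g1) - mean(g2)) / sp else 0)
  }
  rows <- list(
    welch_row("positive_items", rowMeans(X[, polarity == "positive",
                                           drop = FALSE])),
    welch_row("negative_items", rowMeans(X[, polarity == "negative",
                                           drop = FALSE]))
  )
  if (!is.null(covariates)) {
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      if (is.numeric(v)) {
        rows <- c(rows, list(welch_row(nm, v)))
      } else {
        ft <- stats::fisher.test(table(factor(v), cls))
        rows <- c(rows, list(data.frame(
          comparison = nm, test = "fisher_exact",
          mean_inconsistent = NA, sd_inconsistent = NA,
          mean_consistent = NA, sd_consistent = NA,
          t = NA, df = NA, p = ft$p.value, d = NA)))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full screen-then-validate workflow
#'
#' Fits both constrained factor mixtures, classifies and screens the sample
#' with each, and for the total and each screened sample computes the
#' polychoric matrix, block-average correlations, eigenvalues, parallel
#' analysis, and all six confirmatory fits (one-factor, two-factor, RIIFA,
#' each with and without the freed error covariance); reports the agreement
#' (kappa) between the two screens and class-profile comparisons for each.
#'
#' @param data Ordinal response matrix.
#' @param item_polarity Polarity map.
#' @param theta_pair Item pair whose error covariance is freed in the
#'   `-theta` model variants (default none).
#' @param covariates Optional covariate data frame for the class profiles.
#' @param n_starts,n_final Multistart settings passed to [fit_fma()].
#' @param pa_sets Permutation sets for [parallel_analysis()].
#' @param seed Integer seed governing all randomness.
#' @return Object of class `screening_report` (nested list, JSON-writable
#'   with [write_report()]).
#' @export
run_screening_pipeline <- function(data, item_polarity, theta_pair = NULL,
                                   covariates = NULL,
                                   n_starts = 200, n_final = 20,
                                   pa_sets = 1000, seed = 1) {
  X <- as_response_matrix(data)
  polarity <- check_polarity(item_polarity, ncol(X))
  names(polarity) <- colnames(X)
  fits <- list(
    steinmann = fit_fma(X, steinmann_spec(polarity), n_starts = n_starts,
                        n_final = n_final, seed = seed),
    arias = fit_fma(X, arias_spec(polarity), n_starts = n_starts,
                    n_final = n_final, seed = seed + 1)
  )
  assign <- lapply(fits, classify)
  kappa <- cohen_kappa(assign$steinmann, assign$arias)
  samples <- list(total = X,
                  steinmann = screen_sample(X, assign$steinmann),
                  arias = screen_sample(X, assign$arias))
  analyze <- function(M, pa_seed) {
    pc <- polychoric(M)
    pa <- parallel_analysis(M, n_sets = pa_sets, seed = pa_seed)
    cfas <- list()
    for (kind in c("one_factor", "two_factor", "riifa")) {
      cfas[[kind]] <- fit_cfa(pc$matrix, nrow(M), cfa_spec(kind, polarity))
      if (!is.null(theta_pair)) {
        cfas[[paste0(kind, "_theta")]] <-
          fit_cfa(pc$matrix, nrow(M), cfa_spec(kind, polarity, theta_pair))
      }
    }
    list(n = nrow(M),
         block_averages = block_average_correlations(pc$matrix, polarity),
         eigenvalues = correlation_eigenvalues(pc$matrix),
         parallel_analysis = pa,
         cfa = cfas)
  }
  analyses <- list(total = analyze(samples$total, seed + 10),
                   steinmann = analyze(samples$steinmann, seed + 11),
                   arias = analyze(samples$arias, seed + 12))
  profiles <- lapply(assign, function(a) {
    tryCatch(compare_classes(X, a, polarity, covariates),
             error = function(e) paste("not computed:", conditionMessage(e)))
  })
  structure(list(
    settings = list(n_starts = n_starts, n_final = n_final,
                    pa_sets = pa_sets, seed = seed,
                    theta_pair = theta_pair),
    fma = fits, assignments = assign, kappa = kappa,
    samples = analyses, class_profiles = profiles
  ), class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Wording-effects screening report\n")
  for (nm in names(x$samples)) {
    a <- x$samples[[nm]]
    cat(sprintf("  %-10s n = %3d  cross-block r = %.2f  eig1 = %.2f  PA: %d\n",
                nm, a$n, a$block_averages["pos_neg"], a$eigenvalues[1],
                a$parallel_analysis$n_retained))
  }
  cat(sprintf("kappa between screens = %.2f (%s)\n",
              x$kappa$kappa, x$kappa$band))
  invisible(x)
}

#' Write a screening report as JSON
#'
#' @param report A `screening_report`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_report <- function(report, file) {
  slim_cfa <- function(f) {
    list(kind = f$spec$kind, theta_pair = f$spec$theta_pair,
         loadings = as.list(f$loadings),
         factor_correlation = f$factor_correlation,
         method_loading = f$method_loading,
         theta_standardized = f$theta_standardized,
         chi_square = f$chi_square, df = f$df, CFI = f$CFI, TLI = f$TLI,
         RMSEA = f$RMSEA, SRMR = f$SRMR)
  }
  out <- list(
    settings = report$settings,
    fma = lapply(report$fma, function(f) {
      list(model = f$spec$model, loglik = f$loglik,
           n_free_parameters = f$n_free_parameters,
           mixing_weight = f$parameters$mixing_weight,
           entropy = f$entropy,
           best_loglik_replications = f$best_loglik_replications)
    }),
    assignments = lapply(report$assignments,
                         function(a) as.character(a$class)),
    kappa = list(kappa = report$kappa$kappa, band = report$kappa$band),
    samples = lapply(report$samples, function(a) {
      list(n = a$n, block_averages = as.list(a$block_averages),
           eigenvalues = a$eigenvalues,
           pa_retained = a$parallel_analysis$n_retained,
           pa_random_means = a$parallel_analysis$mean_random_eigenvalues,
           cfa = lapply(a$cfa, slim_cfa))
    }),
    class_profiles = report$class_profiles
  )
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(file)
}
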