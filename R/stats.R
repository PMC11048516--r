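# Cohort-level statistics: Kendall correlation structure, hierarchical
# clustering, group tests with BH control, LASSO models, demographics tables.

#' Pairwise Kendall rank correlation matrix
#'
#' Kendall's tau-b (tie-corrected) for every pair of biomarker columns, with
#' two-sided p-values and a Bonferroni significance call across the distinct
#' pairs. Constant columns are flagged undefined (`NA` row/column).
#'
#' @param table data.frame (e.g. a `cohort_table`).
#' @param variables columns to correlate; defaults to the 12 CRMBs present.
#' @param alpha familywise level for the Bonferroni call (default 0.05).
#' @return object of class `correlation_matrix`: `tau`, `p_raw`,
#'   `significant`, `n_pairs`, `n`.
#' @export
kendall_matrix <- function(table, variables = NULL, alpha = 0.05) {
  if (is.null(variables)) variables <- intersect(crmb_names(), names(table))
  .assert(length(variables) >= 2, "need at least two variables")
  x <- as.data.frame(table)[, variables, drop = FALSE]
  .assert(nrow(x) >= 10, "need at least 10 subjects")
  k <- length(variables)
  tau <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  diag(tau) <- 1; diag(p) <- 0
  const <- vapply(x, function(v) stats::var(v, na.rm = TRUE) == 0 ||
                    all(is.na(v)), logical(1))
  if (any(const)) warning("constant variable(s) flagged undefined: ",
                          paste(variables[const], collapse = ", "))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (const[i] || const[j]) next
    ct <- suppressWarnings(
      stats::cor.test(x[[i]], x[[j]], method = "kendall", exact = FALSE))
    tau[i, j] <- tau[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  n_pairs <- k * (k - 1) / 2
  sig <- pmin(p * n_pairs, 1) < alpha
  diag(sig) <- NA
  structure(list(tau = tau, p_raw = p, significant = sig,
                 n_pairs = n_pairs, n = nrow(x), alpha = alpha),
            class = "correlation_matrix")
}

#' Cluster biomarkers on their correlation structure
#'
#' Agglomerative clustering with complete linkage on the distance
#' `1 - tau` (sign-preserving, so anticorrelated biomarkers are far apart),
#' cut into exactly `n_subtrees` subtrees. Returns the per-variable labels
#' and the dendrogram leaf order used to arrange correlation heatmaps.
#'
#' @param corr a `correlation_matrix`.
#' @param n_subtrees number of subtrees to cut (default 5).
#' @return list: `labels` (named integer vector), `order` (leaf order),
#'   `hclust` (the tree).
#' @export
cluster_crmbs <- function(corr, n_subtrees = 5) {
  stopifnot(inherits(corr, "correlation_matrix"))
  k <- ncol(corr$tau)
  .assert(n_subtrees >= 1 && n_subtrees <= k,
          "n_subtrees must be between 1 and the variable count",
          "octacrmb_config_error")
  d <- stats::as.dist(1 - corr$tau)
  hc <- stats::hclust(d, method = "complete")
  list(labels = stats::cutree(hc, k = n_subtrees),
       order = hc$order, hclust = hc)
}

#' Per-biomarker group difference tests
#'
#' Welch (unequal-variance) unpaired two-sided t-test of each biomarker
#' between the two groups, with Benjamini-Hochberg control across the
#' biomarkers; significance declared at adjusted p < `alpha`.
#'
#' @param table a `cohort_table` (needs a two-level `group` column).
#' @param variables biomarker columns; defaults to the CRMBs present.
#' @param alpha adjusted-p significance level (default 0.1).
#' @return data.frame: variable, mean per group, t, df, p_raw, p_adjusted,
#'   significant.
#' @export
group_difference_tests <- function(table, variables = NULL, alpha = 0.1) {
  if (is.null(variables)) variables <- intersect(crmb_names(), names(table))
  g <- factor(table$group)
  .assert(nlevels(g) == 2, "exactly two groups required")
  lv <- levels(g)
  res <- lapply(variables, function(v) {
    x1 <- table[[v]][g == lv[1]]; x2 <- table[[v]][g == lv[2]]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    if (length(x1) < 2 || length(x2) < 2 ||
        (stats::var(x1) == 0 && stats::var(x2) == 0)) {
      return(data.frame(variable = v, mean_1 = mean(x1), mean_2 = mean(x2),
                        t = NA_real_, df = NA_real_, p_raw = NA_real_))
    }
    tt <- stats::t.test(x1, x2, var.equal = FALSE)
    data.frame(variable = v, mean_1 = mean(x1), mean_2 = mean(x2),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value)
  })
  out <- do.call(rbind, res)
  names(out)[2:3] <- paste0("mean_", lv)
  out$p_adjusted <- bh_adjust(out$p_raw)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out
}

#' LASSO biomarker model with cross-validated penalty
#'
#' Regresses RVO status (binomial) or initial BCVA (gaussian) on the twelve
#' CRMBs and clinical covariates. Continuous predictors are standardized to
#' zero mean / unit variance before fitting; the penalty is selected by
#' k-fold cross-validation with deviance as the criterion (`lambda.min` by
#' default, the 1-SE rule available). Predictors with non-zero coefficients
#' at the selected penalty are the ones significant in the prediction.
#'
#' @param table a `cohort_table`.
#' @param outcome `"rvo_status"` or `"bcva_initial"`.
#' @param predictors predictor columns; default = the 12 CRMBs plus age, sex
#'   and the comorbidity indicators present.
#' @param folds CV folds (default 10).
#' @param seed seed for the fold assignment.
#' @param lambda_rule `"min"` or `"1se"`.
#' @return object of class `lasso_result`: family, `lambda_selected`,
#'   `coefficients` (standardized scale, zeros included), `nonzero`,
#'   `cv_folds`, `seed`, and the underlying `cv.glmnet` fit.
#' @export
lasso_model <- function(table, outcome = c("rvo_status", "bcva_initial"),
                        predictors = NULL, folds = 10, seed = 1L,
                        lambda_rule = c("min", "1se")) {
  outcome <- match.arg(outcome)
  lambda_rule <- match.arg(lambda_rule)
  tab <- as.data.frame(table)
  if (is.null(predictors)) {
    predictors <- c(intersect(crmb_names(), names(tab)),
                    intersect(c("age", "sex", "diabetes", "hypertension",
                                "hyperlipidaemia", "atherosclerosis"),
                              names(tab)))
    if (outcome == "rvo_status") {
      predictors <- setdiff(predictors, "group")
    }
  }
  .assert(nrow(tab) >= 20, "need at least 20 subjects")
  x <- sapply(predictors, function(v) {
    col <- tab[[v]]
    if (is.logical(col)) return(as.numeric(col))
    if (is.character(col) || is.factor(col)) {
      return(as.numeric(factor(col)) - 1)
    }
    as.numeric(scale(col))
  })
  x <- as.matrix(x)
  if (outcome == "rvo_status") {
    y <- as.numeric(factor(tab$group)) - 1
    family <- "binomial"
    if (min(table(y)) < 2) stop("need both groups for the binomial model")
  } else {
    y <- as.numeric(scale(tab$bcva_initial))
    family <- "gaussian"
  }
  foldid <- .with_seed(seed, sample(rep(seq_len(folds), length.out = nrow(x))))
  cv <- glmnet::cv.glmnet(x, y, family = family, foldid = foldid,
                          type.measure = "deviance", standardize = FALSE)
  lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  cf <- as.matrix(stats::coef(cv, s = lam))
  coefs <- cf[-1, 1]
  names(coefs) <- predictors
  structure(list(family = family, lambda_selected = lam,
                 coefficients = coefs,
                 nonzero = names(coefs)[coefs != 0],
                 cv_folds = folds, seed = seed, lambda_rule = lambda_rule,
                 fit = cv),
            class = "lasso_result")
}

#' @export
print.lasso_result <- function(x, ...) {
  cat(sprintf("<lasso_result> family %s, lambda %.4g (%s rule), %d/%d nonzero\n",
              x$family, x$lambda_selected, x$lambda_rule,
              length(x$nonzero), length(x$coefficients)))
  if (length(x$nonzero)) print(round(x$coefficients[x$nonzero], 4))
  invisible(x)
}

#' Two-proportion chi-square test
#'
#' Pearson chi-square on the 2x2 table `[[a, b], [c, d]]` without continuity
#' correction (df = 1, two-sided) - the convention that reproduces published
#' demographics-table p-values.
#'
#' @param a,b counts in group 1 (e.g. yes/no).
#' @param c,d counts in group 2.
#' @return list: `chi_sq`, `df`, `p_value`.
#' @export
two_proportion_chisq <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  .assert(all(m >= 0) && all(rowSums(m) > 0) && all(colSums(m) > 0),
          "all table margins must be positive")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi_sq = unname(ct$statistic), df = 1L, p_value = ct$p.value)
}

#' Welch t-test from summary statistics
#'
#' Unequal-variance two-sided t-test with Satterthwaite degrees of freedom,
#' computed from group means, SDs and sizes (as printed in demographic
#' summary tables).
#'
#' @param mean1,sd1,n1 group-1 summary.
#' @param mean2,sd2,n2 group-2 summary.
#' @return list: `t`, `df`, `p_value`.
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  .assert(n1 >= 2 && n2 >= 2, "group sizes must be >= 2")
  .assert(sd1 > 0 && sd2 > 0, "SDs must be positive")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1 (`stats::p.adjust(method = "BH")`).
#'
#' @param p_values numeric vector in \[0, 1\] (`NA` allowed).
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  .assert(all(ok), "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Demographics statistics from a printed summary table
#'
#' Recomputes the statistics column of a published-style demographics table:
#' Pearson chi-square (no continuity correction) for binary rows, Welch
#' t-test for continuous rows, and a BH-adjusted column over all tested rows.
#'
#' @param summary data.frame with columns `variable`, `type`
#'   (`"binary"`/`"continuous"`), `g1_a`, `g1_b`, `g1_n`, `g2_a`, `g2_b`,
#'   `g2_n`. Binary rows use `a`/`b` as the two category counts (`n`
#'   ignored); continuous rows use `a` = mean, `b` = SD with group size `n`.
#' @param p_digits optionally round raw p-values to this many digits before
#'   the BH pass - published tables that print rounded p-values adjust the
#'   rounded values (default `NULL`, no rounding).
#' @param alpha significance level on the adjusted column (default 0.05).
#' @return data.frame: variable, type, statistic, p_value, p_adjusted,
#'   significant. Rows whose test is undefined (e.g. an empty 2x2 margin)
#'   get `NA` statistics and are excluded from the BH family.
#' @export
demographics_from_summary <- function(summary, p_digits = NULL, alpha = 0.05) {
  need <- c("variable", "type", "g1_a", "g1_b", "g1_n", "g2_a", "g2_b", "g2_n")
  .assert(all(need %in% names(summary)),
          paste("summary must have columns:", paste(need, collapse = ", ")),
          "octacrmb_schema_error")
  .assert(nrow(summary) > 0, "empty summary table", "octacrmb_schema_error")
  rows <- lapply(seq_len(nrow(summary)), function(i) {
    s <- summary[i, ]
    r <- tryCatch({
      if (s$type == "binary") {
        x <- two_proportion_chisq(s$g1_a, s$g1_b, s$g2_a, s$g2_b)
        list(stat = x$chi_sq, p = x$p_value)
      } else {
        x <- welch_t_from_summary(s$g1_a, s$g1_b, s$g1_n,
                                  s$g2_a, s$g2_b, s$g2_n)
        list(stat = x$t, p = x$p_value)
      }
    }, error = function(e) list(stat = NA_real_, p = NA_real_))
    data.frame(variable = s$variable, type = s$type,
               statistic = r$stat, p_value = r$p)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p_value)
  p_for_bh <- if (is.null(p_digits)) out$p_value[ok] else
    round(out$p_value[ok], p_digits)
  out$p_adjusted <- NA_real_
  out$p_adjusted[ok] <- bh_adjust(p_for_bh)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out
}

#' Demographics statistics from a raw cohort table
#'
#' Builds the per-group summary (counts for binary rows, mean and SD for
#' continuous rows) from subject-level data and runs the same tests as
#' [demographics_from_summary()].
#'
#' @param table a `cohort_table`.
#' @param binary_vars,continuous_vars variables to summarize; defaults cover
#'   sex, eye and the comorbidities, and age plus initial BCVA.
#' @param alpha significance level on the adjusted column.
#' @return list: `summary` (the per-group summary data.frame) and `tests`
#'   (as from [demographics_from_summary()]).
#' @export
demographics_table <- function(table,
                               binary_vars = c("sex", "eye", "diabetes",
                                               "hypertension",
                                               "hyperlipidaemia",
                                               "atherosclerosis"),
                               continuous_vars = c("age", "bcva_initial"),
                               alpha = 0.05) {
  g <- factor(table$group)
  .assert(nlevels(g) == 2, "both groups must be present")
  lv <- levels(g)
  mk <- function(v, type) {
    x1 <- table[[v]][g == lv[1]]; x2 <- table[[v]][g == lv[2]]
    if (type == "binary") {
      u <- sort(unique(c(as.character(x1), as.character(x2))))
      data.frame(variable = v, type = "binary",
                 g1_a = sum(as.character(x1) == u[length(u)]),
                 g1_b = sum(as.character(x1) != u[length(u)]),
                 g1_n = length(x1),
                 g2_a = sum(as.character(x2) == u[length(u)]),
                 g2_b = sum(as.character(x2) != u[length(u)]),
                 g2_n = length(x2))
    } else {
      data.frame(variable = v, type = "continuous",
                 g1_a = mean(x1), g1_b = stats::sd(x1), g1_n = length(x1),
                 g2_a = mean(x2), g2_b = stats::sd(x2), g2_n = length(x2))
    }
  }
  summ <- rbind(
    do.call(rbind, lapply(intersect(binary_vars, names(table)), mk,
                          type = "binary")),
    do.call(rbind, lapply(intersect(continuous_vars, names(table)), mk,
                          type = "continuous")))
  list(summary = summ,
       tests = demographics_from_summary(summ, alpha = alpha))
}

#' Render a demographics test table as markdown
#' @param tests data.frame from [demographics_from_summary()].
#' @return character vector of markdown lines.
#' @export
format_demographics_md <- function(tests) {
  c("| Variable | Type | p-value | Adjusted p |",
    "|---|---|---|---|",
    sprintf("| %s | %s | %.4f | %.4f |",
            tests$variable, tests$type, tests$p_value, tests$p_adjusted))
}
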