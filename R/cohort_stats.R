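## Cohort-level statistics: Grubbs outlier screening, factorial
## between-subject ANOVA (Type III, sum-to-zero coding), Bonferroni-corrected
## Pearson correlation matrices and Bonferroni post-hoc pairwise tests.

#' Grubbs' test for a single outlier
#'
#' Two-sided: `G = max |x - mean| / sd`, compared against the
#' t-distribution-based critical value
#' `((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n - 2)`. By default a single pass flags at most
#' the one most extreme value; `iterative = TRUE` repeats the screen on the
#' remaining values until no outlier is found.
#'
#' @param values numeric vector, n >= 3 (NAs dropped).
#' @param alpha significance level (default 0.05).
#' @param iterative repeat the screen after removing each flagged value.
#' @return a `grubbs_result`: list with `g` (statistic per remaining pass),
#'   `critical`, `outlier_idx` (indices into the original vector), `n_used`.
#' @export
grubbs_screen <- function(values, alpha = 0.05, iterative = FALSE) {
  idx_all <- which(!is.na(values))
  x <- values[idx_all]
  if (length(x) < 3) {
    stop("insufficient data: Grubbs' test needs n >= 3")
  }
  crit <- function(n) {
    t <- stats::qt(1 - alpha / (2 * n), n - 2)
    ## as alpha -> 0 the critical value approaches the attainable maximum
    ## (n-1)/sqrt(n); guard the t = Inf limit so nothing is ever flagged there
    if (!is.finite(t)) return((n - 1) / sqrt(n))
    (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
  }
  out_idx <- integer(0)
  g_trace <- numeric(0)
  c_trace <- numeric(0)
  keep <- seq_along(x)
  repeat {
    n <- length(keep)
    if (n < 3) break
    s <- stats::sd(x[keep])
    if (!is.finite(s) || s == 0) break  # constant data: no outlier
    dev <- abs(x[keep] - mean(x[keep]))
    i_max <- which.max(dev)
    g <- dev[i_max] / s
    cv <- crit(n)
    g_trace <- c(g_trace, g)
    c_trace <- c(c_trace, cv)
    if (g > cv + 1e-10) {
      out_idx <- c(out_idx, idx_all[keep[i_max]])
      keep <- keep[-i_max]
      if (!iterative) break
    } else {
      break
    }
  }
  structure(list(g = g_trace, critical = c_trace, outlier_idx = out_idx,
                 n_used = length(idx_all)),
            class = "grubbs_result")
}

#' Screen a long-format cohort table cell-wise with Grubbs' test
#'
#' Applies [grubbs_screen()] once within every genotype x sex x age x measure
#' cell (the unit at which group statistics are computed) and returns the
#' table with flagged values set to NA.
#'
#' @param table long-format data.frame with columns `genotype`, `sex`,
#'   `age_weeks`, `measure`, `value`.
#' @param alpha significance level per cell.
#' @param iterative passed to [grubbs_screen()].
#' @return the table with an added logical column `screened` and flagged
#'   values replaced by NA.
#' @export
grubbs_screen_table <- function(table, alpha = 0.05, iterative = FALSE) {
  key <- interaction(table$genotype, table$sex, table$age_weeks,
                     table$measure, drop = TRUE)
  table$screened <- FALSE
  for (lv in levels(key)) {
    w <- which(key == lv)
    if (sum(!is.na(table$value[w])) < 3) next
    res <- grubbs_screen(table$value[w], alpha, iterative)
    if (length(res$outlier_idx)) {
      flagged <- w[res$outlier_idx]
      table$screened[flagged] <- TRUE
      table$value[flagged] <- NA_real_
    }
  }
  table
}

#' Factorial between-subject ANOVA (Type III)
#'
#' Fits a fully crossed fixed-effects model by least squares with sum-to-zero
#' factor coding and reports Type III sums of squares (robust to the
#' unbalanced cells that missing data produce). Age, when included, is
#' treated as a categorical between-subject factor.
#'
#' @param table data.frame in long or wide format containing the factors and
#'   the response.
#' @param factors character vector of factor column names (2 or 3).
#' @param response response column name.
#' @return an `anova_result` data.frame: term, F, df1, df2, p.
#' @export
factorial_anova <- function(table, factors, response = "value") {
  stopifnot(length(factors) >= 2, all(factors %in% names(table)),
            response %in% names(table))
  d <- table[stats::complete.cases(table[, c(factors, response)]),
             c(factors, response)]
  for (f in factors) {
    d[[f]] <- factor(d[[f]])
    if (nlevels(droplevels(d[[f]])) < 2) {
      stop("design degeneracy: factor '", f,
           "' has fewer than 2 levels after missing-data removal")
    }
    d[[f]] <- droplevels(d[[f]])
  }
  fml <- stats::as.formula(paste(response, "~",
                                 paste(factors, collapse = " * ")))
  contr <- stats::setNames(rep(list("contr.sum"), length(factors)), factors)
  if (stats::var(d[[response]]) == 0) {
    ## constant response: every effect sum of squares is exactly zero
    tl <- attr(stats::terms(fml), "term.labels")
    out <- data.frame(term = tl, F = 0, df1 = NA_integer_,
                      df2 = NA_integer_, p = 1, stringsAsFactors = FALSE)
    class(out) <- c("anova_result", "data.frame")
    return(out)
  }
  fit <- stats::lm(fml, data = d, contrasts = contr)
  a3 <- car::Anova(fit, type = 3)
  terms <- rownames(a3)
  keep <- !terms %in% c("(Intercept)", "Residuals")
  df2 <- a3["Residuals", "Df"]
  out <- data.frame(term = terms[keep], F = a3$`F value`[keep],
                    df1 = a3$Df[keep], df2 = df2,
                    p = a3$`Pr(>F)`[keep], stringsAsFactors = FALSE)
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Bonferroni-corrected Pearson correlation matrix
#'
#' Pairwise-complete Pearson correlations over a set of measures, with the
#' significance level corrected by the number of comparisons:
#' adjusted alpha = `alpha / choose(k, 2)`.
#'
#' @param data either a wide data.frame/matrix (one column per measure) or a
#'   long-format table with `subject`, `measure`, `value` columns.
#' @param measures measure (column) names; defaults to all.
#' @param alpha base significance level (default 0.05).
#' @param min_pairs minimum paired observations for a pair to be computed.
#' @return a `correlation_plan`: list with `r` (matrix), `p` (matrix),
#'   `n_comparisons`, `adjusted_alpha`, `significant` (logical matrix),
#'   `omitted` (pairs with too few observations).
#' @export
bonferroni_correlations <- function(data, measures = NULL, alpha = 0.05,
                                    min_pairs = 3) {
  if (all(c("subject", "measure", "value") %in% names(data))) {
    wide <- stats::reshape(
      data[, c("subject", "measure", "value")],
      idvar = "subject", timevar = "measure", direction = "wide"
    )
    names(wide) <- sub("^value\\.", "", names(wide))
    data <- wide[, -1, drop = FALSE]
  }
  data <- as.data.frame(data)
  if (is.null(measures)) measures <- names(data)
  k <- length(measures)
  stopifnot(k >= 2)
  m <- choose(k, 2)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(measures, measures))
  diag(r) <- 1
  omitted <- character(0)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      x <- data[[measures[i]]]; y <- data[[measures[j]]]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < min_pairs) {
        omitted <- c(omitted, paste(measures[i], measures[j], sep = ":"))
        warning("pair ", measures[i], ":", measures[j],
                " omitted: fewer than ", min_pairs, " paired observations")
        next
      }
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  adj <- alpha / m
  structure(list(r = r, p = p, n_comparisons = m, adjusted_alpha = adj,
                 significant = !is.na(p) & p < adj, omitted = omitted),
            class = "correlation_plan")
}

#' Pairwise Welch t tests with Bonferroni correction
#'
#' All pairwise two-sample comparisons between group levels; raw p-values are
#' multiplied by the number of comparisons (capped at 1).
#'
#' @param values numeric response vector.
#' @param groups grouping factor (>= 2 levels).
#' @return data.frame: group1, group2, estimate (mean difference), t, p_raw,
#'   p_adjusted.
#' @export
posthoc_bonferroni <- function(values, groups) {
  groups <- factor(groups)
  lv <- levels(groups)
  if (length(lv) < 2) stop("nothing to compare: fewer than 2 groups")
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  out <- lapply(seq_len(m), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    tt <- stats::t.test(values[groups == g1], values[groups == g2],
                        var.equal = FALSE)
    data.frame(group1 = g1, group2 = g2,
               estimate = unname(diff(rev(tt$estimate))),
               t = unname(tt$statistic), p_raw = tt$p.value,
               p_adjusted = min(1, tt$p.value * m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
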