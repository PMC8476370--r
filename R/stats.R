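# Statistical battery: Mann-Kendall trend, t tests, Mann-Whitney U,
# Type III factorial ANOVA/ANCOVA, simple effects, Tukey-Kramer.

new_stat <- function(test, statistic, df = NULL, p_value, effect = NULL,
                     summaries = NULL, note = NULL) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, effect = effect, summaries = summaries,
                 note = note),
            class = "srtt_stat")
}

#' @export
print.srtt_stat <- function(x, ...) {
  st <- paste(sprintf("%s = %.4g", names(x$statistic), x$statistic),
              collapse = ", ")
  dfs <- if (is.null(x$df)) "" else {
    sprintf(" df = %s,", paste(signif(x$df, 5), collapse = ", "))
  }
  cat(sprintf("<%s> %s,%s p = %.4g\n", x$test, st, dfs, x$p_value))
  if (!is.null(x$effect)) {
    cat("  effect:", paste(sprintf("%s = %.4g", names(x$effect), x$effect),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

group_summary <- function(...) {
  gs <- list(...)
  do.call(rbind, lapply(names(gs), function(nm) {
    x <- gs[[nm]]
    data.frame(label = nm, n = length(x), mean = mean(x),
               sd = stats::sd(x), stringsAsFactors = FALSE)
  }))
}

#' Mann-Kendall test for a monotonic trend
#'
#' Computes `S = sum_{i<j} sign(x_j - x_i)`, the tie-corrected Kendall tau,
#' and a two-sided p value from the normal approximation with continuity
#' correction and tie-adjusted variance. Used on trial-RT series to test for
#' learning (a decreasing monotonic trend).
#'
#' @param series ordered numeric values (time order = vector order);
#'   length >= 3.
#' @return An `srtt_stat` with statistics `S`, `tau` and `var_S`.
#' @export
mann_kendall <- function(series) {
  x <- as.numeric(series)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) stop("mann_kendall needs at least 3 observations")
  d <- outer(x, x, "-")  # d[i, j] = x_i - x_j
  S <- -sum(sign(d[upper.tri(d)]))  # sum over i < j of sign(x_j - x_i)
  t_counts <- as.vector(table(x))
  n0 <- n * (n - 1) / 2
  n1 <- sum(t_counts * (t_counts - 1) / 2)
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(t_counts * (t_counts - 1) * (2 * t_counts + 5))) / 18
  if (n0 - n1 <= 0 || var_S <= 0) {
    return(new_stat("mann_kendall", c(S = 0, tau = 0, var_S = 0),
                    p_value = 1, note = "all values tied"))
  }
  tau <- S / sqrt((n0 - n1) * n0)
  z <- if (S > 0) (S - 1) / sqrt(var_S) else if (S < 0) (S + 1) / sqrt(var_S) else 0
  p <- 2 * stats::pnorm(-abs(z))
  new_stat("mann_kendall", c(S = S, tau = tau, var_S = var_S),
           p_value = min(1, p))
}

#' One-sample t test
#'
#' Two-sided test of the mean against `mu0`, with Cohen's d
#' (`(mean - mu0) / sd`). Used to test whether group difference scores
#' differ from zero.
#'
#' @param values numeric sample.
#' @param mu0 null mean.
#' @return An `srtt_stat`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  x <- as.numeric(values)
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("one_sample_t needs at least 2 observations")
  if (stats::sd(x) == 0) stop("one_sample_t: zero variance in sample")
  tt <- stats::t.test(x, mu = mu0)
  new_stat("one_sample_t", c(t = unname(tt$statistic)),
           df = unname(tt$parameter), p_value = tt$p.value,
           effect = c(cohens_d = (mean(x) - mu0) / stats::sd(x)),
           summaries = group_summary(sample = x))
}

#' Independent-samples t test (pooled variance)
#'
#' Two-sided Student t test with pooled variance and Cohen's d based on the
#' pooled standard deviation.
#'
#' @param a,b numeric samples.
#' @return An `srtt_stat`.
#' @export
independent_t <- function(a, b) {
  a <- as.numeric(a[!is.na(a)])
  b <- as.numeric(b[!is.na(b)])
  if (length(a) < 2L || length(b) < 2L) {
    stop("independent_t needs at least 2 observations per group")
  }
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) stop("independent_t: zero pooled variance")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  new_stat("independent_t", c(t = unname(tt$statistic)),
           df = unname(tt$parameter), p_value = tt$p.value,
           effect = c(cohens_d = (mean(a) - mean(b)) / sqrt(sp2)),
           summaries = group_summary(a = a, b = b))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test; U is reported for the first sample, with the
#' p value from the normal approximation with tie correction and continuity
#' correction.
#'
#' @param a,b numeric samples.
#' @return An `srtt_stat` with statistic `U`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a[!is.na(a)])
  b <- as.numeric(b[!is.na(b)])
  if (!length(a) || !length(b)) stop("mann_whitney_u needs non-empty samples")
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))
  new_stat("mann_whitney_u", c(U = unname(wt$statistic)),
           p_value = wt$p.value,
           summaries = group_summary(a = a, b = b))
}

anova_effect_sizes <- function(tab) {
  # tab: term, sum_sq, df, F, p including Residuals row
  ss_res <- tab$sum_sq[tab$term == "Residuals"]
  eff <- tab$term != "Residuals"
  ss_tot <- sum(tab$sum_sq[eff]) + ss_res
  tab$eta_sq <- ifelse(eff, tab$sum_sq / ss_tot, NA_real_)
  tab$partial_eta_sq <- ifelse(eff, tab$sum_sq / (tab$sum_sq + ss_res),
                               NA_real_)
  tab
}

car_anova_table <- function(fit, type) {
  a <- car::Anova(fit, type = type)
  tab <- data.frame(term = rownames(a),
                    sum_sq = a[["Sum Sq"]],
                    df = a[["Df"]],
                    F = a[["F value"]],
                    p_value = a[["Pr(>F)"]],
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[tab$term != "(Intercept)", ]
  df_res <- tab$df[tab$term == "Residuals"]
  tab$df_den <- ifelse(tab$term == "Residuals", NA_real_, df_res)
  anova_effect_sizes(tab)
}

#' Between-subjects factorial ANOVA (Type III)
#'
#' Fits the full factorial linear model with sum-to-zero effect coding and
#' reports Type III sums of squares (the appropriate convention for the
#' unbalanced cells that post hoc learner sorting produces), F tests, and
#' both classical and partial eta squared.
#'
#' @param data data.frame holding the response and factors.
#' @param response response column name (a difference score).
#' @param factors character vector of 2 or 3 factor column names.
#' @param type sums-of-squares type, 3 (default) or 2.
#' @return An object of class `srtt_anova`: `table` (term-level results) and
#'   the underlying `fit`.
#' @export
factorial_anova <- function(data, response, factors, type = 3) {
  stopifnot(length(factors) >= 2L, all(c(response, factors) %in% names(data)))
  data <- data[stats::complete.cases(data[c(response, factors)]), ]
  data[factors] <- lapply(data[factors], factor)
  tab <- table(data[factors])
  if (any(tab == 0L)) {
    empty <- which(tab == 0L, arr.ind = TRUE)[1, , drop = TRUE]
    cell <- paste(mapply(function(d, i) dimnames(tab)[[d]][i],
                         seq_along(empty), empty), collapse = ":")
    stop("empty design cell: ", cell)
  }
  if (any(tab < 2L)) {
    stop("every design cell needs at least 2 observations")
  }
  fml <- stats::reformulate(paste(factors, collapse = "*"), response)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  fit <- stats::lm(fml, data = data)
  structure(list(table = car_anova_table(fit, type), fit = fit,
                 response = response, factors = factors, type = type),
            class = "srtt_anova")
}

#' @export
print.srtt_anova <- function(x, ...) {
  cat(sprintf("<anova> %s ~ %s (Type %s SS)\n", x$response,
              paste(x$factors, collapse = " * "), x$type))
  print(x$table, digits = 4)
  invisible(x)
}

#' Factorial ANCOVA (Type III)
#'
#' As [factorial_anova()] but with a numeric covariate entered additively
#' (e.g. the recall score entered before learner sorting).
#'
#' @inheritParams factorial_anova
#' @param covariate numeric covariate column name.
#' @return An `srtt_anova`.
#' @export
ancova <- function(data, response, factors, covariate, type = 3) {
  stopifnot(all(c(response, factors, covariate) %in% names(data)),
            is.numeric(data[[covariate]]))
  data <- data[stats::complete.cases(data[c(response, factors, covariate)]), ]
  data[factors] <- lapply(data[factors], factor)
  fml <- stats::as.formula(paste(response, "~", covariate, "+",
                                 paste(factors, collapse = "*")))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  fit <- stats::lm(fml, data = data)
  structure(list(table = car_anova_table(fit, type), fit = fit,
                 response = response, factors = factors,
                 covariate = covariate, type = type),
            class = "srtt_anova")
}

#' Simple-effects analysis
#'
#' Tests the effect of `factor` separately within each level of `within`,
#' using each level's own within-level error term (a one-way ANOVA on the
#' subset).
#'
#' @param data data.frame.
#' @param response response column name.
#' @param factor factor whose simple effects are tested.
#' @param within stratifying factor.
#' @return data.frame: `within_level`, `df1`, `df2`, `F`, `p_value`.
#' @export
simple_effects <- function(data, response, factor, within) {
  stopifnot(all(c(response, factor, within) %in% names(data)))
  lv <- unique(as.character(data[[within]]))
  out <- lapply(sort(lv), function(L) {
    sub <- data[as.character(data[[within]]) == L, ]
    sub[[factor]] <- droplevels(base::factor(sub[[factor]]))
    if (nlevels(sub[[factor]]) < 2L) {
      return(data.frame(within_level = L, df1 = NA, df2 = NA, F = NA,
                        p_value = NA))
    }
    fit <- stats::aov(stats::reformulate(factor, response), data = sub)
    a <- summary(fit)[[1]]
    data.frame(within_level = L, df1 = a$Df[1], df2 = a$Df[2],
               F = a$`F value`[1], p_value = a$`Pr(>F)`[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  row.names(out) <- NULL
  out
}

#' Tukey-Kramer pairwise cell comparisons
#'
#' Collapses the design factors to a single cell factor and runs Tukey's HSD
#' (the Tukey-Kramer adjustment applies automatically under unequal n).
#'
#' @param data data.frame.
#' @param response response column name.
#' @param factors factor column names defining the cells.
#' @return data.frame: `comparison`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_posthoc <- function(data, response, factors) {
  stopifnot(all(c(response, factors) %in% names(data)))
  data <- data[stats::complete.cases(data[c(response, factors)]), ]
  cellv <- do.call(interaction, c(unname(data[factors]), list(sep = "")))
  d2 <- data.frame(y = data[[response]], cell = droplevels(cellv))
  fit <- stats::aov(y ~ cell, data = d2)
  th <- stats::TukeyHSD(fit)$cell
  data.frame(comparison = rownames(th), diff = th[, "diff"],
             lwr = th[, "lwr"], upr = th[, "upr"], p_adj = th[, "p adj"],
             stringsAsFactors = FALSE, row.names = NULL)
}

# recursively strip non-serializable bits for JSON export
stat_to_list <- function(x) {
  if (inherits(x, "srtt_stat")) {
    return(list(test = x$test, statistic = as.list(x$statistic),
                df = x$df, p_value = x$p_value,
                effect = if (!is.null(x$effect)) as.list(x$effect),
                summaries = x$summaries, note = x$note))
  }
  if (inherits(x, "srtt_anova")) {
    return(list(test = "anova", type = x$type, response = x$response,
                factors = x$factors, covariate = x$covariate,
                table = x$table))
  }
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, stat_to_list))
  x
}

#' Serialize statistical results to JSON
#'
#' @param results a (possibly nested) list of `srtt_stat` / `srtt_anova`
#'   objects and data.frames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
stats_to_json <- function(results, path) {
  jsonlite::write_json(stat_to_list(results), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")
  invisible(path)
}
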