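# Association-statistics suite: log transforms, Pearson/partial correlation,
# two-tailed t-test, quadratic (curvilinear) regression, Bonferroni
# adjustment, Kruskal-Wallis with Dunn post-hoc comparisons, 2x2 chi-square
# with relative risk and odds ratio, standardised betas, Tukey-fence outlier
# flagging and n-weighted pooled means. Standard fits go through base R
# (lm, cor.test, t.test, kruskal.test, chisq.test); the conventions around
# them (transform bookkeeping, exclusion policies, SPSS-style pairwise
# comparisons) are made explicit here. Complete-case analysis throughout.

#' Log10 transform, optionally after reflection
#'
#' `"log10"` maps `x -> log10(x)` and requires positive values.
#' `"reflect_then_log10"` maps `x -> log10(K + 1 - x)` with `K = max(x)`;
#' it is used for variables containing zeros or negatives (e.g. BMI change)
#' and is order-reversing. `K` is recorded so the transform is invertible.
#'
#' @param values Numeric vector (NAs pass through).
#' @param mode `"log10"` or `"reflect_then_log10"`.
#' @return List with `transformed`, `mode`, and `K` (`NA` for plain log10).
#' @export
transform_log <- function(values, mode = c("log10", "reflect_then_log10")) {
  mode <- match.arg(mode)
  if (mode == "log10") {
    bad <- which(!is.na(values) & values <= 0)
    if (length(bad) > 0) {
      stop("log10 transform requires positive values; offending indices: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    list(transformed = log10(values), mode = mode, K = NA_real_)
  } else {
    K <- max(values, na.rm = TRUE)
    list(transformed = log10(K + 1 - values), mode = mode, K = K)
  }
}

#' Invert a transform_log result
#'
#' @param trans A list returned by [transform_log()].
#' @return The original values.
#' @export
invert_transform_log <- function(trans) {
  if (trans$mode == "log10") 10^trans$transformed
  else trans$K + 1 - 10^trans$transformed
}

#' Pearson or partial correlation
#'
#' With no controls, the Pearson correlation with a two-sided t-based p
#' value. With controls, the partial correlation computed by residualising
#' `x` and `y` on the controls (ordinary least squares with intercept) and
#' correlating the residuals, with the t test on `n - 2 - k` degrees of
#' freedom for `k` controls. Complete cases only.
#'
#' @param x,y Numeric vectors.
#' @param controls Optional list (or data frame) of covariate vectors.
#' @return Tibble with `r`, `p`, `n`, `df`, `n_controls`.
#' @export
correlation <- function(x, y, controls = list()) {
  if (is.data.frame(controls)) controls <- as.list(controls)
  k <- length(controls)
  dat <- data.frame(x = x, y = y)
  for (i in seq_len(k)) dat[[paste0("c", i)]] <- controls[[i]]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < 3 + k) stop("need at least ", 3 + k, " complete cases", call. = FALSE)
  if (stats::sd(dat$x) == 0 || stats::sd(dat$y) == 0) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = n, df = NA_integer_,
                          n_controls = k))
  }
  if (k == 0) {
    ct <- stats::cor.test(dat$x, dat$y)
    return(tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = n,
                          df = unname(ct$parameter), n_controls = 0L))
  }
  Z <- as.matrix(dat[, paste0("c", seq_len(k)), drop = FALSE])
  rx <- stats::lm.fit(cbind(1, Z), dat$x)$residuals
  ry <- stats::lm.fit(cbind(1, Z), dat$y)$residuals
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  tibble::tibble(r = r, p = p, n = n, df = as.integer(df), n_controls = as.integer(k))
}

#' Two-sample two-tailed t-test
#'
#' Pooled-variance Student t by default; Welch via `var_equal = FALSE`.
#' Identical degenerate groups give `t = 0, p = 1`.
#'
#' @param group_a,group_b Numeric vectors (n >= 2 each after NA removal).
#' @param var_equal Pool the variances (default `TRUE`).
#' @return Tibble with `t`, `df`, `p`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
t_test_two_tailed <- function(group_a, group_b, var_equal = TRUE) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble::tibble(t = 0, df = length(a) + length(b) - 2, p = 1,
                            mean_a = mean(a), mean_b = mean(b),
                            n_a = length(a), n_b = length(b)))
    }
    stop("degenerate comparison: zero variance with unequal means", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_a = mean(a), mean_b = mean(b),
                 n_a = length(a), n_b = length(b))
}

#' Tukey-fence outlier flags
#'
#' Quartiles are Tukey hinges (`fivenum`); fences sit at
#' `Q1 - k * IQR` and `Q3 + k * IQR` with `k = 1.5` for ordinary outliers
#' (`"boxplot_1_5"`) or `k = 3` for extreme outliers (`"extreme_3_0"`).
#'
#' @param values Numeric vector (n >= 4 after NA removal).
#' @param policy `"boxplot_1_5"` or `"extreme_3_0"`.
#' @return Logical vector the length of `values` (`NA` stays `NA`).
#' @export
flag_outliers <- function(values, policy = c("boxplot_1_5", "extreme_3_0")) {
  policy <- match.arg(policy)
  k <- if (policy == "boxplot_1_5") 1.5 else 3.0
  v <- values[!is.na(values)]
  if (length(v) < 4) stop("outlier flagging needs n >= 4", call. = FALSE)
  fn <- stats::fivenum(v)
  q1 <- fn[2]; q3 <- fn[4]
  iqr <- q3 - q1
  lo <- q1 - k * iqr; hi <- q3 + k * iqr
  out <- values < lo | values > hi
  out
}

#' Quadratic (curvilinear) regression
#'
#' Ordinary least squares of `y` on `(1, x, x^2)`. Reports both
#' coefficients, the multiple correlation `r = sqrt(r2)`, the overall model
#' F-test p value, and the vertex `-b1/(2*b2)` when the curve opens
#' downwards (the fitted optimum of the predictor). Optionally excludes
#' response outliers first (Tukey fences on `y`).
#'
#' @param x,y Numeric vectors.
#' @param exclude_outliers `"none"`, `"boxplot_1_5"` or `"extreme_3_0"`,
#'   applied to the response before fitting.
#' @return Tibble with `intercept`, `b1`, `b2`, `r`, `r2`, `p` (model F),
#'   `p_b2` (quadratic-term t test), `n`, `n_excluded`, `vertex_x`.
#' @export
quadratic_fit <- function(x, y, exclude_outliers = c("none", "boxplot_1_5", "extreme_3_0")) {
  exclude_outliers <- match.arg(exclude_outliers)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n_excluded <- 0L
  if (exclude_outliers != "none" && length(y) >= 4) {
    drop <- flag_outliers(y, exclude_outliers)
    n_excluded <- sum(drop)
    x <- x[!drop]; y <- y[!drop]
  }
  if (length(x) < 5) stop("quadratic fit needs n >= 5 after exclusions", call. = FALSE)
  if (length(unique(x)) < 3) stop("collinear design: fewer than 3 distinct x values", call. = FALSE)
  fit <- stats::lm(y ~ x + I(x^2))
  sm <- summary(fit)
  beta <- stats::coef(fit)
  fstat <- sm$fstatistic
  p_model <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  vertex <- if (!is.na(beta[3]) && beta[3] < 0) -beta[2] / (2 * beta[3]) else NA_real_
  tibble::tibble(
    intercept = unname(beta[1]), b1 = unname(beta[2]), b2 = unname(beta[3]),
    r = sqrt(sm$r.squared), r2 = sm$r.squared,
    p = unname(p_model), p_b2 = sm$coefficients["I(x^2)", "Pr(>|t|)"],
    n = length(x), n_excluded = n_excluded, vertex_x = unname(vertex)
  )
}

#' Bonferroni adjustment
#'
#' @param p_values Numeric vector of raw p values.
#' @param m Number of tests (default `length(p_values)`).
#' @param alpha Family-wise level (default 0.05).
#' @return List with `threshold` (`alpha/m`), `significant` (raw p below the
#'   threshold) and `adjusted_p` (`min(1, m * p)`).
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values), alpha = 0.05) {
  stopifnot(m >= 1)
  list(threshold = alpha / m,
       significant = p_values < alpha / m,
       adjusted_p = pmin(1, m * p_values))
}

#' Kruskal-Wallis test with Dunn post-hoc multiple comparisons
#'
#' Kruskal-Wallis H with tie correction (via `kruskal.test`) and pairwise
#' Dunn z tests on the pooled mean ranks with the tie-corrected variance and
#' Bonferroni-adjusted p values, matching the SPSS-style "pairwise multiple
#' comparisons" convention.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels (coerced to factor).
#' @return List with `summary` (tibble: `H`, `df`, `p`, `n`), `groups`
#'   (per-group n, mean, median, mean rank) and `pairwise` (tibble:
#'   `group_1`, `group_2`, `z`, `p`, `p_adjusted`).
#' @export
kruskal_wallis_mc <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok]))
  k <- nlevels(groups)
  n <- length(values)
  stopifnot(k >= 2, n >= 5)
  if (length(unique(values)) == 1) {
    lev <- levels(groups)
    pairs <- utils::combn(lev, 2)
    mid_rank <- (n + 1) / 2
    return(list(
      summary = tibble::tibble(H = 0, df = k - 1L, p = 1, n = n),
      groups = tibble::tibble(group = lev,
                              n = as.integer(table(groups)[lev]),
                              mean = rep(values[1], k), median = rep(values[1], k),
                              mean_rank = rep(mid_rank, k)),
      pairwise = tibble::tibble(group_1 = pairs[1, ], group_2 = pairs[2, ],
                                z = 0, p = 1, p_adjusted = 1)
    ))
  }
  kw <- stats::kruskal.test(values, groups)
  ranks <- rank(values)
  grp_tab <- tibble::tibble(
    group = levels(groups),
    n = as.integer(table(groups)[levels(groups)]),
    mean = as.numeric(tapply(values, groups, mean)[levels(groups)]),
    median = as.numeric(tapply(values, groups, stats::median)[levels(groups)]),
    mean_rank = as.numeric(tapply(ranks, groups, mean)[levels(groups)])
  )
  # Dunn z: difference of mean ranks over its tie-corrected standard error
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(levels(groups), 2)
  pw <- lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    n1 <- grp_tab$n[grp_tab$group == g1]; n2 <- grp_tab$n[grp_tab$group == g2]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n1 + 1 / n2))
    z <- (grp_tab$mean_rank[grp_tab$group == g1] -
            grp_tab$mean_rank[grp_tab$group == g2]) / se
    tibble::tibble(group_1 = g1, group_2 = g2, z = z,
                   p = 2 * stats::pnorm(-abs(z)))
  })
  pw <- dplyr::bind_rows(pw)
  pw$p_adjusted <- pmin(1, pw$p * nrow(pw))
  list(
    summary = tibble::tibble(H = unname(kw$statistic), df = as.integer(kw$parameter),
                             p = kw$p.value, n = n),
    groups = grp_tab,
    pairwise = pw
  )
}

#' 2x2 chi-square with relative risk and odds ratio
#'
#' Rows are exposure groups (exposed first), columns outcome yes/no.
#' Pearson chi-square without continuity correction by default (Yates via
#' `correct = TRUE`). `RR = (a/(a+b)) / (c/(c+d))`, `OR = ad/bc`; a zero
#' cell triggers the Haldane-Anscombe 0.5 correction for the OR, flagged in
#' the output.
#'
#' @param table_2x2 2x2 matrix of counts `rbind(c(a, b), c(c, d))`.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return Tibble with `chi_sq`, `df`, `p`, `relative_risk`, `odds_ratio`,
#'   `or_corrected` (logical), `n`.
#' @export
chi_square_rr <- function(table_2x2, correct = FALSE) {
  m <- as.matrix(table_2x2)
  stopifnot(all(dim(m) == c(2, 2)), all(m >= 0))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("chi-square requires positive margins", call. = FALSE)
  }
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  if (c == 0) stop("relative risk undefined: reference-group risk is zero", call. = FALSE)
  rr <- (a / (a + b)) / (c / (c + d))
  zero_cell <- any(m == 0)
  if (zero_cell) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    or <- (a * d) / (b * c)
  }
  tibble::tibble(chi_sq = unname(ct$statistic), df = as.integer(ct$parameter),
                 p = ct$p.value, relative_risk = rr, odds_ratio = or,
                 or_corrected = zero_cell, n = sum(m))
}

#' Standardised regression coefficients
#'
#' z-scores the response and every predictor, fits ordinary least squares,
#' and returns the standardised betas with their two-sided p values.
#'
#' @param response Numeric vector.
#' @param predictors Named list or data frame of predictor vectors.
#' @return Tibble with `predictor`, `beta`, `p`, and an `n` attribute column.
#' @export
standardized_betas <- function(response, predictors) {
  if (is.data.frame(predictors)) predictors <- as.list(predictors)
  stopifnot(length(predictors) >= 1)
  if (is.null(names(predictors)) || any(!nzchar(names(predictors)))) {
    names(predictors) <- paste0("x", seq_along(predictors))
  }
  dat <- data.frame(.y = response, predictors)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < length(predictors) + 2) {
    stop("need at least ", length(predictors) + 2, " complete cases", call. = FALSE)
  }
  zdat <- as.data.frame(lapply(dat, function(v) as.numeric(scale(v))))
  X <- as.matrix(zdat[, -1, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    cm <- stats::cor(X)
    diag(cm) <- 0
    idx <- which(abs(abs(cm) - max(abs(cm))) < 1e-12, arr.ind = TRUE)[1, ]
    stop(sprintf("perfect collinearity between '%s' and '%s'",
                 colnames(X)[idx[1]], colnames(X)[idx[2]]), call. = FALSE)
  }
  fit <- stats::lm(.y ~ ., data = zdat)
  sm <- summary(fit)$coefficients
  tibble::tibble(
    predictor = names(predictors),
    beta = unname(sm[-1, "Estimate"]),
    p = unname(sm[-1, "Pr(>|t|)"]),
    n = n
  )
}

#' n-weighted pooled mean of group means
#'
#' @param means Group means.
#' @param ns Group sizes (>= 1).
#' @return `sum(n_i * m_i) / sum(n_i)`.
#' @examples
#' pooled_mean(c(7.50, 6.96), c(34, 27))  # 7.26 to 2 dp
#' @export
pooled_mean <- function(means, ns) {
  stopifnot(length(means) == length(ns), all(ns >= 1))
  sum(means * ns) / sum(ns)
}
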