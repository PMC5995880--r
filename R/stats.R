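#' Mann-Whitney U test
#'
#' Rank-sum test with `U = min(U1, U2)` and midrank tie handling. The
#' two-tailed p-value is exact (from the null permutation distribution of U)
#' when there are no ties and `n1 * n2 <= 400`, and a tie-corrected normal
#' approximation with continuity correction otherwise.
#'
#' @param a,b Numeric samples.
#' @return One-row tibble: `u`, `p_value`, `n1`, `n2`, `method`
#'   ("exact"/"normal").
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  check_that(length(a) >= 1 && length(b) >= 1, "both samples must be non-empty")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)                     # midranks
  r1 <- sum(rk[seq_len(n1)])
  u1 <- r1 - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  if (!has_ties && n1 * n2 <= 400) {
    p <- min(1, 2 * pwilcox(u, n1, n2))
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu + 0.5) / sqrt(sigma2)   # continuity-corrected, u <= mu
      p <- min(1, 2 * pnorm(z))
    }
    method <- "normal"
  }
  tibble::tibble(u = u, p_value = p, n1 = n1, n2 = n2, method = method)
}

#' Two-way factorial ANOVA with Type-II sums of squares
#'
#' The genotype x session analysis used for the per-cell metrics: fits
#' `value ~ A * B` by least squares and reports Type-II main effects and the
#' interaction, which handle the unbalanced cell counts typical of per-unit
#' data (cells drop in and out across sessions). On balanced designs
#' Type-II equals the classical textbook decomposition.
#'
#' @param data Data frame in long format.
#' @param value Name of the response column (string).
#' @param factor_a,factor_b Names of the two factor columns (strings;
#'   defaults `"genotype"` and `"session_index"`).
#' @return An object of class `ratemapr_anova` with [tidy()] and
#'   [glance()] methods; `tidy()` gives one row per effect (`term`, `sumsq`,
#'   `df`, `df_resid`, `statistic`, `p_value`).
#' @export
anova2 <- function(data, value, factor_a = "genotype",
                   factor_b = "session_index") {
  check_that(all(c(value, factor_a, factor_b) %in% names(data)),
             "named columns not all present in `data`")
  d <- data.frame(
    y = as.numeric(data[[value]]),
    A = factor(data[[factor_a]]),
    B = factor(data[[factor_b]]))
  d <- d[complete.cases(d), ]
  check_that(nlevels(droplevels(d$A)) >= 2 && nlevels(droplevels(d$B)) >= 2,
             "each factor needs at least 2 observed levels")
  d$A <- droplevels(d$A); d$B <- droplevels(d$B)
  cells <- table(d$A, d$B)
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)[1, ]
    abort(sprintf("empty design cell: %s = %s, %s = %s",
                  factor_a, rownames(cells)[idx[1]],
                  factor_b, colnames(cells)[idx[2]]),
          class = "ratemapr_invalid_input")
  }
  fit <- lm(y ~ A * B, data = d)
  if (var(d$y) == 0) {
    # constant response: every effect SS is 0 and F degenerates to 0
    terms_map <- c(A = factor_a, B = factor_b,
                   `A:B` = paste0(factor_a, ":", factor_b))
    dfs <- c((nlevels(d$A) - 1), (nlevels(d$B) - 1),
             (nlevels(d$A) - 1) * (nlevels(d$B) - 1))
    df_resid <- nrow(d) - sum(dfs) - 1
    tidy_tab <- tibble::tibble(
      term = unname(terms_map), sumsq = 0, df = dfs, df_resid = df_resid,
      statistic = 0, p_value = 1)
    return(structure(
      list(table = tidy_tab, fit = fit, data = d, value = value,
           factor_a = factor_a, factor_b = factor_b,
           ss_resid = 0, df_resid = df_resid),
      class = "ratemapr_anova"))
  }
  tab <- car::Anova(fit, type = 2)
  df_resid <- tab["Residuals", "Df"]
  terms_map <- c(A = factor_a, B = factor_b, `A:B` = paste0(factor_a, ":", factor_b))
  rows <- intersect(rownames(tab), names(terms_map))
  tidy_tab <- tibble::tibble(
    term = unname(terms_map[rows]),
    sumsq = tab[rows, "Sum Sq"],
    df = tab[rows, "Df"],
    df_resid = df_resid,
    statistic = tab[rows, "F value"],
    p_value = tab[rows, "Pr(>F)"])
  structure(
    list(table = tidy_tab, fit = fit, data = d,
         value = value, factor_a = factor_a, factor_b = factor_b,
         ss_resid = tab["Residuals", "Sum Sq"], df_resid = df_resid),
    class = "ratemapr_anova")
}

#' @export
print.ratemapr_anova <- function(x, ...) {
  cat(sprintf("Two-way Type-II ANOVA of %s ~ %s * %s\n",
              x$value, x$factor_a, x$factor_b))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @rdname anova2
#' @param x A `ratemapr_anova` object.
#' @param ... Unused.
#' @export
tidy.ratemapr_anova <- function(x, ...) x$table

#' @rdname anova2
#' @export
glance.ratemapr_anova <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
    sigma = s$sigma, df.residual = x$df_resid, nobs = nrow(x$data))
}

#' Bonferroni-adjusted pairwise contrasts within strata
#'
#' The post-hoc step after [anova2()] when the interaction is of interest:
#' for each stratum (level of `factor_b`), contrasts the two `factor_a`
#' groups with a t statistic built on the ANOVA residual variance, then
#' multiplies each p by the number of comparisons performed (capped at 1).
#'
#' @param fit A `ratemapr_anova` from [anova2()].
#' @param strata Which levels of `factor_b` to test (default: all).
#' @return Tibble: one row per stratum with `stratum`, the two group means,
#'   `diff`, `statistic`, `df`, `p_raw`, `p_adjusted`, `n_comparisons`.
#' @export
bonferroni_pairs <- function(fit, strata = NULL) {
  stopifnot(inherits(fit, "ratemapr_anova"))
  d <- fit$data
  levs_a <- levels(d$A)
  check_that(length(levs_a) == 2,
             "pairwise contrasts require exactly 2 groups in factor_a")
  all_strata <- levels(d$B)
  if (is.null(strata)) strata <- all_strata
  strata <- as.character(strata)
  unknown <- setdiff(strata, all_strata)
  if (length(unknown) > 0) {
    abort(paste0("unknown stratum: ", paste(unknown, collapse = ", ")),
          class = "ratemapr_invalid_input")
  }
  mse <- fit$ss_resid / fit$df_resid
  k <- length(strata)
  purrr::map_dfr(strata, function(s) {
    y1 <- d$y[d$A == levs_a[1] & d$B == s]
    y2 <- d$y[d$A == levs_a[2] & d$B == s]
    se <- sqrt(mse * (1 / length(y1) + 1 / length(y2)))
    tstat <- (mean(y1) - mean(y2)) / se
    p <- 2 * pt(-abs(tstat), df = fit$df_resid)
    tibble::tibble(
      stratum = s,
      mean_1 = mean(y1), mean_2 = mean(y2), diff = mean(y1) - mean(y2),
      n_1 = length(y1), n_2 = length(y2),
      statistic = tstat, df = fit$df_resid,
      p_raw = p, p_adjusted = min(1, p * k), n_comparisons = k)
  })
}

#' Per-group mean and SEM panel summary
#'
#' The figure-panel summary: per combination of the grouping columns, the
#' number of non-missing observations, their mean and the standard error of
#' the mean (`sd / sqrt(n)`; `NA` for n < 2).
#'
#' @param data Data frame.
#' @param value Name of the value column (string).
#' @param group_by Character vector of grouping columns (default
#'   `c("genotype", "session_index")`).
#' @return Tibble with the grouping columns plus `n`, `mean`, `sem`,
#'   `n_missing`.
#' @export
panel_summary <- function(data, value,
                          group_by = c("genotype", "session_index")) {
  check_that(value %in% names(data), "`value` column not found")
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      n = sum(!is.na(.data[[value]])),
      mean = mean(.data[[value]], na.rm = TRUE),
      sem = ifelse(sum(!is.na(.data[[value]])) >= 2,
                   sd(.data[[value]], na.rm = TRUE) /
                     sqrt(sum(!is.na(.data[[value]]))), NA_real_),
      n_missing = sum(is.na(.data[[value]])),
      .groups = "drop") |>
    dplyr::mutate(mean = ifelse(.data$n == 0, NA_real_, .data$mean))
}

#' Plot a panel summary as points with SEM error bars
#'
#' @param summary Tibble from [panel_summary()].
#' @param x,colour Names of the columns mapped to the x axis and colour
#'   (defaults `"session_index"` and `"genotype"`).
#' @return A ggplot object.
#' @export
plot_panel_summary <- function(summary, x = "session_index",
                               colour = "genotype") {
  ggplot2::ggplot(summary, ggplot2::aes(
    x = factor(.data[[x]]), y = .data$mean,
    colour = .data[[colour]], group = .data[[colour]])) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.3)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.2, position = ggplot2::position_dodge(0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(0.3)) +
    ggplot2::labs(x = x, y = "mean ± SEM") +
    ggplot2::theme_minimal()
}
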