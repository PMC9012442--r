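#' Normality gate for paired differences
#'
#' Shapiro-Wilk on the paired differences decides the analysis route:
#' p > alpha keeps the parametric route (paired t-test, mean +/- sd summaries),
#' otherwise the nonparametric route (Wilcoxon signed-rank, median (range)
#' summaries). Constant differences cannot be tested and route nonparametric
#' with a warning.
#'
#' @param differences numeric vector of paired differences (n >= 3).
#' @param alpha gate significance level.
#' @return list: \code{route} ("parametric"/"nonparametric"),
#'   \code{shapiro_w}, \code{shapiro_p}.
#' @export
normality_gate <- function(differences, alpha = 0.05) {
  if (length(differences) < 3) stop("normality gate requires n >= 3")
  if (diff(range(differences)) == 0) {
    warning("constant differences: normality undefined, routing nonparametric")
    return(list(route = "nonparametric", shapiro_w = NA_real_, shapiro_p = NA_real_))
  }
  sw <- stats::shapiro.test(differences)
  list(route = if (sw$p.value > alpha) "parametric" else "nonparametric",
       shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value)
}

#' Paired pre/post comparison
#'
#' Routes through \code{normality_gate}: paired t-test on the parametric
#' route, Wilcoxon signed-rank on the nonparametric route (exact distribution
#' for n <= 25 without ties, normal approximation with continuity correction
#' otherwise; zero differences dropped per the Wilcoxon convention). The
#' effect size is the standardized mean difference of the paired differences
#' (mean/sd). Identical pre and post values short-circuit to t = 0, p = 1.
#'
#' @param pre,post paired per-specimen values.
#' @param alpha significance level (used by the gate and the summary flag).
#' @return object of class \code{test_result}: \code{test}, \code{statistic},
#'   \code{p_value}, \code{effect_size}, \code{route}, \code{significant},
#'   \code{summary_pre}, \code{summary_post}, \code{gate}.
#' @export
paired_compare <- function(pre, post, alpha = 0.05) {
  if (length(pre) != length(post))
    stop("pre and post must pair per specimen")
  d <- post - pre
  if (all(d == 0)) {
    res <- list(test = "paired t-test", statistic = 0, p_value = 1,
                effect_size = 0, route = "parametric",
                significant = FALSE,
                summary_pre = fmt_mean_sd(pre), summary_post = fmt_mean_sd(post),
                gate = list(route = "parametric", shapiro_w = NA_real_,
                            shapiro_p = NA_real_))
    class(res) <- "test_result"
    return(res)
  }
  gate <- normality_gate(d, alpha)
  es <- mean(d) / stats::sd(d)
  if (gate$route == "parametric") {
    tt <- stats::t.test(post, pre, paired = TRUE)
    res <- list(test = "paired t-test", statistic = unname(tt$statistic),
                p_value = tt$p.value, effect_size = es, route = gate$route,
                significant = tt$p.value <= alpha,
                summary_pre = fmt_mean_sd(pre), summary_post = fmt_mean_sd(post),
                gate = gate)
  } else {
    dd <- d[d != 0]
    exact <- length(dd) <= 25 && !any(duplicated(abs(dd)))
    wt <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE,
                                              exact = exact, correct = TRUE))
    res <- list(test = "Wilcoxon signed-rank", statistic = unname(wt$statistic),
                p_value = wt$p.value, effect_size = es, route = gate$route,
                significant = wt$p.value <= alpha,
                summary_pre = fmt_median_range(pre),
                summary_post = fmt_median_range(post),
                gate = gate)
  }
  class(res) <- "test_result"
  res
}

fmt_mean_sd <- function(x) sprintf("%.1f ± %.1f", mean(x), stats::sd(x))
fmt_median_range <- function(x)
  sprintf("%.1f (%.1f-%.1f)", stats::median(x), min(x), max(x))

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g%s (effect size d = %.3g)\n",
              x$test, x$statistic, x$p_value,
              if (x$significant) " *" else "", x$effect_size))
  cat(sprintf("  pre %s, post %s [%s route]\n",
              x$summary_pre, x$summary_post, x$route))
  invisible(x)
}

#' Repeated-measures two-way ANOVA over spaces and condition
#'
#' Within-subject two-factor ANOVA (interspinous space, 8 levels; surgical
#' condition, pre/post) with specimen as the subject factor, on a complete
#' balanced table. Sphericity of the multi-level space factor is handled by
#' the Greenhouse-Geisser correction, reported alongside the uncorrected
#' p-values. Tukey HSD pairwise comparisons use the studentized range against
#' each effect's own error stratum.
#'
#' @param records data.frame with columns \code{specimen}, \code{space},
#'   \code{condition}, \code{value}.
#' @param alpha significance level for flagging.
#' @return object of class \code{rm_anova}: \code{table} (effect, df, F, p,
#'   p_gg, epsilon), \code{tukey} (named list of pairwise data.frames).
#' @export
rm_anova_spaces <- function(records, alpha = 0.05) {
  need <- c("specimen", "space", "condition", "value")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  df <- data.frame(specimen = factor(records$specimen),
                   space = factor(records$space),
                   condition = factor(records$condition),
                   value = records$value)
  tab <- table(df$specimen, df$space, df$condition)
  if (any(tab != 1))
    stop("unbalanced or incomplete table: every specimen needs exactly one ",
         "value per space x condition cell (no imputation)")
  ns <- nlevels(df$specimen); nk <- nlevels(df$space); nc <- nlevels(df$condition)

  fit <- stats::aov(value ~ space * condition + Error(specimen / (space * condition)),
                    data = df)
  sm <- summary(fit)
  pull <- function(stratum, effect) {
    st <- sm[[paste0("Error: ", stratum)]][[1]]
    i <- match(effect, trimws(rownames(st)))
    er <- grep("Residuals", rownames(st))
    c(df1 = st[i, "Df"], df2 = st[er, "Df"],
      F = st[i, "F value"], p = st[i, "Pr(>F)"],
      ms_err = st[er, "Mean Sq"])
  }
  eff <- list(space = pull("specimen:space", "space"),
              condition = pull("specimen:condition", "condition"),
              `space:condition` = pull("specimen:space:condition", "space:condition"))

  # Greenhouse-Geisser epsilon per within effect from the covariance of the
  # subject-by-cell matrix under orthonormal effect contrasts
  df$cell <- interaction(df$space, df$condition, lex.order = TRUE)
  cells <- stats::xtabs(value ~ specimen + cell, data = df)
  S <- stats::cov(as.matrix(cells))
  onc <- function(k) {
    C <- stats::contr.helmert(k)
    qr.Q(qr(C))
  }
  gg_eps <- function(M) {
    E <- M %*% S %*% t(M)
    (sum(diag(E)))^2 / (nrow(E) * sum(E^2))
  }
  # cell order from interaction(space, condition, lex.order = TRUE) is
  # space-major: kron(space contrast, condition mean/contrast)
  eps <- c(space = gg_eps(kronecker(t(onc(nk)), t(rep(1, nc)) / nc)),
           condition = gg_eps(kronecker(t(rep(1, nk)) / nk, t(onc(nc)))),
           `space:condition` = gg_eps(kronecker(t(onc(nk)), t(onc(nc)))))

  table_out <- do.call(rbind, lapply(names(eff), function(nm) {
    e <- eff[[nm]]
    p_gg <- stats::pf(e["F"], e["df1"] * eps[nm], e["df2"] * eps[nm],
                      lower.tail = FALSE)
    data.frame(effect = nm, df1 = e["df1"], df2 = e["df2"], F = e["F"],
               p = e["p"], epsilon_gg = eps[nm], p_gg = unname(p_gg),
               row.names = NULL)
  }))

  tukey_factor <- function(fac, e) {
    lev <- levels(df[[fac]])
    means <- tapply(df$value, df[[fac]], mean)
    nh <- nrow(df) / length(lev)  # observations per marginal mean
    pairs <- utils::combn(lev, 2)
    diffs <- means[pairs[2, ]] - means[pairs[1, ]]
    se <- sqrt(e["ms_err"] / nh)
    q <- abs(diffs) / se
    data.frame(level_a = pairs[1, ], level_b = pairs[2, ],
               diff = as.numeric(diffs),
               p_adj = stats::ptukey(q, length(lev), e["df2"], lower.tail = FALSE),
               row.names = NULL)
  }
  tukey <- list(space = tukey_factor("space", eff$space),
                condition = tukey_factor("condition", eff$condition))

  structure(list(table = table_out, tukey = tukey, alpha = alpha,
                 n_specimens = ns, n_spaces = nk, n_conditions = nc),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("repeated-measures ANOVA (%d specimens x %d spaces x %d conditions)\n",
              x$n_specimens, x$n_spaces, x$n_conditions))
  tb <- x$table
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %-16s F(%g, %g) = %.3f, p = %.4g (GG eps %.3f, p = %.4g)%s\n",
                tb$effect[i], tb$df1[i], tb$df2[i], tb$F[i], tb$p[i],
                tb$epsilon_gg[i], tb$p_gg[i],
                if (tb$p[i] <= x$alpha) " *" else ""))
  }
  invisible(x)
}

#' Power of the paired t-test
#'
#' Noncentral-t power computation for a paired (one-sample on differences)
#' t-test at standardized effect size d. Exactly one of \code{n} and
#' \code{power} must be NULL: the missing one is returned (required n is the
#' smallest integer achieving the target power).
#'
#' @param effect_size_d standardized mean difference of the paired
#'   differences.
#' @param n sample size (pairs).
#' @param power target power.
#' @param alpha significance level.
#' @param two_sided two-sided test (default).
#' @return list with \code{n}, \code{power}, \code{effect_size_d},
#'   \code{alpha}.
#' @examples
#' power_paired(0.5, n = 34)$power       # ~0.80
#' power_paired(0.5, power = 0.8)$n      # 34
#' @export
power_paired <- function(effect_size_d, n = NULL, power = NULL, alpha = 0.05,
                         two_sided = TRUE) {
  if (is.null(n) == is.null(power))
    stop("exactly one of n and power must be supplied")
  pw <- function(n) {
    df <- n - 1
    ncp <- abs(effect_size_d) * sqrt(n)
    if (two_sided) {
      crit <- stats::qt(1 - alpha / 2, df)
      stats::pt(crit, df, ncp, lower.tail = FALSE) + stats::pt(-crit, df, ncp)
    } else {
      crit <- stats::qt(1 - alpha, df)
      stats::pt(crit, df, ncp, lower.tail = FALSE)
    }
  }
  if (is.null(power)) {
    if (n < 2) stop("n must be >= 2")
    return(list(n = n, power = pw(n), effect_size_d = effect_size_d,
                alpha = alpha))
  }
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  if (effect_size_d == 0) stop("zero effect size: required n is unbounded")
  # bracket around the normal-approximation estimate, then binary search
  zb <- stats::qnorm(power)
  za <- stats::qnorm(1 - alpha / (if (two_sided) 2 else 1))
  n_hi <- max(4, ceiling(2 * ((za + zb) / abs(effect_size_d))^2) + 10)
  while (pw(n_hi) < power) n_hi <- n_hi * 2
  n_lo <- 2
  while (n_hi - n_lo > 1) {
    mid <- floor((n_lo + n_hi) / 2)
    if (pw(mid) >= power) n_hi <- mid else n_lo <- mid
  }
  list(n = n_hi, power = pw(n_hi), effect_size_d = effect_size_d,
       alpha = alpha)
}
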