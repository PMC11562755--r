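new_test <- function(test, statistic, df = NULL, p = NA_real_,
                     posttests = NULL, flags = character(), ...) {
  structure(c(list(test = test, statistic = statistic, df = df, p = p,
                   posttests = posttests, flags = flags), list(...)),
            class = "drg_test")
}

#' @export
print.drg_test <- function(x, ...) {
  stat <- paste(sprintf("%s = %.4g", names(x$statistic), x$statistic),
                collapse = ", ")
  dfs <- if (!is.null(x$df))
    paste0(" (df ", paste(format(x$df, digits = 4), collapse = ", "), ")")
  else ""
  fmt_p <- function(p) ifelse(is.na(p), "NA",
                              ifelse(p < 0.001, "< 0.001",
                                     sprintf("= %.3f", p)))
  pv <- if (length(x$p) > 1)
    paste(paste0("P(", names(x$p), ") ", fmt_p(x$p)), collapse = ", ")
  else paste("P", fmt_p(x$p))
  cat(x$test, ": ", stat, dfs, ", ", pv, "\n", sep = "")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  if (!is.null(x$posttests)) {
    cat("  posttests:\n")
    print(x$posttests, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Paired t test
#'
#' Two-sided paired t test on per-animal values:
#' `t = mean(d) / (sd(d)/sqrt(n))` with `df = n - 1`. A zero-variance
#' difference with nonzero mean is reported as `p = 0` with a flag; identical
#' vectors give `t = 0, p = 1`.
#'
#' @param x,y paired numeric vectors (same length >= 2, matched by animal).
#' @return a `drg_test`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(new_test("Paired t test", c(t = 0), df = c(df = n - 1), p = 1,
                      flags = "zero-variance differences (all zero)"))
    return(new_test("Paired t test",
                    c(t = sign(mean(d)) * Inf), df = c(df = n - 1), p = 0,
                    flags = "zero-variance differences with nonzero mean"))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  new_test("Paired t test", c(t = unname(tt$statistic)),
           df = c(df = unname(tt$parameter)), p = tt$p.value)
}

#' One-way ANOVA with Tukey posttests
#'
#' `F = MSB/MSW` with `(k - 1, N - k)` df, fitted with [stats::aov()];
#' all-pairs posttests are Tukey HSD via the studentized range distribution.
#'
#' @param groups named list of numeric samples (>= 2 groups, each n >= 2).
#' @return a `drg_test` with a `posttests` data frame (comparison,
#'   difference, adjusted p, method).
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs n >= 2", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups),
                                      vapply(groups, length, integer(1)))))
  if (stats::var(df$value) == 0)
    return(new_test("One-way ANOVA", c(F = NA_real_),
                    df = c(df1 = length(groups) - 1,
                           df2 = nrow(df) - length(groups)), p = NA_real_,
                    flags = "all observations identical; F undefined"))
  fit <- stats::aov(value ~ group, data = df)
  s <- summary(fit)[[1]]
  Fv <- s[["F value"]][1]; pv <- s[["Pr(>F)"]][1]
  flags <- character()
  if (s[["Mean Sq"]][2] == 0) {
    Fv <- Inf; pv <- 0
    flags <- "zero within-group variance"
    post <- NULL
  } else {
    th <- stats::TukeyHSD(fit)$group
    post <- data.frame(comparison = rownames(th), diff = th[, "diff"],
                       p_adj = th[, "p adj"], method = "tukey",
                       row.names = NULL)
  }
  new_test("One-way ANOVA",
           c(F = Fv), df = c(df1 = s$Df[1], df2 = s$Df[2]), p = pv,
           posttests = post, flags = flags)
}

#' Two-way mixed (split-plot) repeated-measures ANOVA
#'
#' Between-subjects factor crossed with a complete within-subjects factor,
#' decomposed by explicit least squares into the classical split-plot strata:
#' the between effect is tested against subject-within-group error, the
#' within effect and the interaction against the within-subjects error.
#' Sphericity is assumed (no Greenhouse-Geisser correction), matching
#' uncorrected RM ANOVA reporting. Unbalanced group sizes are handled by
#' unweighted (cell-means) sums of squares for the effects — equivalent to
#' Type III — and flagged; incomplete within-subject data is an error (no
#' imputation).
#'
#' Posttests must be declared, never inferred: `posttest = "tukey"` runs
#' all-pairs comparisons of the between-group means (studentized range on the
#' subject stratum); `posttest = "sidak"` runs the comparisons given in
#' `comparisons` (data frame with columns `g1`, `g2`, `within`) using the
#' pooled between-at-within error with Satterthwaite df and Sidak adjustment
#' over `family_size` comparisons.
#'
#' @param data data frame in long format.
#' @param subject,between,within,value column names.
#' @param posttest `"none"`, `"tukey"`, or `"sidak"`.
#' @param comparisons for `"sidak"`: data frame (`g1`, `g2`, `within`).
#' @param family_size declared family size for the Sidak adjustment
#'   (default: number of comparisons).
#' @return a `drg_test` with statistics `F_between`, `F_within`,
#'   `F_interaction`, their df pairs and p values, and the full SS table in
#'   `$ss_table`.
#' @export
mixed_anova <- function(data, subject = "subject", between = "between",
                        within = "within", value = "value",
                        posttest = c("none", "tukey", "sidak"),
                        comparisons = NULL, family_size = NULL) {
  posttest <- match.arg(posttest)
  stopifnot(all(c(subject, between, within, value) %in% names(data)))
  s <- factor(data[[subject]]); g <- factor(data[[between]])
  w <- factor(data[[within]]); y <- as.numeric(data[[value]])

  tab <- table(s, w)
  if (any(tab != 1))
    stop("incomplete within-subject data: every subject must be measured ",
         "exactly once at every within level", call. = FALSE)
  sg <- table(s, g)
  if (any(rowSums(sg > 0) != 1))
    stop("each subject must belong to exactly one between level",
         call. = FALSE)
  G <- nlevels(g); k <- nlevels(w)
  subj_group <- g[match(levels(s), s)]
  n_g <- as.numeric(table(subj_group))
  if (any(n_g < 2))
    stop("need >= 2 subjects per between level", call. = FALSE)
  balanced <- length(unique(n_g)) == 1
  N <- nlevels(s)

  grand <- mean(y)
  m_s <- tapply(y, s, mean)
  m_gw <- tapply(y, list(g, w), mean)          # G x k cell means
  m_g_raw <- tapply(y, g, mean)
  flags <- character()

  if (balanced) {
    n <- n_g[1]
    m_w <- tapply(y, w, mean)
    ss_between <- k * n * sum((m_g_raw - grand)^2)
    ss_within_f <- n * G * sum((m_w - grand)^2)
    ss_inter <- n * sum((m_gw - outer(m_g_raw, rep(1, k)) -
                           outer(rep(1, G), m_w) + grand)^2)
  } else {
    flags <- "unbalanced between groups: unweighted-means (Type III) SS"
    n_t <- G / sum(1 / n_g)                    # harmonic mean group size
    mt_g <- rowMeans(m_gw); mt_w <- colMeans(m_gw); mt <- mean(m_gw)
    ss_between <- k * n_t * sum((mt_g - mt)^2)
    ss_within_f <- n_t * G * sum((mt_w - mt)^2)
    ss_inter <- n_t * sum((m_gw - outer(mt_g, rep(1, k)) -
                             outer(rep(1, G), mt_w) + mt)^2)
  }
  # error strata from raw data
  ss_subj <- k * sum((m_s - m_g_raw[subj_group])^2)
  fit_cell <- m_gw[cbind(g, w)]
  ss_err <- sum((y - fit_cell - m_s[s] + m_g_raw[g])^2)
  ss_total <- sum((y - grand)^2)

  df_b <- G - 1; df_subj <- sum(n_g - 1)
  df_w <- k - 1; df_i <- (G - 1) * (k - 1); df_e <- df_subj * (k - 1)
  ms <- function(ss, df) if (df > 0) ss / df else NA_real_
  MS_subj <- ms(ss_subj, df_subj); MS_err <- ms(ss_err, df_e)
  # a zero-SS effect is no effect (F = 0), even against a zero error MS
  fratio <- function(ss_num, df_num, ms_den) {
    if (df_num <= 0) return(NA_real_)
    if (ss_num <= 1e-12 * max(1, ss_total)) return(0)
    ss_num / df_num / ms_den
  }
  F_b <- fratio(ss_between, df_b, MS_subj)
  F_w <- fratio(ss_within_f, df_w, MS_err)
  F_i <- fratio(ss_inter, df_i, MS_err)
  p_b <- if (df_b > 0) stats::pf(F_b, df_b, df_subj, lower.tail = FALSE)
         else NA_real_
  p_w <- stats::pf(F_w, df_w, df_e, lower.tail = FALSE)
  p_i <- if (df_i > 0) stats::pf(F_i, df_i, df_e, lower.tail = FALSE)
         else NA_real_

  ss_table <- data.frame(
    term = c("between", "subjects(between)", "within", "interaction",
             "error(within)", "total"),
    SS = c(ss_between, ss_subj, ss_within_f, ss_inter, ss_err, ss_total),
    df = c(df_b, df_subj, df_w, df_i, df_e, N * k - 1))

  post <- NULL
  if (posttest == "tukey") {
    if (G < 2) stop("Tukey posttests need >= 2 between levels", call. = FALSE)
    if (!balanced)
      flags <- c(flags, "Tukey on unbalanced groups via harmonic mean n")
    n_eff <- G / sum(1 / n_g)
    se <- sqrt(MS_subj / (k * n_eff))
    pairs <- utils::combn(levels(g), 2)
    post <- data.frame(
      comparison = paste(pairs[2, ], pairs[1, ], sep = "-"),
      diff = m_g_raw[pairs[2, ]] - m_g_raw[pairs[1, ]],
      p_adj = stats::ptukey(abs(m_g_raw[pairs[2, ]] - m_g_raw[pairs[1, ]]) /
                              se, G, df_subj, lower.tail = FALSE),
      method = "tukey", row.names = NULL)
  } else if (posttest == "sidak") {
    if (is.null(comparisons))
      stop("posttest 'sidak' requires declared comparisons", call. = FALSE)
    m_fam <- family_size %||% nrow(comparisons)
    # between-group comparison at one within level: pooled error
    var_p <- (MS_subj + (k - 1) * MS_err) / k
    df_sat <- (MS_subj + (k - 1) * MS_err)^2 /
      (MS_subj^2 / df_subj + ((k - 1) * MS_err)^2 / df_e)
    post <- do.call(rbind, lapply(seq_len(nrow(comparisons)), function(r) {
      g1 <- as.character(comparisons$g1[r])
      g2 <- as.character(comparisons$g2[r])
      wl <- as.character(comparisons$within[r])
      n1 <- n_g[match(g1, levels(g))]; n2 <- n_g[match(g2, levels(g))]
      diff <- m_gw[g1, wl] - m_gw[g2, wl]
      tstat <- diff / sqrt(var_p * (1 / n1 + 1 / n2))
      p_raw <- 2 * stats::pt(abs(tstat), df_sat, lower.tail = FALSE)
      data.frame(comparison = paste0(g1, "-", g2, " @ ", wl), diff = diff,
                 t = tstat, p_raw = p_raw,
                 p_adj = sidak_adjust(p_raw, m_fam), method = "sidak")
    }))
  }

  new_test("Two-way mixed RM ANOVA",
           c(F_between = F_b, F_within = F_w, F_interaction = F_i),
           df = c(df_between = df_b, df_subjects = df_subj,
                  df_within = df_w, df_interaction = df_i, df_error = df_e),
           p = c(between = p_b, within = p_w, interaction = p_i),
           posttests = post, flags = flags, ss_table = ss_table)
}

#' Sidak familywise adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, capped at 1. The declared family size `m` must
#' cover all comparisons made.
#'
#' @param p raw p-values.
#' @param m family size (>= number of p-values).
#' @return adjusted p-values.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  check_prob(p, "p")
  if (m < 1 || abs(m - round(m)) > 1e-9)
    stop("m must be a positive integer", call. = FALSE)
  if (m < length(p))
    stop("family size m smaller than the number of comparisons",
         call. = FALSE)
  pmin(1, 1 - (1 - p)^m)
}

#' Shapiro-Wilk normality test
#'
#' Royston's approximation (as implemented in [stats::shapiro.test()]),
#' valid for 3 <= n <= 5000; used as a normality gate at alpha = 0.05 before
#' parametric tests.
#'
#' @param x numeric sample.
#' @return a `drg_test` with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  n <- length(x)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero-variance sample", call. = FALSE)
  sw <- stats::shapiro.test(x)
  new_test("Shapiro-Wilk normality test", c(W = unname(sw$statistic)),
           p = sw$p.value)
}

#' Power of the two-sided two-sample t test
#'
#' Exact power from the noncentral t distribution: with `n` per group the
#' test has `df = 2n - 2` and noncentrality `d * sqrt(n/2)`.
#'
#' @param n per-group sample size (>= 2).
#' @param d Cohen's d.
#' @param alpha two-sided significance level.
#' @return power in `[0, 1]`.
#' @export
power_t <- function(n, d, alpha = 0.05) {
  df <- 2 * n - 2
  crit <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n / 2)
  1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
}

#' Minimal per-group n for a target power
#'
#' Scans n = 2, 3, ... and returns the smallest per-group sample size at
#' which the two-sided two-sample t test (equal n, pooled variance) attains
#' the requested power, using the exact noncentral-t power function.
#'
#' @param d Cohen's d (> 0).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param n_max search bound.
#' @return integer per-group n.
#' @export
power_sample_size_t <- function(d, alpha = 0.05, power = 0.8, n_max = 1e6) {
  if (d <= 0) stop("d must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)", call. = FALSE)
  n <- 2
  while (power_t(n, d, alpha) < power) {
    n <- n + 1
    if (n > n_max) stop("requested power unattainable at n <= n_max",
                        call. = FALSE)
  }
  as.integer(n)
}
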