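# Inference layer: per-nest control-vs-test Welch t-tests, one-way
# within-subject ANOVA for the habituation design, and the three a
# priori Helmert contrasts (control vs all test days; test day 1 vs
# days 2-3; test day 2 vs day 3).

#' Welch two-sample t-test
#'
#' Unequal-variance t with Welch-Satterthwaite fractional degrees of
#' freedom (the default); `pooled = TRUE` gives the classical
#' equal-variance test.  Two-sided throughout.
#'
#' @param x,y numeric samples (each n >= 2).
#' @param metric label carried into the result.
#' @param pooled use the pooled-variance t instead of Welch.
#' @return one-row data.frame of class `comparison_result`: `metric`,
#'   `t`, `df`, `p`, `mean_x`, `mean_y`, `sd_x`, `sd_y`, `n_x`, `n_y`,
#'   `flag`.
#' @export
welch_t_test <- function(x, y, metric = "metric", pooled = FALSE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop_insufficient("each sample needs at least 2 finite values")
  flag <- "ok"
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      res <- list(statistic = 0,
                  parameter = length(x) + length(y) - 2,
                  p.value = 1)
      flag <- "zero_variance"
    } else {
      stop_insufficient("zero variance in both samples with unequal means")
    }
  } else {
    res <- stats::t.test(x, y, var.equal = pooled)
  }
  out <- data.frame(metric = metric,
                    t = unname(res$statistic),
                    df = unname(res$parameter),
                    p = res$p.value,
                    mean_x = mean(x), mean_y = mean(y),
                    sd_x = stats::sd(x), sd_y = stats::sd(y),
                    n_x = length(x), n_y = length(y),
                    flag = flag, stringsAsFactors = FALSE)
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' One-way repeated-measures ANOVA
#'
#' Complete within-subject design: every subject measured once under
#' every condition.  The condition effect is tested against the
#' condition-by-subject interaction, F on (k - 1) and (k - 1)(n - 1)
#' degrees of freedom.  The Greenhouse-Geisser sphericity estimate and
#' the epsilon-corrected p-value are computed and reported alongside but
#' not applied to the headline F.
#'
#' @param data numeric matrix or data.frame, one row per subject, one
#'   column per condition; no missing cells.
#' @param conditions condition labels in design order (default: column
#'   names).
#' @return list of class `anova_result`: `F`, `df_num`, `df_den`, `p`,
#'   `means` (per condition), `gg_epsilon`, `p_gg`, `n_subjects`,
#'   `conditions`.
#' @export
rm_anova <- function(data, conditions = colnames(data)) {
  m <- as.matrix(data)
  if (anyNA(m)) stop_insufficient("missing cells: complete data required")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2)
    stop_insufficient("need >= 2 subjects and >= 2 conditions")
  if (is.null(conditions)) conditions <- paste0("cond", seq_len(k))

  long <- data.frame(
    value = as.vector(m),
    condition = factor(rep(conditions, each = n), levels = conditions),
    subject = factor(rep(seq_len(n), times = k)))
  fit <- stats::aov(value ~ condition + Error(subject), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  F <- tab["condition", "F value"]
  df_num <- tab["condition", "Df"]
  df_den <- tab["Residuals", "Df"]
  p <- tab["condition", "Pr(>F)"]
  # no condition effect at all: guard against 0/0 rounding noise
  tol <- 1e-12 * (1 + sum((m - mean(m))^2))
  if (is.na(F) || tab["condition", "Sum Sq"] <= tol) { F <- 0; p <- 1 }

  # Greenhouse-Geisser epsilon from the double-centred covariance matrix
  S <- stats::cov(m)
  C <- diag(k) - 1 / k
  Sc <- C %*% S %*% C
  eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
  p_gg <- stats::pf(F, eps * df_num, eps * df_den, lower.tail = FALSE)

  structure(list(F = unname(F), df_num = df_num, df_den = df_den,
                 p = unname(p), means = colMeans(m),
                 gg_epsilon = eps, p_gg = unname(p_gg),
                 n_subjects = n, conditions = conditions),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df_num, x$df_den, x$F, x$p))
  cat(sprintf("  GG epsilon = %.3f (corrected p = %.4g)\n",
              x$gg_epsilon, x$p_gg))
  invisible(x)
}

#' A priori Helmert contrasts for the four-condition habituation design
#'
#' Conditions in order (control, day 1, day 2, day 3).  The three
#' orthogonal contrasts are (1) control vs all test days, (2) test day 1
#' vs days 2-3, (3) test day 2 vs day 3; coefficient vectors
#' (3,-1,-1,-1), (0,2,-1,-1), (0,0,1,-1) each scaled to unit sum of
#' squares.  Each contrast is evaluated on per-subject contrast scores
#' with an exact one-sample t against zero; a normal-approximation z and
#' its p-value are reported alongside.
#'
#' @param data subject x condition matrix/data.frame with exactly 4
#'   complete columns in design order.
#' @return data.frame, one row per contrast: `label`, `estimate`, `t`,
#'   `df`, `p`, `z`, `p_z`.  The normalised coefficient matrix is
#'   attached as attribute `coefficients`.
#' @export
helmert_contrasts <- function(data) {
  m <- as.matrix(data)
  if (ncol(m) != 4)
    stop_format("the habituation design needs exactly 4 conditions")
  if (anyNA(m)) stop_insufficient("missing cells: complete data required")
  n <- nrow(m)
  if (n < 2) stop_insufficient("need >= 2 subjects")

  raw <- rbind(c(3, -1, -1, -1),
               c(0, 2, -1, -1),
               c(0, 0, 1, -1))
  coefs <- raw / sqrt(rowSums(raw^2))
  labels <- c("control_vs_test_days", "day1_vs_days23", "day2_vs_day3")

  rows <- lapply(1:3, function(i) {
    scores <- as.vector(m %*% coefs[i, ])
    est <- mean(scores)
    se <- stats::sd(scores) / sqrt(n)
    if (se == 0) {
      null_est <- abs(est) <= 1e-10 * max(1, max(abs(m)))
      if (null_est) est <- 0
      tval <- if (null_est) 0 else sign(est) * Inf
      p <- if (null_est) 1 else 0
    } else {
      tt <- stats::t.test(scores, mu = 0)
      tval <- unname(tt$statistic); p <- tt$p.value
    }
    z <- if (se == 0) tval else est / se
    data.frame(label = labels[i], estimate = est, t = tval, df = n - 1,
               p = p, z = z, p_z = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "coefficients") <- coefs
  out
}

#' Metric-by-metric control-vs-test comparison
#'
#' One Welch t-test per metric column, control as the first sample (so a
#' negative t means the test group is larger).  No multiplicity
#' adjustment by default; `holm = TRUE` adds a Holm-adjusted column.
#'
#' @param metrics_control,metrics_test per-ant metric tables sharing the
#'   requested columns.
#' @param metric_list character vector of metric column names.
#' @param holm add Holm-corrected p-values.
#' @param pooled passed to [welch_t_test()].
#' @return data.frame, one `comparison_result` row per metric.
#' @export
batch_compare <- function(metrics_control, metrics_test, metric_list,
                          holm = FALSE, pooled = FALSE) {
  missing <- setdiff(metric_list,
                     intersect(names(metrics_control), names(metrics_test)))
  if (length(missing))
    stop_format(paste0("unknown metric column(s): ",
                       paste(missing, collapse = ", ")))
  rows <- lapply(metric_list, function(mname) {
    welch_t_test(metrics_control[[mname]], metrics_test[[mname]],
                 metric = mname, pooled = pooled)
  })
  out <- do.call(rbind, rows)
  if (holm) out$p_holm <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  out
}
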