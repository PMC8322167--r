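#' Across-channel variance of an event
#'
#' The unbiased (n-1) sample variance of a subject's usable per-channel
#' impedance changes for one event. A focal injury drives one sector far
#' harder than the rest, so its across-channel variance is large; a global
#' event moves every channel together and its variance is small. This single
#' value per subject-event is the basis of the focal/global discrimination.
#'
#' @param dz Numeric vector of per-channel impedance changes (NAs dropped).
#' @return Variance in ohms^2, or `NA` with fewer than 2 usable channels.
#' @export
channel_variance <- function(dz) {
  dz <- dz[is.finite(dz)]
  if (length(dz) < 2) return(NA_real_)
  stats::var(dz)
}

#' Levene's test for equality of variances
#'
#' Classical Levene test: a one-way ANOVA on absolute deviations from each
#' group's centre, with an F-distribution p-value. Chosen over alternatives
#' such as Bartlett's for robustness to non-normality at small sample sizes.
#' Centre is the group mean by default; `center = "median"` gives the
#' Brown-Forsythe variant.
#'
#' @param values Numeric vector of observations.
#' @param group Grouping vector (>= 2 groups, each with >= 2 values).
#' @param center `"mean"` or `"median"`.
#' @return One-row tibble: `statistic` (W), `df1`, `df2`, `p_value`,
#'   `center`.
#' @export
levene_test <- function(values, group, center = c("mean", "median")) {
  center <- match.arg(center)
  ok <- is.finite(values) & !is.na(group)
  values <- values[ok]; group <- factor(group[ok])
  k <- nlevels(group)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(group) < 2)) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  cfun <- if (center == "mean") mean else stats::median
  centres <- tapply(values, group, cfun)
  d <- abs(values - centres[group])
  n <- length(d); ni <- tabulate(group)
  di <- tapply(d, group, mean)
  dbar <- mean(d)
  ss_between <- sum(ni * (di - dbar)^2)
  ss_within <- sum((d - di[group])^2)
  df1 <- k - 1; df2 <- n - k
  if (ss_within == 0 && ss_between == 0) {
    return(tibble::tibble(statistic = 0, df1 = df1, df2 = df2, p_value = 1,
                          center = center))
  }
  w <- (ss_between / df1) / (ss_within / df2)
  tibble::tibble(statistic = w, df1 = df1, df2 = df2,
                 p_value = stats::pf(w, df1, df2, lower.tail = FALSE),
                 center = center)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t with Welch-Satterthwaite degrees of freedom, used to
#' compare per-subject single-value variances between focal and global events
#' without assuming equal spread.
#'
#' @param group_a,group_b Numeric vectors (>= 2 values each).
#' @return One-row tibble: `statistic` (t), `df`, `p_value`, `mean_a`,
#'   `mean_b`.
#' @export
welch_t <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    eq <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    return(tibble::tibble(statistic = if (eq) 0 else Inf,
                          df = length(group_a) + length(group_b) - 2,
                          p_value = if (eq) 1 else 0,
                          mean_a = mean(group_a), mean_b = mean(group_b)))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value,
                 mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Analysis of means (ANOM) of per-event standard deviations
#'
#' Compares each event class's mean standard deviation against the grand
#' mean with decision limits
#' `grand_mean +/- h * s_pooled * sqrt((k - 1) / (k * n))`. The critical
#' value `h` is the Bonferroni-adjusted two-sided t quantile
#' `qt(1 - alpha / (2k), df)` -- a standard, auditable approximation to
#' Nelson's exact h. Events whose means fall outside the limits are flagged
#' as significantly different from the group mean.
#'
#' @param event_stds Tibble with columns `event` and `std` (one row per
#'   subject-event standard deviation).
#' @param alpha Familywise significance level (default 0.05).
#' @return List of class `bim_anom`: `grand_mean`, `h`, `df`, `limits`
#'   (tibble `event`, `n`, `mean_std`, `lower`, `upper`, `flagged`) and
#'   `flagged_events`.
#' @export
anom_std <- function(event_stds, alpha = 0.05) {
  d <- event_stds[is.finite(event_stds$std), ]
  counts <- table(d$event)
  if (length(counts) < 2) stop("need at least 2 event classes", call. = FALSE)
  if (any(counts < 2)) {
    stop("each event class needs at least 2 subjects", call. = FALSE)
  }
  k <- length(counts)
  n_tot <- nrow(d)
  grand <- mean(d$std)
  means <- tapply(d$std, d$event, mean)
  vars <- tapply(d$std, d$event, stats::var)
  df <- n_tot - k
  s_pooled <- sqrt(sum((counts - 1) * vars) / df)
  if (length(unique(counts)) > 1) {
    warning("unbalanced event classes: decision limits use per-class n",
            call. = FALSE)
  }
  h <- stats::qt(1 - alpha / (2 * k), df)
  half <- h * s_pooled * sqrt((k - 1) / (k * as.numeric(counts)))
  limits <- tibble::tibble(event = names(counts), n = as.integer(counts),
                           mean_std = as.numeric(means[names(counts)]),
                           lower = grand - half, upper = grand + half)
  limits$flagged <- limits$mean_std < limits$lower |
    limits$mean_std > limits$upper
  structure(list(grand_mean = grand, h = h, df = df, s_pooled = s_pooled,
                 alpha = alpha, limits = limits,
                 flagged_events = limits$event[limits$flagged]),
            class = "bim_anom")
}

#' @export
print.bim_anom <- function(x, ...) {
  cat("<bim_anom> grand mean ", signif(x$grand_mean, 4), ", h = ",
      signif(x$h, 4), " (df ", x$df, ")\n", sep = "")
  print(x$limits)
  invisible(x)
}

#' Focal vs global variance summary for a cohort
#'
#' Assembles the channel-variance statistics separating focal from global
#' events: per subject-event across-channel variance and standard deviation
#' of the impedance changes, a Levene test on the pooled per-channel changes
#' (focal group vs global group), a Welch t-test on the per-subject
#' single-value variances, an ANOM of per-event standard deviations, and the
#' within-subject focal-greater-than-global variance comparison.
#'
#' Variance is computed on raw impedance changes (ohms^2); a normalized-map
#' variant is available by passing normalized changes in `delta_z`.
#'
#' @param channel_metrics Tibble with `subject`, `phase`, `channel`,
#'   `delta_z`.
#' @param focal_phases,global_phases Phase names forming the two event
#'   classes (defaults: inflation + deflation vs global_terminal).
#' @param alpha ANOM significance level.
#' @return List of class `bim_variance_summary`: `per_event` (tibble
#'   `subject`, `phase`, `class`, `variance`, `std`), `within_subject`
#'   (tibble `subject`, `var_focal`, `var_global`, `focal_greater`),
#'   `levene`, `welch`, `anom`.
#' @export
variance_summary <- function(channel_metrics,
                             focal_phases = c("inflation", "deflation"),
                             global_phases = "global_terminal",
                             alpha = 0.05) {
  cm <- channel_metrics
  per_event <- cm |>
    dplyr::group_by(.data$subject, .data$phase) |>
    dplyr::summarise(variance = channel_variance(.data$delta_z),
                     std = sqrt(variance), .groups = "drop") |>
    dplyr::mutate(class = dplyr::case_when(
      .data$phase %in% focal_phases ~ "focal",
      .data$phase %in% global_phases ~ "global",
      TRUE ~ "other"))
  pooled <- cm |>
    dplyr::mutate(class = dplyr::case_when(
      .data$phase %in% focal_phases ~ "focal",
      .data$phase %in% global_phases ~ "global",
      TRUE ~ NA_character_)) |>
    dplyr::filter(!is.na(.data$class), is.finite(.data$delta_z))
  levene <- levene_test(pooled$delta_z, pooled$class)
  sv <- per_event |>
    dplyr::filter(.data$class != "other") |>
    dplyr::group_by(.data$subject, .data$class) |>
    dplyr::summarise(variance = mean(.data$variance, na.rm = TRUE),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "class", values_from = "variance")
  welch <- if (nrow(sv) >= 2) {
    welch_t(sv$focal, sv$global)
  } else {
    # single-subject cohorts cannot support a between-subject test
    tibble::tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                   mean_a = mean(sv$focal), mean_b = mean(sv$global))
  }
  within <- sv |>
    dplyr::transmute(.data$subject, var_focal = .data$focal,
                     var_global = .data$global,
                     focal_greater = .data$focal > .data$global)
  anom <- if (length(unique(per_event$subject)) >= 2) {
    anom_std(per_event |>
               dplyr::transmute(event = .data$phase, std = .data$std),
             alpha = alpha)
  } else NULL
  structure(list(per_event = per_event, within_subject = within,
                 levene = levene, welch = welch, anom = anom),
            class = "bim_variance_summary")
}

#' @export
print.bim_variance_summary <- function(x, ...) {
  cat("<bim_variance_summary>\n  Levene W = ",
      signif(x$levene$statistic, 4), ", p = ",
      format.pval(x$levene$p_value), "\n  Welch t = ",
      signif(x$welch$statistic, 4), ", df = ", signif(x$welch$df, 4),
      ", p = ", format.pval(x$welch$p_value), "\n  ",
      sum(x$within_subject$focal_greater, na.rm = TRUE), "/",
      nrow(x$within_subject),
      " subjects with var(focal) > var(global)\n", sep = "")
  invisible(x)
}
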