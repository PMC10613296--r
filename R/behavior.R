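# Behavioral quantification: psychometric curve fitting over morphed-face
# choices, ambiguity grouping, modulation indices, ambiguity sensitivity
# (delta RT), and group comparisons.

#' Map a morph level to its ambiguity level
#'
#' The seven-level morph grid groups into three ambiguity levels:
#' 0/100 percent fear are unambiguous anchors, 30/70 intermediate, and
#' 40/50/60 highly ambiguous.
#'
#' @param morph_pct Integer vector of morph levels (percent fear).
#' @return Character vector: "anchor", "intermediate" or "high".
#' @export
#' @examples
#' group_ambiguity(c(0, 50, 100))
group_ambiguity <- function(morph_pct) {
  if (!all(morph_pct %in% morph_grid())) {
    bad <- unique(morph_pct[!morph_pct %in% morph_grid()])
    stop_invalid("morph level(s) off the task grid: ",
                 paste(bad, collapse = ", "))
  }
  out <- character(length(morph_pct))
  out[morph_pct %in% c(0, 100)] <- "anchor"
  out[morph_pct %in% c(30, 70)] <- "intermediate"
  out[morph_pct %in% c(40, 50, 60)] <- "high"
  out
}

# Logistic psychometric curve P(x) = p_inf / (1 + exp(-alpha (x - x_half))).
psychometric_curve <- function(x, p_inf, x_half, alpha_slope) {
  p_inf / (1 + exp(-alpha_slope * (x - x_half)))
}

# Per-level observed fear proportions from a session table.
fear_proportions <- function(session) {
  lv <- sort(unique(session$morph_pct))
  prop <- vapply(lv, function(x) {
    mean(session$choice[session$morph_pct == x] == "fear")
  }, numeric(1))
  data.frame(morph_pct = lv, p_fear = prop,
             n = as.integer(table(factor(session$morph_pct, levels = lv))))
}

#' Fit the logistic psychometric function to a behavioral session
#'
#' Least-squares fit of `P(x) = p_inf / (1 + exp(-alpha_slope (x -
#' x_half)))` to the per-morph-level observed proportions of "fear"
#' choices. `x_half` is the discrimination threshold (the level at which
#' judgments flip) and `alpha_slope` the sensitivity (steepness). The fit
#' uses bounded multi-start optimization (`p_inf` in (0, 1.05],
#' `x_half` in \[0, 100\], `alpha_slope` in (0, 5\]) with moment-based and
#' gridded starting points, which avoids the local minima that plague
#' flat-slope regimes.
#'
#' @param session Behavioral session data.frame (see [gen_behavior()]).
#' @return Object of class `psychometric_fit`: list with `p_inf`, `x_half`,
#'   `alpha_slope`, `rss`, `converged`, and `message`. Sessions where every
#'   choice is identical leave the slope unidentifiable and are returned
#'   with `converged = FALSE`.
#' @export
fit_psychometric <- function(session) {
  if (!all(c("morph_pct", "choice") %in% names(session))) {
    stop_invalid("session needs columns morph_pct and choice")
  }
  pr <- fear_proportions(session)
  fit_psychometric_props(pr$morph_pct, pr$p_fear)
}

#' @describeIn fit_psychometric Fit directly to per-level fear proportions
#'   (the quantity the least-squares objective is defined on).
#' @param morph_pct Morph levels (percent fear).
#' @param p_fear Observed fear proportion at each level.
#' @export
fit_psychometric_props <- function(morph_pct, p_fear) {
  if (length(morph_pct) != length(p_fear) || length(morph_pct) < 2) {
    stop_invalid("need >= 2 distinct morph levels to fit")
  }
  pr <- data.frame(morph_pct = morph_pct, p_fear = p_fear)
  if (stats::var(pr$p_fear) == 0) {
    return(structure(list(p_inf = NA_real_, x_half = NA_real_,
                          alpha_slope = NA_real_, rss = NA_real_,
                          converged = FALSE,
                          message = "all choices identical across levels; slope unidentifiable"),
                     class = "psychometric_fit"))
  }
  x <- pr$morph_pct; y <- pr$p_fear
  rss_fn <- function(par) {
    sum((y - psychometric_curve(x, par[1], par[2], par[3]))^2)
  }
  lower <- c(1e-3, 0, 1e-4)
  upper <- c(1.05, 100, 5)
  # moment-based start: p_inf from the top proportion, x_half from the
  # level closest to half-max, slope from a logit-scale secant
  p0 <- min(max(max(y), 0.1), 1.05)
  xh0 <- x[which.min(abs(y - p0 / 2))]
  starts <- rbind(
    c(p0, xh0, 0.1),
    as.matrix(expand.grid(p_inf = c(p0, 1),
                          x_half = c(30, 50, 70),
                          alpha_slope = c(0.05, 0.2, 1)))
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::nlminb(pmin(pmax(starts[i, ], lower), upper), rss_fn,
                    lower = lower, upper = upper,
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(p_inf = NA_real_, x_half = NA_real_,
                          alpha_slope = NA_real_, rss = NA_real_,
                          converged = FALSE,
                          message = "all optimizer starts failed"),
                     class = "psychometric_fit"))
  }
  par <- best$par
  ok <- best$convergence == 0 && is.finite(best$objective)
  structure(list(p_inf = par[1], x_half = par[2], alpha_slope = par[3],
                 rss = best$objective, converged = ok,
                 message = if (ok) "ok" else best$message),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Psychometric fit: NOT converged (", x$message, ")\n", sep = "")
  } else {
    cat(sprintf(
      "Psychometric fit: p_inf = %.3f, x_half = %.2f%%, alpha = %.4f (rss %.2e)\n",
      x$p_inf, x$x_half, x$alpha_slope, x$rss))
  }
  invisible(x)
}

# Per-level means of a measure column, with missing values dropped
# per-measure (not per-session).
measure_column <- function(measure) {
  switch(measure,
         rt = "rt_s",
         confidence = "confidence",
         confidence_rt = "confidence_rt_s",
         stop_invalid("measure must be one of rt, confidence, confidence_rt"))
}

level_mean <- function(session, measure, level) {
  col <- measure_column(measure)
  if (!col %in% names(session)) {
    stop_invalid("session has no column for measure '", measure, "'")
  }
  lv <- group_ambiguity(session$morph_pct)
  v <- session[[col]][lv == level]
  v <- v[is.finite(v)]
  if (!length(v)) {
    stop_invalid("no non-missing '", measure, "' trials at level ", level)
  }
  mean(v)
}

#' Ambiguity modulation index of a behavioral measure
#'
#' The modulation of a measure by ambiguity: the difference between its
#' mean on high-ambiguity trials and on anchor trials, normalized by the
#' anchor mean, `(high - anchor) / anchor`. Positive values mean the
#' measure is inflated under ambiguity (typical for RT), negative that it
#' is suppressed (typical for confidence).
#'
#' @param session Behavioral session data.frame.
#' @param measure One of "rt", "confidence", "confidence_rt".
#' @return List of class `modulation_index`: `measure`, `value`,
#'   `high_mean`, `anchor_mean`.
#' @export
modulation_index <- function(session, measure = c("rt", "confidence",
                                                  "confidence_rt")) {
  measure <- match.arg(measure)
  hm <- level_mean(session, measure, "high")
  am <- level_mean(session, measure, "anchor")
  if (am == 0) {
    stop_invalid("anchor mean of '", measure,
                 "' is zero; modulation undefined")
  }
  structure(list(measure = measure, value = (hm - am) / am,
                 high_mean = hm, anchor_mean = am),
            class = "modulation_index")
}

#' Ambiguity sensitivity: RT difference between high-ambiguity and anchor
#'
#' The un-normalized mean reaction-time difference (seconds) between
#' high-ambiguity and anchor trials. This is the behavioral predictor used
#' by the connectivity prediction model.
#'
#' @param session Behavioral session data.frame.
#' @return List of class `ambiguity_sensitivity` with `delta_rt` (seconds),
#'   `high_mean`, `anchor_mean`.
#' @export
ambiguity_sensitivity <- function(session) {
  hm <- level_mean(session, "rt", "high")
  am <- level_mean(session, "rt", "anchor")
  structure(list(delta_rt = hm - am, high_mean = hm, anchor_mean = am),
            class = "ambiguity_sensitivity")
}

#' Compare a behavioral quantity across participant groups
#'
#' Two independent groups: two-tailed two-sample t-test (pooled variance)
#' with Cohen's d. More than two groups: one-way ANOVA, or one-way
#' repeated-measures ANOVA when `design = "repeated"` (groups must then be
#' aligned by participant and of equal length).
#'
#' @param values_by_group Named list of numeric vectors, one per group.
#' @param design "independent" or "repeated".
#' @return List with `statistic`, `df`, `p_value`, `effect_size`,
#'   `method`.
#' @export
group_compare <- function(values_by_group,
                          design = c("independent", "repeated")) {
  design <- match.arg(design)
  if (!is.list(values_by_group) || length(values_by_group) < 2) {
    stop_invalid("need >= 2 groups")
  }
  ns <- lengths(values_by_group)
  if (any(ns < 2)) stop_invalid("each group needs >= 2 values")
  if (length(values_by_group) == 2 && design == "independent") {
    x <- values_by_group[[1]]; y <- values_by_group[[2]]
    tt <- stats::t.test(x, y, var.equal = TRUE)
    return(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, effect_size = cohens_d(x, y),
                method = "two-sample t-test (pooled variance), Cohen's d"))
  }
  if (design == "repeated") {
    if (length(unique(ns)) != 1) {
      stop_invalid("repeated design needs equal group lengths")
    }
    mat <- do.call(cbind, values_by_group)
    res <- rm_anova(mat)
    return(list(statistic = res$F, df = c(res$df1, res$df2),
                p_value = res$p_value, effect_size = res$partial_eta2,
                method = res$method))
  }
  vals <- unlist(values_by_group, use.names = FALSE)
  grp <- factor(rep(names(values_by_group), ns))
  fit <- stats::aov(vals ~ grp)
  s <- summary(fit)[[1]]
  eta2 <- s[["Sum Sq"]][1] / sum(s[["Sum Sq"]])
  list(statistic = s[["F value"]][1], df = s[["Df"]],
       p_value = s[["Pr(>F)"]][1], effect_size = eta2,
       method = "one-way ANOVA, eta squared")
}
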