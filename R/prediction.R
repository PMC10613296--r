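# Linear prediction of amygdala-dmPFC functional connectivity from
# behavioral ambiguity sensitivity (delta RT), and group comparisons of
# predicted connectivity against a control cohort.

#' Connectivity prediction model
#'
#' The linear map `y = a * delta_rt + b` from a participant's ambiguity
#' sensitivity (mean RT difference between high-ambiguity and anchor
#' trials, in seconds) to the strength of amygdala-dmPFC functional
#' connectivity (dimensionless model units). The default coefficients
#' (a = 2.4739, b = -0.1329) are the published fit from fMRI data; they
#' are configuration, and [fit_prediction_model()] can refit them from
#' paired observations.
#'
#' @param a Slope, connectivity units per second.
#' @param b Intercept, connectivity units.
#' @return Object of class `prediction_model`.
#' @export
prediction_model <- function(a = 2.4739, b = -0.1329) {
  check_scalar(a, "a"); check_scalar(b, "b")
  structure(list(a = a, b = b), class = "prediction_model")
}

#' Predict connectivity from ambiguity sensitivity
#'
#' @param model A [prediction_model()].
#' @param delta_rt Ambiguity sensitivity in seconds (vectorized).
#' @return Predicted connectivity `a * delta_rt + b`.
#' @export
predict_connectivity <- function(model, delta_rt) {
  if (!inherits(model, "prediction_model")) {
    stop_invalid("model must be a prediction_model")
  }
  if (!is.numeric(delta_rt) || any(!is.finite(delta_rt))) {
    stop_invalid("delta_rt must be finite numeric")
  }
  model$a * delta_rt + model$b
}

#' Refit the prediction model from paired observations
#'
#' Ordinary least squares of connectivity on delta RT. Provided as a
#' generic utility; the default published coefficients are used when no
#' paired fMRI data are available.
#'
#' @param delta_rt Numeric vector, seconds.
#' @param connectivity Numeric vector, same length.
#' @return A [prediction_model()] with fitted `a`, `b`.
#' @export
fit_prediction_model <- function(delta_rt, connectivity) {
  if (length(delta_rt) != length(connectivity) || length(delta_rt) < 3) {
    stop_invalid("need >= 3 paired observations")
  }
  co <- stats::coef(stats::lm(connectivity ~ delta_rt))
  prediction_model(a = unname(co[2]), b = unname(co[1]))
}

#' Compare predicted connectivity across groups
#'
#' Predicts connectivity for every participant from their delta RT, then
#' tests each non-control group against the control group with a
#' two-tailed two-sample t-test (pooled variance) and Cohen's d. Since
#' the prediction is affine, these statistics are identical to the same
#' tests on delta RT itself. Normalized predictions (`y` minus the
#' control-group mean) are returned for reporting.
#'
#' @param delta_rt_by_group Named list of numeric vectors (seconds), one
#'   per group; must include `control_label`.
#' @param control_label Name of the control group (default "control").
#' @param model A [prediction_model()].
#' @return Object of class `group_prediction`: list with `predicted`
#'   (named list of y per group), `normalized` (y minus control mean),
#'   `comparisons` (data.frame: group, t, df, p_value, cohens_d,
#'   mean_diff), `control_label`, `model`.
#' @export
compare_groups_prediction <- function(delta_rt_by_group,
                                      control_label = "control",
                                      model = prediction_model()) {
  if (!control_label %in% names(delta_rt_by_group)) {
    stop_invalid("control group '", control_label, "' missing")
  }
  if (any(lengths(delta_rt_by_group) < 2)) {
    stop_invalid("each group needs >= 2 participants")
  }
  predicted <- lapply(delta_rt_by_group, predict_connectivity,
                      model = model)
  ctrl <- predicted[[control_label]]
  normalized <- lapply(predicted, function(y) y - mean(ctrl))
  others <- setdiff(names(predicted), control_label)
  comparisons <- do.call(rbind, lapply(others, function(g) {
    tt <- stats::t.test(predicted[[g]], ctrl, var.equal = TRUE)
    data.frame(group = g, t = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value,
               cohens_d = cohens_d(predicted[[g]], ctrl),
               mean_diff = mean(predicted[[g]]) - mean(ctrl),
               stringsAsFactors = FALSE)
  }))
  structure(list(predicted = predicted, normalized = normalized,
                 comparisons = comparisons,
                 control_label = control_label, model = model),
            class = "group_prediction")
}
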