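#' @export
print.cea_scenario <- function(x, ...) {
  cat(sprintf("Statin primary-prevention scenario: threshold %.1f%%, start age %d\n",
              100 * x$threshold, x$start_age))
  cat(sprintf("  calibration target (10-y risk): %.4f  [k female %.3f, male %.3f]\n",
              x$target_risk, x$k[["female"]], x$k[["male"]]))
  cat(sprintf("  NNT (5 y): %.0f   QALYs gained: %.3f", x$nnt_5y, x$qaly_gain))
  if (all(is.finite(x$qaly_ci)))
    cat(sprintf(" (95%% CI %.3f-%.3f)", x$qaly_ci[1], x$qaly_ci[2]))
  cat("\n")
  cat(sprintf("  ICER: %.0f Eur/QALY   avoided event costs: %.0f Eur\n",
              x$icer, x$avoided_event_costs))
  cat(sprintf("  treated share: %.2f%%   mean treated risk: %.2f%%   budget: %.2f bn Eur/y\n",
              100 * x$share, 100 * x$mean_risk_treated, x$budget / 1e9))
  if (is.finite(x$le_gain_treated_pop))
    cat(sprintf("  LE gain: treated population %.2f y, total population %.2f y\n",
                x$le_gain_treated_pop, x$le_gain_total_pop))
  invisible(x)
}

#' @export
summary.cea_scenario <- function(object, ...) {
  out <- data.frame(
    sex = SEXES,
    k = unname(object$k[SEXES]),
    qaly_gain = vapply(SEXES, function(sx)
      object$per_sex[[sx]]$qaly_tx - object$per_sex[[sx]]$qaly_untx, numeric(1)),
    le_gain = vapply(SEXES, function(sx)
      object$per_sex[[sx]]$le_tx - object$per_sex[[sx]]$le_untx, numeric(1)),
    statin_cost = vapply(SEXES, function(sx)
      object$per_sex[[sx]]$statin, numeric(1)),
    arr_5y = vapply(SEXES, function(sx)
      object$per_sex[[sx]]$arr5, numeric(1)),
    weight = unname(object$sex_weights[SEXES]))
  structure(list(scenario = object, per_sex = out), class = "summary.cea_scenario")
}

#' @export
print.summary.cea_scenario <- function(x, ...) {
  print(x$scenario)
  cat("\nPer-sex components:\n")
  print(x$per_sex, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
print.cea_grid <- function(x, digits = 3, ...) {
  cat("Statin primary-prevention scenario grid\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Plot a scenario grid
#'
#' Base-graphics summary: QALYs gained and ICER against start age, one line
#' per risk threshold.
#'
#' @param x A `cea_grid`.
#' @param which `"qaly"` or `"icer"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.cea_grid <- function(x, which = c("qaly", "icer"), ...) {
  which <- match.arg(which)
  col <- if (which == "qaly") "qaly_gain" else "icer_eur"
  ths <- sort(unique(x$threshold_pct))
  ages <- sort(unique(x$start_age))
  m <- sapply(ths, function(th)
    x[[col]][x$threshold_pct == th][order(x$start_age[x$threshold_pct == th])])
  graphics::matplot(ages, m, type = "b", pch = 19, lty = 1,
                    xlab = "Age at start of therapy (years)",
                    ylab = if (which == "qaly") "QALYs gained" else "ICER (Eur/QALY)",
                    ...)
  graphics::legend("topright", legend = sprintf("%.1f%%", ths),
                   col = seq_along(ths), lty = 1, pch = 19,
                   title = "Risk threshold", bty = "n")
  invisible(x)
}

#' Plot a cohort trajectory
#'
#' State occupancy over age as stacked shares of the cohort.
#'
#' @param x A `cohort_trajectory`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.cohort_trajectory <- function(x, ...) {
  occ <- x$dist[-1L, , drop = FALSE]
  graphics::matplot(x$ages, occ, type = "l", lty = 1, lwd = 2,
                    xlab = "Age (years)", ylab = "State occupancy", ...)
  graphics::legend("right", legend = colnames(occ), col = 1:7, lty = 1,
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}

#' Export a trajectory as tidy data
#'
#' @param traj A `cohort_trajectory`.
#' @param arm Label recorded in the `arm` column.
#' @return Long data frame: `age`, `sex`, `arm`, `state`, `occupancy`, with
#'   incident-event columns repeated per state row's age.
#' @export
trajectory_as_data_frame <- function(traj, arm = if (traj$treated) "treated" else "untreated") {
  occ <- traj$dist[-1L, , drop = FALSE]
  long <- do.call(rbind, lapply(STATES, function(st)
    data.frame(age = traj$ages, sex = traj$sex, arm = arm, state = st,
               occupancy = occ[, st])))
  ev <- as.data.frame(traj$events)
  ev$age <- traj$ages
  merge(long, ev, by = "age", sort = TRUE)
}
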