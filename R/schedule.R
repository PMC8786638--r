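#' Experimental design plan
#'
#' The study design: 12 mesocosm tanks (6 per treatment), each group
#' assayed in the arena twice a week for seven weeks, plus home-tank assays
#' twice a day, four days a week.
#'
#' @param n_tanks Number of independent mesocosm tanks.
#' @param groups_per_treatment Tanks per treatment arm.
#' @param arena_assays_per_week Arena trials per group per week.
#' @param weeks Study duration in weeks.
#' @param home_assays_per_day Home-tank assays per day.
#' @param home_days_per_week Home-tank assay days per week.
#' @return List of class `experiment_plan`.
#' @export
experiment_plan <- function(n_tanks = 12, groups_per_treatment = 6,
                            arena_assays_per_week = 2, weeks = 7,
                            home_assays_per_day = 2,
                            home_days_per_week = 4) {
  v <- c(n_tanks, groups_per_treatment, arena_assays_per_week, weeks,
         home_assays_per_day, home_days_per_week)
  if (any(v < 0) || any(v != round(v))) {
    stop("all plan counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(environment()), class = "experiment_plan")
}

#' Enumerate trial counts implied by an experiment plan
#'
#' @param plan An [experiment_plan()].
#' @return List with `arena_trials_per_group`, `arena_trials_total` and
#'   `home_trials_total`. The default plan gives 14 arena trials per group,
#'   168 arena trials and 672 home-tank trials in total.
#' @examples
#' enumerate_schedule(experiment_plan())
#' @export
enumerate_schedule <- function(plan = experiment_plan()) {
  stopifnot(inherits(plan, "experiment_plan"))
  per_group <- plan$arena_assays_per_week * plan$weeks
  list(arena_trials_per_group = per_group,
       arena_trials_total = per_group * plan$n_tanks,
       home_trials_total = plan$n_tanks * plan$home_assays_per_day *
         plan$home_days_per_week * plan$weeks)
}
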