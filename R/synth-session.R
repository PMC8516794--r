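#' Simulate a complete participant session
#'
#' Runs the whole generator for one participant: a schedule per block of the
#' config's block plan, continuous EEG with stimulus-locked ERPs, a gyroscope
#' stream (the last sporadic block carries the forced ambulatory "lunch"
#' bout), behavioural responses, and optional artifact injection. All draws
#' derive from `seed`, so the session is fully reproducible.
#'
#' @param profile A [participant_profile()].
#' @param config A [session_config()].
#' @param participant Participant id.
#' @param artifact_plans Optional list of [artifact_plan()]s, one per block
#'   (or a single plan recycled); `NULL` injects nothing.
#' @param seed Integer seed.
#' @return A list of class `oddball_session` with elements `schedules`,
#'   `recordings` (gyro attached), `behavior`, `gyro_states`, `artifact_logs`,
#'   `profile`, `config`, `participant`, `seed`.
#' @export
#' @examples
#' cfg <- session_config(n_participants = 1, block_plan = "rapid", n_trials = 12)
#' ses <- simulate_session(participant_profile(), cfg, seed = 1)
#' ses$recordings[[1]]
simulate_session <- function(profile, config, participant = 1L,
                             artifact_plans = NULL, seed = 1L) {
  set.seed(seed)
  plan <- config$block_plan
  lunch_block <- tail(which(plan == "sporadic"), 1)
  re <- draw_random_effects(profile)

  schedules <- list(); recordings <- list()
  gyro_states <- list(); artifact_logs <- list()
  behavior <- list()

  for (b in seq_along(plan)) {
    sch <- generate_schedule(plan[b], n_trials = config$n_trials,
                             target_fraction = config$target_fraction)
    rec <- simulate_eeg(profile, sch, config, participant = participant,
                        block = b)
    g <- simulate_gyro(config, recording_duration(rec), variant = plan[b],
                       lunch = length(lunch_block) && b == lunch_block)
    rec$gyro <- g$gyro
    rec$gyro_rate <- g$rate

    if (!is.null(artifact_plans)) {
      ap <- if (inherits(artifact_plans, "artifact_plan")) artifact_plans else
        artifact_plans[[b]]
      inj <- inject_artifacts(rec, ap)
      rec <- inj$recording
      artifact_logs[[b]] <- inj$log
    } else {
      artifact_logs[[b]] <- tibble(kind = character(), channel = character(),
                                   start_s = numeric(), end_s = numeric(),
                                   param = numeric())
    }

    behavior[[b]] <- simulate_behavior(profile, stats::setNames(list(sch), b),
                                       participant = participant,
                                       random_effects = re)
    schedules[[b]] <- sch
    recordings[[b]] <- rec
    gyro_states[[b]] <- g$state
  }

  structure(
    list(schedules = schedules, recordings = recordings,
         behavior = bind_rows(behavior), gyro_states = gyro_states,
         artifact_logs = artifact_logs, profile = profile, config = config,
         participant = participant, seed = seed),
    class = "oddball_session"
  )
}

#' @export
print.oddball_session <- function(x, ...) {
  cat(sprintf("<oddball_session> participant %s, %d blocks (%s), seed %s\n",
              x$participant, length(x$recordings),
              paste(x$config$block_plan, collapse = "/"), x$seed))
  invisible(x)
}
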