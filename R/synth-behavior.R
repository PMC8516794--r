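#' Inverse-Gaussian random deviates
#'
#' Michael-Schucany-Haas transformation sampler for the inverse-Gaussian
#' (Wald) distribution with mean `mu` and shape `lambda` (variance
#' `mu^3 / lambda`).
#'
#' @param n Number of draws.
#' @param mu Mean (vectorized).
#' @param lambda Shape (vectorized).
#' @return Numeric vector of positive deviates.
#' @export
rinvgauss <- function(n, mu, lambda) {
  stopifnot(all(mu > 0), all(lambda > 0))
  mu <- rep_len(mu, n); lambda <- rep_len(lambda, n)
  y <- rnorm(n)^2
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  z <- runif(n)
  ifelse(z <= mu / (mu + x), x, mu^2 / x)
}

#' Draw by-participant random effects for the behavioural models
#'
#' Intercept and slope deviations are independent, each mean-zero Gaussian
#' with the SDs in the profile.
#'
#' @param profile A [participant_profile()].
#' @return List with `rt = c(intercept, slope)` and `miss = c(intercept,
#'   slope)` link-scale deviations.
#' @export
draw_random_effects <- function(profile) {
  list(
    rt = c(rnorm(1, 0, profile$rt_random_sds[1]),
           rnorm(1, 0, profile$rt_random_sds[2])),
    miss = c(rnorm(1, 0, profile$miss_random_sds[1]),
             rnorm(1, 0, profile$miss_random_sds[2]))
  )
}

#' Simulate target-response behaviour for one participant
#'
#' For every scored target trial a miss is drawn from the logit-scale miss
#' model; hits receive a reaction time drawn from the inverse-Gaussian RT
#' model with response-scale mean `1 / eta` (inverse link) and the profile's
#' shape. Random effects are drawn once per participant (or passed in).
#'
#' @param profile A [participant_profile()].
#' @param schedules Named list of `oddball_schedule` objects, one per block;
#'   names (or indices) become the block id.
#' @param participant Participant id recorded in the table.
#' @param random_effects Optional list as returned by [draw_random_effects()];
#'   drawn from the profile when `NULL`.
#' @param seed Optional integer seed.
#'
#' @return Tibble with columns `participant`, `block`, `variant`, `trial`,
#'   `role`, `miss`, `rt_s` (NA when missed); one row per scored target.
#' @export
#' @examples
#' sch <- list(b1 = generate_schedule("rapid", seed = 1))
#' simulate_behavior(participant_profile(), sch, seed = 1)
simulate_behavior <- function(profile, schedules, participant = 1L,
                              random_effects = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(random_effects)) random_effects <- draw_random_effects(profile)
  if (is.null(names(schedules))) names(schedules) <- seq_along(schedules)

  purrr::imap(schedules, function(sch, block) {
    variant <- attr(sch, "variant")
    x <- as.numeric(variant == "sporadic")
    eta_rt <- profile$rt_intercept_link + random_effects$rt[1] +
      (profile$rt_slope_link + random_effects$rt[2]) * x
    if (eta_rt <= 0) abort("non-positive response-scale RT mean implied by profile.")
    eta_miss <- profile$miss_intercept_link + random_effects$miss[1] +
      (profile$miss_slope_link + random_effects$miss[2]) * x

    tg <- sch[sch$scored & sch$role == "target", ]
    n <- nrow(tg)
    miss <- rbinom(n, 1, stats::plogis(eta_miss)) == 1
    rt <- rep(NA_real_, n)
    rt[!miss] <- rinvgauss(sum(!miss), 1 / eta_rt, profile$rt_shape)
    tibble(
      participant = participant, block = block, variant = variant,
      trial = tg$trial, role = "target", miss = miss, rt_s = rt
    )
  }) %>% bind_rows()
}
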