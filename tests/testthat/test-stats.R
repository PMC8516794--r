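test_that("Wald chi-square follows its closed form", {
  w <- wald_chisq(2, 1)
  expect_equal(w$chisq, 4)
  expect_equal(w$df, 1)
  expect_equal(w$p.value, 0.0455, tolerance = 1e-3)
  expect_equal(wald_chisq(0, 1)$p.value, 1)

  # agreement with the squared z test for arbitrary (beta, se)
  set.seed(16)
  for (i in 1:20) {
    b <- rnorm(1); s <- rexp(1) + 0.1
    expect_equal(wald_chisq(b, s)$p.value,
                 2 * pnorm(abs(b / s), lower.tail = FALSE), tolerance = 1e-12)
  }
})

test_that("response-scale summaries invert the link functions", {
  sch <- list(a = generate_schedule("rapid", seed = 1),
              b = generate_schedule("sporadic", seed = 2))
  set.seed(17)
  beh <- dplyr::bind_rows(lapply(1:6, function(p)
    simulate_behavior(participant_profile(), sch, participant = p)))
  fit <- fit_glmm(dplyr::filter(beh, !miss), "rt_s", "variant",
                  family = "inverse_gaussian")
  eta <- fit$response_scale$eta_link
  expect_equal(fit$response_scale$mean_response, 1 / eta)
  expect_equal(eta[1], fit$beta_link[["intercept"]])
  expect_equal(eta[2], sum(fit$beta_link))

  beh$miss_num <- as.numeric(beh$miss)
  fitm <- fit_glmm(beh, "miss_num", "variant", family = "binomial")
  expect_equal(fitm$response_scale$mean_response,
               stats::plogis(fitm$response_scale$eta_link))

  expect_error(wald_chisq(fit, "nonexistent"), "no coefficient")
  expect_error(fit_glmm(dplyr::filter(beh, participant == 1, !miss),
                        "rt_s", "variant"), "2 participants")
})

test_that("model comparison ranks the true family first and flags nesting", {
  set.seed(18)
  sch <- list(a = generate_schedule("rapid", seed = 3),
              b = generate_schedule("sporadic", seed = 4))
  wins <- replicate(5, {
    beh <- dplyr::bind_rows(lapply(1:6, function(p)
      simulate_behavior(participant_profile(), sch, participant = p)))
    d <- dplyr::filter(beh, !miss)
    fits <- list(
      invgauss = fit_glmm(d, "rt_s", "variant", family = "inverse_gaussian"),
      gauss = fit_glmm(d, "rt_s", "variant", family = "gaussian")
    )
    cmp <- compare_models(fits)
    cmp$model[1] == "invgauss"
  })
  expect_gte(sum(wins), 4)

  # identical models tie at zero likelihood difference
  beh <- dplyr::bind_rows(lapply(1:6, function(p)
    simulate_behavior(participant_profile(), sch, participant = p)))
  d <- dplyr::filter(beh, !miss)
  f1 <- fit_glmm(d, "rt_s", "variant", family = "inverse_gaussian")
  f2 <- fit_glmm(d, "rt_s", "variant", family = "inverse_gaussian")
  cmp <- compare_models(list(a = f1, b = f2))
  expect_equal(cmp$logLik[1], cmp$logLik[2], tolerance = 1e-6)
  expect_false(isTRUE(cmp$nested[1] && cmp$lr_df[1] > 0))

  # differing data are refused
  d2 <- d[-(1:5), ]
  f3 <- fit_glmm(d2, "rt_s", "variant", family = "inverse_gaussian")
  expect_error(compare_models(list(a = f1, b = f3)), "differing data")

  # non-nested pair (different family) carries no LR test
  fits2 <- compare_models(list(ig = f1, g = fit_glmm(d, "rt_s", "variant",
                                                     family = "gaussian")))
  expect_true(is.na(fits2$lr_p[1]) || !fits2$nested[1])
})

test_that("repeated-measures ANOVA matches pencil-and-paper sums of squares", {
  # 3 participants x 2 blocks, worked by hand:
  # values p1: 1, 3; p2: 2, 4; p3: 3, 8
  # grand = 3.5; subject means 2, 3, 5.5; block means 2, 5
  # SS_subj = 2*((2-3.5)^2+(3-3.5)^2+(5.5-3.5)^2) = 2*6.5 = 13
  # SS_block = 3*((2-3.5)^2+(5-3.5)^2) = 13.5
  # SS_total = 6.25+0.25+2.25+0.25+0.25+20.25 = 29.5 => SS_err = 3
  # F = 13.5 / (3/2) = 9, ges = 13.5/29.5
  d <- tibble::tibble(participant = rep(1:3, each = 2),
                      block = rep(1:2, 3),
                      value = c(1, 3, 2, 4, 3, 8))
  a <- rm_anova(d)
  expect_equal(a$F, 9)
  expect_equal(a$df, c(1, 2))
  expect_equal(a$ges, 13.5 / 29.5)
  expect_equal(unname(a$ss), c(13.5, 13, 3))

  # identical values: zero effect
  d0 <- dplyr::mutate(d, value = 5)
  a0 <- rm_anova(d0)
  expect_true(is.nan(a0$F))
  expect_equal(a0$ges, 0)

  expect_error(rm_anova(d[-1, ]), "incomplete")
})

test_that("post hoc t tests separate planted rapid and sporadic block means", {
  set.seed(19)
  d <- tidyr::expand_grid(participant = 1:8, block = 1:5) %>%
    dplyr::mutate(value = ifelse(block %in% c(2, 4), 6, 2) +
                    rnorm(dplyr::n(), 0, 0.3))
  a <- rm_anova(d)
  ph <- a$posthoc
  is_pair <- function(x, y, b1, b2) (x == b1 & y == b2) | (x == b2 & y == b1)
  cross <- ph$block_a %in% c("1", "3", "5") != ph$block_b %in% c("1", "3", "5")
  expect_true(all(ph$p_adj[cross] < 0.001))
  rapid_pairs <- !cross & ph$block_a %in% c("1", "3", "5")
  expect_true(all(ph$p_adj[rapid_pairs] > 0.05))

  # Bonferroni adjustment is monotone and never below the raw p
  expect_true(all(ph$p_adj >= ph$p_raw))
  expect_equal(ph$p_adj, pmin(1, ph$p_raw * nrow(ph)))
})
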