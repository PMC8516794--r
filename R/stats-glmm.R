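#' Fit a condition-contrast mixed model
#'
#' Fits the two-level mixed models used throughout the analysis: a fixed
#' two-level factor (oddball variant for behaviour, stimulus role for ERP
#' amplitudes), a random intercept per participant and a by-participant
#' random slope for the factor. The slope and intercept are independent by
#' default (the correlated structure is available but can be
#' non-identifiable at n = 8). Gaussian/identity models use `lme4::lmer`
#' (maximum likelihood); all other family/link pairs use `lme4::glmer` with
#' the Laplace approximation.
#'
#' @param data Long tibble; must contain `participant`, the `fixed` column
#'   (two-level factor or character) and the `response` column.
#' @param response Name of the response column (e.g. `"rt_s"`, `"miss"`,
#'   `"amplitude_uv"`).
#' @param fixed Name of the two-level fixed-factor column (e.g. `"variant"`,
#'   `"role"`); the first level in sort order is the reference.
#' @param family `"inverse_gaussian"`, `"gamma"`, `"gaussian"` or
#'   `"binomial"`.
#' @param link Link function; defaults to the family's canonical analysis
#'   choice (`inverse` for inverse-Gaussian, `logit` for binomial,
#'   `identity` for Gaussian, `inverse` for gamma).
#' @param random `"independent"` or `"correlated"` intercept/slope structure.
#' @return An object of class `oddball_fit` with link-scale coefficients and
#'   SEs, log-likelihood, variance components, response-scale condition
#'   means, convergence/singularity flags, and the underlying lme4 fit.
#' @export
#' @examples
#' sch <- list(b1 = generate_schedule("rapid", seed = 1),
#'             b2 = generate_schedule("sporadic", seed = 2))
#' beh <- purrr::map_dfr(1:4, function(p)
#'   simulate_behavior(participant_profile(), sch, participant = p, seed = p))
#' fit <- fit_glmm(dplyr::filter(beh, !miss), "rt_s", "variant",
#'                 family = "inverse_gaussian")
#' tidy(fit)
fit_glmm <- function(data, response, fixed = "variant",
                     family = c("inverse_gaussian", "gamma", "gaussian",
                                "binomial"),
                     link = NULL,
                     random = c("independent", "correlated")) {
  family <- match.arg(family)
  random <- match.arg(random)
  if (is.null(link)) {
    link <- switch(family, inverse_gaussian = "inverse", gamma = "inverse",
                   gaussian = "identity", binomial = "logit")
  }
  stopifnot(all(c("participant", fixed, response) %in% names(data)))
  lv <- sort(unique(as.character(data[[fixed]])))
  if (length(lv) != 2) abort("the fixed factor must have exactly two levels.")
  if (length(unique(data$participant)) < 2) {
    abort("need at least 2 participants.")
  }
  d <- tibble(
    participant = factor(data$participant),
    x = as.numeric(as.character(data[[fixed]]) == lv[2]),
    y = data[[response]]
  )
  d <- d[!is.na(d$y), ]

  fam <- switch(family,
    inverse_gaussian = stats::inverse.gaussian(link = link),
    gamma = stats::Gamma(link = link),
    binomial = stats::binomial(link = link),
    gaussian = stats::gaussian(link = link)
  )
  re <- if (random == "independent") "(1 | participant) + (0 + x | participant)"
        else "(1 + x | participant)"
  form <- stats::as.formula(paste("y ~ x +", re))

  gaussian_identity <- family == "gaussian" && link == "identity"
  fit <- withCallingHandlers(
    if (gaussian_identity) {
      lme4::lmer(form, data = d, REML = FALSE)
    } else {
      lme4::glmer(form, data = d, family = fam)
    },
    warning = function(w) invokeRestart("muffleWarning")
  )

  sm <- withCallingHandlers(summary(fit),
                            warning = function(w) invokeRestart("muffleWarning"))
  beta <- lme4::fixef(fit)
  se <- sm$coefficients[, "Std. Error"]
  names(beta) <- names(se) <- c("intercept", lv[2])
  linkinv <- fam$linkinv
  eta <- c(beta[1], beta[1] + beta[2])
  resp_means <- tibble(level = lv, eta_link = unname(eta),
                       mean_response = unname(linkinv(eta)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  singular <- lme4::isSingular(fit)

  structure(
    list(fit = fit, response = response, fixed = fixed, levels = lv,
         family = family, link = link, random = random,
         beta_link = beta, se_link = se,
         loglik = as.numeric(logLik(fit)), n_par = attr(logLik(fit), "df"),
         vc = as_tibble(vc), response_scale = resp_means,
         converged = conv, singular = singular,
         data_fingerprint = c(nrow(d), sum(d$y), sum(d$x))),
    class = "oddball_fit"
  )
}

#' @export
print.oddball_fit <- function(x, ...) {
  cat(sprintf("<oddball_fit> %s(%s), %s random effects; logLik %.2f%s%s\n",
              x$family, x$link, x$random, x$loglik,
              if (!x$converged) " [non-convergence flagged]" else "",
              if (x$singular) " [singular fit]" else ""))
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_glmm
#' @param x An `oddball_fit`.
#' @param ... Unused.
#' @export
tidy.oddball_fit <- function(x, ...) {
  w <- purrr::map(names(x$beta_link), ~ wald_chisq(x, .x))
  tibble(
    term = names(x$beta_link),
    estimate_link = unname(x$beta_link),
    se_link = unname(x$se_link),
    chisq = purrr::map_dbl(w, "chisq"),
    df = purrr::map_dbl(w, "df"),
    p.value = purrr::map_dbl(w, "p.value")
  )
}

#' @rdname fit_glmm
#' @export
glance.oddball_fit <- function(x, ...) {
  tibble(family = x$family, link = x$link, random = x$random,
         logLik = x$loglik, df = x$n_par,
         AIC = 2 * x$n_par - 2 * x$loglik,
         converged = x$converged, singular = x$singular)
}

#' Wald chi-square test of a single coefficient
#'
#' `chisq = (beta / SE)^2` on 1 degree of freedom, the square of the Wald z
#' test.
#'
#' @param fit An `oddball_fit`, or a numeric coefficient estimate.
#' @param coefficient Coefficient name (for a fit), or the coefficient's SE
#'   (when `fit` is numeric).
#' @return List with `chisq`, `df`, `p.value`.
#' @export
#' @examples
#' wald_chisq(2, 1)  # chisq 4, p ~ 0.0455
wald_chisq <- function(fit, coefficient) {
  if (is.numeric(fit)) {
    beta <- fit; se <- coefficient
  } else {
    if (!coefficient %in% names(fit$beta_link)) {
      abort(sprintf("no coefficient named '%s' in the fit.", coefficient))
    }
    beta <- fit$beta_link[[coefficient]]
    se <- fit$se_link[[coefficient]]
  }
  chisq <- (beta / se)^2
  list(chisq = chisq, df = 1, p.value = pchisq(chisq, 1, lower.tail = FALSE))
}

#' Rank candidate models and run likelihood-ratio tests
#'
#' Orders fits on the same data by log-likelihood. For nested pairs (same
#' family and link, one fixed/random structure contained in the other) the
#' likelihood-ratio statistic `2 * delta logLik` is referred to a chi-square
#' on the parameter-count difference; non-nested pairs (different families or
#' links) are reported by log-likelihood only and flagged.
#'
#' @param fits Named list of `oddball_fit`s on identical data.
#' @return Tibble ranked by log-likelihood with LR tests against the
#'   next-ranked model.
#' @export
compare_models <- function(fits) {
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  fp <- purrr::map(fits, "data_fingerprint")
  if (length(unique(purrr::map_chr(fp, paste, collapse = ","))) != 1) {
    abort("models were fit on differing data.")
  }
  tab <- purrr::imap(fits, function(f, nm) {
    glance(f) %>% mutate(model = nm, .before = 1)
  }) %>%
    bind_rows() %>%
    arrange(dplyr::desc(.data$logLik))

  nested <- function(a, b) a$family == b$family && a$link == b$link
  lr <- purrr::map(seq_len(nrow(tab)), function(i) {
    if (i == nrow(tab)) return(tibble(lr_stat = NA_real_, lr_df = NA_real_,
                                      lr_p = NA_real_, nested = NA))
    a <- fits[[tab$model[i]]]; b <- fits[[tab$model[i + 1]]]
    if (!nested(a, b) || a$n_par == b$n_par) {
      return(tibble(lr_stat = NA_real_, lr_df = NA_real_, lr_p = NA_real_,
                    nested = FALSE))
    }
    stat <- 2 * abs(a$loglik - b$loglik)
    df <- abs(a$n_par - b$n_par)
    tibble(lr_stat = stat, lr_df = df,
           lr_p = pchisq(stat, df, lower.tail = FALSE), nested = TRUE)
  }) %>% bind_rows()
  dplyr::bind_cols(tab, lr)
}
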