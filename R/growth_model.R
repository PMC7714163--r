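## Gompertz-with-deceleration nonlinear mixed-effects growth model.
##
## Head circumference Y_ij of subject i at post-menstrual age t_ij (weeks):
##
##   Y_ij = (L_p + L_i) * exp(-(a_p + a_i) * exp(-b_p * t * (1 - th_p * (1 - exp(-(l_p + l_i) * t))))) + e_ij
##
## Five population fixed effects (growth limit L_p, log-ratio a_p, growth
## rate b_p, deceleration rate th_p, deceleration nonlinearity l_p); diagonal
## random effects on L, a and l only; iid Gaussian residuals. The per-subject
## sums L_p+L_i, a_p+a_i, l_p+l_i are the growth phenotypes linf, alpha and
## lambda used by the dependency scans.

#' Growth-curve model function with analytic gradient
#'
#' Evaluates the five-parameter deceleration-Gompertz curve and its gradient
#' with respect to the parameters (generated with [stats::deriv()] at install
#' time). Exported so that \pkg{nlme} can resolve it when fitting; use
#' [predict_growth()] for ordinary prediction.
#'
#' @param t time (weeks); `linf,alpha,beta,theta,lambda` curve parameters.
#' @name growth_curve_deriv
#' @export
growth_curve_deriv <- stats::deriv(
  ~ linf * exp(-alpha * exp(-beta * t * (1 - theta * (1 - exp(-lambda * t))))),
  c("linf", "alpha", "beta", "theta", "lambda"),
  function.arg = c("t", "linf", "alpha", "beta", "theta", "lambda")
)

#' Population parameters of the growth model
#'
#' Defaults are point estimates from a large multi-cohort reference fit of
#' head-circumference growth (N = 11,818 subjects, 2-18 measurements each at
#' 8-290 weeks post-menstrual age); they serve as simulation ground truth.
#'
#' @param linf population growth limit L_p (cm).
#' @param alpha log-ratio parameter (dimensionless); Y(0) = linf * exp(-alpha).
#' @param beta growth rate (1/week).
#' @param theta deceleration rate (dimensionless, < 1).
#' @param lambda deceleration nonlinearity (1/week).
#' @param var_linf,var_alpha,var_lambda random-effect variances (diagonal).
#' @param var_resid residual variance.
#' @export
growth_population_params <- function(linf = 49.96582, alpha = 5.62027,
                                     beta = 0.10450, theta = 0.75950,
                                     lambda = 0.01667,
                                     var_linf = 1.305845,
                                     var_alpha = 0.1648373,
                                     var_lambda = 0.0005637008,
                                     var_resid = 0.7218403) {
  if (linf <= 0) stop_field("linf", "growth limit must be positive")
  vars <- c(var_linf = var_linf, var_alpha = var_alpha,
            var_lambda = var_lambda, var_resid = var_resid)
  bad <- names(vars)[vars < 0]
  if (length(bad)) stop_field(bad[1], "variance must be non-negative")
  structure(list(linf = linf, alpha = alpha, beta = beta, theta = theta,
                 lambda = lambda, var_linf = var_linf, var_alpha = var_alpha,
                 var_lambda = var_lambda, var_resid = var_resid),
            class = "growth_population_params")
}

#' @export
print.growth_population_params <- function(x, ...) {
  cat("<growth_population_params>\n")
  cat(sprintf("  fixed : linf %.4f  alpha %.4f  beta %.5f  theta %.5f  lambda %.6f\n",
              x$linf, x$alpha, x$beta, x$theta, x$lambda))
  cat(sprintf("  var   : linf %.4g  alpha %.4g  lambda %.4g  resid %.4g\n",
              x$var_linf, x$var_alpha, x$var_lambda, x$var_resid))
  invisible(x)
}

#' Predict head circumference from the growth model
#'
#' @param t post-menstrual age in weeks (vectorized), t >= 0.
#' @param params a [growth_population_params].
#' @param effects subject deviations, named or positional
#'   `c(linf, alpha, lambda)`.
#' @return predicted head circumference (cm). At t = 0 the curve equals
#'   `(linf + L_i) * exp(-(alpha + a_i))`; as t grows (theta < 1) it
#'   approaches `linf + L_i`.
#' @export
predict_growth <- function(t, params, effects = c(0, 0, 0)) {
  stopifnot(inherits(params, "growth_population_params"), all(t >= 0))
  ef <- rep_len(as.numeric(effects), 3)
  as.numeric(growth_curve_deriv(
    t, params$linf + ef[1], params$alpha + ef[2], params$beta,
    params$theta, params$lambda + ef[3]
  ))
}

#' Simulate longitudinal growth observations
#'
#' Subjects draw diagonal-Gaussian deviations in (linf, alpha, lambda), follow
#' their own growth curve, and are observed with iid Gaussian residual noise
#' at a realistic visit schedule: antenatal ultrasounds plus postnatal visits
#' (18 candidate visits between 8 and 290 weeks post-menstrual age), each
#' attended independently, keeping between 2 and 18 observations per subject.
#'
#' @param params a [growth_population_params] (ground truth).
#' @param n_subjects number of subjects.
#' @param obs_times_per_subject optional list/vector of fixed observation
#'   times used for every subject (overrides the visit schedule).
#' @param attendance probability a scheduled visit is attended.
#' @param time_jitter SD (weeks) of visit-time jitter.
#' @param seed RNG seed.
#' @return data.frame of class `growth_observations` with columns
#'   `subject_id`, `time_weeks`, `hc_cm`; true per-subject deviations are in
#'   attribute `"true_effects"`.
#' @export
simulate_growth_trajectories <- function(params, n_subjects,
                                         obs_times_per_subject = NULL,
                                         attendance = 0.6, time_jitter = 1,
                                         seed = 1L) {
  stopifnot(inherits(params, "growth_population_params"), is_count(n_subjects))
  schedule <- c(12, 20, 27, 33, 40, 43, 52, 65, 78, 91, 104, 117, 130, 143,
                156, 196, 235, 275)
  with_seed(seed, {
    eff <- cbind(
      linf = stats::rnorm(n_subjects, 0, sqrt(params$var_linf)),
      alpha = stats::rnorm(n_subjects, 0, sqrt(params$var_alpha)),
      lambda = stats::rnorm(n_subjects, 0, sqrt(params$var_lambda))
    )
    rows <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      if (is.null(obs_times_per_subject)) {
        take <- which(stats::runif(length(schedule)) < attendance)
        while (length(take) < 2L) take <- which(stats::runif(length(schedule)) < attendance)
        t_i <- schedule[take] + stats::rnorm(length(take), 0, time_jitter)
        t_i <- pmin(pmax(t_i, 8), 290)
      } else {
        t_i <- as.numeric(obs_times_per_subject)
      }
      mu <- predict_growth(t_i, params, eff[i, ])
      y <- mu + stats::rnorm(length(t_i), 0, sqrt(params$var_resid))
      rows[[i]] <- data.frame(subject_id = sprintf("S%04d", i),
                              time_weeks = t_i, hc_cm = y)
    }
    obs <- do.call(rbind, rows)
    rownames(obs) <- NULL
    attr(obs, "true_effects") <- data.frame(subject_id = sprintf("S%04d", seq_len(n_subjects)), eff)
    class(obs) <- c("growth_observations", "data.frame")
    obs
  })
}

## Data-driven starting values: population-curve nonlinear least squares over
## a coarse grid of shape parameters, refined with nls.
init_growth_params <- function(obs) {
  t <- obs$time_weeks; y <- obs$hc_cm
  linf0 <- max(y)
  grid <- expand.grid(alpha = c(3, 5, 7), beta = c(0.05, 0.1, 0.2),
                      theta = c(0.5, 0.75, 0.9), lambda = c(0.005, 0.017, 0.05))
  sse <- apply(grid, 1, function(g) {
    mu <- linf0 * exp(-g[["alpha"]] * exp(-g[["beta"]] * t *
      (1 - g[["theta"]] * (1 - exp(-g[["lambda"]] * t)))))
    sum((y - mu)^2)
  })
  best <- grid[which.min(sse), ]
  start <- c(linf = linf0, alpha = best$alpha, beta = best$beta,
             theta = best$theta, lambda = best$lambda)
  fit <- tryCatch(
    stats::nls(
      hc_cm ~ growth_curve_deriv(time_weeks, linf, alpha, beta, theta, lambda),
      data = obs, start = as.list(start),
      control = stats::nls.control(maxiter = 200, warnOnly = TRUE)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit)) start <- stats::coef(fit)
  start
}

#' Fit the population growth model
#'
#' Maximum-likelihood nonlinear mixed-effects fit (Lindstrom-Bates
#' alternating algorithm as implemented in \pkg{nlme}) of the five fixed
#' effects, the three diagonal random-effect variances and the residual
#' variance. Starting values are estimated from the data unless supplied.
#'
#' @param obs a `growth_observations` data.frame (`subject_id`, `time_weeks`,
#'   `hc_cm`), each subject contributing at least 2 observations.
#' @param init optional [growth_population_params] or named numeric vector of
#'   fixed-effect starting values.
#' @param control passed to [nlme::nlmeControl()].
#' @return an object of class `growth_model_fit`: list with `params` (a
#'   [growth_population_params] holding the estimates), `fixed_se`, `logLik`,
#'   `n_subjects`, `n_obs`, and the underlying `nlme` fit in `$fit`.
#' @export
fit_growth_population <- function(obs, init = NULL, control = list()) {
  stopifnot(all(c("subject_id", "time_weeks", "hc_cm") %in% names(obs)))
  counts <- table(obs$subject_id)
  if (any(counts < 2)) {
    stop(sprintf("%d subject(s) have fewer than 2 observations", sum(counts < 2)),
         call. = FALSE)
  }
  start <- if (inherits(init, "growth_population_params")) {
    c(linf = init$linf, alpha = init$alpha, beta = init$beta,
      theta = init$theta, lambda = init$lambda)
  } else if (is.numeric(init)) {
    init[c("linf", "alpha", "beta", "theta", "lambda")]
  } else {
    init_growth_params(obs)
  }
  ctl <- do.call(nlme::nlmeControl,
                 utils::modifyList(list(maxIter = 200, msMaxIter = 200,
                                        pnlsMaxIter = 15, returnObject = TRUE),
                                   control))
  dat <- data.frame(subject_id = obs$subject_id, time_weeks = obs$time_weeks,
                    hc_cm = obs$hc_cm)
  fit <- tryCatch(
    nlme::nlme(
      hc_cm ~ growth_curve_deriv(time_weeks, linf, alpha, beta, theta, lambda),
      data = dat,
      fixed = linf + alpha + beta + theta + lambda ~ 1,
      random = nlme::pdDiag(linf + alpha + lambda ~ 1),
      groups = ~subject_id,
      start = start, method = "ML", control = ctl
    ),
    error = function(e) {
      stop(sprintf("growth model failed to converge: %s", conditionMessage(e)),
           call. = FALSE)
    }
  )
  fe <- nlme::fixef(fit)
  vc <- nlme::VarCorr(fit)
  ## VarCorr rows follow the pdDiag order (linf, alpha, lambda) + Residual
  vars <- suppressWarnings(as.numeric(vc[, "Variance"]))
  names(vars) <- rownames(vc)
  params <- growth_population_params(
    linf = fe[["linf"]], alpha = fe[["alpha"]], beta = fe[["beta"]],
    theta = fe[["theta"]], lambda = fe[["lambda"]],
    var_linf = vars[["linf"]], var_alpha = vars[["alpha"]],
    var_lambda = vars[["lambda"]], var_resid = vars[["Residual"]]
  )
  se <- sqrt(diag(fit$varFix))
  structure(
    list(params = params, fixed_se = se, logLik = as.numeric(stats::logLik(fit)),
         n_subjects = length(counts), n_obs = nrow(obs), fit = fit),
    class = "growth_model_fit"
  )
}

#' @export
print.growth_model_fit <- function(x, ...) {
  cat(sprintf("<growth_model_fit> %d subjects, %d observations, logLik %.1f\n",
              x$n_subjects, x$n_obs, x$logLik))
  print(x$params)
  invisible(x)
}

#' Per-subject growth phenotypes by penalized nonlinear least squares
#'
#' Conditional-mode estimates of the subject deviations (L_i, a_i, l_i) given
#' fixed population parameters: for each subject, minimizes the residual sum
#' of squares over its own observations plus the Gaussian random-effect
#' penalty `b' D^-1 b` implied by the population variance components. The
#' reported phenotypes are population value + subject deviation. Subjects with
#' fewer than 2 usable observations are flagged and get zero deviations.
#'
#' @param obs a `growth_observations` data.frame.
#' @param pop a [growth_population_params] (e.g. from
#'   [fit_growth_population()]`$params`).
#' @return data.frame of class `subject_growth_phenotypes` with columns
#'   `subject_id`, `linf`, `alpha`, `lambda`, `n_obs`, `flagged`.
#' @export
subject_effects <- function(obs, pop) {
  stopifnot(inherits(pop, "growth_population_params"))
  ids <- unique(obs$subject_id)
  vars <- c(pop$var_linf, pop$var_alpha, pop$var_lambda)
  free <- vars > 0
  sigma2 <- max(pop$var_resid, 1e-8)
  out <- data.frame(subject_id = ids, linf = pop$linf, alpha = pop$alpha,
                    lambda = pop$lambda, n_obs = 0L, flagged = FALSE,
                    stringsAsFactors = FALSE)
  flagged_any <- FALSE
  for (k in seq_along(ids)) {
    sel <- obs$subject_id == ids[k]
    t_i <- obs$time_weeks[sel]; y_i <- obs$hc_cm[sel]
    out$n_obs[k] <- length(t_i)
    if (length(t_i) < 2L) {
      out$flagged[k] <- TRUE
      flagged_any <- TRUE
      next
    }
    objective <- function(b) {
      ef <- numeric(3); ef[free] <- b
      mu <- predict_growth(t_i, pop, ef)
      sum((y_i - mu)^2) / sigma2 + sum(ef[free]^2 / vars[free])
    }
    if (any(free)) {
      opt <- stats::optim(rep(0, sum(free)), objective, method = "BFGS",
                          control = list(maxit = 200))
      ef <- numeric(3); ef[free] <- opt$par
    } else {
      ef <- numeric(3)
    }
    out$linf[k] <- pop$linf + ef[1]
    out$alpha[k] <- pop$alpha + ef[2]
    out$lambda[k] <- pop$lambda + ef[3]
  }
  if (flagged_any) {
    warning(sprintf("%d subject(s) with < 2 observations: deviations set to 0",
                    sum(out$flagged)), call. = FALSE)
  }
  class(out) <- c("subject_growth_phenotypes", "data.frame")
  out
}
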