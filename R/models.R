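# Mixed-effects response models and the flee/stay group comparison.
#
# The inferential surface is point estimates with 95% and 75%
# intervals; the backend is a frequentist mixed-model fit (REML for
# the Gaussian model, Laplace for the Bernoulli model) with Wald
# intervals, recorded in the result so downstream consumers know what
# produced the numbers.

wald_intervals <- function(est, se) {
  data.frame(l95 = est + stats::qnorm(0.025) * se,
             u95 = est + stats::qnorm(0.975) * se,
             l75 = est + stats::qnorm(0.125) * se,
             u75 = est + stats::qnorm(0.875) * se)
}

check_design <- function(df, covars) {
  for (v in covars) {
    if (!v %in% names(df)) stop("missing covariate column '", v, "'")
    x <- df[[v]]
    if (anyNA(x)) stop("degenerate-design error: NA values in '", v, "'")
    if (stats::sd(x) == 0)
      stop("degenerate-design error: covariate '", v, "' is constant")
  }
}

fit_result <- function(coefs, sigma_u, sigma_resid, n_events, n_individuals,
                       backend, converged, separation = FALSE) {
  structure(list(coefficients = coefs, sigma_u = sigma_u,
                 sigma_resid = sigma_resid, n_events = n_events,
                 n_individuals = n_individuals, backend = backend,
                 converged = converged, separation = separation),
            class = "hm_fit")
}

#' @exportS3Method base::print
print.hm_fit <- function(x, ...) {
  cat(sprintf("<hm_fit> backend %s, %d events, %d individuals\n",
              x$backend, x$n_events, x$n_individuals))
  print(transform(x$coefficients,
                  estimate = signif(estimate, 4), l95 = signif(l95, 4),
                  u95 = signif(u95, 4)))
  cat(sprintf("sigma_u = %.4g, residual = %.4g, converged = %s%s\n",
              x$sigma_u, x$sigma_resid, x$converged,
              if (isTRUE(x$separation)) ", SEPARATION FLAGGED" else ""))
  invisible(x)
}

#' Linear mixed model of the log distance response
#'
#' Fits `log(Dist) ~ Bush + Fam + Dogs + Beat + Shot` with a
#' per-individual random intercept, for either the immediate
#' (`dist_immediate`) or delayed (`dist_delayed`) cumulative distance.
#' Covariates enter on their natural scales (proportion, index,
#' per-hectare densities, count) unless `standardize = TRUE`.
#'
#' With a single individual the model degrades gracefully to a
#' fixed-intercept linear regression (`sigma_u` pinned at 0, with a
#' warning).
#'
#' @param events classified event table with `fam` filled.
#' @param response `"immediate"` or `"delayed"`.
#' @param standardize centre and scale the covariates before fitting?
#' @return an `hm_fit`: coefficient table (`term`, `estimate`, `se`,
#'   `l95`, `u95`, `l75`, `u75`), random-intercept sd `sigma_u`,
#'   residual sd, sizes, backend and convergence flag.
#' @export
fit_distance_model <- function(events,
                               response = c("immediate", "delayed"),
                               standardize = FALSE) {
  response <- match.arg(response)
  ycol <- paste0("dist_", response)
  covars <- c("bush", "fam", "dogs_per_ha", "beaters_per_ha", "gunshots")
  df <- events[!is.na(events$classification) & !is.na(events[[ycol]]), ,
               drop = FALSE]
  if (nrow(df) < 10L) stop("at least 10 classified events are required")
  if (any(df[[ycol]] <= 0)) stop("distances must be positive for the log link")
  check_design(df, covars)
  df$.y <- log(df[[ycol]])
  if (standardize) for (v in covars) df[[v]] <- as.numeric(scale(df[[v]]))
  n_ind <- length(unique(df$individual_id))
  fml <- stats::reformulate(c(covars, "(1 | individual_id)"),
                            response = ".y")
  if (n_ind < 2L) {
    warning("single individual: fitting a fixed-intercept regression, ",
            "sigma_u pinned at 0")
    fit <- stats::lm(stats::reformulate(covars, response = ".y"), data = df)
    sm <- summary(fit)
    est <- stats::coef(fit); se <- sm$coefficients[, 2L]
    coefs <- cbind(data.frame(term = names(est), estimate = unname(est),
                              se = unname(se)),
                   wald_intervals(unname(est), unname(se)))
    return(fit_result(coefs, 0, sm$sigma, nrow(df), n_ind, "lm", TRUE))
  }
  fit <- lme4::lmer(fml, data = df, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular =
                                                  "ignore"))
  sm <- summary(fit)
  est <- lme4::fixef(fit)
  se <- sm$coefficients[, "Std. Error"]
  vc <- as.data.frame(lme4::VarCorr(fit))
  coefs <- cbind(data.frame(term = names(est), estimate = unname(est),
                            se = unname(se)),
                 wald_intervals(unname(est), unname(se)))
  rownames(coefs) <- NULL
  conv <- length(fit@optinfo$conv$lme4$messages) == 0L
  fit_result(coefs,
             sigma_u = vc$sdcor[vc$grp == "individual_id"],
             sigma_resid = vc$sdcor[vc$grp == "Residual"],
             n_events = nrow(df), n_individuals = n_ind,
             backend = "lme4::lmer (REML, Wald intervals)",
             converged = conv)
}

#' Logistic mixed model of the short-return probability
#'
#' Fits `short_return ~ Hunt + Fam + Hunt:Fam` with a per-individual
#' random intercept, where `Hunt` is 1 for post-hunt records and 0
#' for controls and the response is the 72-h dichotomy (0 = returned
#' sooner, 1 = returned later; see [short_return_indicator()]).
#' Records with an unresolved indicator are dropped. Complete
#' separation is reported via the `separation` flag (interval
#' blow-up) rather than silently returning huge coefficients; a
#' response with no variation is a degenerate design and errors.
#'
#' @param records `ReturnRecord` table with `individual_id` and `fam`
#'   columns.
#' @return an `hm_fit` (coefficients `(Intercept)`, `hunt`, `fam`,
#'   `hunt:fam` on the log-odds scale).
#' @export
fit_return_model <- function(records) {
  df <- records[!is.na(records$short_return) & !is.na(records$fam), ,
                drop = FALSE]
  if (!nrow(df)) stop("no records with a resolved short-return indicator")
  if (length(unique(df$condition)) < 2L)
    stop("both post-hunt and control records are required")
  df$hunt <- as.integer(df$condition == "post_hunt")
  if (length(unique(df$short_return)) < 2L)
    stop("separation error: all responses identical")
  n_ind <- length(unique(df$individual_id))
  fit <- suppressMessages(lme4::glmer(
    short_return ~ hunt * fam + (1 | individual_id),
    data = df, family = stats::binomial(),
    control = lme4::glmerControl(check.conv.singular = "ignore")))
  sm <- summary(fit)
  est <- lme4::fixef(fit)
  se <- sm$coefficients[, "Std. Error"]
  names(est) <- sub("hunt:fam", "hunt:fam", names(est))
  coefs <- cbind(data.frame(term = names(est), estimate = unname(est),
                            se = unname(se)),
                 wald_intervals(unname(est), unname(se)))
  rownames(coefs) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0L
  separation <- any(abs(est) > 15) || any(se > 50)
  if (separation)
    warning("possible complete separation: interval blow-up flagged")
  fit_result(coefs, sigma_u = vc$sdcor[1L], sigma_resid = NA_real_,
             n_events = nrow(df), n_individuals = n_ind,
             backend = "lme4::glmer (Laplace, Wald intervals)",
             converged = conv, separation = separation)
}

#' Two-sample comparison of distances between flee and stay groups
#'
#' Pooled-variance two-sample t statistic on the total cumulative
#' distances of fleeing vs staying events (df = n1 + n2 - 2).
#'
#' @param events classified event table.
#' @param response `"immediate"` or `"delayed"`.
#' @return list with `statistic` (t, staying minus fleeing in the
#'   standard two-level ordering), `df`, `p_value`, group sizes and
#'   medians.
#' @export
compare_group_distances <- function(events,
                                    response = c("immediate", "delayed")) {
  response <- match.arg(response)
  ycol <- paste0("dist_", response)
  df <- events[!is.na(events$classification) & !is.na(events[[ycol]]), ,
               drop = FALSE]
  yf <- df[[ycol]][df$classification == "fleeing"]
  ys <- df[[ycol]][df$classification == "staying"]
  if (length(yf) < 2L || length(ys) < 2L)
    stop("both groups need at least 2 events for a comparison")
  tt <- stats::t.test(ys, yf, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       n_fleeing = length(yf), n_staying = length(ys),
       median_fleeing = stats::median(yf), median_staying = stats::median(ys))
}
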