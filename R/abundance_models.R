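# Maximum-likelihood fitting of discrete abundance models to degree data,
# AIC model selection, and between-group distribution comparison.
#
# Observations are node degrees (one observation per node, support
# x = 1, 2, ...). Candidate models:
#   zeta_powerlaw  P(x) = x^(-alpha) / zeta(alpha),        alpha > 1
#   logseries      P(x) = -p^x / (x * log(1 - p)),         p in (0, 1)
#   geometric      P(x) = (1 - p)^(x - 1) * p,             p in (0, 1)
# All three have one free parameter, so AIC = 2 - 2 * loglik.

.abundance_models <- c("zeta_powerlaw", "logseries", "geometric")

#' Log probability mass of the candidate abundance models
#'
#' @param x Integer vector of degrees (all >= 1).
#' @param model Model name.
#' @param par Parameter value (`alpha` for `zeta_powerlaw`, `p` otherwise).
#' @return Numeric vector of log-probabilities.
#' @keywords internal
.log_pmf <- function(x, model, par) {
  switch(model,
    zeta_powerlaw = -par * log(x) - log(pracma::zeta(par)),
    logseries = x * log(par) - log(x) - log(-log(1 - par)),
    geometric = (x - 1) * log1p(-par) + log(par),
    abort(sprintf("unknown model '%s'", model))
  )
}

.check_degrees <- function(degrees) {
  if (length(degrees) < 10) abort("need at least 10 degree observations")
  if (any(degrees < 1) || any(degrees != round(degrees))) {
    abort("degrees must be integers >= 1")
  }
  as.numeric(degrees)
}

#' Akaike Information Criterion
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of free parameters (>= 0).
#' @return `2 * k - 2 * loglik`.
#' @export
#' @examples
#' aic_of(-100, 1) # 202
aic_of <- function(loglik, k) {
  if (k < 0) abort("k must be >= 0")
  2 * k - 2 * loglik
}

#' Fit one discrete abundance model by maximum likelihood
#'
#' The single parameter is found by 1-D optimisation of the log-likelihood
#' (relative tolerance 1e-8); the geometric model additionally has the
#' closed form p-hat = n / sum(x), which the optimiser reproduces and which
#' is used directly. Degenerate samples sitting on a parameter boundary
#' (all degrees equal to 1 under the zeta or geometric model) are an error.
#'
#' @param degrees Integer vector of node degrees (>= 1), at least 10.
#' @param model One of `"zeta_powerlaw"`, `"logseries"`, `"geometric"`.
#' @return Object of class `"abundance_fit"`: list with `model`, `params`
#'   (named list), `loglik`, `aic`, `n`.
#' @export
fit_abundance <- function(degrees, model = c("zeta_powerlaw", "logseries",
                                             "geometric")) {
  model <- match.arg(model)
  x <- .check_degrees(degrees)
  n <- length(x)

  if (model == "zeta_powerlaw") {
    if (all(x == 1)) {
      abort("all degrees equal 1: zeta exponent diverges (boundary)")
    }
    # profile: loglik(alpha) = -alpha * sum(log x) - n * log(zeta(alpha))
    s <- sum(log(x))
    nll <- function(a) a * s + n * log(pracma::zeta(a))
    opt <- optimize(nll, interval = c(1 + 1e-8, 60), tol = 1e-10)
    par <- list(alpha = opt$minimum)
    ll <- -opt$objective
  } else if (model == "logseries") {
    sx <- sum(x)
    nll <- function(p) -(sx * log(p) - sum(log(x)) - n * log(-log(1 - p)))
    opt <- optimize(nll, interval = c(1e-12, 1 - 1e-12), tol = 1e-10)
    par <- list(p = opt$minimum)
    ll <- -opt$objective
  } else {
    p_hat <- n / sum(x)
    if (p_hat >= 1) {
      abort("all degrees equal 1: geometric p-hat = 1 (boundary)")
    }
    par <- list(p = p_hat)
    ll <- sum(.log_pmf(x, "geometric", p_hat))
  }

  structure(
    list(model = model, params = par, loglik = ll,
         aic = aic_of(ll, 1L), n = n),
    class = "abundance_fit"
  )
}

#' @export
print.abundance_fit <- function(x, ...) {
  cat(sprintf("<abundance_fit> %s: %s = %.4f, loglik = %.2f, AIC = %.2f, n = %d\n",
              x$model, names(x$params)[1], x$params[[1]], x$loglik, x$aic, x$n))
  invisible(x)
}

#' @export
tidy.abundance_fit <- function(x, ...) {
  tibble(model = x$model, term = names(x$params)[1],
         estimate = unname(x$params[[1]]))
}

#' @export
glance.abundance_fit <- function(x, ...) {
  tibble(model = x$model, logLik = x$loglik, AIC = x$aic, nobs = x$n)
}

#' Fit several abundance models and select by AIC
#'
#' All models in the set are fitted; the model with the smallest AIC wins.
#' Near-exact AIC ties (|difference| < 1e-9) are broken by lexicographic
#' model name (all candidates have one parameter). A model that fails to
#' fit (boundary data) is recorded with a note instead of aborting the
#' table.
#'
#' @param degrees Integer degree vector.
#' @param models Character vector of candidate model names.
#' @return Object of class `"abundance_selection"`: list with `fits`
#'   (tibble sorted by AIC: model, estimate, loglik, aic, delta_aic, n,
#'   note), `best` (model name), and the fitted `"abundance_fit"` objects.
#' @export
select_abundance_model <- function(degrees, models = .abundance_models) {
  if (length(models) == 0) abort("empty model set")
  models <- match.arg(models, .abundance_models, several.ok = TRUE)
  fits <- lapply(models, function(m) {
    tryCatch(fit_abundance(degrees, m), error = function(e) conditionMessage(e))
  })
  names(fits) <- models

  tab <- purrr::map_dfr(models, function(m) {
    f <- fits[[m]]
    if (is.character(f)) {
      tibble(model = m, term = NA_character_, estimate = NA_real_,
             loglik = NA_real_, aic = NA_real_, n = NA_integer_, note = f)
    } else {
      tibble(model = m, term = names(f$params)[1],
             estimate = unname(f$params[[1]]), loglik = f$loglik,
             aic = f$aic, n = f$n, note = NA_character_)
    }
  })
  if (all(is.na(tab$aic))) abort("no model could be fitted")

  # sort by AIC with the documented tie-break; failed fits sink to the end
  ord <- order(round(tab$aic / 1e-9) * 1e-9, tab$model, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  tab$delta_aic <- tab$aic - min(tab$aic, na.rm = TRUE)

  structure(
    list(fits = tab, best = tab$model[1],
         models = fits[!vapply(fits, is.character, logical(1))]),
    class = "abundance_selection"
  )
}

#' @export
print.abundance_selection <- function(x, ...) {
  cat(sprintf("<abundance_selection> best: %s\n", x$best))
  print(as.data.frame(x$fits[, c("model", "estimate", "loglik", "aic", "delta_aic")]))
  invisible(x)
}

#' @export
tidy.abundance_selection <- function(x, ...) x$fits

#' @export
glance.abundance_selection <- function(x, ...) {
  best <- x$fits[1, ]
  tibble(best_model = x$best, best_aic = best$aic, n_models = nrow(x$fits),
         nobs = best$n)
}

#' Compare the degree distributions of two node groups
#'
#' Fits the same candidate model set to two disjoint degree datasets
#' (e.g. transcription factors versus all other mRNAs, with the TF set
#' subtracted from the mRNA set beforehand) and reports whether AIC
#' selects the same model family for both — the criterion used to call
#' two abundance distributions similar.
#'
#' @param degrees_a,degrees_b Integer degree vectors for the two groups.
#' @param models Candidate model names.
#' @return List of class `"abundance_comparison"`: `selection_a`,
#'   `selection_b`, `same_best_model` (logical).
#' @export
compare_degree_distributions <- function(degrees_a, degrees_b,
                                         models = .abundance_models) {
  sel_a <- select_abundance_model(degrees_a, models)
  sel_b <- select_abundance_model(degrees_b, models)
  structure(
    list(selection_a = sel_a, selection_b = sel_b,
         same_best_model = identical(sel_a$best, sel_b$best)),
    class = "abundance_comparison"
  )
}

#' @export
tidy.abundance_comparison <- function(x, ...) {
  bind_rows(
    mutate(x$selection_a$fits, group = "a"),
    mutate(x$selection_b$fits, group = "b")
  ) |>
    select("group", dplyr::everything())
}

#' Probability mass of a fitted abundance model
#'
#' @param fit An `"abundance_fit"`.
#' @param x Integer support points (>= 1).
#' @return Numeric vector of probabilities.
#' @export
abundance_pmf <- function(fit, x) {
  stopifnot(inherits(fit, "abundance_fit"))
  exp(.log_pmf(x, fit$model, fit$params[[1]]))
}

#' Plot observed degree abundance against fitted models
#'
#' @param object An `"abundance_selection"`.
#' @param degrees The degree vector the selection was fitted on.
#' @param ... Unused.
#' @return A ggplot object: observed degree-class abundances (points) with
#'   each fitted model's expected abundance curve, on log-log axes.
#' @export
autoplot.abundance_selection <- function(object, degrees, ...) {
  obs <- count(tibble(degree = degrees), .data$degree, name = "abundance")
  grid <- sort(unique(obs$degree))
  n <- length(degrees)
  curves <- purrr::map_dfr(object$models, function(f) {
    tibble(model = f$model, degree = grid,
           expected = n * abundance_pmf(f, grid))
  })
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$degree, y = .data$abundance)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$expected, colour = .data$model)) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "abundance", colour = "model") +
    ggplot2::theme_minimal()
}
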