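# Scenario fitting by Poisson composite likelihood over JAFS cells, and
# AIC-based model selection.

MODEL_ZERO_FLOOR <- 1e-12   # floor for model cells before taking logs

#' Poisson composite log-likelihood of an observed spectrum
#'
#' The scale parameter theta is profiled analytically: `theta_hat` is the
#' ratio of observed to model mass over unmasked cells, and the
#' log-likelihood is the sum over unmasked cells of the Poisson
#' log-density of the observed count with mean `theta_hat * model`.
#' Model cells below `r format(MODEL_ZERO_FLOOR)` are floored there so a
#' finite Monte-Carlo model spectrum always yields a finite likelihood.
#'
#' @param obs Observed `jafs` (SNP counts; fractional entries from
#'   projection are allowed).
#' @param model_per_theta Model `jafs` of expected counts per unit theta;
#'   must match `obs` in shape, folding and mask.
#' @return A list with `loglik` and `theta_hat`.
#' @export
poisson_loglik <- function(obs, model_per_theta) {
  m <- model_per_theta
  if (!identical(dim(obs$entries), dim(m$entries)))
    abort("observed and model spectra differ in shape")
  if (!identical(obs$folded, m$folded))
    abort("observed and model spectra differ in folding")
  mask <- obs$mask | m$mask
  o <- obs$entries[!mask]
  mu <- pmax(m$entries[!mask], MODEL_ZERO_FLOOR)
  theta_hat <- sum(o) / sum(mu)
  lam <- theta_hat * mu
  list(loglik = sum(o * log(lam) - lam - lgamma(o + 1)),
       theta_hat = theta_hat)
}

# ---------------------------------------------------------------------------
# parameter transforms: positive parameters on log scale, proportions on
# logit scale, and sub-epoch durations (Tam, Tsc) as logit fractions of Ts

param_kind <- function(name) {
  if (name %in% c("P", "O", "f")) "frac"
  else if (name %in% c("Tam", "Tsc", "Th")) "frac_of_Ts"
  else "pos"
}

to_transformed <- function(p) {
  x <- numeric(length(p))
  names(x) <- names(p)
  for (nm in names(p)) {
    x[nm] <- switch(param_kind(nm),
      frac = qlogis(clamp01(p[[nm]])),
      frac_of_Ts = qlogis(clamp01(p[[nm]] / p[["Ts"]])),
      pos = log(p[[nm]])
    )
  }
  x
}

from_transformed <- function(x) {
  p <- list()
  # Ts first so fractions of it can be recovered
  ord <- names(x)[order(names(x) != "Ts")]
  for (nm in ord) {
    p[[nm]] <- switch(param_kind(nm),
      frac = plogis(x[[nm]]),
      frac_of_Ts = plogis(x[[nm]]) * p[["Ts"]],
      pos = exp(x[[nm]])
    )
  }
  p[names(x)]
}

clamp01 <- function(x) pmin(pmax(x, 1e-8), 1 - 1e-8)

default_init <- function(model) {
  pars <- model_params(model)
  vals <- vapply(pars, function(nm) switch(nm,
    nu1 = 1, nu2 = 1, nu3 = 1,
    M12 = 1, M21 = 1, me12 = 0.1, me21 = 0.1,
    m13 = 1, m31 = 1, m23 = 1, m32 = 1,
    Ts = 1, Tam = 0.5, Tsc = 0.5, Th = 0.5,
    P = 0.5, O = 0.8, f = 0.5), numeric(1))
  as.list(setNames(vals, pars))
}

#' Fit a demographic scenario to an observed spectrum
#'
#' Maximizes the Poisson composite likelihood over the model's free
#' parameters with Nelder-Mead on transformed coordinates (log for
#' positive parameters, logit for proportions; the durations of the
#' ancient-migration and secondary-contact phases are logit fractions of
#' the split time, which enforces their chronology).  The expected
#' spectrum is evaluated by Monte Carlo with a fixed, restart-specific
#' simulation seed (common random numbers), so the objective is
#' deterministic within a restart and the whole fit is reproducible.
#' `n_restarts` independent optimizations are run from log-uniformly
#' perturbed starting points (factors up to 3) and the best is returned.
#'
#' @param obs Observed `jafs`.
#' @param model Model name (see [model_params()]).
#' @param n_restarts Number of independent optimizations (default 10).
#' @param seed Integer seed controlling starts and simulation streams.
#' @param n_reps Monte-Carlo genealogies per objective evaluation.
#' @param init Optional named list of starting values (defaults per
#'   model).
#' @param maxit Maximum Nelder-Mead iterations per restart (default
#'   `60 * k`).
#' @return A `scenario_fit` with the MLE, log-likelihood, optimal theta,
#'   parameter count `k`, and a per-restart log.
#' @export
fit_scenario <- function(obs, model, n_restarts = 10, seed = 1,
                         n_reps = 10000, init = NULL, maxit = NULL) {
  pars <- model_params(model)
  k <- length(pars)
  if (is.null(maxit)) maxit <- 60L * k
  init <- init %||% default_init(model)
  if (!setequal(names(init), pars))
    abort(sprintf("init must supply exactly: %s", paste(pars, collapse = ", ")))
  sizes <- obs$sample_sizes
  objective <- function(x, sim_seed) {
    p <- from_transformed(setNames(as.list(x), pars))
    sc <- tryCatch(compile_scenario(model, p), error = function(e) NULL)
    if (is.null(sc)) return(1e12)
    e <- expected_jafs(sc, sizes, n_reps = n_reps, seed = sim_seed)
    if (obs$folded) e <- fold_jafs(e)
    -poisson_loglik(obs, e)$loglik
  }
  restarts <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    restart_seed <- seed + 7919L * r
    set.seed(restart_seed)
    start <- init
    if (r > 1) {   # first restart runs from the unperturbed init
      for (nm in pars) {
        start[[nm]] <- switch(param_kind(nm),
          pos = init[[nm]] * exp(runif(1, -log(3), log(3))),
          frac = clamp01(init[[nm]] + runif(1, -0.25, 0.25)),
          frac_of_Ts = init[[nm]]   # rescaled with Ts below
        )
      }
      for (nm in intersect(c("Tam", "Tsc", "Th"), pars))
        start[[nm]] <- clamp01(init[[nm]] / init[["Ts"]] +
                                 runif(1, -0.2, 0.2)) * start[["Ts"]]
    }
    sim_seed <- (seed * 131L + r * 7L) %% 2000000000L
    opt <- optim(to_transformed(start), objective, sim_seed = sim_seed,
                 method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-7))
    restarts[[r]] <- tibble(
      restart = r, loglik = -opt$value,
      convergence = opt$convergence, seed = restart_seed,
      par = list(from_transformed(setNames(as.list(opt$par), pars)))
    )
  }
  log <- dplyr::bind_rows(restarts)
  if (all(!is.finite(log$loglik)))
    abort("all restarts failed to produce a finite likelihood")
  best <- which.max(log$loglik)
  best_par <- log$par[[best]]
  # final evaluation at the MLE to recover theta_hat
  sc <- compile_scenario(model, best_par)
  e <- expected_jafs(sc, sizes, n_reps = n_reps,
                     seed = (seed * 131L + best * 7L) %% 2000000000L)
  if (obs$folded) e <- fold_jafs(e)
  pl <- poisson_loglik(obs, e)
  structure(list(
    model = model, par = best_par, loglik = pl$loglik,
    theta_hat = pl$theta_hat, k = k,
    restarts = log[, c("restart", "loglik", "convergence", "seed")],
    n_restarts = n_restarts, n_reps = n_reps, seed = seed,
    sample_sizes = sizes
  ), class = "scenario_fit")
}

#' @export
#' @method print scenario_fit
print.scenario_fit <- function(x, ...) {
  cat(sprintf("<scenario_fit> %s: loglik %.2f, theta %.2f, AIC %.2f (k = %d)\n",
              x$model, x$loglik, x$theta_hat, aic(x), x$k))
  cat("  ", paste(sprintf("%s=%.3g", names(x$par), unlist(x$par)),
                  collapse = ", "), "\n")
  invisible(x)
}

#' Tidy the parameter estimates of a fitted scenario
#'
#' @param x A `scenario_fit`.
#' @param ... Unused.
#' @return A tibble with `term` and `estimate`.
#' @export
tidy.scenario_fit <- function(x, ...) {
  tibble(term = names(x$par), estimate = unlist(x$par))
}

#' One-row summary of a fitted scenario
#'
#' @param x A `scenario_fit`.
#' @param ... Unused.
#' @return A tibble with `model`, `k`, `loglik`, `theta_hat`, `AIC` and
#'   restart diagnostics.
#' @export
glance.scenario_fit <- function(x, ...) {
  tibble(model = x$model, k = x$k, loglik = x$loglik,
         theta_hat = x$theta_hat, AIC = aic(x),
         n_restarts = x$n_restarts,
         n_converged = sum(x$restarts$convergence == 0))
}

#' Akaike information criterion
#'
#' `AIC = 2k - 2 log L`, on the composite likelihood (no small-sample
#' correction).
#'
#' @param x A `scenario_fit`, or a numeric maximized log-likelihood.
#' @param ... Passed to methods.
#' @export
aic <- function(x, ...) UseMethod("aic")

#' @rdname aic
#' @export
aic.scenario_fit <- function(x, ...) 2 * x$k - 2 * x$loglik

#' @rdname aic
#' @param k Number of free parameters (numeric method only).
#' @export
aic.numeric <- function(x, k, ...) 2 * k - 2 * x

#' AIC-based model comparison table
#'
#' Ranks fitted scenarios by AIC and computes the selection quantities:
#' `delta_aic` relative to the best model, the retention rule
#' `delta_aic < 10`, the model score `(delta_max - delta_aic) /
#' delta_max` mapping the best model to 1 and the worst to 0, and Akaike
#' weights `w_aic = exp(-delta_aic / 2)` normalized over the compared
#' set.
#'
#' @param fits A list of `scenario_fit` objects, or a data frame with
#'   columns `model`, `loglik` and `k`.
#' @param retain_delta Retention threshold on `delta_aic` (default 10).
#' @return A tibble with one row per model: `model`, `k`, `loglik`,
#'   `AIC`, `delta_aic`, `retained`, `score`, `w_aic`, sorted by AIC.
#' @export
model_selection <- function(fits, retain_delta = 10) {
  tab <- if (is.data.frame(fits)) {
    as_tibble(fits)
  } else {
    purrr::map_dfr(fits, function(f)
      tibble(model = f$model, k = f$k, loglik = f$loglik))
  }
  if (nrow(tab) < 2) abort("model selection needs at least two fits")
  tab$AIC <- 2 * tab$k - 2 * tab$loglik
  tab$delta_aic <- tab$AIC - min(tab$AIC)
  delta_max <- max(tab$delta_aic)
  if (delta_max == 0) {
    warn("all models have identical AIC; scores set to 1")
    tab$score <- 1
  } else {
    tab$score <- (delta_max - tab$delta_aic) / delta_max
  }
  tab$retained <- tab$delta_aic < retain_delta
  w <- exp(-tab$delta_aic / 2)
  tab$w_aic <- w / sum(w)
  dplyr::arrange(tab, .data$AIC)
}

#' Bar chart of Akaike weights across compared models
#'
#' @param object A model table from [model_selection()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_model_weights <- function(object, ...) {
  ggplot(object, aes(x = stats::reorder(.data$model, .data$AIC),
                     y = .data$w_aic, fill = .data$retained)) +
    geom_col() +
    labs(x = NULL, y = "Akaike weight") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
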