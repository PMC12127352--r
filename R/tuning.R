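# Hyperparameter search over (lambda, gamma): exhaustive grid search and
# Bayesian optimization with a Gaussian-process surrogate and the Expected
# Improvement acquisition. The objective is any deterministic function
# (lambda, gamma) -> scalar to be maximized; for calibration tuning use
# pdfc_objective(), which evaluates episode-set mean accuracy on a FIXED
# episode seed so all trials are compared on identical episodes.

#' Define a (lambda, gamma) search space
#'
#' @param lam_bounds,gamma_bounds Length-2 numeric intervals (finite,
#'   lower < upper). Defaults to `[0, 1]` for both, the range in which both
#'   parameters have their direct geometric meaning.
#' @param scale `"linear"` (default) or `"log"`; log scale suits wide
#'   ranges such as `[1e-3, 10]`.
#' @param grid_steps Optional length-2 positive step sizes `(lambda, gamma)`
#'   used by [grid_search()]; the reference protocol uses 0.1 and 0.2.
#' @return A `search_space` list.
#' @export
search_space <- function(lam_bounds = c(0, 1), gamma_bounds = c(0, 1),
                         scale = c("linear", "log"),
                         grid_steps = c(0.1, 0.2)) {
  scale <- match.arg(scale)
  for (b in list(lam_bounds, gamma_bounds)) {
    if (length(b) != 2 || any(!is.finite(b)) || b[1] >= b[2]) {
      abort_validation("bounds must be finite length-2 intervals with lower < upper")
    }
  }
  if (scale == "log" && (lam_bounds[1] <= 0 || gamma_bounds[1] <= 0)) {
    abort_validation("log scale requires strictly positive bounds")
  }
  if (!is.null(grid_steps) &&
      (length(grid_steps) != 2 || any(!is.finite(grid_steps)) || any(grid_steps <= 0))) {
    abort_validation("grid_steps must be two positive step sizes")
  }
  structure(list(lam_bounds = as.numeric(lam_bounds),
                 gamma_bounds = as.numeric(gamma_bounds),
                 scale = scale, grid_steps = grid_steps),
            class = "search_space")
}

new_search_result <- function(method, trials, m = NULL) {
  ok <- is.finite(trials$objective)
  if (!any(ok)) abort_validation("all objective evaluations failed")
  best <- which(ok)[which.max(trials$objective[ok])]  # first-encountered max
  structure(list(
    method = method,
    trials = trials,
    best_params = calibration_params(m = m %||% 10, lam = trials$lam[best],
                                     gamma = trials$gamma[best]),
    best_objective = trials$objective[best]
  ), class = "search_result")
}

#' Exhaustive grid search
#'
#' Evaluates every lattice point of the space (both endpoints included) in
#' row-major order (lambda outer, gamma inner); ties on the maximum go to
#' the first point encountered.
#'
#' @param objective Function `(lam, gamma) -> scalar` to maximize; it must
#'   be deterministic (fix any internal evaluation seed in the closure).
#' @param space A [search_space()] with `grid_steps` set.
#' @return A `search_result`: `best_params`, `best_objective`, and the full
#'   `trials` tibble in evaluation order.
#' @examples
#' res <- grid_search(function(l, g) -(l - 0.5)^2 - (g - 0.4)^2,
#'                    search_space())
#' res$best_params[c("lam", "gamma")]
#' @export
grid_search <- function(objective, space = search_space()) {
  if (is.null(space$grid_steps)) abort_validation("space has no grid_steps")
  lam_grid <- seq(space$lam_bounds[1], space$lam_bounds[2], by = space$grid_steps[1])
  gam_grid <- seq(space$gamma_bounds[1], space$gamma_bounds[2], by = space$grid_steps[2])
  if (length(lam_grid) == 0 || length(gam_grid) == 0) {
    abort_validation("empty grid")
  }
  grid <- expand.grid(gamma = gam_grid, lam = lam_grid)[, c("lam", "gamma")]
  obj <- purrr::map2_dbl(grid$lam, grid$gamma, function(l, g) {
    v <- tryCatch(objective(l, g), error = function(e) NA_real_)
    if (!is_scalar_num(v)) NA_real_ else v
  })
  trials <- tibble(iteration = seq_len(nrow(grid)), lam = grid$lam,
                   gamma = grid$gamma, objective = obj)
  new_search_result("grid", trials)
}

# ---- Gaussian-process surrogate ------------------------------------------
# Zero-mean GP with squared-exponential kernel on inputs rescaled to the
# unit square; signal variance by analytic ML given the length-scale,
# length-scale picked by marginal likelihood over a small grid. A small
# nugget keeps the Cholesky stable (the objective is deterministic).

gp_fit <- function(X, y, nugget = 1e-8) {
  mu <- mean(y)
  yc <- y - mu
  d2 <- as.matrix(stats::dist(X))^2
  best <- NULL
  for (ls in c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6)) {
    K <- exp(-d2 / (2 * ls^2))
    diag(K) <- diag(K) + nugget
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) next
    alpha0 <- backsolve(ch, forwardsolve(t(ch), yc))
    s2 <- max(sum(yc * alpha0) / length(y), 1e-12)  # ML signal variance
    # log marginal likelihood up to constants, profiled over s2
    ll <- -0.5 * length(y) * log(s2) - sum(log(diag(ch)))
    if (is.null(best) || ll > best$ll) {
      best <- list(ll = ll, ls = ls, s2 = s2, chol = ch, alpha = alpha0 / s2,
                   X = X, mu = mu, nugget = nugget)
    }
  }
  if (is.null(best)) abort_validation("GP fit failed")
  best
}

gp_predict <- function(fit, Xnew) {
  d2 <- outer(rowSums(Xnew^2), rowSums(fit$X^2), "+") - 2 * Xnew %*% t(fit$X)
  Ks <- fit$s2 * exp(-pmax(d2, 0) / (2 * fit$ls^2))
  mean <- fit$mu + as.vector(Ks %*% fit$alpha)
  v <- backsolve(fit$chol, t(Ks / fit$s2), transpose = TRUE)
  var <- pmax(fit$s2 * (1 + fit$nugget) - fit$s2 * colSums(v^2), 1e-12)
  list(mean = mean, sd = sqrt(var))
}

expected_improvement <- function(mean, sd, best) {
  z <- (mean - best) / sd
  (mean - best) * pnorm(z) + sd * dnorm(z)
}

to_unit <- function(p, space) {
  lb <- c(space$lam_bounds[1], space$gamma_bounds[1])
  ub <- c(space$lam_bounds[2], space$gamma_bounds[2])
  if (space$scale == "log") {
    p <- log(p); lb <- log(lb); ub <- log(ub)
  }
  sweep(sweep(p, 2, lb), 2, ub - lb, "/")
}

from_unit <- function(u, space) {
  lb <- c(space$lam_bounds[1], space$gamma_bounds[1])
  ub <- c(space$lam_bounds[2], space$gamma_bounds[2])
  if (space$scale == "log") {
    lb <- log(lb); ub <- log(ub)
    exp(sweep(sweep(u, 2, ub - lb, "*"), 2, lb, "+"))
  } else {
    sweep(sweep(u, 2, ub - lb, "*"), 2, lb, "+")
  }
}

#' Bayesian optimization with a GP surrogate and Expected Improvement
#'
#' Starts from a 10-point Latin-hypercube initial design (counted within
#' `n_iterations`), then repeatedly fits the surrogate to all finite
#' observations and evaluates the candidate maximizing Expected Improvement
#' over a seeded Latin-hypercube candidate set. Returns the best *observed*
#' objective, never a surrogate prediction. Deterministic under `seed`;
#' trials whose objective is non-finite are recorded as failures and
#' skipped by the surrogate.
#'
#' @param objective Function `(lam, gamma) -> scalar` to maximize.
#' @param space A [search_space()].
#' @param n_iterations Total objective evaluations, >= 2 (default 100, the
#'   reference protocol).
#' @param seed Integer RNG seed (default 1).
#' @param n_init Initial-design size (default `min(10, n_iterations - 1)`).
#' @param n_candidates Candidate points scored per iteration (default 500).
#' @return A `search_result`.
#' @export
bayes_search <- function(objective, space = search_space(), n_iterations = 100,
                         seed = 1, n_init = min(10, n_iterations - 1),
                         n_candidates = 500) {
  if (!is_count(n_iterations) || n_iterations < 2) {
    abort_validation("n_iterations must be an integer >= 2")
  }
  set.seed(seed)
  U <- as.matrix(lhs::randomLHS(n_init, 2))
  eval_pt <- function(u) {
    p <- from_unit(matrix(u, 1), space)
    v <- tryCatch(objective(p[1], p[2]), error = function(e) NA_real_)
    if (!is_scalar_num(v)) NA_real_ else v
  }
  obs_u <- matrix(NA_real_, n_iterations, 2)
  obs_y <- rep(NA_real_, n_iterations)
  for (i in seq_len(n_init)) {
    obs_u[i, ] <- U[i, ]
    obs_y[i] <- eval_pt(U[i, ])
  }
  for (i in seq(n_init + 1, length.out = n_iterations - n_init)) {
    ok <- which(is.finite(obs_y[seq_len(i - 1)]))
    cand <- as.matrix(lhs::randomLHS(n_candidates, 2))
    if (length(ok) >= 2) {
      fit <- tryCatch(gp_fit(obs_u[ok, , drop = FALSE], obs_y[ok]),
                      error = function(e) NULL)
    } else {
      fit <- NULL
    }
    if (is.null(fit)) {
      pick <- cand[1, ]
    } else {
      pr <- gp_predict(fit, cand)
      ei <- expected_improvement(pr$mean, pr$sd, max(obs_y[ok]))
      pick <- cand[which.max(ei), ]
    }
    obs_u[i, ] <- pick
    obs_y[i] <- eval_pt(pick)
  }
  P <- from_unit(obs_u, space)
  trials <- tibble(iteration = seq_len(n_iterations), lam = P[, 1],
                   gamma = P[, 2], objective = obs_y)
  new_search_result("bayes", trials)
}

#' Episode-accuracy objective for calibration tuning
#'
#' Builds the deterministic `(lam, gamma) -> mean accuracy` objective used
#' to tune the calibration: every trial evaluates the same episodes (fixed
#' evaluation seed), so parameter comparisons are free of sampling noise.
#'
#' @param fs Target-domain feature set the episodes are drawn from.
#' @param ref Reference bank for the calibration.
#' @param spec An [episode_spec()].
#' @param m Calibration neighborhood size (fixed during the search).
#' @param episodes_per_run,runs Protocol size per evaluation.
#' @param seed Fixed evaluation seed shared by all trials.
#' @return Function `(lam, gamma) -> mean accuracy`.
#' @export
pdfc_objective <- function(fs, ref, spec = episode_spec(), m = 10,
                           episodes_per_run = 100, runs = 1, seed = 1) {
  R <- ref_matrix(ref)
  force(fs); force(spec)
  function(lam, gamma) {
    cal <- pdfc_calibrator(R, calibration_params(m = m, lam = lam, gamma = gamma))
    ev <- run_evaluation(fs, spec, episodes_per_run = episodes_per_run,
                         runs = runs, calibrator = cal, seed = seed)
    ev$summary$mean_accuracy
  }
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("%s search: %d trials, best objective %.4f at lambda = %g, gamma = %g\n",
              x$method, nrow(x$trials), x$best_objective,
              x$best_params$lam, x$best_params$gamma))
  invisible(x)
}
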