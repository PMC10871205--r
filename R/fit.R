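#' Options controlling the constrained least-squares fits
#'
#' The fits minimise the sum of squared errors between the model output
#' and the observed Adaptation Index over retained strides, subject to
#' all rates lying in \[0, 1\] and, for the implicit pair, the
#' identifiability constraints `Bfast >= 5*Bslow` and
#' `Aslow >= Afast + eps` (the strict ordering implemented with a small
#' tolerance). The implicit parameters are initialised at
#' `Afast = 0.92, Bfast = 0.03, Aslow = 0.996, Bslow = 0.004` on every
#' restart; the explicit rate is initialised uniformly at random per
#' restart (`n_restarts` of them, default 10). The single-rate model is
#' initialised at `A = 0.96, B = 0.017`.
#'
#' Each restart runs a log-barrier constrained Nelder-Mead search
#' ([stats::constrOptim()]) followed by a box-bounded L-BFGS-B polish
#' that is accepted only when it stays feasible and lowers the SSE.
#' Richer models additionally evaluate the nested model's solution
#' embedded in their parameter space, which protects the model comparison
#' from local-minimum artifacts and guarantees
#' `SSE(vc) <= SSE(dual)` (the dual embeds exactly as `Bexplicit = 0`)
#' and, up to the `eps` ordering tolerance, `SSE(dual) <= SSE(single)`.
#'
#' @param n_restarts Number of random explicit-rate initialisations.
#' @param eps Tolerance turning `Aslow > Afast` into `Aslow >= Afast + eps`.
#' @param reltol Relative convergence tolerance of the inner simplex.
#' @param maxit Maximum inner iterations per restart.
#' @param seed Optional integer seed making the restarts reproducible.
#' @return A `fit_options` list.
#' @export
fitOptions <- function(n_restarts = 10L, eps = 1e-4, reltol = 1e-12,
                       maxit = 2000L, seed = NULL) {
  if (n_restarts < 1L) stop("n_restarts must be >= 1")
  if (eps <= 0) stop("eps must be > 0")
  structure(list(n_restarts = as.integer(n_restarts), eps = eps,
                 reltol = reltol, maxit = as.integer(maxit), seed = seed),
            class = "fit_options")
}

# canonical fitting input: raw-grid perturbation/feedback signals plus
# observed AI at retained raw-grid positions
fitData <- function(ai, schedule = NULL) {
  if (inherits(ai, "ai_series")) {
    d <- ai[ai$phase %in% c("Adaptation", "Deadaptation"), ]
    d <- d[order(match(d$phase, c("Adaptation", "Deadaptation")), d$stride), ]
    keep <- d$retained & is.finite(d$ai)
    list(pert = as.numeric(d$phase == "Adaptation"),
         fb = if ("feedback_on" %in% names(d)) as.logical(d$feedback_on)
              else rep(FALSE, nrow(d)),
         idx = which(keep), obs = d$ai[keep])
  } else if (is.numeric(ai)) {
    if (is.null(schedule))
      stop("a schedule is required when fitting a bare AI vector")
    g <- modelGrid(schedule)
    if (length(ai) != length(g$pert))
      stop("AI vector length must match the Adaptation+Deadaptation grid")
    keep <- is.finite(ai)
    list(pert = g$pert, fb = g$fb, idx = which(keep), obs = ai[keep])
  } else if (is.list(ai) && all(c("pert", "obs", "idx") %in% names(ai))) {
    ai$fb <- ai$fb %||% rep(FALSE, length(ai$pert))
    ai
  } else stop("ai must be an ai_series, a numeric AI vector, or a fit-data list")
}

modelSpecs <- list(
  single = list(k = 2L, names = c("A", "B")),
  dual = list(k = 4L, names = c("Afast", "Bfast", "Aslow", "Bslow")),
  vc = list(k = 5L, names = c("Afast", "Bfast", "Aslow", "Bslow", "Bexplicit"))
)

sseFun <- function(model, fd) {
  idx <- as.integer(fd$idx); obs <- fd$obs; pert <- fd$pert; fb <- fd$fb
  switch(model,
    single = function(th) cpp_sse_single(pert, th[1], th[2], idx, obs),
    dual = function(th) cpp_sse_vc(pert, fb, th[1], th[2], th[3], th[4], 0,
                                   idx, obs),
    vc = function(th) cpp_sse_vc(pert, fb, th[1], th[2], th[3], th[4], th[5],
                                 idx, obs))
}

# linear inequality system ui %*% theta - ci >= 0 for constrOptim
constraintSystem <- function(model, eps) {
  k <- modelSpecs[[model]]$k
  ui <- rbind(diag(k), -diag(k))
  ci <- c(rep(0, k), rep(-1, k))
  if (model %in% c("dual", "vc")) {
    bf5bs <- c(0, 1, 0, -5, rep(0, k - 4L))
    order_a <- c(-1, 0, 1, 0, rep(0, k - 4L))
    ui <- rbind(ui, bf5bs, order_a)
    ci <- c(ci, 0, eps)
  }
  list(ui = ui, ci = ci)
}

feasible <- function(model, theta, eps, slack = 1e-9) {
  cs <- constraintSystem(model, eps)
  all(cs$ui %*% theta - cs$ci >= -slack)
}

# nudge a start strictly inside the feasible region
interiorise <- function(model, theta, eps) {
  theta <- pmin(pmax(theta, 1e-6), 1 - 1e-6)
  if (model %in% c("dual", "vc")) {
    if (theta[2] < 5 * theta[4]) theta[4] <- theta[2] / 5 * (1 - 1e-3)
    if (theta[3] < theta[1] + eps) theta[1] <- max(1e-6, theta[3] - 2 * eps)
  }
  theta
}

runRestart <- function(model, fd, start, options) {
  f <- sseFun(model, fd)
  cs <- constraintSystem(model, options$eps)
  start <- interiorise(model, start, options$eps)
  fit <- tryCatch(
    stats::constrOptim(start, f, grad = NULL, ui = cs$ui, ci = cs$ci,
                       mu = 1e-6, outer.iterations = 15, outer.eps = 1e-10,
                       control = list(maxit = options$maxit,
                                      reltol = options$reltol)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  theta <- fit$par
  value <- f(theta)
  # box-bounded quasi-Newton polish, kept only if it stays feasible
  pol <- tryCatch(
    stats::optim(theta, f, method = "L-BFGS-B", lower = 0, upper = 1,
                 control = list(factr = 10, maxit = 500)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value < value &&
      feasible(model, pol$par, options$eps)) {
    theta <- pol$par
    value <- pol$value
  }
  list(par = theta, value = value, convergence = fit$convergence)
}

#' Fit a learning model to an Adaptation Index series
#'
#' Constrained multi-restart least squares for one of the three candidate
#' models (see [fitOptions()] for the bounds, constraints,
#' initialisations and restart scheme). The model is simulated on the
#' full raw Adaptation + De-adaptation stride grid; residuals are taken
#' on retained strides only.
#'
#' @param model One of `"single"`, `"dual"`, `"vc"`.
#' @param ai An `ai_series` from [preprocess()], a numeric AI vector on
#'   the grid of `schedule` (NA for removed strides), or a list with
#'   elements `pert`, `fb`, `idx`, `obs`.
#' @param options A [fitOptions()] list.
#' @param schedule Required only when `ai` is a bare numeric vector.
#' @param nested Optionally, the `fit_result` of the nested model
#'   (`single` for `dual`, `dual` for `vc`) whose solution seeds an extra
#'   deterministic restart. Computed internally when `NULL`.
#' @return A `fit_result` list: `model`, `params` (named vector), `sse`,
#'   `n_obs`, `r2`, `restarts` (per-restart audit: initial explicit rate,
#'   converged SSE, stage label), `flags` (`bound_hit`,
#'   `constraint_active`), `convergence`.
#' @examples
#' traj <- simulateVC(vcParams(Bexplicit = 0.2), phaseSchedule())
#' fit <- fitModel("vc", traj$x, fitOptions(n_restarts = 2, seed = 1),
#'                 schedule = phaseSchedule())
#' round(fit$params, 3)
#' @export
fitModel <- function(model, ai, options = fitOptions(), schedule = NULL,
                     nested = NULL) {
  model <- match.arg(model, c("single", "dual", "vc"))
  fd <- fitData(ai, schedule)
  spec <- modelSpecs[[model]]
  if (length(fd$obs) <= spec$k)
    stop("series has fewer retained strides than parameters")
  if (!is.null(options$seed)) set.seed(options$seed)

  starts <- list()
  labels <- character(0)
  init_bexp <- numeric(0)
  if (model == "single") {
    starts <- list(c(0.96, 0.017))
    labels <- "default"
    init_bexp <- NA_real_
  } else if (model == "dual") {
    starts <- list(c(0.92, 0.03, 0.996, 0.004))
    labels <- "default"
    init_bexp <- NA_real_
    if (is.null(nested))
      nested <- fitModel("single", fd, options)
    starts <- c(starts, list(embedSingleInDual(nested$params, options$eps)))
    labels <- c(labels, "nested-seed")
    init_bexp <- c(init_bexp, NA_real_)
  } else {
    be <- stats::runif(options$n_restarts)
    starts <- lapply(be, function(b) c(0.92, 0.03, 0.996, 0.004, b))
    labels <- rep("random-explicit", options$n_restarts)
    init_bexp <- be
    if (is.null(nested))
      nested <- fitModel("dual", fd, options)
    starts <- c(starts, list(c(nested$params, 1e-3)))
    labels <- c(labels, "nested-seed")
    init_bexp <- c(init_bexp, 1e-3)
  }

  f <- sseFun(model, fd)
  rows <- list()
  cand_par <- list()
  cand_val <- numeric(0)
  conv <- integer(0)
  for (i in seq_along(starts)) {
    r <- runRestart(model, fd, starts[[i]], options)
    if (is.null(r)) next
    rows[[length(rows) + 1L]] <-
      data.frame(restart = i, stage = labels[i], init_Bexplicit = init_bexp[i],
                 t(stats::setNames(r$par, spec$names)), sse = r$value)
    cand_par[[length(cand_par) + 1L]] <- r$par
    cand_val <- c(cand_val, r$value)
    conv <- c(conv, r$convergence)
  }
  if (length(cand_val) == 0L)
    stop("optimizer failed to converge on every restart")
  # evaluate the nested solution embedded verbatim as a final candidate
  if (model == "vc" && !is.null(nested)) {
    emb <- c(nested$params, Bexplicit = 0)
    cand_par[[length(cand_par) + 1L]] <- emb
    cand_val <- c(cand_val, f(emb))
    conv <- c(conv, 0L)
    rows[[length(rows) + 1L]] <-
      data.frame(restart = length(starts) + 1L, stage = "nested-candidate",
                 init_Bexplicit = 0,
                 t(stats::setNames(emb, spec$names)), sse = f(emb))
  }
  best <- which.min(cand_val) # ties broken by lowest restart index
  theta <- stats::setNames(cand_par[[best]], spec$names)
  sse <- cand_val[best]
  obs <- fd$obs
  sst <- sum((obs - mean(obs))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  cs <- constraintSystem(model, options$eps)
  margins <- drop(cs$ui %*% theta - cs$ci)
  k <- spec$k
  structure(list(model = model, params = theta, sse = sse,
                 n_obs = length(obs), r2 = r2,
                 restarts = do.call(rbind, rows),
                 flags = list(
                   bound_hit = any(margins[seq_len(2 * k)] < 1e-6),
                   constraint_active = length(margins) > 2 * k &&
                     any(margins[-seq_len(2 * k)] < 1e-6)),
                 convergence = conv[best]),
            class = "fit_result")
}

# single-rate (A, B) embedded in the dual-rate space at the eps-ordering
# boundary; exact embedding is impossible under Aslow >= Afast + eps
embedSingleInDual <- function(p, eps) {
  A <- p[["A"]]; B <- p[["B"]]
  if (B <= 0) { Bf <- 1e-5; Bs <- 1e-6 } else {
    Bs <- B * (1 - 1e-3) / 6
    Bf <- B - Bs
  }
  c(max(1e-6, A - 2 * eps), Bf, min(A, 1 - 1e-6), Bs)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s-model fit: SSE = %.6g over %d strides, r2 = %.4f\n",
              x$model, x$sse, x$n_obs, x$r2))
  print(round(x$params, 5))
  invisible(x)
}

#' Fit all three models with shared nested seeding
#'
#' Fits the single-rate, dual-rate and voluntary-correction models to the
#' same series, reusing each reduced fit to seed (and lower-bound) the
#' richer one, which enforces the nested SSE ordering
#' `SSE(vc) <= SSE(dual) <= SSE(single)`.
#'
#' @inheritParams fitModel
#' @return Named list of `fit_result`s: `single`, `dual`, `vc`.
#' @export
fitAllModels <- function(ai, options = fitOptions(), schedule = NULL) {
  fd <- fitData(ai, schedule)
  single <- fitModel("single", fd, options)
  dual <- fitModel("dual", fd, options, nested = single)
  vc <- fitModel("vc", fd, options, nested = dual)
  list(single = single, dual = dual, vc = vc)
}

#' Coefficient of determination
#'
#' `1 - SSE/SStotal`, with the total sum of squares about the observed
#' mean. Values below 0 indicate a fit worse than the mean.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return A single number, at most 1.
#' @export
rSquared <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 2L) stop("need at least 2 points")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("observed series has zero variance")
  1 - sum((observed - predicted)^2) / sst
}

#' Bootstrap the group-average model fit
#'
#' Resamples participants with replacement, averages their Adaptation
#' Index stride-by-stride (participants aligned on raw stride index and
#' truncated to the cohort-minimum phase length; removed strides are
#' skipped in the average), fits the model to each bootstrap average, and
#' summarises the r-squared values over resamples.
#'
#' @param ai_list List of `ai_series`, one per participant, sharing one
#'   schedule.
#' @param model One of `"single"`, `"dual"`, `"vc"`.
#' @param n_boot Number of bootstrap resamples (>= 2; 1000 in the
#'   canonical analysis).
#' @param options A [fitOptions()].
#' @param seed Integer seed for the resampling.
#' @return List with `mean_r2`, `ci` (percentile 95% interval), `r2`
#'   (per-sample vector), `n_boot`.
#' @export
bootstrapGroupFit <- function(ai_list, model = "vc", n_boot = 1000L,
                              options = fitOptions(), seed = 1L) {
  if (length(ai_list) < 2L) stop("need at least 2 participants")
  if (n_boot < 2L) stop("n_boot must be >= 2")
  mats <- lapply(ai_list, function(ai) {
    d <- ai[ai$phase %in% c("Adaptation", "Deadaptation"), ]
    d <- d[order(match(d$phase, c("Adaptation", "Deadaptation")), d$stride), ]
    d$ai[!d$retained] <- NA_real_
    d
  })
  nA <- min(vapply(mats, function(d) sum(d$phase == "Adaptation"), 0L))
  nD <- min(vapply(mats, function(d) sum(d$phase == "Deadaptation"), 0L))
  Y <- vapply(mats, function(d) {
    c(d$ai[d$phase == "Adaptation"][seq_len(nA)],
      d$ai[d$phase == "Deadaptation"][seq_len(nD)])
  }, numeric(nA + nD))
  fb <- with(mats[[1]], c(feedback_on[phase == "Adaptation"][seq_len(nA)],
                          feedback_on[phase == "Deadaptation"][seq_len(nD)]))
  pert <- rep(c(1, 0), c(nA, nD))
  set.seed(seed)
  draws <- matrix(sample.int(length(ai_list), n_boot * length(ai_list),
                             replace = TRUE), nrow = n_boot)
  r2 <- vapply(seq_len(n_boot), function(b) {
    ybar <- rowMeans(Y[, draws[b, ], drop = FALSE], na.rm = TRUE)
    keep <- is.finite(ybar)
    fd <- list(pert = pert, fb = fb, idx = which(keep), obs = ybar[keep])
    fit <- fitModel(model, fd, options)
    fit$r2
  }, 0)
  list(mean_r2 = mean(r2),
       ci = stats::quantile(r2, c(0.025, 0.975), names = FALSE),
       r2 = r2, n_boot = n_boot)
}
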