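#' Settings for the Bayesian models
#'
#' Sampler and prior settings shared by [fitGroupTimeModel()],
#' [bayesianRegression()] and [likelihoodComparison()]. Effects get
#' normal priors centred on 0 with SD `prior_scale` times the pooled SD
#' of the data (wide, so they only make inferences conservative); the
#' residual SD gets a uniform prior on (0, `prior_scale` x pooled SD).
#'
#' @param n_draws Total posterior draws across chains (default 10,000).
#' @param n_tune Adaptation + burn-in iterations per chain (default 2,000).
#' @param chains Number of MCMC chains.
#' @param seed Integer seed; chains get derived RNG streams, so results
#'   are exactly reproducible.
#' @param prior_scale Width multiplier for the priors.
#' @param rhat_threshold Convergence warning threshold for the split-chain
#'   potential scale reduction factor.
#' @return A `bayes_spec` list.
#' @export
bayesSpec <- function(n_draws = 10000L, n_tune = 2000L, chains = 4L,
                      seed = 1L, prior_scale = 10, rhat_threshold = 1.01) {
  if (n_draws < 1000L) stop("n_draws must be >= 1000 for reported summaries")
  if (prior_scale <= 0) stop("prior_scale must be > 0")
  structure(list(n_draws = as.integer(n_draws), n_tune = as.integer(n_tune),
                 chains = as.integer(chains), seed = as.integer(seed),
                 prior_scale = prior_scale, rhat_threshold = rhat_threshold),
            class = "bayes_spec")
}

jagsInits <- function(spec) {
  lapply(seq_len(spec$chains), function(ch)
    list(.RNG.name = "base::Wichmann-Hill",
         # chain-specific streams; modulo keeps large seeds in range
         .RNG.seed = (as.numeric(spec$seed) * 1000 + ch) %% 2147483646 + 1))
}

runJags <- function(model_string, data, monitor, spec) {
  m <- rjags::jags.model(textConnection(model_string), data = data,
                         n.chains = spec$chains, n.adapt = spec$n_tune,
                         inits = jagsInits(spec), quiet = TRUE)
  per_chain <- ceiling(spec$n_draws / spec$chains)
  s <- rjags::coda.samples(m, monitor, n.iter = per_chain)
  rhat <- if (spec$chains > 1L)
    tryCatch(coda::gelman.diag(s, multivariate = FALSE)$psrf[, 1],
             error = function(e) rep(NA_real_, length(monitor)))
  else rep(NA_real_, length(monitor))
  draws <- do.call(rbind, lapply(s, as.matrix))
  draws <- draws[, monitor, drop = FALSE] # coda orders columns alphabetically
  rhat <- rhat[monitor]
  list(model = m, draws = draws, rhat = rhat)
}

summariseDraws <- function(draws, rhat = NULL, mass = 0.95) {
  out <- do.call(rbind, lapply(colnames(draws), function(p) {
    d <- draws[, p]
    h <- hdi(d, mass)
    data.frame(parameter = p, mean = mean(d), hdi_low = h[1], hdi_high = h[2],
               p_difference = pDifference(d),
               rhat = if (is.null(rhat)) NA_real_ else unname(rhat[p]),
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Bayesian 2x2 group-by-time model
#'
#' Estimates group, time and interaction effects on a timepoint measure.
#' The likelihood is normal with a common SD; the mean is
#' `b0 + bg*g + bt*t + bgt*g*t` with sum-to-zero (+1/2, -1/2) coding for
#' group and time, so `bg` is the marginal group difference, `bt` the
#' within-subject time difference, and `bgt` the interaction
#' (difference of differences) — the contrasts reported as posterior
#' mean, 95% highest density interval and p_difference.
#'
#' @param long Data frame with columns `participant`, `group` (2 levels),
#'   `timepoint` (2 levels), `value`; at least 2 participants per cell.
#' @param spec A [bayesSpec()].
#' @param ref Optional character(2) vectors `ref$group` / `ref$time`
#'   fixing which level is coded +1/2 first (defaults to the levels'
#'   sort order; differences are level1 - level2).
#' @return A `group_time_fit` list: `summary` (a `posterior_summary` for
#'   `group`, `time`, `interaction`, `mu0`, `sigma`), `draws` matrix,
#'   `data` (the modelled rows with codes), `spec`, `levels`. A warning
#'   is issued when any split-chain Rhat exceeds the threshold.
#' @examples
#' \donttest{
#' d <- expand.grid(participant = 1:8, group = c("control", "stroke"),
#'                  timepoint = c("FeedbackOn", "FeedbackOff"))
#' d$value <- rnorm(nrow(d), 0.5, 0.1)
#' fit <- fitGroupTimeModel(d, bayesSpec(n_draws = 2000, n_tune = 500))
#' fit$summary
#' }
#' @export
fitGroupTimeModel <- function(long, spec = bayesSpec(), ref = NULL) {
  need <- c("participant", "group", "timepoint", "value")
  stopifnot(all(need %in% names(long)))
  long <- long[is.finite(long$value), , drop = FALSE]
  gl <- ref$group %||% sort(unique(long$group))
  tl <- ref$time %||% sort(unique(long$timepoint))
  if (length(gl) != 2L || length(tl) != 2L)
    stop("exactly two groups and two timepoints are required")
  long <- long[long$group %in% gl & long$timepoint %in% tl, , drop = FALSE]
  cells <- table(long$group, long$timepoint)
  if (any(cells < 2L)) stop("need at least 2 participants per cell")
  g <- ifelse(long$group == gl[1], 0.5, -0.5)
  t <- ifelse(long$timepoint == tl[1], 0.5, -0.5)
  sdp <- stats::sd(long$value)
  if (sdp == 0) sdp <- 1e-6
  model <- "model {
    for (i in 1:N) {
      y[i] ~ dnorm(b0 + bg*g[i] + bt*t[i] + bgt*g[i]*t[i], tau)
    }
    b0 ~ dnorm(0, prec_b)
    bg ~ dnorm(0, prec_b)
    bt ~ dnorm(0, prec_b)
    bgt ~ dnorm(0, prec_b)
    sigma ~ dunif(0, sd_upper)
    tau <- pow(sigma, -2)
  }"
  data <- list(y = long$value, g = g, t = t, N = nrow(long),
               prec_b = 1 / (spec$prior_scale * sdp)^2,
               sd_upper = spec$prior_scale * sdp)
  r <- runJags(model, data, c("b0", "bg", "bt", "bgt", "sigma"), spec)
  colnames(r$draws) <- c("mu0", "group", "time", "interaction", "sigma")
  names(r$rhat) <- colnames(r$draws)
  if (any(r$rhat > spec$rhat_threshold, na.rm = TRUE))
    warning("MCMC convergence diagnostic above threshold: max Rhat = ",
            round(max(r$rhat, na.rm = TRUE), 4))
  out <- list(summary = summariseDraws(r$draws, r$rhat),
              draws = r$draws,
              data = data.frame(long, g = g, t = t),
              spec = spec, levels = list(group = gl, time = tl))
  class(out) <- "group_time_fit"
  out
}

#' @export
print.group_time_fit <- function(x, ...) {
  cat(sprintf("Bayesian group x time model (%s vs %s; %s vs %s)\n",
              x$levels$group[1], x$levels$group[2],
              x$levels$time[1], x$levels$time[2]))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Highest density interval
#'
#' The narrowest contiguous interval containing `mass` of the draws: the
#' shortest window of `ceiling(mass*n)` consecutive sorted values.
#'
#' @param draws Numeric vector of posterior draws (>= 100 for a stable
#'   interval; fewer are allowed but imprecise).
#' @param mass Probability mass, in (0, 1).
#' @return Numeric `c(low, high)`.
#' @examples
#' hdi(rnorm(1e5)) # about c(-1.96, 1.96)
#' @export
hdi <- function(draws, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  draws <- sort(draws[is.finite(draws)])
  n <- length(draws)
  if (n < 2L) stop("need at least 2 finite draws")
  m <- ceiling(mass * n)
  if (m >= n) return(c(draws[1], draws[n]))
  lo <- seq_len(n - m)
  widths <- draws[lo + m] - draws[lo]
  i <- which.min(widths)
  c(draws[i], draws[i + m])
}

#' Probability of a difference
#'
#' Percentage of posterior draws on the majority side of zero (draws
#' exactly at zero are split evenly), so values run from 50 (no evidence
#' of a direction) to 100 (all draws on one side).
#'
#' @param draws Numeric vector of posterior draws.
#' @return A percentage in \[50, 100\].
#' @export
pDifference <- function(draws) {
  draws <- draws[is.finite(draws)]
  if (length(draws) == 0L) stop("no draws")
  z <- sum(draws == 0) / 2
  pos <- sum(draws > 0) + z
  100 * max(pos, length(draws) - pos) / length(draws)
}

#' Posterior predictive check for the group-by-time model
#'
#' Simulates replicated datasets from posterior draws and compares the
#' replicated cell means and SDs with the observed ones. The tail
#' probability per cell and statistic is
#' `min(P(rep >= obs), P(rep <= obs))`; cells below `flag_below` are
#' flagged as misfit.
#'
#' @param fit A `group_time_fit` from [fitGroupTimeModel()].
#' @param n_rep Number of replicated datasets (drawn evenly from the
#'   posterior).
#' @param flag_below Flagging threshold for tail probabilities.
#' @return Data frame per cell x statistic: observed value, mean
#'   replicated value, `tail_prob`, `flag`.
#' @export
posteriorPredictiveCheck <- function(fit, n_rep = 500L, flag_below = 0.05) {
  stopifnot(inherits(fit, "group_time_fit"))
  d <- fit$data
  dr <- fit$draws
  pick <- round(seq(1, nrow(dr), length.out = min(n_rep, nrow(dr))))
  cells <- split(seq_len(nrow(d)), paste(d$group, d$timepoint, sep = ":"))
  rows <- list()
  for (cn in names(cells)) {
    i <- cells[[cn]]
    mu_cell <- function(b) b["mu0"] + b["group"] * d$g[i][1] +
      b["time"] * d$t[i][1] + b["interaction"] * d$g[i][1] * d$t[i][1]
    obs_m <- mean(d$value[i]); obs_s <- stats::sd(d$value[i])
    rep_stats <- vapply(pick, function(j) {
      b <- dr[j, ]
      y <- stats::rnorm(length(i), mu_cell(b), b["sigma"])
      c(mean(y), stats::sd(y))
    }, numeric(2))
    for (stat in 1:2) {
      obs <- if (stat == 1) obs_m else obs_s
      reps <- rep_stats[stat, ]
      p <- min(mean(reps >= obs), mean(reps <= obs))
      rows[[length(rows) + 1L]] <- data.frame(
        cell = cn, statistic = c("mean", "sd")[stat], observed = obs,
        replicated_mean = mean(reps), tail_prob = p, flag = p < flag_below,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Bayesian simple linear regression
#'
#' Regresses a learning measure on a covariate (e.g. a Lower Extremity
#' Fugl-Meyer score) with a normal likelihood and wide priors, returning
#' the slope posterior with its 95% HDI and p_difference.
#'
#' @param y Numeric outcome (learning measure).
#' @param x Numeric covariate with non-zero variance; pairs with
#'   non-finite values are dropped (>= 5 required).
#' @param spec A [bayesSpec()].
#' @return A `posterior_summary` with rows `slope`, `intercept`, `sigma`,
#'   with the draws matrix attached as attribute `draws`.
#' @export
bayesianRegression <- function(y, x, spec = bayesSpec()) {
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  if (length(y) < 5L) stop("need at least 5 paired observations")
  if (stats::sd(x) == 0) stop("covariate has zero variance")
  sdy <- stats::sd(y)
  if (sdy == 0) sdy <- 1e-6
  xc <- x - mean(x)
  model <- "model {
    for (i in 1:N) { y[i] ~ dnorm(a + b * xc[i], tau) }
    a ~ dnorm(ybar, prec_a)
    b ~ dnorm(0, prec_b)
    sigma ~ dunif(0, sd_upper)
    tau <- pow(sigma, -2)
  }"
  data <- list(y = y, xc = xc, N = length(y), ybar = mean(y),
               prec_a = 1 / (spec$prior_scale * sdy)^2,
               prec_b = 1 / (spec$prior_scale * sdy / stats::sd(x))^2,
               sd_upper = spec$prior_scale * sdy)
  r <- runJags(model, data, c("b", "a", "sigma"), spec)
  # report the intercept on the original covariate scale
  r$draws[, "a"] <- r$draws[, "a"] - r$draws[, "b"] * mean(x)
  colnames(r$draws) <- c("slope", "intercept", "sigma")
  names(r$rhat) <- colnames(r$draws)
  out <- summariseDraws(r$draws, r$rhat)
  attr(out, "draws") <- r$draws
  out
}

#' Normal versus Student-t likelihood comparison
#'
#' Fits the group-by-time mean structure under a normal and under a
#' Student-t likelihood (degrees of freedom `nu - 1 ~ Exponential(1/29)`)
#' and compares them by DIC (penalised deviance). A lower DIC is
#' preferred; normal data should favour the normal likelihood, heavy
#' tails the t.
#'
#' @inheritParams fitGroupTimeModel
#' @param n_dic Iterations used for the DIC estimate.
#' @return List with `dic_normal`, `dic_t`, `difference`
#'   (normal - t; negative prefers normal) and `preferred`.
#' @export
likelihoodComparison <- function(long, spec = bayesSpec(), n_dic = 2000L) {
  need <- c("participant", "group", "timepoint", "value")
  stopifnot(all(need %in% names(long)))
  long <- long[is.finite(long$value), , drop = FALSE]
  gl <- sort(unique(long$group)); tl <- sort(unique(long$timepoint))
  if (length(gl) != 2L || length(tl) != 2L)
    stop("exactly two groups and two timepoints are required")
  g <- ifelse(long$group == gl[1], 0.5, -0.5)
  t <- ifelse(long$timepoint == tl[1], 0.5, -0.5)
  sdp <- stats::sd(long$value)
  if (sdp == 0) sdp <- 1e-6
  data <- list(y = long$value, g = g, t = t, N = nrow(long),
               prec_b = 1 / (spec$prior_scale * sdp)^2,
               sd_upper = spec$prior_scale * sdp)
  lik <- c(normal = "y[i] ~ dnorm(mu[i], tau)",
           t = "y[i] ~ dt(mu[i], tau, nu)")
  extra <- c(normal = "",
             t = "numin1 ~ dexp(0.0344827586)\n    nu <- numin1 + 1")
  dic <- sapply(names(lik), function(l) {
    model <- sprintf("model {
    for (i in 1:N) {
      %s
      mu[i] <- b0 + bg*g[i] + bt*t[i] + bgt*g[i]*t[i]
    }
    b0 ~ dnorm(0, prec_b)
    bg ~ dnorm(0, prec_b)
    bt ~ dnorm(0, prec_b)
    bgt ~ dnorm(0, prec_b)
    sigma ~ dunif(0, sd_upper)
    tau <- pow(sigma, -2)
    %s
  }", lik[[l]], extra[[l]])
    m <- rjags::jags.model(textConnection(model), data = data,
                           n.chains = max(2L, spec$chains),
                           n.adapt = spec$n_tune,
                           inits = jagsInits(spec), quiet = TRUE)
    d <- rjags::dic.samples(m, n.iter = n_dic, type = "pD")
    sum(d$deviance) + sum(d$penalty)
  })
  list(dic_normal = dic[["normal"]], dic_t = dic[["t"]],
       difference = dic[["normal"]] - dic[["t"]],
       preferred = if (dic[["normal"]] <= dic[["t"]]) "normal" else "t")
}
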