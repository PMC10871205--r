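#' Information criteria for least-squares fits
#'
#' Gaussian least-squares forms: `AIC = n*ln(SSE/n) + 2k` and
#' `BIC = n*ln(SSE/n) + k*ln(n)` for a model with `k` free parameters fit
#' to `n` observations. A zero SSE gives `-Inf` with a warning.
#'
#' @param sse Sum of squared errors (> 0 for a finite value).
#' @param n_obs Number of fitted observations (> k).
#' @param k Number of free parameters (single = 2, dual = 4, vc = 5).
#' @return The criterion value (dimensionless).
#' @examples
#' aicSSE(1, 100, 2) # 100*log(0.01) + 4
#' @export
aicSSE <- function(sse, n_obs, k) {
  checkIC(sse, n_obs, k)
  if (sse == 0) { warning("SSE is 0; AIC is -Inf"); return(-Inf) }
  n_obs * log(sse / n_obs) + 2 * k
}

#' @rdname aicSSE
#' @export
bicSSE <- function(sse, n_obs, k) {
  checkIC(sse, n_obs, k)
  if (sse == 0) { warning("SSE is 0; BIC is -Inf"); return(-Inf) }
  n_obs * log(sse / n_obs) + k * log(n_obs)
}

checkIC <- function(sse, n_obs, k) {
  if (sse < 0) stop("sse must be >= 0")
  if (n_obs <= k) stop("n_obs must exceed the parameter count")
  invisible(NULL)
}

#' Compare the three candidate models across a cohort
#'
#' Builds the per-participant AIC/BIC table for the single-rate,
#' dual-rate and voluntary-correction fits, and summarises the pairwise
#' AIC differences against the voluntary-correction model (positive
#' values favour it) with participant-level bootstrap percentile
#' intervals.
#'
#' @param fits List, one element per participant, each a named list of
#'   `fit_result`s (`single`, `dual`, `vc`) on the identical retained
#'   strides — as produced by [fitAllModels()].
#' @param n_boot Bootstrap resamples for the difference intervals.
#' @param seed Seed for the bootstrap.
#' @return List with `table` (participant x model criteria) and
#'   `contrasts` (mean AIC difference and 95% interval for
#'   single - vc and dual - vc).
#' @export
compareModels <- function(fits, n_boot = 1000L, seed = 1L) {
  ks <- c(single = 2L, dual = 4L, vc = 5L)
  rows <- list()
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    n_obs <- unique(vapply(f[c("single", "dual", "vc")],
                           function(x) as.numeric(x$n_obs), 0))
    if (length(n_obs) != 1L)
      stop("models were not fit on identical retained strides for participant ",
           names(fits)[i] %||% i)
    for (m in c("single", "dual", "vc"))
      rows[[length(rows) + 1L]] <- data.frame(
        participant = names(fits)[i] %||% as.character(i), model = m,
        k = ks[[m]], n_obs = n_obs, sse = f[[m]]$sse, r2 = f[[m]]$r2,
        aic = aicSSE(f[[m]]$sse, n_obs, ks[[m]]),
        bic = bicSSE(f[[m]]$sse, n_obs, ks[[m]]),
        stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  wide <- function(m) tab$aic[tab$model == m]
  d_single <- wide("single") - wide("vc")
  d_dual <- wide("dual") - wide("vc")
  set.seed(seed)
  boot_ci <- function(d) {
    bm <- vapply(seq_len(n_boot), function(b)
      mean(d[sample.int(length(d), replace = TRUE)]), 0)
    stats::quantile(bm, c(0.025, 0.975), names = FALSE)
  }
  contrasts <- data.frame(
    contrast = c("single-vc", "dual-vc"),
    mean = c(mean(d_single), mean(d_dual)),
    rbind(boot_ci(d_single), boot_ci(d_dual)))
  names(contrasts)[3:4] <- c("lo95", "hi95")
  list(table = tab, contrasts = contrasts)
}

#' Model-recovery analysis
#'
#' Simulates noisy Adaptation Index datasets from each candidate model,
#' refits all three models to every simulation, and tallies how often the
#' generating model wins under AIC and under BIC. A criterion that
#' recovers its own generator (a diagonally dominant confusion matrix)
#' can be trusted for the model comparison; the mean diagonal decides
#' between AIC and BIC.
#'
#' @param n_sims Simulations per generating model.
#' @param gen_params Named list with elements `single`, `dual`, `vc`
#'   giving the generating parameter vectors.
#' @param noise_sd Observation noise SD (Adaptation Index units).
#' @param schedule A [phaseSchedule()].
#' @param options A [fitOptions()] used for every fit.
#' @param seed Integer seed; reproduces the matrix exactly.
#' @return A `recovery_matrix` list: `aic` and `bic` 3x3 count matrices
#'   (rows = generating model, columns = selected model), `n_sims`,
#'   `mean_diagonal` (named, per criterion), and `preferred_criterion`.
#' @export
modelRecovery <- function(n_sims = 100L,
                          gen_params = list(
                            single = c(A = 0.96, B = 0.017),
                            dual = c(Afast = 0.92, Bfast = 0.03,
                                     Aslow = 0.996, Bslow = 0.004),
                            vc = c(Afast = 0.92, Bfast = 0.03, Aslow = 0.996,
                                   Bslow = 0.004, Bexplicit = 0.2)),
                          noise_sd = 0.05, schedule = phaseSchedule(),
                          options = fitOptions(), seed = 1L) {
  if (n_sims < 1L) stop("n_sims must be >= 1")
  models <- c("single", "dual", "vc")
  if (!all(models %in% names(gen_params)))
    stop("gen_params needs elements single, dual, vc")
  g <- modelGrid(schedule)
  set.seed(seed)
  sim_seeds <- matrix(sample.int(2^31 - 2, 3L * n_sims), nrow = 3L,
                      dimnames = list(models, NULL))
  tally <- list(aic = matrix(0L, 3, 3, dimnames = list(models, models)),
                bic = matrix(0L, 3, 3, dimnames = list(models, models)))
  for (gen in models) {
    theta <- gen_params[[gen]]
    x <- modelOutput(gen, unname(theta), g$pert, g$fb)
    for (j in seq_len(n_sims)) {
      set.seed(sim_seeds[gen, j])
      y <- x + stats::rnorm(length(x), 0, noise_sd)
      opts <- options
      opts$seed <- sim_seeds[gen, j]
      fits <- fitAllModels(y, opts, schedule = schedule)
      n <- length(y)
      for (crit in c("aic", "bic")) {
        fun <- if (crit == "aic") aicSSE else bicSSE
        vals <- vapply(models, function(m)
          fun(fits[[m]]$sse, n, modelSpecs[[m]]$k), 0)
        win <- models[which.min(vals)]
        tally[[crit]][gen, win] <- tally[[crit]][gen, win] + 1L
      }
    }
  }
  md <- vapply(tally, function(m) mean(diag(m)) / n_sims, 0)
  structure(list(aic = tally$aic, bic = tally$bic, n_sims = n_sims,
                 mean_diagonal = md,
                 preferred_criterion = names(md)[which.max(md)]),
            class = "recovery_matrix")
}

#' @export
print.recovery_matrix <- function(x, ...) {
  cat("Model recovery (", x$n_sims, "sims per generating model)\nAIC:\n")
  print(x$aic)
  cat("BIC:\n")
  print(x$bic)
  cat(sprintf("mean diagonal: AIC %.2f, BIC %.2f -> %s preferred\n",
              x$mean_diagonal[["aic"]], x$mean_diagonal[["bic"]],
              toupper(x$preferred_criterion)))
  invisible(x)
}
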