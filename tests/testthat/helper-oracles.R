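# Independent stride-loop oracles for the learning models, coded directly
# from the update equations with explicit state vectors (kept deliberately
# separate from the package's simulation code paths).

oracle_vc <- function(Afast, Bfast, Aslow, Bslow, Bexplicit, pert, fb) {
  n <- length(pert)
  xf <- xs <- xe <- numeric(n + 1)
  x <- err <- numeric(n)
  for (s in seq_len(n)) {
    ximp <- xf[s] + xs[s]
    err[s] <- pert[s] - ximp
    x[s] <- xe[s] + ximp
    xf[s + 1] <- Afast * xf[s] + Bfast * err[s]
    xs[s + 1] <- Aslow * xs[s] + Bslow * err[s]
    xe[s + 1] <- if (s < n && fb[s + 1]) Bexplicit * err[s] else 0
  }
  list(x = x, xfast = xf[1:n], xslow = xs[1:n], xexplicit = xe[1:n],
       error = err)
}

oracle_single <- function(A, B, pert) {
  n <- length(pert)
  x <- numeric(n + 1)
  for (s in seq_len(n)) x[s + 1] <- A * x[s] + B * (pert[s] - x[s])
  x[1:n]
}

# random feasible parameter draws (bounds plus the ordering constraints)
random_vc_params <- function() {
  Afast <- runif(1, 0, 0.99)
  Aslow <- runif(1, Afast + 1e-4, 1)
  Bslow <- runif(1, 0, 0.15)
  Bfast <- runif(1, 5 * Bslow, 1)
  c(Afast = Afast, Bfast = Bfast, Aslow = Aslow, Bslow = Bslow,
    Bexplicit = runif(1))
}

# hand-coded Adaptation Index normalisation oracle: min of
# the first 10 retained Adaptation asymmetries / max of the first 10
# retained De-adaptation asymmetries
oracle_ai <- function(phase, sla, retained) {
  firstTen <- function(ph) {
    i <- which(phase == ph & retained)
    i[seq_len(min(10, length(i)))]
  }
  pA <- min(sla[firstTen("Adaptation")])
  pD <- max(sla[firstTen("Deadaptation")])
  ai <- rep(NA_real_, length(sla))
  ai[phase == "Adaptation"] <- (sla[phase == "Adaptation"] - pA) / abs(pA)
  ai[phase == "Deadaptation"] <- sla[phase == "Deadaptation"] / abs(pD)
  ai
}

# bare asymmetry series for preprocessing unit tests
make_asym <- function(phase, sla, baseline_corrected = FALSE) {
  out <- data.frame(phase = phase,
                    stride = unlist(lapply(rle(phase)$lengths, seq_len)),
                    sla = sla, retained = TRUE, feedback_on = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "baseline_corrected") <- baseline_corrected
  attr(out, "participant_id") <- "T01"
  attr(out, "group") <- "test"
  class(out) <- c("asymmetry_series", "data.frame")
  out
}

# balanced 2x2 long table from cell means
make_long <- function(n_per_group = c(control = 18L, stroke = 17L),
                      group_eff = 0, time_eff = 0, interaction = 0,
                      grand = 0.5, sd = 0.1) {
  rows <- list()
  for (g in names(n_per_group)) for (tp in c("FeedbackOn", "FeedbackOff")) {
    gc <- if (g == names(n_per_group)[1]) 0.5 else -0.5
    tc <- if (tp == "FeedbackOff") 0.5 else -0.5 # sort order: Off < On
    mu <- grand + group_eff * gc + time_eff * tc + interaction * gc * tc
    rows[[length(rows) + 1L]] <- data.frame(
      participant = paste0(g, seq_len(n_per_group[[g]])), group = g,
      timepoint = tp, value = rnorm(n_per_group[[g]], mu, sd),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
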