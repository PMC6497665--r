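SCENARIO_SCORES <- list(
  "P"         = -4:-1,
  "P+I"       = -4:0,
  "P+I+A"     = -4:4,
  "P+I+A+K"   = -4:5,
  "I+A"       = 0:4,
  "I+A+K"     = 0:5,
  "A"         = 1:4,
  "A+K"       = 1:5
)

#' Simulation scenarios
#'
#' Each of the eight scenarios allows a different part of the behaviour
#' scale: P peaceful behaviours (-4..-1), I ignoring (0), A aggressive
#' behaviours (1..4), K killing (5). P and P+I emulate encounters within
#' a nest, the others encounters between nests.
#'
#' @param name one of `"P"`, `"P+I"`, `"P+I+A"`, `"P+I+A+K"`, `"I+A"`,
#'   `"I+A+K"`, `"A"`, `"A+K"` (spaces and case are ignored).
#' @return object of class `etho_scenario` with `name` and
#'   `allowed_scores`.
#' @export
scenario <- function(name) {
  if (inherits(name, "etho_scenario")) return(name)
  key <- toupper(gsub("[[:space:]]", "", name))
  if (!key %in% names(SCENARIO_SCORES)) {
    stop("unknown scenario '", name, "'; available: ",
         paste(names(SCENARIO_SCORES), collapse = ", "))
  }
  structure(list(name = key, allowed_scores = as.integer(SCENARIO_SCORES[[key]])),
            class = "etho_scenario")
}

#' @export
print.etho_scenario <- function(x, ...) {
  cat("Scenario ", x$name, ": allowed scores {",
      paste(x$allowed_scores, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' @rdname scenario
#' @export
scenario_names <- function() names(SCENARIO_SCORES)

#' @rdname scenario
#' @param allowed_scores integer subset of -4..5 for an ad-hoc scenario
#'   outside the eight standard ones.
#' @export
custom_scenario <- function(allowed_scores, name = "custom") {
  allowed_scores <- as.integer(allowed_scores)
  if (!length(allowed_scores) || anyDuplicated(allowed_scores) ||
      !all(allowed_scores %in% -4:5)) {
    stop("allowed_scores must be a non-empty unique subset of -4..5")
  }
  structure(list(name = name, allowed_scores = sort(allowed_scores)),
            class = "etho_scenario")
}

# One simulated encounter: behaviours are drawn uniformly without
# replacement from the allowed set; each drawn behaviour receives a
# random duration; stop when (i) all seconds are assigned (remaining
# behaviours get 0 s), (ii) one behaviour is left (it gets the
# remainder), or (iii) killing is drawn (it is immediately assigned all
# remaining seconds). Duration rules: "remaining" draws U{1..remaining
# seconds}; "capped" draws U{1..t_obs} truncated to the remaining budget.
sim_one_durations <- function(allowed, t_obs, rule) {
  k <- length(allowed)
  d <- integer(k)
  ord <- if (k > 1L) sample.int(k) else 1L
  rem <- as.integer(t_obs)
  for (j in seq_len(k)) {
    i <- ord[j]
    if (allowed[i] == KILL_SCORE || j == k) {
      d[i] <- rem
      break
    }
    dur <- if (rule == "capped") min(sample.int(t_obs, 1L), rem)
           else sample.int(rem, 1L)
    d[i] <- dur
    rem <- rem - dur
    if (rem == 0L) break
  }
  d
}

#' Simulate one encounter duration profile
#'
#' @param scen a [scenario()] or scenario name.
#' @param t_obs encounter length in seconds (default 170).
#' @param rule duration rule: `"remaining"` (default) draws each
#'   behaviour's duration uniformly from 1..remaining seconds;
#'   `"capped"` draws uniformly from 1..`t_obs` and truncates to the
#'   remaining budget.
#' @return a [duration_profile()] totalling `t_obs` seconds with support
#'   inside the scenario's allowed scores.
#' @export
simulate_profile <- function(scen, t_obs = 170L,
                             rule = c("remaining", "capped")) {
  scen <- scenario(scen)
  rule <- match.arg(rule)
  d <- sim_one_durations(scen$allowed_scores, t_obs, rule)
  duration_profile(stats::setNames(d, scen$allowed_scores))
}

# Matrix of n simulated encounters (rows) x allowed scores (columns).
sim_durations_matrix <- function(allowed, n, t_obs, rule) {
  D <- matrix(0L, nrow = n, ncol = length(allowed))
  for (i in seq_len(n)) D[i, ] <- sim_one_durations(allowed, t_obs, rule)
  colnames(D) <- allowed
  D
}

#' Simulate a data set of averaged encounters
#'
#' Generates `n_averaged` pairing groups, each holding
#' `replicates_per_averaged` single-worker encounters of `t_obs`
#' seconds; the mean index vector over the replicates of one group
#' represents the mean behaviour of one colony pairing. All simulated
#' encounters are labelled internest (the simulations make no
#' intranest/internest distinction).
#'
#' @inheritParams simulate_profile
#' @param n_averaged number of averaged encounters (groups).
#' @param replicates_per_averaged replicate encounters per group
#'   (default 5).
#' @param seed optional integer seed for reproducibility.
#' @return list of [pairing_group()]s.
#' @examples
#' sim <- simulate_dataset("A", n_averaged = 3, seed = 1)
#' length(sim)  # 3 groups x 5 encounters
#' @export
simulate_dataset <- function(scen, n_averaged = 10000L,
                             replicates_per_averaged = 5L, t_obs = 170L,
                             rule = c("remaining", "capped"), seed = NULL) {
  scen <- scenario(scen)
  rule <- match.arg(rule)
  stopifnot(n_averaged >= 1, replicates_per_averaged >= 1, t_obs >= 1)
  if (!is.null(seed)) set.seed(seed)
  allowed <- scen$allowed_scores
  lapply(seq_len(n_averaged), function(g) {
    pid <- sprintf("sim%s_%05d", gsub("\\+", "", scen$name), g)
    encs <- lapply(seq_len(replicates_per_averaged), function(r) {
      d <- sim_one_durations(allowed, t_obs, rule)
      encounter(encounter_id = sprintf("%s_r%d", pid, r), pairing_id = pid,
                replicate = r, encounter_type = "internest",
                profiles = list(w1 = duration_profile(stats::setNames(d, allowed))),
                t_obs = t_obs)
    })
    pairing_group(encs)
  })
}

# Vectorised per-encounter statistics from a duration matrix.
matrix_stats <- function(D, allowed) {
  n <- nrow(D)
  nz <- allowed != 0L
  den <- rowSums(D[, nz, drop = FALSE])
  ai <- ifelse(den > 0, as.vector(D[, nz, drop = FALSE] %*% allowed[nz]) / den,
               NA_real_)
  pres <- D > 0L
  mmai <- do.call(pmax, lapply(seq_along(allowed),
                               function(j) ifelse(pres[, j], allowed[j], -Inf)))
  mmpi <- do.call(pmin, lapply(seq_along(allowed),
                               function(j) ifelse(pres[, j], allowed[j], Inf)))
  kill_col <- which(allowed == KILL_SCORE)
  list(ai = ai,
       mmai = mmai, mmpi = mmpi,
       d_agg = rowSums(D[, allowed > 0L, drop = FALSE]),
       d_pcf = rowSums(D[, allowed < 0L, drop = FALSE]),
       killed = if (length(kill_col)) D[, kill_col] > 0L else rep(FALSE, n))
}

# Vectorised MBI cascade on matrix_stats output.
matrix_mbi <- function(st, t) {
  agg <- st$d_agg > t
  pcf <- st$d_pcf > t
  out <- numeric(length(st$mmai))
  out[agg & !pcf] <- st$mmai[agg & !pcf]
  out[pcf & !agg] <- st$mmpi[pcf & !agg]
  out[agg & pcf] <- (st$mmai[agg & pcf] + st$mmpi[agg & pcf]) / 2
  out[st$killed] <- KILL_SCORE
  out
}

group_mean <- function(x, g) {
  ok <- !is.na(x)
  s <- rowsum(ifelse(ok, x, 0), g)
  n <- rowsum(as.numeric(ok), g)
  m <- s / n
  m[n == 0] <- NA_real_
  as.vector(m)
}

#' Simulate a scenario and summarise the behaviour indices
#'
#' Runs the encounter generator for one scenario, estimates the MBI time
#' thresholds from the simulated encounters by the scan-and-first-argmax
#' procedure (unless thresholds are supplied), averages the five indices
#' over the replicates of each group, and reports grand mean and SD per
#' index over all averaged encounters. Groups in which every replicate
#' has an undefined AI (all ignoring) are dropped from the AI mean; the
#' count is reported.
#'
#' The computation is vectorised over encounters and reproduces exactly
#' the per-encounter pipeline ([encounter_indices()] / [pairing_means()])
#' applied to [simulate_dataset()] output.
#'
#' @inheritParams simulate_dataset
#' @param t_agg,t_pcf optional fixed MBI thresholds (seconds); estimated
#'   from the simulated data when `NULL`.
#' @return object of class `simulation_summary`: list with `scenario`,
#'   `n_averaged`, `replicates`, `t_obs`, `rule`, `t_agg`, `t_pcf`,
#'   `mean` and `sd` (named over the five indices), `n_ai_missing`.
#' @export
summarize_simulation <- function(scen, n_averaged = 10000L,
                                 replicates_per_averaged = 5L, t_obs = 170L,
                                 rule = c("remaining", "capped"),
                                 t_agg = NULL, t_pcf = NULL, seed = NULL) {
  scen <- scenario(scen)
  rule <- match.arg(rule)
  if (!is.null(seed)) set.seed(seed)
  allowed <- scen$allowed_scores
  n <- n_averaged * replicates_per_averaged
  D <- sim_durations_matrix(allowed, n, t_obs, rule)
  g <- rep(seq_len(n_averaged), each = replicates_per_averaged)
  st <- matrix_stats(D, allowed)

  if (is.null(t_agg) || is.null(t_pcf)) {
    counts <- vapply(0:t_obs, function(tt) {
      v <- matrix_mbi(st, tt)
      c(sum(v > 0), sum(v < 0))
    }, numeric(2))
    curve <- structure(data.frame(t = 0:t_obs,
                                  n_aggressive = as.integer(counts[1, ]),
                                  n_peaceful = as.integer(counts[2, ])),
                       class = c("threshold_curve", "data.frame"))
    choice <- suppressWarnings(threshold_select(curve))
    if (is.null(t_agg)) t_agg <- choice$t_agg
    if (is.null(t_pcf)) t_pcf <- choice$t_pcf
  }

  per_index <- list(mmai = st$mmai, mbi_agg = matrix_mbi(st, t_agg),
                    ai = st$ai, mbi_pcf = matrix_mbi(st, t_pcf),
                    mmpi = st$mmpi)
  gm <- lapply(per_index, group_mean, g = g)
  structure(list(scenario = scen$name, n_averaged = n_averaged,
                 replicates = replicates_per_averaged, t_obs = t_obs,
                 rule = rule, t_agg = t_agg, t_pcf = t_pcf,
                 mean = vapply(gm, mean, numeric(1), na.rm = TRUE),
                 sd = vapply(gm, stats::sd, numeric(1), na.rm = TRUE),
                 n_ai_missing = sum(is.na(gm$ai))),
            class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, digits = 3, ...) {
  cat("Simulation ", x$scenario, ": ", x$n_averaged, " averaged encounters x ",
      x$replicates, " replicates x ", x$t_obs, " s (duration rule: ",
      x$rule, ")\n", sep = "")
  cat("MBI thresholds: t_agg = ", x$t_agg, ", t_pcf = ", x$t_pcf, "\n", sep = "")
  m <- rbind(mean = x$mean, sd = x$sd)
  print(round(m, digits))
  if (x$n_ai_missing > 0) {
    cat("AI undefined (all ignoring) in ", x$n_ai_missing,
        " averaged encounter(s); dropped from the AI mean\n", sep = "")
  }
  invisible(x)
}
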