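# Independent oracles and fixture builders used across the suite.
# These re-derive expected values by brute force / literal transcription
# and stay independent of the package code paths they check.

# Literal transcription of the MBI decision flowchart: nested queries,
# nothing shared with ethoindex::mbi().
oracle_mbi <- function(durations, t) {
  s <- as.integer(names(durations))
  d <- as.numeric(durations)
  if (any(s == 5L & d > 0)) return(5)
  highest <- max(s[d > 0]) + 0
  lowest <- min(s[d > 0]) + 0
  agg_seconds <- sum(d[s > 0])
  pcf_seconds <- sum(d[s < 0])
  if (agg_seconds > t) {
    if (pcf_seconds > t) (highest + lowest) / 2 else highest
  } else {
    if (pcf_seconds > t) lowest else 0
  }
}

# Exact two-sided Mann-Whitney p by full enumeration of all rank splits.
oracle_mwu_exact <- function(x, y) {
  n <- length(x); m <- length(y)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(x, y)
  mu <- n * m / 2
  u_obs <- u_stat(x, y)
  us <- apply(utils::combn(n + m, n), 2,
              function(i) u_stat(pooled[i], pooled[-i]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Step-down Holm by hand: sort, multiply by m..1, cumulative max, cap.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(cummax((m - seq_len(m) + 1) * p[o]), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force threshold choice: double loop over (t, encounter) using the
# oracle cascade, then first argmax.
oracle_threshold_choice <- function(profiles, t_range) {
  n_agg <- n_pcf <- integer(length(t_range))
  for (k in seq_along(t_range)) {
    vals <- vapply(profiles, oracle_mbi, numeric(1), t = t_range[k])
    n_agg[k] <- sum(vals > 0)
    n_pcf[k] <- sum(vals < 0)
  }
  list(t_agg = if (max(n_agg) == 0) t_range[1] else t_range[which.max(n_agg)],
       t_pcf = if (max(n_pcf) == 0) t_range[1] else t_range[which.max(n_pcf)],
       n_agg = n_agg, n_pcf = n_pcf)
}

# Quick fixture: a single-worker internest encounter from named durations.
make_enc <- function(durations, id = "e1", pairing = "pa", replicate = 1,
                     type = "internest", t_obs = sum(durations)) {
  encounter(encounter_id = id, pairing_id = pairing, replicate = replicate,
            encounter_type = type,
            profiles = list(w1 = duration_profile(durations)), t_obs = t_obs)
}

# A small valid two-encounter, two-worker ethogram data.frame for CSV tests.
make_ethogram_df <- function(t_obs = 20) {
  rows <- list()
  series <- list(
    e1 = list(wA = c(rep(-2, t_obs - 5), rep(3, 5)),
              wB = rep(-3, t_obs)),
    e2 = list(wA = c(rep(0, t_obs - 2), rep(5, 2)),
              wB = rep(1, t_obs)))
  for (eid in names(series)) {
    for (w in names(series[[eid]])) {
      rows[[paste(eid, w)]] <- data.frame(
        pairing_id = "p1", encounter_id = eid,
        replicate = match(eid, names(series)),
        encounter_type = "internest", day = 1L, worker = w,
        second = seq_len(t_obs), score = series[[eid]][[w]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
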