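#' Aggression Index (AI)
#'
#' The duration-weighted mean behaviour score over all seconds of tactile
#' interaction: `AI = sum(s_i * t_i) / T`, where `t_i` is the number of
#' seconds behaviour `i` (score `s_i`) was displayed and `T` is the total
#' number of interaction seconds. Ignoring (score 0) does not count as
#' interaction and is excluded from both numerator and denominator; all
#' other behaviours, peaceful and aggressive (including killing seconds),
#' are included.
#'
#' An encounter consisting entirely of ignoring has no defined AI and
#' returns `NA` (a distinct missing marker, not 0).
#'
#' @param x a [duration_profile()] or per-second score series.
#' @return numeric AI value, or `NA_real_` when no nonzero-score second
#'   exists.
#' @examples
#' ai(duration_profile(c(`-2` = 100, `0` = 60, `3` = 10)))  # -170/110
#' @export
ai <- function(x) {
  p <- as_profile(x)
  s <- profile_scores(p)
  nz <- s != 0L
  T_int <- sum(p[nz])
  if (T_int == 0L) return(NA_real_)
  sum(s[nz] * as.integer(p[nz])) / T_int
}

#' Maximum and minimum behaviour scores of an encounter
#'
#' `mmai()` returns the highest score displayed for at least one second —
#' the per-encounter ingredient of the Mean Maximum Aggression Index. It
#' can be negative when only peaceful behaviour occurred. `mmpi()` is its
#' peace counterpart: the lowest (most peaceful) score observed.
#'
#' @param x a [duration_profile()] or per-second score series.
#' @return integer score.
#' @export
mmai <- function(x) max(profile_scores(as_profile(x)))

#' @rdname mmai
#' @export
mmpi <- function(x) min(profile_scores(as_profile(x)))

#' Aggregate peaceful / aggressive durations of an encounter
#'
#' Counts the total seconds of aggressive behaviour (score > 0, killing
#' included), peaceful behaviour (score < 0) and ignoring (score 0), and
#' flags whether a kill occurred.
#'
#' @param x a [duration_profile()] or per-second score series.
#' @return list with `d_agg`, `d_pcf`, `d_ignore` (seconds) and `killed`.
#' @export
duration_summary <- function(x) {
  p <- as_profile(x)
  s <- profile_scores(p)
  d <- as.integer(p)
  list(d_agg = sum(d[s > 0L]), d_pcf = sum(d[s < 0L]),
       d_ignore = sum(d[s == 0L]), killed = any(s == KILL_SCORE))
}

#' Mean Behaviour Index (MBI) decision cascade
#'
#' The MBI buffers the extreme-value indices against episodic behaviour
#' with a time threshold `t` (seconds). The cascade:
#' \enumerate{
#'   \item killing occurred: MBI = 5;
#'   \item otherwise determine the encounter maximum (MMAI ingredient)
#'     and minimum (MMPI ingredient) scores and the aggregate aggressive
#'     and peaceful durations;
#'   \item aggressive duration > `t` and peaceful duration <= `t`
#'     (aggression dominated): MBI = encounter maximum;
#'   \item both durations <= `t` (ignoring dominated): MBI = 0;
#'   \item peaceful duration > `t` and aggressive duration <= `t`
#'     (peace dominated): MBI = encounter minimum;
#'   \item both durations > `t` (switching between distinct aggression
#'     and distinct peace): MBI = arithmetic mean of maximum and minimum.
#' }
#' All comparisons are strict ("larger than t"). With `t = 0` a single
#' second of any non-ignoring behaviour decides the branch; with `t`
#' equal to the encounter length every kill-free encounter scores 0.
#'
#' `MBI_agg` and `MBI_pcf` are this cascade evaluated at the two
#' empirically chosen thresholds, see [mbi_thresholds()].
#'
#' @param x a [duration_profile()] or per-second score series.
#' @param t time threshold in seconds, `0 <= t <= total seconds`.
#' @return numeric MBI value.
#' @examples
#' p <- duration_profile(c(`-2` = 100, `0` = 60, `3` = 10))
#' mbi(p, 15)   # -2  : peace dominated
#' mbi(p, 5)    # 0.5 : both exceeded the threshold
#' mbi(p, 120)  # 0   : ignoring dominated
#' @export
mbi <- function(x, t) {
  p <- as_profile(x)
  if (t < 0 || t > sum(p)) stop("t must be in [0, ", sum(p), "]")
  d <- duration_summary(p)
  if (d$killed) return(KILL_SCORE + 0)
  agg <- d$d_agg > t
  pcf <- d$d_pcf > t
  if (agg && !pcf) return(mmai(p) + 0)
  if (!agg && !pcf) return(0)
  if (pcf && !agg) return(mmpi(p) + 0)
  (mmai(p) + mmpi(p)) / 2
}

INDEX_NAMES <- c("mmai", "mbi_agg", "ai", "mbi_pcf", "mmpi")

# All five indices of one worker profile.
worker_indices <- function(profile, t_agg, t_pcf) {
  c(mmai = mmai(profile) + 0, mbi_agg = mbi(profile, t_agg),
    ai = ai(profile), mbi_pcf = mbi(profile, t_pcf),
    mmpi = mmpi(profile) + 0)
}

#' Index vector of one encounter
#'
#' Computes all five indices per worker and averages them across the
#' encounter's workers with equal weight. A worker whose AI is undefined
#' (all ignoring) is dropped from the AI mean only; if no worker has a
#' defined AI, the encounter AI is `NA`.
#'
#' @param enc an [encounter()].
#' @param t_agg,t_pcf time thresholds (seconds) for `MBI_agg`/`MBI_pcf`.
#' @return named numeric vector `mmai, mbi_agg, ai, mbi_pcf, mmpi`.
#' @export
index_vector <- function(enc, t_agg, t_pcf) {
  m <- vapply(enc$profiles, worker_indices, numeric(5),
              t_agg = t_agg, t_pcf = t_pcf)
  rowMeans(m, na.rm = TRUE) * ifelse(rowSums(!is.na(m)) > 0, 1, NA_real_)
}

#' Per-encounter index table
#'
#' @param x pairing groups, a single group, or a list of encounters.
#' @param t_agg,t_pcf time thresholds (seconds).
#' @return data.frame with one row per encounter: identifiers plus the
#'   five index columns and the aggregate durations.
#' @export
encounter_indices <- function(x, t_agg, t_pcf) {
  encs <- collect_encounters(x)
  rows <- lapply(encs, function(e) {
    v <- index_vector(e, t_agg, t_pcf)
    ds <- lapply(e$profiles, duration_summary)
    cbind(data.frame(pairing_id = as.character(e$pairing_id),
                     encounter_id = as.character(e$encounter_id),
                     replicate = e$replicate, encounter_type = e$encounter_type,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(v)),
          data.frame(d_agg = mean(vapply(ds, `[[`, 0, "d_agg")),
                     d_pcf = mean(vapply(ds, `[[`, 0, "d_pcf")),
                     killed = any(vapply(ds, `[[`, NA, "killed"))))
  })
  do.call(rbind, rows)
}

#' Pairing means of the behaviour indices
#'
#' Averages the encounter-level index vectors over the replicates of each
#' pairing (unweighted), mirroring the averaged-encounter procedure of
#' the assay: worker means first, then the replicate mean represents the
#' colony pairing. Encounters with undefined AI are dropped from the AI
#' mean; the number dropped is reported in the `n_ai_missing` column.
#'
#' @param x pairing groups (or an encounter index table from
#'   [encounter_indices()]).
#' @param t_agg,t_pcf time thresholds (seconds); unused when `x` is
#'   already an index table.
#' @return data.frame with one row per pairing: the five index means,
#'   `n_replicates` and `n_ai_missing`.
#' @export
pairing_means <- function(x, t_agg = NULL, t_pcf = NULL) {
  tab <- if (is.data.frame(x)) x else encounter_indices(x, t_agg, t_pcf)
  out <- lapply(split(tab, tab$pairing_id), function(sub) {
    v <- colMeans(sub[INDEX_NAMES], na.rm = TRUE)
    v[colSums(!is.na(sub[INDEX_NAMES])) == 0] <- NA_real_
    cbind(data.frame(pairing_id = sub$pairing_id[1],
                     encounter_type = sub$encounter_type[1],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(v)),
          data.frame(n_replicates = nrow(sub),
                     n_ai_missing = sum(is.na(sub$ai))))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fraction of encounters with near-tied aggressive and peaceful time
#'
#' When aggressive and peaceful interactions accumulate similar
#' durations they cancel in the AI; this statistic reports how often
#' that happens: the fraction of encounters whose aggregate aggressive
#' and peaceful durations differ by less than `delta` seconds (strict).
#'
#' @param x pairing groups, encounters, or an [encounter_indices()] table.
#' @param delta near-tie width in seconds (default 10).
#' @return fraction in \[0, 1\].
#' @export
near_tie_fraction <- function(x, delta = 10) {
  tab <- if (is.data.frame(x)) x else {
    encs <- collect_encounters(x)
    do.call(rbind, lapply(encs, function(e) {
      ds <- lapply(e$profiles, duration_summary)
      data.frame(d_agg = mean(vapply(ds, `[[`, 0, "d_agg")),
                 d_pcf = mean(vapply(ds, `[[`, 0, "d_pcf")))
    }))
  }
  mean(abs(tab$d_agg - tab$d_pcf) < delta)
}
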