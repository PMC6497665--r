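# Killing is coded 5 on the adapted scale and is absorbing: once scored,
# every later second of the encounter belongs to it.
KILL_SCORE <- 5L

ETHOGRAM_COLS <- c("pairing_id", "encounter_id", "replicate", "encounter_type",
                   "day", "worker", "second", "score")
PROFILE_COLS <- c("pairing_id", "encounter_id", "replicate", "encounter_type",
                  "worker", "score", "seconds")

#' Duration profile of an encounter
#'
#' A duration profile maps each behaviour score to the total number of
#' seconds it was displayed. It is the sufficient statistic for all five
#' behaviour indices: the indices depend only on how long each score was
#' shown, not on the order of behaviours (killing ordering is already
#' folded in, since everything after a kill is scored as killing).
#'
#' @param durations named non-negative numeric vector; names are integer
#'   scores, values seconds.
#' @return object of class `duration_profile`: a named integer vector of
#'   seconds per score, sorted by score, zero entries dropped.
#' @examples
#' duration_profile(c(`-2` = 100, `0` = 60, `3` = 10))
#' @export
duration_profile <- function(durations) {
  if (is.null(names(durations))) stop("durations must be named by score")
  s <- as.integer(names(durations))
  if (anyNA(s)) stop("profile names must be integer scores")
  d <- as.integer(durations)
  if (any(d < 0)) stop("durations must be non-negative")
  d <- tapply(d, s, sum)  # merge duplicate score entries
  d <- d[d > 0]
  o <- order(as.integer(names(d)))
  structure(as.integer(d[o]), names = names(d)[o], class = "duration_profile")
}

#' @export
print.duration_profile <- function(x, ...) {
  cat("Duration profile (", sum(x), " s):\n", sep = "")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Convert a per-second score series to a duration profile
#'
#' @param series integer vector of scores, one per second.
#' @return a [duration_profile()].
#' @examples
#' to_profile(c(rep(-2, 100), rep(0, 60), rep(3, 10)))
#' @export
to_profile <- function(series) {
  if (inherits(series, "duration_profile")) return(series)
  tab <- table(as.integer(series))
  duration_profile(stats::setNames(as.integer(tab), names(tab)))
}

#' @rdname to_profile
#' @export
as_profile <- to_profile

profile_scores <- function(profile) as.integer(names(profile))

#' Validate (and optionally repair) a per-second score series
#'
#' Checks that a series has the expected length, that every score is on
#' the scale, and that killing is absorbing: once the kill score occurs,
#' every later second must carry it (observation stops at a kill, so the
#' remaining time is attributed to killing). Violations are rejected, not
#' silently repaired; `repair_kill = TRUE` forward-fills the kill score
#' instead.
#'
#' @param series integer vector of per-second scores.
#' @param t_obs expected length in seconds (default 170).
#' @param scale an [etho_scale()] giving the admissible scores.
#' @param repair_kill forward-fill the kill score after its first
#'   occurrence instead of erroring.
#' @return the validated (possibly repaired) integer series.
#' @export
validate_series <- function(series, t_obs = 170L, scale = adapted_scale(),
                            repair_kill = FALSE) {
  series <- as.integer(series)
  if (length(series) != t_obs) {
    stop("series has ", length(series), " seconds, expected ", t_obs)
  }
  bad <- !(series %in% scale$entries$score)
  if (any(bad)) {
    stop("score ", series[which(bad)[1]], " at second ", which(bad)[1],
         " is not on the scale")
  }
  k <- which(series == KILL_SCORE)
  if (length(k) && any(series[seq(k[1], length(series))] != KILL_SCORE)) {
    if (repair_kill) {
      series[seq(k[1], length(series))] <- KILL_SCORE
    } else {
      off <- k[1] + which(series[seq(k[1], length(series))] != KILL_SCORE)[1] - 1L
      stop("killing at second ", k[1], " is not absorbing: score ",
           series[off], " at second ", off)
    }
  }
  series
}

#' Construct a one-on-one encounter
#'
#' An encounter holds the scored behaviour of one or two workers, either
#' as per-second series (observed data) or directly as duration profiles
#' (simulated data). Profiles are derived from series when both are
#' given implicitly.
#'
#' @param encounter_id,pairing_id identifiers.
#' @param replicate replicate index within the pairing.
#' @param encounter_type `"intranest"` or `"internest"`.
#' @param series named list of 1 or 2 integer per-second series, or NULL.
#' @param profiles named list of [duration_profile()]s; computed from
#'   `series` when omitted.
#' @param day optional integer day of the assay.
#' @param t_obs scored encounter length in seconds.
#' @param scale scoring scale used for validation of series.
#' @param repair_kill passed to [validate_series()].
#' @return object of class `encounter`.
#' @export
encounter <- function(encounter_id, pairing_id, replicate = 1L,
                      encounter_type = c("internest", "intranest"),
                      series = NULL, profiles = NULL, day = NA_integer_,
                      t_obs = 170L, scale = adapted_scale(),
                      repair_kill = FALSE) {
  encounter_type <- match.arg(encounter_type)
  if (is.null(series) && is.null(profiles)) {
    stop("an encounter needs series or profiles")
  }
  if (!is.null(series)) {
    if (!length(series) %in% 1:2) {
      stop("an encounter must have 1 or 2 workers, got ", length(series))
    }
    series <- lapply(series, validate_series, t_obs = t_obs, scale = scale,
                     repair_kill = repair_kill)
    if (is.null(profiles)) profiles <- lapply(series, to_profile)
  }
  if (!length(profiles) %in% 1:2) {
    stop("an encounter must have 1 or 2 workers, got ", length(profiles))
  }
  profiles <- lapply(profiles, function(p) {
    p <- as_profile(p)
    if (sum(p) != t_obs) {
      stop("profile totals ", sum(p), " s, expected ", t_obs)
    }
    p
  })
  if (is.null(names(profiles))) names(profiles) <- paste0("w", seq_along(profiles))
  structure(list(encounter_id = encounter_id, pairing_id = pairing_id,
                 replicate = as.integer(replicate),
                 encounter_type = encounter_type, day = day,
                 series = series, profiles = profiles, t_obs = as.integer(t_obs)),
            class = "encounter")
}

#' @export
print.encounter <- function(x, ...) {
  cat("Encounter ", x$encounter_id, " (pairing ", x$pairing_id, ", ",
      x$encounter_type, ", ", length(x$profiles), " worker(s), ",
      x$t_obs, " s)\n", sep = "")
  invisible(x)
}

#' Group replicate encounters of one colony pairing
#'
#' @param encounters list of [encounter()]s sharing `pairing_id` and
#'   `encounter_type`.
#' @return object of class `pairing_group`.
#' @export
pairing_group <- function(encounters) {
  if (!length(encounters)) stop("a pairing group needs >= 1 replicate")
  pid <- unique(vapply(encounters, function(e) as.character(e$pairing_id), ""))
  typ <- unique(vapply(encounters, function(e) e$encounter_type, ""))
  if (length(pid) != 1L) stop("replicates mix pairing ids: ", paste(pid, collapse = ", "))
  if (length(typ) != 1L) stop("replicates mix encounter types within pairing ", pid)
  structure(list(pairing_id = pid, encounter_type = typ, encounters = encounters),
            class = "pairing_group")
}

#' @export
print.pairing_group <- function(x, ...) {
  cat("Pairing ", x$pairing_id, " (", x$encounter_type, "): ",
      length(x$encounters), " replicate encounter(s)\n", sep = "")
  invisible(x)
}

# Flatten a list of pairing groups (or encounters) into a list of encounters.
collect_encounters <- function(x) {
  if (inherits(x, "encounter")) return(list(x))
  if (inherits(x, "pairing_group")) return(x$encounters)
  if (is.list(x)) return(do.call(c, lapply(x, collect_encounters)))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as encounters")
}

normalise_minus <- function(x) {
  # typographic minus signs (U+2212, U+2013) occur in hand-edited files
  gsub("−|–", "-", as.character(x))
}

#' Read a long-format ethogram CSV
#'
#' One row per scored second and worker, with header
#' `pairing_id,encounter_id,replicate,encounter_type,day,worker,second,score`.
#' Every (encounter, worker) must contribute exactly `t_obs` rows covering
#' seconds 1..`t_obs`. Rows violating the scale, missing or duplicated
#' seconds, and non-absorbing killing are rejected with a row-level
#' message (rows counted including the header). The 10 s acclimatisation
#' window is assumed already removed upstream; seconds are 1-based.
#'
#' @param path CSV file path.
#' @param scale an [etho_scale()]; scores are checked against it.
#' @param t_obs scored seconds per worker (default 170).
#' @param translate apply the scale's translation map to the scores
#'   before validation (for data coded on an original scale).
#' @param repair_kill forward-fill the kill score instead of rejecting
#'   non-absorbing killing.
#' @return list of [pairing_group()]s.
#' @export
read_ethogram <- function(path, scale = adapted_scale(), t_obs = 170L,
                          translate = FALSE, repair_kill = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!identical(names(df), ETHOGRAM_COLS)) {
    stop("bad ethogram header: expected ", paste(ETHOGRAM_COLS, collapse = ","))
  }
  if (!nrow(df)) return(list())
  df$second <- as.integer(df$second)
  df$replicate <- as.integer(df$replicate)
  df$score <- as.integer(normalise_minus(df$score))
  df$day <- suppressWarnings(as.integer(df$day))
  if (translate) df$score <- translate_scale(df$score, scale)
  row_no <- seq_len(nrow(df)) + 1L  # file row numbers including header

  bad <- !(df$score %in% scale$entries$score)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("row ", row_no[i], ": score ", df$score[i], " is not on the scale")
  }
  key <- paste(df$encounter_id, df$worker, sep = "\r")
  dup <- duplicated(paste(key, df$second, sep = "\r"))
  if (any(dup)) {
    i <- which(dup)[1]
    stop("row ", row_no[i], ": duplicate second ", df$second[i],
         " for encounter ", df$encounter_id[i], " worker ", df$worker[i])
  }

  groups <- list()
  for (eid in unique(df$encounter_id)) {
    sub <- df[df$encounter_id == eid, ]
    series <- list()
    for (w in unique(sub$worker)) {
      ws <- sub[sub$worker == w, ]
      missing <- setdiff(seq_len(t_obs), ws$second)
      if (length(missing) || nrow(ws) != t_obs) {
        stop("encounter ", eid, " worker ", w, ": expected seconds 1..",
             t_obs, if (length(missing)) paste0(", missing second ", missing[1])
             else paste0(", got ", nrow(ws), " rows"))
      }
      series[[w]] <- ws$score[order(ws$second)]
    }
    first <- sub[1, ]
    enc <- encounter(encounter_id = eid, pairing_id = first$pairing_id,
                     replicate = first$replicate,
                     encounter_type = first$encounter_type,
                     series = series, day = first$day, t_obs = t_obs,
                     scale = scale, repair_kill = repair_kill)
    groups[[first$pairing_id]] <- c(groups[[first$pairing_id]], list(enc))
  }
  unname(lapply(groups, pairing_group))
}

#' Write pairing groups as a long-format ethogram CSV
#'
#' Inverse of [read_ethogram()]: writes one row per worker and second.
#' Requires encounters built from per-second series (observed data);
#' profile-only encounters are written with [write_profiles()].
#'
#' @param groups list of [pairing_group()]s (or encounters).
#' @param path output CSV path.
#' @export
write_ethogram <- function(groups, path) {
  encs <- collect_encounters(groups)
  rows <- lapply(encs, function(e) {
    if (is.null(e$series)) {
      stop("encounter ", e$encounter_id, " has no per-second series; ",
           "use write_profiles()")
    }
    do.call(rbind, lapply(names(e$series), function(w) {
      data.frame(pairing_id = e$pairing_id, encounter_id = e$encounter_id,
                 replicate = e$replicate, encounter_type = e$encounter_type,
                 day = e$day, worker = w, second = seq_along(e$series[[w]]),
                 score = e$series[[w]], stringsAsFactors = FALSE)
    }))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(ncol = length(ETHOGRAM_COLS), nrow = 0)),
                    ETHOGRAM_COLS)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write wide-format duration-profile CSVs
#'
#' Wide format has one row per (worker, score) with header
#' `pairing_id,encounter_id,replicate,encounter_type,worker,score,seconds`.
#'
#' @param path CSV file path.
#' @param t_obs seconds per encounter; profile totals are checked.
#' @return `read_profiles`: list of [pairing_group()]s.
#' @export
read_profiles <- function(path, t_obs = 170L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!identical(names(df), PROFILE_COLS)) {
    stop("bad profile header: expected ", paste(PROFILE_COLS, collapse = ","))
  }
  df$score <- as.integer(normalise_minus(df$score))
  df$seconds <- as.integer(df$seconds)
  df$replicate <- as.integer(df$replicate)
  groups <- list()
  for (eid in unique(df$encounter_id)) {
    sub <- df[df$encounter_id == eid, ]
    profs <- lapply(split(sub, sub$worker), function(ws) {
      duration_profile(stats::setNames(ws$seconds, ws$score))
    })
    first <- sub[1, ]
    enc <- encounter(encounter_id = eid, pairing_id = first$pairing_id,
                     replicate = first$replicate,
                     encounter_type = first$encounter_type,
                     profiles = profs, t_obs = t_obs)
    groups[[first$pairing_id]] <- c(groups[[first$pairing_id]], list(enc))
  }
  unname(lapply(groups, pairing_group))
}

#' @rdname read_profiles
#' @param groups list of [pairing_group()]s (or encounters).
#' @export
write_profiles <- function(groups, path) {
  encs <- collect_encounters(groups)
  rows <- lapply(encs, function(e) {
    do.call(rbind, lapply(names(e$profiles), function(w) {
      p <- e$profiles[[w]]
      data.frame(pairing_id = e$pairing_id, encounter_id = e$encounter_id,
                 replicate = e$replicate, encounter_type = e$encounter_type,
                 worker = w, score = profile_scores(p),
                 seconds = as.integer(p), stringsAsFactors = FALSE)
    }))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(ncol = length(PROFILE_COLS), nrow = 0)),
                    PROFILE_COLS)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
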