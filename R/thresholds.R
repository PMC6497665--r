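#' Classify an index value as aggressive, peaceful or neutral
#'
#' Values above zero are aggressive, below zero peaceful, exactly zero
#' neutral.
#'
#' @param x numeric vector of index values.
#' @return character vector in `{"aggressive","peaceful","neutral"}`.
#' @export
classify <- function(x) {
  ifelse(is.na(x), NA_character_,
         ifelse(x > 0, "aggressive", ifelse(x < 0, "peaceful", "neutral")))
}

# Worker-level cascade ingredients of one encounter, computed once so a
# threshold scan never touches the profiles again.
worker_cascade_stats <- function(e) {
  t(vapply(e$profiles, function(p) {
    d <- duration_summary(p)
    c(killed = as.numeric(d$killed), d_agg = d$d_agg, d_pcf = d$d_pcf,
      mmai = mmai(p), mmpi = mmpi(p))
  }, numeric(5)))
}

# Per-worker MBI at threshold t from precomputed worker stats; rows are
# workers. Worker cascades are evaluated individually, then averaged.
mbi_at <- function(stats_mat, t) {
  killed <- stats_mat[, "killed"] > 0
  agg <- stats_mat[, "d_agg"] > t
  pcf <- stats_mat[, "d_pcf"] > t
  out <- numeric(nrow(stats_mat))
  out[agg & !pcf] <- stats_mat[agg & !pcf, "mmai"]
  out[pcf & !agg] <- stats_mat[pcf & !agg, "mmpi"]
  both <- agg & pcf
  out[both] <- (stats_mat[both, "mmai"] + stats_mat[both, "mmpi"]) / 2
  out[killed] <- KILL_SCORE
  out
}

#' Scan the time threshold and count classified encounters
#'
#' Evaluates the MBI cascade for every threshold `t` in `t_range` and
#' counts, per `t`, the encounters classified aggressive (MBI > 0) and
#' peaceful (MBI < 0). Classification happens at the encounter level
#' (after worker averaging), before replicate averaging. The thresholds
#' are meant to be determined on internest encounters only; intranest
#' encounters present in `x` are excluded with a warning.
#'
#' @param x pairing groups or encounters.
#' @param t_range integer thresholds to scan (default `0:t_obs`).
#' @return a `threshold_curve`: data.frame with columns `t`,
#'   `n_aggressive`, `n_peaceful`.
#' @export
threshold_scan <- function(x, t_range = NULL) {
  encs <- collect_encounters(x)
  if (!length(encs)) stop("no encounters to scan")
  intra <- vapply(encs, function(e) e$encounter_type == "intranest", NA)
  if (any(intra)) {
    warning("dropping ", sum(intra), " intranest encounter(s) from threshold scan")
    encs <- encs[!intra]
    if (!length(encs)) stop("no internest encounters to scan")
  }
  if (is.null(t_range)) t_range <- 0:max(vapply(encs, `[[`, 0L, "t_obs"))
  wstats <- lapply(encs, worker_cascade_stats)
  counts <- vapply(t_range, function(tt) {
    v <- vapply(wstats, function(w) mean(mbi_at(w, tt)), numeric(1))
    c(sum(v > 0), sum(v < 0))
  }, numeric(2))
  structure(data.frame(t = as.integer(t_range),
                       n_aggressive = as.integer(counts[1, ]),
                       n_peaceful = as.integer(counts[2, ])),
            class = c("threshold_curve", "data.frame"))
}

#' Select the MBI time thresholds from a scan curve
#'
#' The threshold for `MBI_agg` is the lowest `t` at which the number of
#' aggressive internest encounters reaches its maximum over the scan
#' range; the threshold for `MBI_pcf` is defined analogously on the
#' peaceful count. When a maximum count is 0 (no encounter of that class
#' exists at any threshold) the convention `t = 0` is returned with a
#' warning.
#'
#' @param curve a `threshold_curve` from [threshold_scan()].
#' @return a `threshold_choice`: list with `t_agg`, `t_pcf`,
#'   `max_n_agg`, `max_n_pcf` and the curve.
#' @export
threshold_select <- function(curve) {
  first_argmax <- function(n, what) {
    m <- max(n)
    if (m == 0) {
      warning("no ", what, " encounter at any threshold; returning t = 0")
      return(list(t = curve$t[1], max = 0L))
    }
    list(t = curve$t[which.max(n)], max = m)
  }
  a <- first_argmax(curve$n_aggressive, "aggressive")
  p <- first_argmax(curve$n_peaceful, "peaceful")
  structure(list(t_agg = a$t, t_pcf = p$t,
                 max_n_agg = a$max, max_n_pcf = p$max, curve = curve),
            class = "threshold_choice")
}

#' @export
print.threshold_choice <- function(x, ...) {
  cat("MBI time thresholds (first t attaining the maximum count):\n")
  cat(sprintf("  t_agg = %d (%d aggressive encounter(s))\n", x$t_agg, x$max_n_agg))
  cat(sprintf("  t_pcf = %d (%d peaceful encounter(s))\n", x$t_pcf, x$max_n_pcf))
  invisible(x)
}

#' Estimate MBI thresholds from data
#'
#' Convenience wrapper: scan then select.
#'
#' @inheritParams threshold_scan
#' @return a `threshold_choice`.
#' @export
mbi_thresholds <- function(x, t_range = NULL) {
  threshold_select(threshold_scan(x, t_range))
}

#' @export
plot.threshold_curve <- function(x, choice = NULL, ...) {
  graphics::plot(x$t, x$n_aggressive, type = "s", col = "firebrick",
                 xlab = "time threshold t [s]",
                 ylab = "encounters classified",
                 ylim = range(0, x$n_aggressive, x$n_peaceful), ...)
  graphics::lines(x$t, x$n_peaceful, type = "s", col = "steelblue")
  if (!is.null(choice)) {
    graphics::abline(v = choice$t_agg, col = "firebrick", lty = 2)
    graphics::abline(v = choice$t_pcf, col = "steelblue", lty = 2)
  }
  graphics::legend("topright", c("aggressive", "peaceful"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}

#' Write a threshold curve as CSV
#'
#' @param curve a `threshold_curve`.
#' @param path output path; header `t,n_aggressive,n_peaceful`.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
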