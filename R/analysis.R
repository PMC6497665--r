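#' Fit the behaviour-index analysis to a set of encounters
#'
#' The central entry point: takes scored encounters (pairing groups from
#' [read_ethogram()], [read_profiles()] or [simulate_dataset()]),
#' determines the two MBI time thresholds empirically from the internest
#' encounters (scan over all t, first t attaining the maximum number of
#' aggressive resp. peaceful encounters) unless fixed thresholds are
#' supplied, and computes all five behaviour indices at encounter level
#' and as pairing means.
#'
#' @param x pairing groups, encounters, or a list of either.
#' @param t_agg,t_pcf fixed MBI thresholds in seconds; when `NULL` they
#'   are estimated from the data.
#' @param t_range thresholds to scan when estimating (default
#'   `0:t_obs`).
#' @return object of class `index_analysis` with components
#'   `encounters` (per-encounter index table), `pairings` (pairing
#'   means), `t_agg`, `t_pcf`, `thresholds` (the `threshold_choice`, or
#'   `NULL` when thresholds were supplied), `near_tie` (fraction of
#'   encounters whose aggressive and peaceful durations differ by < 10
#'   s) and `call`.
#' @examples
#' sim <- simulate_dataset("P+I+A", n_averaged = 20, seed = 1)
#' fit <- index_analysis(sim)
#' coef(fit)
#' summary(fit)
#' @export
index_analysis <- function(x, t_agg = NULL, t_pcf = NULL, t_range = NULL) {
  encs <- collect_encounters(x)
  if (!length(encs)) stop("no encounters")
  choice <- NULL
  if (is.null(t_agg) || is.null(t_pcf)) {
    choice <- mbi_thresholds(encs, t_range)
    if (is.null(t_agg)) t_agg <- choice$t_agg
    if (is.null(t_pcf)) t_pcf <- choice$t_pcf
  }
  etab <- encounter_indices(encs, t_agg, t_pcf)
  ptab <- pairing_means(etab)
  ptab$t_agg <- t_agg
  ptab$t_pcf <- t_pcf
  structure(list(encounters = etab, pairings = ptab,
                 t_agg = t_agg, t_pcf = t_pcf, thresholds = choice,
                 near_tie = near_tie_fraction(etab),
                 call = match.call()),
            class = "index_analysis")
}

#' @export
print.index_analysis <- function(x, digits = 3, ...) {
  cat("Behaviour-index analysis\n")
  cat("  ", nrow(x$encounters), " encounter(s) in ", nrow(x$pairings),
      " pairing(s)\n", sep = "")
  cat("  MBI thresholds: t_agg = ", x$t_agg, " s, t_pcf = ", x$t_pcf, " s",
      if (!is.null(x$thresholds)) " (estimated)" else " (fixed)", "\n",
      sep = "")
  cat("  Grand means over pairings:\n")
  print(round(colMeans(x$pairings[INDEX_NAMES], na.rm = TRUE), digits))
  invisible(x)
}

#' @export
coef.index_analysis <- function(object, ...) {
  c(t_agg = object$t_agg, t_pcf = object$t_pcf)
}

#' @export
summary.index_analysis <- function(object, ...) {
  grand <- colMeans(object$pairings[INDEX_NAMES], na.rm = TRUE)
  grand_sd <- vapply(object$pairings[INDEX_NAMES], stats::sd, numeric(1),
                     na.rm = TRUE)
  by_type <- table(vapply(split(object$pairings,
                                object$pairings$encounter_type),
                          nrow, 0L))
  cls <- table(factor(classify(object$encounters$mbi_agg),
                      levels = c("aggressive", "neutral", "peaceful")))
  structure(list(fit = object, grand = grand, grand_sd = grand_sd,
                 n_encounters = nrow(object$encounters),
                 n_pairings = nrow(object$pairings),
                 n_ai_missing = sum(is.na(object$encounters$ai)),
                 n_killed = sum(object$encounters$killed),
                 mbi_agg_classes = cls,
                 near_tie = object$near_tie),
            class = "summary.index_analysis")
}

#' @export
print.summary.index_analysis <- function(x, digits = 3, ...) {
  print(x$fit)
  cat("  Index SD over pairings:\n")
  print(round(x$grand_sd, digits))
  cat("  Encounters: ", x$n_encounters,
      " (killed: ", x$n_killed,
      ", AI undefined: ", x$n_ai_missing, ")\n", sep = "")
  cat("  MBI_agg classification of encounters: ",
      paste(names(x$mbi_agg_classes), x$mbi_agg_classes, collapse = ", "),
      "\n", sep = "")
  cat("  Near-tied encounters (|d_agg - d_pcf| < 10 s): ",
      round(100 * x$near_tie, 1), "%\n", sep = "")
  invisible(x)
}

#' @export
plot.index_analysis <- function(x, ...) {
  if (!is.null(x$thresholds)) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
    plot(x$thresholds$curve, choice = x$thresholds,
         main = "Threshold scan")
  }
  m <- x$pairings[INDEX_NAMES]
  graphics::boxplot(m, ylab = "index value [score units]",
                    main = "Pairing means", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Write an index report CSV
#'
#' One row per pairing mean and (optionally) per encounter, with header
#' `pairing_id,level,mmai,mbi_agg,ai,mbi_pcf,mmpi,n_replicates,t_agg,t_pcf`.
#'
#' @param fit an `index_analysis`.
#' @param path output path.
#' @param encounters also write encounter-level rows.
#' @export
write_index_report <- function(fit, path, encounters = FALSE) {
  p <- fit$pairings
  rows <- data.frame(pairing_id = p$pairing_id, level = "pairing_mean",
                     p[INDEX_NAMES], n_replicates = p$n_replicates,
                     t_agg = fit$t_agg, t_pcf = fit$t_pcf,
                     stringsAsFactors = FALSE)
  if (encounters) {
    e <- fit$encounters
    rows <- rbind(data.frame(pairing_id = e$pairing_id, level = "encounter",
                             e[INDEX_NAMES], n_replicates = 1L,
                             t_agg = fit$t_agg, t_pcf = fit$t_pcf,
                             stringsAsFactors = FALSE),
                  rows)
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
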