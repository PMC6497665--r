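#' Anderson-Darling normality check
#'
#' Thin wrapper over [nortest::ad.test()]; requires n > 7.
#'
#' @param values numeric sample.
#' @return `htest` object with statistic `A` and `p.value`.
#' @export
anderson_darling <- function(values) nortest::ad.test(values)

#' Spearman rank correlation matrix of an index table
#'
#' @param index_table data.frame (or matrix) whose numeric columns are
#'   index values; non-numeric columns are dropped.
#' @param use observation handling, passed to [stats::cor()]; defaults to
#'   pairwise complete observations (AI may be missing).
#' @return symmetric rho matrix.
#' @export
spearman_matrix <- function(index_table, use = "pairwise.complete.obs") {
  m <- as.matrix(index_table[vapply(index_table, is.numeric, NA)])
  stats::cor(m, method = "spearman", use = use)
}

#' Pairwise Wilcoxon-Mann-Whitney p-values between index columns
#'
#' Two-sided; exact for small samples without ties, otherwise the normal
#' approximation with tie correction (the [stats::wilcox.test()]
#' defaults). Missing values are dropped per column.
#'
#' @inheritParams spearman_matrix
#' @return symmetric matrix of two-sided p-values (diagonal `NA`).
#' @export
pairwise_mwu <- function(index_table) {
  cols <- index_table[vapply(index_table, is.numeric, NA)]
  k <- length(cols)
  p <- matrix(NA_real_, k, k, dimnames = list(names(cols), names(cols)))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      x <- cols[[i]][!is.na(cols[[i]])]
      y <- cols[[j]][!is.na(cols[[j]])]
      p[i, j] <- p[j, i] <-
        suppressWarnings(stats::wilcox.test(x, y)$p.value)
    }
  }
  p
}

#' Bonferroni-Holm correction
#'
#' Step-down Holm adjustment with monotonicity enforcement, capped at 1
#' (delegates to [stats::p.adjust()]).
#'
#' @param p numeric vector of raw p-values.
#' @param n family size; defaults to `length(p)`.
#' @return adjusted p-values, same order as input.
#' @export
holm_adjust <- function(p, n = length(p)) stats::p.adjust(p, method = "holm", n = n)

#' Compare behaviour indices of one data block
#'
#' For every pair among the five indices: Spearman rank correlation (rho
#' and its p-value) between the pairing-level values, and a two-sided
#' Wilcoxon-Mann-Whitney test of the difference between the index means.
#' Both p-value families (10 pairs each) are Bonferroni-Holm corrected
#' within the block.
#'
#' @param x an `index_analysis` fit, a pairing-means table, or any
#'   data.frame containing the index columns.
#' @param indices columns to compare (default the five indices).
#' @return object of class `index_comparison`: data.frame with one row
#'   per pair (`index_a`, `index_b`, `rho`, `p_rho`, `p_rho_holm`,
#'   `p_mwu`, `p_mwu_holm`), with the per-index means and family size as
#'   attributes.
#' @export
compare_indices <- function(x, indices = INDEX_NAMES) {
  tab <- if (inherits(x, "index_analysis")) x$pairings else x
  if (!all(indices %in% names(tab))) {
    stop("missing index columns: ",
         paste(setdiff(indices, names(tab)), collapse = ", "))
  }
  cols <- tab[indices]
  pairs <- utils::combn(indices, 2)
  rows <- apply(pairs, 2, function(pr) {
    a <- cols[[pr[1]]]; b <- cols[[pr[2]]]
    ok <- !is.na(a) & !is.na(b)
    ct <- suppressWarnings(
      stats::cor.test(a[ok], b[ok], method = "spearman", exact = FALSE))
    mwu <- suppressWarnings(
      stats::wilcox.test(a[!is.na(a)], b[!is.na(b)])$p.value)
    data.frame(index_a = pr[1], index_b = pr[2],
               rho = unname(ct$estimate), p_rho = ct$p.value, p_mwu = mwu,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_rho_holm <- holm_adjust(out$p_rho)
  out$p_mwu_holm <- holm_adjust(out$p_mwu)
  out <- out[c("index_a", "index_b", "rho", "p_rho", "p_rho_holm",
               "p_mwu", "p_mwu_holm")]
  structure(out,
            means = colMeans(cols, na.rm = TRUE),
            family_size = ncol(pairs),
            class = c("index_comparison", "data.frame"))
}

#' @export
print.index_comparison <- function(x, digits = 3, ...) {
  cat("Pairwise index comparison (", attr(x, "family_size"),
      " pairs, Holm-corrected within block)\n", sep = "")
  cat("Index means:\n")
  print(round(attr(x, "means"), digits))
  df <- as.data.frame(x)
  df[-(1:2)] <- lapply(df[-(1:2)], signif, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an index comparison as CSV
#'
#' @param comparison an `index_comparison`.
#' @param path output path.
#' @export
write_comparison <- function(comparison, path) {
  utils::write.csv(as.data.frame(comparison), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
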