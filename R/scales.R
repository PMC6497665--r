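#' Scoring scales for dyadic encounter ethograms
#'
#' An `etho_scale` holds an ordered set of integer behaviour scores with
#' labels, and optionally a translation map from some other (original)
#' scale onto this one. Positive scores denote aggressive behaviour,
#' negative scores peaceful behaviour, 0 ignoring, and the maximum score
#' killing (absorbing: once it occurs the encounter is over).
#'
#' @param scores integer vector of scores, strictly increasing after
#'   sorting; duplicates are an error.
#' @param labels character vector of behaviour names, same length.
#' @param translation optional named integer vector mapping original
#'   scores (names) to scores of this scale (values).
#' @return An object of class `etho_scale`: a list with elements
#'   `entries` (data.frame with columns `score`, `label`) and
#'   `translation`.
#' @seealso [adapted_scale()], [ds3_scale()], [translate_scale()]
#' @export
etho_scale <- function(scores, labels, translation = NULL) {
  scores <- as.integer(scores)
  if (anyDuplicated(scores)) stop("scores must be unique")
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length")
  }
  o <- order(scores)
  if (!is.null(translation)) {
    translation <- vapply(translation, as.integer, integer(1))
    if (is.null(names(translation)) || anyDuplicated(names(translation))) {
      stop("translation must have unique names (original scores)")
    }
    # the map's domain is this scale; its targets live on the scale
    # being translated to and are not constrained here
    if (!all(names(translation) %in% as.character(scores))) {
      stop("translation domain must be scores of this scale")
    }
  }
  structure(
    list(entries = data.frame(score = scores[o], label = as.character(labels)[o],
                              stringsAsFactors = FALSE),
         translation = translation),
    class = "etho_scale")
}

#' @export
print.etho_scale <- function(x, ...) {
  cat("Ethogram scoring scale (", nrow(x$entries), " behaviours)\n", sep = "")
  for (i in rev(seq_len(nrow(x$entries)))) {
    cat(sprintf("  %+d  %s\n", x$entries$score[i], x$entries$label[i]))
  }
  if (!is.null(x$translation)) {
    cat("Translation from original scores:",
        paste0(names(x$translation), "→", x$translation, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' The adapted -4..+5 scoring scale
#'
#' The reference scale used throughout the package: scores range from -4
#' (trophallaxis, the most peaceful behaviour) through 0 (ignoring) to +5
#' (killing). Aggressive behaviours are positive, peaceful behaviours
#' negative.
#'
#' @return An `etho_scale` with the ten behaviours.
#' @export
adapted_scale <- function() {
  etho_scale(
    scores = c(5L, 4L, 3L, 2L, 1L, 0L, -1L, -2L, -3L, -4L),
    labels = c("Killing",
               "Fighting with gaster flexion",
               "Fighting without gaster flexion",
               "Mandible threatening",
               "Avoiding",
               "Ignoring",
               "Being next to each other without touching",
               "Antennation",
               "Allogrooming",
               "Trophallaxis"))
}

#' The original 0..7 scale with translation onto the adapted scale
#'
#' Historic data coded on a 0..7 scale (0 ignoring, 1 being next to each
#' other, 2 antennation, 3 allogrooming and trophallaxis, 4 avoiding,
#' 5 mandible threatening, 6 biting, 7 fighting) is translated onto the
#' adapted scale so that peaceful behaviours become negative. The
#' original score 3 collapses allogrooming and trophallaxis onto -3; the
#' adapted -4 is unreachable from this scale, and killing was not coded.
#'
#' @return An `etho_scale` carrying the translation map.
#' @export
ds3_scale <- function() {
  etho_scale(
    scores = c(7L, 6L, 5L, 4L, 0L, 1L, 2L, 3L),
    labels = c("Fighting", "Biting", "Mandible threatening", "Avoiding",
               "Ignoring", "Being next to each other without touching",
               "Antennation", "Allogrooming and trophallaxis"),
    translation = c("0" = 0L, "1" = -1L, "2" = -2L, "3" = -3L,
                    "4" = 1L, "5" = 2L, "6" = 3L, "7" = 4L))
}

#' Translate a scored series onto another scale
#'
#' Applies a scale's translation map element-wise to a vector of scores
#' (e.g. a per-second series coded on the original 0..7 scale).
#'
#' @param scores integer vector of scores on the original scale.
#' @param translation a named integer map, or an `etho_scale` whose
#'   `translation` is used.
#' @return integer vector of translated scores, same length.
#' @examples
#' translate_scale(c(7, 3, 0), ds3_scale())  # 4, -3, 0
#' @export
translate_scale <- function(scores, translation) {
  if (inherits(translation, "etho_scale")) {
    translation <- translation$translation
    if (is.null(translation)) stop("scale carries no translation map")
  }
  key <- as.character(as.integer(scores))
  unmapped <- setdiff(unique(key), names(translation))
  if (length(unmapped)) {
    stop("scores not in translation domain: ", paste(unmapped, collapse = ", "))
  }
  unname(translation[key])
}

#' Read a scoring-scale configuration file
#'
#' Reads a YAML or JSON file (chosen by extension) with fields `scores`,
#' `labels` and optionally `translation` (a map original score -> score).
#'
#' @param path file path ending in .yml/.yaml or .json.
#' @return an `etho_scale`.
#' @export
read_scale <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yml = , yaml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path),
    stop("unsupported scale config extension: ", ext))
  tr <- cfg$translation
  if (!is.null(tr)) tr <- unlist(tr)
  etho_scale(cfg$scores, cfg$labels, translation = tr)
}
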