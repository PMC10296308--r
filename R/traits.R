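#' Construct a Big Five personality profile
#'
#' Trait scores on the questionnaire item scale (1-5 for the 50-item IPIP
#' five-factor instrument): E extroversion, A agreeableness,
#' C conscientiousness, N neuroticism, O openness.
#'
#' @param E,A,C,N,O numeric trait scores.
#' @return an object of class \code{personality_profile} (named numeric).
#' @export
personality_profile <- function(E, A, C, N, O) {
  p <- c(E = as.numeric(E), A = as.numeric(A), C = as.numeric(C),
         N = as.numeric(N), O = as.numeric(O))
  if (!all(is.finite(p))) stop("trait scores must be finite")
  structure(p, class = "personality_profile")
}

#' Big Five trait column names (E, A, C, N, O)
#' @export
TRAIT_NAMES <- c("E", "A", "C", "N", "O")

#' Load per-subject Big Five trait scores from CSV
#'
#' Expects columns \code{subject_id, E, A, C, N, O}. Scores outside the item
#' scale bounds produce a validation warning (the load still succeeds);
#' duplicated subjects are an error.
#'
#' @param path CSV file path.
#' @param scale_bounds length-2 numeric, the questionnaire item scale
#'   (default \code{c(1, 5)}, the 5-point item scale).
#' @return named list mapping subject_id to \code{\link{personality_profile}}.
#' @export
load_traits <- function(path, scale_bounds = c(1, 5)) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", TRAIT_NAMES)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("traits CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in traits CSV: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  scores <- as.matrix(df[, TRAIT_NAMES])
  if (!is.numeric(scores) || any(!is.finite(scores)))
    stop("trait scores must be numeric and finite")
  oob <- scores < scale_bounds[1] | scores > scale_bounds[2]
  if (any(oob))
    warning(sum(oob), " trait score(s) outside scale bounds [",
            scale_bounds[1], ", ", scale_bounds[2], "]", call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    personality_profile(df$E[i], df$A[i], df$C[i], df$N[i], df$O[i]))
  names(out) <- df$subject_id
  out
}

#' Scale trait scores to the unit interval
#'
#' Maps scores from the questionnaire item scale to [0, 1], the range of the
#' personality branch's sigmoid outputs.
#'
#' @param traits matrix/vector of scores or a \code{personality_profile}.
#' @param scale_bounds the item scale, default \code{c(1, 5)}.
#' @return object of the same shape with entries in [0, 1].
#' @export
scale_traits_unit <- function(traits, scale_bounds = c(1, 5)) {
  (unclass(traits) - scale_bounds[1]) / diff(scale_bounds)
}

#' Binarize trait scores at the cohort median
#'
#' Classification-style metrics for the continuous personality outputs are
#' computed after thresholding each trait at its cohort median (high vs low).
#' The same per-trait thresholds must be applied to predictions and targets.
#'
#' @param scores numeric matrix, subjects x traits.
#' @param thresholds optional per-trait thresholds; default column medians.
#' @return list with logical matrix \code{high} and the \code{thresholds}.
#' @export
binarize_traits <- function(scores, thresholds = NULL) {
  scores <- as.matrix(scores)
  if (is.null(thresholds)) thresholds <- apply(scores, 2, median)
  list(high = sweep(scores, 2, thresholds, ">="), thresholds = thresholds)
}
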