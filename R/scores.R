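# Closed-form screening scores: the ACE-I and renin inhibition percentages
# of the in vitro assays, and the toxicity threshold rule applied to
# externally computed SVM scores. SVM scores are input data; no toxicity
# model is trained or shipped.

#' ACE-I inhibition percentage
#'
#' `[(A_blank1 - A_inhibitor) / (A_blank1 - A_blank2)] * 100`, where blank 1
#' is the uninhibited (negative) control and blank 2 the reagent blank.
#' Values outside `[0, 100]` (pathological absorbances) are returned as-is
#' with a warning.
#'
#' @param a_blank1 Absorbance of the negative control.
#' @param a_inhibitor Absorbance with the sample.
#' @param a_blank2 Absorbance of the reagent blank.
#' @return Percent inhibition (vectorised).
#' @examples
#' ace_inhibition(1.0, 0.4, 0.2)  # 75
#' @export
ace_inhibition <- function(a_blank1, a_inhibitor, a_blank2) {
  if (any(!is.finite(a_blank1) | !is.finite(a_inhibitor) |
          !is.finite(a_blank2))) {
    stop("absorbances must be finite", call. = FALSE)
  }
  if (any(a_blank1 == a_blank2)) {
    stop("a_blank1 must differ from a_blank2 (zero denominator)",
         call. = FALSE)
  }
  pct <- (a_blank1 - a_inhibitor) / (a_blank1 - a_blank2) * 100
  if (any(pct < 0 | pct > 100)) {
    warning("inhibition percentage outside [0, 100]", call. = FALSE)
  }
  pct
}

#' Renin inhibition percentage
#'
#' `[(initial_activity - inhibitor_activity) / initial_activity] * 100`.
#'
#' @param initial_activity Fluorescence of the uninhibited reaction (> 0).
#' @param inhibitor_activity Fluorescence with the sample.
#' @return Percent inhibition (vectorised).
#' @examples
#' renin_inhibition(200, 50)  # 75
#' @export
renin_inhibition <- function(initial_activity, inhibitor_activity) {
  if (any(!is.finite(initial_activity) | !is.finite(inhibitor_activity))) {
    stop("activities must be finite", call. = FALSE)
  }
  if (any(initial_activity <= 0)) {
    stop("initial activity must be positive", call. = FALSE)
  }
  (initial_activity - inhibitor_activity) / initial_activity * 100
}

#' Toxicity call from an SVM score
#'
#' A sequence is called toxic iff its score strictly exceeds the threshold
#' (default 0.0); a score exactly at the threshold is non-toxic.
#'
#' @param svm_score Numeric score(s), externally computed.
#' @param threshold Decision threshold (default 0).
#' @return `data.frame` with columns svm_score, threshold, label
#'   (`"toxic"` / `"non_toxic"`).
#' @examples
#' toxicity_call(-1.3)$label  # "non_toxic"
#' @export
toxicity_call <- function(svm_score, threshold = 0) {
  if (any(!is.finite(svm_score))) {
    stop("SVM scores must be finite", call. = FALSE)
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold))
  data.frame(
    svm_score = svm_score,
    threshold = threshold,
    label = ifelse(svm_score > threshold, "toxic", "non_toxic"),
    stringsAsFactors = FALSE
  )
}
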