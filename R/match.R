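# Exact-sequence matching of digestion fragments against a bioactive-peptide
# reference. Matching is whole-sequence equality only (case-normalised): a
# reference dipeptide does not match inside a longer fragment. "Novel" means
# absent from the loaded reference, nothing more.

#' Load a bioactive-peptide reference
#'
#' Reads a TSV with columns `sequence`, `activity`, `citation`. Rows sharing a
#' sequence are merged with the union of their activities. With `path = NULL`
#' the bundled 16-entry di/tri-peptide reference is returned. Substituting a
#' larger reference changes what counts as "novel" downstream.
#'
#' @param path Path to a reference TSV, or `NULL` for the bundled table.
#' @return `data.frame` with columns `sequence`, `activities` (activity labels
#'   collapsed with "; ") and `citations`.
#' @export
load_reference <- function(path = NULL) {
  if (is.null(path)) path <- pkg_extdata("bioactive_reference.tsv")
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("sequence", "activity", "citation"), names(raw))
  if (length(missing)) {
    stop("reference file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(raw)) {
    return(data.frame(sequence = character(0), activities = character(0),
                      citations = character(0), stringsAsFactors = FALSE))
  }
  raw$sequence <- toupper(trimws(raw$sequence))
  invisible(lapply(raw$sequence, validate_sequence))
  if (any(nchar(raw$sequence) < 2L)) {
    stop("reference sequences must have length >= 2", call. = FALSE)
  }
  uniq <- unique(raw$sequence)
  data.frame(
    sequence = uniq,
    activities = vapply(uniq, function(s) {
      paste(unique(raw$activity[raw$sequence == s]), collapse = "; ")
    }, character(1)),
    citations = vapply(uniq, function(s) {
      paste(unique(raw$citation[raw$sequence == s]), collapse = "; ")
    }, character(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Partition a fragment pool into known bioactives and novel fragments
#'
#' @param pool A `"fragment_pool"` from [digest_pool()], or a character vector
#'   of fragment sequences.
#' @param reference A reference `data.frame` from [load_reference()].
#' @return An object of class `"match_report"`: list with `matched`
#'   (`data.frame`: sequence, activities, citations), `novel` (character
#'   vector), and `counts` (named: total, matched, novel).
#' @examples
#' match_pool(c("VK", "DEVIPGA"))$counts
#' @export
match_pool <- function(pool, reference = load_reference()) {
  seqs <- if (inherits(pool, "fragment_pool")) pool$fragments$sequence
          else toupper(as.character(pool))
  hit <- seqs %in% reference$sequence
  matched <- reference[match(seqs[hit], reference$sequence), , drop = FALSE]
  rownames(matched) <- NULL
  report <- list(
    matched = matched,
    novel = seqs[!hit],
    counts = c(total = length(seqs), matched = sum(hit), novel = sum(!hit))
  )
  class(report) <- "match_report"
  report
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> %d fragments: %d previously reported, %d novel\n",
              x$counts["total"], x$counts["matched"], x$counts["novel"]))
  if (nrow(x$matched)) {
    cat("  known: ", paste(x$matched$sequence, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
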