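# Orchestration of the full in silico cascade:
# digest -> bitterness/mass -> bioactive matching -> (optional) allergenicity
# -> (optional) toxicity, collected into a machine-readable screen report.

#' Run the full in silico screening cascade
#'
#' @param peptides Input peptides (list of [peptide()], character vector, or
#'   single peptide).
#' @param ruleset Digestion dialect (default [gi_ruleset()]).
#' @param reference Bioactive reference from [load_reference()] (default: the
#'   bundled table).
#' @param refset Optional `"allergen_refset"`; if `NULL` the allergenicity
#'   stage is marked skipped.
#' @param svm_scores Optional named numeric vector of externally computed SVM
#'   toxicity scores, named by fragment sequence; if `NULL` the toxicity
#'   stage is marked skipped. Pool fragments without a score are labelled
#'   `"no_score"`.
#' @param min_length Minimum fragment length kept in the pool.
#' @param k Neighbours for the allergenicity stage.
#' @return An object of class `"screen_report"`: list with
#'   `parents` (per-input `data.frame`: id, sequence, n, mono_mass, avg_mass,
#'   q_value, bitter, intact, n_fragments, fragments), `pool`
#'   (`"fragment_pool"`), `match` (`"match_report"`), `allergen` and
#'   `toxicity` (data frames, or the string `"skipped"`), `counts` (named:
#'   parents, unique_fragments, matched, novel, intact) and `provenance`.
#' @examples
#' rep <- screen_peptides(c("DEVIPGAL", "PVGCLPK"))
#' rep$counts
#' @export
screen_peptides <- function(peptides, ruleset = gi_ruleset(),
                            reference = load_reference(), refset = NULL,
                            svm_scores = NULL, min_length = 2L, k = 1L) {
  peptides <- as_peptide_list(peptides)
  if (!length(peptides)) stop("need at least one peptide", call. = FALSE)

  pool <- tryCatch(digest_pool(peptides, ruleset, min_length = min_length),
                   error = function(e) stop("digestion stage failed: ",
                                            conditionMessage(e), call. = FALSE))
  bitter <- tryCatch(classify_bitter(peptides),
                     error = function(e) stop("bitterness stage failed: ",
                                              conditionMessage(e), call. = FALSE))
  parents <- bitter
  parents$mono_mass <- vapply(peptides, monoisotopic_mass, numeric(1))
  parents$avg_mass <- parents$mw
  parents$mw <- NULL
  parents$intact <- peptide_sequences(peptides) %in% pool$intact
  parents$n_fragments <- vapply(pool$digestions, function(d) {
    nrow(d$fragments)
  }, integer(1))
  parents$fragments <- vapply(pool$digestions, function(d) {
    paste(d$fragments$sequence, collapse = ";")
  }, character(1))

  match <- tryCatch(match_pool(pool, reference),
                    error = function(e) stop("matching stage failed: ",
                                             conditionMessage(e), call. = FALSE))

  allergen <- "skipped"
  if (!is.null(refset)) {
    allergen <- tryCatch(classify_pool(pool, refset, k = k),
                         error = function(e) stop("allergenicity stage failed: ",
                                                  conditionMessage(e),
                                                  call. = FALSE))
  }

  toxicity <- "skipped"
  if (!is.null(svm_scores)) {
    scores <- svm_scores[pool$fragments$sequence]
    toxicity <- data.frame(sequence = pool$fragments$sequence,
                           svm_score = as.numeric(scores),
                           stringsAsFactors = FALSE)
    has <- !is.na(toxicity$svm_score)
    toxicity$label <- "no_score"
    if (any(has)) {
      toxicity$label[has] <- toxicity_call(toxicity$svm_score[has])$label
    }
  }

  counts <- c(parents = length(peptides),
              unique_fragments = nrow(pool$fragments),
              matched = unname(match$counts["matched"]),
              novel = unname(match$counts["novel"]),
              intact = length(pool$intact))
  stopifnot(counts["matched"] + counts["novel"] == counts["unique_fragments"])

  structure(
    list(parents = parents, pool = pool, match = match, allergen = allergen,
         toxicity = toxicity, counts = counts,
         provenance = list(
           dialect = ruleset$name,
           min_length = as.integer(min_length),
           k = as.integer(k),
           allergen_l_max = if (is.null(refset)) NA_integer_
                            else refset$meta$l_max,
           package_version = as.character(utils::packageVersion("algapept")))),
    class = "screen_report"
  )
}

#' Screen the bundled study peptides
#'
#' Runs [screen_peptides()] on the 48 identified peptides with the default
#' dialect, the bundled bioactive reference and the fixture SVM scores,
#' reproducing the headline pool counts.
#'
#' @return A `"screen_report"`.
#' @export
screen_fixtures <- function() {
  fx <- load_fixtures()
  scores <- stats::setNames(fx$fragment_truth$svm_score,
                            fx$fragment_truth$sequence)
  screen_peptides(fx$peptides, svm_scores = scores)
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n",
      sprintf("  parents          : %d (%d bitter, %d digestion-resistant)\n",
              x$counts["parents"], sum(x$parents$bitter), x$counts["intact"]),
      sprintf("  unique fragments : %d (length >= %d)\n",
              x$counts["unique_fragments"], x$provenance$min_length),
      sprintf("  known bioactives : %d\n", x$counts["matched"]),
      sprintf("  novel fragments  : %d\n", x$counts["novel"]),
      sep = "")
  if (is.character(x$allergen)) {
    cat("  allergenicity    : skipped\n")
  } else {
    cat(sprintf("  allergenicity    : %d allergen / %d non-allergen / %d not classifiable\n",
                sum(x$allergen$label == "allergen"),
                sum(x$allergen$label == "non_allergen"),
                sum(x$allergen$label == "not_classifiable")))
  }
  if (is.character(x$toxicity)) {
    cat("  toxicity         : skipped\n")
  } else {
    cat(sprintf("  toxicity         : %d toxic / %d non-toxic / %d unscored\n",
                sum(x$toxicity$label == "toxic"),
                sum(x$toxicity$label == "non_toxic"),
                sum(x$toxicity$label == "no_score")))
  }
  cat(sprintf("  dialect          : %s\n", x$provenance$dialect))
  invisible(x)
}

#' @export
summary.screen_report <- function(object, ...) {
  print(object)
  cat("\nBitter parents:\n")
  b <- object$parents[object$parents$bitter,
                      c("sequence", "q_value", "avg_mass")]
  if (nrow(b)) print(b, row.names = FALSE) else cat("  none\n")
  if (nrow(object$match$matched)) {
    cat("\nPreviously reported bioactive fragments:\n")
    print(object$match$matched, row.names = FALSE)
  }
  invisible(object)
}

report_as_list <- function(report) {
  list(
    counts = as.list(report$counts),
    provenance = report$provenance,
    parents = report$parents,
    fragments = report$pool$fragments,
    intact = report$pool$intact,
    matched = report$match$matched,
    novel = report$match$novel,
    allergen = if (is.character(report$allergen)) "skipped"
               else report$allergen,
    toxicity = if (is.character(report$toxicity)) "skipped"
               else report$toxicity
  )
}

#' Write a screen report to disk
#'
#' JSON output is a single self-describing file; TSV output writes two files,
#' `<path>_parents.tsv` and `<path>_fragments.tsv`.
#'
#' @param report A `"screen_report"`.
#' @param path Output path (for TSV, the prefix).
#' @param format `"json"` or `"tsv"`.
#' @return Invisibly, the path(s) written.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  stopifnot(inherits(report, "screen_report"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report_as_list(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "rows")
    return(invisible(path))
  }
  paths <- paste0(path, c("_parents.tsv", "_fragments.tsv"))
  utils::write.table(report$parents, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  frag <- report$pool$fragments
  frag$known_bioactive <- frag$sequence %in% report$match$matched$sequence
  if (!is.character(report$allergen)) {
    frag$allergen_label <-
      report$allergen$label[match(frag$sequence, report$allergen$sequence)]
  }
  if (!is.character(report$toxicity)) {
    frag$toxicity_label <-
      report$toxicity$label[match(frag$sequence, report$toxicity$sequence)]
  }
  utils::write.table(frag, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read back a JSON screen report
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return A plain list mirroring the JSON structure.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}
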