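# Bundled study fixtures: the 48 LC-MS/MS-identified peptides with their
# printed masses, m/z, charges and Q-values; the 16-entry bioactive
# di/tri-peptide reference; the 70 digestion fragments with SVM toxicity
# scores and allergenicity labels; and the 7 digestion-resistant peptides.

#' Load the bundled study fixtures
#'
#' Reads the plain-text fixture tables shipped with the package and checks
#' their integrity (cardinalities 48 / 16 / 70 = 28 + 42 / 7; the intact set
#' must be a subset of the identified peptides; all sequences must validate).
#'
#' @return An object of class `"fixture_set"`: a list with elements
#'   \describe{
#'     \item{identified_peptides}{`data.frame`, 48 rows: fraction, sequence,
#'       modifications, observed/calculated MW, observed/theoretical m/z,
#'       charge, printed Q-value.}
#'     \item{peptides}{the same 48 records as a list of [peptide()] objects
#'       (modifications parsed).}
#'     \item{bioactive_reference}{`data.frame` of 16 unique di/tri-peptides
#'       with activity labels and citations (duplicated sequences merged).}
#'     \item{fragment_truth}{`data.frame`, 70 rows: fragment sequence, printed
#'       MW, SVM toxicity score, PeptideRanker score, allergen label.}
#'     \item{intact_truth}{character vector of the 7 digestion-resistant
#'       sequences.}
#'   }
#' @examples
#' fx <- load_fixtures()
#' nrow(fx$identified_peptides)  # 48
#' @export
load_fixtures <- function() {
  tab1 <- utils::read.delim(pkg_extdata("identified_peptides.tsv"),
                            stringsAsFactors = FALSE)
  truth <- utils::read.delim(pkg_extdata("digestion_fragments.tsv"),
                             stringsAsFactors = FALSE)
  intact <- utils::read.delim(pkg_extdata("intact_peptides.tsv"),
                              stringsAsFactors = FALSE)
  ref <- load_reference()

  if (nrow(tab1) != 48L) {
    stop("fixture integrity: expected 48 identified peptides, found ",
         nrow(tab1), call. = FALSE)
  }
  if (anyDuplicated(truth$sequence) || nrow(truth) != 70L) {
    stop("fixture integrity: expected 70 unique digestion fragments",
         call. = FALSE)
  }
  n_all <- sum(truth$allergen == "allergen")
  if (n_all != 28L || nrow(truth) - n_all != 42L) {
    stop("fixture integrity: expected 28 allergenic + 42 non-allergenic",
         call. = FALSE)
  }
  if (nrow(ref) != 16L) {
    stop("fixture integrity: expected 16 bioactive reference entries",
         call. = FALSE)
  }
  if (!all(intact$sequence %in% tab1$sequence)) {
    stop("fixture integrity: intact peptides must be identified peptides",
         call. = FALSE)
  }

  peptides <- Map(function(s, m, i) peptide(s, id = i, modifications = m),
                  tab1$sequence, tab1$modifications,
                  paste0(tab1$fraction, "_", tab1$sequence))
  names(peptides) <- NULL
  # fragment truth sequences must also validate
  invisible(lapply(truth$sequence, validate_sequence))

  structure(
    list(identified_peptides = tab1,
         peptides = peptides,
         bioactive_reference = ref,
         fragment_truth = truth,
         intact_truth = intact$sequence),
    class = "fixture_set"
  )
}

#' @export
print.fixture_set <- function(x, ...) {
  cat("<fixture_set>\n",
      sprintf("  identified peptides : %d\n", nrow(x$identified_peptides)),
      sprintf("  bioactive reference : %d\n", nrow(x$bioactive_reference)),
      sprintf("  fragment truth      : %d (%d allergen / %d non-allergen)\n",
              nrow(x$fragment_truth),
              sum(x$fragment_truth$allergen == "allergen"),
              sum(x$fragment_truth$allergen == "non_allergen")),
      sprintf("  digestion-resistant : %d\n", length(x$intact_truth)),
      sep = "")
  invisible(x)
}
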