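# Ney Q-rule bitterness prediction.
#
# Q is the arithmetic mean of per-residue side-chain hydrophobicity
# contributions (delta-f, cal/mol): Q = sum(delta_f) / n. A peptide is
# predicted bitter when Q strictly exceeds 1400 cal/mol AND its molecular
# weight is below 6 kDa (average-mass scale).

#' Ney Q-value of a peptide
#'
#' Mean per-residue delta-f in cal/mol. Depends only on amino-acid
#' composition, so it is invariant under permutation of the sequence.
#'
#' @param x A [peptide()], a sequence string, or a character vector of
#'   sequences.
#' @return Numeric Q-value(s) in cal/mol.
#' @examples
#' q_value("SGAASASGAA")  # 377
#' q_value("PPNPPNPPN")   # 1743.33
#' @export
q_value <- function(x) {
  if (is.character(x) && length(x) > 1L) {
    return(vapply(x, q_value, numeric(1)))
  }
  p <- as_peptide(x)
  res <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  unname(mean(delta_f_table()[res]))
}

#' Q-rule bitterness classification
#'
#' Applies the conjunction `Q > 1400 cal/mol AND MW < 6000 Da`. The Q
#' threshold is strict: a peptide scoring exactly 1400 is not bitter. MW is
#' computed on the average-mass scale.
#'
#' @param x A [peptide()], a sequence string, or a character vector.
#' @return `data.frame` with columns id, sequence, n, q_value, mw, bitter.
#' @examples
#' classify_bitter("SAGVLPWK")$bitter  # TRUE (Q = 1500)
#' @export
classify_bitter <- function(x) {
  peptides <- as_peptide_list(x)
  q <- vapply(peptides, q_value, numeric(1))
  mw <- vapply(peptides, average_mass, numeric(1))
  data.frame(
    id = peptide_ids(peptides),
    sequence = peptide_sequences(peptides),
    n = nchar(peptide_sequences(peptides)),
    q_value = q,
    mw = mw,
    bitter = q > 1400 & mw < 6000,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Bitter subset of a peptide collection
#'
#' @param peptides Peptides (list, character vector, or single peptide).
#' @return The rows of [classify_bitter()] flagged bitter, input order
#'   preserved.
#' @export
bitter_subset <- function(peptides) {
  if (length(peptides) == 0L) {
    return(classify_bitter(character(0)))
  }
  res <- classify_bitter(peptides)
  res[res$bitter, , drop = FALSE]
}
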