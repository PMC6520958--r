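# Peptide mass and mass-to-charge computation.
#
# Monoisotopic masses reproduce the identified-peptide "Calculated MW" and
# "Theoretical m/z" columns; average masses reproduce the fragment-table MW
# column. Deamidation is a +0.984016 Da monoisotopic delta per site, not a
# sequence edit, so digestion and Q-values see the unmodified letter.

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water, plus the mass delta of
#' every annotated modification (deamidation: +0.984016 Da per site).
#'
#' @param x A [peptide()] or a sequence string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("ATKPAN")  # 600.32
#' @export
monoisotopic_mass <- function(x) {
  p <- as_peptide(x)
  res <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  m <- sum(mono_mass_table()[res]) + water_mono_mass()
  if (nrow(p$modifications)) {
    m <- m + sum(.modification_registry[p$modifications$kind])
  }
  unname(m)
}

#' Average peptide mass
#'
#' Sum of residue average masses plus one (average-mass) water. Modifications
#' are ignored on this scale; it is used for the coarse 6 kDa bitterness bound
#' and the fragment-table MW comparisons.
#'
#' @param x A [peptide()] or a sequence string.
#' @return Mass in Da.
#' @examples
#' average_mass("AAK")  # 288.347
#' @export
average_mass <- function(x) {
  p <- as_peptide(x)
  res <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  unname(sum(avg_mass_table()[res]) + water_avg_mass())
}

#' Theoretical m/z of a protonated peptide
#'
#' `(mono_mass + z * 1.007276) / z` for charge state `z`.
#'
#' @param mono_mass Monoisotopic (neutral) mass in Da.
#' @param z Positive integer charge.
#' @return m/z in Da per unit charge.
#' @examples
#' theoretical_mz(monoisotopic_mass("ATKPAN"), 2)  # 301.17
#' @export
theoretical_mz <- function(mono_mass, z) {
  if (any(!is.finite(z)) || any(z < 1) || any(z != as.integer(z))) {
    stop("charge z must be a positive integer", call. = FALSE)
  }
  (mono_mass + z * proton_mass()) / z
}

#' Mass summary table for a set of peptides
#'
#' @param peptides Peptides (list, character vector, or single peptide).
#' @param charges Integer charge states for which m/z columns are added.
#' @return `data.frame` with id, sequence, n, mono_mass, avg_mass and one
#'   `mz_z<k>` column per requested charge.
#' @export
mass_table <- function(peptides, charges = 1:3) {
  peptides <- as_peptide_list(peptides)
  mono <- vapply(peptides, monoisotopic_mass, numeric(1))
  out <- data.frame(
    id = peptide_ids(peptides),
    sequence = peptide_sequences(peptides),
    n = nchar(peptide_sequences(peptides)),
    mono_mass = mono,
    avg_mass = vapply(peptides, average_mass, numeric(1)),
    stringsAsFactors = FALSE
  )
  for (z in charges) out[[paste0("mz_z", z)]] <- theoretical_mz(mono, z)
  rownames(out) <- NULL
  out
}
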