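# Per-residue constants: Ney delta-f hydrophobicity contributions (cal/mol),
# IUPAC monoisotopic and average residue masses (Da), and the five
# principal-component E-descriptors used for the ACC transform.

.algapept_cache <- new.env(parent = emptyenv())

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "algapept")
  if (!nzchar(path)) stop("bundled data file not found: ", file, call. = FALSE)
  path
}

#' Residue property table
#'
#' The 20-row table of per-residue constants: `delta_f` (Ney side-chain
#' hydrophobicity contribution, cal/mol), `mono_mass` and `avg_mass`
#' (monoisotopic and average residue masses, Da), and the five E-descriptor
#' columns `e1`..`e5` used by [acc_transform()].
#'
#' @return A `data.frame` with row names equal to the residue letters.
#' @export
residue_properties <- function() {
  if (is.null(.algapept_cache$props)) {
    props <- utils::read.delim(pkg_extdata("residue_properties.tsv"),
                               stringsAsFactors = FALSE)
    stopifnot(nrow(props) == 20L,
              setequal(props$residue, aa_alphabet()),
              all(props$mono_mass > 0), all(props$avg_mass > 0))
    rownames(props) <- props$residue
    .algapept_cache$props <- props
  }
  .algapept_cache$props
}

# named lookup vectors
delta_f_table <- function() {
  p <- residue_properties()
  stats::setNames(p$delta_f, p$residue)
}

mono_mass_table <- function() {
  p <- residue_properties()
  stats::setNames(p$mono_mass, p$residue)
}

avg_mass_table <- function() {
  p <- residue_properties()
  stats::setNames(p$avg_mass, p$residue)
}

#' E-descriptor matrix
#'
#' Five-dimensional principal-component amino-acid descriptors, one row per
#' residue. Any numeric matrix with 20 named rows can be substituted in
#' [acc_transform()].
#'
#' @return A 20 x 5 numeric matrix with residue row names.
#' @export
e_descriptors <- function() {
  p <- residue_properties()
  m <- as.matrix(p[, c("e1", "e2", "e3", "e4", "e5")])
  rownames(m) <- p$residue
  m
}

# named physical constants (Da)
water_mono_mass <- function() 18.010565
water_avg_mass  <- function() 18.01528
proton_mass     <- function() 1.007276
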