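# Seeded synthetic-data generators. They emulate the statistical structure of
# the study inputs -- short peptides (length 2-23) drawn from the 20-letter
# alphabet with the residue usage of the identified-peptide fixture -- plus
# separable allergen/non-allergen reference populations for exercising the
# ACC + k-NN machinery without any external training database.

#' Empirical residue composition of the identified-peptide fixture
#'
#' @return Named numeric vector of 20 sampling weights (sums to 1).
#' @export
empirical_composition <- function() {
  if (is.null(.algapept_cache$composition)) {
    tab1 <- utils::read.delim(pkg_extdata("identified_peptides.tsv"),
                              stringsAsFactors = FALSE)
    res <- unlist(strsplit(tab1$sequence, "", fixed = TRUE))
    counts <- table(factor(res, levels = aa_alphabet()))
    .algapept_cache$composition <- as.numeric(counts) / sum(counts)
    names(.algapept_cache$composition) <- aa_alphabet()
  }
  .algapept_cache$composition
}

#' Generator configuration
#'
#' @param seed Integer seed; identical seeds give identical output.
#' @param n_peptides Number of peptides to generate (default 48, the size of
#'   the identified-peptide population).
#' @param length_range Inclusive length bounds, default `c(2, 23)` (the
#'   fixture's fragment-to-parent length span).
#' @param composition Per-residue sampling weights (named over the alphabet
#'   or length-20 in alphabet order); default: empirical fixture frequencies.
#' @param cluster_separation Non-negative scale of the composition bias
#'   separating the two synthetic reference populations in descriptor space
#'   (0 = identical populations; around 10 = widely separated clusters).
#' @param n_reference Reference-set entries per class.
#' @param ref_length_range Length bounds for reference peptides (must exceed
#'   the ACC lag used downstream).
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(seed = 1L, n_peptides = 48L,
                             length_range = c(2L, 23L), composition = NULL,
                             cluster_separation = 10, n_reference = 200L,
                             ref_length_range = c(10L, 20L)) {
  if (is.null(composition)) composition <- empirical_composition()
  if (is.null(names(composition))) names(composition) <- aa_alphabet()
  stopifnot(length(composition) == 20L,
            setequal(names(composition), aa_alphabet()))
  if (any(composition < 0) || sum(composition) <= 0) {
    stop("composition weights must be non-negative and not all zero",
         call. = FALSE)
  }
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1] < 1L ||
      length_range[1] > length_range[2]) {
    stop("invalid length_range", call. = FALSE)
  }
  if (cluster_separation < 0) {
    stop("cluster_separation must be >= 0", call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 n_peptides = as.integer(n_peptides),
                 length_range = length_range,
                 composition = composition[aa_alphabet()],
                 cluster_separation = cluster_separation,
                 n_reference = as.integer(n_reference),
                 ref_length_range = as.integer(ref_length_range)),
            class = "generator_config")
}

sample_peptides <- function(n, length_range, weights, prefix) {
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  seqs <- vapply(lens, function(len) {
    paste(sample(aa_alphabet(), len, replace = TRUE, prob = weights),
          collapse = "")
  }, character(1))
  unname(Map(function(s, i) validate_sequence(s, id = i),
             seqs, sprintf("%s%04d", prefix, seq_len(n))))
}

#' Generate random peptides
#'
#' Lengths are uniform over `length_range`; residues are drawn independently
#' with the configured composition. Reproducible under the configured seed.
#'
#' @param config A [generator_config()].
#' @return List of [peptide()] objects.
#' @examples
#' length(generate_peptides(generator_config(seed = 1, n_peptides = 10)))
#' @export
generate_peptides <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    unname(sample_peptides(config$n_peptides, config$length_range,
                           config$composition, "s"))
  })
}

#' Generate a synthetic labelled reference set
#'
#' Produces two labelled peptide populations whose residue compositions are
#' biased in opposite directions along the first E-descriptor (the
#' hydrophobicity axis): class weights are proportional to
#' `exp(-s * e1)` (allergen-labelled, hydrophobic-rich) and `exp(+s * e1)`
#' (non-allergen-labelled), with `s = cluster_separation`. At `s = 0` the
#' populations are identical (1-NN recovery is at chance); for large `s`
#' their ACC vectors form well-separated clusters and held-out recovery
#' approaches 100%.
#'
#' @param config A [generator_config()].
#' @param l_max ACC lag for the cached reference vectors (reference lengths
#'   must exceed it).
#' @return An `"allergen_refset"` (see [build_reference_set()]) with an
#'   additional `peptides` element.
#' @export
generate_reference_sets <- function(config = generator_config(), l_max = 8L) {
  stopifnot(inherits(config, "generator_config"))
  if (config$ref_length_range[1] <= l_max) {
    stop("ref_length_range must exceed l_max", call. = FALSE)
  }
  e1 <- e_descriptors()[aa_alphabet(), 1]
  s <- config$cluster_separation
  w_all <- exp(-s * e1) / sum(exp(-s * e1))
  w_non <- exp(+s * e1) / sum(exp(+s * e1))
  peps <- with_seed(config$seed, {
    c(sample_peptides(config$n_reference, config$ref_length_range, w_all, "a"),
      sample_peptides(config$n_reference, config$ref_length_range, w_non, "n"))
  })
  labels <- rep(c("allergen", "non_allergen"), each = config$n_reference)
  refset <- build_reference_set(peps, labels, l_max = l_max)
  refset$peptides <- unname(peps)
  refset
}
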