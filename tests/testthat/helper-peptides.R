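# Shared test scaffolding: seeded random peptides and a tiny two-entry
# allergen reference set built in code.

random_peptides <- function(n, seed, length_range = c(2L, 23L)) {
  generate_peptides(generator_config(seed = seed, n_peptides = n,
                                     length_range = length_range))
}

tiny_refset <- function(l_max = 3L) {
  build_reference_set(c(a1 = "IIIIVVLL", n1 = "DDEEKKRR"),
                      c("allergen", "non_allergen"), l_max = l_max)
}
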