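test_that("ACC vectors have fixed length d^2 * l_max regardless of peptide length", {
  v <- acc_transform("AANITVPAAN", l_max = 8)  # 10-mer, d = 5
  expect_length(v, 200L)
  lens <- c(9, 12, 17, 23, 30)
  for (n in lens) {
    p <- paste(rep(c("A", "K", "I", "D"), length.out = n), collapse = "")
    expect_length(acc_transform(p, l_max = 8), 200L)
  }
  expect_error(acc_transform("AA", l_max = 8), "too short for lag")
  expect_error(acc_transform("AANITVPA", l_max = 8), "too short")  # n == l_max
})

test_that("homopolymer ACC components equal descriptor products", {
  E <- e_descriptors()
  v <- acc_transform(strrep("A", 15), l_max = 4)
  for (l in 1:4) {
    for (j in 1:5) {
      for (k in 1:5) {
        expect_equal(v[[sprintf("l%d.e%d%d", l, j, k)]],
                     E["A", j] * E["A", k], tolerance = 1e-12)
      }
    }
  }
})

test_that("identical sequences give identical vectors and distance zero", {
  a <- acc_transform("NQVTNLIVA")
  b <- acc_transform("NQVTNLIVA")
  expect_identical(unclass(a), unclass(b))
  refset <- build_reference_set(c(a1 = "NQVTNLIVA", n1 = "DDEEKKRRDD"),
                                c("allergen", "non_allergen"), l_max = 8)
  pred <- knn_classify("NQVTNLIVA", refset)
  expect_equal(pred$nearest_distance, 0, tolerance = 1e-12)
  expect_equal(pred$label, "allergen")
  expect_equal(pred$nearest_id, "a1")
})

test_that("nearest-neighbour calls are deterministic under ties and reordering", {
  # two entries with identical sequences tie at every distance: the
  # lexicographically lowest id must win regardless of storage order
  seqs <- c(b9 = "IIIIVVLLII", a1 = "IIIIVVLLII", n1 = "DDEEKKRRDD")
  labs <- c("allergen", "allergen", "non_allergen")
  fwd <- build_reference_set(seqs, labs, l_max = 3)
  rev <- build_reference_set(seqs[c(3, 1, 2)], labs[c(3, 1, 2)], l_max = 3)
  q <- "IIIIVVLLII"
  expect_equal(knn_classify(q, fwd)$nearest_id, "a1")
  expect_equal(knn_classify(q, rev)$nearest_id, "a1")
  # reordering a tie-free reference set never changes predictions
  cfg <- generator_config(seed = 5, n_reference = 15)
  rs <- generate_reference_sets(cfg, l_max = 3)
  perm <- rev(seq_along(rs$ids))
  rs_perm <- structure(list(ids = rs$ids[perm], labels = rs$labels[perm],
                            acc = rs$acc[perm, , drop = FALSE],
                            meta = rs$meta),
                       class = "allergen_refset")
  for (s in c("KDEAATRNKD", "LIVIAAFVLI", "GGSSTTPPAA")) {
    expect_equal(knn_classify(s, rs)[, c("label", "nearest_id")],
                 knn_classify(s, rs_perm)[, c("label", "nearest_id")])
  }
})

test_that("metadata mismatches are configuration errors", {
  refset <- tiny_refset(l_max = 3)
  q <- acc_transform("NQVTNLIVA", l_max = 5)
  expect_error(knn_classify(q, refset), "metadata mismatch")
})

test_that("classify_pool is total and marks short fragments explicitly", {
  refset <- build_reference_set(c(a1 = "IIVVLLIIVVLL", n1 = "DDEEKKRRDDEE"),
                                c("allergen", "non_allergen"), l_max = 8)
  out <- classify_pool(c("AA", "IIVVLLIIVVLL", "DDEEKKRRDDEE"), refset)
  expect_equal(nrow(out), 3L)
  expect_equal(out$label,
               c("not_classifiable", "allergen", "non_allergen"))
  expect_true(is.na(out$nearest_distance[1]))
})

test_that("1-NN agrees with an independent kNN implementation", {
  skip_if_not_installed("class")
  rs <- generate_reference_sets(generator_config(seed = 9, n_reference = 40,
                                                 cluster_separation = 2))
  queries <- generate_peptides(generator_config(seed = 10, n_peptides = 30,
                                                length_range = c(9, 20)))
  ours <- vapply(queries, function(p) knn_classify(p, rs)$label, "")
  qacc <- t(vapply(queries, function(p) {
    as.numeric(acc_transform(p, l_max = rs$meta$l_max))
  }, numeric(ncol(rs$acc))))
  theirs <- as.character(class::knn(rs$acc, qacc, factor(rs$labels), k = 1))
  expect_equal(unname(ours), theirs)
})

test_that("well-separated synthetic clusters are recovered, overlap is chance", {
  rs <- generate_reference_sets(generator_config(seed = 7, n_reference = 120))
  expect_gte(knn_holdout_accuracy(rs, seed = 7), 0.9)
  rs0 <- generate_reference_sets(generator_config(seed = 7, n_reference = 120,
                                                  cluster_separation = 0))
  acc0 <- knn_holdout_accuracy(rs0, seed = 7)
  expect_gt(acc0, 0.3)
  expect_lt(acc0, 0.7)
})
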