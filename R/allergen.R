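# Allergenicity classification machinery: auto- and cross-covariance (ACC)
# transformation of per-residue descriptor strings into uniform-length
# vectors, followed by k-nearest-neighbour (default k = 1) classification
# against a labelled reference set.
#
# For a peptide of length n with descriptor matrix Z (n x d), the ACC
# component for descriptor pair (j, k) at lag l is
#   A_jk(l) = sum_{i=1}^{n-l} Z[i, j] * Z[i+l, k] / (n - l),
# giving a vector of fixed length d^2 * l_max for every peptide longer than
# l_max, irrespective of n.

acc_meta <- function(v) attr(v, "acc_meta")

#' ACC transform of a peptide
#'
#' @param x A [peptide()] or a sequence string of length > `l_max`.
#' @param l_max Maximum lag (default 8).
#' @param descriptors Numeric matrix of per-residue descriptors with residue
#'   row names (default: the bundled five E-descriptors).
#' @param descriptor_set Label stored in the vector metadata.
#' @return Numeric vector of length `ncol(descriptors)^2 * l_max`, named
#'   `l<lag>.e<j><k>`, with an `acc_meta` attribute (d, l_max, set name).
#' @examples
#' length(acc_transform("AANITVPAAN", l_max = 8))  # 5^2 * 8 = 200
#' @export
acc_transform <- function(x, l_max = 8L, descriptors = e_descriptors(),
                          descriptor_set = "E5") {
  p <- as_peptide(x)
  res <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  l_max <- as.integer(l_max)
  if (l_max < 1L) stop("l_max must be >= 1", call. = FALSE)
  if (n <= l_max) {
    stop(sprintf("sequence too short for lag: length %d <= l_max %d", n, l_max),
         call. = FALSE)
  }
  Z <- descriptors[res, , drop = FALSE]
  d <- ncol(Z)
  out <- numeric(d * d * l_max)
  nm <- character(d * d * l_max)
  idx <- 0L
  for (l in seq_len(l_max)) {
    head_z <- Z[seq_len(n - l), , drop = FALSE]
    tail_z <- Z[seq_len(n - l) + l, , drop = FALSE]
    cp <- crossprod(head_z, tail_z) / (n - l)  # d x d: pair (j, k)
    for (j in seq_len(d)) {
      for (k in seq_len(d)) {
        idx <- idx + 1L
        out[idx] <- cp[j, k]
        nm[idx] <- sprintf("l%d.e%d%d", l, j, k)
      }
    }
  }
  names(out) <- nm
  attr(out, "acc_meta") <- list(d = d, l_max = l_max,
                                descriptor_set = descriptor_set)
  out
}

#' Build a labelled ACC reference set
#'
#' Computes and caches the ACC vector of every reference peptide.
#'
#' @param peptides Peptides (list, character vector, or single peptide), all
#'   longer than `l_max`.
#' @param labels Character vector of `"allergen"` / `"non_allergen"` labels,
#'   one per peptide; both labels must be represented.
#' @param l_max,descriptors,descriptor_set Passed to [acc_transform()].
#' @return An object of class `"allergen_refset"`: list with `ids`, `labels`,
#'   `acc` (matrix, one row per entry) and `meta`.
#' @export
build_reference_set <- function(peptides, labels, l_max = 8L,
                                descriptors = e_descriptors(),
                                descriptor_set = "E5") {
  peptides <- as_peptide_list(peptides)
  labels <- as.character(labels)
  stopifnot(length(labels) == length(peptides))
  if (!all(labels %in% c("allergen", "non_allergen"))) {
    stop("labels must be 'allergen' or 'non_allergen'", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both labels must be represented in a reference set", call. = FALSE)
  }
  ids <- peptide_ids(peptides)
  if (anyDuplicated(ids)) stop("reference ids must be unique", call. = FALSE)
  vecs <- lapply(peptides, acc_transform, l_max = l_max,
                 descriptors = descriptors, descriptor_set = descriptor_set)
  acc <- do.call(rbind, vecs)
  rownames(acc) <- ids
  structure(list(ids = ids, labels = labels, acc = acc,
                 meta = acc_meta(vecs[[1]])),
            class = "allergen_refset")
}

#' @export
print.allergen_refset <- function(x, ...) {
  cat(sprintf(
    "<allergen_refset> %d entries (%d allergen / %d non-allergen), d = %d, l_max = %d\n",
    length(x$ids), sum(x$labels == "allergen"),
    sum(x$labels == "non_allergen"), x$meta$d, x$meta$l_max))
  invisible(x)
}

#' k-nearest-neighbour allergenicity call
#'
#' Euclidean distance in ACC space; `k = 1` assigns the label of the single
#' nearest reference entry. Exact distance ties are broken deterministically
#' by the lexicographically lowest reference id, so predictions never depend
#' on reference ordering.
#'
#' @param query An ACC vector from [acc_transform()], a [peptide()], or a
#'   sequence string (peptides are transformed with the reference metadata).
#' @param refset An `"allergen_refset"`.
#' @param k Number of neighbours (default 1; larger k uses majority vote,
#'   ties going to the nearer neighbourhood's label).
#' @return A one-row `data.frame`: query_id, label, nearest_id,
#'   nearest_distance.
#' @export
knn_classify <- function(query, refset, k = 1L) {
  stopifnot(inherits(refset, "allergen_refset"))
  if (!length(refset$ids)) stop("empty reference set", call. = FALSE)
  query_id <- NA_character_
  if (!is.numeric(query)) {
    p <- as_peptide(query)
    query_id <- p$id
    query <- acc_transform(p, l_max = refset$meta$l_max,
                           descriptor_set = refset$meta$descriptor_set)
  }
  meta <- acc_meta(query)
  if (is.null(meta) || meta$d != refset$meta$d ||
      meta$l_max != refset$meta$l_max ||
      !identical(meta$descriptor_set, refset$meta$descriptor_set)) {
    stop("ACC metadata mismatch between query and reference set",
         call. = FALSE)
  }
  dif <- sweep(refset$acc, 2L, as.numeric(query))
  dist <- sqrt(rowSums(dif * dif))
  ord <- order(dist, refset$ids)  # deterministic tie-break on id
  k <- min(as.integer(k), length(dist))
  nn <- ord[seq_len(k)]
  label <- if (k == 1L) refset$labels[nn] else {
    tab <- sort(table(refset$labels[nn]), decreasing = TRUE)
    names(tab)[1]
  }
  data.frame(query_id = query_id, label = label,
             nearest_id = refset$ids[ord[1]],
             nearest_distance = dist[ord[1]],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify every fragment of a pool
#'
#' Fragments shorter than `l_max + 1` cannot be ACC-transformed and are
#' reported with the explicit label `"not_classifiable"` rather than dropped.
#'
#' @param pool A `"fragment_pool"` or character vector of sequences.
#' @param refset An `"allergen_refset"`.
#' @param k Number of neighbours.
#' @return `data.frame` with one row per fragment: sequence, label,
#'   nearest_id, nearest_distance.
#' @export
classify_pool <- function(pool, refset, k = 1L) {
  seqs <- if (inherits(pool, "fragment_pool")) pool$fragments$sequence
          else toupper(as.character(pool))
  rows <- lapply(seqs, function(s) {
    if (nchar(s) <= refset$meta$l_max) {
      data.frame(sequence = s, label = "not_classifiable",
                 nearest_id = NA_character_, nearest_distance = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      pred <- knn_classify(s, refset, k = k)
      data.frame(sequence = s, label = pred$label,
                 nearest_id = pred$nearest_id,
                 nearest_distance = pred$nearest_distance,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Held-out 1-NN label-recovery accuracy of a reference set
#'
#' Splits the reference entries into train/test portions and reports the
#' fraction of held-out entries whose label is recovered by k-NN against the
#' training portion. Used to validate synthetic reference sets.
#'
#' @param refset An `"allergen_refset"`.
#' @param prop_train Fraction of entries used as neighbours (default 0.5;
#'   split is stratified by label).
#' @param k Number of neighbours.
#' @param seed Integer seed for the split.
#' @return Accuracy in `[0, 1]`.
#' @export
knn_holdout_accuracy <- function(refset, prop_train = 0.5, k = 1L, seed = 1L) {
  stopifnot(inherits(refset, "allergen_refset"))
  idx <- with_seed(seed, {
    unlist(lapply(unique(refset$labels), function(lab) {
      members <- which(refset$labels == lab)
      sample(members, size = max(1L, round(prop_train * length(members))))
    }))
  })
  train <- structure(list(ids = refset$ids[idx], labels = refset$labels[idx],
                          acc = refset$acc[idx, , drop = FALSE],
                          meta = refset$meta),
                     class = "allergen_refset")
  test <- setdiff(seq_along(refset$ids), idx)
  if (!length(test)) stop("hold-out split left no test entries", call. = FALSE)
  pred <- vapply(test, function(i) {
    v <- refset$acc[i, ]
    attr(v, "acc_meta") <- refset$meta
    knn_classify(v, train, k = k)$label
  }, character(1))
  mean(pred == refset$labels[test])
}
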