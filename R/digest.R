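# Simulated gastrointestinal digestion: a declarative P4-P4' context-window
# cleavage-rule engine. A candidate site lies between residues i and i+1
# (1-based); relative positions P4..P1 sit N-terminal of the site and
# P1'..P4' C-terminal. An enzyme cuts a site iff at least one of its "cleave"
# rules matches and none of its "block" rules matches; under the simultaneous
# (union-of-sites) semantics a site is cut iff any enzyme cuts it.
#
# Rule TSV cells: "." unconstrained, "KR" required set, "^P" forbidden set.
# Positions beyond the termini carry no residue: they satisfy forbidden sets
# and fail required sets.

.window_positions <- c("p4", "p3", "p2", "p1", "p1p", "p2p", "p3p", "p4p")
.window_offsets   <- c(-3L, -2L, -1L, 0L, 1L, 2L, 3L, 4L)

parse_rule_row <- function(row) {
  constraints <- list()
  for (k in seq_along(.window_positions)) {
    cell <- trimws(row[[.window_positions[k]]])
    if (cell == "." || !nzchar(cell)) next
    forbidden <- startsWith(cell, "^")
    set <- strsplit(sub("^\\^", "", cell), "", fixed = TRUE)[[1]]
    bad <- setdiff(set, aa_alphabet())
    if (length(bad)) stop("unknown residue in rule set: ", bad[1], call. = FALSE)
    constraints[[length(constraints) + 1L]] <-
      list(offset = .window_offsets[k], forbidden = forbidden, set = set)
  }
  if (!any(!vapply(constraints, `[[`, logical(1), "forbidden"))) {
    stop("cleavage rule must constrain at least one required set", call. = FALSE)
  }
  list(enzyme = row$enzyme, kind = row$kind, constraints = constraints)
}

#' Read a cleavage rule set from TSV
#'
#' Expected columns: `enzyme`, `ec`, `kind` (`cleave` or `block`), and the
#' eight window positions `p4, p3, p2, p1, p1p, p2p, p3p, p4p`.
#'
#' @param path Path to a rule TSV file.
#' @param name Dialect label (defaults to the file name).
#' @return An object of class `"cleavage_ruleset"`.
#' @export
read_cleavage_rules <- function(path, name = basename(path)) {
  rules <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  needed <- c("enzyme", "kind", .window_positions)
  missing <- setdiff(needed, names(rules))
  if (length(missing)) {
    stop("rule file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(rules$kind %in% c("cleave", "block"))) {
    stop("rule kind must be 'cleave' or 'block'", call. = FALSE)
  }
  parsed <- lapply(seq_len(nrow(rules)), function(i) parse_rule_row(rules[i, ]))
  structure(list(name = name, rules = rules, parsed = parsed),
            class = "cleavage_ruleset")
}

#' Write a cleavage rule set to TSV
#'
#' Inverse of [read_cleavage_rules()]; the round trip is stable.
#'
#' @param ruleset A `"cleavage_ruleset"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cleavage_rules <- function(ruleset, path) {
  stopifnot(inherits(ruleset, "cleavage_ruleset"))
  utils::write.table(ruleset$rules, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The default gastrointestinal rule dialect
#'
#' The bundled four-enzyme rule set: trypsin (cut after K/R with the classical
#' exception motifs), low-specificity chymotrypsin (cut after F/Y/W/L/M/H with
#' the documented vetoes), and pepsin at pH 1.3 (F/L) and pH > 2 (F/L/W/Y) on
#' both the P1 and P1' side with proline- and basic-residue context vetoes.
#' The dialect was calibrated against the bundled fragment tables; see the
#' methods vignette.
#'
#' @param enzymes Optional character vector restricting the dialect to a
#'   subset of its enzymes.
#' @return A `"cleavage_ruleset"`.
#' @export
gi_ruleset <- function(enzymes = NULL) {
  if (is.null(.algapept_cache$gi_ruleset)) {
    .algapept_cache$gi_ruleset <-
      read_cleavage_rules(pkg_extdata("cleavage_rules_gi.tsv"),
                          name = "gi_default")
  }
  rs <- .algapept_cache$gi_ruleset
  if (!is.null(enzymes)) {
    keep <- rs$rules$enzyme %in% enzymes
    unknown <- setdiff(enzymes, rs$rules$enzyme)
    if (length(unknown)) {
      stop("unknown enzyme(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    rs <- structure(list(name = paste0(rs$name, "_subset"),
                         rules = rs$rules[keep, , drop = FALSE],
                         parsed = rs$parsed[keep]),
                    class = "cleavage_ruleset")
  }
  rs
}

#' @export
print.cleavage_ruleset <- function(x, ...) {
  cat(sprintf("<cleavage_ruleset> '%s': %d rules (%d cleave, %d block) for %s\n",
              x$name, nrow(x$rules), sum(x$rules$kind == "cleave"),
              sum(x$rules$kind == "block"),
              paste(unique(x$rules$enzyme), collapse = ", ")))
  invisible(x)
}

# rule match over all candidate sites at once -> logical vector
rule_matches_sites <- function(res, sites, rule) {
  ok <- rep(TRUE, length(sites))
  n <- length(res)
  for (con in rule$constraints) {
    idx <- sites + con$offset
    inside <- idx >= 1L & idx <= n
    aa <- rep(NA_character_, length(sites))
    aa[inside] <- res[idx[inside]]
    if (con$forbidden) {
      ok <- ok & (is.na(aa) | !(aa %in% con$set))
    } else {
      ok <- ok & (!is.na(aa) & aa %in% con$set)
    }
  }
  ok
}

#' Cleavage sites of a peptide under a rule set
#'
#' @param x A [peptide()] or a sequence string.
#' @param ruleset A `"cleavage_ruleset"` (default: [gi_ruleset()]).
#' @return Sorted integer vector of cut sites; site `i` lies between residues
#'   `i` and `i + 1`.
#' @examples
#' cleavage_sites("ATKPAN")  # integer(0): the K|P junction is vetoed
#' @export
cleavage_sites <- function(x, ruleset = gi_ruleset()) {
  stopifnot(inherits(ruleset, "cleavage_ruleset"))
  p <- as_peptide(x)
  res <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  if (n < 2L) return(integer(0))
  sites <- seq_len(n - 1L)
  cut <- rep(FALSE, n - 1L)
  for (enz in unique(vapply(ruleset$parsed, `[[`, character(1), "enzyme"))) {
    cleaves <- rep(FALSE, n - 1L)
    blocks <- rep(FALSE, n - 1L)
    for (rule in ruleset$parsed) {
      if (rule$enzyme != enz) next
      m <- rule_matches_sites(res, sites, rule)
      if (rule$kind == "cleave") cleaves <- cleaves | m else blocks <- blocks | m
    }
    cut <- cut | (cleaves & !blocks)
  }
  sites[cut]
}

make_digestion_result <- function(p, sites) {
  n <- nchar(p$sequence)
  bounds <- c(0L, sites, n)
  frag <- data.frame(
    sequence = substring(p$sequence, utils::head(bounds, -1L) + 1L, bounds[-1L]),
    start = utils::head(bounds, -1L) + 1L,
    end = bounds[-1L],
    stringsAsFactors = FALSE
  )
  structure(list(parent = p, cut_sites = sites, fragments = frag),
            class = "digestion_result")
}

#' Digest a peptide
#'
#' Applies all enzymes of the rule set simultaneously (their cut sites are
#' unioned in one pass) and returns the resulting fragments, which partition
#' the parent.
#'
#' @inheritParams cleavage_sites
#' @return An object of class `"digestion_result"`: list with `parent`,
#'   `cut_sites`, and a fragment `data.frame` (sequence, start, end; residue
#'   coordinates, ends inclusive).
#' @examples
#' digest("DEVIPGAL")$fragments$sequence  # "DEVIPGA" "L"
#' @export
digest <- function(x, ruleset = gi_ruleset()) {
  p <- as_peptide(x)
  make_digestion_result(p, cleavage_sites(p, ruleset))
}

#' @export
print.digestion_result <- function(x, ...) {
  cat(sprintf("<digestion_result> %s: %d cut site(s) -> %s\n",
              x$parent$sequence, length(x$cut_sites),
              paste(x$fragments$sequence, collapse = " | ")))
  invisible(x)
}

#' Is a peptide digestion-resistant?
#'
#' @inheritParams cleavage_sites
#' @return `TRUE` iff no rule cuts the peptide (single fragment = parent).
#' @export
is_intact <- function(x, ruleset = gi_ruleset()) {
  length(cleavage_sites(x, ruleset)) == 0L
}

#' Naive reference digestion (testing oracle)
#'
#' Evaluates every rule at every site with plain per-position loops, sharing
#' no code with the vectorised engine. Must agree with [digest()] on all
#' inputs.
#'
#' @inheritParams cleavage_sites
#' @return A `"digestion_result"`.
#' @export
brute_force_digest <- function(x, ruleset = gi_ruleset()) {
  stopifnot(inherits(ruleset, "cleavage_ruleset"))
  p <- as_peptide(x)
  res <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  sites <- integer(0)
  if (n >= 2L) {
    enzymes <- unique(ruleset$rules$enzyme)
    for (i in seq_len(n - 1L)) {
      site_cut <- FALSE
      for (enz in enzymes) {
        matched <- FALSE
        vetoed <- FALSE
        for (j in seq_along(ruleset$parsed)) {
          rule <- ruleset$parsed[[j]]
          if (rule$enzyme != enz) next
          hit <- TRUE
          for (con in rule$constraints) {
            k <- i + con$offset
            aa <- if (k >= 1L && k <= n) res[k] else NA_character_
            if (con$forbidden) {
              if (!is.na(aa) && aa %in% con$set) { hit <- FALSE; break }
            } else {
              if (is.na(aa) || !(aa %in% con$set)) { hit <- FALSE; break }
            }
          }
          if (hit) {
            if (rule$kind == "cleave") matched <- TRUE else vetoed <- TRUE
          }
        }
        if (matched && !vetoed) { site_cut <- TRUE; break }
      }
      if (site_cut) sites <- c(sites, i)
    }
  }
  make_digestion_result(p, sites)
}

#' Pool the unique digestion fragments of many peptides
#'
#' Digests every parent, drops fragments shorter than `min_length`, and
#' deduplicates across the pool while tracking provenance. Intact parents
#' appear as their own (single) fragment.
#'
#' @param peptides Peptides (list, character vector, or single peptide).
#' @param ruleset A `"cleavage_ruleset"`.
#' @param min_length Minimum fragment length kept (default 2: single residues
#'   are uninformative for dipeptide matching).
#' @return An object of class `"fragment_pool"`: list with
#'   `fragments` (`data.frame`: sequence, n_occurrences, parents, starts),
#'   `digestions` (per-parent `"digestion_result"`s), `intact` (sequences of
#'   digestion-resistant parents), `min_length`, and `ruleset_name`.
#' @examples
#' pool <- digest_pool(c("DEVIPGAL", "PVGCLPK"))
#' pool$fragments$sequence
#' @export
digest_pool <- function(peptides, ruleset = gi_ruleset(), min_length = 2L) {
  peptides <- as_peptide_list(peptides)
  if (!length(peptides)) stop("need at least one peptide", call. = FALSE)
  ids <- peptide_ids(peptides)
  digestions <- lapply(peptides, digest, ruleset = ruleset)
  names(digestions) <- ids

  rows <- do.call(rbind, lapply(seq_along(digestions), function(i) {
    fr <- digestions[[i]]$fragments
    fr$parent <- ids[i]
    fr
  }))
  rows <- rows[nchar(rows$sequence) >= min_length, , drop = FALSE]

  uniq <- unique(rows$sequence)
  frag <- data.frame(
    sequence = uniq,
    n_occurrences = as.integer(table(rows$sequence)[uniq]),
    parents = vapply(uniq, function(s) {
      paste(unique(rows$parent[rows$sequence == s]), collapse = ";")
    }, character(1)),
    starts = vapply(uniq, function(s) {
      paste(rows$start[rows$sequence == s], collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  intact <- peptide_sequences(peptides)[
    vapply(digestions, function(d) length(d$cut_sites) == 0L, logical(1))]
  structure(list(fragments = frag, digestions = digestions,
                 intact = unname(intact), min_length = min_length,
                 ruleset_name = ruleset$name),
            class = "fragment_pool")
}

#' @export
print.fragment_pool <- function(x, ...) {
  cat(sprintf(
    "<fragment_pool> %d unique fragments (length >= %d) from %d parents; %d intact [dialect %s]\n",
    nrow(x$fragments), x$min_length, length(x$digestions), length(x$intact),
    x$ruleset_name))
  invisible(x)
}
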