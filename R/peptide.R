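# Core peptide domain type: a validated residue sequence over the standard
# 20-letter alphabet, an optional id, and optional site-specific modifications.

#' The 20-letter amino-acid alphabet
#'
#' Residue one-letter codes accepted by [validate_sequence()]. Ambiguity and
#' non-standard codes (B, J, O, U, X, Z) are rejected everywhere.
#'
#' @return Character vector of the 20 residue letters.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# registered modifications and their monoisotopic mass deltas (Da)
.modification_registry <- c(deamidation = 0.984016)

# residues a modification may annotate
.modification_targets <- list(deamidation = c("N", "Q"))

#' Construct a peptide
#'
#' @param sequence Character scalar over the 20-letter alphabet (any case).
#' @param id Optional text label.
#' @param modifications Optional `data.frame` with columns `position` (1-based
#'   residue index) and `kind` (a registered modification name, currently only
#'   `"deamidation"`), or a search-engine-style annotation string such as
#'   `"Deamidated (N)@2"`.
#' @return An object of class `"peptide"`: a list with elements `id`,
#'   `sequence` and `modifications`.
#' @examples
#' peptide("ATKPAN", id = "p1")
#' peptide("INNNKIITNL", modifications = "Deamidated (N)@2")
#' @export
peptide <- function(sequence, id = NULL, modifications = NULL) {
  p <- validate_sequence(sequence, id = id)
  if (!is.null(modifications)) {
    if (is.character(modifications)) {
      modifications <- parse_modifications(modifications)
    }
    p$modifications <- validate_modifications(modifications, p$sequence)
  }
  p
}

#' Validate a raw peptide sequence
#'
#' Trims whitespace, uppercases, and checks every character against the
#' 20-letter alphabet. Ambiguity codes (B, J, O, U, X, Z) are rejected.
#'
#' @param raw Character scalar.
#' @param id Optional label attached to the returned peptide.
#' @return A `"peptide"` object with no modifications.
#' @examples
#' validate_sequence("atkpan")$sequence  # "ATKPAN"
#' @export
validate_sequence <- function(raw, id = NULL) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop("sequence must be a single character string", call. = FALSE)
  }
  seq <- toupper(trimws(raw))
  if (!nzchar(seq)) stop("empty peptide sequence", call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% aa_alphabet()))
  if (length(bad)) {
    stop(sprintf("illegal residue '%s' at position %d", chars[bad[1]], bad[1]),
         call. = FALSE)
  }
  structure(
    list(id = if (is.null(id)) NA_character_ else as.character(id),
         sequence = seq,
         modifications = empty_modifications()),
    class = "peptide"
  )
}

empty_modifications <- function() {
  data.frame(position = integer(0), kind = character(0),
             stringsAsFactors = FALSE)
}

# "Deamidated (N)@2" / "Deamidated (N)@2; Deamidated (Q)@5" -> data.frame
parse_modifications <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) return(empty_modifications())
  parts <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  kind <- ifelse(grepl("^Deamidated", parts, ignore.case = TRUE),
                 "deamidation", NA_character_)
  if (anyNA(kind)) {
    stop("unrecognised modification annotation: ", parts[is.na(kind)][1],
         call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(sub("^.*@", "", parts)))
  if (anyNA(pos)) stop("modification annotation lacks '@<position>'", call. = FALSE)
  data.frame(position = pos, kind = kind, stringsAsFactors = FALSE)
}

validate_modifications <- function(mods, sequence) {
  stopifnot(is.data.frame(mods), all(c("position", "kind") %in% names(mods)))
  mods$position <- as.integer(mods$position)
  mods$kind <- as.character(mods$kind)
  unknown <- setdiff(mods$kind, names(.modification_registry))
  if (length(unknown)) {
    stop("unregistered modification kind: ", unknown[1], call. = FALSE)
  }
  n <- nchar(sequence)
  if (any(mods$position < 1L | mods$position > n)) {
    stop("modification position outside sequence (length ", n, ")", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(mods))) {
    targets <- .modification_targets[[mods$kind[i]]]
    if (!(chars[mods$position[i]] %in% targets)) {
      stop(sprintf("%s not annotatable at %s%d (allowed residues: %s)",
                   mods$kind[i], chars[mods$position[i]], mods$position[i],
                   paste(targets, collapse = "/")), call. = FALSE)
    }
  }
  mods[order(mods$position), , drop = FALSE]
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("<peptide> %s  %s (%d aa)\n",
              ifelse(is.na(x$id), "", x$id), x$sequence, nchar(x$sequence)))
  if (nrow(x$modifications)) {
    cat("  modifications: ",
        paste(sprintf("%s@%d", x$modifications$kind, x$modifications$position),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.character.peptide <- function(x, ...) x$sequence

# Coerce x (peptide | character scalar) to a peptide.
as_peptide <- function(x) {
  if (inherits(x, "peptide")) return(x)
  if (is.character(x) && length(x) == 1L) return(validate_sequence(x))
  stop("expected a peptide or a single sequence string", call. = FALSE)
}

# Coerce x (list of peptides | character vector | single peptide) to a list of
# peptides; character vector names become ids, else p1, p2, ...
as_peptide_list <- function(x) {
  if (inherits(x, "peptide")) return(list(x))
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("p", seq_along(x))
    return(unname(Map(function(s, i) validate_sequence(s, id = i), x, ids)))
  }
  if (is.list(x)) {
    stopifnot(all(vapply(x, inherits, logical(1), "peptide")))
    return(x)
  }
  stop("expected peptides (list, character vector, or single peptide)",
       call. = FALSE)
}

peptide_ids <- function(peptides) {
  ids <- vapply(peptides, function(p) p$id, character(1))
  ids[is.na(ids)] <- paste0("p", which(is.na(ids)))
  ids
}

peptide_sequences <- function(peptides) {
  vapply(peptides, function(p) p$sequence, character(1))
}

#' Read peptides from a FASTA file
#'
#' Accepts wrapped or unwrapped sequence lines. Every sequence is validated
#' against the 20-letter alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A list of [peptide()] objects (empty list for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  content <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), ";"))
  if (!length(content)) return(list())
  first <- content[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop(sprintf("malformed FASTA: sequence before header at line %d", first),
         call. = FALSE)
  }
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  unname(Map(function(s, i) validate_sequence(s, id = i),
             as.character(set), ids))
}

#' Write peptides to a FASTA file
#'
#' @param peptides Peptides (list of [peptide()], or character vector).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(peptides, path) {
  peptides <- as_peptide_list(peptides)
  set <- Biostrings::AAStringSet(peptide_sequences(peptides))
  names(set) <- peptide_ids(peptides)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
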