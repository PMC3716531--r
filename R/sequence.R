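#' Developmental sequences
#'
#' A developmental sequence is an ordered list of simultaneity blocks
#' ("ranks"): each rank is a non-empty set of event labels observed at the
#' same position in ontogeny, at the resolution of the study. Events of the
#' catalogue that do not occur in the taxon (or were not observed) are
#' recorded as `missing` and score unknown in every event pair.
#'
#' The text notation writes consecutive events separated by commas and
#' simultaneous events joined by dashes, e.g. `"A,B-C,D"` is the sequence
#' with ranks \{A\}, \{B, C\}, \{D\}.
#'
#' @param taxon Taxon (or node) identifier.
#' @param ranks A list of character vectors, one per simultaneity block.
#' @param missing Character vector of absent/unobserved event labels.
#' @param catalog An [event_catalog] the labels are validated against.
#' @return An object of class `dev_sequence`.
#' @export
dev_sequence <- function(taxon, ranks, missing = character(), catalog = NULL) {
  ranks <- lapply(ranks, as.character)
  missing <- as.character(missing)
  if (any(vapply(ranks, length, 1L) == 0)) {
    stop("every rank must contain at least one event", call. = FALSE)
  }
  placed <- unlist(ranks, use.names = FALSE)
  dup <- unique(placed[duplicated(placed)])
  if (length(dup) > 0) {
    stop("event(s) repeated in sequence: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  both <- intersect(placed, missing)
  if (length(both) > 0) {
    stop("event(s) both placed and missing: ", paste(both, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(catalog)) {
    assert_catalog_labels(c(placed, missing), catalog)
  }
  structure(
    list(taxon = as.character(taxon), ranks = ranks, missing = sort(missing)),
    class = "dev_sequence"
  )
}

#' Parse a developmental sequence from text notation
#'
#' Commas separate consecutive ranks, dashes join simultaneous events:
#' `"A,B-C,D"` has three ranks with B and C simultaneous. Catalogue events
#' that are neither placed nor declared absent are treated as missing, as
#' are events listed in `absent`.
#'
#' @param text The sequence string.
#' @param catalog An [event_catalog].
#' @param taxon Taxon identifier to attach.
#' @param absent Character vector (or single comma-separated string) of
#'   events declared absent in this taxon.
#' @return A [dev_sequence].
#' @examples
#' cat4 <- event_catalog(data.frame(
#'   label = c("A", "B", "C", "D"), description = "",
#'   category = c("hatching", rep("morphological", 3))
#' ))
#' s <- parse_sequence("A,B-C,D", cat4, taxon = "toy")
#' s$ranks
#' @export
parse_sequence <- function(text, catalog, taxon = "unknown", absent = character()) {
  stopifnot(length(text) == 1, is.character(text))
  if (length(absent) == 1 && grepl(",", absent)) {
    absent <- strsplit(absent, ",", fixed = TRUE)[[1]]
  }
  absent <- trimws(absent[nzchar(trimws(absent))])
  text <- trimws(text)
  if (!nzchar(text)) stop("empty sequence string", call. = FALSE)
  rank_strings <- strsplit(text, ",", fixed = TRUE)[[1]]
  ranks <- lapply(rank_strings, function(r) {
    toks <- trimws(strsplit(r, "-", fixed = TRUE)[[1]])
    toks[nzchar(toks)]
  })
  placed <- unlist(ranks, use.names = FALSE)
  assert_catalog_labels(c(placed, absent), catalog)
  missing <- union(setdiff(event_labels(catalog), placed), absent)
  dev_sequence(taxon, ranks, missing, catalog)
}

#' Render a developmental sequence in text notation
#' @param seq A [dev_sequence].
#' @return A single string in comma/dash notation.
#' @export
format_sequence <- function(seq) {
  stopifnot(inherits(seq, "dev_sequence"))
  paste(vapply(seq$ranks, paste, "", collapse = "-"), collapse = ",")
}

#' @export
format.dev_sequence <- function(x, ...) format_sequence(x)

#' @export
print.dev_sequence <- function(x, ...) {
  cat("<dev_sequence> ", x$taxon, "\n  ", format_sequence(x), "\n", sep = "")
  if (length(x$missing) > 0) {
    cat("  missing: ", paste(x$missing, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Rank index of every placed event
#'
#' @param seq A [dev_sequence].
#' @return Named integer vector mapping event label to 1-based rank index.
#' @export
event_ranks <- function(seq) {
  stopifnot(inherits(seq, "dev_sequence"))
  if (length(seq$ranks) == 0) return(stats::setNames(integer(0), character(0)))
  lens <- vapply(seq$ranks, length, 1L)
  stats::setNames(rep(seq_along(seq$ranks), lens),
                  unlist(seq$ranks, use.names = FALSE))
}

#' @export
as_tibble.dev_sequence <- function(x, ...) {
  r <- event_ranks(x)
  dplyr::bind_rows(
    tibble::tibble(taxon = x$taxon, event = names(r), rank = unname(r)),
    tibble::tibble(taxon = x$taxon, event = x$missing,
                   rank = rep(NA_integer_, length(x$missing)))
  )
}

#' Read per-taxon developmental sequences from a TSV file
#'
#' The file must have a header and columns `taxon` and `sequence`; an
#' optional `absent` column lists comma-separated declared-absent events.
#' Additional columns are carried along untouched.
#'
#' @param path Path to the sequence table.
#' @param catalog An [event_catalog].
#' @return A tibble with one row per taxon and a list-column `seq` of
#'   [dev_sequence] objects.
#' @examples
#' cat27 <- read_event_catalog(
#'   system.file("extdata", "branchiopod_events.tsv", package = "parsimovr"))
#' pen <- read_sequences(
#'   system.file("extdata", "penilia_avirostris.tsv", package = "parsimovr"),
#'   cat27)
#' pen$seq[[1]]
#' @export
read_sequences <- function(path, catalog) {
  if (!file.exists(path)) stop("sequence file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE)
  if (!all(c("taxon", "sequence") %in% names(df))) {
    stop("sequence file needs columns 'taxon' and 'sequence'", call. = FALSE)
  }
  if (nrow(df) == 0) stop("sequence file has no rows", call. = FALSE)
  absent <- if ("absent" %in% names(df)) df$absent else rep("", nrow(df))
  absent[is.na(absent)] <- ""
  df <- tibble::as_tibble(df)
  df$seq <- purrr::pmap(
    list(df$sequence, df$taxon, absent),
    function(s, tx, ab) parse_sequence(s, catalog, taxon = tx, absent = ab)
  )
  df
}

#' Write developmental sequences to a TSV file
#' @param seq_tbl A tibble with a `seq` list-column (as from
#'   [read_sequences()] or [simulate_on_tree()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seq_tbl, path) {
  seqs <- seq_tbl$seq
  out <- tibble::tibble(
    taxon = vapply(seqs, function(s) s$taxon, ""),
    sequence = vapply(seqs, format_sequence, ""),
    absent = vapply(seqs, function(s) paste(s$missing, collapse = ","), "")
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
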