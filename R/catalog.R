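#' Event catalogues
#'
#' An event catalogue is the ordered list of developmental events a study
#' scores: a short `label`, a free-text `description`, and a `category`
#' that is one of `"morphological"`, `"hatching"` or `"molt"`. The row
#' order of the catalogue defines the canonical event order used to orient
#' event pairs, so two catalogues with the same rows in a different order
#' encode different (but equivalent) character sets.
#'
#' A catalogue may contain at most one hatching event; labels must be
#' unique. The bundled branchiopod catalogue
#' (`system.file("extdata", "branchiopod_events.tsv", package = "parsimovr")`)
#' has 27 events: one hatching event (A), five molts (I, O, V, Y, AA) and
#' 21 morphological events.
#'
#' @param entries A data frame with columns `label`, `description`,
#'   `category` (extra columns are kept but ignored).
#' @return A tibble of class `event_catalog`.
#' @examples
#' cat4 <- event_catalog(data.frame(
#'   label = c("A", "B", "C", "D"),
#'   description = c("hatch", "eye", "limb", "molt 1"),
#'   category = c("hatching", "morphological", "morphological", "molt")
#' ))
#' event_labels(cat4)
#' @export
event_catalog <- function(entries) {
  entries <- tibble::as_tibble(entries)
  required <- c("label", "description", "category")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0) {
    stop("catalogue is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  entries$label <- as.character(entries$label)
  entries$category <- as.character(entries$category)
  dup <- unique(entries$label[duplicated(entries$label)])
  if (length(dup) > 0) {
    stop("duplicate event label(s) in catalogue: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_cat <- setdiff(unique(entries$category), valid_categories())
  if (length(bad_cat) > 0) {
    stop("unknown event category: ", paste(bad_cat, collapse = ", "),
         "; must be one of ", paste(valid_categories(), collapse = ", "),
         call. = FALSE)
  }
  if (sum(entries$category == "hatching") > 1) {
    stop("catalogue may contain at most one hatching event", call. = FALSE)
  }
  if (nrow(entries) == 0) stop("catalogue is empty", call. = FALSE)
  class(entries) <- c("event_catalog", class(entries))
  entries
}

valid_categories <- function() c("morphological", "hatching", "molt")

#' Read an event catalogue from a TSV file
#'
#' The file must be tab-separated with a header row and columns
#' `label`, `description`, `category`.
#'
#' @param path Path to the catalogue file.
#' @return A tibble of class [event_catalog].
#' @examples
#' path <- system.file("extdata", "branchiopod_events.tsv", package = "parsimovr")
#' cat27 <- read_event_catalog(path)
#' nrow(cat27) # 27
#' @export
read_event_catalog <- function(path) {
  if (!file.exists(path)) stop("catalogue file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE, check.names = TRUE)
  event_catalog(df)
}

#' @rdname event_catalog
#' @param catalog An [event_catalog].
#' @export
event_labels <- function(catalog) {
  stopifnot(inherits(catalog, "event_catalog"))
  catalog$label
}

#' Labels of a given category
#' @param catalog An [event_catalog].
#' @param category One of `"morphological"`, `"hatching"`, `"molt"`.
#' @return Character vector of labels, in catalogue order.
#' @export
category_labels <- function(catalog, category) {
  category <- match.arg(category, valid_categories())
  catalog$label[catalog$category == category]
}

#' @export
print.event_catalog <- function(x, ...) {
  cat("<event_catalog> ", nrow(x), " events (",
      sum(x$category == "morphological"), " morphological, ",
      sum(x$category == "hatching"), " hatching, ",
      sum(x$category == "molt"), " molt)\n", sep = "")
  NextMethod()
}

assert_catalog_labels <- function(labels, catalog, what = "event") {
  unknown <- setdiff(labels, event_labels(catalog))
  if (length(unknown) > 0) {
    stop("unknown ", what, " label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  invisible(labels)
}
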