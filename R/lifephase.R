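#' Identify the metamorphosis molt of a sequence
#'
#' The metamorphosis molt ends the larval phase: it is the earliest molt
#' after hatching that is followed by no further morphological event.
#' Morphological events simultaneous with a molt are treated as occurring
#' within the stage that molt closes (so they do not disqualify it).
#'
#' @param seq A [dev_sequence] containing the hatching event and at least
#'   one molt after it.
#' @param catalog The [event_catalog].
#' @return The molt's event label.
#' @examples
#' cat27 <- read_event_catalog(
#'   system.file("extdata", "branchiopod_events.tsv", package = "parsimovr"))
#' pen <- read_sequences(
#'   system.file("extdata", "penilia_avirostris.tsv", package = "parsimovr"),
#'   cat27)
#' metamorphosis_molt(pen$seq[[1]], cat27) # "O"
#' @export
metamorphosis_molt <- function(seq, catalog) {
  r <- event_ranks(seq)
  hatch <- intersect(names(r), category_labels(catalog, "hatching"))
  if (length(hatch) == 0) stop("hatching event not placed in sequence",
                               call. = FALSE)
  hatch_rank <- r[[hatch]]
  molts <- intersect(names(r), category_labels(catalog, "molt"))
  molts <- molts[r[molts] > hatch_rank]
  if (length(molts) == 0) stop("no molt after hatching", call. = FALSE)
  morph <- intersect(names(r), category_labels(catalog, "morphological"))
  last_morph <- if (length(morph) == 0) -Inf else max(r[morph])
  # earliest molt with no morphological event strictly after it
  ok <- molts[r[molts] >= last_morph]
  if (length(ok) == 0) {
    stop("no metamorphosis identifiable: morphological events occur after ",
         "every molt", call. = FALSE)
  }
  ok[which.min(r[ok])]
}

#' Classify events of a sequence into life phases
#'
#' Morphological events strictly before hatching are embryonic; from
#' hatching up to and including the metamorphosis molt, larval; after it,
#' juvenile. Events simultaneous with hatching or with the metamorphosis
#' molt count as larval (a logged convention; printed sequences never
#' exhibit these ties). Molts strictly between hatching and the
#' metamorphosis molt are the pre-metamorphosis molts.
#'
#' @inheritParams metamorphosis_molt
#' @return A tibble with one row per catalogue event: `event`, `category`,
#'   `rank` (NA if missing) and `phase` in
#'   `c("embryonic", "larval", "juvenile", "hatching",
#'   "pre-metamorphosis molt", "metamorphosis molt", "post-metamorphosis
#'   molt", "pre-hatching molt", NA)`.
#' @export
classify_phases <- function(seq, catalog) {
  r <- event_ranks(seq)
  hatch <- intersect(names(r), category_labels(catalog, "hatching"))
  if (length(hatch) == 0) stop("hatching event not placed in sequence",
                               call. = FALSE)
  hatch_rank <- r[[hatch]]
  meta <- metamorphosis_molt(seq, catalog)
  meta_rank <- r[[meta]]

  out <- tibble::tibble(
    event = event_labels(catalog),
    category = catalog$category,
    rank = unname(r[event_labels(catalog)])
  )
  phase <- rep(NA_character_, nrow(out))
  for (i in seq_len(nrow(out))) {
    rk <- out$rank[i]
    if (is.na(rk)) next
    if (out$category[i] == "hatching") {
      phase[i] <- "hatching"
    } else if (out$category[i] == "molt") {
      phase[i] <- if (rk < hatch_rank) "pre-hatching molt"
        else if (out$event[i] == meta) "metamorphosis molt"
        else if (rk < meta_rank) "pre-metamorphosis molt"
        else "post-metamorphosis molt"
    } else {
      phase[i] <- if (rk < hatch_rank) "embryonic"
        else if (rk <= meta_rank) "larval"
        else "juvenile"
    }
  }
  out$phase <- phase
  out
}

#' Life-phase summary of a sequence
#'
#' Counts, per sequence, the embryonic and larval morphological events,
#' the pre-metamorphosis molts, and the pre-metamorphosis stages: the
#' inter-molt intervals between hatching and the metamorphosis molt
#' (inclusive) containing at least one morphological event. An event
#' simultaneous with a molt belongs to the stage that molt closes.
#'
#' @inheritParams metamorphosis_molt
#' @param node Optional node/taxon label for the output row (defaults to
#'   the sequence's taxon).
#' @param optimization Tag for the output row, e.g. `"observed"`,
#'   `"ACCTRAN"`, `"DELTRAN"`.
#' @return A one-row tibble: `node`, `optimization`, `embryonic`, `larval`,
#'   `pre_meta_molts`, `pre_meta_stages`, `metamorphosis_molt`,
#'   `unplaced` (catalogue events missing from the sequence).
#' @examples
#' cat27 <- read_event_catalog(
#'   system.file("extdata", "branchiopod_events.tsv", package = "parsimovr"))
#' pen <- read_sequences(
#'   system.file("extdata", "penilia_avirostris.tsv", package = "parsimovr"),
#'   cat27)
#' phase_summary(pen$seq[[1]], cat27) # 6 embryonic, 13 larval, 1 molt, 2 stages
#' @export
phase_summary <- function(seq, catalog, node = NULL, optimization = "observed") {
  cls <- classify_phases(seq, catalog)
  r <- event_ranks(seq)
  hatch <- intersect(names(r), category_labels(catalog, "hatching"))
  hatch_rank <- r[[hatch]]
  meta <- metamorphosis_molt(seq, catalog)
  meta_rank <- r[[meta]]

  pre_molts <- cls$event[!is.na(cls$phase) & cls$phase == "pre-metamorphosis molt"]
  # stage boundaries: hatching, then molts in rank order up to metamorphosis
  bounds <- c(hatch_rank, sort(unname(r[pre_molts])), meta_rank)
  morph_ranks <- cls$rank[cls$category == "morphological" &
                            !is.na(cls$phase) & cls$phase == "larval"]
  stages <- 0L
  for (k in seq_len(length(bounds) - 1)) {
    lo <- bounds[k]
    hi <- bounds[k + 1]
    # interval (lo, hi]: events tied with the closing molt count inside;
    # events tied with hatching (lo = hatch) also count in the first stage
    inside <- morph_ranks > lo & morph_ranks <= hi
    if (k == 1) inside <- inside | morph_ranks == lo
    if (any(inside)) stages <- stages + 1L
  }

  tibble::tibble(
    node = node %||% seq$taxon,
    optimization = optimization,
    embryonic = sum(cls$phase == "embryonic", na.rm = TRUE),
    larval = sum(cls$phase == "larval", na.rm = TRUE),
    pre_meta_molts = length(pre_molts),
    pre_meta_stages = stages,
    metamorphosis_molt = meta,
    unplaced = sum(is.na(cls$rank))
  )
}

#' Life-phase summaries for every node of a reconstruction
#'
#' Derives the ancestral sequence at every internal node under each
#' resolved optimization (repairing transitively inconsistent ancestral
#' tables by collapsing cycles into simultaneity ranks, with a flag), adds
#' the observed tip sequences, and summarizes each with [phase_summary()].
#' Nodes whose derived sequence lacks the hatching event or an
#' identifiable metamorphosis are flagged in the `note` column rather than
#' dropped.
#'
#' @param recon A resolved `epp_recon` (both optimizations resolved).
#' @param catalog The [event_catalog].
#' @param tip_seqs Optional list of observed [dev_sequence]s (named by
#'   taxon) to include as `"observed"` rows.
#' @return A tibble with one row per node x optimization, Table-style
#'   columns as in [phase_summary()], plus `note`.
#' @export
summarize_tree <- function(recon, catalog, tip_seqs = NULL) {
  rows <- list()
  add_row <- function(seq, node, optimization) {
    note <- if (isTRUE(attr(seq, "repaired"))) "repaired" else ""
    row <- tryCatch(
      phase_summary(seq, catalog, node = node, optimization = optimization),
      error = function(e) tibble::tibble(
        node = node, optimization = optimization,
        embryonic = NA_integer_, larval = NA_integer_,
        pre_meta_molts = NA_integer_, pre_meta_stages = NA_integer_,
        metamorphosis_molt = NA_character_, unplaced = NA_integer_
      )
    )
    row$note <- if (is.na(row$embryonic[1])) paste0(note, " unsummarizable")
                else note
    rows[[length(rows) + 1]] <<- row
  }
  if (!is.null(tip_seqs)) {
    for (s in tip_seqs) add_row(s, s$taxon, "observed")
  }
  internal <- recon$tree$node.label
  for (optimization in names(recon$resolved)) {
    for (nd in internal) {
      code <- node_code(recon, nd, optimization)
      seq <- derive_sequence(code, catalog, node = nd, repair = TRUE)
      add_row(seq, nd, optimization)
    }
  }
  dplyr::bind_rows(rows)
}
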