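#' Full ancestral-sequence analysis
#'
#' Runs the whole event-pairing pipeline: encodes the observed sequences,
#' reconstructs ancestral event-pair states on the tree under parsimony,
#' resolves both ACCTRAN and DELTRAN, derives ancestral developmental
#' sequences at every internal node, and extracts per-branch character
#' changes.
#'
#' @param seq_tbl Tibble with a `seq` list-column of [dev_sequence]s (one
#'   per tip; see [read_sequences()]).
#' @param tree Rooted `phylo` tree whose tip labels match the taxa.
#' @param catalog The [event_catalog].
#' @param treatment Character treatment, `"unordered"` (default) or
#'   `"ordered"`.
#' @return An object of class `epp_analysis`: `recon` (resolved
#'   `epp_recon`), `catalog`, `tip_seqs`, `ancestors` (tibble `node`,
#'   `optimization`, `seq` list-column, `repaired` flag), `changes` (named
#'   list of change tibbles per optimization).
#' @examples
#' \donttest{
#' cat27 <- read_event_catalog(
#'   system.file("extdata", "branchiopod_events.tsv", package = "parsimovr"))
#' tree <- read_tree(
#'   system.file("extdata", "branchiopoda.nwk", package = "parsimovr"))
#' sim <- simulate_on_tree(tree, random_root_sequence(cat27, 9, seed = 7),
#'                         shift_model(n_shifts_per_branch = 1, seed = 7))
#' ana <- reconstruct_ancestors(sim$sequences, tree, cat27)
#' summarize_tree(ana$recon, cat27)
#' }
#' @export
reconstruct_ancestors <- function(seq_tbl, tree, catalog,
                                  treatment = c("unordered", "ordered")) {
  treatment <- match.arg(treatment)
  codes <- encode_sequences(seq_tbl, catalog)
  recon <- fitch_mpr(tree, codes, treatment)
  recon <- resolve_acctran(recon)
  recon <- resolve_deltran(recon)

  anc_rows <- list()
  for (optimization in c("ACCTRAN", "DELTRAN")) {
    for (nd in recon$tree$node.label) {
      code <- node_code(recon, nd, optimization)
      s <- derive_sequence(code, catalog, node = nd, repair = TRUE)
      anc_rows[[length(anc_rows) + 1]] <- tibble::tibble(
        node = nd, optimization = optimization, seq = list(s),
        repaired = isTRUE(attr(s, "repaired"))
      )
    }
  }
  tip_seqs <- stats::setNames(seq_tbl$seq,
                              vapply(seq_tbl$seq, function(s) s$taxon, ""))
  structure(
    list(recon = recon, catalog = catalog, tip_seqs = tip_seqs,
         ancestors = dplyr::bind_rows(anc_rows),
         changes = list(ACCTRAN = branch_changes(recon, "ACCTRAN"),
                        DELTRAN = branch_changes(recon, "DELTRAN"))),
    class = "epp_analysis"
  )
}

#' @export
print.epp_analysis <- function(x, ...) {
  cat("<epp_analysis> ", length(x$tip_seqs), " taxa, ",
      nrow(x$recon$pairs), " event-pair characters, total tree length ",
      sum(x$recon$length), "\n", sep = "")
  invisible(x)
}

branch_label <- function(parent, child) paste0(parent, "->", child)

#' Infer heterochronic event movements on every branch
#'
#' For each branch and each optimization, enumerates all minimal movement
#' sets explaining the branch's event-pair changes, takes the
#' necessary-movement consensus, and intersects the two optimizations into
#' the conservative cross-optimization consensus (optimization-specific
#' movements are kept in side channels).
#'
#' @param analysis An `epp_analysis` from [reconstruct_ancestors()].
#' @return An object of class `parsimov_shifts`: `ACCTRAN` and `DELTRAN`
#'   (named lists of `shift_report` per branch), `consensus` (named list
#'   of `cross_report`), and `indeterminate` per-branch unknown-change
#'   counts.
#' @export
infer_shifts <- function(analysis) {
  stopifnot(inherits(analysis, "epp_analysis"))
  catalog <- analysis$catalog
  tree <- analysis$recon$tree
  nm <- node_names(tree)
  branches <- apply(tree$edge, 1, function(e) branch_label(nm[e[1]], nm[e[2]]))

  reports <- list()
  for (optimization in c("ACCTRAN", "DELTRAN")) {
    chg <- analysis$changes[[optimization]]
    per_branch <- list()
    for (b in seq_along(branches)) {
      e <- tree$edge[b, ]
      sub <- chg[chg$parent == nm[e[1]] & chg$child == nm[e[2]], , drop = FALSE]
      sets <- minimal_move_sets(sub, catalog)
      per_branch[[branches[b]]] <- consensus_shifts(sets, sub,
                                                    branch = branches[b])
    }
    reports[[optimization]] <- per_branch
  }
  consensus <- lapply(branches, function(b) {
    cross_optimization_consensus(reports$ACCTRAN[[b]], reports$DELTRAN[[b]])
  })
  names(consensus) <- branches
  structure(
    list(ACCTRAN = reports$ACCTRAN, DELTRAN = reports$DELTRAN,
         consensus = consensus,
         indeterminate = attr(analysis$changes$ACCTRAN, "indeterminate")),
    class = "parsimov_shifts"
  )
}

#' @export
print.parsimov_shifts <- function(x, ...) {
  n_mov <- sum(vapply(x$consensus, function(r) nrow(r$necessary), 1L))
  n_joint <- sum(vapply(x$consensus, function(r) nrow(r$joint), 1L))
  cat("<parsimov_shifts> ", length(x$consensus), " branches: ",
      n_mov, " consensus movement(s), ", n_joint, " joint group(s)\n", sep = "")
  invisible(x)
}

#' Movement table in printed-report shape
#'
#' Flattens a `parsimov_shifts` object into one row per reported movement
#' (or joint group, rendered as `"C/D"`), with the branch, direction,
#' reference events, and a `status` column: `"consensus"` for movements
#' present under both optimizations, `"joint"` for joint groups, and
#' `"ACCTRAN_only"`/`"DELTRAN_only"` for the side channels.
#'
#' @param shifts A `parsimov_shifts` object.
#' @return A tibble with columns `branch`, `event`, `direction`,
#'   `reference`, `status`.
#' @export
shift_table <- function(shifts) {
  stopifnot(inherits(shifts, "parsimov_shifts"))
  rows <- list()
  fmt_ref <- function(r) paste(r, collapse = ",")
  for (b in names(shifts$consensus)) {
    cr <- shifts$consensus[[b]]
    for (i in seq_len(nrow(cr$necessary))) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        branch = b, event = cr$necessary$event[i],
        direction = cr$necessary$direction[i],
        reference = fmt_ref(cr$necessary$reference[[i]]), status = "consensus")
    }
    for (i in seq_len(nrow(cr$joint))) {
      dirs <- unique(cr$joint$directions[[i]])
      rows[[length(rows) + 1]] <- tibble::tibble(
        branch = b,
        event = if (length(dirs) == 1)
          paste(cr$joint$events[[i]], collapse = "/")
        else paste0(cr$joint$events[[i]], "(",
                    cr$joint$directions[[i]], ")", collapse = "/"),
        direction = if (length(dirs) == 1) dirs else "mixed",
        reference = fmt_ref(cr$joint$reference[[i]]), status = "joint")
    }
    for (side in c("acctran_only", "deltran_only")) {
      tb <- cr[[side]]
      for (i in seq_len(nrow(tb))) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          branch = b, event = tb$event[i], direction = tb$direction[i],
          reference = fmt_ref(tb$reference[[i]]),
          status = paste0(toupper(sub("_only", "", side)), "_only"))
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(branch = character(0), event = character(0),
                          direction = character(0), reference = character(0),
                          status = character(0)))
  }
  dplyr::bind_rows(rows)
}

# ---- broom-style methods ----------------------------------------------------

#' Tidy a reconstruction into its per-branch changes
#' @param x An `epp_recon` (resolved) or `parsimov_shifts` object.
#' @param optimization Which resolution to tidy (for reconstructions).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.epp_recon <- function(x, optimization = c("ACCTRAN", "DELTRAN"), ...) {
  branch_changes(x, match.arg(optimization))
}

#' @rdname tidy.epp_recon
#' @export
tidy.parsimov_shifts <- function(x, ...) shift_table(x)

#' One-row summary of a reconstruction
#' @param x An `epp_recon`.
#' @param ... Unused.
#' @export
glance.epp_recon <- function(x, ...) {
  tibble::tibble(
    n_characters = nrow(x$pairs),
    n_taxa = length(x$tree$tip.label),
    total_length = sum(x$length),
    n_variable = sum(x$length > 0),
    n_root_ambiguous = sum(x$root_ambiguous),
    treatment = x$treatment
  )
}

#' @rdname glance.epp_recon
#' @export
glance.parsimov_shifts <- function(x, ...) {
  tb <- shift_table(x)
  tibble::tibble(
    n_branches = length(x$consensus),
    n_consensus = sum(tb$status == "consensus"),
    n_joint = sum(tb$status == "joint"),
    n_acctran_only = sum(tb$status == "ACCTRAN_only"),
    n_deltran_only = sum(tb$status == "DELTRAN_only")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# ---- plotting ---------------------------------------------------------------

#' Phase-coloured rendering of a developmental sequence
#'
#' A tile per event along the rank axis, coloured by life phase —
#' the plotted analogue of colour-coded sequence figures.
#'
#' @param seq A [dev_sequence].
#' @param catalog The [event_catalog].
#' @return A ggplot object.
#' @export
plot_sequence_phases <- function(seq, catalog) {
  cls <- classify_phases(seq, catalog)
  cls <- cls[!is.na(cls$rank), , drop = FALSE]
  cls <- dplyr::arrange(cls, .data$rank, match(.data$event, event_labels(catalog)))
  cls$slot <- stats::ave(seq_along(cls$rank), cls$rank, FUN = seq_along)
  phase_group <- ifelse(grepl("molt|hatching", cls$phase), "landmark", cls$phase)
  cls$fill <- factor(phase_group,
                     levels = c("embryonic", "larval", "juvenile", "landmark"))
  ggplot2::ggplot(cls, ggplot2::aes(x = .data$rank, y = .data$slot,
                                    fill = .data$fill)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.6) +
    ggplot2::geom_text(ggplot2::aes(label = .data$event), size = 3) +
    ggplot2::scale_fill_manual(
      values = c(embryonic = "#c23b3b", larval = "#3b6ec2",
                 juvenile = "#888888", landmark = "#3ba05a"),
      drop = FALSE, name = "phase") +
    ggplot2::labs(x = "rank (simultaneity block)", y = NULL,
                  title = seq$taxon) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Stacked life-phase counts per node
#'
#' @param summary_tbl Output of [summarize_tree()] (or row-bound
#'   [phase_summary()] calls).
#' @return A ggplot object.
#' @export
plot_phase_summary <- function(summary_tbl) {
  long <- tidyr::pivot_longer(summary_tbl, c("embryonic", "larval"),
                              names_to = "phase", values_to = "events")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$node, y = .data$events,
                                     fill = .data$phase)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~optimization) +
    ggplot2::scale_fill_manual(values = c(embryonic = "#c23b3b",
                                          larval = "#3b6ec2")) +
    ggplot2::labs(x = NULL, y = "morphological events") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.epp_recon <- function(object, optimization = c("ACCTRAN", "DELTRAN"),
                               ...) {
  optimization <- match.arg(optimization)
  chg <- branch_changes(object, optimization)
  counts <- dplyr::count(chg, .data$parent, .data$child, name = "changes")
  counts$branch <- branch_label(counts$parent, counts$child)
  ggplot2::ggplot(counts, ggplot2::aes(x = stats::reorder(.data$branch,
                                                          .data$changes),
                                       y = .data$changes)) +
    ggplot2::geom_col(fill = "#3b6ec2") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste("event-pair changes,", optimization)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# ---- NEXUS export -----------------------------------------------------------

#' Export linearized event-pairing codes as a NEXUS character matrix
#'
#' Standard datatype, symbols `"012"`, missing `"?"`, one character per
#' canonically oriented event pair, character labels `first_vs_second` —
#' suitable for verification in external parsimony software.
#'
#' @param codes Named list of `pair_code` tibbles (see
#'   [encode_sequences()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nexus_codes <- function(codes, path) {
  stopifnot(length(codes) > 0)
  ref <- codes[[1]]
  n_char <- nrow(ref)
  labels <- paste0(ref$first, "_vs_", ref$second)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("#NEXUS")
  w("BEGIN DATA;")
  w("  DIMENSIONS NTAX=", length(codes), " NCHAR=", n_char, ";")
  w("  FORMAT DATATYPE=STANDARD SYMBOLS=\"012\" MISSING=?;")
  w("  CHARLABELS")
  w("    ", paste(labels, collapse = " "), ";")
  w("  MATRIX")
  for (nmx in names(codes)) {
    w("    ", gsub("[^A-Za-z0-9_]", "_", nmx), "  ",
      linearize_code(codes[[nmx]], collapse = TRUE))
  }
  w("  ;")
  w("END;")
  invisible(path)
}
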