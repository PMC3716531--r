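#' The packaged regression scenario
#'
#' A fixed, fully deterministic end-to-end validation scenario on the
#' bundled six-taxon branchiopod topology: a 9-rank root sequence over the
#' 27-event catalogue drawn once from a frozen seed, and one explicit
#' planted shift of displacement 3 on every branch, with no rank merges
#' and no event losses. The shifted events were chosen once, by an
#' identifiability argument for the two root-adjacent branches of a
#' rooted tree (see the methods vignette), and are part of the scenario
#' definition.
#'
#' @return A list: `tree`, `root_seq`, `model` (a [shift_model] with the
#'   explicit shift table), `seed`.
#' @export
regression_scenario <- function() {
  tree <- read_tree(system.file("extdata", "branchiopoda.nwk",
                                package = "parsimovr"))
  catalog <- read_event_catalog(system.file("extdata",
                                            "branchiopod_events.tsv",
                                            package = "parsimovr"))
  seed <- 16L
  root_seq <- random_root_sequence(catalog, n_ranks = 9, seed = seed)
  shifts <- tibble::tribble(
    ~child,            ~event, ~direction, ~displacement,
    "Anostraca",       "T",    "late",     3L,
    "Phyllopoda",      "B",    "early",    3L,
    "Notostraca",      "Q",    "early",    3L,
    "Diplostraca",     "H",    "late",     3L,
    "Laevicaudata",    "P",    "early",    3L,
    "Onychocaudata",   "R",    "late",     3L,
    "Spinicaudata",    "Z",    "early",    3L,
    "Cladoceromorpha", "E",    "late",     3L,
    "Cyclestherida",   "K",    "early",    3L,
    "Cladocera",       "O",    "late",     3L
  )
  model <- shift_model(shifts = shifts, merge_prob = 0, loss_prob = 0,
                       seed = seed)
  list(tree = tree, root_seq = root_seq, model = model, seed = seed,
       catalog = catalog)
}

#' Read a simulation scenario from a flat key-value file
#'
#' Lines of the form `key = value`; `#` starts a comment. Recognized
#' keys: `n_ranks`, `seed`, `n_shifts_per_branch`, `displacement_min`,
#' `displacement_max`, `merge_prob`, `loss_prob`.
#'
#' @param path Path to the scenario file.
#' @return A list with `n_ranks`, `seed` and a [shift_model].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2
  if (any(bad)) {
    stop("malformed scenario line: ", lines[bad][1], call. = FALSE)
  }
  vals <- stats::setNames(
    as.numeric(trimws(vapply(kv, `[`, "", 2))),
    trimws(vapply(kv, `[`, "", 1))
  )
  known <- c("n_ranks", "seed", "n_shifts_per_branch", "displacement_min",
             "displacement_max", "merge_prob", "loss_prob")
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(vals))) stop("non-numeric scenario value", call. = FALSE)
  get <- function(k, default) if (k %in% names(vals)) vals[[k]] else default
  seed <- as.integer(get("seed", 1))
  list(
    n_ranks = as.integer(get("n_ranks", 9)),
    seed = seed,
    model = shift_model(
      n_shifts_per_branch = as.integer(get("n_shifts_per_branch", 1)),
      displacement_range = c(as.integer(get("displacement_min", 3)),
                             as.integer(get("displacement_max", 4))),
      merge_prob = get("merge_prob", 0),
      loss_prob = get("loss_prob", 0),
      seed = seed
    )
  )
}
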