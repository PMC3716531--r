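#' Shift models for simulated sequence evolution
#'
#' A shift model specifies how developmental sequences evolve along the
#' branches of a tree. Either an explicit per-branch table of shifts is
#' given (`shifts`: columns `child` — the branch is the edge leading into
#' that node —, `event`, `direction`, `displacement`), or a random regime
#' (`n_shifts_per_branch`, displacements drawn uniformly from
#' `displacement_range`). A simultaneity-merge probability models low
#' chronological resolution (adjacent ranks fused), and an event-loss
#' probability removes events from a subtree. A seed is mandatory whenever
#' any stochastic component is active.
#'
#' @param shifts Optional explicit shift table (disables the random regime).
#' @param n_shifts_per_branch Number of random shifts per branch.
#' @param displacement_range Integer range (inclusive) for random
#'   displacements; displacements are at least 1.
#' @param merge_prob Per-branch probability that a random adjacent rank
#'   pair is merged.
#' @param loss_prob Per-branch, per-event probability of loss.
#' @param seed Integer seed; required unless the model is fully explicit
#'   and noise-free.
#' @return A list of class `shift_model`.
#' @export
shift_model <- function(shifts = NULL, n_shifts_per_branch = 1,
                        displacement_range = c(3, 4),
                        merge_prob = 0, loss_prob = 0, seed = NULL) {
  stochastic <- is.null(shifts) || merge_prob > 0 || loss_prob > 0
  if (stochastic && is.null(seed)) {
    stop("a seed is mandatory for any stochastic regime", call. = FALSE)
  }
  stopifnot(merge_prob >= 0, merge_prob <= 1, loss_prob >= 0, loss_prob <= 1)
  if (!is.null(shifts)) {
    shifts <- tibble::as_tibble(shifts)
    stopifnot(all(c("child", "event", "direction", "displacement") %in%
                    names(shifts)))
    stopifnot(all(shifts$displacement >= 1),
              all(shifts$direction %in% c("early", "late")))
  } else {
    stopifnot(displacement_range[1] >= 1)
  }
  structure(list(shifts = shifts, n_shifts_per_branch = n_shifts_per_branch,
                 displacement_range = displacement_range,
                 merge_prob = merge_prob, loss_prob = loss_prob, seed = seed),
            class = "shift_model")
}

#' Draw a random root developmental sequence
#'
#' Events are assigned uniformly to `n_ranks` ordered simultaneity blocks
#' (each rank guaranteed non-empty), after which the landmark events —
#' hatching first, then the molts in catalogue order — are rearranged onto
#' the sorted multiset of their drawn ranks, so hatching never follows a
#' molt and molts keep their catalogue order. Deterministic per seed.
#'
#' @param catalog An [event_catalog].
#' @param n_ranks Number of simultaneity blocks (at most the event count).
#' @param seed Integer seed.
#' @param taxon Label for the sequence.
#' @return A [dev_sequence].
#' @export
random_root_sequence <- function(catalog, n_ranks, seed, taxon = "root") {
  labels <- event_labels(catalog)
  n <- length(labels)
  if (n_ranks > n || n_ranks < 1) {
    stop("n_ranks must be between 1 and the event count (", n, ")",
         call. = FALSE)
  }
  rng <- local_rng(seed)
  # one event per rank first (non-emptiness), remainder uniform
  rank_of <- integer(n)
  first_n <- rng$sample(n, n_ranks)
  rank_of[first_n] <- rng$sample(n_ranks, n_ranks)
  rest <- setdiff(seq_len(n), first_n)
  if (length(rest) > 0) rank_of[rest] <- rng$sample_int(n_ranks, length(rest))
  # impose landmark order on the drawn ranks
  landmarks <- c(category_labels(catalog, "hatching"),
                 category_labels(catalog, "molt"))
  li <- match(landmarks, labels)
  if (length(li) > 0) rank_of[li] <- sort(rank_of[li])
  ranks <- lapply(sort(unique(rank_of)), function(k) labels[rank_of == k])
  dev_sequence(taxon, ranks, character(0), catalog)
}

# small deterministic RNG wrapper that does not disturb the global stream
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  with_state <- function(f) {
    old2 <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old2)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old2, envir = globalenv())
    })
    f()
  }
  list(
    sample = function(n, size) with_state(function() sample.int(n, size)),
    sample_int = function(n, size) with_state(function() sample.int(n, size, replace = TRUE)),
    runif = function(k) with_state(function() stats::runif(k)),
    pick = function(x) with_state(function() x[sample.int(length(x), 1)])
  )
}

#' Move one event earlier or later in a sequence
#'
#' The event is removed from its simultaneity block and re-inserted
#' `displacement` rank positions earlier or later. If the event shared its
#' block, it merges into the existing block at the target position; if it
#' was alone, it travels as its own singleton block past `displacement`
#' neighbouring blocks. Displacements beyond the sequence boundary are
#' clamped to the terminal position and flagged with attribute
#' `clamped = TRUE`. All event-pair states not involving the shifted event
#' are unchanged, and (absent clamping) applying the opposite shift
#' restores the original sequence.
#'
#' @param seq A [dev_sequence].
#' @param event Label of a placed event.
#' @param direction `"early"` or `"late"`.
#' @param displacement Positive integer number of rank positions.
#' @return The shifted [dev_sequence].
#' @export
apply_shift <- function(seq, event, direction, displacement) {
  direction <- match.arg(direction, c("early", "late"))
  stopifnot(displacement >= 1)
  r <- event_ranks(seq)
  if (!event %in% names(r)) {
    stop("event '", event, "' is not placed in the sequence", call. = FALSE)
  }
  ri <- r[[event]]
  ranks <- seq$ranks
  alone <- length(ranks[[ri]]) == 1
  ranks[[ri]] <- setdiff(ranks[[ri]], event)
  clamped <- FALSE
  if (alone) {
    ranks <- ranks[-ri]
    m <- length(ranks)
    q <- if (direction == "early") ri - displacement else ri + displacement
    if (q < 1) { q <- 1; clamped <- TRUE }
    if (q > m + 1) { q <- m + 1; clamped <- TRUE }
    ranks <- append(ranks, list(event), after = q - 1)
  } else {
    m <- length(ranks)
    t <- if (direction == "early") ri - displacement else ri + displacement
    if (t < 1) { t <- 1; clamped <- TRUE }
    if (t > m) { t <- m; clamped <- TRUE }
    ranks[[t]] <- sort(c(ranks[[t]], event))
  }
  out <- dev_sequence(seq$taxon, ranks, seq$missing)
  if (clamped) attr(out, "clamped") <- TRUE
  out
}

#' Simulate sequence evolution on a tree
#'
#' Applies the shift model from the root toward the tips: on each branch,
#' planted shifts (explicit or randomly drawn), then optional rank merges
#' and event losses. The full ground truth — every shift actually applied,
#' with clamping flags — is logged per branch.
#'
#' @param tree A rooted `phylo` tree with named nodes.
#' @param root_seq The [dev_sequence] at the root.
#' @param model A [shift_model].
#' @return A list of class `epp_sim`: `tree`, `root` (the root sequence),
#'   `sequences` (tibble with `seq` list-column for the tips, suitable for
#'   [encode_sequences()]), `node_sequences` (every node's true sequence),
#'   `truth` (tibble `parent`, `child`, `event`, `direction`,
#'   `displacement`, `clamped`).
#' @export
simulate_on_tree <- function(tree, root_seq, model) {
  stopifnot(inherits(model, "shift_model"))
  tree <- validate_tree(tree)
  rng <- if (!is.null(model$seed)) local_rng(model$seed + 1L) else NULL
  nm <- node_names(tree)
  n_tip <- length(tree$tip.label)
  seqs <- vector("list", n_tip + tree$Nnode)
  root <- root_index(tree)
  seqs[[root]] <- root_seq
  ch <- children_list(tree)
  truth <- list()
  for (u in preorder_nodes(tree)) {
    for (v in ch[[u]]) {
      s <- seqs[[u]]
      s$taxon <- nm[v]
      if (!is.null(model$shifts)) {
        spec <- model$shifts[model$shifts$child == nm[v], , drop = FALSE]
        for (i in seq_len(nrow(spec))) {
          s2 <- apply_shift(s, spec$event[i], spec$direction[i],
                            spec$displacement[i])
          truth[[length(truth) + 1]] <- tibble::tibble(
            parent = nm[u], child = nm[v], event = spec$event[i],
            direction = spec$direction[i], displacement = spec$displacement[i],
            clamped = isTRUE(attr(s2, "clamped"))
          )
          s <- s2
        }
      } else {
        shiftable <- setdiff(names(event_ranks(s)), character(0))
        for (i in seq_len(model$n_shifts_per_branch)) {
          # resample until the shift is not fully clamped away (bounded)
          for (try in 1:50) {
            ev <- rng$pick(shiftable)
            dir <- rng$pick(c("early", "late"))
            disp <- rng$pick(seq(model$displacement_range[1],
                                 model$displacement_range[2]))
            ri <- event_ranks(s)[[ev]]
            nr <- length(s$ranks)
            feasible <- if (dir == "early") ri - 1 >= 1 else nr - ri >= 1
            if (feasible) break
          }
          s2 <- apply_shift(s, ev, dir, disp)
          truth[[length(truth) + 1]] <- tibble::tibble(
            parent = nm[u], child = nm[v], event = ev, direction = dir,
            displacement = disp, clamped = isTRUE(attr(s2, "clamped"))
          )
          s <- s2
        }
      }
      if (model$merge_prob > 0) {
        k <- 1L
        while (k < length(s$ranks)) {
          if (rng$runif(1) < model$merge_prob) {
            s$ranks[[k]] <- sort(c(s$ranks[[k]], s$ranks[[k + 1]]))
            s$ranks[[k + 1]] <- NULL
          } else k <- k + 1L
        }
        s <- dev_sequence(s$taxon, s$ranks, s$missing)
      }
      if (model$loss_prob > 0) {
        placed <- names(event_ranks(s))
        lose <- placed[rng$runif(length(placed)) < model$loss_prob]
        if (length(lose) > 0) {
          ranks <- lapply(s$ranks, setdiff, y = lose)
          ranks <- ranks[vapply(ranks, length, 1L) > 0]
          s <- dev_sequence(s$taxon, ranks, union(s$missing, lose))
        }
      }
      seqs[[v]] <- s
    }
  }
  tips <- tibble::tibble(
    taxon = tree$tip.label,
    seq = seqs[seq_len(n_tip)]
  )
  truth_tbl <- if (length(truth) > 0) dplyr::bind_rows(truth) else
    tibble::tibble(parent = character(0), child = character(0),
                   event = character(0), direction = character(0),
                   displacement = integer(0), clamped = logical(0))
  structure(list(tree = tree, root = root_seq, sequences = tips,
                 node_sequences = stats::setNames(seqs, nm), truth = truth_tbl),
            class = "epp_sim")
}

#' Compare inferred movements against simulated ground truth
#'
#' For each planted shift, checks whether it was recovered as a necessary
#' movement, as a member of a joint group, or as a member of at least one
#' minimal movement set on its true branch; necessary movements on a
#' branch with no planted shift of that event/direction count as false
#' positives.
#'
#' @param truth Ground-truth shift tibble from [simulate_on_tree()].
#' @param reports Named list of `shift_report`s (names `"parent->child"`),
#'   as produced by [infer_shifts()] for one optimization.
#' @return A list: `per_shift` tibble (one row per planted shift with
#'   logicals `necessary`, `joint`, `in_minimal_set`), and `summary` with
#'   `recall_necessary`, `recall_any`, `precision_necessary`,
#'   `direction_accuracy`.
#' @export
recovery_metrics <- function(truth, reports) {
  branch_key <- function(p, c) paste0(p, "->", c)
  per <- truth
  per$branch <- branch_key(per$parent, per$child)
  unknown_branches <- setdiff(per$branch, names(reports))
  if (length(unknown_branches) > 0) {
    stop("truth references branches absent from reports: ",
         paste(unknown_branches, collapse = ", "), call. = FALSE)
  }
  check <- function(branch, event, direction) {
    rep <- reports[[branch]]
    nec <- any(rep$necessary$event == event &
                 rep$necessary$direction == direction)
    jnt <- any(vapply(seq_len(nrow(rep$joint)), function(i) {
      any(rep$joint$events[[i]] == event &
            rep$joint$directions[[i]] == direction)
    }, TRUE))
    inset <- any(vapply(rep$sets, function(s) {
      any(s$event == event & s$direction == direction)
    }, TRUE))
    dir_found <- any(vapply(rep$sets, function(s) any(s$event == event), TRUE))
    c(nec = nec, jnt = jnt, inset = inset, evt = dir_found)
  }
  flags <- t(vapply(seq_len(nrow(per)), function(i) {
    check(per$branch[i], per$event[i], per$direction[i])
  }, c(nec = TRUE, jnt = TRUE, inset = TRUE, evt = TRUE)))
  per$necessary <- flags[, "nec"]
  per$joint <- flags[, "jnt"]
  per$in_minimal_set <- flags[, "inset"]

  # false positives: necessary movements not planted on that branch
  n_fp <- 0L; n_nec <- 0L
  for (b in names(reports)) {
    nec <- reports[[b]]$necessary
    n_nec <- n_nec + nrow(nec)
    for (i in seq_len(nrow(nec))) {
      planted <- any(per$branch == b & per$event == nec$event[i] &
                       per$direction == nec$direction[i])
      if (!planted) n_fp <- n_fp + 1L
    }
  }
  evt_hits <- flags[, "evt"]
  summary <- tibble::tibble(
    n_planted = nrow(per),
    recall_necessary = mean(per$necessary),
    recall_any = mean(per$in_minimal_set),
    precision_necessary = if (n_nec == 0) NA_real_ else 1 - n_fp / n_nec,
    direction_accuracy = if (!any(evt_hits)) NA_real_ else
      mean(per$in_minimal_set[evt_hits])
  )
  list(per_shift = per, summary = summary)
}
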