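#' Candidate event movements for a branch
#'
#' A change in one event-pair character on a branch can be explained by
#' either of the two underlying events moving. For each change on the
#' branch this lists the two directed movements that account for it; the
#' union over all changes is the candidate search space (at most two
#' movements per event).
#'
#' @param changes A tibble of changes for one branch (columns `first`,
#'   `second`, `from`, `to` — see [branch_changes()]).
#' @param catalog The [event_catalog] (labels validated against it).
#' @return A tibble with columns `event`, `direction` (`"early"`/`"late"`),
#'   deduplicated, in catalogue order.
#' @export
candidate_movements <- function(changes, catalog) {
  if (nrow(changes) == 0) {
    return(tibble::tibble(event = character(0), direction = character(0)))
  }
  assert_catalog_labels(unique(c(changes$first, changes$second)), catalog)
  up <- changes$to > changes$from
  cand <- dplyr::bind_rows(
    tibble::tibble(event = changes$second, direction = ifelse(up, "late", "early")),
    tibble::tibble(event = changes$first, direction = ifelse(up, "early", "late"))
  )
  cand <- dplyr::distinct(cand)
  ord <- order(match(cand$event, event_labels(catalog)),
               match(cand$direction, c("early", "late")))
  cand[ord, ]
}

#' Does a directed movement account for an event-pair change?
#'
#' With the canonical pair orientation (the state is the timing of the
#' `second` event relative to the `first`), an increase in state means the
#' second event moved later or the first moved earlier, and a decrease the
#' converse. States are compared numerically (0 < 1 < 2) for direction
#' only.
#'
#' @param event Event label of the movement.
#' @param direction `"early"` or `"late"`.
#' @param first,second The pair, canonically oriented.
#' @param from,to Known states before and after the change (`from != to`).
#' @return Logical (vectorized over changes).
#' @export
accounts_for <- function(event, direction, first, second, from, to) {
  if (any(is.na(from)) || any(is.na(to))) {
    stop("changes with unknown states must be filtered out before ",
         "movement analysis", call. = FALSE)
  }
  stopifnot(all(from != to), all(direction %in% c("early", "late")))
  up <- to > from
  (event == second & direction == "late" & up) |
    (event == second & direction == "early" & !up) |
    (event == first & direction == "early" & up) |
    (event == first & direction == "late" & !up)
}

# movement key helpers
movement_key <- function(event, direction) paste(event, direction, sep = ":")

# "C/D late" when directions agree, "B(early)/C(late)" otherwise
format_joint <- function(events, directions) {
  if (length(unique(directions)) == 1) {
    paste(paste(events, collapse = "/"), directions[1])
  } else {
    paste(paste0(events, "(", directions, ")"), collapse = "/")
  }
}

#' Enumerate all minimum-size movement sets explaining a branch's changes
#'
#' Finds every minimum-cardinality set of directed event movements such
#' that each event-pair change on the branch is accounted for by at least
#' one member ([accounts_for()]). No set may contain both directions of
#' the same event. The search is exact: a branch-and-bound over the two
#' candidate movements of each change, which enumerates each minimal
#' cover exactly once.
#'
#' @param changes Tibble of known-state changes for one branch.
#' @param catalog The [event_catalog].
#' @return A list of tibbles (`event`, `direction`), each one minimal
#'   movement set; the empty change set yields a single empty set. The
#'   attribute `minimal_size` records the common cardinality.
#' @export
minimal_move_sets <- function(changes, catalog) {
  empty <- tibble::tibble(event = character(0), direction = character(0))
  if (nrow(changes) == 0) {
    out <- list(empty)
    attr(out, "minimal_size") <- 0L
    return(out)
  }
  cand <- candidate_movements(changes, catalog)
  ckey <- movement_key(cand$event, cand$direction)
  n_change <- nrow(changes)

  # per change, indices (into cand) of the two movements that account for it
  cover <- lapply(seq_len(n_change), function(i) {
    which(accounts_for(cand$event, cand$direction,
                       changes$first[i], changes$second[i],
                       changes$from[i], changes$to[i]))
  })
  stopifnot(all(vapply(cover, length, 1L) >= 1))
  # which changes each movement accounts for
  covers_of <- lapply(seq_len(nrow(cand)), function(m) {
    which(vapply(cover, function(cc) m %in% cc, TRUE))
  })

  best_size <- Inf
  solutions <- list()

  # depth-first: state is (chosen movement indices, excluded movement
  # indices, set of uncovered changes)
  recurse <- function(chosen, excluded, uncovered) {
    if (length(uncovered) == 0) {
      if (length(chosen) < best_size) {
        best_size <<- length(chosen)
        solutions <<- list(sort(chosen))
      } else if (length(chosen) == best_size) {
        solutions <<- c(solutions, list(sort(chosen)))
      }
      return(invisible(NULL))
    }
    if (length(chosen) + 1 > best_size) return(invisible(NULL))
    i <- uncovered[1]
    opts <- cover[[i]]
    allowed <- function(m) {
      if (m %in% excluded) return(FALSE)
      # both directions of one event may not co-occur
      opp <- which(cand$event == cand$event[m] & cand$direction != cand$direction[m])
      !(length(opp) == 1 && opp %in% chosen)
    }
    live <- Filter(allowed, opts)
    if (length(live) == 0) return(invisible(NULL))
    # branch: include live[1]; or exclude live[1] and (if present) include
    # the alternative — the standard duplicate-free cover enumeration
    m1 <- live[[1]]
    recurse(c(chosen, m1), excluded,
            setdiff(uncovered, covers_of[[m1]]))
    if (length(live) > 1) {
      m2 <- live[[2]]
      recurse(c(chosen, m2), c(excluded, m1),
              setdiff(uncovered, covers_of[[m2]]))
    }
  }
  recurse(integer(0), integer(0), seq_len(n_change))

  # drop any solutions larger than the finally-found optimum (guarded by
  # the bound, but kept for safety) and deduplicate
  sizes <- vapply(solutions, length, 1L)
  solutions <- solutions[sizes == min(sizes)]
  keys <- vapply(solutions, function(s) paste(s, collapse = ","), "")
  solutions <- solutions[!duplicated(keys)]

  out <- lapply(solutions, function(s) cand[s, , drop = FALSE])
  attr(out, "minimal_size") <- nrow(out[[1]])
  attr(out, "candidates") <- cand
  out
}

#' Consensus of minimal movement sets for one branch
#'
#' Necessary movements are those present in every minimal set — the
#' movements that must form part of any equally most parsimonious
#' explanation of the branch's event-pair changes. Movements that are
#' interchangeable alternatives (every minimal set contains exactly one
#' member of the group, each member with its own direction) are reported
#' as joint groups, mirroring rows like "C/D" in printed shift tables.
#' The two alternatives explaining a single pair-change move in opposite
#' directions; shared-direction groups arise when the alternatives explain
#' the same suite of changes the same way. Reference
#' events — the partner events of the changes a movement accounts for —
#' are attached to each reported movement.
#'
#' @param min_sets Output of [minimal_move_sets()].
#' @param changes The branch's change tibble the sets were computed from.
#' @param branch Branch label (conventionally `"parent->child"`).
#' @return A list of class `shift_report`: `branch`, `minimal_size`,
#'   `necessary` (tibble `event`, `direction`, `reference` list-column),
#'   `joint` (tibble with parallel list-columns `events`, `directions`,
#'   plus `reference`), `n_sets`, and `sets` (the full enumeration).
#' @export
consensus_shifts <- function(min_sets, changes, branch = "") {
  stopifnot(length(min_sets) >= 1)
  keys <- lapply(min_sets, function(s) movement_key(s$event, s$direction))
  all_mov <- unique(unlist(keys))
  necessary_keys <- Reduce(intersect, keys)

  ref_events <- function(event, direction) {
    if (nrow(changes) == 0) return(character(0))
    acc <- accounts_for(event, direction, changes$first, changes$second,
                        changes$from, changes$to)
    partners <- ifelse(changes$first == event, changes$second, changes$first)
    sort(unique(partners[acc]))
  }
  split_key <- function(k) strsplit(k, ":", fixed = TRUE)[[1]]

  necessary <- tibble::tibble(
    event = vapply(necessary_keys, function(k) split_key(k)[1], "",
                   USE.NAMES = FALSE),
    direction = vapply(necessary_keys, function(k) split_key(k)[2], "",
                       USE.NAMES = FALSE)
  )
  necessary$reference <- purrr::map2(necessary$event, necessary$direction,
                                     ref_events)

  # joint groups among non-necessary movements: movements whose occurrence
  # patterns over the minimal sets partition the sets exactly
  optional <- setdiff(all_mov, necessary_keys)
  n_sets <- length(min_sets)
  occ <- lapply(optional, function(k) which(vapply(keys, function(ks) k %in% ks, TRUE)))
  names(occ) <- optional
  used <- character(0)
  joint_rows <- list()
  for (k in optional) {
    if (k %in% used) next
    members <- k
    covered <- occ[[k]]
    for (k2 in setdiff(optional, c(used, k))) {
      if (length(intersect(occ[[k2]], covered)) == 0) {
        members <- c(members, k2)
        covered <- c(covered, occ[[k2]])
      }
    }
    exact <- length(covered) == n_sets && !anyDuplicated(covered) &&
      length(members) >= 2
    if (exact) {
      evs <- vapply(members, function(m) split_key(m)[1], "", USE.NAMES = FALSE)
      dirs <- vapply(members, function(m) split_key(m)[2], "", USE.NAMES = FALSE)
      ord <- order(evs)
      refs <- sort(unique(unlist(lapply(members, function(m) {
        p <- split_key(m); ref_events(p[1], p[2])
      }))))
      joint_rows[[length(joint_rows) + 1]] <- tibble::tibble(
        events = list(evs[ord]), directions = list(dirs[ord]),
        reference = list(refs)
      )
      used <- c(used, members)
    }
  }
  joint <- if (length(joint_rows) > 0) dplyr::bind_rows(joint_rows) else
    tibble::tibble(events = list(), directions = list(), reference = list())

  structure(
    list(branch = branch, minimal_size = attr(min_sets, "minimal_size"),
         necessary = necessary, joint = joint,
         n_sets = length(min_sets), sets = min_sets),
    class = "shift_report"
  )
}

#' @export
print.shift_report <- function(x, ...) {
  cat("<shift_report> branch ", x$branch, ": ", x$n_sets,
      " minimal set(s) of size ", x$minimal_size, "\n", sep = "")
  if (nrow(x$necessary) > 0) {
    for (i in seq_len(nrow(x$necessary))) {
      cat("  necessary: ", x$necessary$event[i], " ", x$necessary$direction[i],
          " (rel. ", paste(x$necessary$reference[[i]], collapse = ", "), ")\n",
          sep = "")
    }
  }
  if (nrow(x$joint) > 0) {
    for (i in seq_len(nrow(x$joint))) {
      cat("  joint: ", format_joint(x$joint$events[[i]],
                                    x$joint$directions[[i]]), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Movements inferred under both ACCTRAN and DELTRAN
#'
#' The conservative consensus across optimizations: necessary movements
#' (and joint groups) present in both reports are kept; movements unique
#' to one optimization are retained in side channels (`acctran_only`,
#' `deltran_only`) rather than discarded.
#'
#' @param acctran,deltran `shift_report`s for the same branch.
#' @return A list of class `cross_report`: `branch`, `necessary`, `joint`,
#'   `acctran_only`, `deltran_only`.
#' @export
cross_optimization_consensus <- function(acctran, deltran) {
  stopifnot(inherits(acctran, "shift_report"), inherits(deltran, "shift_report"))
  if (!identical(acctran$branch, deltran$branch)) {
    stop("reports are for different branches: ", acctran$branch, " vs ",
         deltran$branch, call. = FALSE)
  }
  key_n <- function(r) movement_key(r$necessary$event, r$necessary$direction)
  ka <- key_n(acctran); kd <- key_n(deltran)
  both <- intersect(ka, kd)
  necessary <- acctran$necessary[ka %in% both, , drop = FALSE]

  jkey <- function(r) vapply(seq_len(nrow(r$joint)), function(i) {
    format_joint(r$joint$events[[i]], r$joint$directions[[i]])
  }, "")
  ja <- jkey(acctran); jd <- jkey(deltran)
  joint <- acctran$joint[ja %in% intersect(ja, jd), , drop = FALSE]

  structure(
    list(branch = acctran$branch,
         necessary = necessary, joint = joint,
         acctran_only = acctran$necessary[!(ka %in% both), , drop = FALSE],
         deltran_only = deltran$necessary[!(kd %in% both), , drop = FALSE]),
    class = "cross_report"
  )
}

#' @export
print.cross_report <- function(x, ...) {
  cat("<cross_report> branch ", x$branch, ": ", nrow(x$necessary),
      " consensus movement(s), ", nrow(x$joint), " joint group(s), ",
      nrow(x$acctran_only), " ACCTRAN-only, ", nrow(x$deltran_only),
      " DELTRAN-only\n", sep = "")
  invisible(x)
}
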