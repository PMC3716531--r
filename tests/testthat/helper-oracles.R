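# Independent brute-force oracles, kept deliberately naive.

# Minimum number of state changes over all full labelings of the internal
# nodes (and of unknown leaves), by exhaustive enumeration; also returns
# the set of states each node takes in at least one optimal labeling.
oracle_parsimony <- function(tree, leaf_states, states = 0:2,
                             cost = function(a, b) as.numeric(a != b)) {
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  free <- c(which(is.na(leaf_states)), (n_tip + 1):n_node)
  fixed <- setdiff(seq_len(n_tip), free)
  grid <- as.matrix(expand.grid(rep(list(states), length(free))))
  full <- matrix(0L, nrow(grid), n_node)
  full[, fixed] <- matrix(rep(leaf_states[fixed], each = nrow(grid)),
                          nrow(grid))
  full[, free] <- grid
  changes <- numeric(nrow(grid))
  for (e in seq_len(nrow(tree$edge))) {
    changes <- changes + cost(full[, tree$edge[e, 1]], full[, tree$edge[e, 2]])
  }
  best <- min(changes)
  opt <- full[changes == best, , drop = FALSE]
  mpr <- lapply(seq_len(n_node), function(v) sort(unique(opt[, v])))
  list(length = best, mpr = mpr)
}

# All minimum-size movement sets by exhaustive subset enumeration over the
# candidate movements (both directions of every participating event),
# honouring the no-opposite-directions constraint.
oracle_min_covers <- function(changes, catalog) {
  cand <- candidate_movements(changes, catalog)
  nc <- nrow(cand)
  accounted <- function(idx) {
    all(vapply(seq_len(nrow(changes)), function(i) {
      any(accounts_for(cand$event[idx], cand$direction[idx],
                       changes$first[i], changes$second[i],
                       changes$from[i], changes$to[i]))
    }, TRUE))
  }
  valid <- list()
  for (mask in seq_len(2^nc) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(nc) - 1)) > 0)
    ev <- cand$event[idx]
    if (anyDuplicated(ev)) next
    if (length(idx) > 0 || nrow(changes) == 0) {
      if (nrow(changes) == 0 || accounted(idx)) {
        valid[[length(valid) + 1]] <- idx
      }
    }
  }
  sizes <- vapply(valid, length, 1L)
  valid <- valid[sizes == min(sizes)]
  lapply(valid, function(idx) cand[idx, , drop = FALSE])
}

# canonical string form of a movement set, for set-of-sets comparison
movement_set_key <- function(s) {
  paste(sort(paste(s$event, s$direction)), collapse = "|")
}

movement_sets_equal <- function(a, b) {
  setequal(vapply(a, movement_set_key, ""), vapply(b, movement_set_key, ""))
}

# random branch change tibble over a small catalogue: k changes on distinct
# pairs with random known states
random_changes <- function(catalog, k) {
  labels <- event_labels(catalog)
  pairs <- utils::combn(labels, 2)
  pick <- sample.int(ncol(pairs), k)
  from <- sample(0:2, k, replace = TRUE)
  shift <- sample(1:2, k, replace = TRUE)
  to <- (from + shift) %% 3L
  tibble::tibble(parent = "p", child = "c",
                 first = pairs[1, pick], second = pairs[2, pick],
                 from = as.integer(from), to = as.integer(to))
}
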