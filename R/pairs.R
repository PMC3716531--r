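#' Event-pair characters
#'
#' The event-pairing encoding turns a ranked developmental sequence over an
#' n-event catalogue into n(n-1)/2 three-state characters, one per
#' unordered event pair. Pairs are oriented canonically: for catalogue
#' order `first` before `second`, the character records the timing of
#' `second` relative to `first`:
#'
#' * `0` — second event before the first,
#' * `1` — both simultaneous (same rank),
#' * `2` — second event after the first,
#' * `NA` — unknown (either event missing in the taxon).
#'
#' Pair tables are tibbles with columns `first`, `second`, `state` and an
#' attribute `node` naming the taxon or tree node; rows are in lexicographic
#' catalogue order, which is also the order of the linearized code.
#'
#' @name pair_code
NULL

canonical_pairs <- function(catalog) {
  labels <- event_labels(catalog)
  n <- length(labels)
  if (n < 2) {
    return(tibble::tibble(first = character(0), second = character(0)))
  }
  idx <- utils::combn(n, 2)
  tibble::tibble(first = labels[idx[1, ]], second = labels[idx[2, ]])
}

new_pair_code <- function(pairs, state, node, labels) {
  out <- tibble::tibble(first = pairs$first, second = pairs$second,
                        state = as.integer(state))
  attr(out, "node") <- node
  attr(out, "event_order") <- labels
  class(out) <- c("pair_code", class(out))
  out
}

#' Encode a developmental sequence as event-pair characters
#'
#' @param seq A [dev_sequence].
#' @param catalog The [event_catalog] defining pair orientation.
#' @return A `pair_code` tibble with n(n-1)/2 rows (351 for the bundled
#'   27-event catalogue). Pairs involving a missing event score `NA`.
#' @examples
#' cat4 <- event_catalog(data.frame(
#'   label = c("A", "B", "C", "D"), description = "",
#'   category = c("hatching", rep("morphological", 3))
#' ))
#' encode_sequence(parse_sequence("A,B-C,D", cat4, "toy"), cat4)
#' @export
encode_sequence <- function(seq, catalog) {
  stopifnot(inherits(seq, "dev_sequence"))
  assert_catalog_labels(c(unlist(seq$ranks), seq$missing), catalog)
  pairs <- canonical_pairs(catalog)
  r <- event_ranks(seq)
  r1 <- unname(r[pairs$first])
  r2 <- unname(r[pairs$second])
  state <- ifelse(is.na(r1) | is.na(r2), NA_integer_,
                  ifelse(r2 < r1, 0L, ifelse(r2 == r1, 1L, 2L)))
  new_pair_code(pairs, state, seq$taxon, event_labels(catalog))
}

#' Encode a table of sequences
#'
#' @param seq_tbl Tibble with a `seq` list-column (see [read_sequences()]).
#' @param catalog An [event_catalog].
#' @return A named list of `pair_code` tibbles, one per taxon.
#' @export
encode_sequences <- function(seq_tbl, catalog) {
  codes <- lapply(seq_tbl$seq, encode_sequence, catalog = catalog)
  names(codes) <- vapply(seq_tbl$seq, function(s) s$taxon, "")
  codes
}

#' Linearize an event-pair table into a character code
#'
#' Produces the sequential event-pairing code: one symbol per pair in
#' lexicographic catalogue order, `"0"`/`"1"`/`"2"` for known states and
#' `"?"` for unknown. The code round-trips losslessly through
#' [delinearize_code()].
#'
#' @param code A `pair_code` tibble (see [encode_sequence()]).
#' @param collapse If `TRUE`, return a single string instead of a vector.
#' @return Character vector of length n(n-1)/2, or a single string.
#' @export
linearize_code <- function(code, collapse = FALSE) {
  stopifnot(inherits(code, "pair_code"))
  sym <- ifelse(is.na(code$state), "?", as.character(code$state))
  if (collapse) paste(sym, collapse = "") else sym
}

#' Rebuild an event-pair table from a linearized code
#'
#' @param symbols Character vector of `"0"`, `"1"`, `"2"`, `"?"` (or one
#'   collapsed string), in lexicographic catalogue order.
#' @param catalog The [event_catalog] the code was produced from.
#' @param node Identifier to attach to the rebuilt table.
#' @return A `pair_code` tibble.
#' @export
delinearize_code <- function(symbols, catalog, node = "unknown") {
  if (length(symbols) == 1 && nchar(symbols) > 1) {
    symbols <- strsplit(symbols, "", fixed = TRUE)[[1]]
  }
  pairs <- canonical_pairs(catalog)
  if (length(symbols) != nrow(pairs)) {
    stop("code has ", length(symbols), " symbols but catalogue implies ",
         nrow(pairs), call. = FALSE)
  }
  bad <- setdiff(unique(symbols), c("0", "1", "2", "?"))
  if (length(bad) > 0) {
    stop("invalid code symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  state <- suppressWarnings(as.integer(symbols))
  new_pair_code(pairs, state, node, event_labels(catalog))
}

# Relation matrix: entry [i, j] = sign(rank(j) - rank(i)) in {-1, 0, 1, NA};
# +1 means i precedes j. Built from the canonical states (state = timing of
# second relative to first: 2 means first precedes second).
relation_matrix <- function(code) {
  labels <- attr(code, "event_order")
  n <- length(labels)
  rel <- matrix(NA_integer_, n, n, dimnames = list(labels, labels))
  diag(rel) <- 0L
  i <- match(code$first, labels)
  j <- match(code$second, labels)
  v <- code$state - 1L           # 0,1,2 -> -1,0,1 = sign(rank j - rank i)
  rel[cbind(i, j)] <- v
  rel[cbind(j, i)] <- -v
  rel
}

#' Check transitive consistency of an event-pair table
#'
#' A pair table derived from a genuine ranked sequence satisfies
#' transitivity: if A precedes B and B precedes C then A precedes C, with
#' the analogous rules for ties. This check enumerates all event triples
#' whose three known pairwise states admit no assignment of ranks.
#'
#' Note that an inconsistent table whose contradiction runs only through
#' cycles of length four or more with unknown chords has no violating
#' triple; [derive_sequence()] additionally detects such cycles.
#'
#' @param code A `pair_code` tibble.
#' @return A tibble of violating triples (`a`, `b`, `c` with their three
#'   pairwise relations); zero rows means no triple-level violation.
#' @export
check_consistency <- function(code) {
  stopifnot(inherits(code, "pair_code"))
  labels <- attr(code, "event_order")
  n <- length(labels)
  empty <- tibble::tibble(a = character(0), b = character(0), c = character(0),
                          ab = integer(0), bc = integer(0), ac = integer(0))
  if (n < 3) return(empty)
  rel <- relation_matrix(code)
  triples <- utils::combn(n, 3)
  ab <- rel[cbind(triples[1, ], triples[2, ])]
  bc <- rel[cbind(triples[2, ], triples[3, ])]
  ac <- rel[cbind(triples[1, ], triples[3, ])]
  known <- !(is.na(ab) | is.na(bc) | is.na(ac))
  # a triple of relations is satisfiable iff it is transitively closed:
  # the only impossible fully-known patterns are those where the implied
  # ac from (ab, bc) contradicts the stored ac.
  implied_conflict <- function(ab, bc, ac) {
    # if ab and bc agree in sign (or one is 0), ac is forced
    forced <- ifelse(ab == 0L, bc, ifelse(bc == 0L, ab,
              ifelse(ab == bc, ab, NA_integer_)))
    !is.na(forced) & forced != ac
  }
  bad <- known & (
    implied_conflict(ab, bc, ac) |
    implied_conflict(bc, -ac, -ab) |  # b vs c, c vs a => b vs a
    implied_conflict(-ab, ac, bc)     # b vs a, a vs c => b vs c
  )
  if (!any(bad)) return(empty)
  tibble::tibble(
    a = labels[triples[1, bad]], b = labels[triples[2, bad]],
    c = labels[triples[3, bad]],
    ab = ab[bad], bc = bc[bad], ac = ac[bad]
  )
}

#' Derive a developmental sequence from an event-pair table
#'
#' Renders a (possibly partially unknown) event-pair table — typically an
#' ancestral reconstruction — back into a ranked sequence. Events tied by
#' state 1 share a rank; known precedences are honoured exactly; events
#' with no known pair at all go to `missing`. Placement is deterministic:
#' tied groups are layered by longest path over the known precedence
#' relation, so an event sits as early as its constraints allow relative
#' to its predecessors.
#'
#' The derived sequence agrees with every known entry of the input table
#' (`encode_sequence()` of the result reproduces them); unknown entries
#' are resolved arbitrarily but reproducibly.
#'
#' @param code A `pair_code` tibble.
#' @param catalog The [event_catalog].
#' @param node Identifier for the resulting sequence.
#' @param repair If `FALSE` (default), an inconsistent table is an error
#'   carrying the violating triples. If `TRUE`, each strongly connected
#'   component of the precedence graph is collapsed into a single
#'   simultaneity rank and the result is flagged with attribute
#'   `repaired = TRUE` plus the violations found.
#' @return A [dev_sequence]; with `repair = TRUE` possibly carrying
#'   attributes `repaired` and `violations`.
#' @export
derive_sequence <- function(code, catalog, node = NULL, repair = FALSE) {
  stopifnot(inherits(code, "pair_code"))
  if (is.null(node)) node <- attr(code, "node") %||% "unknown"
  labels <- attr(code, "event_order")
  stopifnot(identical(labels, event_labels(catalog)))
  n <- length(labels)
  rel <- relation_matrix(code)

  known_any <- rowSums(!is.na(rel[, , drop = FALSE])) > 1  # beyond diagonal
  placed_idx <- which(known_any)
  missing_lab <- labels[!known_any]
  if (length(placed_idx) == 0) {
    stop("no known event-pair states; nothing to derive", call. = FALSE)
  }

  # union-find over ties (rel == 0 off-diagonal)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in placed_idx) for (j in placed_idx) {
    if (i < j && !is.na(rel[i, j]) && rel[i, j] == 0L) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  grp <- vapply(seq_len(n), find, 1L)

  # group-level precedence edges; detect direct contradictions (i<j and i>j
  # inside one tie group)
  groups <- sort(unique(grp[placed_idx]))
  gid <- match(grp, groups)
  m <- length(groups)
  adj <- matrix(FALSE, m, m)
  contradiction <- FALSE
  for (i in placed_idx) for (j in placed_idx) {
    if (!is.na(rel[i, j]) && rel[i, j] == 1L) {   # rank(i) < rank(j)
      gi <- gid[i]; gj <- gid[j]
      if (gi == gj) contradiction <- TRUE else adj[gi, gj] <- TRUE
    }
  }

  sccs <- strongly_connected_components(adj)
  cyclic <- any(vapply(sccs, length, 1L) > 1)
  if (contradiction || cyclic) {
    triples <- check_consistency(code)
    if (!repair) {
      msg <- if (nrow(triples) > 0) {
        paste0("inconsistent event-pair table; e.g. triple (",
               triples$a[1], ", ", triples$b[1], ", ", triples$c[1], ")")
      } else {
        "inconsistent event-pair table (cycle through unknown-chord pairs)"
      }
      cond <- simpleError(msg)
      cond$violations <- triples
      stop(cond)
    }
    # collapse each SCC (and any tie-group contradiction) into one rank
    scc_of <- integer(m)
    for (k in seq_along(sccs)) scc_of[sccs[[k]]] <- k
    m2 <- length(sccs)
    adj2 <- matrix(FALSE, m2, m2)
    for (a in seq_len(m)) for (b in seq_len(m)) {
      if (adj[a, b] && scc_of[a] != scc_of[b]) adj2[scc_of[a], scc_of[b]] <- TRUE
    }
    gid <- scc_of[gid]
    adj <- adj2
    m <- m2
  }

  # longest-path layering over the (now acyclic) group DAG
  layer <- rep(1L, m)
  repeat {
    changed <- FALSE
    for (a in seq_len(m)) for (b in seq_len(m)) {
      if (adj[a, b] && layer[b] < layer[a] + 1L) {
        layer[b] <- layer[a] + 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  ranks <- vector("list", max(layer))
  for (lv in seq_len(max(layer))) {
    members <- placed_idx[layer[gid[placed_idx]] == lv]
    ranks[[lv]] <- labels[sort(members)]
  }
  ranks <- ranks[vapply(ranks, length, 1L) > 0]

  out <- dev_sequence(node, ranks, missing_lab, catalog)
  if ((contradiction || cyclic)) {
    attr(out, "repaired") <- TRUE
    attr(out, "violations") <- check_consistency(code)
  }
  out
}

# Tarjan-free iterative SCC (Kosaraju) on a small boolean adjacency matrix.
strongly_connected_components <- function(adj) {
  m <- nrow(adj)
  if (m == 0) return(list())
  order <- integer(0)
  visited <- rep(FALSE, m)
  for (s in seq_len(m)) {
    if (visited[s]) next
    stack <- list(list(v = s, i = 0L))
    visited[s] <- TRUE
    while (length(stack) > 0) {
      top <- stack[[length(stack)]]
      nxt <- which(adj[top$v, ] & !visited)
      if (length(nxt) == 0) {
        order <- c(order, top$v)
        stack[[length(stack)]] <- NULL
      } else {
        visited[nxt[1]] <- TRUE
        stack[[length(stack) + 1]] <- list(v = nxt[1], i = 0L)
      }
    }
  }
  # second pass on transpose in reverse finish order
  comp <- rep(0L, m)
  ncomp <- 0L
  for (s in rev(order)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    queue <- s
    comp[s] <- ncomp
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      preds <- which(adj[, v] & comp == 0L)
      comp[preds] <- ncomp
      queue <- c(queue, preds)
    }
  }
  split(seq_len(m), comp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
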