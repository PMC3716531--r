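#' Parsimony reconstruction of event-pair characters
#'
#' [fitch_mpr()] reconstructs ancestral states for every event-pair
#' character on a rooted tree under parsimony. Characters are unordered
#' (Fitch; any state-to-state change costs 1) by default; an ordered
#' (additive, 0–1–2) treatment is available via `treatment = "ordered"`.
#' The implementation is a unit-cost dynamic program over subtree costs
#' (below pass) and rest-of-tree costs (above pass), which yields, per
#' character and node, the exact set of states attained by at least one
#' most-parsimonious reconstruction (the MPR state set), and per character
#' the minimum number of changes on the tree.
#'
#' Missing leaf states (unknown event pairs) are compatible with every
#' state and contribute no length.
#'
#' @param tree A rooted `phylo` tree with named nodes (see [parse_newick()]).
#' @param codes Named list of `pair_code` tibbles, one per tip label (see
#'   [encode_sequences()]); all over the same catalogue.
#' @param treatment `"unordered"` (default) or `"ordered"`.
#' @return An object of class `epp_recon` with components `tree`, `pairs`,
#'   `length` (per-character minimum changes), `mpr` (per-node MPR state
#'   sets), and `root_ambiguous`.
#' @export
fitch_mpr <- function(tree, codes, treatment = c("unordered", "ordered")) {
  treatment <- match.arg(treatment)
  tree <- validate_tree(tree)
  tips <- tree$tip.label
  absent <- setdiff(tips, names(codes))
  if (length(absent) > 0) {
    stop("no event-pair data for tip(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  ref <- codes[[tips[1]]]
  pairs <- tibble::tibble(first = ref$first, second = ref$second)
  event_order <- attr(ref, "event_order")
  for (tp in tips) {
    if (!identical(codes[[tp]]$first, pairs$first) ||
        !identical(codes[[tp]]$second, pairs$second)) {
      stop("pair tables are not over the same catalogue (tip ", tp, ")",
           call. = FALSE)
    }
  }
  n_char <- nrow(pairs)
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode

  tip_states <- matrix(NA_integer_, n_char, n_tip, dimnames = list(NULL, tips))
  for (k in seq_len(n_tip)) tip_states[, k] <- codes[[tips[k]]]$state

  W <- if (treatment == "unordered") 1 - diag(3) else abs(outer(0:2, 0:2, "-"))

  ch <- children_list(tree)
  po <- postorder_nodes(tree)

  below <- vector("list", n_node)   # n_char x 3 subtree cost
  Tt <- vector("list", n_node)      # n_char x 3: min_s(below[s] + W[t, s])
  for (v in po) {
    if (v <= n_tip) {
      b <- matrix(Inf, n_char, 3)
      s <- tip_states[, v]
      known <- !is.na(s)
      b[cbind(which(known), s[known] + 1L)] <- 0
      b[!known, ] <- 0
    } else {
      b <- matrix(0, n_char, 3)
      for (cv in ch[[v]]) b <- b + Tt[[cv]]
    }
    below[[v]] <- b
    tm <- matrix(0, n_char, 3)
    for (t in 1:3) {
      tm[, t] <- pmin(b[, 1] + W[t, 1], b[, 2] + W[t, 2], b[, 3] + W[t, 3])
    }
    Tt[[v]] <- tm
  }

  root <- root_index(tree)
  len <- pmin(below[[root]][, 1], below[[root]][, 2], below[[root]][, 3])

  # above pass: cost of the rest of the tree given this node's state
  above <- vector("list", n_node)
  above[[root]] <- matrix(0, n_char, 3)
  for (u in preorder_nodes(tree)) {
    if (u <= n_tip) next
    sib_sum <- matrix(0, n_char, 3)
    for (cv in ch[[u]]) sib_sum <- sib_sum + Tt[[cv]]
    for (v in ch[[u]]) {
      inner <- above[[u]] + sib_sum - Tt[[v]]
      av <- matrix(0, n_char, 3)
      for (s in 1:3) {
        av[, s] <- pmin(inner[, 1] + W[1, s], inner[, 2] + W[2, s],
                        inner[, 3] + W[3, s])
      }
      above[[v]] <- av
    }
  }

  mpr <- vector("list", n_node)
  for (v in seq_len(n_node)) {
    opt <- below[[v]] + above[[v]]
    mpr[[v]] <- opt == len   # n_char x 3 logical
  }
  root_ambiguous <- rowSums(mpr[[root]]) > 1

  structure(
    list(tree = tree, pairs = pairs, event_order = event_order,
         treatment = treatment, tip_states = tip_states,
         below = below, mpr = mpr, length = len,
         root_ambiguous = root_ambiguous, W = W,
         resolved = list()),
    class = "epp_recon"
  )
}

#' @export
print.epp_recon <- function(x, ...) {
  cat("<epp_recon> ", nrow(x$pairs), " event-pair characters on ",
      length(x$tree$tip.label), " tips (", x$treatment, ")\n",
      "  total tree length: ", sum(x$length),
      "; resolved: ", paste(names(x$resolved), collapse = ", "), "\n", sep = "")
  invisible(x)
}

resolve_states <- function(recon, mode) {
  tree <- recon$tree
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  n_char <- nrow(recon$pairs)
  W <- recon$W
  ch <- children_list(tree)
  root <- root_index(tree)

  resolved <- matrix(NA_integer_, n_char, n_node,
                     dimnames = list(NULL, node_names(tree)))
  b <- recon$below[[root]]
  # root: lowest optimal state index (0 < 1 < 2)
  rmin <- pmin(b[, 1], b[, 2], b[, 3])
  resolved[, root] <- max.col(b == rmin, ties.method = "first") - 1L

  for (u in preorder_nodes(tree)) {
    pu <- resolved[, u]
    pu[is.na(pu)] <- 0L  # placeholder for no-data characters, masked below
    for (v in ch[[u]]) {
      if (v <= n_tip) {
        resolved[, v] <- recon$tip_states[, v]
        next
      }
      bv <- recon$below[[v]]
      cond <- bv
      for (s in 1:3) cond[, s] <- bv[, s] + W[cbind(pu + 1L, s)]
      cmin <- pmin(cond[, 1], cond[, 2], cond[, 3])
      inset <- cond == cmin
      if (mode == "DELTRAN") {
        # keep the parent state when it is optimal, else lowest index
        keep <- inset[cbind(seq_len(n_char), pu + 1L)]
        pick <- ifelse(keep, pu,
                       max.col(inset, ties.method = "first") - 1L)
      } else {
        # ACCTRAN: prefer an immediate change when cost-neutral
        inset_nonparent <- inset
        inset_nonparent[cbind(seq_len(n_char), pu + 1L)] <- FALSE
        has_alt <- rowSums(inset_nonparent) > 0
        pick <- ifelse(has_alt,
                       max.col(inset_nonparent, ties.method = "first") - 1L,
                       max.col(inset, ties.method = "first") - 1L)
      }
      resolved[, v] <- pick
    }
  }
  # characters with no data at any leaf stay unknown everywhere
  no_data <- rowSums(is.na(recon$tip_states)) == n_tip
  resolved[no_data, ] <- NA_integer_
  resolved
}

#' Resolve ambiguous reconstructions
#'
#' ACCTRAN places changes as close to the root as a most-parsimonious
#' reconstruction allows (earlier transformations, later reversals);
#' DELTRAN delays changes toward the tips (later, parallel changes). Both
#' resolutions conserve the per-character minimum change count. Ties are
#' broken deterministically: at the root by lowest state index (flagged in
#' `root_ambiguous`), elsewhere toward the parent's resolved state
#' (DELTRAN) or toward an immediate change (ACCTRAN), then by lowest state
#' index. Leaves keep their observed states; missing leaf states stay
#' unknown and never generate changes.
#'
#' @param recon An `epp_recon` from [fitch_mpr()].
#' @return The reconstruction with `resolved$ACCTRAN` (or `$DELTRAN`)
#'   filled: an integer matrix characters x nodes.
#' @export
resolve_acctran <- function(recon) {
  stopifnot(inherits(recon, "epp_recon"))
  recon$resolved$ACCTRAN <- resolve_states(recon, "ACCTRAN")
  recon
}

#' @rdname resolve_acctran
#' @export
resolve_deltran <- function(recon) {
  stopifnot(inherits(recon, "epp_recon"))
  recon$resolved$DELTRAN <- resolve_states(recon, "DELTRAN")
  recon
}

#' Number of state changes per character under a resolution
#' @param recon A resolved `epp_recon`.
#' @param optimization `"ACCTRAN"` or `"DELTRAN"`.
#' @return Integer vector of per-character change counts over all branches.
#' @export
resolution_lengths <- function(recon, optimization = c("ACCTRAN", "DELTRAN")) {
  optimization <- match.arg(optimization)
  res <- recon$resolved[[optimization]]
  if (is.null(res)) stop("resolution not computed; call resolve_",
                         tolower(optimization), "() first", call. = FALSE)
  edges <- recon$tree$edge
  total <- integer(nrow(recon$pairs))
  for (e in seq_len(nrow(edges))) {
    p <- res[, edges[e, 1]]
    c_ <- res[, edges[e, 2]]
    total <- total + as.integer(!is.na(p) & !is.na(c_) & p != c_)
  }
  total
}

#' Extract per-branch character changes from a resolved reconstruction
#'
#' One row per (branch, changed character): the pair, the parent state and
#' the child state. Transitions where either endpoint is unknown (a leaf
#' with missing data) are excluded from the change list and counted in the
#' `indeterminate` attribute instead.
#'
#' @param recon A resolved `epp_recon`.
#' @param optimization `"ACCTRAN"` or `"DELTRAN"`.
#' @return A tibble with columns `parent`, `child`, `first`, `second`,
#'   `from`, `to`; attribute `indeterminate` is a per-branch tibble of
#'   unknown-involving character counts. Branches with no changes simply
#'   contribute no rows.
#' @export
branch_changes <- function(recon, optimization = c("ACCTRAN", "DELTRAN")) {
  optimization <- match.arg(optimization)
  res <- recon$resolved[[optimization]]
  if (is.null(res)) stop("resolution not computed; call resolve_",
                         tolower(optimization), "() first", call. = FALSE)
  nm <- node_names(recon$tree)
  edges <- recon$tree$edge
  rows <- vector("list", nrow(edges))
  indet <- vector("list", nrow(edges))
  for (e in seq_len(nrow(edges))) {
    p <- res[, edges[e, 1]]
    c_ <- res[, edges[e, 2]]
    chg <- which(!is.na(p) & !is.na(c_) & p != c_)
    unk <- sum(is.na(p) != is.na(c_))
    rows[[e]] <- tibble::tibble(
      parent = nm[edges[e, 1]], child = nm[edges[e, 2]],
      first = recon$pairs$first[chg], second = recon$pairs$second[chg],
      from = p[chg], to = c_[chg]
    )
    indet[[e]] <- tibble::tibble(parent = nm[edges[e, 1]],
                                 child = nm[edges[e, 2]],
                                 n_indeterminate = unk)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "indeterminate") <- dplyr::bind_rows(indet)
  attr(out, "optimization") <- optimization
  out
}

#' Ancestral event-pair table at a node
#'
#' @param recon A resolved `epp_recon`.
#' @param node Node (or tip) name.
#' @param optimization `"ACCTRAN"` or `"DELTRAN"`.
#' @return A `pair_code` tibble of the node's resolved states.
#' @export
node_code <- function(recon, node, optimization = c("ACCTRAN", "DELTRAN")) {
  optimization <- match.arg(optimization)
  res <- recon$resolved[[optimization]]
  if (is.null(res)) stop("resolution not computed", call. = FALSE)
  nm <- node_names(recon$tree)
  k <- match(node, nm)
  if (is.na(k)) stop("no node named '", node, "' in tree", call. = FALSE)
  new_pair_code(recon$pairs, res[, k], node, recon$event_order)
}
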