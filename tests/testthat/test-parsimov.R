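chg_row <- function(first, second, from, to) {
  tibble::tibble(parent = "p", child = "c", first = first, second = second,
                 from = as.integer(from), to = as.integer(to))
}

test_that("candidate movements are the two signed explanations per change", {
  cat4 <- toy_catalog(4)
  expect_equal(nrow(candidate_movements(chg_row(character(0), character(0),
                                                integer(0), integer(0)),
                                        cat4)), 0L)
  cand <- candidate_movements(chg_row("B", "C", 0, 2), cat4)
  expect_equal(nrow(cand), 2L)
  expect_true(any(cand$event == "C" & cand$direction == "late"))
  expect_true(any(cand$event == "B" & cand$direction == "early"))

  cand2 <- candidate_movements(chg_row("B", "C", 2, 0), cat4)
  expect_true(any(cand2$event == "C" & cand2$direction == "early"))
  expect_true(any(cand2$event == "B" & cand2$direction == "late"))
})

test_that("accounts_for implements the movement semantics", {
  expect_true(accounts_for("j", "late", "i", "j", 0L, 2L))
  expect_false(accounts_for("j", "early", "i", "j", 0L, 2L))
  expect_true(accounts_for("i", "early", "i", "j", 0L, 2L))
  expect_true(accounts_for("i", "late", "i", "j", 2L, 1L))
  expect_true(accounts_for("j", "early", "i", "j", 2L, 1L))
  expect_false(accounts_for("k", "late", "i", "j", 0L, 2L))
  expect_error(accounts_for("j", "late", "i", "j", NA_integer_, 2L),
               "unknown")
})

test_that("single-change branches yield two alternative minimal sets", {
  cat4 <- toy_catalog(4)
  changes <- chg_row("B", "C", 0, 2)
  sets <- minimal_move_sets(changes, cat4)
  expect_equal(attr(sets, "minimal_size"), 1L)
  expect_length(sets, 2L)
  rep <- consensus_shifts(sets, changes, branch = "p->c")
  expect_equal(nrow(rep$necessary), 0L)
  expect_equal(nrow(rep$joint), 1L)
  expect_equal(rep$joint$events[[1]], c("B", "C"))
  # the two alternatives explain the same change in opposite directions
  expect_equal(rep$joint$directions[[1]], c("early", "late"))
})

test_that("shared-event changes compress into one necessary movement", {
  cat4 <- toy_catalog(4)
  changes <- dplyr::bind_rows(chg_row("B", "C", 0, 2),
                              chg_row("B", "D", 0, 2))
  sets <- minimal_move_sets(changes, cat4)
  # (B, early) accounts for both; no other single movement does
  expect_equal(attr(sets, "minimal_size"), 1L)
  expect_length(sets, 1L)
  expect_equal(sets[[1]]$event, "B")
  expect_equal(sets[[1]]$direction, "early")
  rep <- consensus_shifts(sets, changes, branch = "p->c")
  expect_equal(rep$necessary$event, "B")
  expect_setequal(rep$necessary$reference[[1]], c("C", "D"))
})

test_that("empty change sets give one empty minimal set", {
  cat4 <- toy_catalog(4)
  changes <- chg_row(character(0), character(0), integer(0), integer(0))
  sets <- minimal_move_sets(changes, cat4)
  expect_length(sets, 1L)
  expect_equal(nrow(sets[[1]]), 0L)
})

test_that("minimal sets match exhaustive subset enumeration on random toys", {
  set.seed(13)
  cat5 <- plain_catalog(paste0("e", 1:5))
  for (i in 1:150) {
    k <- sample(1:5, 1)
    changes <- random_changes(cat5, k)
    sets <- minimal_move_sets(changes, cat5)
    oracle <- oracle_min_covers(changes, cat5)
    expect_true(movement_sets_equal(sets, oracle),
                label = paste("case", i))
    # every enumerated set accounts for every change
    for (s in sets) {
      for (ci in seq_len(nrow(changes))) {
        expect_true(any(accounts_for(s$event, s$direction,
                                     changes$first[ci], changes$second[ci],
                                     changes$from[ci], changes$to[ci])))
      }
      expect_false(anyDuplicated(s$event) > 0)  # no opposite-direction pairs
    }
  }
})

test_that("relabelling events permutes the solutions identically", {
  set.seed(17)
  cat5 <- plain_catalog(paste0("e", 1:5))
  perm_labels <- paste0("z", 5:1)
  cat5p <- plain_catalog(perm_labels[order(perm_labels)])
  # mapping preserving catalogue-order orientation: e_k -> sorted(z)'s k-th
  map <- stats::setNames(sort(perm_labels), paste0("e", 1:5))
  for (i in 1:25) {
    changes <- random_changes(cat5, sample(1:4, 1))
    permuted <- changes
    permuted$first <- unname(map[changes$first])
    permuted$second <- unname(map[changes$second])
    a <- minimal_move_sets(changes, cat5)
    b <- minimal_move_sets(permuted, cat5p)
    a_mapped <- lapply(a, function(s) {
      s$event <- unname(map[s$event]); s
    })
    expect_true(movement_sets_equal(a_mapped, b), label = paste("case", i))
  }
})

test_that("cross-optimization consensus intersects and keeps side channels", {
  cat4 <- toy_catalog(4)
  changes <- dplyr::bind_rows(chg_row("B", "C", 0, 2),
                              chg_row("B", "D", 0, 2))
  repA <- consensus_shifts(minimal_move_sets(changes, cat4), changes, "p->c")
  same <- cross_optimization_consensus(repA, repA)
  expect_equal(same$necessary$event, repA$necessary$event)
  expect_equal(nrow(same$acctran_only), 0L)

  other_changes <- dplyr::bind_rows(chg_row("C", "D", 0, 2),
                                    chg_row("B", "D", 2, 0))
  repB <- consensus_shifts(minimal_move_sets(other_changes, cat4),
                           other_changes, "p->c")
  crossed <- cross_optimization_consensus(repA, repB)
  expect_equal(nrow(crossed$necessary), 0L)
  expect_gt(nrow(crossed$acctran_only) + nrow(crossed$deltran_only), 0L)

  repC <- repB
  repC$branch <- "x->y"
  expect_error(cross_optimization_consensus(repA, repC), "different branches")
})
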