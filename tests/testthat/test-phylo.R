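test_that("newick parsing validates and round-trips the fixture topology", {
  tree <- fixture_tree()
  expect_equal(ape::Ntip(tree), 6L)
  expect_equal(tree$Nnode, 5L)
  expect_setequal(tree$node.label,
                  c("Branchiopoda", "Phyllopoda", "Diplostraca",
                    "Onychocaudata", "Cladoceromorpha"))
  expect_equal(parse_newick(write_newick(tree))$tip.label, tree$tip.label)

  small <- parse_newick("(A,B);")
  expect_equal(ape::Ntip(small), 2L)
  expect_error(parse_newick("((A,B);"), "unclosed")
  expect_error(parse_newick("(A,B));"), "character 6")
})

encode_leaf_codes <- function(catalog, seqs) {
  codes <- lapply(seqs, encode_sequence, catalog = catalog)
  names(codes) <- vapply(seqs, function(s) s$taxon, "")
  codes
}

test_that("constant and forced characters reconstruct as expected", {
  cat3 <- toy_catalog(3)
  tr <- parse_newick("((t1,t2)n2,(t3,t4)n3)n1;")
  mk <- function(taxon, txt) parse_sequence(txt, cat3, taxon)
  # identical sequences: zero length, same states everywhere
  codes <- encode_leaf_codes(cat3, list(mk("t1", "A,B,C"), mk("t2", "A,B,C"),
                                        mk("t3", "A,B,C"), mk("t4", "A,B,C")))
  recon <- fitch_mpr(tr, codes)
  expect_true(all(recon$length == 0))
  recon <- resolve_deltran(resolve_acctran(recon))
  for (optimization in c("ACCTRAN", "DELTRAN")) {
    expect_equal(nrow(branch_changes(recon, optimization)), 0L)
    res <- recon$resolved[[optimization]]
    expect_true(all(res == res[, 1]))
  }

  # cherries (0,0) vs (2,2): one change per differing character
  codes2 <- encode_leaf_codes(cat3, list(mk("t1", "B,A,C"), mk("t2", "B,A,C"),
                                         mk("t3", "A,B,C"), mk("t4", "A,B,C")))
  recon2 <- fitch_mpr(tr, codes2)
  # pair {A,B} differs (state 0 vs 2); pairs {A,C}, {B,C} constant
  expect_equal(sort(unique(recon2$length)), c(0, 1))
  expect_equal(sum(recon2$length), 1)
  recon2 <- resolve_acctran(recon2)
  chg <- branch_changes(recon2, "ACCTRAN")
  expect_equal(nrow(chg), 1L)
})

test_that("two-leaf ambiguity is resolved deterministically at the root", {
  cat2 <- toy_catalog(2)
  tr <- parse_newick("(t1,t2)r;")
  codes <- encode_leaf_codes(cat2, list(
    parse_sequence("A,B", cat2, "t1"),   # state 2
    parse_sequence("B,A", cat2, "t2")    # state 0
  ))
  recon <- resolve_deltran(resolve_acctran(fitch_mpr(tr, codes)))
  expect_equal(recon$length, 1)
  expect_true(recon$root_ambiguous)
  for (optimization in c("ACCTRAN", "DELTRAN")) {
    chg <- branch_changes(recon, optimization)
    expect_equal(nrow(chg), 1L)
    # root tie-break: lowest state index
    expect_equal(recon$resolved[[optimization]][1, "r"], c(r = 0L))
  }
})

test_that("Fitch lengths match the exhaustive-labeling oracle", {
  set.seed(7)
  n_cases <- 120
  for (i in seq_len(n_cases)) {
    n_tips <- sample(3:6, 1)
    tr <- random_named_tree(n_tips)
    states <- sample(c(0:2, NA), n_tips, replace = TRUE)
    if (all(is.na(states))) states[1] <- 0L
    oracle <- oracle_parsimony(tr, states)
    cat2 <- toy_catalog(2)
    codes <- lapply(seq_len(n_tips), function(k) {
      if (is.na(states[k])) delinearize_code("?", cat2, paste0("t", k))
      else delinearize_code(as.character(states[k]), cat2, paste0("t", k))
    })
    names(codes) <- tr$tip.label
    recon <- fitch_mpr(tr, codes)
    expect_equal(recon$length, oracle$length)
    # MPR state sets match the states used by at least one optimal labeling
    for (v in seq_len(n_tips + tr$Nnode)) {
      if (v <= n_tips && is.na(states[v])) next
      expect_equal(which(recon$mpr[[v]][1, ]) - 1L, oracle$mpr[[v]],
                   label = paste("node", v, "case", i))
    }
  }
})

test_that("both resolutions attain the Fitch length and conserve changes", {
  set.seed(11)
  for (i in 1:40) {
    n_tips <- sample(4:6, 1)
    tr <- random_named_tree(n_tips)
    cat5 <- plain_catalog(paste0("e", 1:5))
    seqs <- lapply(seq_len(n_tips), function(k)
      random_sequence(cat5, n_ranks = 3, p_missing = 0.1,
                      taxon = paste0("t", k)))
    codes <- encode_leaf_codes(cat5, seqs)
    recon <- resolve_deltran(resolve_acctran(fitch_mpr(tr, codes)))
    for (optimization in c("ACCTRAN", "DELTRAN")) {
      expect_equal(resolution_lengths(recon, optimization),
                   as.integer(recon$length))
      chg <- branch_changes(recon, optimization)
      expect_equal(nrow(chg), sum(recon$length))
      # resolved states always belong to the MPR state set at internal
      # nodes (characters with no data at any leaf stay unresolved)
      res <- recon$resolved[[optimization]]
      has_data <- rowSums(!is.na(recon$tip_states)) > 0
      for (v in (n_tips + 1):(n_tips + tr$Nnode)) {
        expect_true(all(recon$mpr[[v]][cbind(which(has_data),
                                             res[has_data, v] + 1L)]))
        expect_true(all(is.na(res[!has_data, v])))
      }
    }
  }
})

test_that("ordered treatment uses additive costs", {
  cat2 <- toy_catalog(2)
  tr <- parse_newick("(t1,t2)r;")
  codes <- list(t1 = delinearize_code("0", cat2, "t1"),
                t2 = delinearize_code("2", cat2, "t2"))
  expect_equal(fitch_mpr(tr, codes, treatment = "unordered")$length, 1)
  expect_equal(fitch_mpr(tr, codes, treatment = "ordered")$length, 2)
})

test_that("missing leaf data never generates changes", {
  cat2 <- toy_catalog(2)
  tr <- parse_newick("((t1,t2)n2,t3)n1;")
  codes <- list(t1 = delinearize_code("2", cat2, "t1"),
                t2 = delinearize_code("?", cat2, "t2"),
                t3 = delinearize_code("2", cat2, "t3"))
  recon <- resolve_deltran(resolve_acctran(fitch_mpr(tr, codes)))
  expect_equal(recon$length, 0)
  for (optimization in c("ACCTRAN", "DELTRAN")) {
    chg <- branch_changes(recon, optimization)
    expect_equal(nrow(chg), 0L)
    indet <- attr(chg, "indeterminate")
    expect_equal(sum(indet$n_indeterminate), 1L)  # the t2 branch
  }
  expect_error(fitch_mpr(tr, codes[c("t1", "t2")]), "no event-pair data")
})
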