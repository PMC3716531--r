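# Shared fixture loaders and toy constructors.

fixture_catalog <- function() {
  read_event_catalog(system.file("extdata", "branchiopod_events.tsv",
                                 package = "parsimovr"))
}

fixture_penilia <- function(catalog = fixture_catalog()) {
  read_sequences(system.file("extdata", "penilia_avirostris.tsv",
                             package = "parsimovr"), catalog)$seq[[1]]
}

fixture_tree <- function() {
  read_tree(system.file("extdata", "branchiopoda.nwk", package = "parsimovr"))
}

toy_catalog <- function(n = 4, molts = character(), hatching = character()) {
  labels <- LETTERS[seq_len(n)]
  category <- rep("morphological", n)
  category[match(molts, labels)] <- "molt"
  category[match(hatching, labels)] <- "hatching"
  event_catalog(data.frame(label = labels, description = "",
                           category = category))
}

# a catalogue with arbitrary labels, all morphological
plain_catalog <- function(labels) {
  event_catalog(data.frame(label = labels, description = "",
                           category = "morphological"))
}

# random developmental sequence over a catalogue: events assigned uniformly
# to 1..n_ranks blocks (empty blocks dropped), optional missing events
random_sequence <- function(catalog, n_ranks, p_missing = 0, taxon = "t") {
  labels <- event_labels(catalog)
  keep <- stats::runif(length(labels)) >= p_missing
  if (!any(keep)) keep[1] <- TRUE
  placed <- labels[keep]
  rk <- sample.int(n_ranks, length(placed), replace = TRUE)
  ranks <- lapply(sort(unique(rk)), function(k) placed[rk == k])
  dev_sequence(taxon, ranks, setdiff(labels, placed), catalog)
}

# random rooted binary tree with named nodes and the given tip count
random_named_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips, rooted = TRUE, br = NULL)
  tr$tip.label <- paste0("t", seq_len(n_tips))
  tr$node.label <- paste0("n", seq_len(tr$Nnode))
  tr
}
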