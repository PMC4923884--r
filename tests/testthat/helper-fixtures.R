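# Shared fixtures, built in code.

# 10-node toy graph: three hubs g1, g5, g9 whose initialized modules are
# U1 = {g1,g2,g3,g4}, U2 = {g5,g6,g7,g8}, U3 = {g10,g2,g6,g9};
# U1 and U2 are disjoint, U3 overlaps both in one gene.
toy_partition_network <- function() {
  network_from_edges(data.frame(
    gene_a = c("g1", "g1", "g1", "g5", "g5", "g5", "g9", "g9", "g9"),
    gene_b = c("g2", "g3", "g4", "g6", "g7", "g8", "g2", "g6", "g10"),
    stringsAsFactors = FALSE))
}

# tiny expression TSV on disk; returns the path
write_toy_expression_tsv <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("gene_id\ts1\ts2",
               "gA\t1.5\t2.5",
               "gB\t0\t-1",
               "gC\t3.25\t4"), path)
  path
}

# annotation data.frame for n samples with given survival/event vectors
make_ann <- function(days, event, ids = sprintf("s%d", seq_along(days))) {
  data.frame(sample_id = ids, survival_days = as.integer(days),
             event = as.logical(event), stringsAsFactors = FALSE)
}

# random initialized-module systems for property tests
random_module_system <- function(n_mods, universe = 12L) {
  genes <- sprintf("x%02d", seq_len(universe))
  mods <- lapply(seq_len(n_mods), function(i) {
    members <- sort(sample(genes, sample(2:4, 1L)))
    structure(list(hub = members[1L], members = members,
                   hub_degree = length(members) - 1L),
              class = "initialized_module")
  })
  # distinct hubs keep tie-breaks meaningful
  hubs <- vapply(mods, `[[`, "", "hub")
  mods[!duplicated(hubs)]
}
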