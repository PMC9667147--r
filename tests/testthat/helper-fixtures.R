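# Small networks built in code, shared across test files.

# Headwater -> mid -> outlet chain of n nodes (node n is the outlet).
chain_network <- function(n = 3, slope = 0.1) {
  as_stream_network(tibble::tibble(
    node_id = seq_len(n),
    x = as.numeric(seq_len(n)), y = 0,
    downstream_id = c(2:n, NA)[seq_len(n)],
    reach_length = 1,
    slope = slope
  ))
}

# Y-shaped 5-node tree: edges B->A, C->B, D->C, E->C (A outlet).
# Persistencies chosen so that at P* = 0.5 the active set {A, C, D}
# splits into components {A} and {C, D}.
toy_y_tree <- function() {
  net <- as_stream_network(tibble::tibble(
    node_id = 1:5,                       # A B C D E
    x = c(0, 0, 0, -1, 1), y = c(0, 1, 2, 3, 3),
    downstream_id = c(NA, 1L, 2L, 3L, 3L),
    reach_length = 1,
    slope = 0.1
  ))
  net$persistency <- c(0.9, 0.3, 0.8, 0.7, 0.2)
  net
}

# Independent largest-connected-patch oracle: induced subgraph of the
# active nodes via igraph, maximum component length by enumeration.
lcp_brute_force <- function(network, p_star) {
  act <- which(network$persistency >= p_star)
  if (length(act) == 0) return(0)
  ds <- match(network$downstream_id, network$node_id)
  from <- seq_len(nrow(network))
  keep <- !is.na(ds) & from %in% act & ds %in% act
  g <- igraph::graph_from_data_frame(
    data.frame(from = from[keep], to = ds[keep]),
    directed = FALSE,
    vertices = data.frame(name = act))
  comp <- igraph::components(g)
  lens <- tapply(network$reach_length[act], comp$membership, sum)
  max(lens)
}

# One hundred-year run per climate, shared by the slower statistical tests.
cached_run <- local({
  cache <- new.env()
  function(label) {
    if (is.null(cache[[label]])) {
      cache[[label]] <- run_scenario(label, n_years = 100, n_nodes = 1215,
                                     seed = 42)
    }
    cache[[label]]
  }
})
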