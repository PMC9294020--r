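# Random connected conductance networks for solver property tests, built
# directly at the node/edge level (independently of the ureter assembler).
random_test_network <- function(seed, n_nodes = 50L, n_extra = 25L) {
  set.seed(seed)
  n <- max(4L, as.integer(n_nodes))
  nodes <- data.frame(
    name = c("pelvis", "bladder", sprintf("n%03d", seq_len(n - 2L))),
    side = c("reservoir", "reservoir", rep("intra", n - 2L)),
    x = seq(0, 1, length.out = n),
    fixed = c(TRUE, TRUE, rep(FALSE, n - 2L)),
    pressure = c(runif(1, 50, 150), 0, rep(NA_real_, n - 2L))
  )
  nodes$id <- seq_len(n)
  # random spanning tree guarantees connectivity, then extra chords
  from <- integer(0); to <- integer(0)
  for (v in 3:n) {
    from <- c(from, sample(v - 1L, 1L)); to <- c(to, v)
  }
  for (k in seq_len(n_extra)) {
    pair <- sample(n, 2L)
    from <- c(from, pair[1L]); to <- c(to, pair[2L])
  }
  m <- length(from)
  edges <- data.frame(
    from = from, to = to, G = 10^runif(m, -8, -4),
    kind = "intra", side = "intra", segment = NA_integer_,
    hole = NA_integer_, D_h = 1e-3, area = 1e-6,
    x0 = 0, x1 = 0)
  structure(list(nodes = nodes, edges = edges,
                 stations = numeric(0), hole_index = integer(0),
                 boundaries = numeric(0), midpoints = numeric(0),
                 seg_lengths = numeric(0), dropped_nodes = character(0),
                 scenario = NULL),
            class = "hydraulic_network")
}

# Normwise relative deviation between two solutions of the same network.
solution_deviation <- function(a, b) {
  dp <- max(abs(a$node_pressures - b$node_pressures)) /
    max(abs(a$node_pressures))
  df <- max(abs(a$edges$flow - b$edges$flow)) / max(abs(a$edges$flow))
  max(dp, df)
}
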