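# small in-code fixtures shared across test files

# complete 2-condition x 3-sample x 3-replicate grid labels
full_grid_labels <- function() {
  g <- expand.grid(r = 1:3, s = 1:3, c = c("A", "I"))
  sprintf("%s_s%d_r%d", g$c, g$s, g$r)
}

# tiny quant table: n proteins on the full 18-column grid, constant value
# `fill`, optionally with cells knocked out
tiny_table <- function(n = 3, fill = 100, species = "human") {
  labs <- full_grid_labels()
  vals <- matrix(fill, n, length(labs), dimnames = list(NULL, labs))
  quant_table(vals,
              protein_id = sprintf("P%02d", seq_len(n)),
              gene_symbol = sprintf("G%02d", seq_len(n)),
              species = rep(species, n))
}

# planted-partition graph: k blocks of `block` nodes, edge prob p_in within
# and p_out between, uniform confidences
planted_graph <- function(k = 3, block = 10, p_in = 0.9, p_out = 0.02) {
  n <- k * block
  nodes <- sprintf("n%02d", seq_len(n))
  lab <- rep(seq_len(k), each = block)
  a <- character(); b <- character(); conf <- numeric()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- if (lab[i] == lab[j]) p_in else p_out
    if (stats::runif(1) < p) {
      a <- c(a, nodes[i]); b <- c(b, nodes[j])
      conf <- c(conf, stats::runif(1, 0.4, 1))
    }
  }
  list(graph = weighted_graph(data.frame(a = a, b = b, confidence = conf,
                                         stringsAsFactors = FALSE)),
       labels = stats::setNames(lab, nodes))
}

# do two cluster labelings define the same partition?
same_partition <- function(m1, m2) {
  m2 <- m2[names(m1)]
  p1 <- split(names(m1), m1)
  p2 <- split(names(m2), m2)
  setequal(lapply(p1, sort), lapply(p2, sort))
}

two_triangle_graph <- function(bridge = 0.1) {
  weighted_graph(data.frame(
    a = c("a1", "a1", "a2", "b1", "b1", "b2", "a1"),
    b = c("a2", "a3", "a3", "b2", "b3", "b3", "b1"),
    confidence = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.9, bridge),
    stringsAsFactors = FALSE))
}
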