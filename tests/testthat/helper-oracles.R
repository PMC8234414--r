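# Independent oracles used across the suite. These re-derive expectations by
# routes separate from the package implementation.

# Classical series solution for the torsion shape factor of a rectangle with
# aspect ratio a/b >= 1 (Saint-Venant series, truncated at n = 199).
beta_series <- function(aspect) {
  n <- seq(1, 199, by = 2)
  (1 / 3) - (64 / pi^5) * (1 / aspect) * sum(tanh(n * pi * aspect / 2) / n^5)
}

# Noiseless lagged-logistic deflection curve (mirrors the generator's stated
# closed form, written out independently).
logistic_deflection <- function(t, F_inf, k, t_half = 900, tau = 300) {
  s0 <- 1 / (1 + exp(t_half / tau))
  s <- 1 / (1 + exp(-(t - t_half) / tau))
  (F_inf / k) * (s - s0) / (1 - s0)
}

# Brute-force DFS enumeration of simple-path sign products on a signed edge
# list (data frame source/target/sign) -- oracle for the igraph-based
# prediction route.
dfs_path_products <- function(edges, from, sink) {
  out <- numeric(0)
  walk <- function(node, visited, prod) {
    if (node == sink) {
      out <<- c(out, prod)
      return(invisible(NULL))
    }
    nxt <- edges[edges$source == node & !(edges$target %in% visited), ]
    for (i in seq_len(nrow(nxt)))
      walk(nxt$target[i], c(visited, nxt$target[i]), prod * nxt$sign[i])
  }
  walk(from, from, 1)
  out
}

default_chip <- function() sensor_chip(100)
paper_beam <- function() beam_geometry(680, 50, 10)
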