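# Independent brute-force oracles and small fixture builders used across the
# test files. These deliberately avoid the package's own vectorized /
# compiled code paths so agreement is evidence, not tautology.

# O(n^2) double-loop contact-network oracle
oracle_edges <- function(cells, threshold = 15) {
  n <- nrow(cells)
  out <- list()
  k <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2)
      if (d <= threshold) {
        k <- k + 1L
        a <- cells$id[i]; b <- cells$id[j]
        out[[k]] <- c(min(a, b), max(a, b))
      }
    }
  }
  if (!k) return(matrix(integer(0), ncol = 2,
                        dimnames = list(NULL, c("id_a", "id_b"))))
  m <- do.call(rbind, out)
  colnames(m) <- c("id_a", "id_b")
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# largest pairwise disk overlap (0 if none)
oracle_max_overlap <- function(cells) {
  n <- nrow(cells)
  mo <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2)
      ov <- cells$radius[i] + cells$radius[j] - d
      if (ov > mo) mo <- ov
    }
  }
  mo
}

# plain-R explicit-Euler reference for the transport substep on a fixed
# network (synchronous update, same order of operations as documented)
oracle_substep <- function(conc, edges, pm, vp_vec, k50_vec, kd, nsub) {
  for (s in seq_len(nsub)) {
    d <- numeric(length(conc))
    if (nrow(edges)) {
      for (k in seq_len(nrow(edges))) {
        i <- edges[k, 1]; j <- edges[k, 2]
        d[i] <- d[i] + pm[k] * (conc[j] - conc[i])
        d[j] <- d[j] + pm[k] * (conc[i] - conc[j])
      }
    }
    d <- d + ifelse(vp_vec > 0, vp_vec / (1 + conc / k50_vec), 0) - kd * conc
    conc <- conc + d
  }
  conc
}

# build a minimal cells data frame at given coordinates
make_cells <- function(x, y, phenotype = "P", conc = 0, t_div = 0, tc = 0,
                       radius = 6.5, id = seq_along(x) - 1L) {
  data.frame(id = as.integer(id), x = x, y = y, radius = radius,
             phenotype = rep_len(phenotype, length(x)),
             t_div = rep_len(t_div, length(x)),
             conc = rep_len(conc, length(x)),
             tc = rep_len(tc, length(x)), stringsAsFactors = FALSE)
}

# colony constructor bypassing gjcolony's network builder (edges supplied or
# recomputed by the oracle) -- used where the network itself is under test
make_colony <- function(cells, time = 0, params = gj_params()) {
  new_colony(cells, time = time, params = params)
}

# random non-degenerate scattered cells over a square of side `spread`
random_cells <- function(n, spread = 120, radius = 6.5) {
  make_cells(runif(n, 0, spread), runif(n, 0, spread), radius = radius)
}

# 2 x 3 grid fixture with hand-computable network/metrics (pitch 13 um):
# edges (0,1),(1,2),(3,4),(4,5),(0,3),(1,4),(2,5); diagonals 18.4 um apart
grid6_cells <- function() {
  make_cells(x = c(0, 13, 26, 0, 13, 26),
             y = c(0, 0, 0, 13, 13, 13))
}
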