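# Small builders used across test files. Everything is generated in code;
# no stored fixtures.

path_adjacency <- function(n) {
  adjacency_from_edges(paste0("p", seq_len(n)),
                       cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L))
}

# tiny valid areal dataset on a 3x4 lattice (n = 12 >= 10)
tiny_dataset <- function(seed = 1) {
  set.seed(seed)
  adj <- make_lattice(3, 4)
  n <- adj$n
  x <- simulate_covariates(n, 3, correlation = 0, seed = seed)
  areal_dataset(ids = adj$ids,
                populations = sample(100:500, n, replace = TRUE),
                counts = cbind(y_1 = rpois(n, 5), y_2 = rpois(n, 3)),
                covariates = x, adjacency = adj,
                orientation = attr(x, "orientation"))
}

# write a units.csv / adjacency.gal pair for load_dataset tests; optionally
# zero out populations or blank covariates for chosen rows
write_bundle <- function(dir, nrows, ncols, zero_pop = integer(0),
                         miss_cov = integer(0), seed = 1) {
  set.seed(seed)
  adj <- make_lattice(nrows, ncols)
  n <- adj$n
  x <- matrix(round(rexp(n * 2), 4), n, 2,
              dimnames = list(NULL, c("x_1", "x_2")))
  df <- data.frame(id = adj$ids,
                   population = sample(50:500, n, replace = TRUE),
                   y_1 = rpois(n, 2), y_2 = rpois(n, 1) + 1L, x)
  df$population[zero_pop] <- 0L
  df$x_2[miss_cov] <- NA
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(df, file.path(dir, "units.csv"), row.names = FALSE)
  write_gal(adj, file.path(dir, "adjacency.gal"))
  dir
}
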