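# Shared fixtures and independent oracles, all built in code.

legs <- function(...) {
  x <- list(...)
  data.frame(mode = names(x), duration_min = as.numeric(unlist(x)))
}

summary_row <- function(wc, car, pt = FALSE, travelled = wc > 0 || car > 0 || pt) {
  data.frame(walkcycle_min = wc, car_min = car, pt_used = pt,
             travelled = travelled)
}

# a classified table for one area built from category counts
area_classified <- function(area_id, n_low = 0, n_high = 0, n_mt = 0,
                            n_st = 0, n_none = 0, n_pst = 0) {
  wc <- c(rep(15, n_low), rep(45, n_high), rep(20, n_mt),
          rep(0, n_st + n_pst), rep(0, n_none))
  car <- c(rep(0, n_low + n_high), rep(30, n_mt), rep(30, n_st),
           rep(90, n_pst), rep(0, n_none))
  n <- length(wc)
  d <- data.frame(person_id = sprintf("%s_p%04d", area_id, seq_len(n)),
                  area_id = area_id, walkcycle_min = wc, car_min = car,
                  pt_used = FALSE,
                  travelled = wc > 0 | car > 0)
  d <- cbind(d, duration_category(d))
  d$mode_group <- mode_group(d)
  d
}

# independent union-find oracle for connected components of an edge list
union_find_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(edges) > 0) for (k in seq_len(nrow(edges))) {
    ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
    if (ra != rb) parent[rb] <- ra
  }
  # path-compress into canonical labels
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Moran's I of a vector over adjacency W (independent spatial statistic)
morans_i <- function(x, W) {
  z <- x - mean(x)
  (length(x) / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
}

small_geography <- function(rows = 4, cols = 4, seed = 301)
  generate_geography(rows, cols, pop_range = c(100, 100), seed = seed)

quick_mcmc <- function(n_iter = 1500, burn_in = 500, thin = 1, seed = 99)
  mcmc_config(n_iter, burn_in, thin, seed = seed)
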