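# Shared fixtures and independent reference implementations used as
# oracles. The reference code deliberately uses plain loops and base
# arithmetic, independent of the package's vectorised paths.

# naive per-track statistics (oracle for trackstats)
naive_track_stats <- function(tr) {
  n <- length(tr$t_min)
  d_tot <- 0
  for (i in seq_len(n - 1L)) {
    d_tot <- d_tot + sqrt((tr$x_um[i + 1L] - tr$x_um[i])^2 +
                          (tr$y_um[i + 1L] - tr$y_um[i])^2)
  }
  d_net <- sqrt((tr$x_um[n] - tr$x_um[1L])^2 + (tr$y_um[n] - tr$y_um[1L])^2)
  t_net <- tr$t_min[n] - tr$t_min[1L]
  list(d_tot = d_tot, d_net = d_net, t_net = t_net,
       speed = d_net / t_net, directionality = d_net / d_tot)
}

# scalar spring-accumulation oracle: constant per-step force magnitude f,
# full conservation; returns the 1-based step index of the first move
# (first step where the accumulated total exceeds the threshold)
naive_first_move_step <- function(f, threshold, k_spring = 1) {
  spring <- 0
  step <- 0
  repeat {
    step <- step + 1
    total <- spring + f
    if (total > threshold) return(step)
    spring <- k_spring * total
    if (step > 10000) stop("no move within 10000 steps")
  }
}

# random track generator for property tests
random_track <- function(id, seed) {
  set.seed(seed)
  n <- sample(3:30, 1)
  t <- cumsum(c(0, sample(c(15, 30, 45), n - 1, replace = TRUE)))
  track(id, t, cumsum(rnorm(n, sd = 5)), cumsum(rnorm(n, sd = 5)),
        channel = sample(c("green", "red"), 1))
}

# L-shaped hand track: (0,0) -> (3,0) -> (3,4) at t = 0, 30, 70 min
l_track <- function() track("L", c(0, 30, 70), c(0, 3, 3), c(0, 0, 4))

# small two-genotype laminar fraction table with a shift in one zone
shifted_fraction_table <- function(n_zones = 5, n_rep = 5, shift = 0.25,
                                   shifted_zone = 2, seed = 42) {
  set.seed(seed)
  rows <- list()
  for (g in c("a", "b")) {
    for (r in seq_len(n_rep)) {
      base <- rep(1, n_zones)
      if (g == "b") {
        base[shifted_zone] <- base[shifted_zone] + shift * n_zones
      }
      p <- base / sum(base)
      counts <- stats::rmultinom(1, 400, p)[, 1]
      rows[[length(rows) + 1L]] <-
        data.frame(zone = seq_len(n_zones), genotype = g,
                   replicate = paste0(g, r), fraction = counts / sum(counts))
    }
  }
  do.call(rbind, rows)
}
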