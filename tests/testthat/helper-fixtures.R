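# Shared fixtures: tiny source matrices, random LAD instances, and an
# exact least-absolute-deviation oracle (linear program via boot::simplex).

# the two-food / two-FA textbook cases
vertex_foods <- function() {
  cbind(food1 = c("16:0" = 100, "18:1" = 0),
        food2 = c("16:0" = 0, "18:1" = 100))
}

overlap_foods <- function() {
  cbind(food1 = c("16:0" = 80, "18:1" = 20),
        food2 = c("16:0" = 60, "18:1" = 40))
}

toy_fat <- function() c("16:0" = 38, "18:1" = 62)

# three distinguishable 3-FA sources on a common total
toy_sources <- function() {
  M <- cbind(a = c(60, 30, 10), b = c(10, 60, 30), c = c(25, 25, 50))
  rownames(M) <- c("16:0", "18:1", "18:2")
  M
}

# random instance of the LAD-over-simplex problem: k sources, m FAs,
# all signatures on a common total so raw and rescaled fitting coincide
random_lad_instance <- function(k, m = 10, total = 1000) {
  M <- matrix(exp(stats::rnorm(m * k, 3, 1)), m, k)
  M <- sweep(M, 2, colSums(M), "/") * total
  rownames(M) <- sprintf("%d:0", 11 + seq_len(m))
  colnames(M) <- paste0("s", seq_len(k))
  p <- stats::rexp(k)
  p <- p / sum(p)
  obs <- as.numeric(M %*% p) * exp(stats::rnorm(m, 0, 0.15))
  obs <- obs / sum(obs) * total
  names(obs) <- rownames(M)
  list(M = M, obs = obs)
}

# exact minimum of sum |M p - obs| over the simplex, as a linear program:
# variables (p, e), minimize sum(e) s.t. Mp - e <= obs, Mp + e >= obs,
# sum(p) = 1, everything >= 0
lad_lp <- function(M, obs) {
  k <- ncol(M)
  m <- nrow(M)
  a <- c(rep(0, k), rep(1, m))
  A1 <- cbind(M, -diag(m))
  A2 <- cbind(M, diag(m))
  A3 <- matrix(c(rep(1, k), rep(0, m)), nrow = 1)
  s <- boot::simplex(a = a, A1 = A1, b1 = unname(obs),
                     A2 = A2, b2 = unname(obs),
                     A3 = A3, b3 = 1, maxi = FALSE)
  list(value = s$value, p = s$soln[seq_len(k)])
}

# independent R-side enumeration of all grid diets (small instances only)
enumerate_grid_deviations <- function(M, obs, nsteps) {
  k <- ncol(M)
  grids <- do.call(expand.grid, rep(list(0:nsteps), k - 1))
  keep <- rowSums(grids) <= nsteps
  grids <- grids[keep, , drop = FALSE]
  apply(grids, 1, function(g) {
    p <- c(unlist(g), nsteps - sum(g)) / nsteps
    sum(abs(as.numeric(M %*% p) - obs))
  })
}

# small site-matched study scenario with diets exactly on the 1% grid
grid_diet_table <- function(sources = c("grass", "roots", "feces")) {
  site_diets <- list(low = c(0.55, 0.32, 0.13),
                     medium = c(0.62, 0.18, 0.20),
                     high = c(0.74, 0.00, 0.26))
  n_per_site <- c(low = 8, medium = 7, high = 5)
  do.call(rbind, lapply(names(site_diets), function(s) {
    out <- data.frame(animal_id = sprintf("%s_%d", s, seq_len(n_per_site[[s]])),
                      site = s, stringsAsFactors = FALSE)
    for (i in seq_along(sources)) out[[sources[i]]] <- site_diets[[s]][i]
    out
  }))
}
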