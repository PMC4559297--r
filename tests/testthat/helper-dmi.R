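# shared fixtures and independent oracles, built in code

# quadratic-loop brute-force oracle for the nearest-neighbor graph length
lp_brute_force <- function(points, neighbor_set, p) {
  n <- nrow(points)
  total <- 0
  for (i in seq_len(n)) {
    dists <- sqrt(colSums((t(points[-i, , drop = FALSE]) - points[i, ])^2))
    dists <- sort(dists)
    total <- total + sum(dists[neighbor_set]^p)
  }
  total
}

# estimator config sized for small test problems
test_rmi_config <- function(min_n = 15L, seed = 1L) {
  rmi_config(min_n = min_n, seed = seed)
}

# expression matrix where `d` target genes share a latent factor in the
# samples where the modulator is high, and are independent elsewhere
make_modulated_expr <- function(m = 60L, d = 4L, n_extra = 20L, seed = 1L,
                                flip = FALSE) {
  withr::with_seed(seed, {
    on <- rep(c(FALSE, TRUE), each = m / 2)
    mod <- ifelse(on, 1, 0) + rnorm(m, sd = 0.1)
    if (flip) mod <- -mod
    z <- rnorm(m)
    targets <- t(vapply(seq_len(d), function(j) {
      ifelse(on, 0.9 * z + sqrt(1 - 0.9^2) * rnorm(m), rnorm(m))
    }, numeric(m)))
    extra <- matrix(rnorm(n_extra * m), nrow = n_extra)
    expr <- rbind(targets, mod, extra)
    rownames(expr) <- c(sprintf("T%02d", seq_len(d)), "MOD",
                        sprintf("G%03d", seq_len(n_extra)))
    colnames(expr) <- sprintf("s%03d", seq_len(m))
    expr
  })
}

# direct (unoptimized) running-sum enrichment oracle
running_sum_es <- function(scores, hits, weight = 1) {
  n <- length(scores)
  w <- abs(scores)^weight
  nh <- sum(w[hits])
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- run + if (i %in% hits) unname(w[i]) / nh else -1 / (n - length(hits))
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}
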