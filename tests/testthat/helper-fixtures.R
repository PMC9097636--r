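# Shared fixture builders; everything is generated in code at test time.

make_shift_fixture <- function(n = 20, seed = 1) {
  foxdyn:::with_seed(seed, {
    shift_table(seq_len(n), sample(c("A", "G", "S", "L", "K"), n, TRUE),
                8 + rnorm(n, sd = 0.4), 115 + rnorm(n, sd = 4),
                state_label = "fixture_free")
  })
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Brute-force rigid superposition oracle: Nelder-Mead over Euler angles
# seeded from a coarse rotation grid; independent of the SVD route.
bruteforce_min_rmsd <- function(P, Q, grid = seq(0, 2 * pi, length.out = 9)) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rot <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(a) sqrt(mean(rowSums((Pc %*% rot(a) - Qc)^2)))
  best <- Inf; best_a <- c(0, 0, 0)
  half <- grid[grid <= pi]
  for (a1 in grid) for (a2 in half) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < best) { best <- v; best_a <- c(a1, a2, a3) }
  }
  for (k in 1:5) {
    o <- stats::optim(best_a, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (o$value < best) { best <- o$value; best_a <- o$par }
  }
  best
}
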