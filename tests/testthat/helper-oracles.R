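# Independent oracles used across the suite. Each is a deliberately naive
# re-derivation (loops, root-finding, explicit regression algebra) kept
# separate from the package's own code paths.

# Helical-wheel moment by explicit per-residue loop.
oracleMoment <- function(helix, scale, twistDeg = 100) {
  res <- strsplit(helix, "")[[1]]
  vx <- 0; vy <- 0
  for (i in seq_along(res)) {
    a <- (i - 1) * twistDeg * pi / 180
    vx <- vx + scale[[res[i]]] * cos(a)
    vy <- vy + scale[[res[i]]] * sin(a)
  }
  sqrt(vx^2 + vy^2) / length(res)
}

# Bound ligand by root-finding on free ligand: free + P*free/(kd+free) = L.
oracleBound <- function(L, P, kd) {
  vapply(L, function(Li) {
    if (Li == 0) return(0)
    f <- stats::uniroot(function(fr) fr + P * fr / (kd + fr) - Li,
                        c(0, Li), tol = 1e-14)$root
    P * f / (kd + f)
  }, numeric(1))
}

# Straight-line least squares by the textbook sums, returning c(a, b) of
# y = a + b x.
oracleLine <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(a = mean(y) - b * mean(x), b = b)
}

# A small random h/p/G pattern under a fixed RNG stream.
randomPattern <- function(n) {
  paste(sample(c("h", "p", "G"), n, replace = TRUE,
               prob = c(0.6, 0.25, 0.15)), collapse = "")
}

reampProtein <- function(...) assembleConstruct(reampSpec(...))
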