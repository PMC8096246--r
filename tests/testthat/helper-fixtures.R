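# Small parameter presets and independent oracles shared across tests.

small_params <- function(...) {
  args <- list(image_shape = c(256L, 256L), n_z_slices = 1L, n_nuclei = 4L,
               foci_per_nucleus = 2L, true_ratio = 0.8, seed = 42L)
  do.call(sim_params, utils::modifyList(args, list(...)))
}

# Exact Wilcoxon rank-sum p by full enumeration of all C(n+m, n) group
# assignments; independent of the implementation under test.
wilcox_exact_enum <- function(x, y, alternative = "two.sided") {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  Us <- apply(utils::combn(n + m, n), 2,
              function(idx) sum(r[idx]) - n * (n + 1) / 2)
  lo <- mean(Us <= W + 1e-9); hi <- mean(Us >= W - 1e-9)
  switch(alternative,
         less = lo, greater = hi,
         two.sided = min(1, 2 * min(lo, hi)))
}

# Brute-force integer-shift normalized cross-correlation argmax (the
# registration oracle): returns the (dy, dx) in [-m, m]^2 maximizing the
# correlation of overlapping regions.
brute_force_shift <- function(ref, mov, m = 10L) {
  best <- c(NA, NA); bestc <- -Inf
  ny <- nrow(ref); nx <- ncol(ref)
  for (dy in -m:m) for (dx in -m:m) {
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    a <- ref[ys - dy, xs - dx]; b <- mov[ys, xs]
    cc <- suppressWarnings(stats::cor(as.vector(a), as.vector(b)))
    if (is.finite(cc) && cc > bestc) { bestc <- cc; best <- c(dy, dx) }
  }
  best
}

# circularly roll a matrix's content by (dy, dx)
roll_matrix <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  m[((seq_len(ny) - 1 - dy) %% ny) + 1, ((seq_len(nx) - 1 - dx) %% nx) + 1]
}

# random N-free DNA sequence
random_dna <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# match detected spot centers to truth rows within tol; returns counts
match_to_truth <- function(centers, truth, tol = 3) {
  used <- logical(nrow(truth))
  tp <- 0L
  for (i in seq_len(nrow(centers))) {
    d2 <- (truth$y - centers[i, 1])^2 + (truth$x - centers[i, 2])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] <= tol^2) { used[j] <- TRUE; tp <- tp + 1L }
  }
  list(tp = tp, fp = nrow(centers) - tp, fn = nrow(truth) - tp)
}
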