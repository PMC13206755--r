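# Shared fixtures: small phantom sets and brute-force metric oracles.

# Small fundus phantoms rendered directly at the training resolution
# (no cropping step) for capacity/determinism checks.
make_phantom_set <- function(n, image_size = 128, seed = 1) {
  lapply(seq_len(n), function(i) {
    set.seed(seed * 1000 + i)
    s <- image_size
    sp <- phantom_spec(image_size = s,
                       disc_center = s / 2 + runif(2, -s / 16, s / 16),
                       disc_radii = c(runif(1, 0.17, 0.25),
                                      runif(1, 0.15, 0.22)) * s,
                       cup_to_disc_ratio = runif(1, 0.35, 0.65),
                       vessel_count = 3, vessel_width = 3,
                       noise_sigma = 0.02, seed = seed * 1000 + i)
    ph <- generate_phantom(sp)
    list(image = ph$image, mask = ph$mask, metadata = ph$metadata)
  })
}

# random blob-like binary masks for metric oracle checks
random_mask <- function(h, w, p_empty = 0.05) {
  if (runif(1) < p_empty) return(matrix(FALSE, h, w))
  m <- matrix(FALSE, h, w)
  for (b in seq_len(sample(1:3, 1))) {
    cr <- runif(1, 1, h); cc <- runif(1, 1, w)
    rr <- runif(1, 1, min(h, w) / 3)
    a <- runif(1, 0.6, 1.4)
    rows <- matrix(seq_len(h), h, w); cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    m <- m | ((rows - cr)^2 / a + (cols - cc)^2 * a <= rr^2)
  }
  m
}

## ---- brute-force oracles (independent of the package implementation) -----

oracle_boundary <- function(mask) {
  pts <- list()
  h <- nrow(mask); w <- ncol(mask)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!mask[r, c]) next
    nb_out <- (r == 1 || !mask[r - 1, c]) || (r == h || !mask[r + 1, c]) ||
      (c == 1 || !mask[r, c - 1]) || (c == w || !mask[r, c + 1])
    if (nb_out) pts[[length(pts) + 1]] <- c(r, c)
  }
  if (!length(pts)) matrix(0, 0, 2) else do.call(rbind, pts)
}

oracle_min_dists <- function(A, B) {
  out <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) {
    best <- Inf
    for (j in seq_len(nrow(B))) {
      d <- sqrt((A[i, 1] - B[j, 1])^2 + (A[i, 2] - B[j, 2])^2)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

oracle_nearest_rank <- function(x, p) sort(x)[ceiling(p * length(x))]

oracle_dsc <- function(pred, gt) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] && gt[i]) tp <- tp + 1
    else if (pred[i]) fp <- fp + 1
    else if (gt[i]) fn <- fn + 1
  }
  if (tp + fp + fn == 0) return(1)
  if (sum(pred) == 0 || sum(gt) == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

oracle_hd95 <- function(pred, gt) {
  A <- oracle_boundary(pred); B <- oracle_boundary(gt)
  if (nrow(A) == 0 && nrow(B) == 0) return(0)
  if (nrow(A) == 0 || nrow(B) == 0)
    return(sqrt(nrow(pred)^2 + ncol(pred)^2))
  max(oracle_nearest_rank(oracle_min_dists(A, B), 0.95),
      oracle_nearest_rank(oracle_min_dists(B, A), 0.95))
}

oracle_asd <- function(pred, gt) {
  A <- oracle_boundary(pred); B <- oracle_boundary(gt)
  if (nrow(A) == 0 && nrow(B) == 0) return(0)
  if (nrow(A) == 0 || nrow(B) == 0)
    return(sqrt(nrow(pred)^2 + ncol(pred)^2))
  mean(oracle_min_dists(A, B))
}
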