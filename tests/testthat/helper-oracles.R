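# Independent reference implementations used to check the package's
# segmentation, morphology and statistics code.  Deliberately written in the
# most literal style available (scalar queues, all-pairs distances,
# exhaustive enumeration) and sharing no code with the implementations under
# test.

# Breadth-first flood fill over in-band voxels, scalar queue.
flood_fill_oracle <- function(inband, seeds, connectivity = "face6") {
  d <- dim(inband)
  offsets <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    m <- abs(dx) + abs(dy) + abs(dz)
    if (m == 0) next
    if (connectivity == "face6" && m != 1) next
    offsets[[length(offsets) + 1]] <- c(dx, dy, dz)
  }
  visited <- array(FALSE, d)
  queue <- lapply(seq_len(nrow(seeds)), function(i) seeds[i, ])
  for (s in queue) if (inband[s[1], s[2], s[3]]) visited[s[1], s[2], s[3]] <- TRUE
  queue <- Filter(function(s) visited[s[1], s[2], s[3]], queue)
  while (length(queue) > 0) {
    p <- queue[[1]]; queue <- queue[-1]
    for (off in offsets) {
      q <- p + off
      if (any(q < 1) || any(q > d)) next
      if (inband[q[1], q[2], q[3]] && !visited[q[1], q[2], q[3]]) {
        visited[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  visited
}

# All-pairs Euclidean distance thresholding.
brute_dilate_oracle <- function(mask, radius) {
  d <- dim(mask)
  src <- which(mask, arr.ind = TRUE)
  out <- array(FALSE, d)
  if (nrow(src) == 0) return(out)
  all_vox <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                   z = seq_len(d[3])))
  for (i in seq_len(nrow(all_vox))) {
    p <- all_vox[i, ]
    d2 <- (src[, 1] - p[1])^2 + (src[, 2] - p[2])^2 + (src[, 3] - p[3])^2
    if (min(d2) <= radius^2 + 1e-9) out[p[1], p[2], p[3]] <- TRUE
  }
  out
}

# City-block (L1) ball dilation, for the iterated-face mode.
brute_l1_dilate_oracle <- function(mask, radius) {
  d <- dim(mask)
  src <- which(mask, arr.ind = TRUE)
  out <- array(FALSE, d)
  if (nrow(src) == 0) return(out)
  all_vox <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                   z = seq_len(d[3])))
  for (i in seq_len(nrow(all_vox))) {
    p <- all_vox[i, ]
    l1 <- abs(src[, 1] - p[1]) + abs(src[, 2] - p[2]) + abs(src[, 3] - p[3])
    if (min(l1) <= radius) out[p[1], p[2], p[3]] <- TRUE
  }
  out
}

# Closed-form Bland-Altman quantities by direct summation.
bland_altman_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  list(mean_difference = m, sd_difference = s,
       lower_limit = m - 2 * s, upper_limit = m + 2 * s)
}

pearson_oracle <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# Midranks by counting, then the Pearson formula on them.
midrank_oracle <- function(x) {
  sapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2)
}

spearman_oracle <- function(x, y) {
  pearson_oracle(midrank_oracle(x), midrank_oracle(y))
}

# Exact two-sided Mann-Whitney p by enumeration over all group assignments.
mann_whitney_exact_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  vals <- c(a, b)
  u_of <- function(idx_a) {
    aa <- vals[idx_a]; bb <- vals[-idx_a]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  }
  u_obs <- u_of(seq_len(na))
  combs <- utils::combn(na + nb, na)
  us <- apply(combs, 2, u_of)
  mu <- na * nb / 2
  # two-sided: assignments at least as extreme (as far from the mean) as observed
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  list(u = u_obs, p = p)
}

# Small noise-free phantom (trachea + one bifurcation) used across shell
# tests; bronchi remain after the trachea exclusion is subtracted.
tube_phantom_spec <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(64, 64, 64), tree_depth = 2, root_radius_voxels = 3,
         noise_sd_hu = 0, include_standards = FALSE),
    list(...))
  do.call(phantom_spec, args)
}

default_pipeline_report <- function(ph, ...) {
  run_pipeline(pipeline_config(
    ph$volume,
    seeds_lumen = matrix(ph$truth$seed_lumen, nrow = 1),
    seeds_lung = matrix(ph$truth$seed_lung, nrow = 1),
    exclusion_mask = ph$truth$trachea_exclusion_mask, ...))
}
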