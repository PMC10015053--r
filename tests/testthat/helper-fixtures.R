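# Shared helpers and independent oracles used across test files.

# brute-force MSD: double loop over all (t, t - tau) pairs
brute_msd <- function(x, y, k) {
  n <- length(x)
  vals <- numeric(0)
  for (t in (k + 1):n)
    vals <- c(vals, (x[t] - x[t - k])^2 + (y[t] - y[t - k])^2)
  sum(vals) / length(vals)
}

# brute-force flood-fill component count (8-connected), recursive stack
flood_count <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  seen <- matrix(FALSE, nr, nc)
  count <- 0
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!bin[r0, c0] || seen[r0, c0]) next
    count <- count + 1
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc && bin[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
    }
  }
  count
}

# independent arc-length summation over polygon vertices
arc_length <- function(p, closed = TRUE) {
  if (closed) p <- rbind(p, p[1, ])
  s <- 0
  for (i in seq_len(nrow(p) - 1))
    s <- s + sqrt(sum((p[i + 1, ] - p[i, ])^2))
  s
}

# adapt synth_polarized_cell output for polarity_map
polar_cells <- function(sim, use_golgi = TRUE) {
  lapply(sim$cells, function(cc) {
    if (use_golgi)
      list(signal = cc$signal, mask = cc$mask, golgi_centroid = cc$golgi_centroid)
    else
      list(signal = cc$signal, mask = cc$mask, theta = cc$front_angle)
  })
}

# grid-placed particles with Gaussian steps: linking fixture with known ids
grid_walk_tracks <- function(n_side = 5, spacing = 10, n_frames = 40,
                             step_sd = 0.2, seed = 1) {
  set.seed(seed)
  starts <- expand.grid(x = (1:n_side) * spacing, y = (1:n_side) * spacing)
  np <- nrow(starts)
  out <- vector("list", np)
  for (i in seq_len(np)) {
    out[[i]] <- data.frame(
      particle_id = i, frame = 0:(n_frames - 1),
      x = starts$x[i] + cumsum(c(0, rnorm(n_frames - 1, 0, step_sd))),
      y = starts$y[i] + cumsum(c(0, rnorm(n_frames - 1, 0, step_sd))))
  }
  do.call(rbind, out)
}

# fraction of consecutive-frame links assigned to the true particle
link_accuracy <- function(truth, linked) {
  # match linked samples back to truth rows by (frame, x, y)
  key <- function(d) paste(d$frame, signif(d$x, 12), signif(d$y, 12))
  truth_id <- truth$particle_id[match(key(linked), key(truth))]
  ok <- 0; tot <- 0
  for (id in unique(linked$particle_id)) {
    sel <- which(linked$particle_id == id)
    if (length(sel) < 2) next
    tids <- truth_id[sel]
    ok <- ok + sum(tids[-1] == tids[-length(tids)])
    tot <- tot + length(sel) - 1
  }
  ok / tot
}
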