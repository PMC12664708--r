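# Fixtures and independent oracles used across the test files.

# quaternion for a rotation of `angle_rad` about unit axis `ax`
quat_about <- function(angle_rad, ax) {
  ax <- ax / sqrt(sum(ax^2))
  c(cos(angle_rad / 2), sin(angle_rad / 2) * ax)
}

# direct 3x3 rotation matrix from a unit quaternion (independent of the
# package's column-one shortcut)
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# a perfectly regular stream with identity-ish orientation
make_regular_stream <- function(id = "navel", n = 270, rate = 90,
                                pos = c(0, 0, 1)) {
  t <- (seq_len(n) - 1) / rate
  tracker_stream(
    data.frame(t = t, px = pos[1] + t, py = pos[2], pz = pos[3],
               qw = 1, qx = 0, qy = 0, qz = 0),
    id, nominal_rate = rate
  )
}

make_simple_session <- function(n = 270, rate = 90) {
  session(list(
    make_regular_stream("left_ankle", n, rate, pos = c(0, 0.06, 0.1)),
    make_regular_stream("right_ankle", n, rate, pos = c(0, -0.06, 0.1)),
    make_regular_stream("navel", n, rate, pos = c(0, 0, 1.0))
  ))
}

zero_noise_profile <- function(condition = "no_wall", seed = 1) {
  prof <- default_profile(condition, seed = seed)
  prof$stride_length_sd <- 0
  prof$stride_time_sd <- 0
  prof$stride_width_sd <- 0
  prof$noise_sd_pos <- 0
  prof$noise_sd_angle <- 0
  prof$dropout_rate <- 0
  prof
}

# exhaustive scan for local extrema of a sampled series (oracle): a
# sample is an extremum when the nearest differing neighbours on both
# sides lie above (minimum) or below (maximum) it
oracle_extrema <- function(x) {
  n <- length(x)
  mins <- maxs <- integer(0)
  for (i in 2:(n - 1)) {
    l <- i - 1
    while (l >= 1 && x[l] == x[i]) l <- l - 1
    r <- i + 1
    while (r <= n && x[r] == x[i]) r <- r + 1
    if (l < 1 || r > n) next
    if (x[l] > x[i] && x[r] > x[i]) mins <- c(mins, i)
    if (x[l] < x[i] && x[r] < x[i]) maxs <- c(maxs, i)
  }
  list(mins = mins, maxs = maxs)
}

# brute-force interval scan for dropout gaps (oracle)
oracle_gaps <- function(t, rate, factor = 3) {
  out <- NULL
  for (i in seq_len(length(t) - 1)) {
    if (t[i + 1] - t[i] > factor / rate) {
      out <- rbind(out, c(t[i] + 1 / rate, t[i + 1]))
    }
  }
  out
}

# independent exhaustive count of simple entry->exit paths in a maze,
# working directly from the open-passage edge list
oracle_count_paths <- function(maze, cap = 2) {
  n <- maze$rows * maze$cols
  adj <- vector("list", n)
  for (k in seq_len(nrow(maze$edges))) {
    a <- maze$edges[k, 1]; b <- maze$edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  start <- (maze$entry[1] - 1L) * maze$cols + maze$entry[2]
  goal <- (maze$exit[1] - 1L) * maze$cols + maze$exit[2]
  count <- 0L
  seen <- logical(n)
  stack <- list(list(node = start, depth = 0L))
  # iterative DFS with explicit path marking
  dfs <- function(node) {
    if (count >= cap) return(invisible(NULL))
    if (node == goal) {
      count <<- count + 1L
      return(invisible(NULL))
    }
    seen[node] <<- TRUE
    for (nb in adj[[node]]) if (!seen[nb]) dfs(nb)
    seen[node] <<- FALSE
    invisible(NULL)
  }
  dfs(start)
  count
}

# brute-force signed mediolateral margin: densely sample the two ML
# border lines of the BoS rectangle and take the minimum distance along
# the ML axis, signed by whether the XCoM lies within the ML extent
oracle_mos_ml <- function(xcom_point, bos, n_samp = 2001) {
  ap <- bos$ap_axis; ml <- bos$ml_axis
  he <- bos$half_extents
  tt <- seq(-he[1], he[1], length.out = n_samp)
  best <- Inf
  for (sgn in c(-1, 1)) {
    border <- t(vapply(tt, function(a) {
      bos$center + a * ap + sgn * he[2] * ml
    }, numeric(2)))
    d <- abs((xcom_point[1] - border[, 1]) * ml[1] +
               (xcom_point[2] - border[, 2]) * ml[2])
    best <- min(best, min(d))
  }
  inside <- abs(sum((xcom_point - bos$center) * ml)) <= he[2]
  if (inside) best else -best
}

# 2-D rotation helper for invariance tests
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# straight corridor maze: the solution path runs along row 1 with
# dead-end stubs into row 2 (spanning tree, unique path, no corners)
corridor_maze <- function(cols = 10, block_size = 0.56) {
  edges <- rbind(
    cbind(seq_len(cols - 1), seq_len(cols - 1) + 1L),     # along row 1
    cbind(seq_len(cols), seq_len(cols) + cols)            # stubs to row 2
  )
  structure(list(
    rows = 2L, cols = as.integer(cols), block_size = block_size,
    entry = c(1L, 1L), exit = c(1L, as.integer(cols)),
    edges = edges, maze_id = sprintf("corridor_%d", cols)
  ), class = "vrgait_maze")
}

# shared small maze set with reasonably long paths (computed once)
test_mazes <- local({
  cache <- NULL
  function(n = 4) {
    if (is.null(cache) || length(cache) < n) {
      cache <<- generate_maze_set(max(n, 4), seed = 2)
    }
    cache[seq_len(n)]
  }
})
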