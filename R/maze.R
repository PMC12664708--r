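#' Grid floor mazes with a unique solution path
#'
#' Mazes live on a rows x cols grid of square blocks (default 7 x 8 blocks
#' of 0.56 m, i.e. 56 blocks). Passages between adjacent blocks follow a
#' spanning tree of the grid graph, so the simple path between any two
#' blocks -- in particular between the entry corner and the exit -- is
#' unique. Cell coordinates are `(row, col)`, 1-based; the centre of cell
#' `(r, c)` is at `((c - 0.5) * block_size, (r - 0.5) * block_size)` in
#' the global horizontal plane.
#'
#' @name maze
NULL

cell_id <- function(r, c, cols) (r - 1L) * cols + c

cell_rc <- function(id, cols) {
  cbind(r = (id - 1L) %/% cols + 1L, c = (id - 1L) %% cols + 1L)
}

#' Centre of grid cells in metres
#' @keywords internal
cell_center <- function(rc, block_size) {
  cbind(x = (rc[, 2] - 0.5) * block_size, y = (rc[, 1] - 0.5) * block_size)
}

grid_neighbors <- function(id, rows, cols) {
  rc <- cell_rc(id, cols)
  r <- rc[, 1]; c <- rc[, 2]
  out <- integer(0)
  if (r > 1L) out <- c(out, cell_id(r - 1L, c, cols))
  if (r < rows) out <- c(out, cell_id(r + 1L, c, cols))
  if (c > 1L) out <- c(out, cell_id(r, c - 1L, cols))
  if (c < cols) out <- c(out, cell_id(r, c + 1L, cols))
  out
}

#' Generate a maze with a unique entry-to-exit path
#'
#' Carves passages with a randomised depth-first search, producing a
#' spanning tree of the grid: every pair of cells is joined by exactly one
#' simple path, which guarantees a unique navigation path from entry to
#' exit. The entry is a grid corner and the exit any other perimeter
#' cell, both chosen by the seed.
#'
#' @param rows,cols grid dimensions (defaults 7 and 8).
#' @param block_size block edge length in metres (default 0.56).
#' @param seed integer seed; identical seeds give identical mazes.
#'
#' @return object of class `vrgait_maze`: a list with `rows`, `cols`,
#'   `block_size`, `entry`, `exit` (cell `(r, c)` integer vectors),
#'   `edges` (two-column matrix of open passages, by cell id) and
#'   `maze_id`.
#' @export
generate_maze <- function(rows = 7, cols = 8, block_size = 0.56, seed = 1) {
  if (rows < 2 || cols < 2) stop("maze requires rows >= 2 and cols >= 2")
  if (block_size <= 0) stop("block_size must be positive")
  rows <- as.integer(rows); cols <- as.integer(cols)
  n <- rows * cols

  with_preserved_seed(seed, {
    corners <- c(cell_id(1L, 1L, cols), cell_id(1L, cols, cols),
                 cell_id(rows, 1L, cols), cell_id(rows, cols, cols))
    entry <- sample(corners, 1L)
    # iterative randomised DFS spanning tree
    visited <- logical(n)
    stack <- entry
    visited[entry] <- TRUE
    edges <- matrix(integer(0), ncol = 2)
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      nb <- grid_neighbors(cur, rows, cols)
      nb <- nb[!visited[nb]]
      if (length(nb) == 0) {
        stack <- stack[-length(stack)]
      } else {
        nxt <- if (length(nb) == 1) nb else sample(nb, 1L)
        visited[nxt] <- TRUE
        edges <- rbind(edges, c(cur, nxt))
        stack <- c(stack, nxt)
      }
    }
    perim <- which(apply(cell_rc(seq_len(n), cols), 1, function(rc) {
      rc[1] %in% c(1L, rows) || rc[2] %in% c(1L, cols)
    }))
    # tree distance (path cell count) from the entry to every cell
    adj <- vector("list", n)
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    dist <- rep(NA_integer_, n)
    dist[entry] <- 1L
    queue <- entry
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (is.na(dist[nb])) {
          dist[nb] <- dist[cur] + 1L
          queue <- c(queue, nb)
        }
      }
    }
    # the exit is a perimeter cell whose path spans the grid
    long_enough <- setdiff(perim[dist[perim] >= max(rows, cols)], entry)
    cand <- if (length(long_enough) > 0) long_enough else
      setdiff(perim, entry)[which.max(dist[setdiff(perim, entry)])]
    exit <- if (length(cand) == 1) cand else sample(cand, 1L)

    dimnames(edges) <- NULL
    structure(
      list(
        rows = rows, cols = cols, block_size = block_size,
        entry = as.integer(cell_rc(entry, cols)[1, ]),
        exit = as.integer(cell_rc(exit, cols)[1, ]),
        edges = edges,
        maze_id = sprintf("maze_%dx%d_s%d", rows, cols, seed)
      ),
      class = "vrgait_maze"
    )
  })
}

#' Run code with a temporary RNG seed, restoring global RNG state after
#' @keywords internal
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' @export
print.vrgait_maze <- function(x, ...) {
  cat(sprintf("<maze> %d x %d blocks of %.2f m | entry (%d,%d) exit (%d,%d)\n",
              x$rows, x$cols, x$block_size,
              x$entry[1], x$entry[2], x$exit[1], x$exit[2]))
  invisible(x)
}

#' Adjacency list of open passages
#' @keywords internal
maze_adjacency <- function(maze) {
  n <- maze$rows * maze$cols
  adj <- vector("list", n)
  for (k in seq_len(nrow(maze$edges))) {
    a <- maze$edges[k, 1]; b <- maze$edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Solution path of a maze
#'
#' Breadth-first search over the open passages from the entry cell to the
#' exit cell. Because passages form a spanning tree this path is the
#' unique simple path between the two.
#'
#' @param maze a `vrgait_maze`.
#' @return tibble with one row per path cell in order: `row`, `col`,
#'   `x`, `y` (cell centre, metres).
#' @export
solution_path <- function(maze) {
  cols <- maze$cols
  start <- cell_id(maze$entry[1], maze$entry[2], cols)
  goal <- cell_id(maze$exit[1], maze$exit[2], cols)
  adj <- maze_adjacency(maze)
  n <- maze$rows * cols
  parent <- rep(NA_integer_, n)
  seen <- logical(n)
  queue <- start; seen[start] <- TRUE
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    if (cur == goal) break
    for (nb in adj[[cur]]) {
      if (!seen[nb]) {
        seen[nb] <- TRUE
        parent[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  if (!seen[goal]) stop("maze has no entry-to-exit path (invalid maze)")
  path <- goal
  while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
  rc <- cell_rc(path, cols)
  xy <- cell_center(rc, maze$block_size)
  tibble::tibble(row = rc[, 1], col = rc[, 2], x = xy[, 1], y = xy[, 2])
}

#' Count simple entry-to-exit paths by exhaustive depth-first enumeration
#'
#' Independent of [solution_path()]; used to verify path uniqueness.
#' Stops early once `cap` paths are found.
#'
#' @param maze a `vrgait_maze`.
#' @param cap stop counting at this many paths (default 2).
#' @return number of distinct simple paths found (at most `cap`).
#' @export
count_simple_paths <- function(maze, cap = 2) {
  cols <- maze$cols
  start <- cell_id(maze$entry[1], maze$entry[2], cols)
  goal <- cell_id(maze$exit[1], maze$exit[2], cols)
  adj <- maze_adjacency(maze)
  n_found <- 0L
  visited <- logical(maze$rows * cols)
  recurse <- function(cur) {
    if (n_found >= cap) return(invisible(NULL))
    if (cur == goal) {
      n_found <<- n_found + 1L
      return(invisible(NULL))
    }
    visited[cur] <<- TRUE
    for (nb in adj[[cur]]) {
      if (!visited[nb]) recurse(nb)
    }
    visited[cur] <<- FALSE
    invisible(NULL)
  }
  recurse(start)
  n_found
}

#' Generate a batch of mazes of equal path length
#'
#' Operationalises "similar complexity" as an identical solution-path
#' cell count across the batch: mazes are drawn from successive seeds and
#' kept when their path length matches `target_len` (default: the path
#' length of the first maze drawn).
#'
#' @param n_mazes number of mazes.
#' @param rows,cols,block_size as in [generate_maze()].
#' @param seed base seed; maze k is drawn from seeds `seed`, `seed+1`, ...
#' @param target_len required solution-path cell count, or `NULL` to use
#'   the first maze's (subject to `min_len`).
#' @param min_len minimum acceptable path cell count when choosing the
#'   target from the first maze (default 20, long enough for several
#'   straight walking bouts).
#' @param max_tries give up after this many candidate seeds.
#' @return list of `vrgait_maze` objects, all with equal path length.
#' @export
generate_maze_set <- function(n_mazes = 4, rows = 7, cols = 8,
                              block_size = 0.56, seed = 1,
                              target_len = NULL, min_len = 20,
                              max_tries = 2000) {
  out <- list()
  s <- seed
  tries <- 0
  while (length(out) < n_mazes && tries < max_tries) {
    m <- generate_maze(rows, cols, block_size, seed = s)
    len <- nrow(solution_path(m))
    if (is.null(target_len) && len >= min_len) target_len <- len
    if (!is.null(target_len) && len == target_len) {
      out[[length(out) + 1]] <- m
    }
    s <- s + 1
    tries <- tries + 1
  }
  if (length(out) < n_mazes) {
    stop("could not assemble ", n_mazes, " mazes of path length ",
         target_len, " within ", max_tries, " seeds")
  }
  out
}

#' Grid cell containing a horizontal point
#' @keywords internal
point_cell <- function(x, y, maze) {
  cbind(
    r = floor(y / maze$block_size) + 1,
    c = floor(x / maze$block_size) + 1
  )
}

#' Maze completion time from the navel trajectory
#'
#' Time from the first navel sample inside the entry cell to the first
#' subsequent navel sample inside the exit cell. The timer endpoints
#' (entry-cell / exit-cell crossings of the navel tracker) are this
#' package's operational definition of completion time.
#'
#' @param session a `vrgait_session`.
#' @param maze the `vrgait_maze` navigated.
#' @return completion time in seconds; `NA` with attribute
#'   `incomplete = TRUE` (and a warning) if the exit cell is never
#'   reached.
#' @export
completion_time <- function(session, maze) {
  nav <- session$streams$navel
  cells <- point_cell(nav$px, nav$py, maze)
  in_entry <- cells[, 1] == maze$entry[1] & cells[, 2] == maze$entry[2]
  in_exit <- cells[, 1] == maze$exit[1] & cells[, 2] == maze$exit[2]
  i0 <- which(in_entry)[1]
  if (is.na(i0)) i0 <- 1L
  i1 <- which(in_exit & seq_along(in_exit) >= i0)[1]
  if (is.na(i1)) {
    warning("trajectory never reaches the exit cell; session incomplete")
    return(structure(NA_real_, incomplete = TRUE))
  }
  nav$t[i1] - nav$t[i0]
}

#' Serialise a maze to JSON
#' @param maze a `vrgait_maze`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_maze <- function(maze, path) {
  obj <- list(
    rows = maze$rows, cols = maze$cols, block_size = maze$block_size,
    entry = maze$entry, exit = maze$exit,
    edges = maze$edges,
    maze_id = maze$maze_id
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a maze from JSON written by [write_maze()]
#' @param path JSON file.
#' @return a `vrgait_maze`.
#' @export
read_maze <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- obj$edges
  if (is.list(edges)) edges <- do.call(rbind, lapply(edges, unlist))
  dimnames(edges) <- NULL
  structure(
    list(
      rows = as.integer(obj$rows), cols = as.integer(obj$cols),
      block_size = obj$block_size,
      entry = as.integer(obj$entry), exit = as.integer(obj$exit),
      edges = matrix(as.integer(edges), ncol = 2),
      maze_id = obj$maze_id
    ),
    class = "vrgait_maze"
  )
}
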