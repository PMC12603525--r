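# Greedy one-to-one point matching shared by detection evaluation and
# object-based colocalization.
#
# Candidate pairs are all (a, b) with Euclidean distance <= max_dist; they are
# visited in ascending distance, ties broken by (a index, b index), and each
# point is used at most once. The result is deterministic for identical input.
greedy_match_points <- function(ax, ay, bx, by, max_dist) {
  na <- length(ax)
  nb <- length(bx)
  empty <- data.frame(a = integer(0), b = integer(0), dist = numeric(0))
  if (na == 0 || nb == 0) return(empty)
  # full pairwise distance matrix; fields in this package hold at most a few
  # thousand puncta per channel so this stays small
  dx <- outer(ax, bx, "-")
  dy <- outer(ay, by, "-")
  d <- sqrt(dx * dx + dy * dy)
  keep <- which(d <= max_dist)
  if (length(keep) == 0) return(empty)
  ai <- ((keep - 1) %% na) + 1
  bi <- ((keep - 1) %/% na) + 1
  dd <- d[keep]
  o <- order(dd, ai, bi)
  ai <- ai[o]; bi <- bi[o]; dd <- dd[o]
  used_a <- logical(na)
  used_b <- logical(nb)
  sel <- logical(length(ai))
  for (k in seq_along(ai)) {
    if (!used_a[ai[k]] && !used_b[bi[k]]) {
      sel[k] <- TRUE
      used_a[ai[k]] <- TRUE
      used_b[bi[k]] <- TRUE
    }
  }
  data.frame(a = ai[sel], b = bi[sel], dist = dd[sel])
}

# Maximum-cardinality one-to-one matching: the greedy ascending-distance
# matching as a warm start, then Kuhn-style augmentation along alternating
# paths until no unmatched A point can reach an unmatched B point through
# feasible edges. The result has provably maximum cardinality among
# one-to-one matchings with all distances <= max_dist, and is deterministic:
# neighbours are explored in (distance, index) order and unmatched A points
# in index order.
match_points_max <- function(ax, ay, bx, by, max_dist) {
  greedy <- greedy_match_points(ax, ay, bx, by, max_dist)
  na <- length(ax)
  nb <- length(bx)
  if (na == 0 || nb == 0) return(greedy)
  dx <- outer(ax, bx, "-")
  dy <- outer(ay, by, "-")
  d <- sqrt(dx * dx + dy * dy)
  feasible <- d <= max_dist
  nbrs <- lapply(seq_len(na), function(a) {
    nb_a <- which(feasible[a, ])
    nb_a[order(d[a, nb_a], nb_a)]
  })
  match_of_b <- rep(NA_integer_, nb)
  match_of_b[greedy$b] <- greedy$a
  match_of_a <- rep(NA_integer_, na)
  match_of_a[greedy$a] <- greedy$b
  # explicit-stack DFS so deep alternating paths cannot overflow
  augment <- function(a0) {
    visited <- rep(FALSE, nb)
    # iterative DFS over alternating paths; stack holds (a, neighbour ptr)
    stack_a <- a0
    stack_ptr <- 1L
    path_b <- integer(0)
    while (length(stack_a) > 0) {
      a <- stack_a[length(stack_a)]
      ptr <- stack_ptr[length(stack_ptr)]
      nb_a <- nbrs[[a]]
      advanced <- FALSE
      while (ptr <= length(nb_a)) {
        b <- nb_a[ptr]
        ptr <- ptr + 1L
        if (visited[b]) next
        visited[b] <- TRUE
        stack_ptr[length(stack_ptr)] <- ptr
        owner <- match_of_b[b]
        if (is.na(owner)) {
          # augment along the stored path
          path_b <- c(path_b, b)
          for (k in rev(seq_along(stack_a))) {
            match_of_b[path_b[k]] <<- stack_a[k]
            match_of_a[stack_a[k]] <<- path_b[k]
          }
          return(TRUE)
        }
        stack_a <- c(stack_a, owner)
        stack_ptr <- c(stack_ptr, 1L)
        path_b <- c(path_b, b)
        advanced <- TRUE
        break
      }
      if (!advanced) {
        if (ptr > length(nb_a)) {
          stack_a <- stack_a[-length(stack_a)]
          stack_ptr <- stack_ptr[-length(stack_ptr)]
          if (length(path_b) > 0) path_b <- path_b[-length(path_b)]
        }
      }
    }
    FALSE
  }
  for (a in seq_len(na)) {
    if (is.na(match_of_a[a])) augment(a)
  }
  a_idx <- which(!is.na(match_of_a))
  b_idx <- match_of_a[a_idx]
  data.frame(a = a_idx, b = b_idx, dist = d[cbind(a_idx, b_idx)])
}

# Coordinate extraction that accepts a puncta_set or a plain data frame with
# x_um / y_um columns.
point_coords <- function(x) {
  if (inherits(x, "puncta_set")) x <- x$puncta
  if (is.data.frame(x)) {
    stopifnot(all(c("x_um", "y_um") %in% names(x)))
    return(data.frame(x_um = x$x_um, y_um = x$y_um))
  }
  stop("expected a puncta_set or a data frame with x_um / y_um columns")
}
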