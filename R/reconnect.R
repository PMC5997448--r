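#' Edges shorter than the critical reconnection length
#'
#' Scans the interior edges of the lateral cells (edges with an endpoint on
#' a cap ring are excluded) and returns those shorter than \code{delta},
#' ascending by length.
#'
#' @param mesh a \code{tube_mesh}.
#' @param delta critical length (default 0.3).
#' @return A data frame with columns \code{v1}, \code{v2}, \code{length}.
#' @export
detect_short_edges <- function(mesh, delta = 0.3) {
  ed <- mesh_edge_table(mesh)
  V <- mesh$vertices
  len <- sqrt(rowSums((V[ed$edges[, 1], , drop = FALSE] -
                         V[ed$edges[, 2], , drop = FALSE])^2))
  keep <- ed$reco_ok & len < delta
  out <- data.frame(v1 = ed$edges[keep, 1], v2 = ed$edges[keep, 2],
                    length = len[keep])
  out[order(out$length), , drop = FALSE]
}

#' T1 neighbor exchange on a short edge
#'
#' Performs the elementary reconnection: the two faces flanking the edge
#' lose it (each keeping one endpoint), the two side faces gain it, and the
#' two vertices are repositioned perpendicular to the old edge within the
#' local tangent plane at its midpoint, separated by \code{1.05 * delta} so
#' the new edge immediately exceeds the critical length. Vertex, edge and
#' face counts are unchanged. The swap is refused (error) when an endpoint
#' lies on a cap ring, when the four involved faces are not distinct, or
#' when a flanking face would drop below 3 sides.
#'
#' @param mesh a \code{tube_mesh}.
#' @param a,b vertex indices of the edge.
#' @param delta critical length used for the post-event separation.
#' @param min_area refuse the swap when any involved face has area below
#'   this (degenerate clusters cannot absorb the repositioned vertices
#'   without tangling).
#' @return A list: \code{mesh} (after the swap), \code{faces_lost} (the two
#'   face indices that lost the edge), \code{faces_gained}.
#' @export
reconnect_edge <- function(mesh, a, b, delta = 0.3, min_area = 0.05) {
  ring <- c(mesh$cap_top, mesh$cap_bottom)
  if (a %in% ring || b %in% ring)
    stop("edge touches a cap ring: reconnection skipped")
  has_a <- vapply(mesh$faces, function(l) a %in% l, logical(1))
  has_b <- vapply(mesh$faces, function(l) b %in% l, logical(1))
  flank <- which(has_a & has_b)
  side_a <- which(has_a & !has_b)
  side_b <- which(has_b & !has_a)
  if (length(flank) != 2L || length(side_a) != 1L || length(side_b) != 1L)
    stop("edge does not have the 4 distinct faces of an interior T1")
  # orient: F1 traverses a -> b, F2 traverses b -> a
  l1 <- mesh$faces[[flank[1]]]
  F1 <- if (l1[match(a, l1) %% length(l1) + 1L] == b) flank[1] else flank[2]
  F2 <- setdiff(flank, F1)
  Fa <- side_a; Fb <- side_b
  if (length(unique(c(F1, F2, Fa, Fb))) != 4L)
    stop("involved faces not distinct")
  if (length(mesh$faces[[F1]]) < 4L || length(mesh$faces[[F2]]) < 4L)
    stop("a flanking face would drop below 3 sides")
  for (f in c(F1, F2, Fa, Fb)) {
    if (polygon_area(mesh, f) < min_area)
      stop("an involved face is degenerate (area < ", min_area,
           "): reconnection skipped")
  }

  loop1 <- mesh$faces[[F1]]; loop2 <- mesh$faces[[F2]]
  loopa <- mesh$faces[[Fa]]; loopb <- mesh$faces[[Fb]]
  nxt <- function(l, v) l[match(v, l) %% length(l) + 1L]
  prv <- function(l, v) l[(match(v, l) - 2L) %% length(l) + 1L]
  x1 <- prv(loop1, a)   # F1: ..., x1, a, b, y1, ...
  y1 <- nxt(loop1, b)
  x2 <- nxt(loop2, a)   # F2: ..., y2, b, a, x2, ...
  y2 <- prv(loop2, b)

  insert_after <- function(l, after, v) append(l, v, after = match(after, l))
  mesh$faces[[F1]] <- setdiff(loop1, b)
  mesh$faces[[F2]] <- setdiff(loop2, a)
  mesh$faces[[Fa]] <- insert_after(loopa, x2, b)  # Fa: ..., x2, b, a, x1, ...
  mesh$faces[[Fb]] <- insert_after(loopb, y1, a)  # Fb: ..., y1, a, b, y2, ...

  # reposition: perpendicular to the old edge in the local tangent plane
  V <- mesh$vertices
  mid <- (V[a, ] + V[b, ]) / 2
  e <- V[b, ] - V[a, ]
  el <- sqrt(sum(e^2))
  e <- if (el > 1e-14) e / el else c(1, 0, 0)
  nrm <- face_normal(V, loop1) + face_normal(V, loop2) +
    face_normal(V, loopa) + face_normal(V, loopb)
  nl <- sqrt(sum(nrm^2))
  nrm <- if (nl > 1e-14) nrm / nl else mid / sqrt(sum(mid[1:2]^2) + 1e-30)
  p <- c(nrm[2] * e[3] - nrm[3] * e[2],
         nrm[3] * e[1] - nrm[1] * e[3],
         nrm[1] * e[2] - nrm[2] * e[1])
  p <- p / sqrt(sum(p^2))
  # a keeps neighbors x1 (F1) and y1 (Fb): place a toward their midpoint
  target <- (V[x1, ] + V[y1, ]) / 2 - mid
  s <- if (sum(target * p) >= 0) 1 else -1
  off <- 1.05 * delta / 2
  mesh$vertices[a, ] <- mid + s * off * p
  mesh$vertices[b, ] <- mid - s * off * p

  list(mesh = mesh, faces_lost = c(F1, F2), faces_gained = c(Fa, Fb))
}

# area-weighted (Newell) normal of a face loop
face_normal <- function(V, loop) {
  v <- V[loop, , drop = FALSE]
  w <- V[c(loop[-1], loop[1]), , drop = FALSE]
  c(sum(v[, 2] * w[, 3] - v[, 3] * w[, 2]),
    sum(v[, 3] * w[, 1] - v[, 1] * w[, 3]),
    sum(v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 2
}

#' Count reconnection (intercalation) events of a run
#'
#' @param traj a \code{trajectory} (or its \code{events} data frame).
#' @param n_cells number of lateral cells used for the frequency.
#' @return A list with \code{n_events} (performed swaps, skipped attempts
#'   excluded) and \code{fraction} (events / cells).
#' @export
count_intercalations <- function(traj, n_cells = NULL) {
  ev <- if (inherits(traj, "trajectory")) traj$events else traj
  if (is.null(n_cells)) {
    if (!inherits(traj, "trajectory"))
      stop("'n_cells' required when passing a bare event table")
    n_cells <- length(traj$mesh$faces)
  }
  n <- if (nrow(ev)) sum(!ev$skipped) else 0L
  list(n_events = n, fraction = n / n_cells)
}
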