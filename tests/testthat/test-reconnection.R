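test_that("short-edge detection matches a brute-force scan", {
  fx <- fixture_60()
  m <- fx$mesh
  # contract one interior edge below the threshold
  ed <- chiratube:::mesh_edge_table(m)
  k <- which(ed$reco_ok)[5]
  a <- ed$edges[k, 1]; b <- ed$edges[k, 2]
  mid <- (m$vertices[a, ] + m$vertices[b, ]) / 2
  dirv <- (m$vertices[b, ] - m$vertices[a, ])
  dirv <- dirv / sqrt(sum(dirv^2))
  m$vertices[a, ] <- mid - 0.05 * dirv
  m$vertices[b, ] <- mid + 0.05 * dirv

  got <- detect_short_edges(m, delta = 0.3)
  # brute force over all unique lateral edges
  V <- m$vertices
  len <- sqrt(rowSums((V[ed$edges[, 1], ] - V[ed$edges[, 2], ])^2))
  want <- which(len < 0.3 & ed$reco_ok)
  expect_setequal(paste(got$v1, got$v2),
                  paste(ed$edges[want, 1], ed$edges[want, 2]))
  expect_true(!is.unsorted(got$length))
  expect_true(paste(a, b) %in% paste(got$v1, got$v2) ||
                paste(b, a) %in% paste(got$v1, got$v2))
})

test_that("all edges at or above delta give an empty detection", {
  fx <- fixture_60()
  ed <- chiratube:::mesh_edge_table(fx$mesh)
  V <- fx$mesh$vertices
  len <- sqrt(rowSums((V[ed$edges[, 1], ] - V[ed$edges[, 2], ])^2))
  tiny <- min(len[ed$reco_ok])
  expect_equal(nrow(detect_short_edges(fx$mesh, delta = tiny * 0.99)), 0L)
})

find_t1_edge <- function(m) {
  ed <- chiratube:::mesh_edge_table(m)
  for (k in which(ed$reco_ok)) {
    a <- ed$edges[k, 1]; b <- ed$edges[k, 2]
    has_a <- vapply(m$faces, function(l) a %in% l, logical(1))
    has_b <- vapply(m$faces, function(l) b %in% l, logical(1))
    flank <- which(has_a & has_b)
    if (length(flank) == 2L && all(lengths(m$faces[flank]) >= 5L) &&
        sum(has_a & !has_b) == 1L && sum(has_b & !has_a) == 1L)
      return(c(a, b))
  }
  stop("no suitable edge")
}

test_that("T1 swaps adjacency and conserves V, E, F", {
  fx <- fixture_60()
  m <- fx$mesh
  e <- find_t1_edge(m)
  count_edges <- function(mm) {
    a <- integer(0); b <- integer(0)
    for (loop in chiratube:::all_faces(mm)) {
      nx <- c(loop[-1], loop[1])
      a <- c(a, pmin(loop, nx)); b <- c(b, pmax(loop, nx))
    }
    sum(!duplicated(paste(a, b)))
  }
  nV <- nrow(m$vertices); nE <- count_edges(m)
  nF <- length(m$faces) + 2L

  sw <- reconnect_edge(m, e[1], e[2], delta = 0.3)
  m1 <- sw$mesh
  expect_silent(validate_tube_mesh(m1))
  expect_equal(nrow(m1$vertices), nV)
  expect_equal(count_edges(m1), nE)
  expect_equal(length(m1$faces) + 2L, nF)

  # the two flanking cells lose the shared edge, the side cells gain it
  F1 <- sw$faces_lost[1]; F2 <- sw$faces_lost[2]
  Fa <- sw$faces_gained[1]; Fb <- sw$faces_gained[2]
  shared <- function(mm, i, j) length(intersect(mm$faces[[i]], mm$faces[[j]]))
  expect_equal(shared(m, F1, F2), 2L)   # before: adjacent
  expect_lt(shared(m1, F1, F2), 2L)     # after: separated
  expect_equal(shared(m1, Fa, Fb), 2L)  # after: joined
  expect_equal(lengths(m1$faces)[c(F1, F2)],
               lengths(m$faces)[c(F1, F2)] - 1L)
  expect_equal(lengths(m1$faces)[c(Fa, Fb)],
               lengths(m$faces)[c(Fa, Fb)] + 1L)

  # repositioned vertices sit 1.05 * delta apart
  newlen <- sqrt(sum((m1$vertices[e[1], ] - m1$vertices[e[2], ])^2))
  expect_equal(newlen, 1.05 * 0.3, tolerance = 1e-12)
})

test_that("applying the swap twice restores the original adjacency", {
  fx <- fixture_60()
  m <- fx$mesh
  e <- find_t1_edge(m)
  sw1 <- reconnect_edge(m, e[1], e[2], delta = 0.3)
  sw2 <- reconnect_edge(sw1$mesh, e[1], e[2], delta = 0.3)
  m2 <- sw2$mesh
  # which cells touch which is restored exactly (the two swapped vertices
  # may exchange labels, which leaves every adjacency unchanged)
  adj0 <- chiratube:::cell_adjacency(m$faces)
  adj2 <- chiratube:::cell_adjacency(m2$faces)
  for (i in seq_along(adj0))
    expect_identical(adj2[[i]], adj0[[i]])
  expect_identical(lengths(m2$faces), lengths(m$faces))
  expect_silent(validate_tube_mesh(m2))
})

test_that("guarded configurations are refused", {
  fx <- fixture_60()
  m <- fx$mesh
  # edge on a cap ring
  ring <- m$cap_top
  loop <- m$faces[[which(vapply(m$faces, function(l) sum(l %in% ring) >= 2,
                                logical(1)))[1]]]
  rv <- loop[loop %in% ring][1:2]
  expect_error(reconnect_edge(m, rv[1], rv[2]), "cap ring")
  # not an edge at all (two far-apart interior vertices)
  interior <- setdiff(seq_len(nrow(m$vertices)),
                      c(m$cap_top, m$cap_bottom))
  far <- interior[order(m$vertices[interior, 3])]
  far <- c(far[1], far[length(far)])
  expect_error(reconnect_edge(m, far[1], far[2]), "4 distinct faces")
})

test_that("intercalation counting summarizes the event log", {
  fx <- fixture_60()
  tr0 <- run_dynamics(fx$mesh, fx$params, t_end = 0.05, reconnect = FALSE)
  expect_equal(count_intercalations(tr0)$n_events, 0L)
  expect_equal(count_intercalations(tr0)$fraction, 0)
  fake <- data.frame(t = c(1, 2, 3), skipped = c(FALSE, FALSE, TRUE))
  got <- count_intercalations(fake, n_cells = 452)
  expect_equal(got$n_events, 2L)
  expect_equal(got$fraction, 2 / 452)
})
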