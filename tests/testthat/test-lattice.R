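test_that("the FCC lattice has 12 equal-norm neighbour directions", {
  d <- neighborDirections()
  expect_equal(nrow(d), 12L)
  expect_true(all(rowSums(d^2) == 2L))
  ## closed under negation: 6 antipodal pairs
  for (k in seq_len(12L))
    expect_true(any(colSums(t(d) == -d[k, ]) == 3L))
  ## angle spectrum relative to any fixed direction: 60 x4, 90 x2,
  ## 120 x4, 180 x1
  for (k in seq_len(12L)) {
    angles <- vapply(seq_len(12L), function(j)
      angleBetween(d[k, ], d[j, ]), 1)
    expect_equal(as.integer(table(angles)),
                 c(1L, 4L, 2L, 4L, 1L))  # 0, 60, 90, 120, 180
  }
})

test_that("angles come from exact integer dot products", {
  expect_equal(angleBetween(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(angleBetween(c(1, 1, 0), c(1, 0, 1)), 60)
  expect_equal(angleBetween(c(1, 1, 0), c(-1, -1, 0)), 180)
  expect_equal(angleBetween(c(1, 1, 0), c(1, -1, 0)), 90)
})

test_that("strategy sets depend on player type and frozen state", {
  inc <- c(1L, 1L, 0L)
  ## frozen large helix: only the incoming direction
  frozenSet <- allowedDirections("HELIX", largeHelix = TRUE,
                                 frozen = TRUE, incoming = inc)
  expect_equal(nrow(frozenSet), 1L)
  expect_equal(as.integer(frozenSet), inc)
  ## small helix: the 0-degree continuation plus the four 60-degree bends
  smallSet <- allowedDirections("HELIX", incoming = inc)
  expect_equal(nrow(smallSet), 5L)
  angs <- apply(smallSet, 1L, angleBetween, d2 = inc)
  expect_equal(sort(as.integer(table(angs))), c(1L, 4L))
  ## three-way branch: all 12, whatever the incoming direction
  expect_equal(nrow(allowedDirections("THREE_WAY_BRANCH",
                                      incoming = inc)), 12L)
  ## root (no incoming): all 12 for every type
  expect_equal(nrow(allowedDirections("HELIX")), 12L)
  ## small two-way junctions bend like helices
  expect_equal(nrow(allowedDirections("TWO_WAY", smallTwoWay = TRUE,
                                      incoming = inc)), 5L)
  expect_equal(nrow(allowedDirections("TWO_WAY", incoming = inc)), 12L)
  expect_error(allowedDirections("NOT_A_TYPE"), "unknown")
})

test_that("exact segment intersection matches simple cases", {
  ## collinear overlapping
  expect_true(edgesIntersect(c(0, 0, 0), c(2, 2, 0),
                             c(1, 1, 0), c(3, 3, 0)))
  ## far apart
  expect_false(edgesIntersect(c(0, 0, 0), c(1, 1, 0),
                              c(5, 5, 5), c(6, 6, 5)))
  ## length-2 segments crossing at a shared midpoint lattice site
  expect_true(edgesIntersect(c(0, 0, 0), c(2, 2, 0),
                             c(2, 0, 0), c(0, 2, 0)))
  ## sharing only a common endpoint does not count
  expect_false(edgesIntersect(c(0, 0, 0), c(1, 1, 0),
                              c(1, 1, 0), c(2, 2, 0)))
  ## but doubling back along the same line does
  expect_true(edgesIntersect(c(0, 0, 0), c(2, 2, 0),
                             c(2, 2, 0), c(1, 1, 0)))
})

test_that("segment intersection agrees with a distance oracle", {
  set.seed(42)
  d <- neighborDirections()
  n <- 0L
  while (n < 2000L) {
    p1 <- as.integer(2 * sample(-3:3, 3L, TRUE))
    len1 <- sample(1:2, 1L); len2 <- sample(1:2, 1L)
    p2 <- p1 + len1 * d[sample.int(12L, 1L), ]
    p3 <- as.integer(2 * sample(-3:3, 3L, TRUE))
    p4 <- p3 + len2 * d[sample.int(12L, 1L), ]
    ## skip pairs sharing an endpoint: the exact test treats those
    ## specially and the distance oracle cannot distinguish them
    if (identical(p1, p3) || identical(p1, p4) ||
        identical(p2, p3) || identical(p2, p4)) next
    n <- n + 1L
    dist <- oracleSegmentDistance(p1, p2, p3, p4)
    expect_equal(edgesIntersect(p1, p2, p3, p4), dist < 1e-9,
                 info = paste(c(p1, p2, p3, p4), collapse = ","))
  }
})

test_that("legal actions exclude collisions and crossings", {
  g <- hairpinGraph()
  conf <- randomEmbedding(g, seed = 1)
  ## 2-player graph on an empty lattice: every allowed direction legal
  acts <- legalActions(conf, playerOrdering(g)[1L])
  expect_equal(nrow(acts), 12L)

  g3 <- threeWayGraph()
  for (s in 1:25) {
    conf <- randomEmbedding(g3, seed = s)
    for (p in playerOrdering(g3)) {
      info <- rnagame:::.treeInfo(g3)
      for (ch in info$children[[p]]) {
        acts <- legalActions(conf, p, ch)
        if (!nrow(acts)) next
        for (k in seq_len(nrow(acts))) {
          nc <- applyAction(conf, p, acts[k, ], child = ch)
          expect_true(oracleSelfAvoiding(positions(nc), edges(g3)))
        }
      }
    }
  }
})

test_that("occupied targets are removed from the legal set", {
  g3 <- threeWayGraph()
  conf <- randomEmbedding(g3, seed = 3)
  info <- rnagame:::.treeInfo(g3)
  ## for every player-edge, directions leading onto an occupied site
  ## are not in the legal set
  for (p in playerOrdering(g3)) {
    for (ch in info$children[[p]]) {
      acts <- legalActions(conf, p, ch)
      len <- info$elen[p, ch]
      if (!nrow(acts)) next
      for (k in seq_len(nrow(acts))) {
        target <- positions(conf)[p, ] + len * acts[k, ]
        occupied <- apply(positions(conf)[-ch, , drop = FALSE], 1L,
                          function(r) all(r == target))
        expect_false(any(occupied))
      }
    }
  }
})

test_that("applying an action translates the subtree rigidly", {
  g3 <- threeWayGraph()
  conf <- randomEmbedding(g3, seed = 5)
  info <- rnagame:::.treeInfo(g3)
  root <- playerOrdering(g3)[1L]
  ch <- info$children[[root]][1L]
  ## re-applying the current direction is a no-op
  len <- info$elen[root, ch]
  cur <- (positions(conf)[ch, ] - positions(conf)[root, ]) / len
  same <- applyAction(conf, root, cur, child = ch)
  expect_identical(positions(same), positions(conf))
  ## a different legal action: child at pos + len*d, subtree distances kept
  acts <- legalActions(conf, root, ch)
  d <- acts[nrow(acts), ]
  moved <- applyAction(conf, root, d, child = ch)
  expect_equal(positions(moved)[ch, ],
               positions(conf)[root, ] + len * d)
  sub <- info$subtree[[ch]]
  before <- dist(positions(conf)[sub, , drop = FALSE])
  after <- dist(positions(moved)[sub, , drop = FALSE])
  expect_equal(as.numeric(after), as.numeric(before))
  ## players outside the subtree did not move
  out <- setdiff(seq_len(nrow(players(g3))), sub)
  expect_identical(positions(moved)[out, ], positions(conf)[out, ])
  ## illegal directions are rejected
  illegal <- setdiff(seq_len(12L), rnagame:::.armIndex(acts))
  if (length(illegal)) {
    dbad <- neighborDirections()[illegal[1L], ]
    expect_error(applyAction(conf, root, dbad, child = ch), "rejected")
  }
})

test_that("two-player embeddings use all 12 directions uniformly", {
  g <- hairpinGraph()
  dirs <- matrix(NA_integer_, 3000L, 3L)
  for (s in seq_len(nrow(dirs))) {
    conf <- randomEmbedding(g, seed = s)
    dirs[s, ] <- (positions(conf)[2L, ] - positions(conf)[1L, ]) / 2L
  }
  counts <- table(apply(dirs, 1L, paste, collapse = ","))
  expect_equal(length(counts), 12L)
  ## multinomial: each count within 3 sigma of n/12
  n <- nrow(dirs)
  expect_true(all(abs(counts - n / 12) <=
                    3 * sqrt(n * (1 / 12) * (11 / 12))))
})

test_that("random embeddings are deterministic and self-avoiding", {
  g3 <- threeWayGraph()
  expect_identical(positions(randomEmbedding(g3, seed = 99)),
                   positions(randomEmbedding(g3, seed = 99)))
  for (s in 1:200) {
    conf <- randomEmbedding(g3, seed = s)
    expect_true(oracleSelfAvoiding(positions(conf), edges(g3)))
  }
})

test_that("Cartesian scaling puts lattice steps at the grid step", {
  g3 <- threeWayGraph()
  conf <- randomEmbedding(g3, seed = 2)
  xyz <- toCartesian(conf)
  e <- edges(g3)
  for (k in seq_len(nrow(e))) {
    dd <- sqrt(sum((xyz[e[k, 1L], ] - xyz[e[k, 2L], ])^2))
    expect_equal(dd, 5.6 * unname(e[k, 3L]), tolerance = 1e-12)
  }
  ## the origin maps to the origin
  expect_equal(xyz[playerOrdering(g3)[1L], ], c(0, 0, 0))
})

test_that("random legal action sequences preserve all invariants", {
  set.seed(7)
  g3 <- threeWayGraph()
  conf <- randomEmbedding(g3, seed = 1)
  info <- rnagame:::.treeInfo(g3)
  owners <- unique(edges(g3)[, 1L])
  for (i in 1:300) {
    p <- sample(players(g3)$id, 1L)
    kids <- info$children[[p]]
    if (!length(kids)) next
    ch <- kids[sample.int(length(kids), 1L)]
    acts <- legalActions(conf, p, ch)
    if (!nrow(acts)) next
    conf <- applyAction(conf, p, acts[sample.int(nrow(acts), 1L), ],
                        child = ch)
    expect_true(validObject(conf))
  }
  expect_true(oracleSelfAvoiding(positions(conf), edges(g3)))
})
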