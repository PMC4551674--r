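#' The 12 nearest-neighbour directions of the FCC lattice
#'
#' The "3D triangular" (face-centred cubic) lattice is realized as the
#' even-coordinate-sum sublattice of Z^3; its 12 nearest-neighbour
#' vectors are the signed permutations of (1, 1, 0), all of squared norm
#' 2, returned in a fixed lexicographic order.
#'
#' @return integer matrix with 12 rows (directions) and 3 columns
#' @export
neighborDirections <- function() {
  cached <- .pkgCache$dirs
  if (!is.null(cached)) return(cached)
  d <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  d <- d[rowSums(d^2) == 2L, , drop = FALSE]
  d <- d[order(d[, 1L], d[, 2L], d[, 3L]), , drop = FALSE]
  dimnames(d) <- NULL
  storage.mode(d) <- "integer"
  .pkgCache$dirs <- d
  d
}

## canonical arm index (1..12) of each row of a direction matrix
.armIndex <- function(m) {
  lut <- .pkgCache$dirLut
  if (is.null(lut)) {
    d <- neighborDirections()
    lut <- integer(64L)
    lut[(d[, 1L] + 1L) * 16L + (d[, 2L] + 1L) * 4L + d[, 3L] + 2L] <-
      seq_len(12L)
    .pkgCache$dirLut <- lut
  }
  lut[(m[, 1L] + 1L) * 16L + (m[, 2L] + 1L) * 4L + m[, 3L] + 2L]
}

#' Angle between two FCC directions, in degrees
#'
#' Computed from the exact integer dot product; the only possible values
#' on this lattice are 0, 60, 90, 120 and 180 degrees.
#'
#' @param d1,d2 integer direction vectors (length 3, squared norm 2)
#' @return the angle in degrees
#' @export
angleBetween <- function(d1, d2) {
  dp <- sum(as.integer(d1) * as.integer(d2))  # in {-2,-1,0,1,2}
  switch(as.character(dp),
         "2" = 0, "1" = 60, "0" = 90, "-1" = 120, "-2" = 180,
         stop("not FCC nearest-neighbour directions"))
}

#' Strategy set of a player type
#'
#' Returns the directions a player may give to its outgoing edge, as a
#' subset of the 12 FCC directions. Helix players keep their orientation
#' or bend by at most 60 degrees (5 directions); a frozen large-helix
#' player may only continue straight; small two-way junctions (one
#' unpaired side shorter than two nucleotides) behave like helices;
#' all other junction players, and any player without an incoming edge
#' (the root), may use all 12 directions.
#'
#' @param ptype player type string
#' @param largeHelix is the player part of a helix with more than 5 bp
#' @param smallTwoWay is the player a small two-way junction
#' @param frozen frozen flag of the player
#' @param incoming integer direction of the edge into the player, or
#'   NULL for the root
#' @return integer matrix of allowed directions (rows)
#' @export
allowedDirections <- function(ptype, largeHelix = FALSE,
                              smallTwoWay = FALSE, frozen = FALSE,
                              incoming = NULL) {
  if (!ptype %in% .PLAYER_TYPES) stop("unknown player type: ", ptype)
  dirs <- neighborDirections()
  if (is.null(incoming)) return(dirs)
  incoming <- as.integer(incoming)
  if (ptype == "HELIX" && largeHelix && frozen)
    return(matrix(incoming, nrow = 1L))
  if (ptype == "HELIX" || (ptype == "TWO_WAY" && smallTwoWay)) {
    dp <- dirs %*% incoming
    return(dirs[dp >= 1L, , drop = FALSE])   # 0 or 60 degrees: dot 2 or 1
  }
  dirs
}

## allowed directions for a specific player row, given incoming direction
.allowedForPlayer <- function(players, id, incoming) {
  allowedDirections(players$ptype[id], players$largeHelix[id],
                    players$smallTwoWay[id], players$frozen[id], incoming)
}

#' Do two straight lattice segments intersect?
#'
#' Exact integer test on the closed segments p1-p2 and p3-p4. Segments
#' sharing only a single common endpoint (as two tree edges at a common
#' node do) are not counted as intersecting.
#'
#' @param p1,p2,p3,p4 integer coordinate triples
#' @return TRUE if the segments share any other point
#' @export
edgesIntersect <- function(p1, p2, p3, p4) {
  cppSegmentsIntersect(as.integer(p1), as.integer(p2),
                       as.integer(p3), as.integer(p4))
}

## "" -> NULL, otherwise the violation message
conformationViolation <- function(pos, edges) {
  storage.mode(pos) <- "integer"
  storage.mode(edges) <- "integer"
  msg <- cppConformationViolation(pos, edges)
  if (nzchar(msg)) msg else NULL
}

#' Is a set of positions a valid conformation of a graph?
#'
#' Checks all embedding invariants: integer FCC positions, distinct
#' players, straight edges of the stated lengths, no edge crossing an
#' occupied site or another edge.
#'
#' @param pos integer position matrix
#' @param graph an [RNAGraph-class]
#' @return TRUE, or the first violation message
#' @export
checkEmbedding <- function(pos, graph) {
  v <- conformationViolation(pos, graph@edges)
  if (is.null(v)) TRUE else v
}

## rooted tree structure in DFS order: for each player its DFS parent,
## the incoming edge length, and the subtree below it (inclusive)
.treeInfo <- function(graph) {
  ord <- graph@ordering
  np <- nrow(graph@players)
  adj <- .adjList(graph)
  elen <- matrix(0L, np, np)
  e <- graph@edges
  for (k in seq_len(nrow(e))) {
    elen[e[k, 1L], e[k, 2L]] <- e[k, 3L]
    elen[e[k, 2L], e[k, 1L]] <- e[k, 3L]
  }
  parent <- rep(0L, np)
  seen <- rep(FALSE, np)
  for (v in ord) {
    seen[v] <- TRUE
    for (w in adj[[v]]) if (!seen[w]) parent[w] <- v
  }
  subtree <- vector("list", np)
  for (v in rev(ord)) {
    s <- v
    for (w in adj[[v]]) if (parent[w] == v) s <- c(s, subtree[[w]])
    subtree[[v]] <- s
  }
  children <- lapply(seq_len(np), function(v)
    ord[ord %in% adj[[v]] & parent[ord] == v])
  list(parent = parent, elen = elen, subtree = subtree,
       children = children, root = ord[1L])
}

#' Legal actions of a player-edge in a conformation
#'
#' The strategy set of the player, restricted to directions whose
#' application (re-placing the child along the outgoing edge and rigidly
#' translating its subtree) causes no position collision and no edge
#' intersection.
#'
#' @param conf a [Conformation-class]
#' @param player player id (owner of the outgoing edge)
#' @param child the child player placed by the action; defaults to the
#'   player's first child in DFS order
#' @return integer matrix of legal directions (possibly 0 rows)
#' @export
legalActions <- function(conf, player, child = NULL) {
  info <- attr(conf@positions, "treeInfo")
  if (is.null(info)) info <- .treeInfo(conf@graph)
  if (is.null(child)) {
    kids <- info$children[[player]]
    if (!length(kids)) stop("player ", player, " has no outgoing edge")
    child <- kids[1L]
  }
  allowed <- .playerAllowed(conf@graph, info, conf@positions, player)
  len <- info$elen[player, child]
  keep <- cppLegalDirs(conf@positions, conf@graph@edges,
                       player, child, len,
                       as.integer(info$subtree[[child]]), allowed)
  allowed[keep, , drop = FALSE]
}

## strategy set of a player given current incoming edge direction
.playerAllowed <- function(graph, info, pos, player) {
  par <- info$parent[player]
  incoming <- NULL
  if (par != 0L) {
    len <- info$elen[par, player]
    incoming <- as.integer((pos[player, ] - pos[par, ]) / len)
  }
  .allowedForPlayer(graph@players, player, incoming)
}

#' Apply a direction to a player's outgoing edge
#'
#' The child is re-placed at pos(player) + edge_length * d and the whole
#' subtree below it is rigidly translated by the child's displacement.
#'
#' @param conf a [Conformation-class]
#' @param player acting player id
#' @param d integer direction (must be legal)
#' @param child the child placed by the action (default: first child)
#' @param check validate legality before applying
#' @return the new [Conformation-class]
#' @export
applyAction <- function(conf, player, d, child = NULL, check = TRUE) {
  info <- .treeInfo(conf@graph)
  if (is.null(child)) {
    kids <- info$children[[player]]
    if (!length(kids)) stop("player ", player, " has no outgoing edge")
    child <- kids[1L]
  }
  pos <- .applyActionPos(conf@positions, info, player, child, as.integer(d))
  if (check) {
    v <- conformationViolation(pos, conf@graph@edges)
    if (!is.null(v)) stop("rejected action: ", v)
  }
  new("Conformation", positions = pos, graph = conf@graph,
      step = conf@step)
}

## positions-only version used in the game loop (no validation)
.applyActionPos <- function(pos, info, player, child, d) {
  len <- info$elen[player, child]
  newChild <- pos[player, ] + len * d
  delta <- newChild - pos[child, ]
  sub <- info$subtree[[child]]
  pos[sub, ] <- sweep(pos[sub, , drop = FALSE], 2L, delta, "+")
  pos
}

#' Random self-avoiding embedding of a graph on the FCC lattice
#'
#' Places the root at the origin and the remaining players in DFS order,
#' choosing uniformly among the legal directions of each edge; dead ends
#' trigger a restart (up to `maxRestarts`). Deterministic given the seed.
#'
#' @param graph an [RNAGraph-class]
#' @param seed integer seed, or NULL to use the current RNG state
#' @param step lattice unit in Angstrom
#' @param maxRestarts restart budget before failing
#' @return a [Conformation-class]
#' @export
randomEmbedding <- function(graph, seed = NULL, step = 5.6,
                            maxRestarts = 1000L) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  info <- .treeInfo(graph)
  np <- nrow(graph@players)
  edgesSoFar <- function(placed) {
    e <- graph@edges
    e[e[, 1L] %in% placed & e[, 2L] %in% placed, , drop = FALSE]
  }
  for (restart in seq_len(maxRestarts)) {
    pos <- matrix(0L, np, 3L)
    placed <- info$root
    ok <- TRUE
    for (v in graph@ordering[-1L]) {
      par <- info$parent[v]
      allowed <- .playerAllowed(graph, info, pos, par)
      ## legality against already-placed part only
      pe <- edgesSoFar(c(placed, v))
      len <- info$elen[par, v]
      cand <- integer(0)
      for (k in seq_len(nrow(allowed))) {
        trial <- pos
        trial[v, ] <- pos[par, ] + len * allowed[k, ]
        sel <- c(placed, v)
        if (is.null(conformationViolation(trial[sel, , drop = FALSE],
                                          .reindexEdges(pe, sel))))
          cand <- c(cand, k)
      }
      if (!length(cand)) { ok <- FALSE; break }
      k <- if (length(cand) == 1L) cand else
        cand[sample.int(length(cand), 1L)]
      pos[v, ] <- pos[par, ] + len * allowed[k, ]
      placed <- c(placed, v)
    }
    if (ok) {
      conf <- new("Conformation", positions = pos, graph = graph,
                  step = step)
      validObject(conf)
      return(conf)
    }
  }
  stop("embedding failure: no self-avoiding embedding after ",
       maxRestarts, " restarts")
}

## re-number edge endpoint ids after subsetting players to `sel`
.reindexEdges <- function(e, sel) {
  if (!nrow(e)) return(e)
  map <- match(seq_len(max(sel)), sel)
  e[, 1L] <- map[e[, 1L]]
  e[, 2L] <- map[e[, 2L]]
  e
}

## incoming edge direction of a player in the rooted tree, or NULL (root)
.incomingDir <- function(pos, info, player) {
  par <- info$parent[player]
  if (par == 0L) return(NULL)
  len <- info$elen[par, player]
  as.integer((pos[player, ] - pos[par, ]) / len)
}

#' Cartesian coordinates of a conformation, in Angstrom
#'
#' Integer lattice coordinates are scaled so one nearest-neighbour step
#' (norm sqrt(2) in the integer basis) equals `step` Angstrom; with the
#' default 5.6 A step, players joined by a length-1 edge (same junction)
#' are 5.6 A apart and length-2 edges span 11.2 A.
#'
#' @param conf a [Conformation-class]
#' @return numeric matrix of player coordinates in Angstrom
#' @export
toCartesian <- function(conf) {
  conf@positions * (conf@step / sqrt(2))
}
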