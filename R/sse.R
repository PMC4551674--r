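#' Decompose a secondary structure into secondary-structure elements
#'
#' Helices are maximal runs of stacked base pairs; every loop region
#' (the unpaired nucleotides enclosed by a helix plus the closing base
#' pairs of all incident helices) becomes one junction element whose
#' kind is given by the number of incident helices: terminal loop
#' (one-way), bulge/internal loop (two-way), three-way or four-way
#' junction.
#'
#' The molecule must have paired 5'-3' ends: top-level unpaired
#' nucleotides or more than one top-level helix are rejected, as is any
#' junction of degree greater than four.
#'
#' @param ss a [SecondaryStructure-class]
#' @return a list of SSE descriptors (kind, nucleotides, and for
#'   helices the base-pair matrix; for junctions the incident helices
#'   and connecting strands)
#' @export
decomposeSSEs <- function(ss) {
  validObject(ss)
  n <- nchar(ss@sequence)
  partner <- .partners(ss)
  if (!nrow(ss@pairs))
    stop("unsupported structure: no base pairs (no helix to anchor the graph)")

  ## top level must be exactly one helix, no unpaired exterior nucleotides
  k <- 1L; topHelices <- 0L
  while (k <= n) {
    if (is.na(partner[k]))
      stop("unsupported structure: unpaired exterior nucleotide at ", k)
    topHelices <- topHelices + 1L
    k <- partner[k] + 1L
  }
  if (topHelices != 1L)
    stop("unsupported structure: ", topHelices,
         " top-level helices (one rooted helix required)")

  ## helices: maximal stacks of pairs
  pr <- ss@pairs
  helixOf <- rep(NA_integer_, n)
  helices <- list()
  for (r in seq_len(nrow(pr))) {
    i <- pr[r, 1L]; j <- pr[r, 2L]
    if (i > 1L && !is.na(partner[i - 1L]) && partner[i - 1L] == j + 1L) {
      h <- helixOf[i - 1L]           # continues the previous stack
    } else {
      helices[[length(helices) + 1L]] <- list(bp = NULL)
      h <- length(helices)
    }
    helices[[h]]$bp <- rbind(helices[[h]]$bp, c(i, j))
    helixOf[i] <- h; helixOf[j] <- h
  }

  sses <- list()
  helixSSE <- integer(length(helices))   # helix number -> SSE index
  for (h in seq_along(helices)) {
    bp <- helices[[h]]$bp
    sses[[length(sses) + 1L]] <- list(
      kind = "HELIX", bp = bp, nBp = nrow(bp),
      nucleotides = sort(c(bp[, 1L], bp[, 2L])))
    helixSSE[h] <- length(sses)
  }

  ## loops: walk the region enclosed by each helix's innermost pair
  for (h in seq_along(helices)) {
    bp <- helices[[h]]$bp
    a <- bp[nrow(bp), 1L]; b <- bp[nrow(bp), 2L]
    innerHelices <- integer(0)
    strands <- list(integer(0))
    k <- a + 1L
    while (k < b) {
      if (is.na(partner[k])) {
        strands[[length(strands)]] <- c(strands[[length(strands)]], k)
        k <- k + 1L
      } else {
        innerHelices <- c(innerHelices, helixOf[k])
        strands[[length(strands) + 1L]] <- integer(0)
        k <- partner[k] + 1L
      }
    }
    degree <- 1L + length(innerHelices)
    if (degree > 4L)
      stop("unsupported structure: junction of degree ", degree)
    kind <- c("ONE_WAY", "TWO_WAY", "THREE_WAY", "FOUR_WAY")[degree]
    closing <- c(a, b)
    for (ih in innerHelices) {
      obp <- helices[[ih]]$bp[1L, ]
      closing <- c(closing, obp)
    }
    nts <- sort(unique(c(unlist(strands), closing)))
    sses[[length(sses) + 1L]] <- list(
      kind = kind,
      nucleotides = nts,
      helices = c(helixSSE[h], helixSSE[innerHelices]),
      strands = strands,
      degree = degree)
  }
  ## order SSEs by first nucleotide for stable, readable ids, remapping
  ## the helix references held by junction SSEs
  ord <- order(vapply(sses, function(s) min(s$nucleotides), 1L))
  inv <- integer(length(sses))
  inv[ord] <- seq_along(sses)
  sses <- sses[ord]
  for (k in seq_along(sses))
    if (!is.null(sses[[k]]$helices))
      sses[[k]]$helices <- inv[sses[[k]]$helices]
  sses
}

## junction-side closing base pair of a helix SSE, as seen from a junction:
## the innermost pair if the helix closes the junction (outer helix),
## the outermost pair if the helix opens into it (inner helix)
.helixClosingPair <- function(sse, outer) {
  bp <- sse$bp
  if (outer) bp[nrow(bp), ] else bp[1L, ]
}

## choose the stacked helix pair at a three-way junction: the two
## helices (adjacent around the loop) whose connecting strand is shortest
.stackedPair <- function(sse, hint = NULL) {
  hs <- sse$helices                       # outer, inner1, inner2
  if (!is.null(hint)) {
    stopifnot(length(hint) == 2L, all(hint %in% hs))
    return(as.integer(hint))
  }
  lens <- vapply(sse$strands, length, 1L) # s1, s2, s3
  adjacent <- list(c(hs[1L], hs[2L]), c(hs[2L], hs[3L]), c(hs[3L], hs[1L]))
  adjacent[[which.min(lens)]]
}

#' Build the players of the coarse-grained game from SSEs
#'
#' A helix of b base pairs becomes ceiling(b/5) players (at most five
#' base pairs each); terminal loops, bulges and two-way junctions one
#' player; a three-way junction a STACK player (for the two coaxially
#' stacked helices) plus a BRANCH player; a four-way junction five
#' players (two stack/branch pairs joined by a LINKER).
#'
#' @param sses SSE list from [decomposeSSEs()]
#' @param stackingHint optional list mapping a junction SSE index to the
#'   two helix SSE indices that stack coaxially; when absent the two
#'   helices with the shortest connecting strand are stacked
#' @param frozen set the frozen flag on players of helices with more
#'   than five base pairs
#' @return data.frame of players (one row each) with a nucleotides list
#'   column; attribute "helixPlayers" maps helix SSE index to its player
#'   ids (outer to inner)
#' @export
buildPlayers <- function(sses, stackingHint = NULL, frozen = FALSE) {
  rows <- list()
  helixPlayers <- list()    # sse index (character) -> player ids
  junctionPlayers <- list() # sse index -> named list of player ids
  addPlayer <- function(ptype, sse, nBp, largeHelix, smallTwoWay,
                        frz, nts) {
    rows[[length(rows) + 1L]] <<- list(
      id = length(rows) + 1L, ptype = ptype, sse = sse,
      kind = sses[[sse]]$kind, nBp = nBp, largeHelix = largeHelix,
      smallTwoWay = smallTwoWay, frozen = frz,
      nt5 = min(nts), nucleotides = list(as.integer(nts)))
    length(rows)
  }
  for (s in seq_along(sses)) {
    sse <- sses[[s]]
    if (sse$kind == "HELIX") {
      b <- sse$nBp
      k <- ceiling(b / 5)
      sizes <- rep(b %/% k, k)
      if (b %% k) sizes[seq_len(b %% k)] <- sizes[seq_len(b %% k)] + 1L
      large <- b > 5L
      start <- 1L
      ids <- integer(0)
      for (ck in seq_len(k)) {
        bp <- sse$bp[start:(start + sizes[ck] - 1L), , drop = FALSE]
        ids <- c(ids, addPlayer("HELIX", s, nrow(bp), large,
                                FALSE, frozen && large,
                                c(bp[, 1L], bp[, 2L])))
        start <- start + sizes[ck]
      }
      helixPlayers[[as.character(s)]] <- ids
    } else if (sse$kind == "ONE_WAY") {
      id <- addPlayer("ONE_WAY", s, NA_integer_, FALSE, FALSE, FALSE,
                      sse$nucleotides)
      junctionPlayers[[as.character(s)]] <- list(loop = id)
    } else if (sse$kind == "TWO_WAY") {
      sideLens <- vapply(sse$strands, length, 1L)
      small <- min(sideLens) < 2L
      id <- addPlayer("TWO_WAY", s, NA_integer_, FALSE, small, FALSE,
                      sse$nucleotides)
      junctionPlayers[[as.character(s)]] <- list(loop = id)
    } else if (sse$kind == "THREE_WAY") {
      stacked <- .stackedPair(sse, stackingHint[[as.character(s)]])
      stackNts <- unlist(lapply(stacked, function(h)
        .helixClosingPair(sses[[h]], outer = h == sse$helices[1L])))
      sid <- addPlayer("THREE_WAY_STACK", s, NA_integer_, FALSE, FALSE,
                       FALSE, stackNts)
      bid <- addPlayer("THREE_WAY_BRANCH", s, NA_integer_, FALSE, FALSE,
                       FALSE, sse$nucleotides)
      junctionPlayers[[as.character(s)]] <- list(
        stack = sid, branch = bid, stacked = stacked,
        unstacked = setdiff(sse$helices, stacked))
    } else if (sse$kind == "FOUR_WAY") {
      hs <- sse$helices                  # outer, i1, i2, i3
      lens <- vapply(sse$strands, length, 1L)
      ## two ways to split the cyclic order (h0 h1 h2 h3) into two
      ## adjacent stacked pairs; pick the smaller total strand length
      splitA <- list(c(hs[1L], hs[2L]), c(hs[3L], hs[4L]))  # s1 + s3
      splitB <- list(c(hs[2L], hs[3L]), c(hs[4L], hs[1L]))  # s2 + s4
      pairs2 <- if (lens[1L] + lens[3L] <= lens[2L] + lens[4L])
        splitA else splitB
      if (!is.null(stackingHint[[as.character(s)]]))
        pairs2 <- stackingHint[[as.character(s)]]
      ids <- list()
      for (q in 1:2) {
        st <- pairs2[[q]]
        stackNts <- unlist(lapply(st, function(h)
          .helixClosingPair(sses[[h]], outer = h == sse$helices[1L])))
        sid <- addPlayer("THREE_WAY_STACK", s, NA_integer_, FALSE,
                         FALSE, FALSE, stackNts)
        bid <- addPlayer("THREE_WAY_BRANCH", s, NA_integer_, FALSE,
                         FALSE, FALSE, sse$nucleotides)
        ids[[q]] <- list(stack = sid, branch = bid, stacked = st)
      }
      lid <- addPlayer("LINKER", s, NA_integer_, FALSE, FALSE, FALSE,
                       sse$nucleotides)
      junctionPlayers[[as.character(s)]] <- list(four = ids, linker = lid)
    }
  }
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(id = r$id, ptype = r$ptype, sse = r$sse, kind = r$kind,
               nBp = r$nBp, largeHelix = r$largeHelix,
               smallTwoWay = r$smallTwoWay, frozen = r$frozen,
               nt5 = r$nt5, stringsAsFactors = FALSE)))
  df$nucleotides <- lapply(rows, function(r) r$nucleotides[[1L]])
  attr(df, "helixPlayers") <- helixPlayers
  attr(df, "junctionPlayers") <- junctionPlayers
  df
}

#' Build the player graph (a tree) from players and SSEs
#'
#' Edges follow the covalent connectivity of the secondary structure.
#' The edge between the STACK and BRANCH players of one three-way
#' junction has length 1 lattice unit (players at the same junction);
#' every other adjacency has length 2.
#'
#' @param players player table from [buildPlayers()]
#' @param sses SSE list from [decomposeSSEs()]
#' @return an [RNAGraph-class] with a DFS ordering
#' @export
buildGraph <- function(players, sses) {
  helixPlayers <- attr(players, "helixPlayers")
  junctionPlayers <- attr(players, "junctionPlayers")
  el <- list()
  addEdge <- function(a, b, len)
    el[[length(el) + 1L]] <<- c(as.integer(a), as.integer(b),
                                as.integer(len))
  ## chain players within one helix (outer to inner), length 2
  for (ids in helixPlayers)
    if (length(ids) > 1L)
      for (k in seq_len(length(ids) - 1L))
        addEdge(ids[k], ids[k + 1L], 2L)
  ## junction internal edges and helix attachments
  for (s in seq_along(sses)) {
    sse <- sses[[s]]
    if (sse$kind == "HELIX") next
    jp <- junctionPlayers[[as.character(s)]]
    ## the junction-side player of helix h: inner end for the outer
    ## helix (it closes this loop), outer end for inner helices
    endOf <- function(h) {
      ids <- helixPlayers[[as.character(h)]]
      if (h == sse$helices[1L]) ids[length(ids)] else ids[1L]
    }
    if (sse$kind %in% c("ONE_WAY", "TWO_WAY")) {
      for (h in sse$helices) addEdge(endOf(h), jp$loop, 2L)
    } else if (sse$kind == "THREE_WAY") {
      addEdge(jp$stack, jp$branch, 1L)
      for (h in jp$stacked) addEdge(endOf(h), jp$stack, 2L)
      addEdge(endOf(jp$unstacked), jp$branch, 2L)
    } else if (sse$kind == "FOUR_WAY") {
      for (q in 1:2) {
        addEdge(jp$four[[q]]$stack, jp$four[[q]]$branch, 1L)
        for (h in jp$four[[q]]$stacked)
          addEdge(endOf(h), jp$four[[q]]$stack, 2L)
        addEdge(jp$four[[q]]$branch, jp$linker, 2L)
      }
    }
  }
  edges <- if (length(el)) do.call(rbind, el) else
    matrix(integer(0), ncol = 3L)
  colnames(edges) <- c("from", "to", "length")
  g <- new("RNAGraph", players = players, edges = edges,
           ordering = integer(0), sses = sses)
  g@ordering <- orderPlayers(g)
  validObject(g)
  g
}

## adjacency list of the player tree
.adjList <- function(graph) {
  np <- nrow(graph@players)
  adj <- vector("list", np)
  e <- graph@edges
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1L]]] <- c(adj[[e[k, 1L]]], e[k, 2L])
    adj[[e[k, 2L]]] <- c(adj[[e[k, 2L]]], e[k, 1L])
  }
  adj
}

#' Depth-first playing order of the players
#'
#' The root is the junction of largest degree nearest the 5'-3' paired
#' end (the STACK player for three- and four-way junctions); when the
#' molecule has no junction beyond terminal loops, the DFS starts from
#' the 5' paired end instead (the outermost helix player), so a hairpin
#' orders as helix, loop and a linear chain keeps its natural order. At
#' a three-way junction the subtree through the unstacked helix (hanging
#' below the BRANCH player) is visited first; all other children are
#' visited in 5' order.
#'
#' @param graph an [RNAGraph-class]
#' @return integer permutation of player ids (a DFS preorder)
#' @export
orderPlayers <- function(graph) {
  pl <- graph@players
  np <- nrow(pl)
  if (np == 1L) return(1L)
  adj <- .adjList(graph)
  degOf <- c(ONE_WAY = 1L, TWO_WAY = 2L, THREE_WAY_STACK = 3L,
             THREE_WAY_BRANCH = 0L, LINKER = 0L, HELIX = 0L)
  jdeg <- degOf[pl$ptype]
  ## four-way stack players stand for a degree-4 junction
  jdeg[pl$ptype == "THREE_WAY_STACK" & pl$kind == "FOUR_WAY"] <- 4L
  if (max(jdeg) >= 2L) {
    cand <- which(jdeg == max(jdeg))
    root <- cand[which.min(pl$nt5[cand])]
  } else {
    helixIds <- which(pl$ptype == "HELIX")
    root <- helixIds[which.min(pl$nt5[helixIds])]
  }
  order <- integer(0)
  visit <- function(v, parent) {
    order <<- c(order, v)
    kids <- setdiff(adj[[v]], parent)
    if (!length(kids)) return()
    first <- kids[pl$ptype[v] == "THREE_WAY_STACK" &
                  pl$ptype[kids] == "THREE_WAY_BRANCH" &
                  pl$sse[kids] == pl$sse[v]]
    rest <- setdiff(kids, first)
    for (k in c(first, rest[order(pl$nt5[rest])])) visit(k, v)
  }
  visit(root, 0L)
  unname(order)
}

#' Ratio of helix players to junction players
#'
#' Used by the default-gameplay rule: with a three-way junction present,
#' the Lennard-Jones potential is selected when this ratio exceeds 1.5,
#' the modified Lennard-Jones otherwise.
#'
#' @param graph an [RNAGraph-class]
#' @return (number of HELIX players) / (number of non-HELIX players)
#' @export
helixJunctionRatio <- function(graph) {
  nH <- sum(graph@players$ptype == "HELIX")
  nJ <- sum(graph@players$ptype != "HELIX")
  if (nJ == 0L)
    stop("undefined ratio: the graph has no junction players")
  nH / nJ
}

#' Build the full coarse-grained graph from a secondary structure
#'
#' Convenience pipeline: [decomposeSSEs()], [buildPlayers()],
#' [buildGraph()].
#'
#' @inheritParams decomposeSSEs
#' @inheritParams buildPlayers
#' @return an [RNAGraph-class]
#' @export
rnaGraph <- function(ss, stackingHint = NULL, frozen = FALSE) {
  sses <- decomposeSSEs(ss)
  buildGraph(buildPlayers(sses, stackingHint, frozen), sses)
}
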