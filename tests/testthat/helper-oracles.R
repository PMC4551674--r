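# Independent oracles used across the suite. Each one deliberately
# re-derives a quantity by brute force, with none of the package's
# internal machinery.

# depth-counting bracket matcher (independent of parseDotBracket's stack)
oracleMatchBrackets <- function(db) {
  ch <- strsplit(db, "")[[1L]]
  pairs <- list()
  for (i in which(ch == "(")) {
    depth <- 0L
    for (j in i:length(ch)) {
      if (ch[j] == "(") depth <- depth + 1L
      if (ch[j] == ")") depth <- depth - 1L
      if (depth == 0L) { pairs[[length(pairs) + 1L]] <- c(i, j); break }
    }
  }
  do.call(rbind, pairs)
}

# floating-point minimum distance between closed 3D segments
oracleSegmentDistance <- function(p1, p2, p3, p4) {
  d1 <- p2 - p1; d2 <- p4 - p3; r <- p1 - p3
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  clamp <- function(x) min(max(x, 0), 1)
  if (a <= 1e-12 && e <= 1e-12) return(sqrt(sum(r * r)))
  if (a <= 1e-12) {
    s <- 0; t <- clamp(f / e)
  } else {
    c1 <- sum(d1 * r)
    if (e <= 1e-12) {
      t <- 0; s <- clamp(-c1 / a)
    } else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      s <- if (den > 1e-12) clamp((b * f - c1 * e) / den) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- clamp(-c1 / a) }
      else if (t > 1) { t <- 1; s <- clamp((b - c1) / a) }
    }
  }
  cp1 <- p1 + s * d1; cp2 <- p3 + t * d2
  sqrt(sum((cp1 - cp2)^2))
}

# brute-force O(E^2) conformation validity: distinct positions, exact
# edge geometry, length-2 midpoints unoccupied, no segment pair within
# 1e-9 except at a shared tree endpoint
oracleSelfAvoiding <- function(pos, edges) {
  np <- nrow(pos)
  if (anyDuplicated(pos)) return(FALSE)
  segs <- list()
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1L]; b <- edges[k, 2L]; len <- edges[k, 3L]
    d <- (pos[b, ] - pos[a, ]) / len
    if (!all(d == round(d)) || sum(d^2) != 2 || sum(d == 0) != 1)
      return(FALSE)
    if (len == 2L) {
      mid <- pos[a, ] + d
      for (i in seq_len(np)) if (all(mid == pos[i, ])) return(FALSE)
    }
    segs[[k]] <- list(p = pos[a, ], q = pos[b, ], a = a, b = b)
  }
  for (i in seq_along(segs)) for (j in seq_along(segs)) {
    if (j <= i) next
    shared <- length(intersect(c(segs[[i]]$a, segs[[i]]$b),
                               c(segs[[j]]$a, segs[[j]]$b))) > 0L
    d <- oracleSegmentDistance(segs[[i]]$p, segs[[i]]$q,
                               segs[[j]]$p, segs[[j]]$q)
    if (!shared && d < 1e-9) return(FALSE)
    if (shared) {
      # sharing a node is fine; any further contact is not: check the
      # segments with the shared endpoint trimmed off slightly
      pi1 <- segs[[i]]$p + 0.05 * (segs[[i]]$q - segs[[i]]$p)
      qi1 <- segs[[i]]$q - 0.05 * (segs[[i]]$q - segs[[i]]$p)
      pj1 <- segs[[j]]$p + 0.05 * (segs[[j]]$q - segs[[j]]$p)
      qj1 <- segs[[j]]$q - 0.05 * (segs[[j]]$q - segs[[j]]$p)
      if (oracleSegmentDistance(pi1, qi1, pj1, qj1) < 1e-9) return(FALSE)
    }
  }
  TRUE
}

# direct R evaluation of one normalized pair score
oraclePairScore <- function(d, form, entry) {
  raw <- switch(form,
    LJ = -entry$A * ((entry$B / d)^12 - 2 * (entry$B / d)^6),
    MODIFIED_LJ = max(-entry$A * ((entry$B / d)^12 - 2 * (entry$B / d)^6), 0),
    GAUSS = sum(vapply(entry$components, function(cm)
      cm$A / (cm$sigma * sqrt(2 * pi)) *
        exp(-(d - cm$mu)^2 / (2 * cm$sigma^2)), 1)),
    INV_SQ = 1 / d^2)
  raw / entry$norm
}

# brute-force double loop over ordered pairs for all player scores,
# from raw integer lattice positions
oraclePlayerScoresPos <- function(pos, step, g, table) {
  xyz <- pos * step / sqrt(2)
  np <- nrow(xyz)
  adj <- diag(np) > 0
  for (k in seq_len(nrow(edges(g)))) {
    adj[edges(g)[k, 1L], edges(g)[k, 2L]] <- TRUE
    adj[edges(g)[k, 2L], edges(g)[k, 1L]] <- TRUE
  }
  types <- players(g)$ptype
  out <- numeric(np)
  for (i in seq_len(np)) for (j in seq_len(np)) {
    if (i == j || adj[i, j]) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    key <- paste(sort(c(types[i], types[j])), collapse = "|")
    out[i] <- out[i] + oraclePairScore(d, table@form,
                                       table@entries[[key]])
  }
  out
}

oraclePlayerScores <- function(conf, table) {
  oraclePlayerScoresPos(positions(conf), conf@step, conf@graph, table)
}

# brute-force RMSD: minimize Eq 2 over a rotation grid, refined locally
oracleRmsdGrid <- function(m, n) {
  mc <- sweep(m, 2, colMeans(m)); nc <- sweep(n, 2, colMeans(n))
  rotmat <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3) %*%
      matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3) %*%
      matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  }
  obj <- function(ang) sqrt(mean(rowSums((mc %*% rotmat(ang) - nc)^2)))
  grid <- expand.grid(a = seq(0, 2 * pi, by = pi / 9),
                      b = seq(0, pi, by = pi / 9),
                      c = seq(0, 2 * pi, by = pi / 9))
  vals <- apply(grid, 1, obj)
  best <- optim(as.numeric(grid[which.min(vals), ]), obj,
                method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-14))
  best$value
}

# is `ord` a valid DFS preorder of the tree? simulate with a stack
oracleIsDFSPreorder <- function(ord, edges, np) {
  adj <- vector("list", np)
  for (k in seq_len(nrow(edges))) {
    adj[[edges[k, 1L]]] <- c(adj[[edges[k, 1L]]], edges[k, 2L])
    adj[[edges[k, 2L]]] <- c(adj[[edges[k, 2L]]], edges[k, 1L])
  }
  if (!setequal(ord, seq_len(np))) return(FALSE)
  visited <- ord[1L]
  stack <- ord[1L]
  for (v in ord[-1L]) {
    repeat {
      if (!length(stack)) return(FALSE)
      top <- stack[length(stack)]
      if (v %in% setdiff(adj[[top]], visited)) break
      if (length(setdiff(adj[[top]], visited))) return(FALSE)
      stack <- stack[-length(stack)]
    }
    visited <- c(visited, v)
    stack <- c(stack, v)
  }
  TRUE
}
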