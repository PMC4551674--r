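#' Generate toy secondary-structure fixtures
#'
#' Deterministic dot-bracket strings for the standard test topologies,
#' with ground-truth element and player counts derived from the player
#' construction rules (ceiling(bp/5) players per helix, one per one- or
#' two-way junction, two per three-way junction, five per four-way
#' junction).
#'
#' @param topology one of "HAIRPIN", "BULGED_HAIRPIN", "THREE_WAY",
#'   "FOUR_WAY", "LONG_HELIX"
#' @param helixLengths base pairs per helix (recycled as needed)
#' @param loopLengths unpaired nucleotides of the terminal loops
#' @param strandLengths unpaired nucleotides of the junction strands
#' @return list with sequence, structure, and expected counts
#' @export
makeFixture <- function(topology = c("HAIRPIN", "BULGED_HAIRPIN",
                                     "THREE_WAY", "FOUR_WAY",
                                     "LONG_HELIX"),
                        helixLengths = NULL, loopLengths = NULL,
                        strandLengths = NULL) {
  topology <- match.arg(topology)
  rep2 <- function(x, n) rep_len(x, n)
  helix <- function(n, close = FALSE)
    strrep(if (close) ")" else "(", n)
  dots <- function(n) strrep(".", n)
  hairpinPlayers <- function(b) ceiling(b / 5)
  if (topology == "HAIRPIN") {
    h <- if (is.null(helixLengths)) 4L else helixLengths[1L]
    l <- if (is.null(loopLengths)) 4L else loopLengths[1L]
    db <- paste0(helix(h), dots(l), helix(h, TRUE))
    expected <- list(nSSE = 2L, nPlayers = hairpinPlayers(h) + 1L,
                     kinds = c(HELIX = 1L, ONE_WAY = 1L))
  } else if (topology == "LONG_HELIX") {
    h <- if (is.null(helixLengths)) 12L else helixLengths[1L]
    l <- if (is.null(loopLengths)) 4L else loopLengths[1L]
    db <- paste0(helix(h), dots(l), helix(h, TRUE))
    expected <- list(nSSE = 2L, nPlayers = hairpinPlayers(h) + 1L,
                     kinds = c(HELIX = 1L, ONE_WAY = 1L))
  } else if (topology == "BULGED_HAIRPIN") {
    hs <- rep2(if (is.null(helixLengths)) 4L else helixLengths, 2L)
    l <- if (is.null(loopLengths)) 4L else loopLengths[1L]
    bulge <- if (is.null(strandLengths)) 1L else strandLengths[1L]
    db <- paste0(helix(hs[1L]), dots(bulge), helix(hs[2L]), dots(l),
                 helix(hs[2L], TRUE), helix(hs[1L], TRUE))
    expected <- list(
      nSSE = 4L,
      nPlayers = sum(ceiling(hs / 5)) + 2L,
      kinds = c(HELIX = 2L, TWO_WAY = 1L, ONE_WAY = 1L))
  } else if (topology == "THREE_WAY") {
    hs <- rep2(if (is.null(helixLengths)) 4L else helixLengths, 3L)
    ls <- rep2(if (is.null(loopLengths)) 4L else loopLengths, 2L)
    ss <- rep2(if (is.null(strandLengths)) c(1L, 2L, 2L) else
      strandLengths, 3L)
    arm <- function(h, l) paste0(helix(h), dots(l), helix(h, TRUE))
    db <- paste0(helix(hs[1L]), dots(ss[1L]), arm(hs[2L], ls[1L]),
                 dots(ss[2L]), arm(hs[3L], ls[2L]), dots(ss[3L]),
                 helix(hs[1L], TRUE))
    expected <- list(
      nSSE = 6L,
      nPlayers = sum(ceiling(hs / 5)) + 2L + 2L,
      kinds = c(HELIX = 3L, THREE_WAY = 1L, ONE_WAY = 2L))
  } else { # FOUR_WAY
    hs <- rep2(if (is.null(helixLengths)) 4L else helixLengths, 4L)
    ls <- rep2(if (is.null(loopLengths)) 4L else loopLengths, 3L)
    ss <- rep2(if (is.null(strandLengths)) c(1L, 2L, 2L, 2L) else
      strandLengths, 4L)
    arm <- function(h, l) paste0(helix(h), dots(l), helix(h, TRUE))
    db <- paste0(helix(hs[1L]), dots(ss[1L]), arm(hs[2L], ls[1L]),
                 dots(ss[2L]), arm(hs[3L], ls[2L]), dots(ss[3L]),
                 arm(hs[4L], ls[3L]), dots(ss[4L]), helix(hs[1L], TRUE))
    expected <- list(
      nSSE = 8L,
      nPlayers = sum(ceiling(hs / 5)) + 5L + 3L,
      kinds = c(HELIX = 4L, FOUR_WAY = 1L, ONE_WAY = 3L))
  }
  seqc <- .fixtureSequence(db)
  list(sequence = seqc, structure = db, expected = expected)
}

## deterministic complementary sequence: G/C on paired positions, A loops
.fixtureSequence <- function(db) {
  ch <- strsplit(db, "")[[1L]]
  out <- ifelse(ch == "(", "G", ifelse(ch == ")", "C", "A"))
  paste(out, collapse = "")
}

## weighted mean of a distance law
.lawMean <- function(law) {
  if (law$distribution == "gaussian") return(law$mu)
  sum(law$weights * law$mu)
}

## draw n samples from a law
.lawSample <- function(law, n) {
  if (law$distribution == "gaussian")
    return(rnorm(n, law$mu, law$sigma))
  k <- sample.int(length(law$weights), n, replace = TRUE,
                  prob = law$weights)
  rnorm(n, law$mu[k], law$sigma[k])
}

## law for a type pair, falling back to "default"
.lawFor <- function(laws, t1, t2) {
  law <- laws[[pairKey(t1, t2)]]
  if (is.null(law)) law <- laws$default
  if (is.null(law)) stop("no distance law for pair ", pairKey(t1, t2))
  law
}

#' Generate a synthetic reference ensemble of player coordinates
#'
#' Emulates a reference set of coarse-grained native structures: each
#' structure keeps adjacent players at their lattice edge distances
#' (edge length x step Angstrom) while non-adjacent inter-player
#' distances follow the requested laws. Each structure is built by
#' placing players sequentially in DFS order at the direction best
#' matching distance targets drawn from the laws, then refining all
#' edge directions jointly (BFGS on the spherical angles). Because hard
#' edge constraints bias the realized distances on branched graphs, the
#' ensemble is calibrated: per-pair-class residual bias shifts the
#' target means and the ensemble is regenerated until every class mean
#' is within `tol` of its law mean (bounded number of rounds).
#'
#' @param graph an [RNAGraph-class]
#' @param laws named list "TYPEA|TYPEB" (or "default") -> list(
#'   distribution = "gaussian" | "bimodal", mu, sigma, weights)
#' @param nStructures number of coordinate sets
#' @param seed integer seed
#' @param step lattice step in Angstrom for adjacent distances
#' @param tol relative tolerance on the empirical class means
#' @param maxTries calibration rounds before failing
#' @return list of [NativeGraph-class] objects
#' @export
makeReferenceEnsemble <- function(graph, laws, nStructures = 100L,
                                  seed = 1L, step = 5.6, tol = 0.05,
                                  maxTries = 5L) {
  set.seed(as.integer(seed))
  info <- .treeInfo(graph)
  types <- graph@players$ptype
  np <- length(types)
  ord <- graph@ordering
  adj <- matrix(FALSE, np, np)
  e <- graph@edges
  for (k in seq_len(nrow(e))) {
    adj[e[k, 1L], e[k, 2L]] <- TRUE
    adj[e[k, 2L], e[k, 1L]] <- TRUE
  }
  keyOf <- matrix("", np, np)
  for (i in seq_len(np)) for (j in seq_len(np))
    keyOf[i, j] <- pairKey(types[i], types[j])
  nonAdjPairs <- which(upper.tri(adj) & !adj, arr.ind = TRUE)
  ## positions from one spherical angle pair per non-root player
  buildCoords <- function(ang) {
    coords <- matrix(0, np, 3L)
    for (i in seq_along(ord[-1L])) {
      v <- ord[-1L][i]; par <- info$parent[v]
      r <- info$elen[par, v] * step
      th <- ang[2L * i - 1L]; ph <- ang[2L * i]
      coords[v, ] <- coords[par, ] +
        r * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    }
    coords
  }
  oneStructure <- function(shift) {
    targets <- matrix(NA_real_, np, np)
    for (r in seq_len(nrow(nonAdjPairs))) {
      i <- nonAdjPairs[r, 1L]; j <- nonAdjPairs[r, 2L]
      law <- .lawFor(laws, types[i], types[j])
      s <- shift[[keyOf[i, j]]]
      if (is.null(s)) s <- 0
      targets[i, j] <- targets[j, i] <- .lawSample(law, 1L) + s
    }
    obj <- function(ang) {
      coords <- buildCoords(ang)
      s <- 0
      for (r in seq_len(nrow(nonAdjPairs))) {
        i <- nonAdjPairs[r, 1L]; j <- nonAdjPairs[r, 2L]
        d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
        s <- s + (d - targets[i, j])^2
      }
      s
    }
    ## greedy sequential initialization, then joint refinement
    ang0 <- numeric(2L * (np - 1L))
    coords <- matrix(0, np, 3L)
    placed <- rep(FALSE, np); placed[info$root] <- TRUE
    for (i in seq_along(ord[-1L])) {
      v <- ord[-1L][i]; par <- info$parent[v]
      r <- info$elen[par, v] * step
      others <- which(placed & !adj[v, ] & seq_len(np) != v)
      cand <- matrix(rnorm(3L * 40L), ncol = 3L)
      cand <- cand / sqrt(rowSums(cand^2))
      if (length(others)) {
        errs <- apply(cand, 1L, function(u) {
          x <- coords[par, ] + r * u
          sum((sqrt(colSums((t(coords[others, , drop = FALSE]) - x)^2)) -
                 targets[v, others])^2)
        })
        u <- cand[which.min(errs), ]
      } else u <- cand[1L, ]
      coords[v, ] <- coords[par, ] + r * u
      ang0[2L * i - 1L] <- acos(min(max(u[3L], -1), 1))
      ang0[2L * i] <- atan2(u[2L], u[1L])
      placed[v] <- TRUE
    }
    fit <- optim(ang0, obj, method = "BFGS",
                 control = list(maxit = 150L))
    buildCoords(fit$par)
  }
  shift <- list()
  for (round in seq_len(maxTries)) {
    ensemble <- lapply(seq_len(nStructures), function(i)
      new("NativeGraph", graph = graph, coords = oneStructure(shift)))
    dists <- pairDistances(ensemble)
    ok <- TRUE
    for (key in names(dists)) {
      tt <- strsplit(key, "|", fixed = TRUE)[[1L]]
      law <- .lawFor(laws, tt[1L], tt[2L])
      bias <- mean(dists[[key]]) - .lawMean(law)
      if (abs(bias) > tol * .lawMean(law)) {
        ok <- FALSE
        s <- shift[[key]]
        if (is.null(s)) s <- 0
        shift[[key]] <- s - bias
      }
    }
    if (ok) return(ensemble)
  }
  stop("generation error: ensemble moments did not reach tolerance ",
       tol, " in ", maxTries, " rounds")
}

#' Non-adjacent inter-player distances of an ensemble, by type pair
#'
#' The raw material for [fitPairParams()]: all pairwise distances
#' between non-adjacent players, pooled over structures and grouped by
#' unordered player-type pair.
#'
#' @param ensemble list of [NativeGraph-class] objects
#' @return named list "TYPEA|TYPEB" -> numeric distances (Angstrom)
#' @export
pairDistances <- function(ensemble) {
  graph <- ensemble[[1L]]@graph
  types <- graph@players$ptype
  np <- length(types)
  adj <- diag(np) > 0
  e <- graph@edges
  for (k in seq_len(nrow(e))) {
    adj[e[k, 1L], e[k, 2L]] <- TRUE
    adj[e[k, 2L], e[k, 1L]] <- TRUE
  }
  out <- list()
  for (ng in ensemble) {
    d <- as.matrix(dist(ng@coords))
    for (i in seq_len(np - 1L))
      for (j in (i + 1L):np) {
        if (adj[i, j]) next
        key <- pairKey(types[i], types[j])
        out[[key]] <- c(out[[key]], d[i, j])
      }
  }
  out
}

#' Write a synthetic all-atom native PDB for a coarse-grained graph
#'
#' Builds a plain-text PDB whose per-nucleotide heavy-atom centres are
#' known exactly: each nucleotide gets three heavy atoms placed
#' symmetrically around its centre (the mean of the coordinates of the
#' players containing it), plus optionally one hydrogen that a correct
#' coarse-graining must ignore. Synthetic stand-in for a crystallographic
#' native structure; used to exercise [coarseGrainNative()].
#'
#' @param native a [NativeGraph-class]
#' @param path output PDB path
#' @param withHydrogens also write one H atom per nucleotide, offset
#'   from the centre
#' @return invisibly, the per-nucleotide centre matrix
#' @export
writeSyntheticNativePDB <- function(native, path, withHydrogens = FALSE) {
  graph <- native@graph
  n <- max(unlist(graph@players$nucleotides))
  centers <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    owners <- which(vapply(graph@players$nucleotides, function(v)
      i %in% v, TRUE))
    centers[i, ] <- colMeans(native@coords[owners, , drop = FALSE])
  }
  off <- rbind(c(1, 0, 0), c(-0.5, 0.5, 0), c(-0.5, -0.5, 0))
  lines <- character(0)
  serial <- 0L
  names3 <- c(" C1'", " C2'", " N1 ")
  for (i in seq_len(n)) {
    for (a in 1:3) {
      serial <- serial + 1L
      xyz <- centers[i, ] + off[a, ]
      lines <- c(lines, sprintf(
        "ATOM  %5d %s   A A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        serial, names3[a], i, xyz[1L], xyz[2L], xyz[3L],
        substr(trimws(names3[a]), 1L, 1L)))
    }
    if (withHydrogens) {
      serial <- serial + 1L
      xyz <- centers[i, ] + c(0, 0, 5)
      lines <- c(lines, sprintf(
        "ATOM  %5d  H1'   A A%4d    %8.3f%8.3f%8.3f  1.00  0.00           H",
        serial, i, xyz[1L], xyz[2L], xyz[3L]))
    }
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(centers)
}
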