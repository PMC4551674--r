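#' Knowledge-based pair scoring forms
#'
#' Four functional forms score the distance d (Angstrom) between two
#' players, by SSE-type pair:
#' \itemize{
#'   \item Lennard-Jones: -A((B/d)^12 - 2 (B/d)^6), single mode of
#'     height A at the preferred distance d = B;
#'   \item modified Lennard-Jones: the positive repulsive part is
#'     flattened to 0, i.e. max(LJ, 0) (zero below B 2^(-1/6));
#'   \item Gaussian mixture: sum of A_k dnorm(d, mu_k, sigma_k), giving
#'     several modes;
#'   \item inverse square: 1/d^2.
#' }
#'
#' @param d distance(s) in Angstrom
#' @param A amplitude
#' @param B preferred distance in Angstrom
#' @param components list of lists with fields A, mu, sigma
#' @return score value(s)
#' @name scoringForms
NULL

#' @rdname scoringForms
#' @export
ljScore <- function(d, A, B) {
  if (any(d <= 0)) stop("distance must be positive")
  q6 <- (B / d)^6
  -A * (q6^2 - 2 * q6)
}

#' @rdname scoringForms
#' @export
modLjScore <- function(d, A, B) {
  pmax(ljScore(d, A, B), 0)
}

#' @rdname scoringForms
#' @export
gaussScore <- function(d, components) {
  if (any(d < 0)) stop("distance must be non-negative")
  if (!length(components)) stop("at least one component required")
  s <- 0
  for (cmp in components) {
    if (cmp$sigma <= 0) stop("sigma must be positive")
    s <- s + cmp$A / (cmp$sigma * sqrt(2 * pi)) *
      exp(-(d - cmp$mu)^2 / (2 * cmp$sigma^2))
  }
  s
}

#' @rdname scoringForms
#' @export
invsqScore <- function(d) {
  if (any(d <= 0)) stop("distance must be positive")
  1 / d^2
}

## evaluate one PairParams entry (normalized)
evalPairScore <- function(d, form, entry) {
  raw <- switch(form,
    LJ = ljScore(d, entry$A, entry$B),
    MODIFIED_LJ = modLjScore(d, entry$A, entry$B),
    GAUSS = gaussScore(d, entry$components),
    INV_SQ = invsqScore(d))
  raw / entry$norm
}

#' Fit the parameters of one scoring form from distance samples
#'
#' For the Lennard-Jones forms the preferred distance B is the mode of a
#' kernel-density estimate of the distances (amplitude A = 1, absorbed
#' by normalization). The Gaussian form is a finite Gaussian mixture
#' fitted by expectation-maximization with the component count (1 to
#' `maxComponents`) selected by BIC; the mixture weights become the
#' amplitudes A_k. The inverse-square form has no fitted parameters.
#' Every form is then normalized so the supremum of the score over the
#' observed distance range equals 1 (for the inverse-square form, whose
#' supremum near zero is unbounded, the value at the smallest observed
#' distance is used).
#'
#' @param distances numeric vector of distances in Angstrom
#' @param form scoring form
#' @param minSamples minimum number of samples required
#' @param maxComponents largest mixture size tried for the GAUSS form
#' @return a PairParams list (form, A, B, components, norm, dmax)
#' @export
fitPairParams <- function(distances, form = c("LJ", "MODIFIED_LJ",
                                              "GAUSS", "INV_SQ"),
                          minSamples = 30L, maxComponents = 5L) {
  form <- match.arg(form)
  distances <- distances[is.finite(distances) & distances > 0]
  if (length(distances) < minSamples)
    stop("insufficient data: ", length(distances), " samples (minimum ",
         minSamples, ")")
  dmax <- max(distances)
  out <- list(form = form, A = 1, B = NA_real_, components = list(),
              norm = 1, dmax = dmax, dmin = min(distances))
  if (form %in% c("LJ", "MODIFIED_LJ")) {
    ## oversmoothed KDE (twice the reference bandwidth): distance
    ## distributions are smooth and only the mode location is needed,
    ## so trading bias for variance stabilizes the estimate
    kde <- stats::density(distances, bw = 2 * stats::bw.nrd0(distances),
                          n = 2048L)
    out$B <- kde$x[which.max(kde$y)]
    out$norm <- out$A                      # maximum is A, at d = B
  } else if (form == "GAUSS") {
    fit <- Mclust(distances, G = seq_len(maxComponents),
                  modelNames = "V", verbose = FALSE)
    if (is.null(fit))                       # fall back to equal variances
      fit <- Mclust(distances, G = seq_len(maxComponents),
                    modelNames = "E", verbose = FALSE)
    w <- fit$parameters$pro
    mu <- fit$parameters$mean
    sg <- sqrt(fit$parameters$variance$sigmasq)
    if (length(sg) == 1L) sg <- rep(sg, length(mu))
    out$components <- lapply(seq_along(mu), function(k)
      list(A = w[k], mu = unname(mu[k]), sigma = sg[k]))
    ## supremum over the observed range: coarse grid + local refinement
    grid <- seq(1e-3, dmax, length.out = 4096L)
    vals <- gaussScore(grid, out$components)
    i <- which.max(vals)
    lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
    opt <- stats::optimize(function(d) gaussScore(d, out$components),
                           c(lo, hi), maximum = TRUE)
    out$norm <- max(vals[i], opt$objective)
  } else { # INV_SQ
    out$norm <- invsqScore(out$dmin)
  }
  out
}

#' Fit a full PairScoreTable from grouped distance samples
#'
#' @param distancesByPair named list "TYPEA|TYPEB" -> numeric distances
#'   (names with the two player types sorted alphabetically)
#' @param form scoring form shared by all entries
#' @param ... passed to [fitPairParams()]
#' @return a [PairScoreTable-class]
#' @export
fitScoreTable <- function(distancesByPair, form = "MODIFIED_LJ", ...) {
  entries <- lapply(distancesByPair, fitPairParams, form = form, ...)
  new("PairScoreTable", form = form, entries = entries)
}

#' Canonical key of an unordered player-type pair
#'
#' @param t1,t2 player type strings
#' @return "A|B" with the types sorted
#' @export
pairKey <- function(t1, t2) {
  paste(sort(c(t1, t2)), collapse = "|")
}

## fetch an entry, erroring on a missing pair
.tableEntry <- function(table, t1, t2) {
  key <- pairKey(t1, t2)
  e <- table@entries[[key]]
  if (is.null(e)) stop("missing parameter for type pair ", key)
  e
}

## Encode the table for the C++ scorer. Returns list(adj, pairIdx, params).
## adj marks pairs excluded from Eq 1 sums (self and edge-adjacent).
.scoreEncoding <- function(graph, table) {
  types <- graph@players$ptype
  np <- length(types)
  adj <- diag(np)
  e <- graph@edges
  for (k in seq_len(nrow(e))) {
    adj[e[k, 1L], e[k, 2L]] <- 1L
    adj[e[k, 2L], e[k, 1L]] <- 1L
  }
  ## only pairs that actually enter the sums (distinct, non-adjacent)
  ## need parameters
  used <- which(upper.tri(adj) & adj == 0L, arr.ind = TRUE)
  keys <- unique(vapply(seq_len(nrow(used)), function(r)
    pairKey(types[used[r, 1L]], types[used[r, 2L]]), ""))
  formId <- match(table@form, c("LJ", "MODIFIED_LJ", "GAUSS", "INV_SQ"))
  params <- matrix(0, max(length(keys), 1L), 20L)
  params[, 4L] <- 1                        # safe norm for unused rows
  for (r in seq_along(keys)) {
    tt <- strsplit(keys[r], "|", fixed = TRUE)[[1L]]
    e <- .tableEntry(table, tt[1L], tt[2L])
    params[r, 1L] <- formId
    params[r, 2L] <- e$A
    params[r, 3L] <- if (is.na(e$B)) 0 else e$B
    params[r, 4L] <- e$norm
    params[r, 5L] <- length(e$components)
    for (k in seq_along(e$components)) {
      params[r, 5L + k] <- e$components[[k]]$A
      params[r, 10L + k] <- e$components[[k]]$mu
      params[r, 15L + k] <- e$components[[k]]$sigma
    }
  }
  pairIdx <- matrix(1L, np, np)
  for (r in seq_len(nrow(used))) {
    i <- used[r, 1L]; j <- used[r, 2L]
    pairIdx[i, j] <- pairIdx[j, i] <-
      match(pairKey(types[i], types[j]), keys)
  }
  storage.mode(adj) <- "integer"
  storage.mode(pairIdx) <- "integer"
  list(adj = adj, pairIdx = pairIdx, params = params)
}

#' Knowledge-based score of one player
#'
#' Sum of the normalized pair scores between player j and every other
#' non-adjacent player, at their Cartesian distances. Frozen helix
#' players are instead scored through their neighbouring junctions (see
#' [frozenHelixScore()]).
#'
#' @param j player id
#' @param conf a [Conformation-class]
#' @param table a [PairScoreTable-class]
#' @return the player's score
#' @export
playerScore <- function(j, conf, table) {
  pl <- conf@graph@players
  if (pl$frozen[j]) return(frozenHelixScore(j, conf, table))
  .rawPlayerScores(conf, table)[j]
}

## per-player Eq 1 sums, no frozen rule applied
.rawPlayerScores <- function(conf, table, enc = NULL) {
  if (is.null(enc)) enc <- .scoreEncoding(conf@graph, table)
  cppPlayerScores(conf@positions, conf@step, enc$adj, enc$pairIdx,
                  enc$params)
}

#' All player scores of a conformation
#'
#' Vector of [playerScore()] values, with the frozen-helix rule applied
#' to frozen players.
#'
#' @inheritParams playerScore
#' @return numeric vector of per-player scores
#' @export
playerScores <- function(conf, table) {
  enc <- .scoreEncoding(conf@graph, table)
  raw <- .rawPlayerScores(conf, table, enc)
  .applyFrozenRule(conf@graph, raw)
}

## frozen helix players: mean over nearest junction neighbours q of
## score(q) / hop-distance(j, q)
.applyFrozenRule <- function(graph, raw) {
  frozenIds <- which(graph@players$frozen)
  if (!length(frozenIds)) return(raw)
  out <- raw
  for (j in frozenIds) {
    nb <- .junctionNeighbors(graph, j)
    if (!nrow(nb)) {
      warning("frozen helix player ", j,
              " has no junction neighbour; using its own score")
      next
    }
    out[j] <- sum(raw[nb$id] / nb$dist) / nrow(nb)
  }
  out
}

## nearest junction players reachable from j walking through helix
## players only, with their hop distances
.junctionNeighbors <- function(graph, j) {
  adj <- .adjList(graph)
  pl <- graph@players
  res <- list()
  frontier <- data.frame(id = j, dist = 0L)
  seen <- j
  while (nrow(frontier)) {
    nxt <- list()
    for (r in seq_len(nrow(frontier))) {
      v <- frontier$id[r]
      for (w in setdiff(adj[[v]], seen)) {
        seen <- c(seen, w)
        if (pl$ptype[w] == "HELIX") {
          nxt[[length(nxt) + 1L]] <- data.frame(id = w,
                                                dist = frontier$dist[r] + 1L)
        } else {
          res[[length(res) + 1L]] <- data.frame(id = w,
                                                dist = frontier$dist[r] + 1L)
        }
      }
    }
    frontier <- if (length(nxt)) do.call(rbind, nxt) else
      data.frame(id = integer(0), dist = integer(0))
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(id = integer(0), dist = integer(0))
}

#' Score of a frozen helix player
#'
#' A frozen helix cannot bend, so its score is borrowed from its
#' surroundings: the scores of its neighbouring junction players, each
#' divided by its hop distance on the graph, averaged over the
#' neighbours.
#'
#' @inheritParams playerScore
#' @return the frozen player's score
#' @export
frozenHelixScore <- function(j, conf, table) {
  raw <- .rawPlayerScores(conf, table)
  nb <- .junctionNeighbors(conf@graph, j)
  if (!nrow(nb)) {
    warning("frozen helix player ", j,
            " has no junction neighbour; using its own score")
    return(raw[j])
  }
  sum(raw[nb$id] / nb$dist) / nrow(nb)
}

#' Total score of a conformation
#'
#' Sum of all player scores; Energy = -TotalScore is used for
#' energy-vs-RMSD diagnostics.
#'
#' @inheritParams playerScore
#' @return the total score
#' @export
totalScore <- function(conf, table) {
  sum(playerScores(conf, table))
}

#' Write / read a PairScoreTable as JSON
#'
#' The file maps "TYPE_A|TYPE_B" keys to the fitted parameters of one
#' functional form.
#'
#' @param table a [PairScoreTable-class]
#' @param path file path
#' @return `readScoreTable` returns the [PairScoreTable-class];
#'   `writeScoreTable` the path, invisibly
#' @export
writeScoreTable <- function(table, path) {
  obj <- list(form = table@form, entries = table@entries)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeScoreTable
#' @export
readScoreTable <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- lapply(obj$entries, function(e) {
    e$A <- as.numeric(e$A)
    e$B <- if (is.null(e$B)) NA_real_ else as.numeric(e$B)
    e$norm <- as.numeric(e$norm)
    e$dmax <- as.numeric(e$dmax)
    e$components <- lapply(e$components, function(cmp)
      list(A = as.numeric(cmp$A), mu = as.numeric(cmp$mu),
           sigma = as.numeric(cmp$sigma)))
    e
  })
  new("PairScoreTable", form = obj$form, entries = entries)
}

#' Synthetic PairScoreTable covering a graph's type pairs
#'
#' Builds a table with stated (not fitted) parameters for every type
#' pair present in a graph: a preferred distance for the LJ forms, a
#' single Gaussian component, unit normalization for INV_SQ at 1 A.
#' Useful for tests and toy games where no reference ensemble exists.
#'
#' @param graph an [RNAGraph-class]
#' @param form scoring form
#' @param B preferred distance (Angstrom) for all pairs
#' @param sigma Gaussian width for the GAUSS form
#' @return a [PairScoreTable-class]
#' @export
uniformScoreTable <- function(graph, form = "MODIFIED_LJ", B = 15,
                              sigma = 3) {
  types <- unique(graph@players$ptype)
  keys <- unique(as.vector(outer(types, types, Vectorize(pairKey))))
  entry <- switch(form,
    LJ = ,
    MODIFIED_LJ = list(form = form, A = 1, B = B, components = list(),
                       norm = 1, dmax = 10 * B, dmin = 0.1),
    GAUSS = {
      comp <- list(list(A = 1, mu = B, sigma = sigma))
      list(form = form, A = 1, B = NA_real_, components = comp,
           norm = gaussScore(B, comp), dmax = 10 * B, dmin = 0.1)
    },
    INV_SQ = list(form = form, A = 1, B = NA_real_, components = list(),
                  norm = 1, dmax = 10 * B, dmin = 1))
  entries <- setNames(rep(list(entry), length(keys)), keys)
  new("PairScoreTable", form = form, entries = entries)
}
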