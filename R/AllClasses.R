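#' @import methods
#' @importFrom mclust Mclust mclustBIC
#' @importFrom stats density bw.nrd0 rnorm runif setNames optim dist
#' @importFrom utils head tail
#' @useDynLib rnagame, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Player / SSE type vocabularies -------------------------------------------

.pkgCache <- new.env(parent = emptyenv())

.SSE_KINDS <- c("HELIX", "ONE_WAY", "TWO_WAY", "THREE_WAY", "FOUR_WAY")
.PLAYER_TYPES <- c("HELIX", "ONE_WAY", "TWO_WAY",
                   "THREE_WAY_STACK", "THREE_WAY_BRANCH", "LINKER")
.SCORING_FORMS <- c("LJ", "MODIFIED_LJ", "GAUSS", "INV_SQ")

#' SecondaryStructure: an RNA sequence with a nested set of base pairs
#'
#' Pairs are stored as a two-column integer matrix of 1-based positions
#' (i < j). Pairing must be an involution (each position in at most one
#' pair) and non-crossing (no pseudoknots).
#'
#' @slot sequence single string over A, C, G, U
#' @slot pairs integer matrix with columns i, j (1-based, i < j)
#' @exportClass SecondaryStructure
setClass("SecondaryStructure",
         representation(sequence = "character", pairs = "matrix"))

setValidity("SecondaryStructure", function(object) {
  seq <- object@sequence
  if (length(seq) != 1L || nchar(seq) < 1L)
    return("sequence must be one non-empty string")
  if (grepl("[^ACGU]", seq))
    return("sequence characters must be in {A,C,G,U}")
  p <- object@pairs
  if (ncol(p) != 2L) return("pairs must have two columns")
  if (nrow(p) == 0L) return(TRUE)
  n <- nchar(seq)
  if (any(p < 1L) || any(p > n)) return("pair index out of range")
  if (any(p[, 1L] >= p[, 2L])) return("pairs must satisfy i < j")
  idx <- c(p[, 1L], p[, 2L])
  if (anyDuplicated(idx)) return("pairing is not an involution")
  ## non-crossing: no i < k < j < l with (i,j),(k,l) pairs
  if (nrow(p) > 1L) {
    o <- order(p[, 1L])
    pi <- p[o, 1L]; pj <- p[o, 2L]
    for (a in seq_len(nrow(p) - 1L)) {
      b <- which(pi > pi[a] & pi < pj[a] & pj > pj[a])
      if (length(b)) return("pairs are crossing (pseudoknot)")
    }
  }
  TRUE
})

#' RNAGraph: the coarse-grained player tree of an RNA secondary structure
#'
#' Players (one or more per secondary-structure element) are the nodes;
#' edges follow covalent connectivity and carry a lattice edge length of
#' 1 (between the stack and branch players of one three-way junction) or
#' 2 (all other adjacencies). The graph is always a tree, and `ordering`
#' is a depth-first preorder used as the playing order.
#'
#' @slot players data.frame with columns id, ptype, sse, kind, nBp,
#'   largeHelix, smallTwoWay, frozen and a list column nucleotides
#' @slot edges integer matrix with columns from, to, length
#' @slot ordering integer permutation of player ids (DFS preorder)
#' @slot sses list of SSE descriptors (kind, nucleotides, helices, ...)
#' @exportClass RNAGraph
setClass("RNAGraph",
         representation(players = "data.frame", edges = "matrix",
                        ordering = "integer", sses = "list"))

setValidity("RNAGraph", function(object) {
  np <- nrow(object@players)
  if (np < 1L) return("graph needs at least one player")
  e <- object@edges
  if (np == 1L) {
    if (nrow(e) != 0L) return("single player graph must have no edges")
    return(TRUE)
  }
  if (nrow(e) != np - 1L) return("a tree needs |players| - 1 edges")
  if (!all(e[, 3L] %in% c(1L, 2L))) return("edge lengths must be 1 or 2")
  ## connectivity by union-find
  parent <- seq_len(np)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_len(nrow(e))) {
    a <- find(e[k, 1L]); b <- find(e[k, 2L])
    if (a == b) return("edges contain a cycle")
    parent[a] <- b
  }
  if (length(unique(vapply(seq_len(np), find, 1L))) != 1L)
    return("graph is not connected")
  if (length(object@ordering) &&
      !setequal(object@ordering, seq_len(np)))
    return("ordering is not a permutation of player ids")
  TRUE
})

#' Conformation: an embedding of an RNAGraph on the FCC lattice
#'
#' Positions are integer lattice coordinates (all-even-sum sublattice of
#' Z^3 whose 12 nearest-neighbour vectors are the signed permutations of
#' (1,1,0)). Every tree edge is a straight lattice segment of its stated
#' edge length; positions are distinct and no two edges intersect.
#'
#' @slot positions integer matrix, one row per player, columns x, y, z
#' @slot graph the RNAGraph being embedded
#' @slot step lattice unit in Angstrom (one nearest-neighbour step)
#' @exportClass Conformation
setClass("Conformation",
         representation(positions = "matrix", graph = "RNAGraph",
                        step = "numeric"))

setValidity("Conformation", function(object) {
  pos <- object@positions
  np <- nrow(object@graph@players)
  if (nrow(pos) != np || ncol(pos) != 3L)
    return("positions must be an n_players x 3 matrix")
  if (any(pos != round(pos))) return("positions must be integers")
  if (any(rowSums(pos) %% 2L != 0L))
    return("positions must lie on the even-sum FCC sublattice")
  if (object@step <= 0) return("step must be positive")
  ok <- conformationViolation(pos, object@graph@edges)
  if (!is.null(ok)) return(ok)
  TRUE
})

#' PairScoreTable: fitted pair potentials per SSE-type pair
#'
#' A symmetric map from unordered player-type pairs ("A|B" with A <= B)
#' to the parameters of one scoring functional form. All entries share
#' the same form and are normalized so the supremum of the score over
#' the fitted distance range is 1.
#'
#' @slot form one of "LJ", "MODIFIED_LJ", "GAUSS", "INV_SQ"
#' @slot entries named list of parameter lists (A, B, components, norm, dmax)
#' @exportClass PairScoreTable
setClass("PairScoreTable",
         representation(form = "character", entries = "list"))

setValidity("PairScoreTable", function(object) {
  if (!object@form %in% .SCORING_FORMS) return("unknown scoring form")
  if (length(object@entries) &&
      is.null(names(object@entries))) return("entries must be named")
  TRUE
})

#' GameConfig: the full set of tunables for one sampling game
#'
#' @slot gameplay "AA", "OA" or "OO"
#' @slot algorithm "UCB" or "EXP3"
#' @slot form scoring form used for rewards
#' @slot frozen freeze large helices (straight-line moves + neighbour scoring)
#' @slot turns total turn budget k (OA/OO runs use k / n_players turns)
#' @slot nSamples number of independent games in a sample set
#' @slot seed integer seed
#' @slot ucbC UCB1 exploration constant
#' @slot exp3Gamma EXP3 mixing constant in (0, 1]
#' @exportClass GameConfig
setClass("GameConfig",
         representation(gameplay = "character", algorithm = "character",
                        form = "character", frozen = "logical",
                        turns = "integer", nSamples = "integer",
                        seed = "integer", ucbC = "numeric",
                        exp3Gamma = "numeric"))

setValidity("GameConfig", function(object) {
  if (!object@gameplay %in% c("AA", "OA", "OO")) return("bad gameplay")
  if (!object@algorithm %in% c("UCB", "EXP3")) return("bad algorithm")
  if (!object@form %in% .SCORING_FORMS) return("bad scoring form")
  if (object@turns < 1L) return("turns must be >= 1")
  if (object@nSamples < 1L) return("nSamples must be >= 1")
  if (object@exp3Gamma <= 0 || object@exp3Gamma > 1)
    return("exp3Gamma must be in (0, 1]")
  TRUE
})

#' SampleSet: conformations generated by independent seeded games
#'
#' @slot conformations list of Conformation objects
#' @slot totalScores numeric vector, one total score per sample
#' @slot rmsds numeric vector of RMSDs to a native structure (or NA)
#' @slot config the GameConfig used
#' @slot seeds integer vector of per-run seeds
#' @exportClass SampleSet
setClass("SampleSet",
         representation(conformations = "list", totalScores = "numeric",
                        rmsds = "numeric", config = "GameConfig",
                        seeds = "integer"))

setValidity("SampleSet", function(object) {
  n <- length(object@conformations)
  if (length(object@totalScores) != n || length(object@seeds) != n)
    return("scores/seeds length must match conformations")
  TRUE
})

#' NativeGraph: player coordinates coarse-grained from a native structure
#'
#' @slot graph the RNAGraph the coordinates refer to
#' @slot coords numeric matrix (Angstrom), one row per player
#' @exportClass NativeGraph
setClass("NativeGraph",
         representation(graph = "RNAGraph", coords = "matrix"))

setValidity("NativeGraph", function(object) {
  if (nrow(object@coords) != nrow(object@graph@players))
    return("one coordinate row per player required")
  if (ncol(object@coords) != 3L) return("coords must have 3 columns")
  TRUE
})

## show methods --------------------------------------------------------------

setMethod("show", "SecondaryStructure", function(object) {
  cat(sprintf("SecondaryStructure: %d nt, %d base pairs\n",
              nchar(object@sequence), nrow(object@pairs)))
})

setMethod("show", "RNAGraph", function(object) {
  tab <- table(object@players$ptype)
  cat(sprintf("RNAGraph: %d players (%s), %d edges\n",
              nrow(object@players),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              nrow(object@edges)))
})

setMethod("show", "Conformation", function(object) {
  cat(sprintf("Conformation: %d players on FCC lattice, step %.2f A\n",
              nrow(object@positions), object@step))
})

setMethod("show", "PairScoreTable", function(object) {
  cat(sprintf("PairScoreTable: form %s, %d type pairs\n",
              object@form, length(object@entries)))
})

setMethod("show", "GameConfig", function(object) {
  cat(sprintf(
    "GameConfig: %s/%s/%s, frozen=%s, turns=%d, nSamples=%d, seed=%d\n",
    object@gameplay, object@algorithm, object@form, object@frozen,
    object@turns, object@nSamples, object@seed))
})

setMethod("show", "SampleSet", function(object) {
  cat(sprintf("SampleSet: %d samples, total score range [%.3f, %.3f]\n",
              length(object@conformations),
              suppressWarnings(min(object@totalScores)),
              suppressWarnings(max(object@totalScores))))
})

setMethod("show", "NativeGraph", function(object) {
  cat(sprintf("NativeGraph: %d player coordinates (Angstrom)\n",
              nrow(object@coords)))
})

## accessors ------------------------------------------------------------------

#' Accessors for the core classes
#'
#' `players()`, `edges()` and `playerOrdering()` return the parts of an
#' [RNAGraph-class]; `positions()` the integer lattice coordinates of a
#' [Conformation-class]; `conformations()` the list of samples in a
#' [SampleSet-class].
#'
#' @param x an object of the documented class
#' @return the corresponding slot content
#' @name accessors
#' @export
players <- function(x) x@players

#' @rdname accessors
#' @export
edges <- function(x) x@edges

#' @rdname accessors
#' @export
playerOrdering <- function(x) x@ordering

#' @rdname accessors
#' @export
positions <- function(x) x@positions

#' @rdname accessors
#' @export
conformations <- function(x) x@conformations

#' @rdname accessors
#' @export
totalScores <- function(x) x@totalScores

#' @rdname accessors
#' @export
sampleRMSDs <- function(x) x@rmsds

#' Construct a GameConfig
#'
#' @param gameplay turn schedule: "AA" (all play, all update), "OA" (one
#'   plays, all update) or "OO" (one plays, one updates)
#' @param algorithm bandit algorithm, "UCB" or "EXP3"
#' @param form scoring form, one of "LJ", "MODIFIED_LJ", "GAUSS", "INV_SQ"
#' @param frozen freeze large helices
#' @param turns total turn budget k
#' @param nSamples samples per run
#' @param seed integer seed
#' @param ucbC UCB1 exploration constant
#' @param exp3Gamma EXP3 mixing constant
#' @return a [GameConfig-class]
#' @export
gameConfig <- function(gameplay = "OA", algorithm = "UCB",
                       form = "MODIFIED_LJ", frozen = TRUE,
                       turns = 4000L, nSamples = 50L, seed = 1L,
                       ucbC = 1, exp3Gamma = 0.1) {
  new("GameConfig", gameplay = gameplay, algorithm = algorithm,
      form = form, frozen = frozen, turns = as.integer(turns),
      nSamples = as.integer(nSamples), seed = as.integer(seed),
      ucbC = ucbC, exp3Gamma = exp3Gamma)
}
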