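## ---------------------------------------------------------------------------
## Multi-armed bandits. A bandit is kept per player-edge (a branching
## player owns one bandit per outgoing edge); its 12 arms are the
## canonical FCC directions, with selection restricted to the legal
## subset at each turn. Rewards are normalized scores in [0, 1].
## ---------------------------------------------------------------------------

#' Create an empty bandit state
#'
#' Arms are the 12 canonical FCC directions; `count`/`mean` drive UCB1,
#' `weight` drives EXP3, `t` counts updates. The most recent action and
#' its EXP3 selection probability are kept so that "all players update"
#' schedules can attribute new rewards.
#'
#' @return a bandit state list
#' @export
newBanditState <- function() {
  list(count = rep(0L, 12L), mean = rep(0, 12L), weight = rep(1, 12L),
       t = 0L, last = NA_integer_, lastProb = NA_real_,
       lastLegalN = NA_integer_)
}

#' UCB1 arm selection
#'
#' Among the legal arms, any unpulled arm is selected first (in
#' canonical direction order); otherwise the arm maximizing
#' mean + c sqrt(2 log t / n) is chosen, ties broken by canonical order.
#'
#' @param state bandit state from [newBanditState()]
#' @param legal integer vector of legal arm indices (1..12)
#' @param ucbC exploration constant c
#' @return the selected arm index, or NA if `legal` is empty (skip turn)
#' @export
ucbSelect <- function(state, legal, ucbC = 1) {
  if (!length(legal)) return(NA_integer_)
  unpulled <- legal[state$count[legal] == 0L]
  if (length(unpulled)) return(min(unpulled))
  t <- max(state$t, 1L)
  ucb <- state$mean[legal] +
    ucbC * sqrt(2 * log(t) / state$count[legal])
  legal[which.max(ucb)]
}

#' EXP3 arm selection
#'
#' Samples an arm from p(a) = (1 - gamma) w_a / sum(w) + gamma / K,
#' restricted and renormalized over the legal set (K = number of legal
#' arms). Uses the current RNG stream.
#'
#' @inheritParams ucbSelect
#' @param gamma mixing constant in (0, 1]
#' @return list(action, prob), or action NA if `legal` is empty
#' @export
exp3Select <- function(state, legal, gamma = 0.1) {
  if (!length(legal)) return(list(action = NA_integer_, prob = NA_real_))
  w <- state$weight[legal]
  p <- (1 - gamma) * w / sum(w) + gamma / length(legal)
  p <- p / sum(p)
  k <- sample.int(length(legal), 1L, prob = p)
  list(action = legal[k], prob = p[k])
}

#' UCB1 state update
#'
#' @inheritParams ucbSelect
#' @param action arm played
#' @param reward normalized score in [0, 1] (values outside are clamped
#'   with a warning)
#' @return the updated state
#' @export
updateUcb <- function(state, action, reward) {
  if (reward < 0 || reward > 1) {
    warning("reward ", signif(reward, 4), " outside [0, 1]; clamped")
    reward <- min(max(reward, 0), 1)
  }
  n <- state$count[action] + 1L
  state$count[action] <- n
  state$mean[action] <- state$mean[action] + (reward - state$mean[action]) / n
  state$t <- state$t + 1L
  state
}

#' EXP3 state update
#'
#' Importance-weighted exponential update:
#' w_a <- w_a exp(gamma reward / (p_a K)).
#'
#' @inheritParams updateUcb
#' @param gamma mixing constant
#' @param prob probability with which `action` was drawn
#' @param nLegal size K of the legal set at selection time
#' @return the updated state
#' @export
updateExp3 <- function(state, action, reward, gamma, prob, nLegal) {
  if (is.na(prob) || prob <= 0) stop("internal error: p_a must be > 0")
  if (reward < 0 || reward > 1) {
    warning("reward ", signif(reward, 4), " outside [0, 1]; clamped")
    reward <- min(max(reward, 0), 1)
  }
  state$weight[action] <- state$weight[action] *
    exp(gamma * reward / (prob * nLegal))
  ## guard against overflow on long runs: weights only matter relatively
  if (max(state$weight) > 1e100)
    state$weight <- state$weight / max(state$weight)
  state$t <- state$t + 1L
  state
}

## ---------------------------------------------------------------------------
## Game state and turn schedules
## ---------------------------------------------------------------------------

## edge table of acting (parent, child) pairs in DFS order
.edgeTable <- function(graph, info) {
  ord <- graph@ordering
  rows <- list()
  for (v in ord)
    for (c in info$children[[v]])
      rows[[length(rows) + 1L]] <- c(v, c)
  if (!length(rows)) return(matrix(integer(0), ncol = 2L))
  do.call(rbind, rows)
}

#' Initialize a game
#'
#' Embeds the graph at random and sets up bandit states, the score
#' encoding, and the per-turn trace. All randomness is drawn from the R
#' RNG stream seeded here.
#'
#' @param graph an [RNAGraph-class]
#' @param config a [GameConfig-class]
#' @param table a [PairScoreTable-class] covering the graph's type pairs
#' @param seed run seed (default: the config seed)
#' @return a game environment
#' @export
newGame <- function(graph, config, table, seed = config@seed) {
  set.seed(as.integer(seed))
  info <- .treeInfo(graph)
  conf <- randomEmbedding(graph, seed = NULL)
  enc <- .scoreEncoding(graph, table)
  np <- nrow(graph@players)
  nTurns <- if (config@gameplay == "AA") config@turns else
    max(1L, config@turns %/% np)
  edges <- .edgeTable(graph, info)
  g <- new.env(parent = emptyenv())
  g$graph <- graph; g$config <- config; g$table <- table
  g$info <- info; g$enc <- enc
  g$pos <- conf@positions
  g$initialPos <- conf@positions
  g$step <- conf@step
  g$edges <- edges
  g$bandits <- replicate(nrow(edges), newBanditState(), simplify = FALSE)
  g$nTurns <- nTurns
  g$turn <- 0L
  ## actors for OA/OO round-robin: players owning >= 1 outgoing edge,
  ## in DFS order
  g$actors <- unique(edges[, 1L][order(match(edges[, 1L], graph@ordering))])
  g$rr <- 0L
  g$scoreHist <- matrix(NA_real_, nTurns, np)
  g$posHist <- matrix(NA_integer_, nTurns, 3L * np)
  g$nonAdj <- np - rowSums(enc$adj)        # reward normalizer per player
  g$frozenNb <- lapply(seq_len(np), function(j)
    if (graph@players$frozen[j]) .junctionNeighbors(graph, j) else NULL)
  g$dirs <- neighborDirections()
  g
}

## per-player scores of the current positions (frozen rule applied)
.gameScores <- function(g) {
  raw <- cppPlayerScores(g$pos, g$step, g$enc$adj, g$enc$pairIdx,
                         g$enc$params)
  pl <- g$graph@players
  for (j in which(pl$frozen)) {
    nb <- g$frozenNb[[j]]
    if (!is.null(nb) && nrow(nb))
      raw[j] <- sum(raw[nb$id] / nb$dist) / nrow(nb)
  }
  raw
}

## rewards in [0, 1]: each pair term has sup 1, so a player's score is
## bounded by its number of non-adjacent partners
.gameRewards <- function(g, scores) {
  pmin(pmax(scores / pmax(g$nonAdj, 1L), 0), 1)
}

## legal arm indices (1..12) for acting edge row k, against positions
.legalArms <- function(g, k) {
  v <- g$edges[k, 1L]; c <- g$edges[k, 2L]
  allowed <- .playerAllowed(g$graph, g$info, g$pos, v)
  armIdx <- .armIndex(allowed)
  keep <- cppLegalDirs(g$pos, g$graph@edges, v, c,
                       g$info$elen[v, c],
                       as.integer(g$info$subtree[[c]]), allowed)
  armIdx[keep]
}

## select an arm for edge row k; returns list(action, prob)
.selectArm <- function(g, k, legal) {
  st <- g$bandits[[k]]
  if (g$config@algorithm == "UCB") {
    list(action = ucbSelect(st, legal, g$config@ucbC), prob = NA_real_,
         nLegal = length(legal))
  } else {
    s <- exp3Select(st, legal, g$config@exp3Gamma)
    s$nLegal <- length(legal)
    s
  }
}

## apply arm `a` on edge row k (positions only, assumed legal)
.applyArm <- function(g, k, a) {
  v <- g$edges[k, 1L]; c <- g$edges[k, 2L]
  g$pos <- .applyActionPos(g$pos, g$info, v, c, g$dirs[a, ])
}

## update bandit k with reward, attributing it to `action`
.updateBandit <- function(g, k, action, reward, prob, nLegal) {
  st <- g$bandits[[k]]
  reward <- min(max(reward, 0), 1)
  if (g$config@algorithm == "UCB") {
    st <- updateUcb(st, action, reward)
  } else {
    st <- updateExp3(st, action, reward, g$config@exp3Gamma, prob, nLegal)
  }
  st$last <- action; st$lastProb <- prob; st$lastLegalN <- nLegal
  g$bandits[[k]] <- st
}

#' Play one game turn
#'
#' Applies one turn of the configured schedule:
#' \describe{
#'   \item{AA}{every player-edge selects an action against the
#'     start-of-turn conformation, actions are applied in DFS order with
#'     legality re-checked at application (illegal ones are skipped),
#'     then all acting bandits update with the post-turn rewards.}
#'   \item{OA}{one player (round-robin in DFS order) selects and applies
#'     actions for its outgoing edges; every player-edge then updates
#'     its most recent action with the new rewards.}
#'   \item{OO}{one player plays and only that player's bandits update.}
#' }
#' A player whose legal set is empty skips its turn without updating.
#'
#' @param g game environment from [newGame()]
#' @return the game environment, invisibly
#' @export
playTurn <- function(g) {
  cfg <- g$config
  nE <- nrow(g$edges)
  if (cfg@gameplay == "AA") {
    ## selection phase: all picks are made against the start-of-turn
    ## conformation (g$pos is untouched until the application phase)
    picks <- vector("list", nE)
    for (k in seq_len(nE)) {
      legal <- .legalArms(g, k)
      picks[[k]] <- if (length(legal)) .selectArm(g, k, legal) else
        list(action = NA_integer_, prob = NA_real_, nLegal = 0L)
    }
    applied <- rep(FALSE, nE)
    for (k in seq_len(nE)) {              # application, legality re-check
      a <- picks[[k]]$action
      if (is.na(a)) next
      legalNow <- .legalArms(g, k)
      if (a %in% legalNow) {
        .applyArm(g, k, a)
        applied[k] <- TRUE
      }
    }
    scores <- .gameScores(g)
    rew <- .gameRewards(g, scores)
    for (k in seq_len(nE))
      if (applied[k])
        .updateBandit(g, k, picks[[k]]$action, rew[g$edges[k, 1L]],
                      picks[[k]]$prob, picks[[k]]$nLegal)
  } else {
    g$rr <- g$rr %% length(g$actors) + 1L
    actor <- g$actors[g$rr]
    acted <- list()
    for (k in which(g$edges[, 1L] == actor)) {
      legal <- .legalArms(g, k)
      if (!length(legal)) next
      pick <- .selectArm(g, k, legal)
      .applyArm(g, k, pick$action)
      acted[[length(acted) + 1L]] <- c(k = k, pick)
    }
    scores <- .gameScores(g)
    rew <- .gameRewards(g, scores)
    for (p in acted)
      .updateBandit(g, p$k, p$action, rew[actor], p$prob, p$nLegal)
    if (cfg@gameplay == "OA") {
      ## all other player-edges re-attribute the new reward to their
      ## most recent action
      actedKs <- vapply(acted, function(p) p$k, 1L)
      for (k in setdiff(seq_len(nE), actedKs)) {
        st <- g$bandits[[k]]
        if (!is.na(st$last))
          .updateBandit(g, k, st$last, rew[g$edges[k, 1L]],
                        st$lastProb, st$lastLegalN)
      }
    }
  }
  g$turn <- g$turn + 1L
  if (g$turn <= nrow(g$scoreHist)) {
    g$scoreHist[g$turn, ] <- scores
    g$posHist[g$turn, ] <- as.integer(g$pos)
  }
  invisible(g)
}

#' Run one full game
#'
#' Random initial embedding followed by the configured number of turns
#' (AA: k turns; OA/OO: k / n_players turns). Deterministic given the
#' seed.
#'
#' @inheritParams newGame
#' @return list with `conformation` (final [Conformation-class]),
#'   `trace` (score and position history plus bookkeeping for
#'   [regret()]), and `game` (the final game environment)
#' @export
runGame <- function(graph, config, table, seed = config@seed) {
  g <- newGame(graph, config, table, seed)
  for (i in seq_len(g$nTurns)) playTurn(g)
  conf <- new("Conformation", positions = g$pos, graph = graph,
              step = g$step)
  trace <- list(scoreHist = g$scoreHist[seq_len(g$turn), , drop = FALSE],
                posHist = g$posHist[seq_len(g$turn), , drop = FALSE],
                initialPos = g$initialPos, graph = graph,
                table = table, step = g$step, config = config)
  list(conformation = conf, trace = trace, game = g)
}

#' Regret of a player after T turns
#'
#' Regret_i(T) = -sum_t score_i(t) + max_p sum_t score'_i(t), the best
#' fixed strategy p being evaluated counterfactually against the
#' recorded positions of the other players (the player's child subtree
#' is re-placed with the fixed direction at every recorded turn). The
#' strategy set is the player's allowed direction set at its initial
#' orientation; a player without an outgoing edge has no strategies and
#' zero regret.
#'
#' @param trace trace from [runGame()]
#' @param player player id
#' @param T number of turns (default: all recorded)
#' @return the regret value at T
#' @export
regret <- function(trace, player, T = nrow(trace$scoreHist)) {
  curve <- regretCurve(trace, player)
  if (T == 0L) return(0)
  curve[T]
}

#' @rdname regret
#' @param trace trace from [runGame()]
#' @return `regretCurve` returns the full regret trajectory over turns
#' @export
regretCurve <- function(trace, player) {
  graph <- trace$graph
  info <- .treeInfo(graph)
  T <- nrow(trace$scoreHist)
  kids <- info$children[[player]]
  if (!length(kids)) return(rep(0, T))
  child <- kids[1L]
  enc <- .scoreEncoding(graph, trace$table)
  dirs <- neighborDirections()
  incoming <- .incomingDir(trace$initialPos, info, player)
  allowed <- .allowedForPlayer(graph@players, player, incoming)
  cumCf <- matrix(NA_real_, T, nrow(allowed))
  for (r in seq_len(nrow(allowed))) {
    cf <- cppCounterfactualScores(trace$posHist, player, child,
                                  info$elen[player, child],
                                  as.integer(info$subtree[[child]]),
                                  as.integer(allowed[r, ]), trace$step,
                                  enc$adj, enc$pairIdx, enc$params)
    cumCf[, r] <- cumsum(cf)
  }
  best <- apply(cumCf, 1L, max)
  -cumsum(trace$scoreHist[, player]) + best
}

#' Generate a sample set of conformations
#'
#' Runs `config@nSamples` independent games with seeds seed, seed+1, ...
#' and keeps the final conformation of each.
#'
#' @inheritParams newGame
#' @param native optional [NativeGraph-class]; when given, the RMSD of
#'   each sample to the native coordinates is stored
#' @return a [SampleSet-class]
#' @export
sampleConformations <- function(graph, config, table, native = NULL) {
  seeds <- config@seed + seq_len(config@nSamples) - 1L
  confs <- vector("list", length(seeds))
  scores <- numeric(length(seeds))
  rmsds <- rep(NA_real_, length(seeds))
  for (i in seq_along(seeds)) {
    res <- runGame(graph, config, table, seed = seeds[i])
    confs[[i]] <- res$conformation
    scores[i] <- totalScore(res$conformation, table)
    if (!is.null(native))
      rmsds[i] <- rmsd(toCartesian(res$conformation), native@coords)
  }
  new("SampleSet", conformations = confs, totalScores = scores,
      rmsds = rmsds, config = config, seeds = as.integer(seeds))
}

#' Default gameplay settings for a molecule
#'
#' Molecules without a three-way junction use the OA game, the UCB
#' algorithm, the modified Lennard-Jones potential and frozen helices.
#' With a three-way junction present, the AA game and the EXP3 algorithm
#' are used, unfrozen, with the Lennard-Jones potential when the
#' helix/junction player ratio exceeds 1.5 and the modified
#' Lennard-Jones otherwise.
#'
#' @param graph an [RNAGraph-class]
#' @param turns,nSamples,seed,ucbC,exp3Gamma passed to [gameConfig()]
#' @return a [GameConfig-class]
#' @export
defaultGameplay <- function(graph, turns = 4000L, nSamples = 50L,
                            seed = 1L, ucbC = 1, exp3Gamma = 0.1) {
  has3way <- any(graph@players$ptype %in%
                 c("THREE_WAY_STACK", "THREE_WAY_BRANCH"))
  if (!has3way) {
    gameConfig("OA", "UCB", "MODIFIED_LJ", frozen = TRUE, turns = turns,
               nSamples = nSamples, seed = seed, ucbC = ucbC,
               exp3Gamma = exp3Gamma)
  } else {
    form <- if (helixJunctionRatio(graph) > 1.5) "LJ" else "MODIFIED_LJ"
    gameConfig("AA", "EXP3", form, frozen = FALSE, turns = turns,
               nSamples = nSamples, seed = seed, ucbC = ucbC,
               exp3Gamma = exp3Gamma)
  }
}
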