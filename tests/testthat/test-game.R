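test_that("UCB selection explores unpulled arms then exploits", {
  st <- newBanditState()
  ## all arms unpulled: first legal arm in canonical order
  expect_equal(ucbSelect(st, c(7L, 3L, 9L)), 3L)
  ## exploitation dominates with equal large counts
  st$count[c(1L, 2L)] <- 1000L
  st$mean[1L] <- 0.9; st$mean[2L] <- 0.1
  st$t <- 2000L
  expect_equal(ucbSelect(st, c(1L, 2L)), 1L)
  ## empty legal set: skip signal
  expect_true(is.na(ucbSelect(st, integer(0))))
})

test_that("UCB updates keep exact running means", {
  st <- newBanditState()
  st <- updateUcb(st, 4L, 1)
  expect_equal(st$mean[4L], 1)
  st <- updateUcb(st, 4L, 0)
  expect_equal(st$mean[4L], 0.5)
  ## batch-mean oracle on a random reward stream
  set.seed(11)
  rewards <- runif(50)
  st <- newBanditState()
  for (r in rewards) st <- updateUcb(st, 2L, r)
  expect_equal(st$mean[2L], mean(rewards))
  expect_equal(st$count[2L], 50L)
  expect_warning(updateUcb(st, 2L, 1.5), "clamped")
})

test_that("EXP3 sampling respects its mixed distribution", {
  set.seed(21)
  st <- newBanditState()
  ## uniform weights: uniform over the legal set
  draws <- replicate(6000, exp3Select(st, 1:4, gamma = 0.2)$action)
  counts <- table(draws)
  expect_equal(length(counts), 4L)
  expect_true(all(abs(counts - 1500) <= 3 * sqrt(6000 * 0.25 * 0.75)))
  ## gamma = 1: uniform regardless of the weights
  st$weight[1L] <- 100
  draws <- replicate(6000, exp3Select(st, 1:2, gamma = 1)$action)
  expect_true(abs(mean(draws == 1L) - 0.5) < 0.03)
  ## probabilities sum to one over the legal set
  s <- exp3Select(st, c(2L, 5L, 8L), gamma = 0.3)
  expect_true(s$action %in% c(2L, 5L, 8L))
  ## single-action legal set: probability 1
  s1 <- exp3Select(st, 5L, gamma = 0.1)
  expect_equal(s1$prob, 1)
})

test_that("EXP3 updates follow the importance-weighted formula", {
  st <- newBanditState()
  ## zero reward leaves weights unchanged
  st2 <- updateExp3(st, 3L, 0, gamma = 0.1, prob = 0.5, nLegal = 4L)
  expect_equal(st2$weight, st$weight)
  ## straight-line re-implementation over a seeded trajectory
  set.seed(31)
  st <- newBanditState()
  wOracle <- rep(1, 12L)
  for (i in 1:200) {
    legal <- sort(sample.int(12L, 5L))
    pick <- exp3Select(st, legal, gamma = 0.15)
    r <- runif(1)
    st <- updateExp3(st, pick$action, r, gamma = 0.15, prob = pick$prob,
                     nLegal = length(legal))
    wOracle[pick$action] <- wOracle[pick$action] *
      exp(0.15 * r / (pick$prob * length(legal)))
  }
  expect_equal(st$weight, wOracle)
  expect_error(updateExp3(st, 1L, 0.5, 0.1, prob = 0, nLegal = 3L),
               "p_a")
})

test_that("UCB finds the best arm of a two-armed Bernoulli bandit", {
  set.seed(41)
  st <- newBanditState()
  pulls <- integer(1e4)
  for (t in seq_along(pulls)) {
    a <- ucbSelect(st, c(1L, 2L), ucbC = 1)
    r <- rbinom(1L, 1L, if (a == 1L) 0.9 else 0.1)
    st <- updateUcb(st, a, r)
    pulls[t] <- a
  }
  expect_gte(mean(tail(pulls, 1000L) == 1L), 0.8)
})

test_that("EXP3 finds the best arm of a two-armed Bernoulli bandit", {
  set.seed(42)
  st <- newBanditState()
  pulls <- integer(1e4)
  for (t in seq_along(pulls)) {
    s <- exp3Select(st, c(1L, 2L), gamma = 0.1)
    r <- rbinom(1L, 1L, if (s$action == 1L) 0.9 else 0.1)
    st <- updateExp3(st, s$action, r, gamma = 0.1, prob = s$prob,
                     nLegal = 2L)
    pulls[t] <- s$action
  }
  expect_gte(mean(tail(pulls, 1000L) == 1L), 0.7)
})

test_that("the default gameplay rule follows molecule features", {
  ## no three-way junction: OA / UCB / modified LJ / frozen
  cfg <- defaultGameplay(hairpinGraph())
  expect_equal(cfg@gameplay, "OA")
  expect_equal(cfg@algorithm, "UCB")
  expect_equal(cfg@form, "MODIFIED_LJ")
  expect_true(cfg@frozen)

  ## three-way junction with helix/junction ratio 2.0: AA / EXP3 / LJ
  gBig <- threeWayGraph(helixLengths = c(20L, 10L, 10L))
  expect_equal(helixJunctionRatio(gBig), 2.0)
  cfg <- defaultGameplay(gBig)
  expect_equal(cfg@gameplay, "AA")
  expect_equal(cfg@algorithm, "EXP3")
  expect_equal(cfg@form, "LJ")
  expect_false(cfg@frozen)

  ## three-way junction with ratio below 1.5: modified LJ
  gSmall <- threeWayGraph()
  expect_lte(helixJunctionRatio(gSmall), 1.5)
  cfg <- defaultGameplay(gSmall)
  expect_equal(cfg@gameplay, "AA")
  expect_equal(cfg@algorithm, "EXP3")
  expect_equal(cfg@form, "MODIFIED_LJ")
})

test_that("gameplays coincide on a single-edge graph with UCB", {
  g <- hairpinGraph()
  tab <- uniformScoreTable(g, "MODIFIED_LJ", B = 11.2)
  ## one player owns the only edge: AA with k turns equals OA/OO with
  ## 2k (budget divided by the 2 players), under the same seed
  resAA <- runGame(g, gameConfig("AA", "UCB", turns = 6L), tab, seed = 5)
  resOA <- runGame(g, gameConfig("OA", "UCB", turns = 12L), tab, seed = 5)
  resOO <- runGame(g, gameConfig("OO", "UCB", turns = 12L), tab, seed = 5)
  expect_identical(positions(resAA$conformation),
                   positions(resOA$conformation))
  expect_identical(positions(resAA$conformation),
                   positions(resOO$conformation))
})

test_that("turn schedules touch the right number of players", {
  g3 <- threeWayGraph()
  tab <- uniformScoreTable(g3, "MODIFIED_LJ", B = 11.2)
  info <- rnagame:::.treeInfo(g3)
  ## an OO turn moves at most one subtree (one acting player)
  gm <- newGame(g3, gameConfig("OO", "UCB", turns = 50L), tab, seed = 9)
  for (i in 1:10) {
    before <- gm$pos
    playTurn(gm)
    movedPlayers <- which(rowSums(gm$pos != before) > 0L)
    if (length(movedPlayers)) {
      ## all moved players lie in subtrees hanging from one actor
      actor <- gm$actors[gm$rr]
      kids <- info$children[[actor]]
      allowedSet <- unlist(info$subtree[kids])
      expect_true(all(movedPlayers %in% allowedSet))
    }
  }
  ## conformation invariants hold after every turn of every schedule
  for (gp in c("AA", "OA", "OO")) {
    algo <- if (gp == "AA") "EXP3" else "UCB"
    gm <- newGame(g3, gameConfig(gp, algo, turns = 60L), tab, seed = 3)
    for (i in seq_len(gm$nTurns)) {
      playTurn(gm)
      expect_null(rnagame:::conformationViolation(gm$pos, edges(g3)))
    }
  }
})

test_that("games are deterministic given the seed", {
  g3 <- threeWayGraph()
  cfg <- defaultGameplay(g3, turns = 120L, nSamples = 3L)
  tab <- uniformScoreTable(g3, cfg@form, B = 11.2)
  r1 <- runGame(g3, cfg, tab, seed = 77)
  r2 <- runGame(g3, cfg, tab, seed = 77)
  expect_identical(positions(r1$conformation), positions(r2$conformation))
  expect_identical(r1$trace$scoreHist, r2$trace$scoreHist)
  ## full sample sets are bit-identical too
  s1 <- sampleConformations(g3, cfg, tab)
  s2 <- sampleConformations(g3, cfg, tab)
  expect_identical(lapply(s1@conformations, positions),
                   lapply(s2@conformations, positions))
  expect_identical(s1@totalScores, s2@totalScores)
})

test_that("sampling yields the requested number of distinct samples", {
  g3 <- threeWayGraph()
  cfg <- defaultGameplay(g3, turns = 80L, nSamples = 8L)
  tab <- uniformScoreTable(g3, cfg@form, B = 11.2)
  set <- sampleConformations(g3, cfg, tab)
  expect_equal(length(conformations(set)), 8L)
  keys <- vapply(conformations(set), function(cf)
    paste(positions(cf), collapse = ","), "")
  expect_gt(length(unique(keys)), 1L)
})

test_that("games improve the total score more often than not", {
  ## the hairpin toy has only the adjacent pair, so its total score is
  ## identically zero and can never deteriorate
  gh <- hairpinGraph()
  tabh <- uniformScoreTable(gh, "MODIFIED_LJ", B = 11.2)
  cfgh <- gameConfig("OA", "UCB", "MODIFIED_LJ", frozen = FALSE,
                     turns = 40L)
  for (s in 1:5) {
    res <- runGame(gh, cfgh, tabh, seed = s)
    expect_true(all(res$trace$scoreHist == 0))
  }
  ## optimization sanity on a 4-player chain with interacting pairs:
  ## the mean total score over the last quarter of the run should beat
  ## the first quarter in most seeded runs (the very last turn is noisy
  ## because UCB keeps exploring untried arms)
  g <- bulgedGraph()
  tab <- uniformScoreTable(g, "MODIFIED_LJ", B = 11.2)
  cfg <- gameConfig("OA", "UCB", "MODIFIED_LJ", frozen = FALSE,
                    turns = 1200L)
  better <- 0L
  for (s in 1:30) {
    res <- runGame(g, cfg, tab, seed = s)
    tot <- rowSums(res$trace$scoreHist)
    q <- length(tot) %/% 4L
    if (mean(tail(tot, q)) >= mean(head(tot, q))) better <- better + 1L
  }
  expect_gte(better / 30, 0.7)
})

test_that("regret matches a brute-force counterfactual evaluation", {
  g3 <- threeWayGraph()
  cfg <- gameConfig("AA", "EXP3", "MODIFIED_LJ", frozen = FALSE,
                    turns = 40L)
  tab <- uniformScoreTable(g3, cfg@form, B = 11.2)
  res <- runGame(g3, cfg, tab, seed = 13)
  trace <- res$trace
  info <- rnagame:::.treeInfo(g3)
  player <- playerOrdering(g3)[1L]      # the three-way stack player
  child <- info$children[[player]][1L]
  len <- info$elen[player, child]
  sub <- info$subtree[[child]]
  np <- nrow(players(g3))
  dirs <- neighborDirections()
  ## brute force: for each fixed strategy, re-place the child at every
  ## recorded turn and recompute the player's score in plain R
  cum <- matrix(0, nrow(trace$scoreHist), 12L)
  for (r in 1:12) {
    for (t in seq_len(nrow(trace$posHist))) {
      pos <- matrix(trace$posHist[t, ], np, 3L)
      delta <- pos[player, ] + len * dirs[r, ] - pos[child, ]
      pos[sub, ] <- sweep(pos[sub, , drop = FALSE], 2L, delta, "+")
      ## counterfactual placements may be geometrically illegal; the
      ## regret only needs their scores, so score raw positions directly
      cum[t, r] <- oraclePlayerScoresPos(pos, trace$step, g3,
                                         tab)[player]
    }
  }
  cumBest <- apply(apply(cum, 2L, cumsum), 1L, max)
  oracleRegret <- -cumsum(trace$scoreHist[, player]) + cumBest
  expect_equal(regretCurve(trace, player), oracleRegret,
               tolerance = 1e-8)
  expect_equal(regret(trace, player, T = 40L), oracleRegret[40L],
               tolerance = 1e-8)
})

test_that("single-strategy players with constant scores have zero regret", {
  ## static trace: a frozen helix player has one strategy (its incoming
  ## direction), and when nothing moves the counterfactual equals the
  ## actual play, so the regret vanishes identically
  gl <- longHelixGraph(12L, frozen = TRUE)
  cfg <- gameConfig("OA", "UCB", "MODIFIED_LJ", frozen = TRUE,
                    turns = 10L)
  tab <- uniformScoreTable(gl, cfg@form, B = 11.2)
  conf <- randomEmbedding(gl, seed = 2)
  raw <- rnagame:::.rawPlayerScores(conf, tab)
  T <- 10L
  trace <- list(
    scoreHist = matrix(rep(raw, each = T), T),
    posHist = matrix(rep(as.integer(positions(conf)), each = T), T),
    initialPos = positions(conf), graph = gl, table = tab,
    step = conf@step, config = cfg)
  pl <- players(gl)
  info <- rnagame:::.treeInfo(gl)
  frozenNonRoot <- which(pl$frozen & info$parent != 0L &
                           lengths(info$children) > 0L)
  expect_gte(length(frozenNonRoot), 1L)
  for (j in frozenNonRoot) {
    inc <- rnagame:::.incomingDir(positions(conf), info, j)
    expect_equal(nrow(rnagame:::.allowedForPlayer(pl, j, inc)), 1L)
    expect_equal(regretCurve(trace, j), rep(0, T), tolerance = 1e-10)
  }
  ## leaf players have no strategies at all
  leaf <- which(lengths(info$children) == 0L)[1L]
  expect_equal(regret(trace, leaf), 0)
  expect_equal(regret(trace, frozenNonRoot[1L], T = 0L), 0)
})
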