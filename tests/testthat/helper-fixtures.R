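# shared toy structures

hairpinGraph <- function(helix = 4L, loop = 4L, frozen = FALSE) {
  fx <- makeFixture("HAIRPIN", helixLengths = helix, loopLengths = loop)
  rnaGraph(parseDotBracket(fx$sequence, fx$structure), frozen = frozen)
}

threeWayGraph <- function(helixLengths = c(4L, 4L, 4L), frozen = FALSE) {
  fx <- makeFixture("THREE_WAY", helixLengths = helixLengths)
  rnaGraph(parseDotBracket(fx$sequence, fx$structure), frozen = frozen)
}

bulgedGraph <- function(frozen = FALSE) {
  fx <- makeFixture("BULGED_HAIRPIN")
  rnaGraph(parseDotBracket(fx$sequence, fx$structure), frozen = frozen)
}

fourWayGraph <- function() {
  fx <- makeFixture("FOUR_WAY")
  rnaGraph(parseDotBracket(fx$sequence, fx$structure))
}

longHelixGraph <- function(bp = 12L, frozen = FALSE) {
  fx <- makeFixture("LONG_HELIX", helixLengths = bp)
  rnaGraph(parseDotBracket(fx$sequence, fx$structure), frozen = frozen)
}
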