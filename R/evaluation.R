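#' Coarse-grain a native 3D structure into player coordinates
#'
#' Each player's coordinate is the geometric centre (unweighted mean) of
#' the heavy (non-hydrogen) atoms of its assigned nucleotides. A
#' three-way STACK player uses the first base pair of the two stacked
#' helices; a BRANCH player all junction heavy atoms.
#'
#' @param pdbPath path to a PDB file whose first model contains the RNA
#'   chain (residues in sequence order)
#' @param graph the [RNAGraph-class] built from the matching secondary
#'   structure
#' @param chain optional chain identifier to select
#' @return a [NativeGraph-class]
#' @export
coarseGrainNative <- function(pdbPath, graph, chain = NULL) {
  pdb <- bio3d::read.pdb(pdbPath, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  ## heavy atoms only
  elt <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                               substr(trimws(at$elety), 1L, 1L),
                               at$elesy)))
  at <- at[elt != "H", , drop = FALSE]
  ## map residues (in order of appearance) to sequence positions
  resKey <- paste(at$chain, at$resno, at$insert, sep = "_")
  resLevels <- unique(resKey)
  n <- max(unlist(graph@players$nucleotides))
  if (length(resLevels) < n)
    stop("mapping error: PDB has ", length(resLevels),
         " residues but the structure needs at least ", n)
  resPos <- match(resKey, resLevels)
  coords <- matrix(NA_real_, nrow(graph@players), 3L)
  for (j in seq_len(nrow(graph@players))) {
    nts <- graph@players$nucleotides[[j]]
    sel <- resPos %in% nts
    if (!any(sel))
      stop("mapping error: no atoms for nucleotides ",
           paste(nts, collapse = ","), " of player ", j)
    coords[j, ] <- c(mean(at$x[sel]), mean(at$y[sel]), mean(at$z[sel]))
  }
  new("NativeGraph", graph = graph, coords = coords)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (determinant +1, reflections excluded) and
#' translation that superpose the point set `m` onto `n` with minimal
#' mean squared distance.
#'
#' @param m,n numeric matrices of matching points (rows), at least 3
#'   non-collinear points
#' @return list(rotation, translation): apply as m %*% rotation +
#'   translation (row-wise)
#' @export
superpose <- function(m, n) {
  m <- as.matrix(m); n <- as.matrix(n)
  if (nrow(m) != nrow(n)) stop("point counts differ")
  if (nrow(m) < 3L) stop("degenerate superposition: fewer than 3 points")
  cm <- colMeans(m); cn <- colMeans(n)
  mc <- sweep(m, 2L, cm); nc <- sweep(n, 2L, cn)
  if (qr(mc)$rank < 2L || qr(nc)$rank < 2L)
    stop("degenerate superposition: collinear points")
  s <- svd(crossprod(mc, nc))              # 3x3
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  list(rotation = R, translation = as.numeric(cn - cm %*% R))
}

#' Root mean square deviation between two player coordinate sets
#'
#' RMSD(m, n) = sqrt(mean over players of the squared distance between
#' matched players), by default after optimal rigid superposition of m
#' onto n (proper rotations only).
#'
#' @param m,n numeric coordinate matrices (Angstrom), same row count
#' @param superposeFirst superpose before measuring
#' @return RMSD in Angstrom
#' @export
rmsd <- function(m, n, superposeFirst = TRUE) {
  m <- as.matrix(m); n <- as.matrix(n)
  if (nrow(m) != nrow(n) || ncol(m) != ncol(n))
    stop("dimension mismatch between coordinate sets")
  if (superposeFirst) {
    tr <- superpose(m, n)
    m <- sweep(m %*% tr$rotation, 2L, tr$translation, "+")
  }
  sqrt(mean(rowSums((m - n)^2)))
}

#' Summarize a sample set against a native structure
#'
#' Computes the superposed RMSD of each sample to the native player
#' coordinates and reports the extremes, the count below a threshold,
#' and (Energy = -TotalScore, RMSD) pairs for funnel diagnostics.
#'
#' @param samples a [SampleSet-class]
#' @param native a [NativeGraph-class] sharing the samples' topology
#' @param threshold RMSD threshold in Angstrom
#' @param table a [PairScoreTable-class] used for the energies (default:
#'   reuse the stored total scores)
#' @return list with rmsd_min, rmsd_max, n_below_threshold, threshold,
#'   rmsds, energy_rmsd_pairs
#' @export
summarizeSamples <- function(samples, native, threshold = 5,
                             table = NULL) {
  nPlayers <- nrow(native@graph@players)
  for (cf in samples@conformations)
    if (nrow(cf@positions) != nPlayers)
      stop("comparison error: sample and native topologies differ")
  rmsds <- vapply(samples@conformations, function(cf)
    rmsd(toCartesian(cf), native@coords), 1)
  energies <- if (is.null(table)) -samples@totalScores else
    -vapply(samples@conformations, totalScore, 1, table = table)
  list(rmsd_min = min(rmsds), rmsd_max = max(rmsds),
       n_below_threshold = sum(rmsds < threshold),
       threshold = threshold, rmsds = rmsds,
       energy_rmsd_pairs = data.frame(energy = energies, rmsd = rmsds))
}

#' Write a sample summary as TSV
#'
#' One row per summarized structure: id, n_players, rmsd_min, rmsd_max,
#' n_below, threshold.
#'
#' @param summaries named list of [summarizeSamples()] results
#' @param nPlayers integer vector of player counts, matching names
#' @param path output path
#' @return invisibly, the path
#' @export
writeSummaryTSV <- function(summaries, nPlayers, path) {
  df <- data.frame(
    id = names(summaries),
    n_players = as.integer(nPlayers),
    rmsd_min = vapply(summaries, `[[`, 1, "rmsd_min"),
    rmsd_max = vapply(summaries, `[[`, 1, "rmsd_max"),
    n_below = vapply(summaries, function(s)
      as.numeric(s$n_below_threshold), 1),
    threshold = vapply(summaries, `[[`, 1, "threshold"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
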