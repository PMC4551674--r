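#' Write conformations as a multi-model pseudo-atom PDB
#'
#' One pseudo-atom per player (record ATOM, atom name "P", residue
#' number = player id, element P), Cartesian Angstrom coordinates, one
#' MODEL block per conformation.
#'
#' @param confs a [Conformation-class], a list of them, or a
#'   [SampleSet-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeSamplesPDB <- function(confs, path) {
  if (is(confs, "SampleSet")) confs <- confs@conformations
  if (is(confs, "Conformation")) confs <- list(confs)
  lines <- character(0)
  for (mdl in seq_along(confs)) {
    xyz <- toCartesian(confs[[mdl]])
    lines <- c(lines, sprintf("MODEL     %4d", mdl))
    for (j in seq_len(nrow(xyz))) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  P   PLR A%4d    %8.3f%8.3f%8.3f  1.00  0.00           P",
        j, j, xyz[j, 1L], xyz[j, 2L], xyz[j, 3L]))
    }
    lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read player coordinates back from a pseudo-atom PDB
#'
#' @param path PDB file written by [writeSamplesPDB()] (or any PDB with
#'   one atom per player per MODEL)
#' @return list of numeric coordinate matrices, one per MODEL
#' @export
readSamplesPDB <- function(path) {
  lines <- readLines(path, warn = FALSE)
  models <- list()
  cur <- NULL
  for (ln in lines) {
    tag <- substr(ln, 1L, 6L)
    if (startsWith(ln, "MODEL")) {
      cur <- list()
    } else if (tag %in% c("ATOM  ", "HETATM")) {
      if (is.null(cur)) cur <- list()
      cur[[length(cur) + 1L]] <- as.numeric(c(
        substr(ln, 31L, 38L), substr(ln, 39L, 46L), substr(ln, 47L, 54L)))
    } else if (startsWith(ln, "ENDMDL")) {
      models[[length(models) + 1L]] <- do.call(rbind, cur)
      cur <- NULL
    }
  }
  if (!is.null(cur) && length(cur))
    models[[length(models) + 1L]] <- do.call(rbind, cur)
  models
}

#' Serialize an RNAGraph to JSON
#'
#' Players (ids, types, base-pair counts, nucleotides), edges with
#' lattice lengths, and the DFS ordering, for inspection and for the
#' evaluation tools.
#'
#' @param graph an [RNAGraph-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeGraphJSON <- function(graph, path) {
  pl <- graph@players
  obj <- list(
    players = lapply(seq_len(nrow(pl)), function(j) list(
      id = pl$id[j], ptype = pl$ptype[j], sse = pl$sse[j],
      kind = pl$kind[j], nBp = pl$nBp[j], frozen = pl$frozen[j],
      nucleotides = pl$nucleotides[[j]])),
    edges = apply(graph@edges, 1L, function(e)
      list(from = e[[1L]], to = e[[2L]], length = e[[3L]])),
    ordering = graph@ordering)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
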