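#' Parse a dot-bracket secondary structure
#'
#' Builds a [SecondaryStructure-class] from a sequence and a dot-bracket
#' string of equal length. Base pairs are found by stack-based bracket
#' matching, which guarantees a nested (pseudoknot-free) involution.
#'
#' @param sequence RNA sequence string over A, C, G, U
#' @param structure dot-bracket string over ".", "(" and ")"
#' @return a [SecondaryStructure-class]
#' @examples
#' parseDotBracket("GGGGAAAACCCC", "((((....))))")
#' @export
parseDotBracket <- function(sequence, structure) {
  sequence <- toupper(sequence)
  if (nchar(sequence) != nchar(structure))
    stop("sequence and structure lines must have equal length")
  ch <- strsplit(structure, "")[[1L]]
  bad <- setdiff(unique(ch), c(".", "(", ")"))
  if (length(bad))
    stop("structure characters must be in {., (, )}; found: ",
         paste(bad, collapse = " "))
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2L)
  open <- integer(0)
  rows <- list()
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      open <- c(open, i)
    } else if (ch[i] == ")") {
      if (!length(open)) stop("unbalanced brackets: unmatched ')' at ", i)
      j <- open[length(open)]
      open <- open[-length(open)]
      rows[[length(rows) + 1L]] <- c(j, i)
    }
  }
  if (length(open))
    stop("unbalanced brackets: ", length(open), " unmatched '('")
  if (length(rows)) {
    pairs <- do.call(rbind, rows)
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  }
  storage.mode(pairs) <- "integer"
  new("SecondaryStructure", sequence = sequence, pairs = pairs)
}

#' Read a dot-bracket (.dbn) file
#'
#' Accepts an optional header line starting with ">" followed by the
#' sequence line and the structure line.
#'
#' @param path file path
#' @return a [SecondaryStructure-class]
#' @export
readDotBracket <- function(path) {
  if (!file.exists(path))
    stop("cannot open dot-bracket file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && startsWith(lines[1L], ">")) lines <- lines[-1L]
  if (length(lines) < 2L)
    stop("dot-bracket file needs a sequence line and a structure line")
  parseDotBracket(trimws(lines[1L]), trimws(lines[2L]))
}

#' Write a dot-bracket (.dbn) file
#'
#' @param ss a [SecondaryStructure-class]
#' @param path output file path
#' @param name header written as ">name"
#' @return invisibly, the path
#' @export
writeDotBracket <- function(ss, path, name = "structure") {
  n <- nchar(ss@sequence)
  db <- rep(".", n)
  if (nrow(ss@pairs)) {
    db[ss@pairs[, 1L]] <- "("
    db[ss@pairs[, 2L]] <- ")"
  }
  writeLines(c(paste0(">", name), ss@sequence,
               paste(db, collapse = "")), path)
  invisible(path)
}

## partner vector: partner[i] = paired index or NA
.partners <- function(ss) {
  n <- nchar(ss@sequence)
  partner <- rep(NA_integer_, n)
  if (nrow(ss@pairs)) {
    partner[ss@pairs[, 1L]] <- ss@pairs[, 2L]
    partner[ss@pairs[, 2L]] <- ss@pairs[, 1L]
  }
  partner
}
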