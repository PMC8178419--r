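#' The canonical amino-acid alphabet
#'
#' The 20 canonical one-letter codes in the fixed order used throughout the
#' package: `A R N D C Q E G H I L K M F P S T W Y V`. This is the order of
#' the value lines in AAindex1 records; every descriptor matrix, feature
#' block and enumeration in the package is documented against it.
#'
#' @return Character vector of 20 single letters.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Coerce input to a triple matrix
#'
#' Residue triples are represented as a character matrix with one row per
#' variant and three columns (`pos1`, `pos2`, `pos3`). Accepted inputs: such
#' a matrix, a length-3 character vector (one triple), a vector of 3-letter
#' strings like `"PLV"`, or a data frame with columns `pos1`, `pos2`, `pos3`.
#'
#' @param x Triples in any accepted form.
#' @return Character matrix, n x 3, columns `pos1..pos3`.
#' @export
as_triples <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3L) stop("triple matrix must have 3 columns", call. = FALSE)
    m <- x
  } else if (is.data.frame(x)) {
    need <- c("pos1", "pos2", "pos3")
    if (!all(need %in% names(x))) {
      stop("data frame must have columns pos1, pos2, pos3", call. = FALSE)
    }
    m <- as.matrix(x[need])
  } else if (is.character(x) && length(x) == 3L && all(nchar(x) == 1L)) {
    m <- matrix(x, nrow = 1L)
  } else if (is.character(x) && all(nchar(x) == 3L)) {
    m <- t(vapply(strsplit(x, ""), identity, character(3)))
  } else {
    stop("cannot interpret input as residue triples", call. = FALSE)
  }
  m <- toupper(m)
  dimnames(m) <- list(NULL, c("pos1", "pos2", "pos3"))
  m
}

#' Collapse a triple matrix to 3-letter strings
#' @param triples Triples in any form accepted by [as_triples()].
#' @return Character vector like `"PLV"`.
#' @export
triple_strings <- function(triples) {
  m <- as_triples(triples)
  paste0(m[, 1L], m[, 2L], m[, 3L])
}

# Validate residue letters; errors name position and offending letter.
check_triples <- function(triples, alphabet = aa_alphabet()) {
  m <- as_triples(triples)
  for (k in 1:3) {
    bad <- which(!(m[, k] %in% alphabet))
    if (length(bad)) {
      stop(sprintf("invalid residue letter '%s' at position %d (row %d)",
                   m[bad[1L], k], k, bad[1L]), call. = FALSE)
    }
  }
  m
}

# Evaluate expr under a temporary RNG seed, restoring global RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
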