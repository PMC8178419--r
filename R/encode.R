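#' Encode a residue triple as a physicochemical feature vector
#'
#' Each of the three mutated positions is mapped to the descriptor values of
#' its residue, and the three blocks are concatenated position-major:
#' position 1 descriptors first, then position 2, then position 3. With the
#' packaged 13-descriptor set this yields 39 features
#' (13 descriptors x 3 positions). Encoding is deterministic and each triple
#' is encoded independently of every other triple.
#'
#' @param triple A single triple (length-3 character vector, `"PLV"` string,
#'   or 1-row matrix).
#' @param table A `descriptor_table`.
#' @return Named numeric vector of length `3 * nrow(table$values)`; names
#'   are `pos<k>_<descriptor_id>`.
#' @export
#' @examples
#' v <- encode_variant(c("P", "L", "V"), paper_descriptors())
#' length(v)  # 39
encode_variant <- function(triple, table) {
  m <- check_triples(triple)
  if (nrow(m) != 1L) stop("encode_variant takes a single triple", call. = FALSE)
  drop(encode_variants(m, table))
}

#' Encode many residue triples into a feature matrix
#'
#' Vectorized form of [encode_variant()]: one row per triple, columns in
#' position-major block layout.
#'
#' @param triples Triples in any form accepted by [as_triples()].
#' @param table A `descriptor_table`.
#' @return Numeric matrix, n x (3 * n_descriptors).
#' @export
encode_variants <- function(triples, table) {
  stopifnot(inherits(table, "descriptor_table"))
  m <- check_triples(triples)
  v <- table$values
  blocks <- lapply(1:3, function(k) t(v[, m[, k], drop = FALSE]))
  out <- do.call(cbind, blocks)
  colnames(out) <- as.vector(vapply(1:3, function(k) {
    paste0("pos", k, "_", rownames(v))
  }, character(nrow(v))))
  rownames(out) <- NULL
  out
}

#' Fit a per-feature standardizer
#'
#' Computes per-column mean and standard deviation (population convention,
#' divisor n) for standardizing feature matrices before L1-penalized
#' fitting, where the penalty is scale-sensitive. Constant columns are
#' flagged and mapped to zero by [apply_scaler()] rather than dividing by
#' zero.
#'
#' @param x Numeric matrix with at least 2 rows.
#' @return A `scaler_params` object: list of `mean`, `sd`, `constant`
#'   (logical per column).
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to fit a scaler", call. = FALSE)
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  structure(list(mean = mu, sd = sdev, constant = sdev == 0),
            class = "scaler_params")
}

#' Apply a fitted standardizer
#'
#' @param x Numeric matrix with the same columns the scaler was fitted on.
#' @param params A `scaler_params` from [fit_scaler()].
#' @return Standardized matrix; fitted columns have mean 0 and population
#'   sd 1, constant columns are all zero.
#' @export
apply_scaler <- function(x, params) {
  stopifnot(inherits(params, "scaler_params"))
  x <- as.matrix(x)
  if (ncol(x) != length(params$mean)) {
    stop(sprintf("scaler fitted on %d columns, matrix has %d",
                 length(params$mean), ncol(x)), call. = FALSE)
  }
  out <- sweep(x, 2L, params$mean)
  divisor <- ifelse(params$constant, 1, params$sd)
  out <- sweep(out, 2L, divisor, "/")
  out[, params$constant] <- 0
  out
}
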