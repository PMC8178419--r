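#' Load a table of amino-acid physicochemical descriptor scales
#'
#' Reads descriptor scales (one numeric value per canonical amino acid per
#' descriptor) from either a CSV file with header
#' `descriptor_id,description,citation,A,R,N,D,...,V` or an AAindex1
#' flat-file (`H`/`D`/`I` record structure, two value lines of ten entries).
#' Columns are reordered into the fixed alphabet order of [aa_alphabet()]
#' regardless of the source ordering.
#'
#' AAindex1 records with `NA` for any amino acid are rejected with an error
#' naming the affected amino acids; duplicated descriptor ids are an error.
#'
#' @param path Path to the source file.
#' @param format `"csv"` or `"aaindex1"`; `"auto"` (default) decides by file
#'   extension (`.csv` vs anything else).
#' @return A `descriptor_table`: list with `info` (data frame of
#'   `descriptor_id`, `description`, `citation`) and `values` (numeric
#'   matrix, one row per descriptor, 20 columns in alphabet order).
#' @seealso [paper_descriptors()] for the packaged 13-descriptor set.
#' @export
load_descriptor_table <- function(path, format = c("auto", "csv", "aaindex1")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "aaindex1"
  }
  tab <- switch(format,
    csv = read_descriptor_csv(path),
    aaindex1 = read_aaindex1(path)
  )
  validate_descriptor_table(tab)
}

new_descriptor_table <- function(info, values) {
  rownames(values) <- info$descriptor_id
  colnames(values) <- aa_alphabet()
  structure(list(info = info, values = values), class = "descriptor_table")
}

validate_descriptor_table <- function(tab) {
  stopifnot(inherits(tab, "descriptor_table"))
  ids <- tab$info$descriptor_id
  if (anyDuplicated(ids)) {
    stop("duplicate descriptor_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (ncol(tab$values) != 20L || !identical(colnames(tab$values), aa_alphabet())) {
    stop("descriptor values must have the 20 canonical amino-acid columns",
         call. = FALSE)
  }
  if (anyNA(tab$values)) {
    bad <- which(apply(is.na(tab$values), 1L, any))
    for (i in bad) {
      aas <- colnames(tab$values)[is.na(tab$values[i, ])]
      stop(sprintf("descriptor '%s' has missing values for amino acid(s): %s",
                   ids[i], paste(aas, collapse = ", ")), call. = FALSE)
    }
  }
  tab
}

read_descriptor_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("descriptor_id", "description", "citation", aa_alphabet())
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("descriptor CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  info <- df[c("descriptor_id", "description", "citation")]
  values <- as.matrix(df[aa_alphabet()])
  storage.mode(values) <- "double"
  new_descriptor_table(info, values)
}

# AAindex1 flat-file: records delimited by "//"; "H" line holds the
# accession, "D" the description, "R"/"A"/"T"/"J" literature fields, and the
# "I" record holds 20 values on the two following lines (A R N D C Q E G H I
# then L K M F P S T W Y V).
read_aaindex1 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(c(0, head(lines, -1) == "//")))
  info <- list(); values <- list()
  for (rec in recs) {
    rec <- rec[rec != "//" & nzchar(trimws(rec))]
    if (!length(rec)) next
    tag <- substring(rec, 1L, 1L)
    h <- trimws(substring(rec[tag == "H"][1L], 2L))
    d <- paste(trimws(substring(rec[tag == "D"], 2L)), collapse = " ")
    r <- rec[tag == "R"]
    cit <- if (length(r)) trimws(substring(r[1L], 2L)) else ""
    i_at <- which(tag == "I")
    if (is.na(h) || !length(i_at)) {
      stop("malformed AAindex1 record (missing H or I line)", call. = FALSE)
    }
    val_lines <- rec[i_at + 1:2]
    toks <- unlist(strsplit(trimws(val_lines), "[[:space:]]+"))
    if (length(toks) != 20L) {
      stop(sprintf("AAindex1 record '%s': expected 20 values, found %d",
                   h, length(toks)), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(toks))
    v[toks %in% c("NA", "NA.")] <- NA_real_
    if (anyNA(v)) {
      stop(sprintf("descriptor '%s' has missing values for amino acid(s): %s",
                   h, paste(aa_alphabet()[is.na(v)], collapse = ", ")),
           call. = FALSE)
    }
    info[[length(info) + 1L]] <- data.frame(
      descriptor_id = h, description = d, citation = cit,
      stringsAsFactors = FALSE)
    values[[length(values) + 1L]] <- v
  }
  if (!length(values)) stop("no AAindex1 records found in ", path, call. = FALSE)
  new_descriptor_table(do.call(rbind, info), do.call(rbind, values))
}

#' The packaged 13-descriptor set
#'
#' Loads the curated table of 13 physicochemical scales used for encoding
#' loop triples: isoelectric point, normalized van der Waals volume,
#' alpha-helix and beta-strand indices for beta-proteins, side-chain
#' contribution to protein stability, a knowledge-based atom-atom potential
#' stability scale, hydropathy index, normalized frequency of turn, free
#' energies in the beta-strand and alpha-helical regions, polarity, side
#' chain interaction parameter, and amino acid distribution. Rows whose
#' citation is tagged "best-match" carry values transcribed from the named
#' published scale; rows tagged "synthetic best-match values" are curated
#' stand-ins with the qualitative structure of the named property (see the
#' package vignette).
#'
#' @return A `descriptor_table` with 13 rows and 20 amino-acid columns.
#' @export
#' @examples
#' d <- paper_descriptors()
#' dim(d$values)
paper_descriptors <- function() {
  path <- system.file("extdata", "descriptors_13.csv", package = "loopwalk",
                      mustWork = TRUE)
  load_descriptor_table(path, format = "csv")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("descriptor_table: %d descriptors x %d amino acids\n",
              nrow(x$values), ncol(x$values)))
  print(x$info[, c("descriptor_id", "description")], row.names = FALSE)
  invisible(x)
}

#' Select one representative descriptor per correlation cluster
#'
#' Deduplicates a descriptor set by average-linkage hierarchical clustering
#' on the distance `1 - |Pearson r|` between descriptor rows, cut into
#' `n_clusters` clusters. Anti-correlated scales carry the same information,
#' hence the absolute correlation. Each cluster is represented by the member
#' with the highest mean absolute correlation to its co-members (singletons
#' represent themselves; ties go to the earlier input row). Zero-variance
#' descriptors cannot be correlated and are dropped with a warning before
#' clustering.
#'
#' @param table A `descriptor_table`.
#' @param n_clusters Number of clusters to cut the tree into.
#' @return A `descriptor_table` of `n_clusters` representatives, in input
#'   order, with a `clusters` attribute giving the full cluster assignment.
#' @export
select_representative_descriptors <- function(table, n_clusters) {
  stopifnot(inherits(table, "descriptor_table"), n_clusters >= 1)
  v <- table$values
  vars <- apply(v, 1L, stats::var)
  usable <- vars > 0
  if (any(!usable)) {
    warning("excluding zero-variance descriptor(s): ",
            paste(rownames(v)[!usable], collapse = ", "), call. = FALSE)
  }
  v <- v[usable, , drop = FALSE]
  if (n_clusters > nrow(v)) {
    stop(sprintf("n_clusters (%d) exceeds usable descriptors (%d)",
                 n_clusters, nrow(v)), call. = FALSE)
  }
  cmat <- abs(cor(t(v)))
  hc <- hclust(as.dist(1 - cmat), method = "average")
  cl <- cutree(hc, k = n_clusters)
  reps <- integer(n_clusters)
  for (k in seq_len(n_clusters)) {
    members <- which(cl == k)
    if (length(members) == 1L) {
      reps[k] <- members
    } else {
      score <- vapply(members, function(i) {
        mean(cmat[i, setdiff(members, i)])
      }, numeric(1))
      reps[k] <- members[which.max(score)]
    }
  }
  keep_ids <- rownames(v)[sort(reps)]
  keep <- table$info$descriptor_id %in% keep_ids
  out <- new_descriptor_table(table$info[keep, , drop = FALSE],
                              table$values[keep, , drop = FALSE])
  attr(out, "clusters") <- setNames(cl, rownames(v))
  out
}
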