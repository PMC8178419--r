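# Shared fixtures and independent oracles, built in code.

# Hand transcription of the hydropathy scale in AAindex1 flat-file layout
# (H/D/R/A/T/J record lines, I header, two value lines of ten).
aaindex1_hydropathy_text <- function() {
  c("H KYTJ820101",
    "D Hydropathy index (Kyte-Doolittle, 1982)",
    "R LIT:0807099b PMID:7108955",
    "A Kyte, J. and Doolittle, R.F.",
    "T A simple method for displaying the hydropathic character of a protein",
    "J J. Mol. Biol. 157, 105-132 (1982)",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "    1.800  -4.500  -3.500  -3.500   2.500  -3.500  -3.500  -0.400  -3.200   4.500",
    "    3.800  -3.900   1.900   2.800  -1.600  -0.800  -0.700  -0.900  -1.300   4.200",
    "//")
}

write_aaindex_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".aaindex1",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Descriptor table built directly from a value matrix (rows = descriptors).
make_descriptor_table <- function(values, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("D%02d", seq_len(nrow(values)))
  df <- data.frame(descriptor_id = ids, description = ids, citation = "test",
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(values))
  names(df)[-(1:3)] <- aa_alphabet()
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  on.exit(unlink(path))
  load_descriptor_table(path, format = "csv")
}

# The worked example of raw screen activities (U/mL): wild-type plus the
# three headline triple mutants.
worked_example_screen <- function() {
  data.frame(
    variant_id = c("WT", "P233G/L234E/V235M", "P233D/L234G/V235G",
                   "P233D/L234P/V235S"),
    pos1 = c("P", "G", "D", "D"), pos2 = c("L", "E", "G", "P"),
    pos3 = c("V", "M", "G", "S"),
    activity_no_heat = c(1000, 1580, 1350, 1220),
    residual_activity = c(52, 560, 800, 800),
    stringsAsFactors = FALSE)
}

# Independent brute-force average-linkage agglomeration on a distance
# matrix; returns cluster assignment at k clusters. O(n^3), tiny n only.
brute_force_average_linkage <- function(d, k) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dij < best_d) { best_d <- dij; best <- c(i, j) }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  out <- integer(n)
  for (i in seq_along(clusters)) out[clusters[[i]]] <- i
  out
}

# Identity scaler for hand-built discrimination models.
identity_scaler <- function(p) {
  structure(list(mean = rep(0, p), sd = rep(1, p),
                 constant = rep(FALSE, p)), class = "scaler_params")
}

# Hand-built discrimination model with given weights/intercept.
make_model <- function(weights, intercept, positive = "yes",
                       negative = "no") {
  structure(list(weights = weights, intercept = intercept,
                 lambda = 0.1, scaler = identity_scaler(length(weights)),
                 positive = positive, negative = negative,
                 contrast = "test",
                 training_meta = list(n = NA, label_counts = NULL,
                                      policy = NULL)),
            class = "discrimination_model")
}
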