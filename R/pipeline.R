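#' Read a screening table of mutant activity records
#'
#' Reads the screening TSV/CSV dialect: columns `variant_id`, `pos1`,
#' `pos2`, `pos3`, `activity_no_heat`, `residual_activity`, with the
#' wild-type enzyme flagged by the reserved `variant_id` `"WT"` (required,
#' exactly once). Malformed rows are reported with their row numbers.
#'
#' @param path Path to the table; tab- or comma-separated decided by
#'   extension (`.csv` means comma).
#' @return List with `records` (mutant rows) and `wildtype` (one row).
#' @export
read_screen_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    read.csv(path, sep = sep, stringsAsFactors = FALSE),
    error = function(e) stop("cannot read screening table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!nrow(df)) stop("screening table '", path, "' has no records", call. = FALSE)
  need <- c("variant_id", "pos1", "pos2", "pos3",
            "activity_no_heat", "residual_activity")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("screening table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(df$activity_no_heat) | df$activity_no_heat <= 0)
  if (length(bad)) {
    stop("non-positive activity_no_heat at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(df$residual_activity) | df$residual_activity < 0)
  if (length(bad)) {
    stop("negative residual_activity at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  check_triples(df[c("pos1", "pos2", "pos3")])
  wt <- df$variant_id == "WT"
  if (sum(wt) != 1L) {
    stop(sprintf("expected exactly one wild-type row (variant_id 'WT'), found %d",
                 sum(wt)), call. = FALSE)
  }
  list(records = df[!wt, , drop = FALSE], wildtype = df[wt, , drop = FALSE])
}

#' Run configuration for the full prioritization pipeline
#'
#' @param screen Either a path to a screening table or the list returned by
#'   [read_screen_table()] / a `synthetic_screen`.
#' @param descriptors Either a path to a descriptor source or a
#'   `descriptor_table`; default the packaged 13-descriptor set.
#' @param top_fraction,bottom_fraction Tertile tail proportions.
#' @param policy A [lambda_policy()] used when fitting the two models.
#' @param loocv_policy Policy used inside leave-one-out folds (default
#'   `cv_once`).
#' @param n_high,n_medium Candidate selection sizes.
#' @param seed Seed recorded in outputs and used for inner-fold assignment.
#' @param out_dir Optional directory; when given, the ranking TSV, weight
#'   TSV and report JSON are written there.
#' @return A `run_config` list.
#' @export
run_config <- function(screen, descriptors = NULL,
                       top_fraction = 0.34, bottom_fraction = 0.34,
                       policy = NULL, loocv_policy = NULL,
                       n_high = 20L, n_medium = 20L,
                       seed = 1L, out_dir = NULL) {
  structure(list(screen = screen, descriptors = descriptors,
                 top_fraction = top_fraction,
                 bottom_fraction = bottom_fraction,
                 policy = policy %||% lambda_policy("cv", seed = seed),
                 loocv_policy = loocv_policy %||%
                   lambda_policy("cv_once", seed = seed),
                 n_high = as.integer(n_high), n_medium = as.integer(n_medium),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

resolve_screen <- function(screen) {
  if (inherits(screen, "synthetic_screen")) {
    list(records = screen$records, wildtype = screen$wildtype)
  } else if (is.character(screen)) {
    read_screen_table(screen)
  } else if (is.list(screen) && all(c("records", "wildtype") %in% names(screen))) {
    screen
  } else {
    stop("cannot interpret 'screen' input", call. = FALSE)
  }
}

resolve_descriptors <- function(descriptors) {
  if (is.null(descriptors)) return(paper_descriptors())
  if (inherits(descriptors, "descriptor_table")) return(descriptors)
  load_descriptor_table(descriptors)
}

#' Run the full mutant-prioritization pipeline
#'
#' End-to-end cascade on a screening table: encode the observed triples,
#' compute thermostability activities, stratify into high/medium/low
#' tertiles, fit the stage-1 discriminator (improved = high + medium vs
#' non-improved = low) and the stage-2 discriminator (high vs medium), each
#' validated by leave-one-out cross-validation; enumerate all unobserved
#' triples, keep those predicted improved, rank the survivors by high-class
#' probability, and select validation candidates. Deterministic for a fixed
#' config.
#'
#' @param config A [run_config()].
#' @return A `run_report`: dataset summary, both `loocv_report`s, the two
#'   fitted models, candidate counts per stage, the ranking, selected
#'   candidates, and the stage-2 weight table. When `config$out_dir` is set,
#'   `ranking.tsv`, `weight_table.tsv` and `report.json` are written there.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  scr <- resolve_screen(config$screen)
  dtab <- resolve_descriptors(config$descriptors)
  records <- scr$records
  triples <- as_triples(records[c("pos1", "pos2", "pos3")])
  dup <- duplicated(triple_strings(triples))
  if (any(dup)) {
    stop("duplicate triples in screen with possibly different activities: ",
         paste(unique(triple_strings(triples)[dup]), collapse = ", "),
         call. = FALSE)
  }
  x <- encode_variants(triples, dtab)
  activity <- as.numeric(
    thermostability_activity(records$activity_no_heat,
                             records$residual_activity))
  labels <- stratify_by_tertiles(activity, config$top_fraction,
                                 config$bottom_fraction)
  lab_counts <- table(labels)

  improved <- ifelse(labels == "low", "non-improved", "improved")
  model1 <- fit_lasso_discriminator(x, improved, positive = "improved",
                                    policy = config$policy,
                                    contrast = "improved_vs_nonimproved")
  loocv1 <- loocv(x, improved, positive = "improved",
                  policy = config$loocv_policy)

  hm <- labels %in% c("high", "medium")
  model2 <- fit_lasso_discriminator(x[hm, , drop = FALSE],
                                    as.character(labels[hm]),
                                    positive = "high",
                                    policy = config$policy,
                                    contrast = "high_vs_medium")
  loocv2 <- loocv(x[hm, , drop = FALSE], as.character(labels[hm]),
                  positive = "high", policy = config$loocv_policy)

  candidates <- enumerate_candidate_triples(triples)
  stage1 <- screen_stage1(model1, candidates, dtab)
  ranking <- rank_stage2(model2, stage1$kept, dtab,
                         p_improved = stage1$p_improved)
  selected <- select_top_candidates(ranking, config$n_high, config$n_medium)
  weights <- extract_weight_table(model2, dtab$info$description)

  report <- structure(list(
    dataset = list(n = nrow(records), label_counts = lab_counts,
                   quota = attr(labels, "counts")),
    labels = labels, activity = activity,
    model1 = model1, model2 = model2,
    loocv1 = loocv1, loocv2 = loocv2,
    counts = list(n_space = 20L^3L, n_observed = nrow(triples),
                  n_candidates = nrow(candidates),
                  n_stage1_kept = nrow(stage1$kept),
                  n_stage1_rejected = stage1$n_rejected,
                  n_ranked = nrow(ranking)),
    ranking = ranking, selected = selected, weight_table = weights,
    seed = config$seed,
    version = as.character(utils::packageVersion("loopwalk")),
    config = config
  ), class = "run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_ranking(ranking, file.path(config$out_dir, "ranking.tsv"))
    utils::write.table(
      data.frame(descriptor = rownames(weights), weights,
                 check.names = FALSE),
      file.path(config$out_dir, "weight_table.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_report(report, file.path(config$out_dir, "report.json"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  cat(sprintf("  n = %d mutants; labels: %s\n", x$dataset$n,
              paste(names(x$dataset$label_counts),
                    x$dataset$label_counts, sep = "=", collapse = ", ")))
  cat(sprintf("  LOOCV accuracy: stage 1 %.3f, stage 2 %.3f\n",
              x$loocv1$accuracy, x$loocv2$accuracy))
  cat(sprintf("  candidates: %d enumerated, %d kept by stage 1, %d ranked\n",
              x$counts$n_candidates, x$counts$n_stage1_kept,
              x$counts$n_ranked))
  invisible(x)
}

#' Write a candidate ranking as TSV
#'
#' Columns: `rank, pos1, pos2, pos3, p_high` and, when present,
#' `p_improved`. An empty ranking writes a header-only file. Output is
#' byte-stable under re-run with a fixed seed.
#'
#' @param ranking A `candidate_ranking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  cols <- intersect(c("rank", "pos1", "pos2", "pos3", "p_high", "p_improved"),
                    names(ranking))
  utils::write.table(as.data.frame(ranking)[cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a ranking TSV
#' @param path Path written by [write_ranking()].
#' @return A `candidate_ranking` data frame.
#' @export
read_ranking <- function(path) {
  df <- read.csv(path, sep = "\t", stringsAsFactors = FALSE,
                 colClasses = c(pos1 = "character", pos2 = "character",
                                pos3 = "character"))
  if (nrow(df)) df$triple <- paste0(df$pos1, df$pos2, df$pos3)
  else df$triple <- character()
  df <- df[c("rank", "pos1", "pos2", "pos3", "triple",
             intersect(c("p_high", "p_improved"), names(df)))]
  class(df) <- c("candidate_ranking", class(df))
  df
}

#' Write a machine-readable run report (JSON)
#'
#' Serializes the summary statistics of a [run_full_pipeline()] report:
#' dataset size and label counts, LOOCV accuracies, per-stage candidate
#' counts, the selected candidates, the weight table, seed and package
#' version.
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  sel <- lapply(report$selected, function(d) {
    as.data.frame(d)[c("rank", "pos1", "pos2", "pos3", "p_high")]
  })
  out <- list(
    n = report$dataset$n,
    label_counts = as.list(report$dataset$label_counts),
    stratification_quota = as.list(report$dataset$quota),
    loocv_accuracy = list(improved_vs_nonimproved = report$loocv1$accuracy,
                          high_vs_medium = report$loocv2$accuracy),
    counts = report$counts,
    selected = sel,
    weight_table = list(descriptors = rownames(report$weight_table),
                        weights = unname(as.data.frame(report$weight_table))),
    seed = report$seed,
    version = report$version
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
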