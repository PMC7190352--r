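# File formats (CSV point tables, JSON landmarks/configs/results, YAML
# pipeline config) and the end-to-end pipeline runner.

NUCLEUS_COLUMNS <- c("sample_id", "nucleus_id", "x_um", "y_um", "z_um",
                     "ch_signal_mean", "ch_dapi_mean", "is_evl", "is_dividing")

#' Read a nucleus table from CSV
#'
#' Expects one row per detected nucleus with columns `sample_id`,
#' `nucleus_id`, `x_um`, `y_um`, `z_um`, `ch_signal_mean`, `ch_dapi_mean`,
#' `is_evl`, `is_dividing` (optionally `is_low_dapi`, `true_dist_um`). All
#' coordinates are micrometres.
#'
#' @param path CSV file path.
#' @return Nucleus table data frame.
#' @export
read_nucleus_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(tbl, NUCLEUS_COLUMNS, sprintf("nucleus table '%s'", path))
  for (col in c("x_um", "y_um", "z_um", "ch_signal_mean", "ch_dapi_mean")) {
    if (!is.numeric(tbl[[col]])) {
      stop(sprintf("column '%s' in '%s' is not numeric", col, path), call. = FALSE)
    }
  }
  for (col in intersect(c("is_evl", "is_dividing", "is_low_dapi"), names(tbl))) {
    tbl[[col]] <- as.logical(tbl[[col]])
    if (anyNA(tbl[[col]])) {
      stop(sprintf("column '%s' in '%s' is not logical", col, path), call. = FALSE)
    }
  }
  key <- paste(tbl$sample_id, tbl$nucleus_id)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate nucleus_id within a sample in '%s'", path), call. = FALSE)
  }
  tbl
}

#' Write a nucleus table to CSV
#' @param tbl nucleus table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_nucleus_table <- function(tbl, path) {
  require_columns(tbl, NUCLEUS_COLUMNS, "nucleus table")
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a reference set (YSL nuclei or wound-site points)
#'
#' CSV with columns `ref_id`, `x_um`, `y_um`, `z_um`, `kind`.
#'
#' @param path CSV file path.
#' @return Reference set data frame.
#' @export
read_reference_set <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  refs <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(refs, c("ref_id", "x_um", "y_um", "z_um"), "reference set")
  refs
}

#' @rdname read_reference_set
#' @param refs reference set data frame.
#' @export
write_reference_set <- function(refs, path) {
  require_columns(refs, c("ref_id", "x_um", "y_um", "z_um"), "reference set")
  utils::write.csv(refs, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a closed outline as ordered vertex CSV
#' @param path CSV file path with columns `x_um`, `y_um`.
#' @return Outline data frame.
#' @export
read_outline <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  o <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(o, c("x_um", "y_um"), "outline")
  validate_outline(o)
  o
}

#' @rdname read_outline
#' @param outline outline data frame.
#' @export
write_outline <- function(outline, path) {
  require_columns(outline, c("x_um", "y_um"), "outline")
  utils::write.csv(outline, path, row.names = FALSE)
  invisible(path)
}

#' Read / write landmarks as JSON
#' @param path JSON file path.
#' @return Landmark list (`tip`, `back`, optional `extension_base`,
#'   `cavities`, `domain_marks`).
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lm <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(lm$extension_base)) lm$extension_base <- as_uv_matrix(lm$extension_base)
  if (!is.null(lm$cavities)) {
    lm$cavities <- lapply(lm$cavities, function(cv) {
      cv$edges <- as_uv_matrix(cv$edges)
      cv
    })
  }
  lm
}

#' @rdname read_landmarks
#' @param landmarks landmark list.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(landmarks, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read / write a clone track CSV
#' @param path CSV with columns `timepoint_min`, `cell_id`, `x_um`, `y_um`,
#'   `z_um`.
#' @return Clone track data frame.
#' @export
read_clone_track <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(tr, c("timepoint_min", "cell_id", "x_um", "y_um", "z_um"),
                  "clone track")
  tr
}

#' @rdname read_clone_track
#' @param track clone track data frame.
#' @export
write_clone_track <- function(track, path) {
  require_columns(track, c("timepoint_min", "cell_id", "x_um", "y_um", "z_um"),
                  "clone track")
  utils::write.csv(track, path, row.names = FALSE)
  invisible(path)
}

#' Read a scoring configuration from YAML or JSON
#'
#' Recognised keys are the arguments of [quant_config()]; unknown keys are
#' rejected with a named error so typos cannot silently fall back to
#' defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A validated [quant_config()].
#' @export
read_quant_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- names(formals(quant_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown configuration key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(raw$control_bright_mean)) {
    raw$control_bright_mean <- unlist(raw$control_bright_mean)
  }
  if (!is.null(raw$bg_band)) raw$bg_band <- as.numeric(unlist(raw$bg_band))
  do.call(quant_config, raw)
}

pipeline_log <- function(lines, stage, sample_id, message) {
  c(lines, sprintf("[%s] sample=%s %s", stage, sample_id, message))
}

#' Run the projection + nuclear scoring pipeline over a batch of samples
#'
#' For each sample, either generates synthetic data (from a
#' [synthetic_nuclei_config()]) or reads nucleus/reference CSVs, projects
#' the nuclei (embryos along the z axis; explants along z with wound
#' re-centering when a re-centering point is available), computes
#' nearest-reference distances, and scores the sample with
#' [quantify_sample()]. Per-sample failures are collected and reported; the
#' run continues.
#'
#' @param samples a list of per-sample descriptions. Each element is a list with
#'   `sample_id`, `condition`, and either `synthetic` (a
#'   [synthetic_nuclei_config()]) or `nuclei_csv` + `refs_csv` paths, plus
#'   optional `sample_kind` (defaults to the synthetic config's kind, else
#'   `"explant"`) and `background`.
#' @param cfg a [quant_config()].
#' @param out_dir optional output directory; when given, per-nucleus CSVs,
#'   per-sample JSON results, a batch summary CSV and the run log are
#'   written there.
#' @return A list of class `pipeline_report`: `results` (per sample),
#'   `summary` (per-condition data frame), `log` (character lines),
#'   `failures` (named error messages). Identical inputs give identical
#'   reports.
#' @export
run_pipeline <- function(samples, cfg = quant_config(), out_dir = NULL) {
  stopifnot(is.list(samples), length(samples) >= 1L)
  log_lines <- character(0)
  results <- list()
  failures <- list()
  for (sp in samples) {
    sid <- sp$sample_id %||% sprintf("sample_%d", length(results) + 1L)
    res <- tryCatch({
      if (!is.null(sp$synthetic)) {
        sim <- generate_nuclei(sp$synthetic, sample_id = sid)
        nuclei <- sim$nuclei
        refs <- sim$refs
        kind <- sp$sample_kind %||% sp$synthetic$sample_kind
        recenter <- attr(sim, "recenter_point")
      } else {
        nuclei <- read_nucleus_table(sp$nuclei_csv)
        refs <- read_reference_set(sp$refs_csv)
        kind <- sp$sample_kind %||% "explant"
        recenter <- sp$recenter_point
      }
      frame <- projection_frame(c(0, 0, 1))
      proj <- project_and_measure(nuclei, refs, frame,
                                  recenter_point = recenter)
      log_lines <<- pipeline_log(log_lines, "project", sid,
                                 sprintf("n=%d projected", nrow(proj)))
      q <- quantify_sample(nuclei, proj, sample_kind = kind, cfg = cfg,
                           background = sp$background)
      for (i in seq_len(nrow(q$drop_log))) {
        log_lines <<- pipeline_log(log_lines, "filter", sid,
                                   sprintf("dropped %d (%s)",
                                           q$drop_log$n_dropped[i],
                                           q$drop_log$reason[i]))
      }
      log_lines <<- pipeline_log(
        log_lines, "quantify", sid,
        sprintf("considered=%d positive=%d bright=%d class=%s",
                q$n_considered, q$n_positive, q$n_bright, q$classification))
      q$sample_id <- sid
      q$condition <- sp$condition %||% "unspecified"
      q$sample_kind <- kind
      q
    }, error = function(e) {
      failures[[sid]] <<- conditionMessage(e)
      log_lines <<- pipeline_log(log_lines, "error", sid, conditionMessage(e))
      NULL
    })
    if (!is.null(res)) results[[sid]] <- res
  }
  summary_df <- if (length(results) > 0L) {
    conds <- vapply(results, function(r) r$condition, character(1))
    pp <- vapply(results, function(r) r$percent_positive, numeric(1))
    cls <- vapply(results, function(r) r$classification, character(1))
    do.call(rbind, lapply(unique(conds), function(cd) {
      sel <- conds == cd
      data.frame(condition = cd,
                 n_samples = sum(sel),
                 mean_percent_positive = mean(pp[sel]),
                 n_present = sum(cls[sel] == "present"),
                 n_strongly_reduced = sum(cls[sel] == "strongly_reduced"),
                 n_absent = sum(cls[sel] == "absent"))
    }))
  } else {
    data.frame()
  }
  report <- structure(list(results = results, summary = summary_df,
                           log = log_lines, failures = failures),
                      class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline report to disk
#'
#' Per-sample scored-nucleus CSVs and JSON results, a batch summary CSV and
#' the run log.
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(report$results)) {
    r <- report$results[[sid]]
    utils::write.csv(r$per_nucleus,
                     file.path(out_dir, sprintf("%s_nuclei.csv", sid)),
                     row.names = FALSE)
    slim <- r[c("sample_id", "condition", "sample_kind", "n_input",
                "n_considered", "n_positive", "percent_positive", "n_bright",
                "bright_ids", "classification", "background")]
    jsonlite::write_json(slim, file.path(out_dir, sprintf("%s_result.json", sid)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (nrow(report$summary) > 0L) {
    utils::write.csv(report$summary, file.path(out_dir, "batch_summary.csv"),
                     row.names = FALSE)
  }
  writeLines(report$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report: %d sample(s), %d failure(s)\n",
              length(x$results), length(x$failures)))
  if (nrow(x$summary) > 0L) print(x$summary)
  invisible(x)
}
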