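#' Render a pipeline report as markdown
#'
#' A compact human-readable account of the run: coding metadata (cutoff and
#' inside/outside-window accounting), detection rates, rate-of-change
#' slopes, LBFTS rates, driving metrics, temporal-proximity and learning
#' tables, and the inference battery in the conventional reporting style.
#'
#' @param report A `cb_report` from [run_pipeline()].
#' @return A single markdown string.
#' @export
render_report <- function(report) {
  md <- function(df, digits = 2) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) round(x, digits))
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    body <- apply(df, 1, function(r) {
      paste0("| ", paste(r, collapse = " | "), " |")
    })
    paste(c(header, sep, body), collapse = "\n")
  }
  fmt_stat <- function(x) {
    if (grepl("t-test", x$method)) {
      sprintf("t(%g) = %.3f, p = %s, d = %.2f", x$df1, x$statistic,
        format.pval(x$p, digits = 3, eps = 1e-3), x$effect_size)
    } else {
      sprintf("F(%g, %g) = %.3f, p = %s, partial eta^2 = %.3f",
        x$df1, x$df2, x$statistic,
        format.pval(x$p, digits = 3, eps = 1e-3), x$effect_size)
    }
  }
  sec <- character()
  push <- function(...) sec <<- c(sec, ..., "")

  push("# Change-detection analysis report")
  n_part <- dplyr::n_distinct(report$outcomes$participant_id)
  push(sprintf("Participants: %d; coded changes: %d; seed: %s.",
    n_part, nrow(report$outcomes),
    format(report$config$seed)))

  push("## Response coding")
  cu <- report$cutoff
  push(sprintf("RT cutoff: %.3f s (mode: %s, %d matched RTs).",
    cu$cutoff_s, cu$mode, cu$n_rts_used))
  if (!is.na(cu$inside_fraction)) {
    push(sprintf(
      "%.1f%% of all presses fall inside the cutoff window; %.1f%% outside.",
      cu$inside_fraction, cu$outside_fraction))
  }
  push(sprintf("Overall detection rate: %.1f%% (misses %.1f%%).",
    100 * mean(report$outcomes$detected),
    100 * mean(!report$outcomes$detected)))

  push("## Detection by complexity")
  push(md(report$detection_by_complexity))
  push("## Detection by change type and complexity")
  push(md(report$detection_by_type_complexity))
  push("## Rate-of-change slopes (percentage points)")
  push(md(report$roc))

  if (!is.null(report$lbfts)) {
    push("## LBFTS errors")
    push(md(report$lbfts))
  }
  if (nrow(report$driving) > 0) {
    push("## Driving metrics (per participant x segment)")
    drv <- report$driving |>
      dplyr::group_by(.data$complexity) |>
      dplyr::summarise(
        avg_speed_kmh = mean(.data$avg_speed_kmh),
        completion_min = mean(.data$completion_min),
        brake_hits = mean(.data$brake_hits), .groups = "drop"
      )
    push(md(drv))
  }
  push("## Property-change detection by temporal proximity")
  push(md(report$temporal_proximity))
  push("## Learning (first vs last segment)")
  push(md(report$learning))
  if (nrow(report$fixation_stats) > 0) {
    push("## Fixations per complexity")
    fxs <- report$fixation_stats |>
      dplyr::group_by(.data$complexity) |>
      dplyr::summarise(
        n_fixations = mean(.data$n_fixations),
        fixations_per_min = mean(.data$fixations_per_min),
        mean_duration_ms = mean(.data$mean_duration_ms), .groups = "drop"
      )
    push(md(fxs))
  }
  if (length(report$stats)) {
    push("## Inferential statistics")
    for (nm in names(report$stats)) {
      x <- report$stats[[nm]]
      if (inherits(x, "cb_stat")) {
        push(sprintf("- %s: %s", nm, fmt_stat(x)))
      } else if (is.list(x) && all(vapply(x, inherits, logical(1),
        "cb_stat"))) {
        for (en in names(x)) {
          push(sprintf("- %s [%s]: %s", nm, en, fmt_stat(x[[en]])))
        }
      } else if (is.data.frame(x)) {
        push(sprintf("### %s", nm), md(x, 4))
      }
    }
  }
  paste(sec, collapse = "\n")
}

# write the report bundle: CSV tables + report.md
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, file) {
    if (!is.null(df) && nrow(df) > 0) {
      write.csv(as.data.frame(df), file.path(out_dir, file),
        row.names = FALSE)
    }
  }
  wr(report$outcomes, "outcomes.csv")
  wr(report$false_alarms, "false_alarms.csv")
  wr(report$timecourses, "timecourses.csv")
  wr(report$detection_by_complexity, "detection_by_complexity.csv")
  wr(report$detection_by_type_complexity,
    "detection_by_type_complexity.csv")
  wr(report$roc, "roc_slopes.csv")
  wr(report$lbfts, "lbfts.csv")
  wr(report$driving, "driving_metrics.csv")
  wr(report$temporal_proximity, "temporal_proximity.csv")
  wr(report$learning, "learning.csv")
  wr(report$fixation_stats, "fixation_stats.csv")
  writeLines(render_report(report), file.path(out_dir, "report.md"))
  invisible(out_dir)
}
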