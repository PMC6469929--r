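# Statistical reporting surface and end-to-end orchestration.

#' Compare two groups of measurements
#'
#' `rank_sum` performs the two-sided Mann-Whitney U (Wilcoxon rank-sum)
#' test: exact enumeration for tie-free samples of at most 20 per group,
#' the normal approximation with tie correction otherwise.
#' `variance_ratio` performs the two-sided F test of equal variances.
#' Group summaries report median with interquartile range (the convention
#' of the cluster plots) or mean with SD on request.
#'
#' @param a,b Numeric samples (`rank_sum` needs n >= 3 per group,
#'   `variance_ratio` n >= 2).
#' @param kind `"rank_sum"` or `"variance_ratio"`.
#' @param summary `"median_iqr"` or `"mean_sd"`.
#' @return A `comparison_result` with the p-value, statistic kind, sample
#'   sizes and per-group summaries.
#' @export
compare_groups <- function(a, b, kind = c("rank_sum", "variance_ratio"),
                           summary = c("median_iqr", "mean_sd")) {
  kind <- match.arg(kind)
  summary <- match.arg(summary)
  a <- as.numeric(a[!is.na(a)])
  b <- as.numeric(b[!is.na(b)])
  min_n <- if (kind == "rank_sum") 3L else 2L
  if (length(a) < min_n || length(b) < min_n) {
    stop(kind, " comparison needs at least ", min_n, " observations per group")
  }
  if (kind == "rank_sum") {
    exact_ok <- length(a) <= 20 && length(b) <= 20 && !anyDuplicated(c(a, b))
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided",
                         exact = exact_ok, correct = !exact_ok)
    )
  } else {
    ht <- stats::var.test(a, b, alternative = "two.sided")
  }
  summarize <- function(x) {
    if (summary == "median_iqr") {
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      list(median = q[2], q25 = q[1], q75 = q[3])
    } else {
      list(mean = mean(x), sd = stats::sd(x))
    }
  }
  structure(
    list(
      statistic_kind = kind,
      p_value = unname(ht$p.value),
      statistic = unname(ht$statistic),
      n = c(a = length(a), b = length(b)),
      summary_a = summarize(a), summary_b = summarize(b),
      summary_kind = summary
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>", x$statistic_kind,
      sprintf("p = %.4g", x$p_value),
      sprintf("(n = %d vs %d)\n", x$n[["a"]], x$n[["b"]]))
  invisible(x)
}

pipeline_log <- function(verbose, ...) {
  if (verbose) message("[fusefid] ", ...)
}

#' Run the full analysis pipeline and emit a report bundle
#'
#' Orchestrates metrics -> classification -> rearrangement typing ->
#' group comparisons over a set of embryo datasets, either simulated on
#' the fly from a [simulation_config()] or read from a directory of
#' serialized datasets. Emits long-format TSV tables (`metrics.tsv`,
#' `labels.tsv`, `defects.tsv`, `rearrangements.tsv`) plus a
#' machine-readable `report.json`. The headline comparison contrasts the
#' whole-arc |Norm.dDME| across embryos at the earliest count frame
#' against the completion frame (rank-sum): a significant drop flags
#' disparity reduction over closure. Reruns with the same seed/config are
#' byte-identical; any stage failure removes partial outputs.
#'
#' @param config A [simulation_config()], or `NULL` when `input` is given.
#' @param input Directory of datasets (as written by [write_dataset()]).
#' @param out_dir Output directory for the report bundle.
#' @param alpha Significance threshold applied to the report flags.
#' @param verbose Log stage progress via `message()`.
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(config = NULL, input = NULL, out_dir,
                         alpha = 0.01, verbose = FALSE) {
  if (is.null(config) && is.null(input)) stop("supply a simulation config or an input directory")
  created <- character(0)
  cleanup <- function() {
    for (f in created) if (file.exists(f)) unlink(f)
  }
  tryCatch({
    if (!is.null(config)) {
      pipeline_log(verbose, "stage simulate: seed ", config$seed, ", n = ", config$n_embryos)
      datasets <- simulate_embryos(config)$datasets
    } else {
      pipeline_log(verbose, "stage load: ", input)
      datasets <- read_datasets(input)
    }
    if (!length(datasets)) stop("empty dataset: no embryos to analyse")
    for (ds in datasets) validate_dataset(ds)

    pipeline_log(verbose, "stage metrics: ", length(datasets), " embryo(s)")
    metric_rows <- list()
    early_vals <- numeric(0)
    late_vals <- numeric(0)
    for (ds in datasets) {
      for (descriptor in c("arc_length", "dme_arc")) {
        s <- disparity_series(ds, descriptor)
        if (!nrow(s)) next
        teq <- equalization_time(s)
        metric_rows[[length(metric_rows) + 1L]] <- data.frame(
          embryo_id = ds$embryo_id, descriptor = descriptor,
          pair_id = attr(s, "pair_id"), t_min = s$t_min, value = s$value,
          equalization_time = teq, stringsAsFactors = FALSE
        )
        if (descriptor == "dme_arc") {
          early_vals <- c(early_vals, abs(s$value[1]))
          late_vals <- c(late_vals, abs(s$value[nrow(s)]))
        }
      }
      for (seg in intersect(CENTRAL_SEGMENTS, names(ds$timeline$t_F))) {
        for (comp in COMPARTMENT_TYPES) {
          for (descriptor in c("width", "dme_compartment")) {
            s <- tryCatch(disparity_series(ds, descriptor, seg, comp),
                          fusefid_validation_error = function(e) NULL)
            if (is.null(s) || !nrow(s)) next
            metric_rows[[length(metric_rows) + 1L]] <- data.frame(
              embryo_id = ds$embryo_id, descriptor = descriptor,
              pair_id = attr(s, "pair_id"), t_min = s$t_min, value = s$value,
              equalization_time = equalization_time(s), stringsAsFactors = FALSE
            )
          }
        }
      }
    }
    metrics <- do.call(rbind, metric_rows)

    pipeline_log(verbose, "stage classify")
    labels <- do.call(rbind, lapply(datasets, function(ds) {
      lab <- classify_interfaces(ds)
      lab$polyline <- NULL
      lab
    }))
    defects <- do.call(rbind, lapply(datasets, interlocking_defects))

    pipeline_log(verbose, "stage rearrange")
    rearr <- do.call(rbind, lapply(datasets, rearrangement_labels))

    pipeline_log(verbose, "stage compare")
    disparity_cmp <- if (length(early_vals) >= 3) {
      compare_groups(early_vals, late_vals, "rank_sum")
    } else {
      NULL # too few embryos for a rank-sum comparison
    }

    report <- list(
      pipeline = "fusefid",
      seed = if (!is.null(config)) config$seed else NA,
      mode = if (!is.null(config)) config$mode else NA,
      n_embryos = length(datasets),
      rows = list(
        metrics = nrow(metrics), labels = nrow(labels),
        defects = nrow(defects), rearrangements = nrow(rearr)
      ),
      equalization_time_median = list(
        arc_length = stats::median(unique(metrics[metrics$descriptor == "arc_length",
                                                  c("embryo_id", "equalization_time")])$equalization_time,
                                   na.rm = TRUE),
        dme_arc = stats::median(unique(metrics[metrics$descriptor == "dme_arc",
                                               c("embryo_id", "equalization_time")])$equalization_time,
                                na.rm = TRUE)
      ),
      comparisons = list(
        disparity_reduction_dme_arc = if (is.null(disparity_cmp)) {
          list(note = "fewer than 3 embryos: comparison not performed")
        } else {
          list(
            statistic_kind = disparity_cmp$statistic_kind,
            p_value = disparity_cmp$p_value,
            n = as.list(disparity_cmp$n),
            early = disparity_cmp$summary_a,
            late = disparity_cmp$summary_b,
            significant = disparity_cmp$p_value < alpha
          )
        }
      ),
      alpha = alpha
    )

    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- file.path(out_dir, c("metrics.tsv", "labels.tsv", "defects.tsv",
                                  "rearrangements.tsv", "report.json"))
    created <- paths
    rownames(metrics) <- rownames(labels) <- rownames(defects) <- rownames(rearr) <- NULL
    write_tsv_table(metrics, paths[1])
    write_tsv_table(labels, paths[2])
    write_tsv_table(defects, paths[3])
    write_tsv_table(rearr, paths[4])
    jsonlite::write_json(report, paths[5], auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    pipeline_log(verbose, "report written to ", out_dir)
    invisible(report)
  }, error = function(e) {
    cleanup()
    stop("pipeline failed at a stage: ", conditionMessage(e), call. = FALSE)
  })
}
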