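# Deterministic CSV writer: numbers via as.character (shortest lossless
# decimal), NA as empty cell, LF endings, byte-stable for identical input.
write_table_csv <- function(df, path) {
  fmt <- function(col) {
    s <- if (is.numeric(col)) as.character(col) else as.character(col)
    s[is.na(col)] <- ""
    s
  }
  cells <- vapply(seq_along(df), function(j) fmt(df[[j]]),
                  character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  rows <- if (nrow(df)) apply(cells, 1, paste, collapse = ",") else character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(df), collapse = ","), rows), con, sep = "\n")
  invisible(path)
}

read_tracks_any <- function(path, format, meta, group_label = "") {
  tracks <- switch(format,
                   mdf = read_mdf(path, meta, group_label = group_label),
                   csv = read_csv_tracks(path, meta),
                   stop("unknown track format '", format, "'"))
  if (format == "csv" && nzchar(group_label))
    for (i in seq_along(tracks))
      if (!nzchar(tracks[[i]]$group_label))
        tracks[[i]]$group_label <- group_label
  tracks
}

#' Run the track-analysis pipeline
#'
#' Reads one or more track files, summarises every filopodium (extent
#' series, model fits, classification, Emax/lifetime/Ve/Vr), and writes a
#' per-filopodium summary table.  When the summaries contain exactly two
#' group labels (or `compare` names two of them), a per-variable cohort
#' comparison table and a dynamic-type proportion table are also written.
#' Counts of accepted, rejected and phase-excluded filopodia are logged to
#' stderr; identical inputs give byte-identical outputs.
#'
#' @param track_files Character vector of input paths.
#' @param format `"csv"` or `"mdf"`.
#' @param meta An [acquisition_meta()].
#' @param groups Optional character vector of group labels, one per file
#'   (overrides labels stored in CSV inputs when those are empty).
#' @param compare Optional length-2 character vector naming the two group
#'   labels to compare; default: compare when exactly two labels present.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `summaries`, `comparisons` (or NULL),
#'   `proportions` (or NULL), and the output file paths.
#' @export
run_analyze <- function(track_files, format = c("csv", "mdf"),
                        meta = acquisition_meta(), groups = NULL,
                        compare = NULL, out_dir = ".") {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_tracks <- list()
  n_rejected <- 0L
  for (i in seq_along(track_files)) {
    g <- if (!is.null(groups)) groups[[i]] else ""
    tracks <- read_tracks_any(track_files[[i]], format, meta, g)
    rej <- attr(tracks, "rejected")
    if (!is.null(rej)) n_rejected <- n_rejected + nrow(rej)
    all_tracks <- c(all_tracks, tracks)
  }
  if (length(all_tracks) == 0) stop("no accepted filopodium tracks in input")
  summaries <- summarize_cohort(all_tracks)
  message(sprintf(
    "analyze: %d accepted, %d rejected; %d Ve-eligible, %d Vr-eligible",
    nrow(summaries), n_rejected,
    sum(summaries$has_elongation), sum(summaries$has_retraction)))
  paths <- list(summary = file.path(out_dir, "filopodium_summaries.csv"))
  write_table_csv(summaries, paths$summary)

  labels <- unique(summaries$group_label)
  comparisons <- NULL; proportions <- NULL
  if (is.null(compare) && length(labels) == 2) compare <- labels
  if (!is.null(compare)) {
    if (length(compare) != 2 || !all(compare %in% labels))
      stop("compare must name two group labels present in the data")
    sa <- summaries[summaries$group_label == compare[1], ]
    sb <- summaries[summaries$group_label == compare[2], ]
    comp_rows <- lapply(c("Emax", "lifetime", "Ve", "Vr"), function(v)
      tryCatch(compare_cohorts(sa, sb, v, compare[1], compare[2]),
               error = function(e) {
                 message("comparison skipped for ", v, ": ",
                         conditionMessage(e))
                 NULL
               }))
    comp_rows <- Filter(Negate(is.null), comp_rows)
    if (length(comp_rows)) {
      comparisons <- do.call(rbind, comp_rows)
      class(comparisons) <- "data.frame"
      paths$comparisons <- file.path(out_dir, "cohort_comparisons.csv")
      write_table_csv(comparisons, paths$comparisons)
    }
  }
  proportions <- type_proportions(summaries)
  paths$proportions <- file.path(out_dir, "type_proportions.csv")
  write_table_csv(proportions, paths$proportions)
  invisible(list(summaries = summaries, comparisons = comparisons,
                 proportions = proportions, paths = paths))
}

#' Simulate a synthetic cohort and write it to disk
#'
#' Writes the cohort in the track CSV dialect plus a ground-truth CSV.
#' With `self_check = TRUE` the emitted tracks are immediately re-analysed
#' and the classification accuracy against the ground-truth labels is
#' reported (100 percent is expected for noiseless, untruncated cohorts).
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory.
#' @param self_check Re-analyse the emitted tracks and report recovery.
#' @return Invisibly, list with `tracks_path`, `truth_path`, and (when
#'   self-checked) `accuracy`.
#' @export
run_simulate <- function(config, out_dir = ".", self_check = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- gen_cohort(config)
  tracks_path <- file.path(out_dir, "synthetic_tracks.csv")
  truth_path <- file.path(out_dir, "synthetic_ground_truth.csv")
  write_cohort_csv(cohort, tracks_path, truth_path)
  out <- list(tracks_path = tracks_path, truth_path = truth_path)
  if (self_check && config$n_tracks > 0) {
    summaries <- summarize_cohort(cohort$tracks)
    acc <- mean(summaries$model_label == cohort$truth$true_label)
    message(sprintf("self-check: classification accuracy %.1f%% (n = %d)",
                    100 * acc, nrow(summaries)))
    out$accuracy <- acc
  }
  invisible(out)
}

#' Run the wing-disc gradient quantification
#'
#' Reads a protrusion-length CSV (`disc_id,group_label,length_um`) and/or
#' an intensity-profile CSV (`channel_label,position_um,intensity`).
#' Reports the mean of the k longest protrusions per disc (discs with
#' fewer than k protrusions are skipped with a warning), per-condition
#' mean and SD of those values, and the domain width of each profile.
#'
#' @param lengths_csv,profiles_csv Input paths (either may be NULL).
#' @param k Number of longest protrusions to average.
#' @param threshold_fraction Domain-width threshold, see [domain_width()].
#' @param out_dir Output directory.
#' @return Invisibly, list with `disc_table`, `condition_table`,
#'   `width_table` and output paths.
#' @export
run_gradient <- function(lengths_csv = NULL, profiles_csv = NULL,
                         k = 10, threshold_fraction = 0.5, out_dir = ".") {
  if (is.null(lengths_csv) && is.null(profiles_csv))
    stop("need at least one of lengths_csv, profiles_csv")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(paths = list())
  if (!is.null(lengths_csv)) {
    len <- utils::read.csv(lengths_csv, stringsAsFactors = FALSE)
    need <- c("disc_id", "group_label", "length_um")
    if (!all(need %in% names(len)))
      stop("lengths CSV must have columns ", paste(need, collapse = ","))
    if (nrow(len) == 0) stop("lengths CSV is empty")
    disc_rows <- list()
    for (key in unique(paste(len$group_label, len$disc_id, sep = "\r"))) {
      gl <- strsplit(key, "\r", fixed = TRUE)[[1]]
      d <- len[len$group_label == gl[1] & len$disc_id == gl[2], ]
      m <- tryCatch(top_k_mean_extent(d$length_um, k), error = function(e) {
        warning("disc ", gl[2], " (", gl[1], ") skipped: ",
                conditionMessage(e), call. = FALSE)
        NA_real_
      })
      if (!is.na(m))
        disc_rows[[length(disc_rows) + 1L]] <-
          data.frame(group_label = gl[1], disc_id = gl[2],
                     top_k_mean_um = m, k = k, stringsAsFactors = FALSE)
    }
    if (length(disc_rows) == 0) stop("no disc had at least k protrusions")
    disc_table <- do.call(rbind, disc_rows)
    cond <- compare_domain_widths(split(disc_table$top_k_mean_um,
                                        disc_table$group_label))
    out$disc_table <- disc_table
    out$condition_table <- cond
    out$paths$discs <- file.path(out_dir, "disc_top_k_extent.csv")
    out$paths$conditions <- file.path(out_dir, "condition_extent_summary.csv")
    write_table_csv(disc_table, out$paths$discs)
    write_table_csv(cond, out$paths$conditions)
  }
  if (!is.null(profiles_csv)) {
    prof <- utils::read.csv(profiles_csv, stringsAsFactors = FALSE)
    need <- c("channel_label", "position_um", "intensity")
    if (!all(need %in% names(prof)))
      stop("profiles CSV must have columns ", paste(need, collapse = ","))
    if (nrow(prof) == 0) stop("profiles CSV is empty")
    width_rows <- lapply(split(prof, prof$channel_label), function(ch) {
      p <- intensity_profile(ch$position_um, ch$intensity,
                             ch$channel_label[1])
      data.frame(channel_label = ch$channel_label[1],
                 width_um = domain_width(p, threshold_fraction),
                 threshold_fraction = threshold_fraction,
                 stringsAsFactors = FALSE)
    })
    width_table <- do.call(rbind, width_rows)
    rownames(width_table) <- NULL
    out$width_table <- width_table
    out$paths$widths <- file.path(out_dir, "domain_widths.csv")
    write_table_csv(width_table, out$paths$widths)
  }
  invisible(out)
}

#' Command-line interface
#'
#' Dispatches the three pipeline entry points:
#' \preformatted{
#' analyze  --tracks f1.csv[,f2.csv...] --format csv|mdf --interval-min 2
#'          --window-min 30 [--group A[,B...]] [--compare A,B] --out DIR
#' simulate --n 100 --p-trapezoid 0.5 --noise 0 --seed 1 --out DIR
#'          [--self-check]
#' gradient [--lengths lengths.csv] [--profiles profiles.csv] [--k 10]
#'          [--threshold 0.5] --out DIR
#' }
#' A YAML config file may be given with `--config`; command-line flags
#' override values from the file.
#'
#' @param args Character vector of arguments (default: the command line).
#' @return Exit status, invisibly (0 on success).
#' @export
filodyn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: filodyn <analyze|simulate|gradient> [flags]")
    return(invisible(1L))
  }
  cmd <- args[[1]]
  opts <- parse_flags(args[-1])
  if (!is.null(opts$config)) {
    file_opts <- yaml::read_yaml(opts$config)
    for (k in names(file_opts))
      if (is.null(opts[[k]])) opts[[k]] <- file_opts[[k]]
  }
  geto <- function(name, default = NULL) {
    if (is.null(opts[[name]])) default else opts[[name]]
  }
  out_dir <- geto("out", ".")
  switch(cmd,
    analyze = {
      files <- strsplit(geto("tracks", stop("--tracks required")), ",")[[1]]
      groups <- if (!is.null(opts$group))
        strsplit(opts$group, ",")[[1]] else NULL
      compare <- if (!is.null(opts$compare))
        strsplit(opts$compare, ",")[[1]] else NULL
      meta <- acquisition_meta(
        frame_interval_min = as.numeric(geto("interval-min", 2)),
        window_min = as.numeric(geto("window-min", 30)))
      run_analyze(files, format = geto("format", "csv"), meta = meta,
                  groups = groups, compare = compare, out_dir = out_dir)
    },
    simulate = {
      config <- generator_config(
        n_tracks = as.integer(geto("n", 100)),
        p_trapezoid = as.numeric(geto("p-trapezoid", 0.5)),
        noise_sigma_um = as.numeric(geto("noise", 0)),
        seed = as.integer(geto("seed", 1)))
      run_simulate(config, out_dir = out_dir,
                   self_check = isTRUE(opts[["self-check"]]))
    },
    gradient = {
      run_gradient(lengths_csv = geto("lengths"),
                   profiles_csv = geto("profiles"),
                   k = as.integer(geto("k", 10)),
                   threshold_fraction = as.numeric(geto("threshold", 0.5)),
                   out_dir = out_dir)
    },
    stop("unknown command '", cmd, "'"))
  invisible(0L)
}

# --flag value / bare --flag (logical TRUE) parser.
parse_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument '", a, "'")
    name <- substring(a, 3)
    if (i < length(args) && !startsWith(args[[i + 1L]], "--")) {
      opts[[name]] <- args[[i + 1L]]
      i <- i + 2L
    } else {
      opts[[name]] <- TRUE
      i <- i + 1L
    }
  }
  opts
}
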