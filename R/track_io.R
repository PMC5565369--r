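#' Acquisition metadata for a tracked movie
#'
#' Describes the imaging conditions under which filopodium tracks were
#' acquired: the frame interval, the length of the analysis window, the
#' pixel size and the size of the tracked region.  Defaults mirror the
#' standard abdominal-histoblast protocol: 2 min between frames, a 30 min
#' analysis window, and a 49 x 76 um tracking region.
#'
#' @param frame_interval_min Minutes between consecutive frames (e.g. 2 or
#'   0.5).
#' @param window_min Length of the analysis time window in minutes.
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param region_width_um,region_height_um Size of the tracked region, um.
#' @param coords Either `"um"` (coordinates in track files are already
#'   calibrated to micrometres, the default) or `"pixel"` (coordinates are
#'   stored in pixels and are multiplied by `pixel_size_um` on read).
#'
#' @return An object of class `acquisition_meta`.
#' @export
#' @examples
#' acquisition_meta(frame_interval_min = 2, window_min = 30)
acquisition_meta <- function(frame_interval_min = 2,
                             window_min = 30,
                             pixel_size_um = 1,
                             region_width_um = 49,
                             region_height_um = 76,
                             coords = c("um", "pixel")) {
  coords <- match.arg(coords)
  vals <- c(frame_interval_min, window_min, pixel_size_um,
            region_width_um, region_height_um)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all acquisition_meta numeric fields must be strictly positive")
  structure(
    list(frame_interval_min = frame_interval_min,
         window_min = window_min,
         pixel_size_um = pixel_size_um,
         region_width_um = region_width_um,
         region_height_um = region_height_um,
         coords = coords),
    class = "acquisition_meta")
}

#' Number of frames in the analysis window
#' @param meta An [acquisition_meta()] object.
#' @return Integer count of frames (frame 1 is at the window start).
#' @export
n_window_frames <- function(meta) {
  as.integer(round(meta$window_min / meta$frame_interval_min)) + 1L
}

#' Construct a paired base/tip filopodium track
#'
#' A filopodium track pairs two point tracks: the base (track #1 in the
#' MTrackJ convention) and the tip (track #2).  Each is an ordered table of
#' `(frame, x, y)` with frames 1-based; internal time is
#' `t = (frame - 1) * frame_interval` in minutes, so velocities downstream
#' are um/min.
#'
#' @param filopodium_id Integer cluster number (unique within a file).
#' @param base,tip Data frames with columns `frame`, `x`, `y` (um).
#' @param frame_interval Minutes per frame.
#' @param window_start_frame,window_end_frame First and last frame of the
#'   analysis window.
#' @param group_label Free-text cohort label (genotype/territory).
#'
#' @return An object of class `filopodium_track`.
#' @export
filopodium_track <- function(filopodium_id, base, tip,
                             frame_interval = 2,
                             window_start_frame = 1L,
                             window_end_frame = NULL,
                             group_label = "") {
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  base <- validate_point_table(base, "base")
  tip <- validate_point_table(tip, "tip")
  if (is.null(window_end_frame))
    window_end_frame <- max(base$frame, tip$frame)
  frames <- c(base$frame, tip$frame)
  if (any(frames < window_start_frame | frames > window_end_frame))
    stop("track frames fall outside [window_start_frame, window_end_frame]")
  base$t <- (base$frame - 1) * frame_interval
  tip$t <- (tip$frame - 1) * frame_interval
  structure(
    list(filopodium_id = as.integer(filopodium_id),
         base = base, tip = tip,
         frame_interval = frame_interval,
         window_start_frame = as.integer(window_start_frame),
         window_end_frame = as.integer(window_end_frame),
         group_label = as.character(group_label)),
    class = "filopodium_track")
}

validate_point_table <- function(df, what) {
  df <- as.data.frame(df)[, c("frame", "x", "y")]
  if (nrow(df) == 0) stop(what, " track has no points")
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    stop(what, " track has non-finite coordinates")
  if (any(df$frame < 1) || any(df$frame != round(df$frame)))
    stop(what, " track frames must be integers >= 1")
  df$frame <- as.integer(df$frame)
  df <- df[order(df$frame), , drop = FALSE]
  if (anyDuplicated(df$frame))
    stop("duplicate frame in ", what, " track")
  rownames(df) <- NULL
  df
}

#' @export
print.filopodium_track <- function(x, ...) {
  cat(sprintf(
    "<filopodium_track #%d '%s': %d base / %d tip points, frames %d..%d, dt = %g min>\n",
    x$filopodium_id, x$group_label, nrow(x$base), nrow(x$tip),
    min(x$base$frame, x$tip$frame), max(x$base$frame, x$tip$frame),
    x$frame_interval))
  invisible(x)
}

# Record types MTrackJ writes that carry no point data for this analysis.
.mdf_ignored_records <- c("Displaying", "Offset", "Origin", "Bounds",
                          "Assembly", "Space", "Time", "Id", "End")

#' Read an MTrackJ data file of base/tip filopodium tracks
#'
#' Parses the text format written by the MTrackJ plugin of ImageJ: a header
#' line beginning `MTrackJ`, then `Assembly` / `Cluster` / `Track` / `Point`
#' records.  Each cluster is one filopodium; within it, track 1 is the base
#' and track 2 the tip.  `Point` records carry
#' `id x y z t(frame) channel`; z and channel are parsed and discarded
#' (the analysis is two-dimensional).  Clusters missing either the base or
#' the tip track are reported in the `rejected` attribute with a reason
#' rather than silently dropped.  Cluster ids listed in `exclude_clusters`
#' (e.g. reference tracks of dying cells or region markers interleaved with
#' filopodia) are likewise rejected with reason `"excluded by config"`.
#'
#' @param path Path to the `.mdf` file.
#' @param meta An [acquisition_meta()] object.  When `meta$coords ==
#'   "pixel"` coordinates are multiplied by `meta$pixel_size_um`.
#' @param group_label Cohort label attached to every track.
#' @param exclude_clusters Integer vector of cluster ids to reject.
#'
#' @return A list of [filopodium_track()] objects, with attributes
#'   `rejected` (data frame: `filopodium_id`, `reason`) and `n_points`
#'   (count of Point records read).
#' @export
read_mdf <- function(path, meta = acquisition_meta(), group_label = "",
                     exclude_clusters = integer()) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !startsWith(trimws(lines[[1]]), "MTrackJ"))
    stop("not an MTrackJ data file (missing 'MTrackJ' header): ", path)
  scale <- if (meta$coords == "pixel") meta$pixel_size_um else 1
  clusters <- list()     # cluster id -> list(track id -> point matrix rows)
  cur_cluster <- NA_integer_
  cur_track <- NA_integer_
  n_points <- 0L
  for (i in seq_along(lines)[-1]) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    kind <- tok[[1]]
    if (kind == "Cluster") {
      cur_cluster <- parse_num_field(tok[2], i, "cluster id")
      key <- as.character(cur_cluster)
      if (is.null(clusters[[key]])) clusters[[key]] <- list()
      cur_track <- NA_integer_
    } else if (kind == "Track") {
      if (is.na(cur_cluster))
        stop("parse error at line ", i, ": Track record outside a Cluster")
      cur_track <- parse_num_field(tok[2], i, "track id")
    } else if (kind == "Point") {
      if (is.na(cur_cluster) || is.na(cur_track))
        stop("parse error at line ", i, ": Point record outside a Track")
      if (length(tok) < 6)
        stop("parse error at line ", i,
             ": Point record needs id x y z t c fields")
      vals <- suppressWarnings(as.numeric(tok[2:7]))
      if (any(is.na(vals)))
        stop("parse error at line ", i, ": non-numeric Point field")
      key <- as.character(cur_cluster)
      tkey <- as.character(cur_track)
      clusters[[key]][[tkey]] <-
        rbind(clusters[[key]][[tkey]],
              c(frame = vals[5], x = vals[2] * scale, y = vals[3] * scale))
      n_points <- n_points + 1L
    } else if (kind %in% .mdf_ignored_records || startsWith(kind, "MTrackJ")) {
      next
    } else {
      stop("parse error at line ", i, ": unknown record type '", kind, "'")
    }
  }
  assemble_clusters(clusters, meta, group_label, exclude_clusters, n_points)
}

parse_num_field <- function(s, line, what) {
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop("parse error at line ", line, ": bad ", what)
  as.integer(v)
}

assemble_clusters <- function(clusters, meta, group_label,
                              exclude_clusters, n_points) {
  tracks <- list()
  rejected <- data.frame(filopodium_id = integer(), reason = character())
  wend <- n_window_frames(meta)
  for (key in names(clusters)) {
    id <- as.integer(key)
    cl <- clusters[[key]]
    if (id %in% exclude_clusters) {
      rejected <- rbind(rejected, data.frame(
        filopodium_id = id, reason = "excluded by config"))
      next
    }
    if (is.null(cl[["1"]])) {
      rejected <- rbind(rejected, data.frame(
        filopodium_id = id, reason = "missing base track"))
      next
    }
    if (is.null(cl[["2"]])) {
      rejected <- rbind(rejected, data.frame(
        filopodium_id = id, reason = "missing tip track"))
      next
    }
    tr <- tryCatch(
      filopodium_track(id,
                       base = as.data.frame(cl[["1"]]),
                       tip = as.data.frame(cl[["2"]]),
                       frame_interval = meta$frame_interval_min,
                       window_start_frame = 1L,
                       window_end_frame = max(wend, cl[["1"]][, "frame"],
                                              cl[["2"]][, "frame"]),
                       group_label = group_label),
      error = function(e) e)
    if (inherits(tr, "error")) stop("cluster ", id, ": ", conditionMessage(tr))
    tracks[[length(tracks) + 1L]] <- tr
  }
  tracks <- tracks[order(vapply(tracks, `[[`, 1L, "filopodium_id"))]
  attr(tracks, "rejected") <- rejected
  attr(tracks, "n_points") <- n_points
  tracks
}

.track_csv_header <- "filopodium_id,role,frame,x_um,y_um,group_label"

#' Read filopodium tracks from the package CSV dialect
#'
#' The dialect is UTF-8, LF-terminated, '.' decimal CSV with the exact
#' header `filopodium_id,role,frame,x_um,y_um,group_label` and
#' `role` one of `base`/`tip`.  Coordinates are micrometres.  The same
#' assembly and validation rules as [read_mdf()] apply; the file round-trips
#' bit-exactly through [write_csv_tracks()] for finite decimal inputs.
#'
#' @param path CSV file path.
#' @param meta An [acquisition_meta()] object (frame interval, window).
#' @return As [read_mdf()].
#' @export
read_csv_tracks <- function(path, meta = acquisition_meta()) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[[1]]) != .track_csv_header)
    stop("expected header '", .track_csv_header, "' in ", path)
  body <- lines[-1][nzchar(lines[-1])]
  clusters <- list()
  groups <- character()
  for (i in seq_along(body)) {
    tok <- strsplit(body[[i]], ",", fixed = TRUE)[[1]]
    if (length(tok) < 5)
      stop("parse error at line ", i + 1, ": expected 6 fields")
    role <- tok[2]
    if (!role %in% c("base", "tip"))
      stop("validation error at line ", i + 1, ": unknown role '", role, "'")
    id <- suppressWarnings(as.integer(tok[1]))
    frame <- suppressWarnings(as.numeric(tok[3]))
    x <- suppressWarnings(as.numeric(tok[4]))
    y <- suppressWarnings(as.numeric(tok[5]))
    if (is.na(id) || is.na(frame) || is.na(x) || is.na(y))
      stop("parse error at line ", i + 1, ": non-numeric field")
    key <- as.character(id)
    tkey <- if (role == "base") "1" else "2"
    if (is.null(clusters[[key]])) clusters[[key]] <- list()
    clusters[[key]][[tkey]] <-
      rbind(clusters[[key]][[tkey]], c(frame = frame, x = x, y = y))
    groups[key] <- if (length(tok) >= 6) tok[6] else ""
  }
  res <- assemble_clusters(clusters, meta, group_label = "",
                           exclude_clusters = integer(),
                           n_points = length(body))
  for (j in seq_along(res))
    res[[j]]$group_label <- groups[[as.character(res[[j]]$filopodium_id)]]
  res
}

#' Write filopodium tracks in the package CSV dialect
#'
#' Rows are sorted by `(filopodium_id, role, frame)` with base before tip,
#' so byte output is deterministic and independent of input order.
#'
#' @param tracks List of [filopodium_track()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csv_tracks <- function(tracks, path) {
  rows <- character()
  ids <- vapply(tracks, `[[`, 1L, "filopodium_id")
  for (tr in tracks[order(ids)]) {
    for (role in c("base", "tip")) {
      pts <- tr[[role]]
      rows <- c(rows, sprintf("%d,%s,%d,%s,%s,%s",
                              tr$filopodium_id, role, pts$frame,
                              as.character(pts$x), as.character(pts$y),
                              tr$group_label))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(.track_csv_header, rows), con, sep = "\n")
  invisible(path)
}

#' Pair base and tip points frame by frame
#'
#' Only frames present in both the base and the tip track are returned, in
#' time order; frames present in only one track are dropped (no
#' interpolation) and the dropped count is reported via `message()` and the
#' `n_dropped` attribute.
#'
#' @param track A [filopodium_track()].
#' @return Data frame with columns `frame`, `t`, `x_base`, `y_base`,
#'   `x_tip`, `y_tip`; attribute `n_dropped`.  Errors with "track too
#'   short" when fewer than 2 paired frames remain.
#' @export
pair_frames <- function(track) {
  common <- intersect(track$base$frame, track$tip$frame)
  n_dropped <- (nrow(track$base) - length(common)) +
    (nrow(track$tip) - length(common))
  if (length(common) < 2)
    stop("track too short: filopodium ", track$filopodium_id,
         " has ", length(common), " paired frame(s)")
  common <- sort(common)
  b <- track$base[match(common, track$base$frame), ]
  p <- track$tip[match(common, track$tip$frame), ]
  if (n_dropped > 0)
    message("filopodium ", track$filopodium_id, ": dropped ", n_dropped,
            " unpaired point(s)")
  out <- data.frame(frame = common, t = b$t,
                    x_base = b$x, y_base = b$y,
                    x_tip = p$x, y_tip = p$y)
  attr(out, "n_dropped") <- n_dropped
  out
}
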