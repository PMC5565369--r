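# Shared fixture builders: tracks, MDF text, summaries.

# Track whose extent series is exactly `extents` at consecutive frames.
make_track <- function(extents, first_frame = 2L, dt = 2,
                       base = c(10, 20), angle = 0.3, id = 1L,
                       window_end_frame = 16L, group_label = "g") {
  frames <- seq(first_frame, length.out = length(extents))
  u <- c(cos(angle), sin(angle))
  filopodium_track(
    id,
    base = data.frame(frame = frames, x = base[1], y = base[2]),
    tip = data.frame(frame = frames,
                     x = base[1] + u[1] * extents,
                     y = base[2] + u[2] * extents),
    frame_interval = dt,
    window_start_frame = 1L,
    window_end_frame = window_end_frame,
    group_label = group_label)
}

series_of <- function(track) {
  compute_extent_series(pair_frames(track), track)
}

# Minimal MTrackJ file text for given clusters:
# clusters = list(list(id=, tracks=list(`1`=matrix frame,x,y, `2`=...)))
mdf_text <- function(clusters) {
  out <- c("MTrackJ 1.5.1 Data File", "Displaying true true true")
  for (cl in clusters) {
    out <- c(out, paste("Cluster", cl$id, "FF0000"))
    for (tid in names(cl$tracks)) {
      out <- c(out, paste("Track", tid, "FF0000 true"))
      m <- cl$tracks[[tid]]
      for (i in seq_len(nrow(m)))
        out <- c(out, sprintf("Point %d %s %s 1.0 %d 1",
                              i, as.character(m[i, "x"]),
                              as.character(m[i, "y"]), m[i, "frame"]))
    }
  }
  c(out, "End of MTrackJ Data File")
}

write_mdf <- function(clusters, path = tempfile(fileext = ".mdf")) {
  writeLines(mdf_text(clusters), path)
  path
}

pts <- function(frames, x, y) {
  cbind(frame = frames, x = rep_len(x, length(frames)),
        y = rep_len(y, length(frames)))
}

# Summary table with a single variable filled, for statistics tests.
fake_summaries <- function(values, group, variable = "Emax") {
  col <- c(Emax = "Emax_um", lifetime = "lifetime_min",
           Ve = "Ve_um_per_min", Vr = "Vr_um_per_min")[[variable]]
  df <- data.frame(filopodium_id = seq_along(values), group_label = group,
                   Emax_um = NA_real_, lifetime_min = NA_real_,
                   model_label = "triangle",
                   Ve_um_per_min = NA_real_, Vr_um_per_min = NA_real_,
                   has_elongation = TRUE, has_retraction = TRUE,
                   stringsAsFactors = FALSE)
  df[[col]] <- values
  df
}
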