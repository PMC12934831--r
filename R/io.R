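#' Write joint tracks to a long-format CSV
#'
#' Layout: one row per (video, agent, frame, joint) with columns
#' `video_id, agent, frame, joint, x, y, z, frame_valid`.  Invalid frames
#' are stored with empty coordinates.
#'
#' @param tracks Named list (by video id) of two-`joint_track` lists.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_joint_tracks <- function(tracks, path) {
  pieces <- lapply(tracks, function(pair) {
    data.table::rbindlist(lapply(pair, function(tr) {
      dm <- dim(tr$coords)
      data.table::data.table(
        video_id = tr$video_id,
        agent = tr$agent,
        frame = rep(seq_len(dm[1]), times = dm[2]),
        joint = rep(seq_len(dm[2]), each = dm[1]),
        x = as.vector(tr$coords[, , 1L]),
        y = as.vector(tr$coords[, , 2L]),
        z = as.vector(tr$coords[, , 3L]),
        frame_valid = rep(tr$frame_valid, times = dm[2])
      )
    }))
  })
  dt <- data.table::rbindlist(pieces)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read joint tracks from a long-format CSV
#'
#' @param path CSV written by [write_joint_tracks()].
#' @return Named list (by video id) of two-`joint_track` lists.
#' @export
read_joint_tracks <- function(path) {
  dt <- data.table::fread(path)
  out <- list()
  for (vid in unique(dt$video_id)) {
    sub_v <- dt[dt$video_id == vid, ]
    pair <- lapply(sort(unique(sub_v$agent)), function(a) {
      sub <- sub_v[sub_v$agent == a, ]
      frames <- max(sub$frame)
      joints <- max(sub$joint)
      coords <- array(NA_real_, dim = c(frames, joints, 3L))
      idx <- cbind(sub$frame, sub$joint)
      coords[cbind(idx, 1L)] <- sub$x
      coords[cbind(idx, 2L)] <- sub$y
      coords[cbind(idx, 3L)] <- sub$z
      valid <- rep(TRUE, frames)
      valid[sub$frame[!sub$frame_valid]] <- FALSE
      structure(list(video_id = vid, agent = a, coords = coords,
                     frame_valid = valid),
                class = "joint_track")
    })
    out[[vid]] <- pair
  }
  out
}

#' Write / read a rating table
#'
#' CSV with header `video_id,split,spatial_expanse,interagent_distance,
#' agents_facing,communicative,physical`.
#'
#' @param ratings Rating data.frame from [generate_ratings()].
#' @param path CSV path.
#' @return `path` invisibly; the data.frame for the reader.
#' @export
write_rating_table <- function(ratings, path) {
  cols <- c("video_id", "split", "spatial_expanse", "interagent_distance",
            "agents_facing", "communicative", "physical")
  data.table::fwrite(ratings[, cols], path)
  invisible(path)
}

#' @rdname write_rating_table
#' @export
read_rating_table <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write / read an embedding set
#'
#' One CSV per set, named `<model>__<layer>.csv` inside `dir`, with a
#' `video_id` column followed by the embedding columns.
#'
#' @param set An `embedding_set`.
#' @param dir Directory for the CSV files.
#' @return The file path invisibly; the `embedding_set` for the reader.
#' @export
write_embedding_set <- function(set, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(set$model_name, "__", set$layer_name, ".csv"))
  df <- data.frame(video_id = set$video_index, set$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_embedding_set
#' @param path Path of a CSV written by [write_embedding_set()].
#' @export
read_embedding_set <- function(path) {
  base <- sub("\\.csv$", "", basename(path))
  parts <- strsplit(base, "__", fixed = TRUE)[[1L]]
  df <- as.data.frame(data.table::fread(path))
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$video_id
  structure(
    list(model_name = parts[1L],
         layer_name = if (length(parts) > 1L) parts[2L] else "layer0",
         matrix = m, video_index = df$video_id, info_level = NA_real_),
    class = "embedding_set"
  )
}

#' Write / read a feature table
#'
#' CSV with a `video_id` column followed by feature columns.
#'
#' @param features Feature data.frame (e.g. from [build_feature_tables()]).
#' @param path CSV path.
#' @return `path` invisibly; the data.frame for the reader.
#' @export
write_feature_table <- function(features, path) {
  data.table::fwrite(features, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  as.data.frame(data.table::fread(path))
}

# feature data.frame -> matrix with video_id rownames
feature_matrix <- function(df) {
  m <- as.matrix(df[, setdiff(names(df), "video_id"), drop = FALSE])
  rownames(m) <- as.character(df$video_id)
  m
}
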