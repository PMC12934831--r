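# Shared fixture builders: everything is generated in code, seeded.

# full synthetic dataset: latents, tracks, feature tables, ratings, split
make_test_dataset <- function(n_videos = 60, seed = 1, noise_sd = 0.02,
                              dropout_rate = 0, rater_sd = 0.5,
                              n_raters = 10, frames = 90,
                              config = scene_config()) {
  lat <- sample_scene_latents(n_videos, config, seed = seed)
  tracks <- render_scene_batch(lat, noise_sd = noise_sd,
                               dropout_rate = dropout_rate,
                               frames = frames, seed = seed + 1)
  feats <- build_feature_tables(tracks)
  ratings <- generate_ratings(lat, n_raters = n_raters, rater_sd = rater_sd,
                              seed = seed + 2)
  ratings <- ratings[ratings$video_id %in% feats$kept, ]
  split <- list(train_ids = ratings$video_id[ratings$split == "train"],
                test_ids = ratings$video_id[ratings$split == "test"])
  list(latents = lat, tracks = tracks, feats = feats, ratings = ratings,
       split = split)
}

fmat <- function(df) {
  m <- as.matrix(df[, setdiff(names(df), "video_id"), drop = FALSE])
  rownames(m) <- df$video_id
  m
}

named_rating <- function(ratings, dim_name) {
  y <- ratings[[dim_name]]
  names(y) <- ratings$video_id
  y
}

# brute-force Pearson r from the definition (independent of stats::cor)
brute_pearson <- function(a, b) {
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# all permutations of 1..n as a matrix of rows (test-local oracle)
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- oracle_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1))
  }))
}
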