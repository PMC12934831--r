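#' Pipeline run configuration
#'
#' Collects every setting of the end-to-end synthetic analysis with
#' defaults matching the study conditions the package emulates: 250 videos
#' at 90 frames, an 80/20 train/test split, five rating dimensions averaged
#' over a 10-rater panel with per-rater noise SD 0.5, five-fold
#' cross-validation repeated twice, a 21-point penalty grid from 1e-10 to
#' 1e10, SRP distortion 0.1, 200 Dirichlet draws at concentrations 0.1 and
#' 1.0, and 5000 permutations.
#'
#' @param n_videos Number of simulated videos.
#' @param frames Frames per video.
#' @param noise_sd Articulation jitter SD (m).
#' @param dropout_rate Per-frame pose-failure probability (default 0.0012,
#'   which fails ~10\% of 90-frame videos, the order observed with real
#'   pose estimators on naturalistic footage).
#' @param n_raters,rater_sd Rater panel size and noise SD.
#' @param train_fraction Fraction of videos in the training split.
#' @param n_models Number of synthetic embedding models (0 skips every
#'   model-dependent stage).
#' @param embed_dim Synthetic embedding width.
#' @param info_levels Pose information levels of the synthetic models
#'   (default evenly spaced on \[0, 1\]).
#' @param folds,repeats Cross-validation layout.
#' @param n_alphas Penalty grid size.
#' @param eps SRP distortion parameter.
#' @param n_gamma,concentrations Grouped-ridge random-search settings.
#' @param n_perm Number of permutations.
#' @param grouped_ratings Ratings to run the grouped-ridge stage on
#'   (default all five).
#' @param scene Scene generator settings ([scene_config()]).
#' @param weights Rating generative weights ([rating_weights()]).
#' @param store_joints If `TRUE`, write the long-format joint-track CSV
#'   into the run directory (large; off by default).
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param yaml Optional path to a YAML file whose keys override the
#'   defaults above.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(n_videos = 250L, frames = 90L,
                            noise_sd = 0.02, dropout_rate = 0.0012,
                            n_raters = 10L, rater_sd = 0.5,
                            train_fraction = 0.8,
                            n_models = 30L, embed_dim = 64L,
                            info_levels = NULL,
                            folds = 5L, repeats = 2L, n_alphas = 21L,
                            eps = 0.1, n_gamma = 200L,
                            concentrations = c(0.1, 1.0),
                            n_perm = 5000L,
                            grouped_ratings = rating_names(),
                            scene = scene_config(),
                            weights = rating_weights(),
                            store_joints = FALSE,
                            seed = 1L, yaml = NULL) {
  cfg <- list(n_videos = as.integer(n_videos), frames = as.integer(frames),
              noise_sd = noise_sd, dropout_rate = dropout_rate,
              n_raters = as.integer(n_raters), rater_sd = rater_sd,
              train_fraction = train_fraction,
              n_models = as.integer(n_models),
              embed_dim = as.integer(embed_dim),
              info_levels = info_levels,
              folds = as.integer(folds), repeats = as.integer(repeats),
              n_alphas = as.integer(n_alphas), eps = eps,
              n_gamma = as.integer(n_gamma),
              concentrations = concentrations,
              n_perm = as.integer(n_perm),
              grouped_ratings = grouped_ratings,
              scene = scene, weights = weights,
              store_joints = isTRUE(store_joints),
              seed = as.integer(seed))
  if (!is.null(yaml)) {
    over <- yaml::read_yaml(yaml)
    for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  }
  if (is.null(cfg$info_levels)) {
    cfg$info_levels <- if (cfg$n_models > 1L) {
      seq(0, 1, length.out = cfg$n_models)
    } else if (cfg$n_models == 1L) 0.5 else numeric(0)
  }
  structure(cfg, class = "run_config")
}

#' The five rating dimension names
#' @return Character vector.
#' @export
rating_names <- function() {
  c("spatial_expanse", "interagent_distance", "agents_facing",
    "communicative", "physical")
}

# named ratings vector for one dimension
rating_vector <- function(ratings, dim_name) {
  y <- ratings[[dim_name]]
  names(y) <- ratings$video_id
  y
}

#' Decode a feature table from embeddings
#'
#' Multi-output ridge with one cross-validated penalty shared across
#' feature columns, scored as the mean test-set Pearson r over columns.
#' Used to quantify how much pose information an embedding carries.
#'
#' @param E Embedding matrix with video-id rownames.
#' @param features Feature matrix/data.frame over the same videos.
#' @param split List with `train_ids`, `test_ids`.
#' @inheritParams ridge_encode
#' @return List with `mean_r`, `per_feature_r`, `alpha`.
#' @export
decode_features <- function(E, features, split, folds = 5L, repeats = 2L,
                            alphas = alpha_grid(), seed = 1) {
  F <- if (is.data.frame(features)) feature_matrix(features) else
    as.matrix(features)
  tr <- split$train_ids; te <- split$test_ids
  alpha <- cv_alpha_multi(E[tr, , drop = FALSE], F[tr, , drop = FALSE],
                          alphas = alphas, folds = folds,
                          repeats = repeats, seed = seed)
  rs <- vapply(seq_len(ncol(F)), function(k) {
    as.numeric(fit_evaluate(E[tr, , drop = FALSE], F[tr, k],
                            E[te, , drop = FALSE], F[te, k], alpha))
  }, numeric(1))
  list(mean_r = mean(rs), per_feature_r = rs, alpha = alpha)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes every stage in order — simulate scenes, tracks and ratings;
#' build the three feature families; encode ratings from joints, 3D and 2D
#' social pose vectors and from every synthetic model embedding; decode
#' pose features from embeddings; grouped ridge (embedding + 3D pose);
#' semi-partial residualization; permutation tests — and writes tidy CSV
#' tables, a permutation summary, and a JSON manifest into `out_dir`.
#' Re-running with an identical config and seed reproduces every output.
#'
#' @param config A `run_config` from [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with all in-memory results (`summary`,
#'   `fig2`...`fig5` tables, `perm_summary`, `manifest`).
#' @export
run_full_pipeline <- function(config = pipeline_config(), out_dir,
                              quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seeds <- list(scenes = derive_seed(config$seed, 1L),
                tracks = derive_seed(config$seed, 2L),
                ratings = derive_seed(config$seed, 3L),
                embeddings = derive_seed(config$seed, 4L),
                encoding = derive_seed(config$seed, 5L),
                grouped = derive_seed(config$seed, 6L),
                semipartial = derive_seed(config$seed, 7L),
                permtest = derive_seed(config$seed, 8L))
  alphas <- alpha_grid(config$n_alphas)
  template <- make_skeleton_template()

  ## --- simulate -----------------------------------------------------------
  say("simulate: %d videos", config$n_videos)
  latents <- sample_scene_latents(config$n_videos, config$scene,
                                  seed = seeds$scenes)
  tracks <- render_scene_batch(latents, template,
                               noise_sd = config$noise_sd,
                               dropout_rate = config$dropout_rate,
                               frames = config$frames, seed = seeds$tracks)
  ratings <- generate_ratings(latents, config$weights,
                              n_raters = config$n_raters,
                              rater_sd = config$rater_sd,
                              train_fraction = config$train_fraction,
                              seed = seeds$ratings)
  write_rating_table(ratings, file.path(out_dir, "ratings.csv"))
  if (config$store_joints) {
    write_joint_tracks(tracks, file.path(out_dir, "joint_tracks.csv"))
  }

  ## --- features -----------------------------------------------------------
  feats <- build_feature_tables(tracks, template)
  say("features: kept %d of %d videos", length(feats$kept), config$n_videos)
  write_feature_table(feats$social3d, file.path(out_dir, "social3d.csv"))
  write_feature_table(feats$social2d, file.path(out_dir, "social2d.csv"))
  write_feature_table(feats$joints, file.path(out_dir, "joints.csv"))
  kept_ratings <- ratings[ratings$video_id %in% feats$kept, ]
  split <- list(
    train_ids = kept_ratings$video_id[kept_ratings$split == "train"],
    test_ids = kept_ratings$video_id[kept_ratings$split == "test"]
  )
  X <- list(joints = feature_matrix(feats$joints),
            social3d = feature_matrix(feats$social3d),
            social2d = feature_matrix(feats$social2d))

  ## --- synthetic model embeddings ----------------------------------------
  have_models <- config$n_models >= 1L
  emb <- list()
  if (have_models) {
    emb <- lapply(seq_len(config$n_models), function(i) {
      generate_embeddings(feats$social3d,
                          info_level = config$info_levels[i],
                          dim = config$embed_dim,
                          seed = derive_seed(seeds$embeddings, i),
                          model_name = sprintf("synthmodel%02d", i))
    })
    names(emb) <- vapply(emb, `[[`, character(1), "model_name")
  } else {
    say("no embedding models configured; skipping model-dependent stages")
  }

  ## --- encode -------------------------------------------------------------
  say("encode: joints / 3D / 2D social pose features")
  summary_rows <- list()
  pose_preds <- list()   # social3d test predictions per rating
  for (dim_name in rating_names()) {
    y <- rating_vector(kept_ratings, dim_name)
    for (fam in names(X)) {
      res <- ridge_encode(X[[fam]], y, split, feature_source = fam,
                          folds = config$folds, repeats = config$repeats,
                          alphas = alphas, seed = seeds$encoding)
      summary_rows[[paste(dim_name, fam)]] <- data.frame(
        target = dim_name, feature_source = fam, layer = NA_character_,
        alpha = res$chosen_alpha, test_r = res$test_r)
      if (fam == "social3d") {
        pose_preds[[dim_name]] <- ridge_predictions(
          X$social3d[split$train_ids, ], y[split$train_ids],
          X$social3d[split$test_ids, ], res$chosen_alpha)
      }
    }
  }

  model_rows <- list()
  model_preds <- list()   # per rating: n_test x n_models matrix
  decode_rows <- list()
  if (have_models) {
    say("encode: %d synthetic model embeddings", length(emb))
    for (dim_name in rating_names()) model_preds[[dim_name]] <-
      matrix(NA_real_, length(split$test_ids), length(emb),
             dimnames = list(split$test_ids, names(emb)))
    for (mi in seq_along(emb)) {
      E <- emb[[mi]]$matrix
      mseed <- derive_seed(seeds$encoding, 100L + mi)
      for (dim_name in rating_names()) {
        y <- rating_vector(kept_ratings, dim_name)
        res <- ridge_encode(E, y, split,
                            feature_source = names(emb)[mi],
                            folds = config$folds, repeats = config$repeats,
                            alphas = alphas, seed = mseed)
        model_rows[[paste(names(emb)[mi], dim_name)]] <- data.frame(
          model = names(emb)[mi], target = dim_name,
          info_level = emb[[mi]]$info_level,
          alpha = res$chosen_alpha, test_r = res$test_r)
        model_preds[[dim_name]][, mi] <- ridge_predictions(
          E[split$train_ids, ], y[split$train_ids],
          E[split$test_ids, ], res$chosen_alpha)
      }
      d3 <- decode_features(E, X$social3d, split, folds = config$folds,
                            repeats = config$repeats, alphas = alphas,
                            seed = mseed)
      d2 <- decode_features(E, X$social2d, split, folds = config$folds,
                            repeats = config$repeats, alphas = alphas,
                            seed = mseed)
      decode_rows[[names(emb)[mi]]] <- data.frame(
        model = names(emb)[mi], info_level = emb[[mi]]$info_level,
        decode3d_r = d3$mean_r, decode2d_r = d2$mean_r)
    }
  }

  ## --- grouped ridge ------------------------------------------------------
  grouped_rows <- list()
  if (have_models) {
    say("grouped ridge: %d models x %d ratings", length(emb),
        length(config$grouped_ratings))
    for (mi in seq_along(emb)) {
      E <- emb[[mi]]$matrix
      for (dim_name in config$grouped_ratings) {
        y <- rating_vector(kept_ratings, dim_name)
        gr <- grouped_ridge_search(
          groups_train = list(embedding = E[split$train_ids, ],
                              pose = X$social3d[split$train_ids, ]),
          groups_test = list(embedding = E[split$test_ids, ],
                             pose = X$social3d[split$test_ids, ]),
          y_train = y[split$train_ids], y_test = y[split$test_ids],
          n_gamma = config$n_gamma,
          concentrations = config$concentrations,
          alphas = alphas, folds = config$folds,
          seed = derive_seed(seeds$grouped, mi))
        grouped_rows[[paste(names(emb)[mi], dim_name)]] <- data.frame(
          model = names(emb)[mi], target = dim_name,
          info_level = emb[[mi]]$info_level,
          gamma_embedding = gr$gamma[["embedding"]],
          gamma_pose = gr$gamma[["pose"]], alpha = gr$alpha,
          combined_r = gr$test_r)
      }
    }
  }

  ## --- semi-partial -------------------------------------------------------
  say("semi-partial residualization")
  pos_cols <- grep("_(x|y|z)$", colnames(X$social3d), value = TRUE)
  dir_cols <- grep("_(dx|dy|dz)$", colnames(X$social3d), value = TRUE)
  predictor_sets <- list(positions = X$social3d[, pos_cols],
                         directions = X$social3d[, dir_cols],
                         social3d = X$social3d)
  semi_rows <- list()
  for (ps in names(predictor_sets)) {
    resid <- semipartial_residualize(X$joints, predictor_sets[[ps]], split,
                                     alphas = alphas, folds = config$folds,
                                     repeats = config$repeats,
                                     seed = seeds$semipartial)
    for (dim_name in rating_names()) {
      y <- rating_vector(kept_ratings, dim_name)
      enc <- semipartial_encode(resid, y, split, folds = config$folds,
                                repeats = config$repeats, alphas = alphas,
                                seed = seeds$semipartial)
      semi_rows[[paste(ps, dim_name)]] <- data.frame(
        predictor_set = ps, target = dim_name,
        residual_alpha = resid$alpha, residual_r = enc$test_r)
    }
  }

  ## --- permutation tests --------------------------------------------------
  say("permutation tests (%d permutations)", config$n_perm)
  perm_rows <- list()
  add_perm <- function(test, target, pt) {
    perm_rows[[paste(test, target)]] <<- data.frame(
      test = test, target = target, observed = pt$observed,
      p = pt$p_value, tails = pt$tails, n_perm = pt$n_perm, seed = pt$seed)
  }
  model_df <- if (have_models) do.call(rbind, model_rows) else NULL
  decode_df <- if (have_models) do.call(rbind, decode_rows) else NULL
  grouped_df <- if (length(grouped_rows)) do.call(rbind, grouped_rows) else NULL
  if (have_models) {
    for (dim_name in rating_names()) {
      y <- rating_vector(kept_ratings, dim_name)[split$test_ids]
      add_perm("group_vs_single", dim_name, perm_group_vs_single(
        model_preds[[dim_name]], pose_preds[[dim_name]], y,
        n_perm = config$n_perm, seed = derive_seed(seeds$permtest, 10L)))
      sub <- model_df[model_df$target == dim_name, ]
      sub <- sub[match(decode_df$model, sub$model), ]
      add_perm("decode_vs_rating_3d", dim_name, perm_correlation(
        decode_df$decode3d_r, sub$test_r, n_perm = config$n_perm,
        seed = derive_seed(seeds$permtest, 20L)))
      add_perm("decode_3d_vs_2d", dim_name, perm_corr_difference(
        decode_df$decode3d_r, decode_df$decode2d_r, sub$test_r,
        n_perm = config$n_perm, seed = derive_seed(seeds$permtest, 30L)))
      if (!is.null(grouped_df) && dim_name %in% config$grouped_ratings) {
        gsub <- grouped_df[grouped_df$target == dim_name, ]
        gsub <- gsub[match(sub$model, gsub$model), ]
        add_perm("paired_improvement", dim_name, perm_paired_improvement(
          sub$test_r, gsub$combined_r, n_perm = config$n_perm,
          seed = derive_seed(seeds$permtest, 40L)))
      }
    }
  }

  ## --- report -------------------------------------------------------------
  summary_df <- do.call(rbind, summary_rows)
  semi_df <- do.call(rbind, semi_rows)
  perm_df <- if (length(perm_rows)) do.call(rbind, perm_rows) else
    data.frame(test = character(0), target = character(0),
               observed = numeric(0), p = numeric(0), tails = character(0),
               n_perm = integer(0), seed = integer(0))
  rownames(summary_df) <- rownames(semi_df) <- rownames(perm_df) <- NULL
  tables <- build_report_tables(summary_df, model_df, decode_df,
                                grouped_df, semi_df, perm_df)
  data.table::fwrite(summary_df, file.path(out_dir, "summary.csv"))
  data.table::fwrite(semi_df, file.path(out_dir, "semipartial_table.csv"))
  data.table::fwrite(perm_df, file.path(out_dir, "perm_summary.csv"))
  if (have_models) {
    data.table::fwrite(model_df, file.path(out_dir, "model_encoding.csv"))
    data.table::fwrite(decode_df, file.path(out_dir, "model_decoding.csv"))
  }
  if (!is.null(grouped_df)) {
    data.table::fwrite(grouped_df, file.path(out_dir, "grouped_ridge.csv"))
  }
  for (nm in names(tables)) {
    if (!is.null(tables[[nm]])) {
      data.table::fwrite(tables[[nm]],
                         file.path(out_dir, paste0(nm, "_table.csv")))
    }
  }
  manifest <- list(
    package = "socialpose3d",
    version = as.character(utils::packageVersion("socialpose3d")),
    config = config[setdiff(names(config), c("scene", "weights"))],
    scene = config$scene, weights = config$weights,
    stage_seeds = seeds,
    kept_videos = length(feats$kept),
    excluded_videos = length(feats$excluded),
    fingerprint = manifest_fingerprint(config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: outputs in %s", out_dir)
  invisible(c(tables, list(summary = summary_df, semipartial = semi_df,
                           perm_summary = perm_df, model_encoding = model_df,
                           model_decoding = decode_df,
                           grouped = grouped_df, manifest = manifest,
                           split = split)))
}

# deterministic config fingerprint (no external digest dependency)
manifest_fingerprint <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# assemble the per-figure tables from the tidy results
build_report_tables <- function(summary_df, model_df, decode_df,
                                grouped_df, semi_df, perm_df) {
  fig3 <- summary_df[, c("target", "feature_source", "test_r")]
  fig2 <- NULL; fig4 <- NULL; fig5 <- NULL
  if (!is.null(model_df)) {
    pose_r <- summary_df[summary_df$feature_source == "social3d",
                         c("target", "test_r")]
    names(pose_r)[2] <- "social3d_r"
    fig2 <- merge(model_df[, c("model", "target", "info_level", "test_r")],
                  pose_r, by = "target")
    p2 <- perm_df[perm_df$test == "group_vs_single", c("target", "p")]
    if (nrow(p2)) fig2 <- merge(fig2, p2, by = "target")
    fig4 <- merge(model_df[, c("model", "target", "test_r")],
                  decode_df, by = "model")
    names(fig4)[names(fig4) == "test_r"] <- "rating_r"
  }
  if (!is.null(grouped_df) && !is.null(model_df)) {
    alone <- model_df[, c("model", "target", "test_r")]
    names(alone)[3] <- "alone_r"
    fig5 <- merge(grouped_df, alone, by = c("model", "target"))
    fig5$improvement <- fig5$combined_r - fig5$alone_r
    frac <- stats::aggregate(improvement ~ target, fig5,
                             function(v) mean(v >= 0))
    names(frac)[2] <- "fraction_improved"
    fig5 <- merge(fig5, frac, by = "target")
    p5 <- perm_df[perm_df$test == "paired_improvement", c("target", "p")]
    if (nrow(p5)) fig5 <- merge(fig5, p5, by = "target")
  }
  list(fig2 = fig2, fig3 = fig3, fig4 = fig4, fig5 = fig5)
}

#' Read the per-figure tables of a completed run
#'
#' @param run_dir Directory written by [run_full_pipeline()].
#' @return Named list of data.frames (`fig2` ... `fig5`, `summary`,
#'   `semipartial`, `perm_summary`, `manifest`); model-dependent tables are
#'   `NULL` when the run had no embedding models.
#' @export
report_tables <- function(run_dir) {
  need <- file.path(run_dir, c("summary.csv", "manifest.json"))
  if (!all(file.exists(need))) {
    stop("incomplete run directory: ", run_dir, call. = FALSE)
  }
  rd <- function(f) {
    p <- file.path(run_dir, f)
    if (file.exists(p)) as.data.frame(data.table::fread(p)) else NULL
  }
  list(summary = rd("summary.csv"),
       semipartial = rd("semipartial_table.csv"),
       perm_summary = rd("perm_summary.csv"),
       fig2 = rd("fig2_table.csv"), fig3 = rd("fig3_table.csv"),
       fig4 = rd("fig4_table.csv"), fig5 = rd("fig5_table.csv"),
       manifest = jsonlite::read_json(file.path(run_dir, "manifest.json")))
}
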