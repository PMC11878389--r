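#' Full-pipeline configuration
#'
#' Collects every knob of the end-to-end run in one serializable list; the
#' effective configuration (and its hash) is embedded in the run's outputs
#' so any artifact can be regenerated bit-identically from the seed.
#'
#' @param seed Master seed; every stage derives its streams from it.
#' @param counts Per-class bank counts.
#' @param train_per_class Training images per class.
#' @param render_n Rendered topogram side (pixels) for the capture stage.
#' @param corner_jitter_px Capture corner jitter (0 disables distortion).
#' @param spec A [cnn_spec()].
#' @param train A [train_config()].
#' @param thresholds Rule-classifier thresholds.
#' @param policy Variant policy.
#' @param qc_n Number of rectified captures to check for zone alignment.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 0, counts = default_bank_counts(),
                            train_per_class = 240, render_n = 128,
                            corner_jitter_px = 6,
                            spec = cnn_spec(), train = train_config(),
                            thresholds = default_rule_thresholds(),
                            policy = default_variant_policy(), qc_n = 5) {
  stopifnot(render_n %% spec$input_size == 0)
  structure(list(seed = as.integer(seed), counts = counts,
                 train_per_class = as.integer(train_per_class),
                 render_n = as.integer(render_n),
                 corner_jitter_px = corner_jitter_px,
                 spec = spec, train = train, thresholds = thresholds,
                 policy = policy, qc_n = as.integer(qc_n)),
            class = "pipeline_config")
}

# hue plane of an RGB canonical frame, block-averaged down to n x n.
# Hue is taken where saturation marks a palette color (rings, background
# and blend artifacts are near-achromatic) and normalised by the warmest
# palette hue span (240 deg).
image_hue_plane <- function(rgb, n) {
  hsvimg <- rgb_to_hsv_image(rgb)
  big <- dim(rgb)[1]
  f <- big / n
  hue <- hsvimg[, , 1]
  valid <- hsvimg[, , 2] > 0.3
  hue[!valid] <- 0
  hsum <- block_reduce(hue, f)
  vsum <- block_reduce(matrix(as.numeric(valid), big, big), f)
  out <- hsum / pmax(vsum, 1)
  pmin(out / 240, 1.5)
}

block_reduce <- function(m, f) {
  n <- nrow(m) / f
  m2 <- matrix(colSums(matrix(m, f)), n, ncol(m))     # reduce rows
  t(matrix(colSums(matrix(t(m2), f)), n, n))          # reduce cols
}

#' Run the whole pipeline: simulate, capture, rectify, contour, train,
#' evaluate
#'
#' Executes every stage in sequence on a seeded synthetic bank: renders
#' each planned topogram, simulates a perspective-distorted capture,
#' rectifies it back into the canonical frame with the known corner quad,
#' derives the hue plane from the rectified HSV image and the contour mask
#' from the examiner oracle, trains the CNN on the training split, and
#' evaluates the trained model on the held-out split. Writes `manifest.tsv`
#' and `report.json` to `out_dir` (if given). The report embeds the seed
#' and config hash; reruns with the same config are bit-identical.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param quiet Suppress stage messages.
#' @return A `pipeline_report` list: `confusion`, `accuracy`, `per_class`,
#'   `screening`, `curve`, `split`, `zone_error_px`, `seed`,
#'   `config_hash`.
#' @export
run_end_to_end <- function(cfg = pipeline_config(), out_dir = NULL,
                           quiet = FALSE) {
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  t0 <- Sys.time()
  stage <- function(what, expr) {
    tic <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", what,
                    conditionMessage(e)), class = "topotype_pipeline_error",
            parent = e)
    })
    say("[%s] %.1fs", what, as.numeric(Sys.time() - tic, units = "secs"))
    out
  }

  plan <- stage("synth", sample_bank(cfg$counts, seed = cfg$seed,
                                     train_per_class = cfg$train_per_class,
                                     policy = cfg$policy))
  N <- nrow(plan)
  n_in <- cfg$spec$input_size
  scale <- default_color_scale()

  x <- array(0, dim = c(cfg$spec$channels, n_in, n_in, N))
  zone_err <- rep(NA_real_, min(cfg$qc_n, N))
  stage("capture+rectify+contour", {
    for (i in seq_len(N)) {
      pm <- make_power_map(plan$params[[i]], grid_n = cfg$render_n)
      tg <- render_topogram(pm, scale)
      cap <- distort_capture(tg, corner_jitter_px = cfg$corner_jitter_px,
                             rng_seed = plan$seed[i])
      rect <- warp_to_canonical(cap$image, cap$true_quad, n = cfg$render_n)
      if (i <= length(zone_err)) {
        zone_err[i] <- tryCatch(
          zone_alignment_error(rect, tg$zones_px),
          topotype_quality_error = function(e) NA_real_)
      }
      cs <- oracle_contour(pm)
      x[1, , , i] <- rasterize_contour(cs, n = n_in, fill = TRUE)
      if (cfg$spec$channels >= 2) x[2, , , i] <- image_hue_plane(rect, n_in)
    }
    NULL
  })

  y <- as.integer(factor(plan$label, levels = CLASS_LABELS))
  tr <- which(plan$split == "train"); te <- which(plan$split == "test")
  if (length(te) == 0) {
    abort("no test split; lower train_per_class or raise counts",
          class = "topotype_config_error")
  }
  train_set <- list(x = x[, , , tr, drop = FALSE], y = y[tr])
  test_set <- list(x = x[, , , te, drop = FALSE], y = y[te])

  model <- stage("build", build_model(cfg$spec, seed = cfg$seed))
  fit <- stage("train", train_cnn(model, train_set, test_set, cfg$train,
                                  quiet = quiet))
  pred <- stage("predict", predict_cnn(fit$model, test_set))
  cm <- confusion_matrix(pred$label, plan$label[te])

  report <- list(
    seed = cfg$seed,
    config_hash = object_hash(unclass_deep(cfg)),
    split = list(train = length(tr), test = length(te)),
    zone_error_px = mean(zone_err, na.rm = TRUE),
    confusion = unclass(cm),
    accuracy = overall_accuracy(cm),
    per_class = per_class_rates(cm),
    screening = screening_metrics(cm),
    curve = fit$curve,
    mean_test_acc = mean(fit$curve$test_acc),
    runtime_s = as.numeric(Sys.time() - t0, units = "secs")
  )
  class(report) <- "pipeline_report"

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_manifest(dplyr::select(plan, -dplyr::any_of(c("params", "id"))),
                   file.path(out_dir, "manifest.tsv"))
    json <- report
    json$confusion <- as.data.frame(unclass(cm))
    json$runtime_s <- NULL
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         digits = NA, auto_unbox = TRUE, force = TRUE)
  }
  report
}

# strip classes recursively so hashing covers only content
unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) x <- lapply(x, unclass_deep)
  x
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report (seed %d, config %s)\n", x$seed, x$config_hash))
  cat(sprintf("  split: %d train / %d test\n", x$split$train, x$split$test))
  cat(sprintf("  mean per-epoch test accuracy: %.2f%%\n", x$mean_test_acc))
  cat(sprintf("  final accuracy: %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              x$accuracy, x$screening$sensitivity, x$screening$specificity))
  invisible(x)
}

#' Report hash for determinism checks
#'
#' Hash of the report's content without runtimes.
#'
#' @param report A `pipeline_report`.
#' @return Hex string.
#' @export
report_hash <- function(report) {
  report$runtime_s <- NULL
  object_hash(unclass_deep(report))
}
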