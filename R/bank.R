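#' Class counts emulating the original diagnostic pattern bank
#'
#' 275 spherical, 302 symmetric, 295 asymmetric and 300 irregular patterns
#' (1,172 in total), of which 240 per class are used for training (960,
#' 81.91%) and the remaining 212 (18.09%) for testing.
#'
#' @return Named integer vector.
#' @export
default_bank_counts <- function() {
  c(SPHERICAL = 275L, SYMMETRIC = 302L, ASYMMETRIC = 295L, IRREGULAR = 300L)
}

#' Plan a synthetic pattern bank
#'
#' Draws per-image surface parameters for the requested class counts and
#' assigns the train/test split: up to `train_per_class` images per class
#' go to training (selected by a seeded random draw within each class), the
#' rest to test. Fully deterministic per seed.
#'
#' @param counts Named vector of per-class image counts.
#' @param seed Master integer seed.
#' @param train_per_class Training images per class (default 240).
#' @param policy Variant policy, see [default_variant_policy()].
#' @return A `bank_plan` tibble: `id`, `file`, `label`, `variant`, `split`,
#'   `seed`, and a `params` list-column of `surface_params` rows.
#' @export
sample_bank <- function(counts = default_bank_counts(), seed = 0,
                        train_per_class = 240,
                        policy = default_variant_policy()) {
  stopifnot(all(counts >= 1))
  labels <- names(counts)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  rows <- purrr::map(labels, function(lab) {
    n <- counts[[lab]]
    item_seeds <- vapply(seq_len(n), function(i) split_seed(seed, "bank", lab, i),
                         integer(1))
    params <- purrr::map(item_seeds, ~ sample_params(lab, policy = policy,
                                                     rng_seed = .x))
    set.seed(split_seed(seed, "bank-split", lab))
    train_idx <- sample.int(n, min(train_per_class, n))
    split <- rep("test", n)
    split[train_idx] <- "train"
    tibble(
      id = sprintf("%s_%04d", tolower(lab), seq_len(n)),
      file = sprintf("%s_%04d.png", tolower(lab), seq_len(n)),
      label = lab,
      variant = vapply(params, function(p) p$variant, character(1)),
      split = split,
      seed = item_seeds,
      params = params
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bank_plan", class(out))
  out
}

#' Build classifier input tensors for a bank plan
#'
#' For each planned image: evaluates the power surface, traces the
#' examiner-oracle contour on a `contour_grid` power map, rasterizes the
#' filled contour mask at the classifier input size, and computes the hue
#' plane (the color-scale hue of each pixel's power bin, normalised to
#' `[0, 1]`; zero outside the corneal disc). Channel 1 is the mask,
#' channel 2 the hue.
#'
#' @param plan A `bank_plan` (or any tibble with `params` and `label`).
#' @param input_size Classifier input side, pixels.
#' @param contour_grid Power-map grid used for contour tracing.
#' @param scale Color scale for the hue plane.
#' @param channels 2 (mask + hue) or 1 (mask only).
#' @return A list: `x` array `(channels, input_size, input_size, N)`,
#'   `y` integer labels 1..4, `meta` (the plan without `params`).
#' @export
build_dataset <- function(plan, input_size = 32, contour_grid = 96,
                          scale = default_color_scale(), channels = 2) {
  N <- nrow(plan)
  x <- array(0, dim = c(channels, input_size, input_size, N))
  g <- grid_polar(input_size, 9 / input_size)
  inside <- g$r <= 4.5
  for (i in seq_len(N)) {
    p <- plan$params[[i]]
    pm <- make_power_map(p, grid_n = contour_grid)
    cs <- oracle_contour(pm)
    mask <- rasterize_contour(cs, n = input_size, fill = TRUE)
    x[1, , , i] <- mask
    if (channels >= 2) {
      hue <- matrix(0, input_size, input_size)
      k <- eval_power(p, g$r[inside], g$theta[inside])
      hue[inside] <- scale$hue_deg[power_bin(k, scale)] / 240
      x[2, , , i] <- hue
    }
  }
  list(x = x,
       y = as.integer(factor(plan$label, levels = CLASS_LABELS)),
       meta = dplyr::select(plan, -dplyr::any_of("params")))
}

#' Generate a synthetic pattern bank on disk
#'
#' Renders every planned image as an 8-bit RGB PNG with a JSON sidecar
#' (label, variant, parameters, seed, scale metadata) and writes the
#' train/test manifest as TSV. Deterministic per seed: the same seed gives
#' byte-identical files.
#'
#' @param counts Per-class counts (named vector).
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed).
#' @param grid_n Rendered image side, pixels.
#' @param train_per_class Training images per class.
#' @param policy Variant policy.
#' @return The manifest tibble, invisibly; files are written to `out_dir`.
#' @export
generate_bank <- function(counts = default_bank_counts(), seed = 0,
                          out_dir, grid_n = 256, train_per_class = 240,
                          policy = default_variant_policy()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste("cannot create", out_dir), class = "topotype_io_error")
  }
  plan <- sample_bank(counts, seed = seed, train_per_class = train_per_class,
                      policy = policy)
  scale <- default_color_scale()
  for (i in seq_len(nrow(plan))) {
    pm <- make_power_map(plan$params[[i]], grid_n = grid_n)
    tg <- render_topogram(pm, scale)
    png::writePNG(tg$image, file.path(out_dir, plan$file[i]))
    sidecar <- file.path(out_dir, sub("\\.png$", ".json", plan$file[i]))
    jsonlite::write_json(tg$sidecar, sidecar, digits = NA, auto_unbox = TRUE)
  }
  manifest <- dplyr::select(plan, -dplyr::any_of(c("params", "id")))
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}

#' Read / write a bank manifest
#'
#' Manifests are tab-separated with a header (`file label variant split
#' seed`, plus any extra columns, which round-trip losslessly).
#'
#' @param rows Manifest tibble.
#' @param path TSV path.
#' @return `read_manifest` returns a tibble; `write_manifest` returns
#'   `path` invisibly.
#' @export
write_manifest <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    abort(paste("no manifest at", path), class = "topotype_io_error")
  }
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, colClasses = NA),
    error = function(e) abort(conditionMessage(e), class = "topotype_io_error")
  )
  as_tibble(df)
}

#' Train/test split bookkeeping of a manifest or plan
#'
#' @param manifest A tibble with a `split` column.
#' @return A tibble with one row per split: `split`, `n`, `pct`
#'   (2-decimal half-up percentage of the total).
#' @export
split_summary <- function(manifest) {
  manifest |>
    dplyr::count(.data$split, name = "n") |>
    dplyr::mutate(pct = round_half_up(100 * .data$n / sum(.data$n)))
}
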