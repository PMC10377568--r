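# End-to-end orchestration: phantom generation -> (optional) training and
# translation -> fidelity metrics -> radiomic features -> statistical report.

#' Evaluate synthetic images against real ones (in memory)
#'
#' The full evaluation schema for a set of aligned image pairs: per-pair
#' fidelity metrics (MAE/MSE/PSNR) with their across-pair summary, the 23
#' radiomic features per image, and the per-feature statistical comparison
#' report.
#'
#' @param real,synthetic Lists of aligned numeric matrices (same length,
#'   matching dimensions).
#' @param masks Optional list of 0/1 masks (one per pair) used for feature
#'   extraction and, if `mask_fidelity` is TRUE, fidelity scoring; `NULL`
#'   uses whole images.
#' @param ids Optional character ids (defaults to `pair_001`, ...).
#' @param alpha Significance level of the comparison report.
#' @param n_bins,radius,connectivity Feature-extraction parameters (defaults
#'   20, 1, 8).
#' @param mask_fidelity Restrict fidelity metrics to the mask (default FALSE:
#'   fidelity sums run over whole images).
#'
#' @return List with `fidelity` (per-pair data frame), `fidelity_summary`,
#'   `features_real`, `features_synth` (matrices), and `report`
#'   (a [build_report()] comparison report).
#' @export
evaluate_synthesis <- function(real, synthetic, masks = NULL, ids = NULL,
                               alpha = 0.05, n_bins = 20, radius = 1,
                               connectivity = 8, mask_fidelity = FALSE) {
  if (length(real) != length(synthetic))
    stop("`real` and `synthetic` must have equal length", call. = FALSE)
  n <- length(real)
  if (n < 1) stop("empty input", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("pair_%03d", seq_len(n))

  fid <- lapply(seq_len(n), function(i)
    fidelity(real[[i]], synthetic[[i]],
             mask = if (mask_fidelity && !is.null(masks)) masks[[i]] else NULL))
  fid_df <- data.frame(
    id = ids,
    mae = vapply(fid, `[[`, numeric(1), "mae"),
    mse = vapply(fid, `[[`, numeric(1), "mse"),
    psnr = vapply(fid, `[[`, numeric(1), "psnr"),
    stringsAsFactors = FALSE
  )
  fid_sum <- summarize_fidelity(mapply(function(r, s) list(real = r, synthetic = s),
                                       real, synthetic, SIMPLIFY = FALSE),
                                mask = NULL)

  feat_one <- function(img, i)
    extract_features(img, mask = if (is.null(masks)) NULL else masks[[i]],
                     n_bins = n_bins, radius = radius, connectivity = connectivity)
  fr <- t(vapply(seq_len(n), function(i) feat_one(real[[i]], i), numeric(23)))
  fs <- t(vapply(seq_len(n), function(i) feat_one(synthetic[[i]], i), numeric(23)))
  rownames(fr) <- rownames(fs) <- ids

  list(fidelity = fid_df, fidelity_summary = fid_sum,
       features_real = fr, features_synth = fs,
       report = build_report(fr, fs, alpha = alpha))
}

.image_stems <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(png|nii|nii\\.gz)$",
                           ignore.case = TRUE))
  stems <- sub("\\.(png|nii|nii\\.gz)$", "", files, ignore.case = TRUE)
  keep <- !duplicated(stems)  # same id in two formats: first alphabetically
  stats::setNames(file.path(dir, files[keep]), stems[keep])
}

#' Evaluate synthetic images against real ones (directories)
#'
#' Directory front end of [evaluate_synthesis()]: images are paired by
#' filename stem across `real_dir` and `synth_dir` (and `mask_dir`, if
#' given), and all outputs are written as CSV plus a JSON manifest when
#' `out_dir` is supplied.
#'
#' @param real_dir,synth_dir Directories of PNG/NIfTI images with matching
#'   stems.
#' @param out_dir Optional output directory for `fidelity.csv`,
#'   `features_real.csv`, `features_synth.csv`, `report.csv` and
#'   `manifest.json`.
#' @param mask_dir Optional directory of mask images (same stems).
#' @param ... Passed to [evaluate_synthesis()].
#' @return The [evaluate_synthesis()] result, invisibly when writing.
#' @export
run_evaluation <- function(real_dir, synth_dir, out_dir = NULL, mask_dir = NULL,
                           ...) {
  rf <- .image_stems(real_dir)
  sf <- .image_stems(synth_dir)
  orphans <- c(setdiff(names(rf), names(sf)), setdiff(names(sf), names(rf)))
  if (length(orphans))
    stop("unmatched ids between real and synthetic directories: ",
         paste(sort(unique(orphans)), collapse = ", "), call. = FALSE)
  ids <- sort(names(rf))
  real <- lapply(rf[ids], read_image)
  synth <- lapply(sf[ids], read_image)
  masks <- NULL
  if (!is.null(mask_dir)) {
    mf <- .image_stems(mask_dir)
    want <- paste0(ids, "_mask")
    have <- intersect(want, names(mf))
    key <- if (length(have) == length(ids)) want else ids
    if (!all(key %in% names(mf)))
      stop("mask files missing for: ",
           paste(setdiff(key, names(mf)), collapse = ", "), call. = FALSE)
    masks <- lapply(mf[key], function(p) (read_image(p) > 0) + 0)
  }
  res <- evaluate_synthesis(real, synth, masks = masks, ids = ids, ...)
  if (!is.null(out_dir)) {
    write_evaluation(res, out_dir)
    return(invisible(res))
  }
  res
}

#' Write an evaluation result set to CSV
#'
#' @param res Result of [evaluate_synthesis()].
#' @param out_dir Destination directory (created if needed).
#' @param config Optional named list recorded in `manifest.json`.
#' @return `out_dir`, invisibly.
#' @export
write_evaluation <- function(res, out_dir, config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$fidelity, file.path(out_dir, "fidelity.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(id = rownames(res$features_real),
                              res$features_real, check.names = FALSE),
                   file.path(out_dir, "features_real.csv"), row.names = FALSE)
  utils::write.csv(data.frame(id = rownames(res$features_synth),
                              res$features_synth, check.names = FALSE),
                   file.path(out_dir, "features_synth.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(res$report),
                   file.path(out_dir, "report.csv"), row.names = FALSE)
  manifest <- list(
    package = "mrisynth",
    version = as.character(utils::packageVersion("mrisynth")),
    alpha = attr(res$report, "alpha"),
    n_real = attr(res$report, "n_real"),
    n_synth = attr(res$report, "n_synth"),
    n_significant = sum(res$report$significant),
    config = config
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Write a phantom dataset to disk
#'
#' Writes per-pair 8-bit PNG and float32 NIfTI images for both domains plus
#' the mask, and a manifest CSV of ids and paths.
#'
#' @param dataset List of `paired_slice` objects.
#' @param out_dir Destination directory.
#' @return Path of the manifest CSV, invisibly.
#' @export
write_phantom_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (sub in c("A", "B", "mask")) {
    dir.create(file.path(out_dir, sub), showWarnings = FALSE)
  }
  rows <- lapply(dataset, function(p) {
    paths <- c(
      png_A = file.path(out_dir, "A", paste0(p$id, ".png")),
      png_B = file.path(out_dir, "B", paste0(p$id, ".png")),
      nii_A = file.path(out_dir, "A", paste0(p$id, ".nii.gz")),
      nii_B = file.path(out_dir, "B", paste0(p$id, ".nii.gz")),
      mask = file.path(out_dir, "mask", paste0(p$id, "_mask.png"))
    )
    write_image(p$image_A, paths[["png_A"]])
    write_image(p$image_B, paths[["png_B"]])
    write_image(p$image_A, paths[["nii_A"]])
    write_image(p$image_B, paths[["nii_B"]])
    write_image(p$mask, paths[["mask"]])
    data.frame(id = p$id, t(paths), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' One-command demonstration pipeline
#'
#' Generates a seeded phantom dataset, trains a toy translation model on a
#' training split, translates the held-out domain-A slices, and evaluates the
#' synthetic domain-B images against the real ones (fidelity + radiomic
#' report).  All artifacts are written under `out_dir`.
#'
#' @param out_dir Output directory.
#' @param n_pairs Total phantom pairs (default 30).
#' @param size Image side (default 32; divisible by 4).
#' @param model `"cyclegan"` or `"dc2anet"`.
#' @param epochs Training epochs (default 5; demo scale).
#' @param n_test Held-out pairs (default `max(4, n_pairs %/% 5)`).
#' @param seed Global seed.
#' @param base_channels,n_res_blocks Toy architecture width/depth.
#' @param alpha Report significance level.
#' @param skip_training If TRUE, evaluate the untrained (randomly
#'   initialized) model instead — useful as a baseline.
#'
#' @return List: `pair` (the trained model), `eval` (evaluation results),
#'   `test_ids`, invisibly.
#' @export
run_full_demo <- function(out_dir, n_pairs = 30, size = 32,
                          model = c("cyclegan", "dc2anet"), epochs = 5,
                          n_test = max(4, n_pairs %/% 5), seed = 1L,
                          base_channels = 8, n_res_blocks = 1, alpha = 0.05,
                          skip_training = FALSE) {
  model <- match.arg(model)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_phantom_dataset(n_pairs, size = size, base_seed = seed)
  test_idx <- seq_len(n_test)
  train_ds <- ds[-test_idx]
  test_ds <- ds[test_idx]

  spec <- gan_spec(image_size = size, base_channels = base_channels,
                   n_res_blocks = n_res_blocks, model_kind = model)
  sched <- train_schedule(epochs = epochs, batch_size = 2,
                          decay_start_epoch = max(1, epochs %/% 2), seed = seed)
  pair <- if (skip_training) {
    withr::with_seed(seed, structure(
      list(G_A2B = build_generator(spec), G_B2A = build_generator(spec),
           D_A = build_discriminator(spec, model == "dc2anet"),
           D_B = build_discriminator(spec, model == "dc2anet"),
           spec = spec, schedule = sched, history = NULL),
      class = "translator_pair"))
  } else {
    train_translator(train_ds, spec, sched)
  }
  if (!is.null(pair$history))
    utils::write.csv(pair$history, file.path(out_dir, "loss_history.csv"),
                     row.names = FALSE)

  real_B <- lapply(test_ds, `[[`, "image_B")
  synth_B <- lapply(test_ds, function(p) translate(pair, p$image_A, "A2B"))
  masks <- lapply(test_ds, `[[`, "mask")
  ids <- vapply(test_ds, `[[`, character(1), "id")
  res <- evaluate_synthesis(real_B, synth_B, masks = masks, ids = ids,
                            alpha = alpha)
  write_evaluation(res, out_dir,
                   config = list(model = model, n_pairs = n_pairs, size = size,
                                 epochs = epochs, seed = seed,
                                 base_channels = base_channels,
                                 n_res_blocks = n_res_blocks))
  invisible(list(pair = pair, eval = res, test_ids = ids))
}
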