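# End-to-end orchestration: manifest handling, the simulate -> mask ->
# register -> tile -> label -> preprocess -> train -> predict -> heatmap ->
# qc -> subsample pipeline, and provenance records.

#' Read a paired-stain sample manifest
#'
#' A CSV with one row per sample: `id`, `reticulin`, `he` (image paths),
#' optional `tissue_mask`, `ret_tissue_mask`, `bone_mask`, `fat_mask`,
#' `field` (phantom ground-truth sidecars), `mpp`, `group`. Paths are
#' resolved relative to the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return A tibble, one row per sample.
#' @export
read_pair_manifest <- function(path) {
  m <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("id", "reticulin", "he") %in% names(m)))
    abort("manifest needs `id`, `reticulin`, `he` columns")
  if (anyDuplicated(m$id)) abort("manifest ids must be unique")
  if (!"mpp" %in% names(m)) m$mpp <- 0.22
  if (any(m$mpp <= 0)) abort("manifest `mpp` must be > 0")
  root <- dirname(normalizePath(path))
  pathcols <- intersect(c("reticulin", "he", "tissue_mask", "ret_tissue_mask",
                          "bone_mask", "fat_mask", "field"), names(m))
  for (cc in pathcols) {
    rel <- !is.na(m[[cc]]) & nzchar(m[[cc]]) & !grepl("^(/|[A-Za-z]:)", m[[cc]])
    m[[cc]][rel] <- file.path(root, m[[cc]][rel])
  }
  m
}

#' Simulate a phantom cohort to disk
#'
#' Generates one phantom pair per spec, writes all rasters and sidecars
#' under `dir`, and writes a `manifest.csv` consumable by
#' [run_end_to_end()].
#'
#' @param specs List of [phantom_spec()]s (names become sample ids).
#' @param dir Output directory.
#' @param groups Optional group label per sample.
#' @return Path to the written manifest.
#' @export
simulate_cohort <- function(specs, dir, groups = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(specs) %||% sprintf("phantom%02d", seq_along(specs))
  rows <- purrr::map2(specs, ids, function(sp, id) {
    pair <- generate_phantom(sp)
    paths <- write_phantom(pair, dir, id)
    tibble(id = id, reticulin = basename(paths$reticulin),
           he = basename(paths$he),
           tissue_mask = basename(paths$tissue_mask),
           ret_tissue_mask = basename(paths$ret_tissue_mask),
           bone_mask = basename(paths$bone_mask),
           fat_mask = basename(paths$fat_mask),
           field = basename(paths$field), mpp = sp$mpp)
  }) |> bind_rows()
  if (!is.null(groups)) rows$group <- groups
  mf <- file.path(dir, "manifest.csv")
  write.csv(as.data.frame(rows), mf, row.names = FALSE)
  mf
}

#' Pipeline configuration
#'
#' @param tile_size Tile side, px.
#' @param min_tissue_fraction Tissue fraction a tile must reach.
#' @param ranking A [ranking_config()].
#' @param fractions Subsampling fractions.
#' @param draws Subsample draws per fraction.
#' @param heterogeneity_threshold Deviation threshold for the
#'   heterogeneous call.
#' @param val_fraction Fraction of labelled tiles held out for validation.
#' @param seed Master seed for the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tile_size = 64L, min_tissue_fraction = 0.5,
                            ranking = ranking_config(), fractions = c(2, 4, 6, 8, 10) / 15,
                            draws = 20L, heterogeneity_threshold = 0.1,
                            val_fraction = 0.25, seed = 1L) {
  structure(list(tile_size = as.integer(tile_size),
                 min_tissue_fraction = min_tissue_fraction,
                 ranking = ranking, fractions = fractions,
                 draws = as.integer(draws),
                 heterogeneity_threshold = heterogeneity_threshold,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_fail <- function(stage, id, parent) {
  abort(sprintf("stage `%s` failed for sample `%s`: %s", stage, id,
                conditionMessage(parent)))
}

load_sample <- function(row) {
  for (f in c("reticulin", "he"))
    if (!file.exists(row[[f]]))
      abort(sprintf("file not found: %s", row[[f]]))
  list(id = row$id,
       he = read_image_png(row$he),
       ret = read_image_png(row$reticulin),
       tissue_mask = if (!is.null(row$tissue_mask) && file.exists(row$tissue_mask %||% ""))
         read_mask_png(row$tissue_mask) else NULL,
       ret_tissue_mask = if (!is.null(row$ret_tissue_mask) && file.exists(row$ret_tissue_mask %||% ""))
         read_mask_png(row$ret_tissue_mask) else NULL,
       bone_mask = if (!is.null(row$bone_mask) && file.exists(row$bone_mask %||% ""))
         read_mask_png(row$bone_mask) else NULL,
       fat_mask = if (!is.null(row$fat_mask) && file.exists(row$fat_mask %||% ""))
         read_mask_png(row$fat_mask) else NULL,
       field = if (!is.null(row$field) && file.exists(row$field %||% ""))
         read_field_tiff(row$field) else NULL,
       mpp = row$mpp)
}

#' Run the full pipeline on a manifest
#'
#' For every sample: load (or reuse) masks, register the reticulin frame
#' onto the H&E frame, extract H&E tiles, label them with the teacher,
#' then train one ranking model on the pooled training tiles, predict CIF
#' maps for all samples, and write per-sample score CSVs, heatmap PNGs, QC
#' and subsample JSONs plus a run-level provenance index. Reruns with the
#' same inputs and seed are byte-identical on the score CSVs.
#'
#' @param manifest Path to a manifest CSV or a tibble from
#'   [read_pair_manifest()].
#' @param out_dir Run directory (created).
#' @param config A [pipeline_config()].
#' @param teacher Tile labeller: `"ground_truth"` (phantom latent field
#'   sidecars; default) or a function `(sample, tile_table) -> labels`.
#' @return Invisibly, a list with the trained model, per-sample results
#'   and the provenance record.
#' @export
run_end_to_end <- function(manifest, out_dir, config = pipeline_config(),
                           teacher = "ground_truth") {
  if (is.character(manifest)) manifest <- read_pair_manifest(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  label_fun <- if (is.function(teacher)) teacher else function(sample, tt) {
    if (is.null(sample$field))
      abort("ground-truth teacher needs a `field` sidecar per sample")
    fake_pair <- structure(list(fibrosis_field = sample$field),
                           class = "phantom_pair")
    ground_truth_tile_labels(fake_pair, tt)$label
  }

  samples <- purrr::map(seq_len(nrow(manifest)), function(i) {
    row <- as.list(manifest[i, ])
    id <- row$id
    s <- tryCatch(load_sample(row), error = function(e) stage_fail("load", id, e))
    if (is.null(s$tissue_mask))
      s$tissue_mask <- tryCatch(compute_tissue_mask(s$he),
                                error = function(e) stage_fail("mask", id, e))
    if (is.null(s$ret_tissue_mask))
      s$ret_tissue_mask <- tryCatch(compute_tissue_mask(s$ret),
                                    error = function(e) stage_fail("mask", id, e))
    s$affine <- tryCatch(estimate_affine(s$ret_tissue_mask, s$tissue_mask),
                         error = function(e) stage_fail("register", id, e))
    s$tiles <- tryCatch(
      extract_tiles(s$he, s$tissue_mask, config$tile_size,
                    config$min_tissue_fraction, s$fat_mask, s$bone_mask),
      error = function(e) stage_fail("tile", id, e))
    s$tiles$label <- tryCatch(label_fun(s, s$tiles),
                              error = function(e) stage_fail("label", id, e))
    s$group <- row$group %||% NA_character_
    s
  })

  # Pool labelled tiles; split train/validation by sample-stratified draw.
  tile_pool <- purrr::map(samples, function(s) {
    tl <- purrr::pmap(list(s$tiles$x0, s$tiles$y0, s$tiles$tile_size),
                      function(x0, y0, t) crop_tile(s$he, x0, y0, t))
    mutate(as_tibble(s$tiles), tile = tl, sample_id = s$id)
  }) |> bind_rows()
  n_pool <- nrow(tile_pool)
  val_idx <- with_seed(config$seed,
                       sort(sample.int(n_pool, max(1L, round(config$val_fraction * n_pool)))))
  train_tab <- tile_pool[setdiff(seq_len(n_pool), val_idx), ]
  val_tab <- tile_pool[val_idx, ]

  model <- tryCatch(
    train_ranking_model(train_tab$tile, train_tab$label, config$ranking),
    error = function(e) stage_fail("train", "<cohort>", e))
  val_map <- predict_cif(model, val_tab$tile)
  val_acc <- tryCatch(
    pairwise_prediction_accuracy(val_map$cif, val_tab$label, config$ranking$delta),
    error = function(e) NA_real_)

  outputs <- list()
  qc_rows <- list()
  for (s in samples) {
    id <- s$id
    tiles_analysable <- if (!anyNA(s$tiles$analysable)) filter_analysable(s$tiles) else s$tiles
    tl <- purrr::pmap(list(tiles_analysable$x0, tiles_analysable$y0,
                           tiles_analysable$tile_size),
                      function(x0, y0, t) crop_tile(s$he, x0, y0, t))
    map <- tryCatch(predict_cif(model, tl, tiles_analysable),
                    error = function(e) stage_fail("predict", id, e))
    cif_csv <- file.path(out_dir, sprintf("cif_%s.csv", id))
    write_cif_map_csv(map, cif_csv)
    hm <- render_heatmap(map, s$he, alpha = 0.6)
    hm_png <- file.path(out_dir, sprintf("heatmap_%s.png", id))
    write_image_png(hm, hm_png)
    aff_json <- file.path(out_dir, sprintf("affine_%s.json", id))
    write_affine_json(s$affine, aff_json)
    sub <- deviation_curve(map, config$fractions, config$draws,
                           seed = config$seed + match(id, manifest$id))
    sub_json <- file.path(out_dir, sprintf("subsample_%s.json", id))
    write_subsample_json(sub, sub_json, config$heterogeneity_threshold)
    if (!is.null(s$bone_mask) && !anyNA(s$tiles$analysable))
      qc_rows[[id]] <- qc_report(s$he, s$tissue_mask, s$bone_mask, s$tiles,
                                 s$mpp, id)
    outputs[[id]] <- list(cif_map = map, cif_csv = cif_csv,
                          heatmap = hm_png, affine = aff_json,
                          subsample = sub, subsample_json = sub_json)
  }
  if (length(qc_rows) > 0) {
    qc_tab <- bind_rows(qc_rows)
    write.csv(as.data.frame(qc_tab), file.path(out_dir, "qc.csv"),
              row.names = FALSE)
  }

  prov <- list(
    package_version = tryCatch(as.character(utils::packageVersion("hecif")),
                               error = function(e) "dev"),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "ranking")],
    ranking_config = unclass(config$ranking),
    n_samples = nrow(manifest),
    n_tiles_train = nrow(train_tab), n_tiles_val = nrow(val_tab),
    validation_pairwise_accuracy = val_acc,
    outputs = purrr::map(outputs, function(o)
      purrr::map(o[c("cif_csv", "heatmap", "affine", "subsample_json")], basename)))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(model = model, samples = outputs, provenance = prov,
                 validation_accuracy = val_acc))
}
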