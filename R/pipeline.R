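# End-to-end pipeline driver: fuse -> binarize -> seeds -> split -> filter ->
# refine -> features (-> evaluate against truth when available), with every
# intermediate written to disk and a structured run log.

#' Run the full image-processing pipeline
#'
#' `config` is a list (or path to a YAML file) with:
#' \describe{
#'   \item{images}{list of entries `green`, `red` (TIFF paths) and optional
#'     `truth` (label TIFF), `classes` (CSV `nucleus_id,tissue_class`).}
#'   \item{simulate}{alternative to `images`: arguments for
#'     [generate_scene()] plus `n_scenes`; scenes are generated in memory.}
#'   \item{out_dir}{output directory (created).}
#'   \item{params}{overrides of [default_config()] (`w_g`, `w_r`,
#'     `local_window`, `sigma`, `r`, `min_area`, `min_mean_intensity`, `w2`,
#'     `glcm_offset`, ...).}
#'   \item{P}{global intensity ceiling; default per-image maximum.}
#'   \item{seed}{base seed for simulation.}
#' }
#' A missing channel file skips that pair with a warning; the run continues.
#'
#' @param config list or YAML path.
#' @return list of per-image results (label maps, feature tables, evaluation)
#'   plus the echoed parameters, invisibly; artifacts under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cf <- utils::modifyList(default_config(), config$params %||% list())
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) message("[wormnuc] ", sprintf(...))
  log_line("parameters: %s",
           paste(names(cf), vapply(cf, function(v)
             paste(format(v), collapse = ","), ""),
             sep = "=", collapse = " "))
  inputs <- list()
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    n_scenes <- sim$n_scenes %||% 1L
    sim$n_scenes <- NULL
    base_seed <- config$seed %||% 1L
    for (s in seq_len(n_scenes)) {
      args <- utils::modifyList(list(seed = base_seed + s - 1L), sim)
      scene <- do.call(generate_scene, args)
      inputs[[s]] <- list(name = sprintf("scene%03d", s),
                          img = scene$image, truth = scene$truth)
    }
  } else if (!is.null(config$images)) {
    for (s in seq_along(config$images)) {
      en <- config$images[[s]]
      if (!file.exists(en$green) || !file.exists(en$red)) {
        warning("missing channel file for pair ", s, "; skipped")
        next
      }
      img <- two_channel_image(read_tiff_gray(en$green),
                               read_tiff_gray(en$red), P = config$P)
      truth <- NULL
      if (!is.null(en$truth) && file.exists(en$truth)) {
        lm <- read_tiff_gray(en$truth)
        storage.mode(lm) <- "integer"
        classes <- NULL
        if (!is.null(en$classes) && file.exists(en$classes)) {
          cc <- utils::read.csv(en$classes)
          classes <- stats::setNames(cc$tissue_class, cc$nucleus_id)
        }
        truth <- list(label_map = lm, classes = classes)
      }
      inputs[[length(inputs) + 1L]] <-
        list(name = sub("_g(\\.tif+)?$", "",  basename(en$green)),
             img = img, truth = truth)
    }
  } else {
    stop("config must provide either 'images' or 'simulate'")
  }
  results <- list()
  for (inp in inputs) {
    log_line("processing %s", inp$name)
    seg <- segment_image(inp$img, cf)
    refined <- refine_all(seg$fused, seg$labels, w2 = cf$w2,
                          margin = cf$margin)
    cls <- if (!is.null(inp$truth) && !is.null(inp$truth$classes)) {
      transfer_classes(inp$truth$label_map, inp$truth$classes, refined)
    } else NULL
    ft <- feature_table(refined, inp$img,
                        glcm_spec(cf$glcm_offset, cf$glcm_levels),
                        classes = cls)
    stem <- file.path(out_dir, inp$name)
    write_tiff_gray(seg$binary, paste0(stem, "_binary.tif"))
    write_tiff_gray(seg$labels, paste0(stem, "_rough_labels.tif"))
    write_tiff_gray(refined, paste0(stem, "_labels.tif"))
    utils::write.csv(as.data.frame(ft), paste0(stem, "_features.csv"),
                     row.names = FALSE)
    res <- list(name = inp$name, labels = refined, features = ft,
                n_nuclei = max(refined))
    if (!is.null(inp$truth)) {
      sc <- seg_score(inp$truth$label_map, refined)
      cat4 <- categorize_objects(inp$truth$label_map, refined)
      res$evaluation <- list(pixel = sc, objects = cat4)
      log_line("  pixel P=%.3f S=%.3f; correct %d/%d", sc$precision,
               sc$sensitivity, cat4$counts["correct"], cat4$total)
      jsonlite::write_json(
        list(precision = sc$precision, sensitivity = sc$sensitivity,
             counts = as.list(cat4$counts), total = cat4$total),
        paste0(stem, "_eval.json"), auto_unbox = TRUE, digits = NA)
    }
    log_line("  %d nuclei segmented", res$n_nuclei)
    results[[inp$name]] <- res
  }
  invisible(list(results = results, params = cf, out_dir = out_dir))
}
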