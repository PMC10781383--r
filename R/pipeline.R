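#' Run the full estimation pipeline on a synthetic scene
#'
#' Convenience wrapper wiring all stages together: render (or accept) a
#' scene, calibrate against the panel, segment and label leaves, optionally
#' MSC-correct, build and normalize the 32-variable feature table, run a
#' selection algorithm, evaluate the prediction model by LOOCV and, if
#' requested, produce the pixel-wise pigment map with per-layer summaries.
#'
#' @param scene A `leaf_scene` from [render_scene()], or a [scene_config()]
#'   to render one.
#' @param target `"chl_ab"` or `"car"`.
#' @param preprocess `"msc"` or `"os"` (original spectra).
#' @param select `"sfs"`, `"corr"`, `"rfe"` or `"none"`.
#' @param select_learner Learner kind for the selection wrapper
#'   (`"pls"`, `"lm"`, `"svm_rbf"`).
#' @param model `"svr_rbf"` or `"plsr"`.
#' @param map Also compute the pixel map and layer summaries.
#' @param repeats Selection CV repeats (see [learner_spec()]).
#' @param seed Seed for all resampling in selection and tuning.
#' @return List with `scene`, `leaves`, `table`, `selection`, `report`
#'   (`eval_report`), `model` (`pigment_model`) and, when `map = TRUE`,
#'   `map` and `layers`.
#' @export
run_pipeline <- function(scene = scene_config(),
                         target = c("chl_ab", "car"),
                         preprocess = c("msc", "os"),
                         select = c("sfs", "corr", "rfe", "none"),
                         select_learner = c("svm_rbf", "lm", "pls"),
                         model = c("svr_rbf", "plsr"),
                         map = FALSE, repeats = 5, seed = 1) {
  target <- match.arg(target)
  preprocess <- match.arg(preprocess)
  select <- match.arg(select)
  select_learner <- match.arg(select_learner)
  model <- match.arg(model)
  if (inherits(scene, "scene_config")) scene <- render_scene(scene)
  stopifnot(inherits(scene, "leaf_scene"))

  refl <- calibrate(scene$image, scene$panel, scene$config$panel_reflectance)
  leaves <- segment_leaves(refl, exclude = scene$panel)
  leaves <- assign_layers(leaves, scene$truth$label_map,
                          scene$truth$leaf_table)
  spectra <- leaves$spectra
  img_for_map <- refl
  if (preprocess == "msc") {
    ideal <- ideal_spectrum(leaves, refl)
    spectra <- msc_correct(spectra, ideal)
    if (map) img_for_map <- msc_correct_image(refl, leaves, ideal)
  }
  targets <- scene$truth$leaf_table[match(leaves$truth_id,
                                          scene$truth$leaf_table$leaf_id), ]
  table <- build_feature_table(spectra, targets)
  table <- normalize_features(table)

  selection <- NULL
  subset <- colnames(table$features)
  if (select != "none") {
    sl <- learner_spec(select_learner, repeats = repeats, seed = seed)
    selection <- switch(select,
      sfs = sfs_select(table, target, sl),
      corr = corr_select(table, target, sl),
      rfe = rfe_select(table, target, sl))
    subset <- selection$subset
  }
  spec <- model_spec(model, seed = seed)
  report <- loocv(spec, table, target, subset)
  fitted <- fit_model(spec, table, target, subset)

  out <- list(scene = scene, leaves = leaves, table = table,
              selection = selection, report = report, model = fitted)
  if (map) {
    out$map <- predict_map(img_for_map, leaves, fitted)
    out$layers <- summarize_layers(out$map, leaves, scene$truth$leaf_table)
  }
  out
}
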