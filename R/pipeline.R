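# End-to-end orchestration: phantom -> preprocess -> (predicted | reference)
# dose -> ISO regions/rings -> constraint template -> evaluation -> gamma,
# with a JSON run manifest recording configs, seeds and file hashes.

#' Run the automatic-planning pipeline on a synthetic case
#'
#' Generates a phantom case, a reference dose, optionally trains the dose
#' prediction network on it and predicts (otherwise the reference dose
#' stands in for the prediction), discretizes the dose into ISO regions and
#' rings, exports ring structures to RTSTRUCT, builds the dialect's
#' constraint template and evaluates its objective, computes plan metrics
#' and a DSC curve, runs gamma analysis at 3%/3 mm and 3%/2 mm, and writes
#' every artifact plus a manifest under `out_dir`.
#'
#' @param out_dir output directory.
#' @param seed global seed; propagated to the phantom, the network and every
#'   other stochastic component.
#' @param modality `"VMAT"` or `"IMRT"`.
#' @param case_type `"single"` or `"SIB"`.
#' @param spec optional [phantom_spec()]; the default is a desk-scale
#'   64 x 64 x 32 grid at 6 mm with the standard volume goals.
#' @param train_steps training steps for the dose-prediction stage; 0 (the
#'   default) skips training and uses the reference dose as the predicted
#'   distribution.
#' @param min_level lowest constrained ring level.
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         modality = c("VMAT", "IMRT"),
                         case_type = c("single", "SIB"),
                         spec = NULL, train_steps = 0, min_level = 25) {
  modality <- match.arg(modality)
  case_type <- match.arg(case_type)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(spec)) {
    spec <- phantom_spec(seed = seed, modality = modality, case_type = case_type,
                         geometry = grid_geometry(c(64, 64, 32), c(6, 6, 6)))
  }
  pp <- preprocess_config(target_spacing = spec$geometry$spacing)
  stages <- list()
  tick <- function(name) stages[[length(stages) + 1L]] <<- name

  tick("phantom")
  case <- generate_case(spec)
  ref <- generate_reference_dose(case)
  case$dose <- ref
  ct_dir <- file.path(out_dir, "ct")
  write_ct_series(case$ct, ct_dir, seed = seed)
  write_structures(case$structures, file.path(out_dir, "anatomy_rtstruct.dcm"),
                   seed = seed)
  write_dose(ref, file.path(out_dir, "reference_rtdose.dcm"), seed = seed)

  tick("preprocess")
  case <- resample_case(case, pp)

  if (train_steps > 0) {
    tick("prediction")
    tr <- train_network(list(case),
                        training_config(learning_rate = 2e-3,
                                        steps = train_steps, seed = seed),
                        network_config(base_width = 8, depth = 3),
                        preprocess = pp)
    pred <- predict_dose(tr$network, case, pp)
    utils::write.csv(tr$history, file.path(out_dir, "training_log.csv"),
                     row.names = FALSE)
  } else {
    tick("prediction (reference surrogate)")
    pred <- ref
  }
  write_dose(pred, file.path(out_dir, "predicted_rtdose.dcm"), seed = seed + 1L)

  tick("iso regions and rings")
  n <- round(prescription_max(pred))
  iso <- make_iso_regions(pred, n)
  rings <- make_rings(iso)
  rings_path <- file.path(out_dir, "rings_rtstruct.dcm")
  rings_to_rtstruct(rings, rings_path, min_level = min_level, seed = seed)

  tick("constraint template")
  dialect <- if (modality == "IMRT") "pinnacle_imrt"
             else if (case_type == "SIB") "monaco_vmat_sib"
             else "monaco_vmat_single"
  organs <- intersect(c("bladder", "rectum", "small_intestine"),
                      names(case$structures))
  tpl <- if (dialect == "pinnacle_imrt") {
    build_template(dialect, n = n, min_level = min_level, organs = organs)
  } else {
    build_template(dialect, n = n, min_level = min_level)
  }
  tpl_path <- file.path(out_dir, sprintf("template_%s.tsv", dialect))
  serialize_template(tpl, tpl_path)

  tick("objective evaluation")
  all_masks <- c(case$structures$masks, rings$rings)
  if (dialect == "pinnacle_imrt") {
    for (org in organs) {
      for (k in c(30, 33, 36, 39)) {
        all_masks[[ring_organ_name(k, org)]] <-
          intersect_ring_organ(rings$rings[[ring_name(k)]],
                               case$structures[[org]])
      }
    }
  }
  obj <- evaluate_objective(pred, tpl, structure_set(all_masks))

  tick("plan metrics")
  pres <- if (case_type == "SIB") c(PTV45 = 45, PTV50 = 50) else c(PTV45 = 45)
  metrics <- plan_metrics(pred, case$structures, pres)
  utils::write.csv(metrics, file.path(out_dir, "plan_metrics.csv"),
                   row.names = FALSE)
  dsc <- dsc_curve(pred, case$dose, prescription_max(pred))
  utils::write.csv(data.frame(level_pct = dsc$level_pct, dsc = dsc$dsc),
                   file.path(out_dir, "dsc_curve.csv"), row.names = FALSE)

  tick("gamma analysis")
  shifted <- perturb_dose(pred, seed = seed, shift_mm = c(3, 0, 0),
                          noise_frac = 0.01)
  # 1 mm search step keeps the desk-scale run fast; the criteria proper are
  # still 3%/3 mm and 3%/2 mm
  g33 <- gamma_analysis(shifted, pred, gamma_criteria(3, 3, step_mm = 1))
  g32 <- gamma_analysis(shifted, pred, gamma_criteria(3, 2, step_mm = 1))
  qa_report(list(g33, g32), file.path(out_dir, "gamma_report.txt"))

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    seed = seed, modality = modality, case_type = case_type,
    phantom = spec[setdiff(names(spec), "geometry")],
    geometry = list(shape = spec$geometry$shape, spacing = spec$geometry$spacing),
    train_steps = train_steps, n = n, min_level = min_level,
    dialect = dialect, stages = unlist(stages),
    objective_total = obj$total,
    gamma_passing = c(`3/3` = g33$passing_rate, `3/2` = g32$passing_rate),
    file_md5 = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
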