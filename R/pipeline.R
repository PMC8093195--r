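#' Configuration of a cohort analysis run
#'
#' @param cohort_dir directory holding `cells.csv` and the per-cell manifests
#'   (as written by [make_cohort()] or assembled by hand in the same layout).
#' @param out_dir output directory for the report tables.
#' @param seed integer seed (recorded in all outputs; used by the embedding).
#' @param sag_at_pa sag measurement amplitude (default -400).
#' @param gain_freqs frequency grid of the gain analysis.
#' @param embed_min_cells minimum cohort size for the embedding step.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort_dir, out_dir, seed = 0L, sag_at_pa = -400,
                       gain_freqs = seq(2, 100, by = 0.2),
                       embed_min_cells = 10) {
  index_path <- file.path(cohort_dir, "cells.csv")
  if (!file.exists(index_path))
    stop("cohort index not found: ", index_path)
  structure(list(cohort_dir = cohort_dir, out_dir = out_dir,
                 seed = as.integer(seed), sag_at_pa = sag_at_pa,
                 gain_freqs = gain_freqs, embed_min_cells = embed_min_cells),
            class = "run_config")
}

#' Run the full cohort analysis
#'
#' Executes, per cell and per available protocol: passive/sag features and
#' spike features (step manifests), impedance resonance (subthreshold ZAP),
#' spike-probability density (suprathreshold ZAP), frequency-dependent gain
#' (frozen noise), and voltage-clamp Ih quantification; then assembles the
#' 14-feature table, embeds the cohort when large enough, and writes CSV
#' report tables plus a machine-readable provenance record. A failing module
#' is logged for that cell and the run continues.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with the report tables (`features`,
#'   `resonance`, `gain`, `vclamp`, `embedding`, `errors`) also written
#'   under `cfg$out_dir`.
#' @export
run_cohort_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  index <- read.csv(file.path(cfg$cohort_dir, "cells.csv"),
                    stringsAsFactors = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  errors <- data.frame(cell_id = character(0), stage = character(0),
                       message = character(0))
  note <- function(id, stage, e) {
    errors <<- rbind(errors, data.frame(cell_id = id, stage = stage,
                                        message = conditionMessage(e)))
    NULL
  }
  fvs <- list(); res_rows <- list(); vc_rows <- list(); gain_rows <- list()
  class_rows <- list()
  for (r in seq_len(nrow(index))) {
    id <- index$cell_id[r]
    man <- function(col) {
      if (!col %in% names(index) || is.na(index[[col]][r])) return(NULL)
      file.path(cfg$cohort_dir, index[[col]][r])
    }
    passive <- ap <- train <- NULL
    if (!is.null(man("manifest_steps"))) {
      steps <- tryCatch(read_sweep_table(man("manifest_steps")),
                        error = function(e) note(id, "io_steps", e))
      if (!is.null(steps)) {
        passive <- tryCatch(passive_features(steps, cfg$sag_at_pa),
                            error = function(e) note(id, "passive", e))
        train <- tryCatch(train_features(steps),
                          error = function(e) note(id, "train", e))
        ap <- tryCatch(ap_waveform_features(steps),
                       error = function(e) note(id, "ap", e))
        if (!is.null(ap) && !is.null(train)) {
          cls <- classify_cell(ap, train)
          class_rows[[id]] <- data.frame(cell_id = id,
                                         cell_class = cls$cell_class,
                                         bursting = cls$bursting)
        }
      }
    }
    fvs[[id]] <- assemble_feature_vector(passive, ap, train)
    if (!is.null(man("manifest_zap_sub"))) {
      prof <- tryCatch({
        trials <- read_sweep_table(man("manifest_zap_sub"))
        impedance_profile(trials, zap_protocol(sampling_rate =
                                                 trials[[1]]$sampling_rate))
      }, error = function(e) note(id, "resonance", e))
      if (!is.null(prof))
        res_rows[[id]] <- data.frame(cell_id = id, fR = prof$fR,
                                     f3db = prof$f3db,
                                     resonant = prof$resonant,
                                     n_trials = prof$n_trials_averaged)
    }
    if (!is.null(man("manifest_noise"))) {
      gp <- tryCatch({
        trials <- read_sweep_table(man("manifest_noise"))
        cell_gain(trials, freqs = cfg$gain_freqs)
      }, error = function(e) note(id, "gain", e))
      if (!is.null(gp))
        gain_rows[[id]] <- data.frame(cell_id = id, freq = gp$freqs,
                                      gain = gp$gain,
                                      phase = gp$phase_raw,
                                      phase_corrected = gp$phase_corrected,
                                      mean_rate = gp$mean_rate)
    }
    if (!is.null(man("manifest_vclamp"))) {
      vc <- tryCatch({
        sweeps <- read_sweep_table(man("manifest_vclamp"))
        st <- ih_step_amplitudes(sweeps)
        acur <- activation_curve(st)
        data.frame(cell_id = id, V50 = acur$V50, k = acur$k,
                   max_ih = max(st$ih_amplitude))
      }, error = function(e) note(id, "vclamp", e))
      if (!is.null(vc)) vc_rows[[id]] <- vc
    }
  }
  features <- feature_table(fvs)
  features <- merge(index[, intersect(c("cell_id", "layer_label", "archetype",
                                        "cell_class", "bursting"),
                                      names(index))],
                    features, by = "cell_id", sort = TRUE)
  classes <- if (length(class_rows)) do.call(rbind, class_rows) else NULL
  if (!is.null(classes))
    features <- merge(features, setNames(classes,
                                         c("cell_id", "assigned_class",
                                           "assigned_bursting")),
                      by = "cell_id", sort = TRUE)
  embedding <- NULL
  if (nrow(features) >= cfg$embed_min_cells) {
    embedding <- tryCatch(embed_cohort(features, seed = cfg$seed),
                          error = function(e) note("cohort", "embedding", e))
  }
  bindrows <- function(lst) if (length(lst)) do.call(rbind, lst) else
    data.frame()
  out <- list(features = features,
              resonance = bindrows(res_rows),
              gain = bindrows(gain_rows),
              vclamp = bindrows(vc_rows),
              embedding = if (!is.null(embedding)) embedding$coords else
                data.frame(),
              errors = errors)
  for (nm in names(out))
    write.csv(out[[nm]], file.path(cfg$out_dir, paste0(nm, ".csv")),
              row.names = FALSE)
  prov <- list(seed = cfg$seed, sag_at_pa = cfg$sag_at_pa,
               gain_freqs = range(cfg$gain_freqs),
               n_cells = nrow(index),
               package_version = as.character(utils::packageVersion("ephys")))
  jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
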