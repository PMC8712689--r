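#' Pipeline configuration
#'
#' Collects every tunable constant of the workflow with the published
#' defaults: 3.63 um/px darkfield and 2.78 um/px fluorescence pixel sizes,
#' cell granulometry 18-207 um by 7.26 um, rind-thickness granulometry up
#' to 1456 um, 0.5 um wall thickness, 500/1000 um parenchyma distance
#' bands, visible gain 2 and the baseline channel set. Unit suffixes are
#' part of every key name.
#'
#' @param darkfield_pixel_um,fluo_pixel_um pixel sizes.
#' @param segmentation [segmentation_params()].
#' @param granulo_sizes_um cell-granulometry sizes.
#' @param rind_max_size_um rind granulometry maximum.
#' @param wall_thickness_um stereology wall thickness.
#' @param visible_gain multispectral assembly gain.
#' @param baseline baseline channel set.
#' @param seed default RNG seed for simulated inputs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(darkfield_pixel_um = 3.63,
                            fluo_pixel_um = 2.78,
                            segmentation = segmentation_params(),
                            granulo_sizes_um = seq(18, 207, by = 7.26),
                            rind_max_size_um = 1456,
                            wall_thickness_um = 0.5,
                            visible_gain = 2,
                            baseline = baseline_channels(),
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load, segmentation, morphometry, stereology,
#' pseudospectra and statistics for a set of sections, writing tidy CSV
#' outputs and a provenance log. Rerunning with identical inputs and
#' configuration is a no-op (content-hash check on the provenance log).
#'
#' @param sections list of section descriptions. Each element is a list
#'   with `id` and either `simulate` (a [phantom_params()]) or `darkfield`
#'   (path to a TIFF; optional `multispectral` path of a stack written by
#'   [write_multispectral()]).
#' @param out_dir output directory.
#' @param config [pipeline_config()].
#' @param composition optional data.frame (as [load_composition_table()])
#'   to correlate against fluorescence; section ids must carry the line in
#'   `line` field of the section description for matching.
#' @return invisible list with the collected tables; files are written to
#'   `out_dir`: `descriptors.csv`, `granulometry.csv`, `pseudospectra.csv`,
#'   `provenance.json`.
#' @export
run_pipeline <- function(sections, out_dir, config = pipeline_config(),
                         composition = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run_hash <- digest_input(list(sections = sections, config = config,
                                composition = composition))
  prov_path <- file.path(out_dir, "provenance.json")
  if (file.exists(prov_path)) {
    prev <- try(jsonlite::read_json(prov_path), silent = TRUE)
    if (!inherits(prev, "try-error") && identical(prev$run_hash, run_hash) &&
        file.exists(file.path(out_dir, "descriptors.csv"))) {
      message("run up to date (hash ", substr(run_hash, 1, 8), "); nothing to do")
      return(invisible(NULL))
    }
  }
  t_start <- Sys.time()
  desc_rows <- list()
  gran_rows <- list()
  spec_rows <- list()
  warnings_log <- character(0)
  for (sec in sections) {
    id <- sec$id %||% stop("every section needs an id")
    if (!is.null(sec$simulate)) {
      ph <- generate_phantom(sec$simulate)
      img <- ph$darkfield
      ms <- ph$multispectral
      px <- sec$simulate$pixel_size_um
    } else {
      img <- read_tiff(sec$darkfield)[[1]]
      ms <- if (!is.null(sec$multispectral)) read_multispectral(sec$multispectral)
      px <- sec$pixel_size_um %||% config$darkfield_pixel_um
    }
    rois <- segment_stem(img, px, config$segmentation)
    if (rois$rind_damaged)
      warnings_log <- c(warnings_log, paste0(id, ": rind flagged as damaged"))
    desc <- stem_descriptors(rois, img, diffEstMeas = 0,
                             granulo_sizes_um = config$granulo_sizes_um)
    ster <- try(stereology_from_descriptors(desc, config$wall_thickness_um),
                silent = TRUE)
    row <- data.frame(section = id, line = sec$line %||% NA_character_,
                      as.data.frame(unclass(desc)[setdiff(names(unclass(desc)),
                                                          character(0))]))
    if (!inherits(ster, "try-error")) {
      row$Pm_CD <- ster$Pm_CD; row$Pr_CD <- ster$Pr_CD
      row$CW_T <- ster$CW_T
      row$Ri_Cw <- ster$Ri_Cw; row$Vb_Cw <- ster$Vb_Cw
      row$Pm_Cw <- ster$Pm_Cw; row$Pr_Cw <- ster$Pr_Cw
    }
    desc_rows[[id]] <- row
    for (roi_name in c("parenchyma_middle", "parenchyma_near_rind")) {
      cv <- try(graylevel_granulometry(img, rois[[roi_name]], "closing",
                                       config$granulo_sizes_um, px),
                silent = TRUE)
      if (!inherits(cv, "try-error") && !cv$degenerate)
        gran_rows[[paste(id, roi_name)]] <-
          data.frame(section = id, roi = roi_name, size_um = cv$sizes_um,
                     value_pct = cv$values_pct)
    }
    if (!is.null(ms) && !inherits(ster, "try-error")) {
      sp <- try(section_pseudospectra(ms, rois, ster$Pm_CD, ster$Pr_CD),
                silent = TRUE)
      if (!inherits(sp, "try-error")) {
        for (t in names(sp$specs)) {
          s <- sp$specs[[t]]
          spec_rows[[paste(id, t)]] <-
            data.frame(section = id, line = sec$line %||% NA_character_,
                       tissue = t, channel = channel_names(),
                       value = unname(s$values),
                       background_corrected = s$background_corrected,
                       density_corrected = s$density_corrected,
                       section_normalized = s$section_normalized)
        }
      } else {
        warnings_log <- c(warnings_log, paste0(id, ": pseudospectra failed"))
      }
    }
  }
  descriptors <- do.call(rbind, c(desc_rows, list(make.row.names = FALSE)))
  write.csv(descriptors, file.path(out_dir, "descriptors.csv"),
            row.names = FALSE)
  if (length(gran_rows))
    write.csv(do.call(rbind, gran_rows), file.path(out_dir, "granulometry.csv"),
              row.names = FALSE)
  if (length(spec_rows))
    write.csv(do.call(rbind, spec_rows),
              file.path(out_dir, "pseudospectra.csv"), row.names = FALSE)
  prov <- list(run_hash = run_hash,
               package_version = as.character(utils::packageVersion("stemhisto")),
               started = format(t_start), finished = format(Sys.time()),
               n_sections = length(sections), warnings = warnings_log)
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE)
  invisible(list(descriptors = descriptors,
                 granulometry = if (length(gran_rows)) do.call(rbind, gran_rows),
                 pseudospectra = if (length(spec_rows)) do.call(rbind, spec_rows),
                 provenance = prov))
}

# content hash of a run request (serialisation-based, version-stable enough
# for idempotence checks within one installation)
digest_input <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2)
  unname(tools::md5sum(tmp))
}
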