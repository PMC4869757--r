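# Orchestration: phantom cohort generation, the full per-patient analysis
# (wash-in maps, normalizations, AIF + Tofts fits, both correlation levels),
# cohort summaries, and run manifests with input/output checksums.

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

file_checksums <- function(paths) {
  paths <- paths[file.exists(paths)]
  sums <- tools::md5sum(paths)
  stats::setNames(unname(sums), basename(paths))
}

#' Generate and write a phantom cohort
#'
#' One phantom per synthetic patient, written as a directory of NIfTI
#' volumes (measured maps, dynamic series with timing sidecars, masks and
#' noise-free truth maps) plus a per-patient YAML and a run manifest
#' recording every seed and output checksum.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{output_dir}{cohort output directory.}
#'     \item{overwrite}{logical; refuse an existing directory when FALSE
#'       (default).}
#'     \item{patients}{list of per-patient lists: `id`, `seed`, and
#'       `modalities` (subset of "fdg", "fmiso", "washin", "adc", "dce";
#'       default all).}
#'     \item{phantom}{optional list of [phantom_config] arguments shared by
#'       all patients (per-patient `seed` overrides its seed).}
#'   }
#' @return list: `datasets` (in-memory `phantom_dataset`s, named by patient
#'   id) and `manifest`. A cohort of zero patients yields an empty manifest.
#' @export
run_phantom_cohort <- function(config) {
  out_dir <- config$output_dir
  overwrite <- isTRUE(config$overwrite)
  patients <- config$patients
  if (is.null(patients)) patients <- list()
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && !overwrite &&
        length(list.files(out_dir)) > 0L)
      stop("output directory ", out_dir,
           " exists and is not empty; set overwrite = TRUE to replace")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  all_mods <- c("fdg", "fmiso", "washin", "adc", "dce")
  datasets <- list()
  manifest <- list(kind = "phantom-cohort",
                   config_hash = config_hash(config),
                   package_version = as.character(
                     utils::packageVersion("petmrcorr")),
                   patients = list())
  for (p in patients) {
    if (is.null(p$id) || is.null(p$seed))
      stop("each patient entry needs an id and a seed")
    mods <- if (is.null(p$modalities)) all_mods else p$modalities
    pargs <- if (is.null(config$phantom)) list() else config$phantom
    pargs$seed <- p$seed
    ph <- make_phantom(do.call(phantom_config, pargs))
    datasets[[p$id]] <- ph
    entry <- list(id = p$id, seed = p$seed, modalities = mods,
                  warnings = ph$warnings)
    if (!is.null(out_dir)) {
      pdir <- file.path(out_dir, p$id)
      dir.create(file.path(pdir, "truth"), recursive = TRUE,
                 showWarnings = FALSE)
      if ("fdg" %in% mods)
        write_volume(ph$maps$fdg, file.path(pdir, "fdg.nii.gz"))
      if ("fmiso" %in% mods)
        write_volume(ph$maps$fmiso, file.path(pdir, "fmiso.nii.gz"))
      if ("adc" %in% mods)
        write_volume(ph$maps$adc, file.path(pdir, "adc.nii.gz"))
      if ("washin" %in% mods)
        write_volume(ph$fmiso_washin_series,
                     file.path(pdir, "fmiso_washin.nii.gz"))
      if ("dce" %in% mods)
        write_volume(ph$dce_series, file.path(pdir, "dce.nii.gz"))
      for (m in names(ph$masks))
        write_volume(ph$masks[[m]],
                     file.path(pdir, paste0("mask_", m, ".nii.gz")))
      for (tn in setdiff(names(ph$truth), "fields"))
        write_volume(ph$truth[[tn]],
                     file.path(pdir, "truth", paste0(tn, ".nii.gz")))
      yaml::write_yaml(
        list(id = p$id, seed = p$seed, modalities = mods,
             injected_activity_MBq = ph$injection$injected_activity_MBq,
             body_weight_kg = ph$injection$body_weight_kg,
             dce_baseline_frames = ph$config$dce_baseline_frames,
             warnings = ph$warnings),
        file.path(pdir, "patient.yaml"))
      entry$checksums <- file_checksums(
        list.files(pdir, recursive = TRUE, full.names = TRUE))
    }
    manifest$patients[[p$id]] <- entry
  }
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(datasets = datasets, manifest = manifest)
}

# assemble a correlation_result from a regions x modalities value matrix
correlation_from_value_matrix <- function(vals, patient, level, n_regions) {
  labs <- colnames(vals)
  k <- length(labs)
  r <- matrix(NA_real_, k, k, dimnames = list(labs, labs)); diag(r) <- 1
  nmat <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  notes <- character()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    keep <- is.finite(vals[, i]) & is.finite(vals[, j])
    res <- tryCatch(
      list(r = spearman_cor(vals[keep, i], vals[keep, j]), n = sum(keep)),
      error = function(e) {
        notes <<- c(notes, sprintf("%s/%s: %s", labs[i], labs[j],
                                   conditionMessage(e)))
        NULL
      })
    if (!is.null(res)) {
      r[i, j] <- r[j, i] <- res$r
      nmat[i, j] <- nmat[j, i] <- res$n
    }
  }
  structure(list(patient = patient, level = level, r = r, n = nmat,
                 excluded = FALSE, reason = NULL, n_regions = n_regions,
                 notes = notes),
            class = "correlation_result")
}

read_phantom_patient <- function(pdir) {
  meta <- yaml::read_yaml(file.path(pdir, "patient.yaml"))
  rd <- function(f) {
    p <- file.path(pdir, f)
    if (file.exists(p)) read_volume(p) else NULL
  }
  list(meta = meta,
       maps = list(fdg = rd("fdg.nii.gz"), fmiso = rd("fmiso.nii.gz"),
                   adc = rd("adc.nii.gz")),
       washin = rd("fmiso_washin.nii.gz"),
       dce = rd("dce.nii.gz"),
       masks = list(
         gtv = read_mask(file.path(pdir, "mask_gtv.nii.gz"), "GTV"),
         muscle = read_mask(file.path(pdir, "mask_muscle.nii.gz"),
                            "background-muscle"),
         carotid = read_mask(file.path(pdir, "mask_carotid.nii.gz"),
                             "carotid")),
       injection = injection_record(meta$injected_activity_MBq,
                                    meta$body_weight_kg),
       dce_baseline_frames = meta$dce_baseline_frames)
}

analyze_one_patient <- function(id, ph, modalities, settings) {
  window <- settings$window
  spec <- settings$spec
  gtv <- ph$masks$gtv

  corr_maps <- list()
  if ("fdg" %in% modalities && !is.null(ph$maps$fdg)) {
    suv <- to_suv(ph$maps$fdg, ph$injection)
    suv$name <- "FDG"
    corr_maps$FDG <- suv
  }
  if ("fmiso" %in% modalities && !is.null(ph$maps$fmiso)) {
    tbr <- to_tbr(ph$maps$fmiso, ph$masks$muscle)
    tbr$name <- "FMISO"
    corr_maps$FMISO <- tbr
  }
  if ("adc" %in% modalities && !is.null(ph$maps$adc)) {
    adc <- ph$maps$adc; adc$name <- "ADC"
    corr_maps$ADC <- adc
  }
  if ("washin" %in% modalities && !is.null(ph$fmiso_washin_series)) {
    af <- mean_activity_map(ph$fmiso_washin_series, window)
    af$name <- "A_FMISO"
    corr_maps$A_FMISO <- af
  }

  tofts_level <- settings$tofts_level
  aif <- NULL
  regional_tofts <- NULL
  if ("dce" %in% modalities && !is.null(ph$dce_series)) {
    nb <- ph$dce_baseline_frames
    enh <- signal_enhancement_series(ph$dce_series, nb)
    ds <- mean_activity_map(enh, window)
    ds$name <- "dS_DCE"
    corr_maps$dS_DCE <- ds

    if (tofts_level != "none") {
      aif <- if (inherits(settings$aif, "aif_model")) settings$aif else {
        nv <- prod(ph$dce_series$grid$shape)
        nt <- dim(enh$frames)[4L]
        cm <- matrix(enh$frames, nv, nt)
        carotid_curve <- colMeans(
          cm[as.vector(ph$masks$carotid$membership), , drop = FALSE])
        fit_aif(carotid_curve, enh$frame_starts)
      }
      fit_cfg <- list(n_baseline_frames = nb, scale = settings$dce_scale,
                      refine = settings$refine)
      if (tofts_level %in% c("voxel", "both")) {
        tm <- fit_tofts_map(ph$dce_series, gtv, aif, fit_cfg)
        tm$ktrans$name <- "Ktrans"; tm$ve$name <- "ve"; tm$vp$name <- "vp"
        corr_maps$Ktrans <- tm$ktrans
        corr_maps$ve <- tm$ve
        corr_maps$vp <- tm$vp
      }
      if (tofts_level %in% c("regional", "both"))
        regional_tofts <- TRUE  # fitted below, on the kept regions
    }
  }

  if (length(corr_maps) < 2L)
    stop("patient ", id, ": fewer than 2 maps available")

  voxel_res <- patient_correlation_matrix(corr_maps, gtv, "voxel",
                                          spec = spec, patient = id,
                                          min_regions = settings$min_regions)

  # regional level: per-region means of every map; DCE kinetic parameters
  # are re-fitted per region (block-averaged curves) rather than averaged
  regions <- partition_regions(gtv, spec)
  if (length(regions) < settings$min_regions) {
    regional_res <- structure(
      list(patient = id, level = "regional", r = NULL, n = NULL,
           excluded = TRUE,
           reason = sprintf("only %d sub-regions (minimum %d)",
                            length(regions), settings$min_regions),
           n_regions = length(regions), notes = character()),
      class = "correlation_result")
  } else {
    nr <- length(regions)
    base_labs <- names(corr_maps)
    base_labs <- setdiff(base_labs, c("Ktrans", "ve", "vp"))
    vals <- matrix(NA_real_, nr, length(base_labs),
                   dimnames = list(NULL, base_labs))
    for (lab in base_labs) {
      v <- as.vector(corr_maps[[lab]]$values)
      vals[, lab] <- vapply(regions, function(rg) {
        x <- v[rg]; x <- x[is.finite(x)]
        if (length(x)) mean(x) else NA_real_
      }, numeric(1))
    }
    if (isTRUE(regional_tofts)) {
      fits <- fit_tofts_regional(
        ph$dce_series, regions, aif,
        list(n_baseline_frames = ph$dce_baseline_frames,
             scale = settings$dce_scale, refine = settings$refine))
      getp <- function(fld) vapply(fits, function(f)
        if (is.null(f)) NA_real_ else f[[fld]], numeric(1))
      vals <- cbind(vals, Ktrans = getp("ktrans"), ve = getp("ve"),
                    vp = getp("vp"))
    }
    regional_res <- correlation_from_value_matrix(vals, id, "regional", nr)
  }

  list(voxel = voxel_res, regional = regional_res,
       maps = corr_maps, aif = aif)
}

#' Run the full multi-parametric correlation analysis over a cohort
#'
#' Per patient: SUV and TBR normalization, wash-in mean maps (FMISO and
#' DCE), per-patient AIF fit from the carotid ROI, extended Tofts fits at
#' the configured level, then pairwise Spearman matrices at voxel and
#' regional level with the sub-region exclusion rule, and a cohort summary.
#' A failing patient is reported and skipped; the run fails only when every
#' patient fails.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{input_dir}{cohort directory from [run_phantom_cohort]
#'       (alternative to `datasets`).}
#'     \item{datasets}{named list of in-memory `phantom_dataset`s
#'       (alternative to `input_dir`).}
#'     \item{patients}{optional per-patient modality restriction: named
#'       list id -> character vector of modalities.}
#'     \item{window}{[integration_window]; default 0-240 s.}
#'     \item{spec}{[region_spec]; default 3x3x4 blocks.}
#'     \item{min_regions}{regional exclusion threshold; default 10.}
#'     \item{tofts_level}{"regional" (default), "voxel", "both" or "none".}
#'     \item{aif}{an [aif_model] to use directly, or "fit" (default) to fit
#'       the carotid curve per patient.}
#'     \item{dce_scale}{enhancement-per-concentration factor for the fits;
#'       default 1 (absorbed into the AIF amplitude when the AIF is fitted
#'       from enhancement).}
#'     \item{refine}{Tofts forward refinement; default 5.}
#'     \item{output_dir}{optional: write result CSVs and a manifest.}
#'   }
#' @return list: `results` (flat list of `correlation_result`s),
#'   `summary` (cohort table from [cohort_summary]), `matrix` (voxel upper /
#'   regional lower median matrix), `failures` (named error messages),
#'   `manifest`, and `details` (per-patient maps and AIF).
#' @export
run_analysis <- function(config) {
  settings <- list(
    window = if (is.null(config$window)) integration_window()
             else config$window,
    spec = if (is.null(config$spec)) region_spec() else config$spec,
    min_regions = if (is.null(config$min_regions)) 10L
                  else config$min_regions,
    tofts_level = if (is.null(config$tofts_level)) "regional"
                  else match.arg(config$tofts_level,
                                 c("regional", "voxel", "both", "none")),
    aif = if (is.null(config$aif)) "fit" else config$aif,
    dce_scale = if (is.null(config$dce_scale)) 1 else config$dce_scale,
    refine = if (is.null(config$refine)) 5 else config$refine)

  all_mods <- c("fdg", "fmiso", "washin", "adc", "dce")
  inputs <- list()
  if (!is.null(config$datasets)) {
    for (id in names(config$datasets)) {
      ph <- config$datasets[[id]]
      inputs[[id]] <- list(
        id = id,
        ph = list(maps = ph$maps, fmiso_washin_series =
                    ph$fmiso_washin_series,
                  dce_series = ph$dce_series, masks = ph$masks,
                  injection = ph$injection,
                  dce_baseline_frames = ph$config$dce_baseline_frames),
        modalities = all_mods)
    }
  } else if (!is.null(config$input_dir)) {
    pdirs <- list.dirs(config$input_dir, recursive = FALSE)
    for (pdir in pdirs) {
      pat <- read_phantom_patient(pdir)
      id <- pat$meta$id
      inputs[[id]] <- list(
        id = id,
        ph = list(maps = pat$maps, fmiso_washin_series = pat$washin,
                  dce_series = pat$dce, masks = pat$masks,
                  injection = pat$injection,
                  dce_baseline_frames = pat$dce_baseline_frames),
        modalities = if (is.null(pat$meta$modalities)) all_mods
                     else unlist(pat$meta$modalities))
    }
  } else stop("config needs either datasets or input_dir")

  if (!is.null(config$patients)) {
    for (id in names(config$patients))
      if (id %in% names(inputs))
        inputs[[id]]$modalities <- config$patients[[id]]
  }

  results <- list(); details <- list(); failures <- character()
  for (id in names(inputs)) {
    inp <- inputs[[id]]
    out <- tryCatch(
      analyze_one_patient(id, inp$ph, inp$modalities, settings),
      error = function(e) conditionMessage(e))
    if (is.character(out)) {
      failures[id] <- out
      message("patient ", id, " failed: ", out)
      next
    }
    results[[paste0(id, ".voxel")]] <- out$voxel
    results[[paste0(id, ".regional")]] <- out$regional
    details[[id]] <- list(maps = out$maps, aif = out$aif)
  }
  if (length(results) == 0L)
    stop("all patients failed: ",
         paste(names(failures), failures, sep = ": ", collapse = "; "))

  summary <- cohort_summary(results)
  mat <- if (nrow(summary)) correlation_matrix_table(summary) else NULL

  manifest <- list(kind = "analysis",
                   config_hash = config_hash(config[setdiff(
                     names(config), "datasets")]),
                   package_version = as.character(
                     utils::packageVersion("petmrcorr")),
                   n_patients = length(inputs),
                   failures = as.list(failures),
                   exclusions = lapply(
                     Filter(function(r) r$excluded, results),
                     function(r) r$reason))

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_csv(results, file.path(config$output_dir,
                                         "correlations.csv"))
    utils::write.csv(summary,
                     file.path(config$output_dir, "cohort_summary.csv"),
                     row.names = FALSE)
    if (!is.null(mat))
      utils::write.csv(mat,
                       file.path(config$output_dir, "median_matrix.csv"))
    manifest$checksums <- file_checksums(list.files(
      config$output_dir, full.names = TRUE, pattern = "\\.csv$"))
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(results = results, summary = summary, matrix = mat,
       failures = failures, manifest = manifest, details = details)
}

#' Write per-patient correlation results as a tidy CSV
#'
#' Columns: patient, pair, level, r, n, excluded.
#'
#' @param results list of `correlation_result`s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  rows <- list()
  for (res in results) {
    if (res$excluded || is.null(res$r)) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient = res$patient, pair = NA_character_, level = res$level,
        r = NA_real_, n = NA_real_, excluded = TRUE,
        stringsAsFactors = FALSE)
      next
    }
    labs <- rownames(res$r)
    k <- length(labs)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      ab <- sort(c(labs[i], labs[j]))
      rows[[length(rows) + 1L]] <- data.frame(
        patient = res$patient, pair = paste(ab, collapse = "/"),
        level = res$level, r = res$r[i, j], n = res$n[i, j],
        excluded = FALSE, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
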