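# End-to-end driver: a structured run configuration and the fixed-order
# pipeline coregister -> preprocess -> weight -> fuse -> evaluate.

#' Default run configuration
#'
#' Nested list of every tunable parameter of the pipeline. Spatial
#' co-registration runs *first* (both modalities are brought onto the
#' MALDI grid before spectral preprocessing), then Raman preprocessing
#' (spike removal, SNIP fluorescence background, vector normalization),
#' then MALDI preprocessing (SNIP chemical background with LLS
#' compression, phase correction, peak picking, mass-relative binning,
#' TIC normalization), then l1-ratio weighting, fusion and PCA.
#'
#' @return named list of class `RunConfig`.
#' @export
default_config <- function() {
  structure(list(
    seed = 42L,
    outdir = NULL,
    input = list(source = "phantom", raman = NULL, maldi = NULL,
                 landmarks = NULL, maldi_format = "imzml"),
    synth = list(),
    snip = list(window_raman = 40L, window_maldi = 25L,
                lls_raman = FALSE, lls_maldi = TRUE,
                order = "increasing"),
    raman = list(spike_z = 8, norm = "l2", target_axis = NULL),
    maldi = list(tolerance_ppm = 200, snr = 6, noise = "local",
                 noise_window = 401L, max_shift = 0.5,
                 anchor_quantile = 0.99, norm = "tic"),
    fuse = list(weight = "auto"),
    evaluate = list(components = 10L, sweep = FALSE,
                    sweep_coefficients = 1:20, sweep_k = 10L,
                    pcs = c(1L, 2L, 3L), correlation = FALSE,
                    composites = FALSE)),
    class = "RunConfig")
}

merge_config <- function(base, over, path = "") {
  unknown <- setdiff(names(over), names(base))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]],
                                 paste0(path, nm, "."))
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Build a run configuration
#'
#' Starts from [default_config()] and applies overrides, rejecting any
#' key the pipeline does not know.
#'
#' @param overrides named list (possibly nested) of overrides, or a path
#'   to a JSON file holding one.
#' @return a `RunConfig`.
#' @export
run_config <- function(overrides = list()) {
  if (is.character(overrides) && length(overrides) == 1L)
    overrides <- jsonlite::read_json(overrides, simplifyVector = TRUE)
  cfg <- merge_config(unclass(default_config()), overrides)
  structure(cfg, class = "RunConfig")
}

log_stage <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
}

pixel_key <- function(coords) paste(signif(coords[, 1], 10),
                                    signif(coords[, 2], 10))

#' Run the full fusion pipeline
#'
#' Executes the fixed stage order (co-registration, per-modality
#' preprocessing, weighting, fusion, PCA evaluation) and returns a
#' machine-readable report. With the default `"phantom"` input the run is
#' fully reproducible from `config$seed` alone; file input reads the
#' Raman map and landmarks as wide CSV and the MALDI map as imzML or wide
#' CSV. When `config$outdir` is set, the report, the resolved
#' configuration, the cumulative-variance curves and (optionally)
#' composites and correlation matrices are written there.
#'
#' @param config a `RunConfig` from [run_config()].
#' @param verbose log one line per stage (default TRUE).
#' @return list of class `RunReport`: fused matrix diagnostics, the PCA
#'   model, the report list that is serialized to JSON, plus the aligned
#'   blocks for further analysis.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  set.seed(as.integer(config$seed))
  report <- list(seed = as.integer(config$seed), stages = character(0))
  mark <- function(s) report$stages <<- c(report$stages, s)

  ## ---- input -----------------------------------------------------------
  truth <- NULL
  if (identical(config$input$source, "phantom")) {
    ph <- do.call(phantom_config, config$synth)
    d <- generate_phantom(ph, seed = config$seed)
    raman <- d$raman; maldi <- d$maldi; truth <- d$truth
    landmarks <- truth$landmarks
    log_stage(verbose, "input", "phantom: raman %d px, maldi %d px",
              n_pixels(raman), n_pixels(maldi))
  } else if (identical(config$input$source, "files")) {
    raman <- read_spectral_map(config$input$raman, "wide_csv", "raman")
    maldi <- read_spectral_map(config$input$maldi,
                               config$input$maldi_format, "maldi")
    landmarks <- read_landmarks(config$input$landmarks)
    log_stage(verbose, "input", "files: raman %d px, maldi %d px",
              n_pixels(raman), n_pixels(maldi))
  } else stop("config error: input.source must be 'phantom' or 'files'")
  mark("input")

  ## ---- co-registration (first, before spectral preprocessing) ----------
  tr <- fit_affine(landmarks)
  rs <- resample_to_grid(raman, maldi$coords, tr)
  raman_g <- rs$map
  log_stage(verbose, "coregister",
            "landmark RMS %.3g um; %d/%d target points covered",
            sqrt(mean(tr$fit_residuals^2)), sum(rs$counts > 0),
            length(rs$counts))
  report$coregister <- list(
    landmark_rms_um = sqrt(mean(tr$fit_residuals^2)),
    covered = sum(rs$counts > 0), targets = length(rs$counts),
    mean_count = mean(rs$counts[rs$counts > 0]))
  mark("coregister")

  ## ---- Raman preprocessing ---------------------------------------------
  if (!is.null(config$raman$target_axis))
    raman_g <- interpolate_axis(raman_g, config$raman$target_axis)
  miss_r <- raman_g$meta$missing_pixels %||% integer(0)
  work <- if (length(miss_r)) drop_pixels(raman_g, miss_r) else raman_g
  mask <- detect_spikes(work, z_threshold = config$raman$spike_z)
  work <- remove_spikes(work, mask)
  work <- subtract_baseline(work, snip_params(config$snip$window_raman,
                                              lls = config$snip$lls_raman,
                                              order = config$snip$order))
  work <- normalize(work, config$raman$norm)
  raman_p <- work
  log_stage(verbose, "raman", "%d spike cells removed; %s-normalized",
            sum(mask$flags), config$raman$norm)
  report$raman <- list(spike_cells = sum(mask$flags),
                       norm = config$raman$norm,
                       n_pixels = n_pixels(raman_p))
  mark("preprocess_raman")

  ## ---- MALDI preprocessing ---------------------------------------------
  mal <- subtract_baseline(maldi, snip_params(config$snip$window_maldi,
                                              lls = config$snip$lls_maldi,
                                              order = config$snip$order))
  phc <- phase_correct(mal, max_shift = config$maldi$max_shift,
                       anchor_quantile = config$maldi$anchor_quantile)
  mal <- phc$data
  plists <- lapply(seq_len(n_pixels(mal)), function(i)
    pick_peaks(mal$axis, mal$intensities[i, ], snr = config$maldi$snr,
               pixel_id = i, noise = config$maldi$noise,
               noise_window = config$maldi$noise_window))
  binned <- bin_peaks(plists, tolerance_ppm = config$maldi$tolerance_ppm,
                      coords = mal$coords)
  maldi_p <- if (identical(config$maldi$norm, "tic"))
    tic_normalize(binned$map, on_zero = "drop")
  else normalize_ms(binned$map, config$maldi$norm)
  log_stage(verbose, "maldi",
            "%d anchors, %d bins, offsets RMS %.4g Da, norm %s",
            length(attr(phc$model, "anchors")),
            length(binned$bins$centroids),
            sqrt(mean(phc$model$offset^2)), config$maldi$norm)
  report$maldi <- list(n_anchors = length(attr(phc$model, "anchors")),
                       n_bins = length(binned$bins$centroids),
                       offset_rms_da = sqrt(mean(phc$model$offset^2)),
                       norm = config$maldi$norm)
  mark("preprocess_maldi")

  ## ---- align pixel sets -------------------------------------------------
  keys_r <- pixel_key(raman_p$coords)
  keys_m <- pixel_key(maldi_p$coords)
  common <- intersect(keys_r, keys_m)
  if (length(common) < 3L) stop("fewer than 3 pixels shared between blocks")
  ir <- match(common, keys_r); im <- match(common, keys_m)
  sub_map <- function(m, i) {
    m$intensities <- m$intensities[i, , drop = FALSE]
    m$coords <- m$coords[i, , drop = FALSE]
    m
  }
  raman_p <- sub_map(raman_p, ir)
  maldi_p <- sub_map(maldi_p, im)
  kept_key <- common
  mark("align")

  ## ---- weighting and fusion --------------------------------------------
  w <- if (identical(config$fuse$weight, "auto")) l1_weight(raman_p, maldi_p)
       else as.numeric(config$fuse$weight)
  fused <- fuse_blocks(raman_p, maldi_p, w = w)
  blocks <- split_blocks(fused)
  report$fuse <- list(
    w = w,
    l1_raman = sum(abs(blocks[[raman_p$modality]])),
    l1_maldi_weighted = sum(abs(blocks[[maldi_p$modality]])),
    n_pixels = nrow(fused$matrix), n_channels = ncol(fused$matrix))
  log_stage(verbose, "fuse", "w = %.6g, fused %d x %d", w,
            nrow(fused$matrix), ncol(fused$matrix))
  mark("fuse")

  ## ---- evaluation -------------------------------------------------------
  k <- min(config$evaluate$components,
           nrow(fused$matrix) - 1L, ncol(fused$matrix))
  model <- pca(fused, k = k)
  report$pca <- list(k = k, explained = model$explained,
                     cumulative = model$cumulative)
  sweep_res <- NULL
  if (isTRUE(config$evaluate$sweep)) {
    sweep_res <- weight_sweep(raman_p, maldi_p,
                              coefficients = config$evaluate$sweep_coefficients,
                              k = min(config$evaluate$sweep_k, k))
    report$sweep <- list(coefficients = sweep_res$coefficients,
                         argmin_per_k = sweep_res$argmin_per_k)
  }
  corr <- NULL
  if (isTRUE(config$evaluate$correlation)) {
    corr <- cross_correlation(raman_p, maldi_p)
    report$correlation <- list(
      max_abs_r = max(abs(corr), na.rm = TRUE),
      mean_abs_r = mean(abs(corr), na.rm = TRUE))
  }
  recovery <- NULL
  if (!is.null(truth)) {
    tm <- truth$component_maps$maldi[
      match(kept_key, pixel_key(maldi$coords)), , drop = FALSE]
    recovery <- score_recovery(model, tm, k = min(3L, k))
    report$recovery <- list(best_abs_r = recovery,
                            lipid = recovery[truth$lipid_component])
  }
  log_stage(verbose, "evaluate", "k = %d, cum[%d] = %.3f%s", k, k,
            model$cumulative[k],
            if (!is.null(recovery))
              sprintf(", lipid recovery |r| = %.3f",
                      recovery[truth$lipid_component]) else "")
  mark("evaluate")

  ## ---- outputs ----------------------------------------------------------
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(unclass(config),
                         file.path(config$outdir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    curves <- data.frame(pc = seq_len(k), explained = model$explained,
                         cumulative = model$cumulative)
    data.table::fwrite(curves, file.path(config$outdir, "curves.csv"))
    if (!is.null(sweep_res)) {
      sw <- data.frame(coefficient = sweep_res$coefficients,
                       sweep_res$curves)
      names(sw)[-1] <- paste0("pc", seq_len(ncol(sweep_res$curves)))
      data.table::fwrite(sw, file.path(config$outdir, "sweep.csv"))
    }
    if (!is.null(corr))
      data.table::fwrite(as.data.frame(corr),
                         file.path(config$outdir, "correlation.csv"))
    if (isTRUE(config$evaluate$composites) && k >= 3L) {
      comp <- rgb_composite(model, fused$coords, pcs = config$evaluate$pcs)
      grDevices::png(file.path(config$outdir, "composite_fused.png"),
                     width = 600, height = 600)
      plot(comp, main = "fused PC composite")
      grDevices::dev.off()
    }
  }

  structure(list(report = report, model = model, fused = fused,
                 raman = raman_p, maldi = maldi_p, sweep = sweep_res,
                 correlation = corr, truth = truth, config = config),
            class = "RunReport")
}

#' @export
print.RunReport <- function(x, ...) {
  cat("<RunReport>\n  stages:", paste(x$report$stages, collapse = " -> "),
      "\n  w =", format(x$report$fuse$w, digits = 6),
      "\n  cumulative explained:",
      paste(sprintf("%.3f", x$report$pca$cumulative), collapse = " "), "\n")
  if (!is.null(x$report$recovery))
    cat("  lipid recovery |r| =",
        sprintf("%.3f", x$report$recovery$lipid), "\n")
  invisible(x)
}
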