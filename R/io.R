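# On-disk formats (NIfTI volume + JSON sidecar), vendor intensity rescaling,
# and the end-to-end multi-vendor pipeline.

#' Write an image series to NIfTI with a JSON sidecar
#'
#' Stores the stack as one 3D NIfTI volume (two spatial dimensions times the
#' series dimension, float64 so pixel data round-trip exactly) plus a JSON
#' sidecar holding the acquisition metadata and, for synthetic data, the
#' ground truth.
#'
#' @param series An `image_series`.
#' @param dir Output directory (created if missing).
#' @param name Base file name (without extension).
#' @return Invisibly, the paths written (`nifti`, `json`).
#' @export
write_series <- function(series, dir, name = "series") {
  stopifnot(inherits(series, "image_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- series$protocol$matrix_size
  arr <- array(unlist(series$images), dim = c(n, n, length(series$images)))
  nii_path <- file.path(dir, paste0(name, ".nii.gz"))
  attr(arr, "pixdim") <- c(series$protocol$pixel_mm,
                           series$protocol$pixel_mm, 1)
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, nii_path, datatype = "double")

  meta <- list(
    modality = series$protocol$modality,
    tr_ms = series$protocol$tr_ms,
    series_values = series$series_values,
    theta180_deg = series$protocol$theta180_deg,
    theta90_deg = series$protocol$theta90_deg,
    field_tesla = series$labels$field_tesla,
    vendor = series$labels$vendor,
    system = series$labels$system,
    pixel_mm = series$protocol$pixel_mm,
    matrix_size = series$protocol$matrix_size,
    noise_sigma = series$protocol$noise_sigma,
    series_scale = rep_len(series$protocol$series_scale,
                           length(series$series_values)),
    seed = series$protocol$rng_seed
  )
  if (!is.null(series$truth)) meta$truth <- series$truth
  json_path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(list(nifti = nii_path, json = json_path))
}

#' Read an image series from NIfTI + JSON sidecar
#'
#' Reconstructs an `image_series` from files written by [write_series()].
#' Images are ordered by their metadata series value (inversion time or flip
#' angle), not by on-disk order.
#'
#' @param path Path to the `.nii.gz` volume (the sidecar is found by
#'   replacing the extension) or to a directory containing exactly one pair.
#' @return An `image_series`.
#' @export
read_series <- function(path) {
  if (dir.exists(path)) {
    nii <- list.files(path, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
    if (length(nii) != 1) stop("expected exactly one NIfTI file in ", path)
    path <- nii
  }
  if (!file.exists(path)) stop("file not found: ", path)
  json_path <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(json_path)) stop("missing JSON sidecar: ", json_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  required <- c("modality", "tr_ms", "series_values", "pixel_mm")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("sidecar is missing required fields: ",
         paste(missing, collapse = ", "))
  }
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3 || dim(arr)[3] != length(meta$series_values)) {
    stop("volume count does not match the sidecar series values")
  }
  ord <- order(meta$series_values)
  vals <- as.numeric(meta$series_values)[ord]
  images <- lapply(ord, function(k) arr[, , k])

  proto_args <- list(
    modality = meta$modality, tr_ms = as.numeric(meta$tr_ms),
    matrix_size = dim(arr)[1], pixel_mm = as.numeric(meta$pixel_mm),
    noise_sigma = as.numeric(meta$noise_sigma %||% 0),
    series_scale = if (!is.null(meta$series_scale))
      as.numeric(meta$series_scale)[ord] else 1,
    rng_seed = meta$seed %||% 1L
  )
  if (!is.null(meta$theta180_deg)) proto_args$theta180_deg <- meta$theta180_deg
  if (!is.null(meta$theta90_deg)) proto_args$theta90_deg <- meta$theta90_deg
  if (meta$modality == "ir") proto_args$ti_list_ms <- vals
  else proto_args$flip_angles_deg <- vals
  protocol <- do.call(acquisition_protocol, proto_args)

  structure(
    list(
      images = images,
      series_values = vals,
      protocol = protocol,
      labels = list(vendor = meta$vendor %||% NA_character_,
                    field_tesla = as.numeric(meta$field_tesla %||% NA_real_),
                    system = meta$system %||% NA_character_),
      truth = if (!is.null(meta$truth)) tibble::as_tibble(meta$truth) else NULL
    ),
    class = "image_series"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply per-series intensity rescaling
#'
#' Divides each image by its series scale slope so signal levels are
#' comparable across series, as required for scanners that store
#' per-series scale factors (e.g. Philips-style private rescaling). A no-op
#' when `scale_slopes` is NULL and the vendor does not require rescaling.
#'
#' @param series An `image_series`.
#' @param scale_slopes One slope per series point (or a scalar). NULL means
#'   no rescaling.
#' @param vendor Vendor label; vendors listed in `require_for` must supply
#'   slopes.
#' @param require_for Vendors for which missing slopes are an error.
#' @return The rescaled `image_series`.
#' @export
apply_intensity_rescale <- function(series, scale_slopes = NULL,
                                    vendor = series$labels$vendor,
                                    require_for = "philips") {
  stopifnot(inherits(series, "image_series"))
  if (is.null(scale_slopes)) {
    if (!is.na(vendor) && tolower(vendor) %in% tolower(require_for)) {
      stop("vendor ", vendor,
           " requires per-series scale slopes, but none were supplied")
    }
    return(series)
  }
  slopes <- rep_len(scale_slopes, length(series$images))
  if (any(!is.finite(slopes)) || any(slopes == 0)) {
    stop("scale slopes must be finite and nonzero")
  }
  series$images <- purrr::map2(series$images, slopes, `/`)
  series
}

#' Configuration for an end-to-end synthetic multi-vendor run
#'
#' @param field_tesla Field strength of the simulated session.
#' @param vendors Tibble with columns `vendor`, `n_systems`, `b1_scale`
#'   (scalar transmit-field scale applied to every system of that vendor).
#' @param modalities Modalities to acquire and fit.
#' @param noise_sigma Quadrature noise standard deviation (signal units).
#' @param placement_jitter_mm,placement_jitter_deg Uniform half-ranges of the
#'   random phantom placement per system.
#' @param seed Base seed; all per-system seeds derive from it.
#' @param layout Optional phantom layout override.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(field_tesla = 3.0,
                            vendors = tibble::tibble(
                              vendor = c("C", "D", "E"),
                              n_systems = 5L,
                              b1_scale = c(1, 0.9, 1)),
                            modalities = c("ir", "vfa"),
                            noise_sigma = 0.01,
                            placement_jitter_mm = 5,
                            placement_jitter_deg = 3,
                            seed = 1L,
                            layout = NULL) {
  stopifnot(all(c("vendor", "n_systems", "b1_scale") %in% names(vendors)),
            all(modalities %in% c("ir", "vfa")))
  structure(
    list(field_tesla = field_tesla, vendors = vendors,
         modalities = modalities, noise_sigma = noise_sigma,
         placement_jitter_mm = placement_jitter_mm,
         placement_jitter_deg = placement_jitter_deg,
         seed = as.integer(seed),
         layout = layout %||% build_layout(field_tesla)),
    class = "pipeline_config"
  )
}

#' Run the full synthetic multi-vendor pipeline
#'
#' For every simulated scanner system: renders IR and VFA magnitude series
#' with the vendor's transmit-field scale and a random phantom placement,
#' segments the 14 spheres on the shortest-TI IR image, reuses those ROIs for
#' the VFA series of the same session, fits T1 per sphere per modality, and
#' assembles normalized-error bias records. Group summaries and per-sphere
#' Tukey-Kramer vendor comparisons are computed per modality.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: per-stage CSV tables and a provenance
#'   JSON (seed, config, package version) are written there.
#' @return A `t1_pipeline_result`: list with `records` (bias records),
#'   `fits`, `summary` (per-vendor group means/CIs), `stats` (per-modality
#'   `t1_stat_result`), and `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  layout <- config$layout
  set.seed(config$seed)

  jobs <- config$vendors |>
    dplyr::rowwise() |>
    dplyr::reframe(vendor = .data$vendor, b1_scale = .data$b1_scale,
                   system = paste0(.data$vendor, seq_len(.data$n_systems)))
  # placements and seeds drawn once, in job order, from the base seed
  jobs$dx <- stats::runif(nrow(jobs), -config$placement_jitter_mm,
                          config$placement_jitter_mm)
  jobs$dy <- stats::runif(nrow(jobs), -config$placement_jitter_mm,
                          config$placement_jitter_mm)
  jobs$rot <- stats::runif(nrow(jobs), -config$placement_jitter_deg,
                           config$placement_jitter_deg)
  jobs$seed <- config$seed + 1000L * seq_len(nrow(jobs))

  all_fits <- list()
  all_records <- list()
  for (i in seq_len(nrow(jobs))) {
    job <- jobs[i, ]
    series <- list()
    for (m in config$modalities) {
      proto <- acquisition_protocol(
        m, noise_sigma = config$noise_sigma, b1_scale = job$b1_scale,
        rng_seed = job$seed + match(m, c("ir", "vfa")))
      s <- render_series(layout, proto, translation_mm = c(job$dx, job$dy),
                         rotation_deg = job$rot)
      s$labels$vendor <- job$vendor
      s$labels$system <- job$system
      series[[m]] <- s
    }
    seg_series <- series[["ir"]] %||% series[[1]]
    rois <- segment_series(seg_series, layout)
    for (m in config$modalities) {
      signals <- roi_means(series[[m]], rois)
      fits <- fit_rois(signals, modality = m,
                       tr_ms = series[[m]]$protocol$tr_ms)
      fits$vendor <- job$vendor
      fits$system <- job$system
      fits$modality <- m
      all_fits[[paste(job$system, m)]] <- fits
      all_records[[paste(job$system, m)]] <-
        bias_records(fits, layout, vendor = job$vendor, modality = m,
                     system = job$system)
    }
  }
  fits <- dplyr::bind_rows(all_fits)
  records <- dplyr::bind_rows(all_records)
  summary <- records |>
    dplyr::group_by(.data$modality) |>
    dplyr::group_modify(~ group_summary(.x)) |>
    dplyr::ungroup()
  stats <- if (dplyr::n_distinct(records$vendor) >= 2) {
    purrr::map(rlang::set_names(config$modalities), function(m) {
      per_sphere_pairwise(records, modality = m)
    })
  } else {
    list()
  }

  result <- structure(
    list(records = records, fits = fits, summary = summary, stats = stats,
         config = config),
    class = "t1_pipeline_result"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(out_dir, "bias_records.csv"),
                     row.names = FALSE)
    utils::write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "group_summary.csv"),
                     row.names = FALSE)
    for (m in names(stats)) {
      utils::write.csv(stats[[m]]$pairwise,
                       file.path(out_dir, paste0("pairwise_", m, ".csv")),
                       row.names = FALSE)
    }
    prov <- list(
      seed = config$seed,
      field_tesla = config$field_tesla,
      vendors = config$vendors,
      modalities = config$modalities,
      noise_sigma = config$noise_sigma,
      package_version = as.character(utils::packageVersion("t1phantom"))
    )
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  result
}

#' @export
print.t1_pipeline_result <- function(x, ...) {
  cat("<t1_pipeline_result>", nrow(x$records), "bias records from",
      dplyr::n_distinct(x$records$system), "systems at",
      x$config$field_tesla, "T\n")
  for (m in names(x$stats)) {
    cat("  ", toupper(m), ": ", sum(x$stats[[m]]$pairwise$significant),
        " of ", nrow(x$stats[[m]]$pairwise),
        " pairwise comparisons significant\n", sep = "")
  }
  invisible(x)
}
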