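#' Analysis configuration
#'
#' Bundles the pipeline's tunable constants. Defaults follow the published
#' protocol for Molecular Cartography fly sections: 4 um colocalization disks,
#' 0.138 um pixels, 36 px (= 4.968 um) grid squares, a strict greater-than-3
#' total-count square filter, size factor 10,000 with natural-log transform,
#' z > 1 gene-set assignment, nonnegative lasso with penalty 1 and a 0.2
#' confidence threshold, and a 100-spot minimum per gene for distance profiles.
#'
#' @param disk_diameter colocalization disk diameter, um.
#' @param pixel_size um per raster pixel.
#' @param bin_pixels grid square side in pixels (side um = `bin_pixels * pixel_size`).
#' @param min_square_counts strict lower bound on square total counts.
#' @param size_factor normalization size factor.
#' @param z_threshold gene-set assignment threshold on z-scores.
#' @param lasso_penalty nonnegative-lasso penalty (sklearn-style alpha).
#' @param weight_threshold minimum lasso weight for a confident match.
#' @param min_gene_spots minimum pooled spots for a gene's distance profile.
#' @param coloc_resolution raster cell size (um) for disk-union areas.
#' @param localization_sigma spot localization precision, um (synthetic jitter).
#' @param morphology tissue-mask recipe: Gaussian blur (ksize 5, sigma 1), two
#'   erosions (5x5 then 4x4), three 50x50 dilations, final blur (5, 1).
#' @param rng_seed optional integer seed for pipeline stages.
#' @return an `analysis_config` (list).
#' @export
analysis_config <- function(disk_diameter = 4,
                            pixel_size = 0.138,
                            bin_pixels = 36L,
                            min_square_counts = 3L,
                            size_factor = 10000,
                            z_threshold = 1,
                            lasso_penalty = 1,
                            weight_threshold = 0.2,
                            min_gene_spots = 100L,
                            coloc_resolution = 0.1,
                            localization_sigma = 0.14,
                            morphology = list(blur1 = c(ksize = 5, sigma = 1),
                                              erode = list(c(5, 5), c(4, 4)),
                                              dilate = list(ksize = c(50, 50), times = 3),
                                              blur2 = c(ksize = 5, sigma = 1)),
                            rng_seed = NULL) {
  for (nm in c("disk_diameter", "pixel_size", "size_factor", "z_threshold",
               "lasso_penalty", "weight_threshold", "coloc_resolution",
               "localization_sigma"))
    .assert_scalar_num(get(nm), nm,
                       positive = nm %in% c("disk_diameter", "pixel_size",
                                            "size_factor", "lasso_penalty",
                                            "coloc_resolution"))
  bin_pixels <- as.integer(bin_pixels)
  min_square_counts <- as.integer(min_square_counts)
  min_gene_spots <- as.integer(min_gene_spots)
  stopifnot(bin_pixels > 0L, min_square_counts >= 0L, min_gene_spots >= 0L)
  structure(list(disk_diameter = disk_diameter, pixel_size = pixel_size,
                 bin_pixels = bin_pixels, min_square_counts = min_square_counts,
                 size_factor = size_factor, z_threshold = z_threshold,
                 lasso_penalty = lasso_penalty,
                 weight_threshold = weight_threshold,
                 min_gene_spots = min_gene_spots,
                 coloc_resolution = coloc_resolution,
                 localization_sigma = localization_sigma,
                 morphology = morphology, rng_seed = rng_seed),
            class = "analysis_config")
}

#' Grid square side length in micrometres
#' @param config an `analysis_config`.
#' @return `bin_pixels * pixel_size` (default 36 * 0.138 = 4.968 um).
#' @export
grid_side <- function(config = analysis_config()) {
  config$bin_pixels * config$pixel_size
}

#' Read / write an analysis configuration as YAML
#'
#' Unknown fields in the file are rejected; absent fields keep their defaults.
#'
#' @param path YAML file.
#' @return [read_config()]: an `analysis_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @param config an `analysis_config`.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  flat <- x[setdiff(names(x), "morphology")]
  for (nm in names(flat))
    cat(sprintf("  %-18s %s\n", nm,
                if (is.null(flat[[nm]])) "NULL" else format(flat[[nm]])))
  cat("  morphology         blur(5,1) erode 5x5,4x4 dilate 50x50 x3 blur(5,1)\n")
  invisible(x)
}
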