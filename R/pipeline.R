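#' Run pipeline stages end-to-end with a reproducibility manifest
#'
#' Executes the requested stages in dependency order under one output
#' directory and writes `manifest.yaml` recording the configuration snapshot,
#' the seed, input/output file MD5 digests and per-stage output paths.
#' Re-running with identical inputs, config and seed reproduces byte-identical
#' outputs for deterministic stages (the manifest carries no timestamps).
#'
#' Stages and their requirements:
#' \describe{
#'   \item{simulate}{none (uses [fly_body_scene()] unless `scene` given);
#'     writes `scene/`.}
#'   \item{rasterize}{needs spots (from simulate or `spots_path`); writes the
#'     filtered, normalized grid under `grid/` plus the raw grid under
#'     `grid_raw/`.}
#'   \item{score}{needs rasterize + `gene_sets`; writes `labels.tsv`.}
#'   \item{coloc}{needs spots; writes `coloc_distance.tsv`,
#'     `coloc_dendrogram.nwk`, `coloc_clusters.tsv`.}
#'   \item{nucdist}{needs spots + nucleus mask (+ `mask_gene` for the tissue
#'     mask); writes `distance_summary.tsv`.}
#'   \item{specificity}{needs spots + a region mask; writes
#'     `specificity.tsv`.}
#'   \item{transfer}{needs rasterize + `profiles`; writes `transfer.tsv`.}
#' }
#'
#' @param out_dir run directory (created).
#' @param stages character vector of stage names (order irrelevant).
#' @param config an [analysis_config()].
#' @param seed integer; all stage randomness derives from it.
#' @param spots_path optional spot-table TSV (alternative to simulate).
#' @param panel required with `spots_path`.
#' @param scene optional [scene_spec()] for simulate.
#' @param gene_sets a [gene_set_config()] (score stage).
#' @param profiles a [cluster_profiles()] or TSV path (transfer stage).
#' @param nucleus_mask_path optional mask image (else the simulated one).
#' @param region_mask_path optional mask image (else the simulated muscle
#'   region).
#' @param mask_gene marker gene for the tissue mask (nucdist stage);
#'   default `"Act88F"`.
#' @param coloc_k cluster count for the coloc stage (default 3).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, stages, config = analysis_config(),
                         seed = 1L, spots_path = NULL, panel = NULL,
                         scene = NULL, gene_sets = NULL, profiles = NULL,
                         nucleus_mask_path = NULL, region_mask_path = NULL,
                         mask_gene = "Act88F", coloc_k = 3L) {
  order_all <- c("simulate", "rasterize", "score", "coloc", "nucdist",
                 "specificity", "transfer")
  bad <- setdiff(stages, order_all)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- order_all[order_all %in% stages]
  deps <- list(score = "rasterize", transfer = "rasterize")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create run directory: ", out_dir)
  manifest <- list(version = as.character(utils::packageVersion("spotgrid")),
                   seed = as.integer(seed),
                   config = unclass(config), stages = stages,
                   outputs = list(), digests = list())
  record <- function(stage, paths) {
    manifest$outputs[[stage]] <<- paths
    for (p in paths)
      manifest$digests[[basename(p)]] <<- unname(tools::md5sum(p))
  }
  bundle <- NULL
  spots <- NULL
  grid <- NULL
  have <- function(st) st %in% names(manifest$outputs)

  load_spots <- function() {
    if (!is.null(spots)) return(spots)
    if (!is.null(spots_path)) {
      if (is.null(panel)) stop("spots_path requires a panel")
      spots <<- read_spot_table(spots_path, panel)
    } else if (!is.null(bundle)) {
      spots <<- bundle$spots
    } else {
      stop("dependency error: stage needs spots — run 'simulate' or pass spots_path")
    }
    spots
  }

  for (stage in stages) {
    for (d in deps[[stage]])
      if (!have(d))
        stop("dependency error: stage '", stage, "' requires stage '", d, "'")
    if (stage == "simulate") {
      bundle <- if (is.null(scene)) fly_body_scene(seed = seed)
                else simulate_scene(scene, seed = seed)
      sdir <- file.path(out_dir, "scene")
      write_scene(bundle, sdir)
      record("simulate", list.files(sdir, full.names = TRUE))
    } else if (stage == "rasterize") {
      sp <- load_spots()
      raw <- rasterize_spots(sp, config)
      grid <- normalize_grid(filter_squares(raw, config$min_square_counts),
                             config$size_factor)
      write_count_matrix(raw, file.path(out_dir, "grid_raw"))
      write_count_matrix(grid, file.path(out_dir, "grid"))
      record("rasterize", c(list.files(file.path(out_dir, "grid_raw"),
                                       full.names = TRUE),
                            list.files(file.path(out_dir, "grid"),
                                       full.names = TRUE)))
    } else if (stage == "score") {
      gs <- gene_sets %||% (if (!is.null(bundle)) bundle$gene_sets)
      if (is.null(gs)) stop("score stage needs gene_sets")
      labels <- assign_labels(score_gene_sets(grid, gs))
      p <- file.path(out_dir, "labels.tsv")
      write_square_labels(labels, p)
      record("score", p)
    } else if (stage == "coloc") {
      sp <- load_spots()
      res <- coloc_distance_matrix(sp, config)
      dpath <- file.path(out_dir, "coloc_distance.tsv")
      utils::write.table(res$distance, dpath, sep = "\t", quote = FALSE)
      cl <- ward_gene_clustering(res, k = min(coloc_k, nrow(res$distance)))
      npath <- file.path(out_dir, "coloc_dendrogram.nwk")
      dendrogram_newick(cl, npath)
      lpath <- file.path(out_dir, "coloc_clusters.tsv")
      data.table::fwrite(data.frame(gene = names(cl$labels),
                                    cluster = cl$labels),
                         lpath, sep = "\t", quote = FALSE)
      record("coloc", c(dpath, npath, lpath))
    } else if (stage == "nucdist") {
      sp <- load_spots()
      nmask <- if (!is.null(nucleus_mask_path)) read_mask(nucleus_mask_path)
               else if (!is.null(bundle)) bundle$nucleus_mask
               else stop("nucdist stage needs a nucleus mask")
      tmask <- NULL
      if (mask_gene %in% sp$gene)
        tmask <- build_tissue_mask(spots_for_genes(sp, mask_gene), config)
      prof <- nearest_nucleus_distances(sp, nmask, tmask,
                                        min_gene_spots = config$min_gene_spots)
      rows <- lapply(prof, function(p) {
        sm <- distance_summary(p)
        data.frame(gene = p$gene, n = p$n, median_um = sm$median,
                   peak_um = sm$density_peak)
      })
      path <- file.path(out_dir, "distance_summary.tsv")
      data.table::fwrite(do.call(rbind, rows), path, sep = "\t", quote = FALSE)
      record("nucdist", path)
    } else if (stage == "specificity") {
      sp <- load_spots()
      rmask <- if (!is.null(region_mask_path)) read_mask(region_mask_path)
               else if (!is.null(bundle)) bundle$region_masks[[1]]
               else stop("specificity stage needs a region mask")
      rep <- region_specificity(sp, rmask)
      path <- file.path(out_dir, "specificity.tsv")
      data.table::fwrite(rep, path, sep = "\t", quote = FALSE)
      record("specificity", path)
    } else if (stage == "transfer") {
      if (is.null(profiles)) stop("transfer stage needs profiles")
      pr <- if (is.character(profiles)) read_cluster_profiles(profiles)
            else cluster_profiles(profiles)
      tr <- lasso_transfer(grid, pr, penalty = config$lasso_penalty,
                           weight_threshold = config$weight_threshold)
      path <- file.path(out_dir, "transfer.tsv")
      write_transfer_result(tr, path)
      record("transfer", path)
    }
  }
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Command-line entry point
#'
#' Thin wrapper over [run_pipeline()] used by the installed script
#' `system.file("cli", "spotgrid.R", package = "spotgrid")`:
#' `Rscript spotgrid.R <stage>[,<stage>...] --out DIR [--seed N]
#' [--config config.yaml] [--spots spots.tsv --panel panel.txt]
#' [--gene-sets sets.yaml] [--profiles profiles.tsv] [--mask-gene GENE]
#' [--nuclei mask.png] [--region mask.png] [--k N]`.
#'
#' @param args character vector of CLI arguments (default: the process's).
#' @return exit status, invisibly (0 on success).
#' @export
spotgrid_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L) {
    cat("usage: spotgrid.R <stages,comma-separated> --out DIR [options]\n")
    return(invisible(1L))
  }
  stages <- strsplit(args[[1]], ",")[[1]]
  opt <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[[i]])
    if (i + 1L > length(args)) stop("missing value for --", key)
    opt[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  if (is.null(opt$out)) stop("--out is required")
  config <- if (!is.null(opt$config)) read_config(opt$config) else analysis_config()
  panel <- if (!is.null(opt$panel)) gene_panel(readLines(opt$panel))
  gene_sets <- if (!is.null(opt[["gene-sets"]]))
    read_gene_sets(opt[["gene-sets"]], panel = panel)
  run_pipeline(out_dir = opt$out, stages = stages, config = config,
               seed = as.integer(opt$seed %||% 1L),
               spots_path = opt$spots, panel = panel,
               gene_sets = gene_sets, profiles = opt$profiles,
               nucleus_mask_path = opt$nuclei,
               region_mask_path = opt$region,
               mask_gene = opt[["mask-gene"]] %||% "Act88F",
               coloc_k = as.integer(opt$k %||% 3L))
  invisible(0L)
}
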