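#' Assemble / validate a pipeline run configuration
#'
#' A run config is a plain named list (or a YAML file with the same
#' fields): either a `scenario` block (arguments to
#' [synthetic_scenario()]) or `inputs` paths (`occurrences`, `grid` =
#' `x0,y0,size,nrows,ncols`, `tree`, `polygons`), plus `reps`, `seed`,
#' `alpha` thresholds, hotspot `levels`, `gap_threshold` and `sar_k`
#' candidates.  The config is validated up front and recorded verbatim in
#' the output manifest.
#'
#' @param config A named list or path to a YAML file.
#' @return The validated config list (class `run_config`).
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(scenario = list(), inputs = NULL, reps = 199L,
                   seed = 1L, alpha_primary = 0.05, alpha_rpe_tail = 0.025,
                   alpha_super = 0.01, levels = c("L1", "L2", "L3"),
                   gap_threshold = 0.10, sar_k = c(2L, 4L),
                   sar_response = "CWE_END", null = "curveball")
  cfg <- utils::modifyList(defaults, config)
  cfg$reps <- as.integer(cfg$reps)
  cfg$seed <- as.integer(cfg$seed)
  cfg$sar_k <- as.integer(cfg$sar_k)
  stopifnot(cfg$reps >= 1, cfg$gap_threshold >= 0, cfg$gap_threshold <= 1,
            cfg$alpha_primary > 0, cfg$alpha_primary < 1,
            all(cfg$levels %in% c("L1", "L2", "L3")),
            length(cfg$sar_k) >= 1)
  structure(cfg, class = c("run_config", "list"))
}

#' Run the full endemism-hotspot pipeline
#'
#' Orders the stages end to end: community (simulate or load), tree
#' (graft if a graft list is supplied), per-cell metrics, null-model
#' p-values, CANAPE classification, percentile hotspots and coldspots,
#' Priority Hotspots, protected-area coverage and gap report, and the
#' SAR-error model of the selected response.  Every stage writes a plain
#' text table into `out_dir`; `manifest.json` records the config verbatim
#' and the MD5 of every file, so two runs with one config are
#' byte-comparable.  A stage failure halts the run with the stage name;
#' completed stage outputs remain on disk next to an `error_manifest`.
#'
#' @param config A [run_config()] (or list / YAML path).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list (`config`, `files` with MD5s).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }
  stage <- "config"
  result <- tryCatch({
    # -- community -----------------------------------------------------
    stage <- "community"
    if (!is.null(cfg$inputs)) {
      g <- as.numeric(strsplit(cfg$inputs$grid, ",")[[1]])
      grid <- grid_spec(g[1], g[2], g[3], g[4], g[5])
      occ <- read_occurrences(cfg$inputs$occurrences)
      asg <- assign_cells(occ, grid)
      if (nrow(asg$rejects))
        emit(asg$rejects, "rejected_records.csv")
      m <- build_matrix(asg$records, grid)
      ledger <- NULL
      sc <- NULL
    } else {
      sc <- do.call(synthetic_scenario,
                    c(cfg$scenario, list(seed = cfg$seed)))
      com <- simulate_grid_community(sc)
      m <- com$matrix
      ledger <- com$ledger
    }
    write_matrix(m, file.path(out_dir, "community"))
    files <- c(files, file.path(out_dir, paste0("community_",
                c("presence", "taxa", "grid"), ".csv")))

    # -- tree ----------------------------------------------------------
    stage <- "tree"
    if (!is.null(cfg$inputs)) {
      tree <- ape::read.tree(cfg$inputs$tree)
      if (!is.null(cfg$inputs$graft_taxa))
        tree <- graft_missing_taxa(
          tree, utils::read.csv(cfg$inputs$graft_taxa), seed = cfg$seed)
      planted <- NULL
    } else {
      tr <- simulate_endemism_tree(sc, list(ledger = ledger))
      tree <- tr$tree
      planted <- tr$planted
    }
    tree_path <- file.path(out_dir, "tree.nwk")
    ape::write.tree(tree, tree_path)
    files <- c(files, tree_path)

    # -- metrics -------------------------------------------------------
    stage <- "metrics"
    met <- cell_metrics(m, tree)
    emit(met, "metrics.csv")

    # -- nulls (endemics only, per the endemism-centre protocol) -------
    stage <- "nulls"
    em <- subset_taxa(m, m$taxon_id[m$endemic])
    nr <- null_pvalues(em, tree, reps = cfg$reps, seed = cfg$seed,
                       null = cfg$null)
    emit(tidy.null_result(nr), "nulls.csv")

    # -- canape --------------------------------------------------------
    stage <- "canape"
    cls <- classify_cells(nr, cfg$alpha_primary, cfg$alpha_rpe_tail,
                          cfg$alpha_super)
    emit(as.data.frame(cls), "canape.csv")
    emit(glance.canape_classification(cls), "canape_summary.csv")

    # -- hotspots ------------------------------------------------------
    stage <- "hotspots"
    hs <- list()
    for (lv in cfg$levels) {
      hs[[paste0("cwe_", lv)]] <-
        percentile_cells(met[!is.na(met$CWE_END), c("cell", "CWE_END")],
                         lv, "high", metric = "CWE_END")
      hs[[paste0("cwe_cold_", lv)]] <-
        percentile_cells(met[!is.na(met$CWE_END), c("cell", "CWE_END")],
                         lv, "low", metric = "CWE_END")
      hs[[paste0("pe_", lv)]] <-
        percentile_cells(met[!is.na(met$PE_obs), c("cell", "PE_obs")],
                         lv, "high", metric = "PE")
    }
    emit(purrr::map_dfr(hs, tidy.hotspot_set), "hotspots.csv")

    # -- priority hotspots --------------------------------------------
    stage <- "priority"
    pri <- lapply(cfg$levels, function(lv)
      priority_hotspots(met[!is.na(met$CWE_END), c("cell", "CWE_END")],
                        met[!is.na(met$PE_obs), c("cell", "PE_obs")], lv))
    names(pri) <- cfg$levels
    emit(purrr::map_dfr(pri, tidy.hotspot_set), "priority.csv")

    # -- protected areas and gaps -------------------------------------
    stage <- "gaps"
    top <- pri[[length(pri)]]$cells      # widest analysed level
    if (!is.null(cfg$inputs) && !is.null(cfg$inputs$polygons)) {
      pa <- filter_marine(read_polygons_geojson(cfg$inputs$polygons))
      pa_ledger <- NULL
    } else {
      sim <- simulate_protected_areas(m$grid, top,
                                      sc$coverage_fraction %||% 0.8,
                                      sc$decoy_count %||% 3L,
                                      seed = sub_seed(sc, 4L))
      pa <- sim$polygons
      pa_ledger <- sim$ledger
    }
    pa_path <- file.path(out_dir, "sac.geojson")
    write_polygons_geojson(pa, pa_path)
    files <- c(files, pa_path)
    cov <- cell_coverage(m$grid, m$cell_id, pa)
    emit(cov, "coverage.csv")
    gaps <- lapply(pri, conservation_gaps, coverage = cov,
                   threshold = cfg$gap_threshold)
    emit(purrr::map_dfr(gaps, glance.gap_report), "gap_summary.csv")
    emit(purrr::map_dfr(gaps, tidy.gap_report), "gaps.csv")

    # -- SAR drivers ---------------------------------------------------
    stage <- "sar"
    if (is.null(sc)) sc <- synthetic_scenario(seed = cfg$seed)
    env <- simulate_sar_surface(sc, cells = m$cell_id)
    resp <- met[[cfg$sar_response]]
    keep <- !is.na(resp)
    Xs <- standardize_predictors(env$data[keep,
            setdiff(names(env$data), c("y")), drop = FALSE])
    sar <- select_sar(resp[keep], Xs,
                      cell_centers(m$grid, m$cell_id[keep]),
                      k_candidates = cfg$sar_k)
    tab <- tidy.sar_fit(sar)
    tab$response <- cfg$sar_response
    tab$GR2 <- glance.sar_fit(sar)$GR2
    tab$AICc <- sar$AICc
    tab$k <- sar$k
    emit(tab, "sar.csv")

    # -- manifest ------------------------------------------------------
    stage <- "manifest"
    manifest <- list(
      config = unclass(cfg),
      files = lapply(stats::setNames(nm = basename(files)), function(f)
        unname(tools::md5sum(file.path(out_dir, f)))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }, error = function(e) {
    jsonlite::write_json(
      list(failed_stage = stage, error = conditionMessage(e),
           completed_files = basename(files)),
      file.path(out_dir, "error_manifest.json"), auto_unbox = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
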