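#' Run configuration
#'
#' One serialisable list carrying every tunable of a screen analysis:
#' paths, segmentation, feature selection, covariance shrinkage, hit-rule
#' constants, QC floor and the simulation config. The effective
#' configuration of every run is echoed verbatim into the run's output
#' directory (`run_config.yaml`) together with every numeric threshold in
#' `run_summary.json`, so results carry their provenance.
#'
#' @param ... Overrides of the defaults, as name = value pairs.
#' @return List of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    min_controls = 8L,
    min_object_area = 10L,
    lambda = 0.1,
    zprime_floor = 0,
    max_features = 10L,
    qc_zprime_floor = 0.4,
    hit_rule = list(min_objects = 5L, disparate_quantile = 0.95,
                    sd_multiplier = 1, rule = "below_nc_ac",
                    require_ac_like = TRUE),
    m_consecutive = 2L,
    sim = list()
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

sim_config_from_run <- function(config) {
  do.call(screen_sim_config,
          c(config$sim, list(seed = config$sim$seed %||% config$seed)))
}

run_log <- function(out_dir, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  cat(msg, "\n", file = file.path(out_dir, "run.log"), append = TRUE)
}

#' Simulate a synthetic screen to a run directory
#'
#' Writes the duplicate-run image screen (field TIFFs, plate maps, truth
#' table, annotation table) described by the configuration. All outputs
#' are pure functions of (config, seed).
#'
#' @param config A [run_config()]; `config$sim` may override any
#'   [screen_sim_config()] field, and `config$sim$n_compound`,
#'   `n_ac`, `n_nc`, `n_replicates` control the layout.
#' @param out_dir Output directory.
#' @return Invisibly, the [simulate_screen()] result.
#' @export
run_simulate <- function(config = run_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- config$sim
  n_ac <- sim$n_ac %||% 16L
  n_nc <- sim$n_nc %||% 16L
  n_compound <- sim$n_compound %||% 352L
  n_replicates <- sim$n_replicates %||% 2L
  sim[c("n_ac", "n_nc", "n_compound", "n_replicates")] <- NULL
  scfg <- do.call(screen_sim_config,
                  c(sim, list(seed = sim$seed %||% config$seed)))
  layouts <- lapply(seq_len(n_replicates), function(r) {
    make_screen_layout(plate_id = sprintf("plate_r%d", r), replicate_id = r,
                       n_ac = n_ac, n_nc = n_nc, n_compound = n_compound)
  })
  ann <- data.frame(compound_id = sprintf("cmp%03d", seq_len(n_compound)),
                    target_class = "synthetic_active",
                    stringsAsFactors = FALSE)
  utils::write.csv(ann, file.path(out_dir, "annotation.csv"),
                   row.names = FALSE)
  write_run_config(config, file.path(out_dir, "run_config.yaml"))
  run_log(out_dir, "simulating ", n_replicates, " plate(s), ",
          n_compound, " compound wells, seed ", scfg$seed)
  invisible(simulate_screen(layouts, scfg, out_dir = out_dir,
                            seed = scfg$seed))
}

read_screen_images <- function(run_dir, layout) {
  w <- layout$wells
  wells <- w$well[w$role != "empty"]
  imgs <- lapply(wells, function(wl) {
    files <- sort(Sys.glob(file.path(run_dir, sprintf("%s_%s_f*.tif",
                                                      layout$plate_id, wl))))
    if (!length(files)) stop("no images for well ", wl, " of plate ",
                             layout$plate_id, call. = FALSE)
    lapply(files, read_well_image)
  })
  names(imgs) <- wells
  imgs
}

#' Analyse a screen run directory
#'
#' Runs the full pipeline on a run directory containing either field
#' images plus plate maps (from [run_simulate()] or an instrument export)
#' or per-plate feature CSVs (`<plate>_features.csv` with `well`, `role`,
#' `compound_id` and feature columns): segmentation, 112-feature
#' aggregation, Z'-based feature selection, control-model fitting,
#' Mahalanobis scoring, triage, duplicate-run hit calling and target-class
#' summary. Plates whose QC Z' falls below `qc_zprime_floor` are flagged
#' and excluded from hit calling. When a `truth.csv` is present, recall
#' and false-discovery proportion against the planted truth are added to
#' the run summary.
#'
#' @param config A [run_config()].
#' @param run_dir Directory with inputs; outputs are written next to them
#'   (scores, QC, hit list, summary JSON and a Markdown report).
#' @return Invisibly, a list with `scores` (per replicate), `qc`, `hits`,
#'   `target_classes`, `summary`.
#' @export
run_analyze <- function(config = run_config(), run_dir) {
  maps <- sort(Sys.glob(file.path(run_dir, "*_map.csv")))
  if (!length(maps)) stop("no plate maps in ", run_dir, call. = FALSE)
  layouts <- lapply(maps, function(p) {
    parse_plate_map(p, plate_id = sub("_map$", "",
                                      tools::file_path_sans_ext(basename(p))))
  })
  hit_cfg <- do.call(hit_rule_config, config$hit_rule)
  qc <- list()
  rep_scores <- list()
  for (lay in layouts) {
    findings <- validate_layout(lay, min_controls = config$min_controls)
    if (length(findings)) {
      stop("layout ", lay$plate_id, " not analysable: ",
           paste(findings, collapse = ", "), call. = FALSE)
    }
    feat_csv <- file.path(run_dir, paste0(lay$plate_id, "_features.csv"))
    if (file.exists(feat_csv)) {
      ft <- utils::read.csv(feat_csv, stringsAsFactors = FALSE)
      meta_cols <- intersect(c("well", "role", "compound_id", "replicate"),
                             names(ft))
      x <- as.matrix(ft[, setdiff(names(ft), meta_cols), drop = FALSE])
      rownames(x) <- ft$well
      roles <- ft$role
      compound_id <- ft$compound_id
      n_objects <- NULL
    } else {
      imgs <- read_screen_images(run_dir, lay)
      ex <- extract_well_features(imgs,
                                  min_object_area = config$min_object_area)
      x <- ex$features
      roles <- lay$wells$role[match(rownames(x), lay$wells$well)]
      compound_id <- lay$wells$compound_id[match(rownames(x),
                                                 lay$wells$well)]
      n_objects <- ex$n_objects
    }
    ps <- score_plate(x, roles, lambda = config$lambda,
                      zprime_floor = config$zprime_floor,
                      max_features = config$max_features)
    sc <- triage_wells(ps$scores, n_objects, config = hit_cfg)
    sc$compound_id <- compound_id
    sc$plate_id <- lay$plate_id
    sc$replicate <- lay$replicate_id
    utils::write.csv(sc, file.path(run_dir,
                                   paste0(lay$plate_id, "_scores.csv")),
                     row.names = FALSE)
    qc[[lay$plate_id]] <- list(plate_id = lay$plate_id,
                               replicate = lay$replicate_id,
                               zprime = ps$zprime$zprime,
                               features_used = ps$subset$names,
                               pass = ps$zprime$zprime >=
                                 config$qc_zprime_floor)
    rep_scores[[length(rep_scores) + 1L]] <- sc
    run_log(run_dir, "plate ", lay$plate_id, ": Z' = ",
            sprintf("%.3f", ps$zprime$zprime),
            if (!qc[[lay$plate_id]]$pass) "  [QC FAIL: excluded]" else "")
  }
  jsonlite::write_json(qc, file.path(run_dir, "qc.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  usable <- vapply(qc, `[[`, TRUE, "pass")[
    vapply(rep_scores, function(s) s$plate_id[1L], "")]
  hits <- if (any(usable)) {
    call_hits(rep_scores[usable], config = hit_cfg)
  } else {
    run_log(run_dir, "no plate passed QC; hit calling skipped")
    data.frame(compound_id = character(0), n_replicates = integer(0),
               n_pass = integer(0), all_pass = logical(0),
               all_ac_like = logical(0), any_dead_disparate = logical(0),
               final_hit = logical(0))
  }
  utils::write.csv(hits, file.path(run_dir, "hits.csv"), row.names = FALSE)
  ann_path <- file.path(run_dir, "annotation.csv")
  classes <- if (file.exists(ann_path)) {
    summarize_target_classes(hits, read_compound_annotation(ann_path))
  } else NULL
  if (!is.null(classes)) {
    utils::write.csv(classes, file.path(run_dir, "target_classes.csv"),
                     row.names = FALSE)
  }
  summary <- list(
    n_plates = length(layouts),
    n_plates_qc_pass = sum(vapply(qc, `[[`, TRUE, "pass")),
    n_compounds = sum(!is.na(hits$compound_id)),
    n_hits = sum(hits$final_hit),
    thresholds = list(min_controls = config$min_controls,
                      min_object_area = config$min_object_area,
                      lambda = config$lambda,
                      zprime_floor = config$zprime_floor,
                      max_features = config$max_features,
                      qc_zprime_floor = config$qc_zprime_floor,
                      hit_rule = config$hit_rule,
                      m_consecutive = config$m_consecutive),
    seed = config$seed)
  truth_path <- file.path(run_dir, "truth.csv")
  if (file.exists(truth_path)) {
    truth <- utils::read.csv(truth_path, stringsAsFactors = FALSE)
    called <- hits$compound_id[hits$final_hit]
    actives <- truth$compound_id[truth$is_active]
    tp <- length(intersect(called, actives))
    summary$truth <- list(
      n_active = length(actives),
      recall = if (length(actives)) tp / length(actives) else NA,
      false_discovery_proportion =
        if (length(called)) 1 - tp / length(called) else 0)
  }
  write_run_config(config, file.path(run_dir, "run_config.yaml"))
  jsonlite::write_json(summary, file.path(run_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res <- list(scores = rep_scores, qc = qc, hits = hits,
              target_classes = classes, summary = summary)
  run_report(run_dir)
  invisible(res)
}

#' Render the consolidated Markdown report of a completed run
#'
#' Re-reads the artifacts written by [run_analyze()] (no recomputation)
#' and renders `report.md`: per-plate QC, the hit list, target-class
#' fractions, truth-based recall/FDR when available, and the effective
#' configuration. Regenerating the report is idempotent.
#'
#' @param run_dir A completed run directory.
#' @return The report path, invisibly.
#' @export
run_report <- function(run_dir) {
  need <- c("qc.json", "hits.csv", "run_summary.json")
  miss <- need[!file.exists(file.path(run_dir, need))]
  if (length(miss)) {
    stop("incomplete run dir, missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  qc <- jsonlite::read_json(file.path(run_dir, "qc.json"))
  hits <- utils::read.csv(file.path(run_dir, "hits.csv"),
                          stringsAsFactors = FALSE)
  summ <- jsonlite::read_json(file.path(run_dir, "run_summary.json"))
  lines <- c("# Screen analysis report", "",
             "## Plate quality control", "",
             "| plate | replicate | Z' | QC pass | features used |",
             "|---|---|---|---|---|")
  for (q in qc) {
    lines <- c(lines, sprintf("| %s | %s | %.3f | %s | %s |",
                              q$plate_id, q$replicate, q$zprime,
                              if (isTRUE(q$pass)) "yes" else "NO",
                              paste(unlist(q$features_used),
                                    collapse = ", ")))
  }
  n_hits <- sum(hits$final_hit %in% TRUE)
  lines <- c(lines, "", "## Hit calling", "",
             sprintf("%d final hit(s) out of %d compounds.", n_hits,
                     nrow(hits)), "")
  if (n_hits > 0L) {
    lines <- c(lines, "| compound | replicates passed | final hit |",
               "|---|---|---|",
               sprintf("| %s | %d/%d | %s |",
                       hits$compound_id[hits$final_hit],
                       hits$n_pass[hits$final_hit],
                       hits$n_replicates[hits$final_hit], "yes"), "")
  }
  tc_path <- file.path(run_dir, "target_classes.csv")
  if (file.exists(tc_path)) {
    tc <- utils::read.csv(tc_path, stringsAsFactors = FALSE)
    lines <- c(lines, "## Target classes of hits", "",
               "| target class | hits | fraction |", "|---|---|---|")
    if (nrow(tc)) {
      lines <- c(lines, sprintf("| %s | %d | %.2f |", tc$target_class,
                                tc$n_hits, tc$fraction))
    }
    lines <- c(lines, "")
  }
  if (!is.null(summ$truth)) {
    lines <- c(lines, "## Recovery vs planted truth", "",
               sprintf("- planted actives: %s", summ$truth$n_active),
               sprintf("- recall: %.3f", summ$truth$recall),
               sprintf("- false-discovery proportion: %.3f",
                       summ$truth$false_discovery_proportion), "")
  }
  lines <- c(lines, "## Effective configuration", "", "```yaml",
             yaml::as.yaml(summ$thresholds), "```", "")
  path <- file.path(run_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
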