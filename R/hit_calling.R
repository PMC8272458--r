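#' Hit-rule configuration
#'
#' Bundles the triage and hit-calling constants. `rule = "below_nc_ac"`
#' (default) formalises the published rule -- a hit looks like the +DOX
#' controls, i.e. its distance to the active-control model is more than
#' `sd_multiplier` SDs *below* the negative-control wells' mean distance to
#' that model. The alternative reading, `rule = "nc_self"`, calls a well
#' when its distance to the negative-control model is more than
#' `sd_multiplier` SDs *above* the NC wells' own self-distance mean; it is
#' provided for comparison, not as the default.
#'
#' @param min_objects Wells with fewer objects are triaged `dead`
#'   (default 5).
#' @param disparate_quantile Quantile of the control score distributions
#'   beyond which (on both distances simultaneously) a well is `disparate`
#'   (default 0.95).
#' @param sd_multiplier SD multiplier of the hit threshold (default 1).
#' @param rule Hit-rule direction, see Description.
#' @param require_ac_like Require `ac_like` triage in every replicate for a
#'   final hit (default `TRUE`).
#' @return List of class `hit_rule_config`.
#' @export
hit_rule_config <- function(min_objects = 5L, disparate_quantile = 0.95,
                            sd_multiplier = 1,
                            rule = c("below_nc_ac", "nc_self"),
                            require_ac_like = TRUE) {
  structure(list(min_objects = as.integer(min_objects),
                 disparate_quantile = disparate_quantile,
                 sd_multiplier = sd_multiplier,
                 rule = match.arg(rule),
                 require_ac_like = isTRUE(require_ac_like)),
            class = "hit_rule_config")
}

#' Triage scored wells
#'
#' Assigns each well exactly one of four classes: `dead` (fewer than
#' `min_objects` objects -- the well is dominated by cell death or empty),
#' `disparate` (far from *both* control phenotypes: its distance to the AC
#' model exceeds the NC wells' `disparate_quantile` of that distance and
#' its distance to the NC model exceeds the AC wells' quantile of theirs),
#' `ac_like` (closer to the active-control model) or `nc_like`. Dead and
#' disparate wells remain in the tables -- they are flagged, never dropped
#' -- but can never become hits.
#'
#' @param scores data.frame with columns `well`, `role`, `mhd_ac`,
#'   `mhd_nc` (e.g. `score_plate(...)$scores`).
#' @param object_counts Named numeric vector of per-well object counts, or
#'   `NULL` when unavailable (image-free runs): no well is triaged dead.
#' @param config A [hit_rule_config()].
#' @return `scores` with an added character column `triage`.
#' @export
triage_wells <- function(scores, object_counts = NULL,
                         config = hit_rule_config()) {
  stopifnot(all(c("well", "role", "mhd_ac", "mhd_nc") %in% names(scores)))
  is_ac <- scores$role == "active_control"
  is_nc <- scores$role == "negative_control"
  if (!any(is_ac) || !any(is_nc)) {
    stop("missing control score distributions", call. = FALSE)
  }
  q_nc_ac <- stats::quantile(scores$mhd_ac[is_nc],
                             config$disparate_quantile, names = FALSE)
  q_ac_nc <- stats::quantile(scores$mhd_nc[is_ac],
                             config$disparate_quantile, names = FALSE)
  counts <- if (is.null(object_counts)) {
    rep(Inf, nrow(scores))
  } else {
    cn <- object_counts[scores$well]
    cn[is.na(cn)] <- Inf
    cn
  }
  triage <- ifelse(counts < config$min_objects, "dead",
            ifelse(scores$mhd_ac > q_nc_ac & scores$mhd_nc > q_ac_nc,
                   "disparate",
            ifelse(scores$mhd_ac <= scores$mhd_nc, "ac_like", "nc_like")))
  scores$triage <- triage
  scores
}

# Per-replicate pass decision for one score table.
replicate_pass <- function(scores, nc_stats, config) {
  thr_stats <- nc_stats
  if (config$rule == "below_nc_ac") {
    thr <- thr_stats$mean - config$sd_multiplier * thr_stats$sd
    scores$mhd_ac < thr
  } else {
    thr <- thr_stats$mean + config$sd_multiplier * thr_stats$sd
    scores$mhd_nc > thr
  }
}

#' Call hits across duplicate runs
#'
#' Applies the 1-SD duplicate-run rule: per replicate a compound well
#' passes when its Mahalanobis distance to the active-control model is
#' more than one SD below the mean of that replicate plate's
#' negative-control wells' distances (see [hit_rule_config()] for the
#' alternative direction). A compound is a final hit only if it passes in
#' *every* replicate (logical AND, >= 2 replicates) and is triaged
#' `ac_like` in every replicate. Compounds present in fewer than two
#' replicates are excluded and reported in the `findings` attribute, never
#' silently dropped.
#'
#' @param replicate_scores List (one per replicate) of triaged score
#'   data.frames with columns `well`, `role`, `compound_id`, `mhd_ac`,
#'   `mhd_nc`, `triage`.
#' @param nc_stats Optional list (one per replicate) of
#'   `list(mean =, sd =)` statistics of the NC wells' `mhd_ac` (or
#'   `mhd_nc` for the alternative rule). Computed from each replicate's
#'   negative-control rows when `NULL`.
#' @param config A [hit_rule_config()].
#' @return data.frame (one row per compound): `compound_id`,
#'   `n_replicates`, `n_pass`, `all_pass`, `all_ac_like`,
#'   `any_dead_disparate`, `final_hit`; attribute `replicates` holds the
#'   long per-replicate detail, attribute `findings` any exclusions.
#' @export
call_hits <- function(replicate_scores, nc_stats = NULL,
                      config = hit_rule_config()) {
  stopifnot(is.list(replicate_scores), length(replicate_scores) >= 1L)
  long <- do.call(rbind, lapply(seq_along(replicate_scores), function(r) {
    s <- replicate_scores[[r]]
    need <- c("compound_id", "mhd_ac", "mhd_nc", "triage", "role")
    stopifnot(all(need %in% names(s)))
    st <- if (is.null(nc_stats)) {
      v <- if (config$rule == "below_nc_ac") {
        s$mhd_ac[s$role == "negative_control"]
      } else {
        s$mhd_nc[s$role == "negative_control"]
      }
      if (length(v) < 2L) {
        stop("replicate ", r, " lacks negative-control scores",
             call. = FALSE)
      }
      list(mean = mean(v), sd = stats::sd(v))
    } else {
      nc_stats[[r]]
    }
    cmp <- s[s$role == "compound", , drop = FALSE]
    data.frame(compound_id = cmp$compound_id, replicate = r,
               mhd_ac = cmp$mhd_ac, mhd_nc = cmp$mhd_nc,
               triage = cmp$triage,
               pass = replicate_pass(cmp, st, config),
               stringsAsFactors = FALSE)
  }))
  split_l <- split(long, long$compound_id)
  n_rep <- vapply(split_l, nrow, 0L)
  findings <- character()
  single <- names(split_l)[n_rep < 2L]
  if (length(single)) {
    findings <- sprintf("compound %s present in only %d replicate(s); excluded from hit calling",
                        single, n_rep[single])
    split_l <- split_l[n_rep >= 2L]
  }
  calls <- do.call(rbind, lapply(split_l, function(g) {
    all_pass <- all(g$pass)
    all_ac <- all(g$triage == "ac_like")
    any_bad <- any(g$triage %in% c("dead", "disparate"))
    data.frame(compound_id = g$compound_id[1L],
               n_replicates = nrow(g),
               n_pass = sum(g$pass),
               all_pass = all_pass,
               all_ac_like = all_ac,
               any_dead_disparate = any_bad,
               final_hit = all_pass && !any_bad &&
                 (!config$require_ac_like || all_ac),
               stringsAsFactors = FALSE)
  }))
  if (is.null(calls)) {
    calls <- data.frame(compound_id = character(0), n_replicates = integer(0),
                        n_pass = integer(0), all_pass = logical(0),
                        all_ac_like = logical(0),
                        any_dead_disparate = logical(0),
                        final_hit = logical(0))
  }
  rownames(calls) <- NULL
  calls <- calls[order(calls$compound_id), , drop = FALSE]
  attr(calls, "replicates") <- long
  attr(calls, "findings") <- findings
  calls
}

#' Validate hits over a concentration range
#'
#' Primary hits are re-screened across an ascending concentration series
#' (8 points in the reference design) in duplicate. A compound is
#' `validated` when at least `m_consecutive` adjacent concentrations pass
#' in *both* replicates at the same concentrations -- a deliberately
#' conservative dose-consistency criterion, configurable because the
#' underlying screen reports validation without defining it numerically.
#'
#' @param validation_scores data.frame with columns `compound_id`,
#'   `concentration_uM`, `replicate`, `pass` (logical per-replicate
#'   1-SD-rule outcome at that concentration).
#' @param m_consecutive Required run length (default 2).
#' @return data.frame per compound: `compound_id`, `n_concentrations`,
#'   `max_consecutive_both`, `validated`.
#' @export
validate_hits <- function(validation_scores, m_consecutive = 2L) {
  need <- c("compound_id", "concentration_uM", "replicate", "pass")
  stopifnot(all(need %in% names(validation_scores)))
  res <- lapply(split(validation_scores, validation_scores$compound_id),
                function(g) {
    concs <- sort(unique(g$concentration_uM))
    reps <- sort(unique(g$replicate))
    if (length(reps) < 2L) {
      stop("compound ", g$compound_id[1L], " lacks duplicate validation runs",
           call. = FALSE)
    }
    grid <- table(g$concentration_uM, g$replicate)
    if (any(grid != 1L)) {
      stop("compound ", g$compound_id[1L],
           " has missing or duplicated concentration points", call. = FALSE)
    }
    both <- vapply(concs, function(cc) {
      all(g$pass[g$concentration_uM == cc])
    }, logical(1))
    run <- max_true_run(both)
    data.frame(compound_id = g$compound_id[1L],
               n_concentrations = length(concs),
               max_consecutive_both = run,
               validated = run >= m_consecutive,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarise hits by annotated target class
#'
#' Tabulates final hits by the target class of their compound (e.g. MEK1,
#' TNKS, PKC), as in the pie-chart summaries of screen reports. Hits whose
#' compound is missing from the annotation are counted under `"unknown"`
#' with a warning.
#'
#' @param hits A [call_hits()] result (or any data.frame with
#'   `compound_id` and `final_hit`); only `final_hit` rows are counted.
#' @param annotation data.frame with `compound_id`, `target_class`.
#' @return data.frame `target_class`, `n_hits`, `fraction`, sorted by
#'   descending count; zero rows for an empty hit list.
#' @export
summarize_target_classes <- function(hits, annotation) {
  stopifnot(all(c("compound_id", "final_hit") %in% names(hits)),
            all(c("compound_id", "target_class") %in% names(annotation)))
  ids <- hits$compound_id[hits$final_hit]
  if (!length(ids)) {
    return(data.frame(target_class = character(0), n_hits = integer(0),
                      fraction = numeric(0)))
  }
  cls <- annotation$target_class[match(ids, annotation$compound_id)]
  if (anyNA(cls)) {
    warning(sum(is.na(cls)), " hit compound(s) lack target-class annotation;",
            " counted as 'unknown'", call. = FALSE)
    cls[is.na(cls)] <- "unknown"
  }
  tab <- sort(table(cls), decreasing = TRUE)
  data.frame(target_class = names(tab),
             n_hits = as.integer(tab),
             fraction = as.numeric(tab) / length(ids),
             stringsAsFactors = FALSE)
}
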