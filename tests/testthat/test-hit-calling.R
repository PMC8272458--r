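make_scores <- function(mhd_ac, mhd_nc, roles, wells = NULL) {
  data.frame(well = wells %||% sprintf("w%03d", seq_along(mhd_ac)),
             role = roles, mhd_ac = mhd_ac, mhd_nc = mhd_nc,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("triage assigns exactly one class per well", {
  roles <- c(rep("active_control", 10), rep("negative_control", 10),
             rep("compound", 5))
  sc <- make_scores(c(stats::rnorm(10, 1, 0.2), stats::rnorm(10, 12, 0.5),
                      2, 11, 30, 1.5, 12),
                    c(stats::rnorm(10, 12, 0.5), stats::rnorm(10, 1, 0.2),
                      11, 2, 30, 13, 1.8),
                    roles)
  tri <- triage_wells(sc, config = hit_rule_config())
  expect_equal(nrow(tri), 25L)
  expect_true(all(tri$triage %in% c("ac_like", "nc_like", "dead",
                                    "disparate")))
  counts <- table(factor(tri$triage, c("ac_like", "nc_like", "dead",
                                       "disparate")))
  expect_equal(sum(counts), 25L)
})

test_that("triage classes follow the decision rules", {
  roles <- c(rep("active_control", 8), rep("negative_control", 8),
             rep("compound", 3))
  ac_ac <- stats::rnorm(8, 1, 0.1)
  nc_ac <- stats::rnorm(8, 12, 0.3)
  sc <- make_scores(c(ac_ac, nc_ac, 0, 100, 12.2),
                    c(stats::rnorm(8, 12, 0.3), stats::rnorm(8, 1, 0.1),
                      12, 100, 1.1),
                    roles)
  counts <- stats::setNames(rep(100, 19), sc$well)
  counts["w017"] <- 0     # first compound well: no objects -> dead
  tri <- triage_wells(sc, object_counts = counts,
                      config = hit_rule_config(min_objects = 5L))
  cmp <- tri[tri$role == "compound", ]
  expect_equal(cmp$triage, c("dead", "disparate", "nc_like"))
  # a compound sitting on the AC mean is ac_like when objects are present
  counts["w017"] <- 50
  tri2 <- triage_wells(sc, object_counts = counts)
  expect_equal(tri2$triage[tri2$well == "w017"], "ac_like")
  expect_error(triage_wells(make_scores(1, 1, "compound")),
               "control score")
})

test_that("the 1-SD duplicate rule demands passes in all replicates", {
  mk_rep <- function(cmp_ac) {
    nc_ac <- c(10, 10.5, 9.5, 10, 10.2, 9.8, 10.1, 9.9)  # mean 10, sd ~0.3
    rbind(
      make_scores(cmp_ac, rep(1, length(cmp_ac)),
                  rep("compound", length(cmp_ac)),
                  wells = sprintf("c%02d", seq_along(cmp_ac))),
      make_scores(nc_ac, stats::rnorm(8, 1, 0.1),
                  rep("negative_control", 8),
                  wells = sprintf("n%02d", 1:8)))
  }
  add_meta <- function(s) {
    s$compound_id <- ifelse(s$role == "compound", s$well, NA)
    s$triage <- ifelse(s$role == "compound", "ac_like", "nc_like")
    s
  }
  # compound 1 passes both, 2 passes only rep 1, 3 passes only rep 2,
  # 4 passes neither, 5 sits exactly at the NC mean
  r1 <- add_meta(mk_rep(c(2, 2, 12, 12, 10)))
  r2 <- add_meta(mk_rep(c(2, 12, 2, 12, 10)))
  hits <- call_hits(list(r1, r2))
  expect_equal(hits$final_hit[match(c("c01", "c02", "c03", "c04", "c05"),
                                    hits$compound_id)],
               c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # an NC-mean-level well is never a hit (strict threshold)
  expect_equal(hits$n_pass[hits$compound_id == "c05"], 0L)
})

test_that("dead or disparate triage vetoes hits; ac_like is required", {
  mk <- function(triage2) {
    nc <- make_scores(stats::rnorm(8, 10, 0.3), stats::rnorm(8, 1, 0.1),
                      rep("negative_control", 8),
                      wells = sprintf("n%02d", 1:8))
    cmp <- make_scores(2, 1, "compound", wells = "c01")
    s <- rbind(cmp, nc)
    s$compound_id <- ifelse(s$role == "compound", s$well, NA)
    s$triage <- ifelse(s$role == "compound", triage2, "nc_like")
    s
  }
  for (bad in c("dead", "disparate", "nc_like")) {
    hits <- call_hits(list(mk("ac_like"), mk(bad)))
    expect_false(hits$final_hit)
  }
  expect_true(call_hits(list(mk("ac_like"), mk("ac_like")))$final_hit)
  # without the ac_like requirement, nc_like no longer vetoes but
  # dead/disparate still do
  cfg <- hit_rule_config(require_ac_like = FALSE)
  expect_true(call_hits(list(mk("ac_like"), mk("nc_like")), config = cfg)$final_hit)
  expect_false(call_hits(list(mk("ac_like"), mk("dead")), config = cfg)$final_hit)
})

test_that("single-replicate compounds are excluded with a finding", {
  nc <- make_scores(stats::rnorm(8, 10, 0.3), stats::rnorm(8, 1, 0.1),
                    rep("negative_control", 8),
                    wells = sprintf("n%02d", 1:8))
  mk <- function(ids) {
    cmp <- make_scores(rep(2, length(ids)), rep(1, length(ids)),
                       rep("compound", length(ids)), wells = ids)
    s <- rbind(cmp, nc)
    s$compound_id <- ifelse(s$role == "compound", s$well, NA)
    s$triage <- ifelse(s$role == "compound", "ac_like", "nc_like")
    s
  }
  hits <- call_hits(list(mk(c("a", "b")), mk("a")))
  expect_equal(hits$compound_id, "a")
  expect_match(attr(hits, "findings"), "only 1 replicate")
})

test_that("lowering mhd_ac can only turn a non-hit into a hit", {
  nc_ac <- c(10, 10.5, 9.5, 10, 10.2, 9.8, 10.1, 9.9)
  mk <- function(cmp_ac) {
    s <- rbind(make_scores(cmp_ac, 1, "compound", wells = "c01"),
               make_scores(nc_ac, stats::rnorm(8, 1, 0.1),
                           rep("negative_control", 8),
                           wells = sprintf("n%02d", 1:8)))
    s$compound_id <- ifelse(s$role == "compound", s$well, NA)
    s$triage <- ifelse(s$role == "compound", "ac_like", "nc_like")
    s
  }
  grid <- seq(14, 2, by = -0.5)
  calls <- vapply(grid, function(v) {
    call_hits(list(mk(v), mk(v)))$final_hit
  }, logical(1))
  # monotone: once a hit, always a hit as mhd_ac decreases further
  expect_true(all(diff(as.integer(calls)) >= 0))
})

test_that("dose validation requires consecutive passes in both replicates", {
  mk <- function(id, p1, p2) {
    data.frame(compound_id = id,
               concentration_uM = rep(2^(0:7) * 0.04, 2),
               replicate = rep(1:2, each = 8),
               pass = c(p1, p2))
  }
  all_pass <- mk("a", rep(TRUE, 8), rep(TRUE, 8))
  expect_true(validate_hits(all_pass)$validated)

  isolated <- mk("b", c(F, F, T, F, F, F, F, F), c(F, F, T, F, F, F, F, F))
  expect_false(validate_hits(isolated)$validated)

  mismatch <- mk("c", c(F, F, F, F, T, T, T, F), c(T, F, F, F, F, F, F, F))
  expect_false(validate_hits(mismatch)$validated)

  aligned <- mk("d", c(F, F, F, F, T, T, T, F), c(F, F, F, F, F, T, T, F))
  res <- validate_hits(aligned)
  expect_true(res$validated)
  expect_equal(res$max_consecutive_both, 2L)

  expect_error(validate_hits(mk("e", rep(TRUE, 8), rep(TRUE, 8))[-1, ]),
               "missing or duplicated")
  one_rep <- mk("f", rep(TRUE, 8), rep(TRUE, 8))
  one_rep <- one_rep[one_rep$replicate == 1L, ]
  expect_error(validate_hits(one_rep), "duplicate validation")
})

test_that("target-class summaries count and normalise hits", {
  hits <- data.frame(compound_id = c("a", "b", "c", "d", "e"),
                     final_hit = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  ann <- data.frame(compound_id = c("a", "b", "c", "d", "e"),
                    target_class = c("MEK1", "MEK1", "TNKS", "PKC", "SRC"))
  tc <- summarize_target_classes(hits, ann)
  expect_equal(tc$target_class[1], "MEK1")
  expect_equal(tc$fraction, c(0.5, 0.25, 0.25))
  expect_equal(sum(tc$fraction), 1)
  expect_equal(sum(tc$n_hits), 4L)

  none <- summarize_target_classes(
    data.frame(compound_id = "a", final_hit = FALSE), ann)
  expect_equal(nrow(none), 0L)

  expect_warning(
    tc2 <- summarize_target_classes(
      data.frame(compound_id = c("a", "zz"), final_hit = c(TRUE, TRUE)),
      ann),
    "unknown")
  expect_true("unknown" %in% tc2$target_class)
})

test_that("true positives in an all-MEK1 synthetic screen are all MEK1", {
  cfg <- screen_sim_config(active_fraction = 0.1)
  sim <- simulate_screen_tables(cfg, n_compound = 100L, seed = 13)
  reps <- lapply(sim$tables, score_replicate_table)
  hits <- call_hits(reps)
  ann <- data.frame(compound_id = sim$truth$compound_id,
                    target_class = "MEK1")
  tp <- hits[hits$final_hit &
               hits$compound_id %in%
                 sim$truth$compound_id[sim$truth$is_active], ]
  expect_gt(nrow(tp), 0L)
  tc <- summarize_target_classes(
    data.frame(compound_id = tp$compound_id, final_hit = TRUE), ann)
  expect_equal(tc$target_class, "MEK1")
  expect_equal(tc$fraction, 1.0)
})
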