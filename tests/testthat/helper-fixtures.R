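# Shared fixtures: all built in code at test time.

# Flat background image with hard-edged ellipses rendered on top.
render_shapes <- function(shapes, size = 201L, background = 400) {
  img <- matrix(background, size, size)
  mpdascreen:::render_objects(img, shapes, profile = "disk")
}

disk_shape <- function(x = 101, y = 101, radius = 20, intensity = 3000) {
  data.frame(x = x, y = y, radius = radius, intensity = intensity,
             eccentricity = 0, theta = 0)
}

# Score one replicate feature table from simulate_screen_tables /
# simulate_feature_table: plate scoring plus triage, compound ids attached.
score_replicate_table <- function(tb, ...) {
  meta <- c("well", "role", "compound_id", "replicate", "is_active",
            "phenotype")
  x <- as.matrix(tb[, setdiff(names(tb), meta), drop = FALSE])
  rownames(x) <- tb$well
  ps <- score_plate(x, tb$role, ...)
  sc <- triage_wells(ps$scores)
  sc$compound_id <- tb$compound_id
  attr(sc, "plate_zprime") <- ps$zprime$zprime
  sc
}

# Minimal 384-well layout data.frame for parser tests.
layout_df <- function(n_ac = 16L, n_nc = 16L, n_compound = 352L) {
  lay <- make_screen_layout(n_ac = n_ac, n_nc = n_nc,
                            n_compound = n_compound)
  w <- lay$wells
  data.frame(well = w$well, role = w$role,
             compound_id = ifelse(is.na(w$compound_id), "", w$compound_id),
             concentration_uM = ifelse(is.na(w$concentration_uM), "",
                                       w$concentration_uM),
             replicate = 1L, stringsAsFactors = FALSE)
}

write_layout_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
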