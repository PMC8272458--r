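#' Well addresses on a 384-well plate
#'
#' A 384-well plate has rows A-P and columns 1-24. The canonical string form
#' is the row letter followed by the zero-padded column, `"A01"` .. `"P24"`;
#' parsing accepts unpadded input (`"A1"`) but always formats padded.
#'
#' @param row Integer row index 1-16, or a letter `"A"`-`"P"`.
#' @param column Integer column 1-24.
#' @return `well_address()` and `format_well()` return canonical well strings;
#'   `parse_well()` returns a data.frame with columns `well`, `row`, `column`.
#' @examples
#' well_address("B", 2)
#' parse_well(c("A01", "P24"))
#' @export
well_address <- function(row, column) {
  if (is.character(row)) row <- match(toupper(row), LETTERS[1:16])
  row <- as.integer(row)
  column <- as.integer(column)
  bad <- is.na(row) | is.na(column) | row < 1L | row > 16L |
    column < 1L | column > 24L
  if (any(bad)) {
    stop("invalid well address: row must be A-P (1-16), column 1-24",
         call. = FALSE)
  }
  sprintf("%s%02d", LETTERS[row], column)
}

#' @rdname well_address
#' @param well Character vector of well strings such as `"A01"` or `"A1"`.
#' @export
parse_well <- function(well) {
  well <- toupper(trimws(as.character(well)))
  m <- regmatches(well, regexec("^([A-P])([0-9]{1,2})$", well))
  bad <- lengths(m) != 3L
  if (any(bad)) {
    stop("malformed well address: ", paste(well[bad], collapse = ", "),
         call. = FALSE)
  }
  row <- match(vapply(m, `[`, "", 2L), LETTERS[1:16])
  column <- as.integer(vapply(m, `[`, "", 3L))
  if (any(column < 1L | column > 24L)) {
    stop("malformed well address: column outside 1-24", call. = FALSE)
  }
  data.frame(well = sprintf("%s%02d", LETTERS[row], column),
             row = row, column = column, stringsAsFactors = FALSE)
}

#' @rdname well_address
#' @export
format_well <- function(row, column) well_address(row, column)

well_roles <- function() {
  c("active_control", "negative_control", "compound", "empty")
}

all_wells_384 <- function() {
  sprintf("%s%02d", rep(LETTERS[1:16], each = 24L), rep(1:24, times = 16L))
}

#' Construct a plate layout
#'
#' A `plate_layout` holds the role assignment of all 384 wells of one plate of
#' one replicate run: which wells carry active controls (+DOX), negative
#' controls (-DOX), library compounds (with compound id and concentration in
#' micromolar), or nothing.
#'
#' @param wells data.frame with columns `well`, `role`, `compound_id`,
#'   `concentration_uM`. All 384 well addresses must appear exactly once;
#'   `compound_id` must be set exactly for `role == "compound"` wells;
#'   concentrations must be positive where present.
#' @param plate_id Plate identifier string.
#' @param replicate_id Replicate run number (>= 1).
#' @return An object of class `plate_layout`.
#' @seealso [parse_plate_map()], [validate_layout()], [make_screen_layout()]
#' @export
plate_layout <- function(wells, plate_id = "plate1", replicate_id = 1L) {
  stopifnot(is.data.frame(wells))
  need <- c("well", "role", "compound_id", "concentration_uM")
  miss <- setdiff(need, names(wells))
  if (length(miss)) {
    stop("plate layout lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pw <- parse_well(wells$well)
  wells$well <- pw$well
  wells$row <- pw$row
  wells$column <- pw$column
  if (anyDuplicated(wells$well)) {
    dup <- unique(wells$well[duplicated(wells$well)])
    stop("duplicate well address: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  missing_addr <- setdiff(all_wells_384(), wells$well)
  if (length(missing_addr)) {
    stop("layout must cover all 384 wells; missing ",
         length(missing_addr), " (first: ", missing_addr[1L], ")",
         call. = FALSE)
  }
  if (!all(wells$role %in% well_roles())) {
    bad <- unique(wells$role[!wells$role %in% well_roles()])
    stop("unknown well role: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  wells$compound_id <- as.character(wells$compound_id)
  blank <- is.na(wells$compound_id) | wells$compound_id == ""
  wells$compound_id[blank] <- NA_character_
  is_cmp <- wells$role == "compound"
  if (any(is_cmp & is.na(wells$compound_id))) {
    stop("compound well lacking compound_id: ",
         paste(wells$well[is_cmp & is.na(wells$compound_id)][1:3],
               collapse = ", "),
         call. = FALSE)
  }
  if (any(!is_cmp & !is.na(wells$compound_id))) {
    stop("compound_id set on a non-compound well", call. = FALSE)
  }
  wells$concentration_uM <- as.numeric(wells$concentration_uM)
  conc <- wells$concentration_uM
  if (any(!is.na(conc) & conc <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  wells <- wells[order(wells$row, wells$column),
                 c("well", "row", "column", "role",
                   "compound_id", "concentration_uM")]
  rownames(wells) <- NULL
  structure(list(plate_id = as.character(plate_id),
                 replicate_id = as.integer(replicate_id),
                 wells = wells),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  tab <- table(factor(x$wells$role, levels = well_roles()))
  cat("plate_layout ", x$plate_id, " (replicate ", x$replicate_id, ")\n",
      sep = "")
  cat("  wells:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read and write plate-map CSV files
#'
#' The plate-map dialect is a long-format CSV with header
#' `well,role,compound_id,concentration_uM,replicate`, one row per well,
#' zero-padded well addresses, empty fields for missing compound id or
#' concentration. `write_plate_map()` emits the canonical form (wells sorted
#' row-major); parsing then writing a canonical file reproduces it byte for
#' byte.
#'
#' @param path CSV file path.
#' @param plate_id Plate identifier; defaults to the file name without
#'   extension.
#' @return `parse_plate_map()` returns a [plate_layout()]; `write_plate_map()`
#'   returns `path` invisibly.
#' @export
parse_plate_map <- function(path, plate_id = NULL) {
  if (!file.exists(path)) stop("plate map not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("well", "role", "compound_id", "concentration_uM", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("plate map lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rep_id <- unique(df$replicate[nzchar(df$replicate)])
  if (length(rep_id) != 1L) {
    stop("plate map must carry exactly one replicate id", call. = FALSE)
  }
  df$concentration_uM[!nzchar(df$concentration_uM)] <- NA
  plate_layout(df[, c("well", "role", "compound_id", "concentration_uM")],
               plate_id = plate_id %||%
                 tools::file_path_sans_ext(basename(path)),
               replicate_id = as.integer(rep_id))
}

#' @rdname parse_plate_map
#' @param layout A [plate_layout()].
#' @export
write_plate_map <- function(layout, path) {
  stopifnot(inherits(layout, "plate_layout"))
  w <- layout$wells
  out <- data.frame(
    well = w$well,
    role = w$role,
    compound_id = ifelse(is.na(w$compound_id), "", w$compound_id),
    concentration_uM = ifelse(is.na(w$concentration_uM), "",
                              format(w$concentration_uM, trim = TRUE,
                                     scientific = FALSE)),
    replicate = layout$replicate_id,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check that a layout is usable for scoring
#'
#' Returns findings rather than raising errors, so callers can decide whether
#' a plate is analysable. Covariance estimation of the control models needs
#' several wells per control role; the default minimum is 8.
#'
#' @param layout A [plate_layout()].
#' @param min_controls Minimum wells required per control role.
#' @return Character vector of findings; empty when the layout is usable.
#'   Possible findings: `"insufficient_active_controls"`,
#'   `"insufficient_negative_controls"`, `"no_compound_wells"`.
#' @export
validate_layout <- function(layout, min_controls = 8L) {
  stopifnot(inherits(layout, "plate_layout"))
  tab <- table(factor(layout$wells$role, levels = well_roles()))
  findings <- character()
  if (tab[["active_control"]] < min_controls) {
    findings <- c(findings, "insufficient_active_controls")
  }
  if (tab[["negative_control"]] < min_controls) {
    findings <- c(findings, "insufficient_negative_controls")
  }
  if (tab[["compound"]] == 0L) findings <- c(findings, "no_compound_wells")
  findings
}

#' Read a compound annotation table
#'
#' Maps each library compound to its annotated molecular target class
#' (e.g. MEK1, TNKS, PKC), used to summarise hit lists.
#'
#' @param path CSV with columns `compound_id`, `target_class`.
#' @return data.frame with unique `compound_id` rows.
#' @export
read_compound_annotation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(c("compound_id", "target_class"), names(df))
  if (length(miss)) {
    stop("annotation lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$compound_id)) {
    stop("duplicate compound_id in annotation table", call. = FALSE)
  }
  df[, c("compound_id", "target_class")]
}

#' Build a standard screening layout
#'
#' Default geometry: active controls fill column 1 (16 wells), negative
#' controls column 24 (16 wells), and compounds the remaining 352 wells,
#' named `cmp001` .. `cmp352` row-major at a single concentration.
#'
#' @param plate_id,replicate_id Plate / replicate identifiers.
#' @param n_ac,n_nc Number of active / negative control wells (<= 16 each,
#'   placed from the top of their columns; remaining column wells are empty).
#' @param n_compound Number of compound wells (<= 352).
#' @param concentration_uM Concentration applied to every compound well.
#' @param compound_ids Optional compound id vector of length `n_compound`.
#' @return A [plate_layout()].
#' @export
make_screen_layout <- function(plate_id = "plate1", replicate_id = 1L,
                               n_ac = 16L, n_nc = 16L, n_compound = 352L,
                               concentration_uM = 5,
                               compound_ids = NULL) {
  stopifnot(n_ac <= 16L, n_nc <= 16L, n_compound <= 352L)
  wells <- parse_well(all_wells_384())
  wells$role <- "empty"
  wells$compound_id <- NA_character_
  wells$concentration_uM <- NA_real_
  ac <- wells$column == 1L & wells$row <= n_ac
  nc <- wells$column == 24L & wells$row <= n_nc
  wells$role[ac] <- "active_control"
  wells$role[nc] <- "negative_control"
  mid <- which(wells$column >= 2L & wells$column <= 23L)
  mid <- mid[seq_len(n_compound)]
  wells$role[mid] <- "compound"
  ids <- compound_ids %||% sprintf("cmp%03d", seq_len(n_compound))
  stopifnot(length(ids) == n_compound)
  wells$compound_id[mid] <- ids
  wells$concentration_uM[mid] <- concentration_uM
  plate_layout(wells[, c("well", "role", "compound_id", "concentration_uM")],
               plate_id = plate_id, replicate_id = replicate_id)
}

#' Group duplicate plate layouts into a screen run
#'
#' A screen run is the unit hit calling operates on: the same plate design
#' run in >= 2 biological replicates plus the compound annotation table.
#' Compounds present in fewer than two replicates cannot enter the
#' duplicate-run hit rule and are reported as findings by [call_hits()].
#'
#' @param layouts List of [plate_layout()]s (distinct `replicate_id`s).
#' @param annotation Optional annotation data.frame
#'   (see [read_compound_annotation()]).
#' @return An object of class `screen_run`.
#' @export
screen_run <- function(layouts, annotation = NULL) {
  stopifnot(is.list(layouts), length(layouts) >= 1L,
            all(vapply(layouts, inherits, TRUE, "plate_layout")))
  reps <- vapply(layouts, `[[`, 1L, "replicate_id")
  if (anyDuplicated(reps)) {
    stop("layouts must have distinct replicate ids", call. = FALSE)
  }
  structure(list(layouts = layouts[order(reps)], annotation = annotation),
            class = "screen_run")
}
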