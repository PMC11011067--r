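# 96-well plate layout model -------------------------------------------------
#
# The screen runs on 96-well plates whose 36 outer wells (rows A and H,
# columns 1 and 12) hold untreated cells to absorb edge effects; the 60
# inner wells hold exactly 3 non-targeting-control (NTC) wells, 2 INCENP
# transfection-QC wells, and 55 candidate siRNAs.

WELL_ROWS <- LETTERS[1:8]
WELL_COLS <- 1:12

all_wells <- function() {
  as.vector(t(outer(WELL_ROWS, WELL_COLS, paste0)))
}

is_edge_well <- function(well) {
  row <- substr(well, 1, 1)
  col <- as.integer(substring(well, 2))
  row %in% c("A", "H") | col %in% c(1L, 12L)
}

#' Construct and validate a plate layout
#'
#' @param wells data.frame with columns `well` ("A1".."H12"), `role`
#'   (`untreated_edge`, `ntc`, `incenp`, `candidate`) and `condition`
#'   (gene symbol for candidates; `NTC`, `INCENP`, `untreated` otherwise).
#' @param plate_id plate identifier.
#' @return a `plate_layout` object.
#' @export
plate_layout <- function(wells, plate_id = "PLATE1") {
  stopifnot(is.data.frame(wells),
            all(c("well", "role", "condition") %in% names(wells)))
  wells$well <- toupper(as.character(wells$well))
  wells$role <- as.character(wells$role)
  wells$condition <- as.character(wells$condition)
  layout <- structure(list(plate_id = plate_id,
                           wells = wells[order(match(wells$well, all_wells())), ]),
                      class = "plate_layout")
  validate_plate_layout(layout)
  layout
}

validate_plate_layout <- function(layout) {
  w <- layout$wells
  dup <- w$well[duplicated(w$well)]
  if (length(dup))
    stop("layout parse error: duplicate well(s) ", paste(dup, collapse = ", "))
  bad <- setdiff(w$well, all_wells())
  if (length(bad))
    stop("layout parse error: invalid well coordinate(s) ",
         paste(bad, collapse = ", "))
  if (nrow(w) != 96L)
    stop("layout error: expected 96 wells, got ", nrow(w))
  roles <- c("untreated_edge", "ntc", "incenp", "candidate")
  if (!all(w$role %in% roles))
    stop("layout parse error: unknown role(s) ",
         paste(setdiff(w$role, roles), collapse = ", "))
  edge <- is_edge_well(w$well)
  off <- w$well[edge & w$role != "untreated_edge"]
  if (length(off))
    stop("layout error: outer well(s) must be untreated_edge: ",
         paste(off, collapse = ", "))
  misplaced <- w$well[!edge & w$role == "untreated_edge"]
  if (length(misplaced))
    stop("layout error: untreated_edge role on inner well(s): ",
         paste(misplaced, collapse = ", "))
  if (sum(w$role == "ntc") != 3L)
    stop("layout error: expected exactly 3 NTC wells, found ",
         sum(w$role == "ntc"))
  if (sum(w$role == "incenp") != 2L)
    stop("layout error: expected exactly 2 INCENP wells, found ",
         sum(w$role == "incenp"))
  invisible(layout)
}

#' The default screen layout
#'
#' 36 untreated outer wells, 3 NTC wells in different plate regions
#' (B2, D6, G10), 2 INCENP wells (B11, G2) and 55 candidate wells.
#'
#' @param candidates character vector of 55 candidate condition names
#'   assigned to the inner wells in row-major order.
#' @param plate_id plate identifier.
#' @return a [plate_layout()].
#' @export
default_screen_layout <- function(candidates = sprintf("CAND%02d", 1:55),
                                  plate_id = "PLATE1") {
  stopifnot(length(candidates) == 55L)
  wells <- data.frame(well = all_wells(), role = "candidate",
                      condition = NA_character_)
  edge <- is_edge_well(wells$well)
  wells$role[edge] <- "untreated_edge"
  wells$condition[edge] <- "untreated"
  ntc <- c("B2", "D6", "G10"); inc <- c("B11", "G2")
  wells$role[wells$well %in% ntc] <- "ntc"
  wells$condition[wells$well %in% ntc] <- "NTC"
  wells$role[wells$well %in% inc] <- "incenp"
  wells$condition[wells$well %in% inc] <- "INCENP"
  cand <- wells$role == "candidate"
  wells$condition[cand] <- candidates
  plate_layout(wells, plate_id = plate_id)
}

#' Read a plate layout from CSV or YAML
#'
#' CSV files need columns `well`, `role`, `condition`; YAML files a
#' `plate_id` and a `wells` list with the same fields. All layout
#' invariants are checked and violations reported with well coordinates.
#'
#' @param path file path (`.csv`, `.yaml`/`.yml`).
#' @return a [plate_layout()].
#' @export
load_layout <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    wells <- do.call(rbind, lapply(y$wells, function(w)
      data.frame(well = w$well, role = w$role,
                 condition = if (is.null(w$condition)) NA_character_
                             else w$condition)))
    plate_layout(wells, plate_id = if (is.null(y$plate_id)) "PLATE1"
                                   else y$plate_id)
  } else {
    wells <- read.csv(path, stringsAsFactors = FALSE)
    pid <- if ("plate_id" %in% names(wells)) wells$plate_id[1] else "PLATE1"
    plate_layout(wells[c("well", "role", "condition")], plate_id = pid)
  }
}

#' Write a plate layout to CSV or YAML
#'
#' @param layout a [plate_layout()].
#' @param path destination (`.csv` or `.yaml`).
#' @export
save_layout <- function(layout, path) {
  stopifnot(inherits(layout, "plate_layout"))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(list(
      plate_id = layout$plate_id,
      wells = lapply(seq_len(nrow(layout$wells)), function(i)
        as.list(layout$wells[i, c("well", "role", "condition")]))
    ), path)
  } else {
    out <- layout$wells[c("well", "role", "condition")]
    out$plate_id <- layout$plate_id
    write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.plate_layout <- function(x, ...) {
  tab <- table(x$wells$role)
  cat(sprintf("<plate_layout> %s: %s\n", x$plate_id,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Role counts of a layout
#'
#' @param layout a [plate_layout()].
#' @return named integer vector over the four well roles (summing to 96).
#' @export
layout_counts <- function(layout) {
  roles <- c("untreated_edge", "ntc", "incenp", "candidate")
  out <- vapply(roles, function(r) sum(layout$wells$role == r), integer(1))
  setNames(out, roles)
}
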