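## Readers and writers: the 4-file CSV layout (glucose, insulin, body
## weight, doses) keyed by mouse_id, a spreadsheet import shim for
## supplementary-shaped workbooks, and manifests.

#' Write a cohort in the 4-file CSV layout
#'
#' Writes \code{glucose.csv} and \code{insulin.csv} (mouse_id, group,
#' time_min, value), \code{bodyweight.csv} (mouse_id, group,
#' body_weight_g), \code{doses.csv} (mouse_id, group, time_min, dose_mg;
#' the dose given in the interval ending at time_min), and
#' \code{manifest.json}. UTF-8, comma separator, '.' decimal; time in
#' minutes, mass in mg.
#'
#' @param records list of \code{\linkS4class{ClampRecord}}s (or the list
#'   returned by \code{\link{generateCohort}}).
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeCohortCSV <- function(records, dir) {
  manifest <- NULL
  if (!is.null(records$records)) {
    manifest <- records$manifest
    records <- records$records
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gl <- do.call(rbind, lapply(records, function(r)
    data.frame(mouse_id = r@mouseId, group = r@group,
               time_min = r@glucoseTimes, glucose_mgdl = r@glucoseValues)))
  ins <- do.call(rbind, lapply(records, function(r)
    data.frame(mouse_id = r@mouseId, group = r@group,
               time_min = r@insulinTimes, insulin_ngml = r@insulinValues)))
  bw <- do.call(rbind, lapply(records, function(r)
    data.frame(mouse_id = r@mouseId, group = r@group,
               body_weight_g = r@bodyWeight)))
  ds <- do.call(rbind, lapply(records, function(r)
    data.frame(mouse_id = r@mouseId, group = r@group,
               time_min = r@doseTimes, dose_mg = r@doses)))
  write.csv(gl, file.path(dir, "glucose.csv"), row.names = FALSE)
  write.csv(ins, file.path(dir, "insulin.csv"), row.names = FALSE)
  write.csv(bw, file.path(dir, "bodyweight.csv"), row.names = FALSE)
  write.csv(ds, file.path(dir, "doses.csv"), row.names = FALSE)
  if (!is.null(manifest))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort from the 4-file CSV layout
#'
#' Validates as it reads: shared mouse ids across the four files, sorted
#' times, positive concentrations, non-negative doses; offending rows are
#' cited in the error message.
#'
#' @param dir directory containing glucose.csv, insulin.csv,
#'   bodyweight.csv, doses.csv.
#' @return Named list of \code{\linkS4class{ClampRecord}}s.
#' @export
readClampDataset <- function(dir) {
  paths <- file.path(dir, c("glucose.csv", "insulin.csv", "bodyweight.csv",
                            "doses.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing dataset files: ", paste(basename(missing),
                                          collapse = ", "))
  gl <- read.csv(paths[1]); ins <- read.csv(paths[2])
  bw <- read.csv(paths[3]); ds <- read.csv(paths[4])
  if (any(ds$dose_mg < 0)) {
    bad <- which(ds$dose_mg < 0)
    stop("negative dose in doses.csv row(s) ",
         paste(head(bad, 5), collapse = ", "),
         " (mouse ", paste(unique(ds$mouse_id[bad]), collapse = ", "), ")")
  }
  for (chk in list(list(gl, "glucose_mgdl", "glucose.csv"),
                   list(ins, "insulin_ngml", "insulin.csv"))) {
    bad <- which(chk[[1]][[chk[[2]]]] <= 0)
    if (length(bad))
      stop("non-positive ", chk[[2]], " in ", chk[[3]], " row(s) ",
           paste(head(bad, 5), collapse = ", "))
  }
  ids <- sort(unique(gl$mouse_id))
  for (d in list(ins, bw, ds)) {
    extra <- setdiff(unique(d$mouse_id), ids)
    lack <- setdiff(ids, unique(d$mouse_id))
    if (length(extra) || length(lack))
      stop("mouse ids mismatch across files; extra: ",
           paste(extra, collapse = ", "), "; missing: ",
           paste(lack, collapse = ", "))
  }
  records <- lapply(ids, function(id) {
    g <- gl[gl$mouse_id == id, ]; i <- ins[ins$mouse_id == id, ]
    d <- ds[ds$mouse_id == id, ]; b <- bw[bw$mouse_id == id, ]
    g <- g[order(g$time_min), ]; i <- i[order(i$time_min), ]
    d <- d[order(d$time_min), ]
    clampRecord(id, g$group[1], b$body_weight_g[1],
                g$time_min, g$glucose_mgdl, i$time_min, i$insulin_ngml,
                d$time_min, d$dose_mg)
  })
  names(records) <- ids
  records
}

#' Import a cohort from supplementary-shaped workbooks
#'
#' Reads four spreadsheets laid out one-sheet-per-group: the glucose,
#' insulin and dose workbooks have a \code{time_min} first column and one
#' column per mouse id; the body-weight workbook has columns
#' \code{mouse_id} and \code{body_weight_g} per sheet. Requires the
#' \pkg{readxl} package. Returns the same records the CSV path would.
#'
#' @param glucoseXlsx,insulinXlsx,bodyweightXlsx,dosesXlsx paths to the
#'   four workbooks.
#' @return Named list of \code{\linkS4class{ClampRecord}}s.
#' @export
readClampWorkbooks <- function(glucoseXlsx, insulinXlsx, bodyweightXlsx,
                               dosesXlsx) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("the readxl package is required for workbook import")
  readLong <- function(path, valueName) {
    sheets <- readxl::excel_sheets(path)
    do.call(rbind, lapply(sheets, function(sh) {
      wide <- as.data.frame(readxl::read_excel(path, sheet = sh))
      ids <- setdiff(names(wide), "time_min")
      do.call(rbind, lapply(ids, function(id)
        setNames(data.frame(id, sh, wide$time_min, wide[[id]]),
                 c("mouse_id", "group", "time_min", valueName))))
    }))
  }
  gl <- readLong(glucoseXlsx, "glucose_mgdl")
  ins <- readLong(insulinXlsx, "insulin_ngml")
  ds <- readLong(dosesXlsx, "dose_mg")
  bw <- do.call(rbind, lapply(readxl::excel_sheets(bodyweightXlsx),
    function(sh) {
      d <- as.data.frame(readxl::read_excel(bodyweightXlsx, sheet = sh))
      data.frame(mouse_id = d$mouse_id, group = sh,
                 body_weight_g = d$body_weight_g)
    }))
  tmp <- tempfile("workbook_import_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  write.csv(gl, file.path(tmp, "glucose.csv"), row.names = FALSE)
  write.csv(ins, file.path(tmp, "insulin.csv"), row.names = FALSE)
  write.csv(bw, file.path(tmp, "bodyweight.csv"), row.names = FALSE)
  write.csv(ds, file.path(tmp, "doses.csv"), row.names = FALSE)
  readClampDataset(tmp)
}

#' Export a fitted parameter table as CSV
#'
#' Columns mirror a per-mouse estimate table: mouse id, k1..k8, G0, I0,
#' RSS.
#'
#' @param paramTable data.frame from \code{\link{fitCohort}}.
#' @param path output file.
#' @return The path, invisibly.
#' @export
exportParamTableCSV <- function(paramTable, path) {
  write.csv(paramTable, path, row.names = FALSE)
  invisible(path)
}
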