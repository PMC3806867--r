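## Readers/writers for plate grids, annotation tables and the long-format
## screen table.  All interchange formats are delimited UTF-8 text; the
## reader sniffs comma vs tab since plate readers vary.  Wells follow the
## A1 convention (rows A-P top to bottom, columns 1-24); everything past
## the reader/writer boundary uses 1-based numeric (row, column).

sniffSep <- function(line) if (lengths(regmatches(line, gregexpr("\t", line))) > 0) "\t" else ","

parseWell <- function(well) {
  m <- regmatches(well, regexec("^([A-Pa-p])0?([0-9]{1,2})$", well))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed well id(s): ", paste(unique(well[bad]), collapse = ", "))
  row <- match(toupper(vapply(m, `[`, "", 2L)), plateRowNames())
  col <- as.integer(vapply(m, `[`, "", 3L))
  if (any(col < 1 | col > PLATE_NCOL))
    stop("well column out of 1-24: ", paste(unique(well[col < 1 | col > PLATE_NCOL]), collapse = ", "))
  data.frame(row = row, column = col)
}

#' Read one raw plate grid
#'
#' Parses a delimited (comma or tab, sniffed) 16 x 24 luminescence grid.
#' Leading lines starting with `#` are metadata (`# key: value`); a
#' `barcode` entry overrides the default barcode (the file name without
#' extension).  An optional header row of column numbers and an optional
#' leading column of row letters A-P are recognised and stripped.  Missing
#' or non-numeric cells raise an error naming the offending well.
#'
#' @param path Path to the grid file.
#' @return A [RawPlate-class].
#' @seealso [writeRawPlate()]
#' @export
readRawPlate <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  metaIdx <- grep("^#", lines)
  meta <- list()
  for (l in lines[metaIdx]) {
    kv <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(kv) == 3L) meta[[trimws(kv[2])]] <- trimws(kv[3])
  }
  body <- lines[setdiff(seq_along(lines), metaIdx)]
  body <- body[nzchar(trimws(body))]
  sep <- sniffSep(body[1])
  cells <- strsplit(body, sep, fixed = TRUE)
  ## drop a header row of column indices
  first <- trimws(cells[[1]])
  if (all(grepl("^[0-9]+$", first[nzchar(first)])) || identical(tolower(first[1]), "row"))
    cells <- cells[-1]
  if (length(cells) != PLATE_NROW)
    stop(sprintf("expected %d data rows in %s, found %d", PLATE_NROW, path, length(cells)))
  grid <- matrix(NA_real_, PLATE_NROW, PLATE_NCOL)
  for (i in seq_len(PLATE_NROW)) {
    v <- trimws(cells[[i]])
    if (toupper(v[1]) %in% plateRowNames()) v <- v[-1]
    if (length(v) != PLATE_NCOL)
      stop(sprintf("row %s of %s has %d cells, expected %d (first absent well: %s%d)",
                   plateRowNames()[i], path, length(v), PLATE_NCOL,
                   plateRowNames()[i], length(v) + 1L))
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num)) {
      j <- which(is.na(num))[1]
      stop(sprintf("non-numeric cell at well %s%d in %s: '%s'",
                   plateRowNames()[i], j, path, v[j]))
    }
    grid[i, ] <- num
  }
  bc <- if (!is.null(meta$barcode)) meta$barcode else
    sub("\\.[^.]*$", "", basename(path))
  meta$barcode <- NULL
  RawPlate(bc, grid, metadata = meta)
}

#' Write a raw plate grid
#'
#' Writes the canonical tab-delimited grid format read back by
#' [readRawPlate()]: metadata lines, a column-number header and one row per
#' plate row with its letter label.
#'
#' @param plate A [RawPlate-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeRawPlate <- function(plate, path) {
  stopifnot(is(plate, "RawPlate"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# barcode: %s", barcode(plate)), con)
  md <- plate@metadata
  for (k in names(md)) writeLines(sprintf("# %s: %s", k, md[[k]]), con)
  writeLines(paste(c("row", seq_len(PLATE_NCOL)), collapse = "\t"), con)
  g <- plateGrid(plate)
  for (i in seq_len(PLATE_NROW))
    writeLines(paste(c(plateRowNames()[i],
                       format(g[i, ], digits = 15, trim = TRUE, scientific = FALSE)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a barcode-linked annotation table
#'
#' Delimited table (comma or tab) with columns `barcode, well, role, drug,
#' concentration_uM, model, bio_rep, tech_rep, library`.  Wells are given
#' in the A1 convention (`A1` or `A01`); concentrations are parsed as uM.
#' Roles are restricted to [screenRoles()]; unknown roles, unknown models
#' (against `models`) and duplicated `(barcode, well)` pairs are errors.
#'
#' @param path Path to the annotation file.
#' @param models Admissible culture-model labels (default [screenModels()];
#'   pass `NULL` to skip the check).
#' @return `data.frame` of typed annotation records with numeric `row` and
#'   `column` added.
#' @export
readAnnotations <- function(path, models = screenModels()) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- sniffSep(readLines(path, n = 1L, warn = FALSE))
  ann <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  need <- c("barcode", "well", "role", "drug", "concentration_uM", "model",
            "bio_rep", "tech_rep", "library")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation file lacks column(s): ", paste(miss, collapse = ", "))
  badRole <- setdiff(unique(ann$role), screenRoles())
  if (length(badRole))
    stop("unknown role(s): ", paste(badRole, collapse = ", "))
  if (!is.null(models)) {
    badModel <- setdiff(unique(ann$model), models)
    if (length(badModel))
      stop("unknown model label(s): ", paste(badModel, collapse = ", "))
  }
  key <- paste(ann$barcode, toupper(ann$well))
  if (anyDuplicated(key))
    stop("duplicated (barcode, well): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  rc <- parseWell(ann$well)
  ann$row <- rc$row
  ann$column <- rc$column
  ann$concentration_uM <- as.numeric(ann$concentration_uM)
  ann$bio_rep <- as.integer(ann$bio_rep)
  ann$tech_rep <- as.integer(ann$tech_rep)
  ann$drug <- as.character(ann$drug)
  smp <- ann$role == "sample"
  if (any(smp & (is.na(ann$drug) | is.na(ann$concentration_uM))))
    stop("sample wells must carry a (drug, concentration) pair")
  if (any(!smp & !is.na(ann$drug)))
    stop("control/empty wells must not carry a drug")
  ann
}

#' @rdname readAnnotations
#' @param annotations Annotation `data.frame` (e.g. from [screenLayouts()]).
#' @export
writeAnnotations <- function(annotations, path) {
  cols <- c("barcode", "well", "role", "drug", "concentration_uM", "model",
            "bio_rep", "tech_rep", "library")
  write.table(annotations[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Assemble plates and annotations into a screen table
#'
#' Inner join of the plate grids with the annotation records on
#' `(barcode, well)`.  Every plate barcode must be annotated (error listing
#' the missing ones); annotations without a plate produce a warning (or an
#' error with `strict = TRUE`).  Wells annotated `empty` are dropped with a
#' logged count.  The output is sorted by (barcode, row, column).
#'
#' @param plates List of [RawPlate-class] objects.
#' @param annotations Annotation `data.frame` ([readAnnotations()] /
#'   [screenLayouts()]).
#' @param strict Error (rather than warn) on annotations with no plate.
#' @return A [ScreenData-class].
#' @examples
#' tr <- makeTruth(4, models = "2D7d", seed = 1)
#' lay <- screenLayouts(tr, bioReps = 1)
#' scr <- assembleScreen(simulateScreen(tr, lay, seed = 2), lay)
#' scr
#' @export
assembleScreen <- function(plates, annotations, strict = FALSE) {
  stopifnot(length(plates) > 0)
  bcs <- vapply(plates, barcode, "")
  noAnn <- setdiff(bcs, unique(annotations$barcode))
  if (length(noAnn))
    stop("plate barcode(s) without annotation: ", paste(noAnn, collapse = ", "))
  orphan <- setdiff(unique(annotations$barcode), bcs)
  if (length(orphan)) {
    msg <- paste("annotation barcode(s) without plate:",
                 paste(orphan, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  if (is.null(annotations$row)) {
    rc <- parseWell(annotations$well)
    annotations$row <- rc$row
    annotations$column <- rc$column
  }
  ann <- annotations[annotations$barcode %in% bcs, ]
  nEmpty <- sum(ann$role == "empty")
  ann <- ann[ann$role != "empty", ]
  grids <- lapply(plates, plateGrid)
  names(grids) <- bcs
  ann$raw <- vapply(seq_len(nrow(ann)), function(i)
    grids[[ann$barcode[i]]][ann$row[i], ann$column[i]], 0)
  ann <- ann[order(ann$barcode, ann$row, ann$column),
             c(SCREEN_REQUIRED_COLS)]
  ScreenData(ann, log = list(dropped_empty = nEmpty, n_plates = length(plates)))
}

#' Read / write the long-format screen table
#'
#' Tab-delimited UTF-8 with one header line; value-identical round trip.
#'
#' @param x A [ScreenData-class].
#' @param path File path.
#' @return `readScreenTable` returns a [ScreenData-class].
#' @export
writeScreenTable <- function(x, path) {
  stopifnot(is(x, "ScreenData"))
  write.table(wells(x), path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeScreenTable
#' @export
readScreenTable <- function(path) {
  w <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  na.strings = c("NA", ""))
  if (!is.null(w$floored)) w$floored <- as.logical(w$floored)
  ScreenData(w)
}

#' Write hit / regression results as JSON
#'
#' @param x A [RankProductResult-class] or [MLRResult-class].
#' @param path Output path.
#' @export
writeResultJSON <- function(x, path) {
  doc <- if (is(x, "RankProductResult")) {
    list(type = "rank_product", comparison = x@comparison,
         direction = x@direction, origins = x@origins,
         permutations = x@permutations, exhaustive = x@exhaustive,
         seed = x@seed, table = resultTable(x))
  } else if (is(x, "MLRResult")) {
    list(type = "mlr", reference = x@reference, mode = x@mode,
         library = x@library, table = resultTable(x))
  } else stop("unsupported result type")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
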