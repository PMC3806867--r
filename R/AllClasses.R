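#' @import methods
#' @importFrom stats median loess loess.control predict lm coef runif rnorm
#'   rlnorm setNames as.dist hclust cor pt t.test quantile complete.cases
#' @importFrom utils read.delim write.table head
NULL

## Controlled vocabularies used throughout the pipeline ----------------------

#' Culture-model, well-role and library vocabularies
#'
#' The five culture-model arms of the screen design: 7-day monolayer
#' (`2D7d`), Matrigel cultures drugged at plating (`MG7d`) or after a 4-day
#' pre-growth (`MG4+7d`), and the corresponding polyHEMA
#' anchorage-independent cultures (`PH7d`, `PH4+7d`).  `screenRoles()` lists
#' the admissible well roles and `screenLibraries()` the two compound
#' libraries: 80 compounds at four concentrations in single wells
#' (`lib80`) and 22 compounds at seven concentrations in two technical
#' replicates (`lib22`).
#'
#' @return Character vector of admissible labels.
#' @examples
#' screenModels()
#' @export
screenModels <- function() c("2D7d", "MG7d", "MG4+7d", "PH7d", "PH4+7d")

#' @rdname screenModels
#' @export
screenRoles <- function() c("sample", "negative_control", "positive_control", "empty")

#' @rdname screenModels
#' @export
screenLibraries <- function() c("lib80", "lib22")

#' @rdname screenModels
#' @export
expressionSamples <- function() c("xenograft", "2D7d", "MG4d", "MG7d", "PH4d", "PH7d")

PLATE_NROW <- 16L
PLATE_NCOL <- 24L

plateRowNames <- function() LETTERS[seq_len(PLATE_NROW)]

## RawPlate -------------------------------------------------------------------

#' RawPlate: one 384-well luminescence grid
#'
#' Container for a single plate-reader acquisition: a barcode, a complete
#' 16 x 24 grid of raw luminescence values (RLU, CellTiter-Glo) and
#' free-form acquisition metadata.  Rows are labelled A-P top to bottom and
#' columns 1-24 left to right (the A1 convention).
#'
#' @slot barcode Single plate barcode string.
#' @slot grid Numeric 16 x 24 matrix of finite, non-negative RLU values.
#' @slot metadata Named list of free-form acquisition metadata.
#'
#' @seealso [readRawPlate()], [writeRawPlate()], [simulateScreen()]
#' @export
setClass("RawPlate",
  slots = c(barcode = "character", grid = "matrix", metadata = "list"),
  prototype = list(barcode = NA_character_,
                   grid = matrix(0, PLATE_NROW, PLATE_NCOL,
                                 dimnames = list(LETTERS[1:16], 1:24)),
                   metadata = list()))

setValidity("RawPlate", function(object) {
  msg <- character()
  if (length(object@barcode) != 1L || is.na(object@barcode) || !nzchar(object@barcode))
    msg <- c(msg, "barcode must be a single non-empty string")
  g <- object@grid
  if (!is.numeric(g) || !identical(dim(g), c(PLATE_NROW, PLATE_NCOL)))
    msg <- c(msg, sprintf("grid must be a numeric %d x %d matrix", PLATE_NROW, PLATE_NCOL))
  else {
    if (any(!is.finite(g)))
      msg <- c(msg, "grid contains non-finite values")
    else if (any(g < 0))
      msg <- c(msg, "grid contains negative values")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RawPlate
#'
#' @param barcode Plate barcode string.
#' @param grid Numeric 16 x 24 matrix (rows A-P, columns 1-24).
#' @param metadata Named list of acquisition metadata.
#' @return A [RawPlate-class] object.
#' @examples
#' p <- RawPlate("P1", matrix(1000, 16, 24))
#' plateGrid(p)[1, 1]
#' @export
RawPlate <- function(barcode, grid, metadata = list()) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "double"
  dimnames(grid) <- list(plateRowNames(), seq_len(PLATE_NCOL))
  new("RawPlate", barcode = as.character(barcode), grid = grid,
      metadata = as.list(metadata))
}

#' @describeIn RawPlate barcode accessor
#' @param object,x A `RawPlate`.
#' @export
setGeneric("barcode", function(x) standardGeneric("barcode"))

#' @rdname RawPlate
#' @export
setMethod("barcode", "RawPlate", function(x) x@barcode)

#' @rdname RawPlate
#' @export
setGeneric("plateGrid", function(x) standardGeneric("plateGrid"))

#' @rdname RawPlate
#' @export
setMethod("plateGrid", "RawPlate", function(x) x@grid)

setMethod("show", "RawPlate", function(object) {
  g <- object@grid
  cat("RawPlate", object@barcode, sprintf("(%d x %d)\n", nrow(g), ncol(g)))
  cat(sprintf("  signal range: %.4g - %.4g RLU, median %.4g\n",
              min(g), max(g), median(g)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

## ScreenData -----------------------------------------------------------------

SCREEN_REQUIRED_COLS <- c("barcode", "row", "column", "role", "drug",
                          "concentration_uM", "model", "bio_rep", "tech_rep",
                          "library", "raw")
SCREEN_VALUE_COLS <- c("corrected", "ctrl_ratio", "loess_log", "centered",
                       "floored")

#' ScreenData: long-format screen table
#'
#' One record per measured well across all plates of a screen, joining the
#' plate grids with the barcode-linked annotations.  Raw values are filled
#' by [assembleScreen()]; the normalization columns (`corrected`,
#' `ctrl_ratio`, `loess_log`, `centered`, `floored`) are filled by
#' [normalizeScreen()] and start as `NA`.
#'
#' @slot wells A `data.frame` with one row per well, columns
#'   `barcode, row, column, role, drug, concentration_uM, model, bio_rep,
#'   tech_rep, library, raw` plus the normalization columns.
#' @slot log Named list recording processing provenance (dropped wells,
#'   per-plate control CV before/after correction, parameters used).
#'
#' @seealso [assembleScreen()], [normalizeScreen()], [wells()]
#' @export
setClass("ScreenData",
  slots = c(wells = "data.frame", log = "list"),
  prototype = list(wells = data.frame(), log = list()))

setValidity("ScreenData", function(object) {
  w <- object@wells
  msg <- character()
  miss <- setdiff(SCREEN_REQUIRED_COLS, names(w))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(w)) {
    key <- paste(w$barcode, w$row, w$column)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicated (barcode, row, column) records")
    bad <- setdiff(unique(w$role), screenRoles())
    if (length(bad))
      msg <- c(msg, paste("unknown roles:", paste(bad, collapse = ", ")))
    smp <- w$role == "sample"
    if (any(smp & (is.na(w$drug) | is.na(w$concentration_uM))))
      msg <- c(msg, "sample wells must carry a (drug, concentration) pair")
  }
  if (length(msg)) msg else TRUE
})

ScreenData <- function(wells, log = list()) {
  for (col in SCREEN_VALUE_COLS)
    if (is.null(wells[[col]]))
      wells[[col]] <- if (col == "floored") FALSE else NA_real_
  rownames(wells) <- NULL
  new("ScreenData", wells = wells, log = log)
}

#' @rdname ScreenData
#' @param x A `ScreenData` object.
#' @export
setGeneric("wells", function(x) standardGeneric("wells"))

#' @rdname ScreenData
#' @export
setMethod("wells", "ScreenData", function(x) x@wells)

#' @rdname ScreenData
#' @export
setGeneric("processingLog", function(x) standardGeneric("processingLog"))

#' @rdname ScreenData
#' @export
setMethod("processingLog", "ScreenData", function(x) x@log)

setMethod("show", "ScreenData", function(object) {
  w <- object@wells
  cat("ScreenData:", nrow(w), "wells on", length(unique(w$barcode)), "plates\n")
  if (nrow(w)) {
    cat("  models:", paste(sort(unique(w$model)), collapse = ", "), "\n")
    cat("  drugs:", length(unique(w$drug[w$role == "sample"])),
        " libraries:", paste(sort(unique(w$library[w$role == "sample"])), collapse = ", "), "\n")
    cat("  normalized:", if (all(is.na(w$loess_log))) "no" else "yes", "\n")
  }
})

## SyntheticTruth -------------------------------------------------------------

#' SyntheticTruth: ground truth of a simulated screen
#'
#' Per drug x culture-model four-parameter Hill dose-response truth, the
#' per-model growth scale (endpoint signal per plated cell relative to 2D),
#' and the plate artifact model (linear row/column gradients, optional
#' radial bowl, edge effect, multiplicative lognormal noise CV).
#'
#' @slot drugs `data.frame` with columns `drug, model, e0, emax, ec50, h`
#'   (viability fractions, EC50 in uM, Hill coefficient).
#' @slot models `data.frame` with columns `model, growth_scale, cells_plated,
#'   response_shift` (log2 shift applied multiplicatively to sample-well
#'   viability, used for calibration studies).
#' @slot plate Named list: `gradient_row`, `gradient_col`, `radial`
#'   (amplitudes as fraction of the plate mean), `edge_effect`
#'   (multiplier on the outermost wells), `noise_cv`, `plate_scale`
#'   (RLU per plated 2D cell), `pos_kill` (positive-control kill fraction).
#' @slot seed Integer master seed the truth was drawn with.
#'
#' @seealso [makeTruth()], [simulateScreen()]
#' @export
setClass("SyntheticTruth",
  slots = c(drugs = "data.frame", models = "data.frame",
            plate = "list", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  d <- object@drugs
  m <- object@models
  p <- object@plate
  msg <- character()
  need <- c("drug", "model", "e0", "emax", "ec50", "h")
  if (!all(need %in% names(d)))
    return("drugs table lacks required columns")
  if (nrow(d)) {
    if (any(d$emax < 0 | d$emax > d$e0)) msg <- c(msg, "need 0 <= emax <= e0")
    if (any(d$ec50 <= 0)) msg <- c(msg, "ec50 must be > 0")
    if (any(d$h <= 0)) msg <- c(msg, "Hill coefficient must be > 0")
  }
  if (any(m$growth_scale <= 0)) msg <- c(msg, "growth_scale must be > 0")
  if (p$noise_cv < 0) msg <- c(msg, "noise_cv must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SyntheticTruth
#' @param x A `SyntheticTruth` object.
#' @export
setGeneric("truthDrugs", function(x) standardGeneric("truthDrugs"))

#' @rdname SyntheticTruth
#' @export
setMethod("truthDrugs", "SyntheticTruth", function(x) x@drugs)

#' @rdname SyntheticTruth
#' @export
setGeneric("truthModels", function(x) standardGeneric("truthModels"))

#' @rdname SyntheticTruth
#' @export
setMethod("truthModels", "SyntheticTruth", function(x) x@models)

#' @rdname SyntheticTruth
#' @export
setGeneric("plateParams", function(x) standardGeneric("plateParams"))

#' @rdname SyntheticTruth
#' @export
setMethod("plateParams", "SyntheticTruth", function(x) x@plate)

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(unique(object@drugs$drug)), "drugs x",
      nrow(object@models), "models (seed", object@seed, ")\n")
  p <- object@plate
  cat(sprintf("  plate artifacts: gradients (%.2g, %.2g), radial %.2g, edge %.2g, noise CV %.2g\n",
              p$gradient_row, p$gradient_col, p$radial, p$edge_effect, p$noise_cv))
})

## LoessFit -------------------------------------------------------------------

#' LoessFit: fitted spatial-bias surface of one plate
#'
#' @slot fitted 16 x 24 matrix of fitted surface values (`NA` where no well
#'   entered the fit).
#' @slot weights 16 x 24 matrix of final robustness weights.
#' @slot span Loess span used.
#' @slot iterations Number of robustness (bisquare re-weighting) passes.
#'
#' @seealso [correctSpatialBias()]
#' @export
setClass("LoessFit",
  slots = c(fitted = "matrix", weights = "matrix",
            span = "numeric", iterations = "integer"))

setMethod("show", "LoessFit", function(object) {
  f <- object@fitted[!is.na(object@fitted)]
  cat(sprintf("LoessFit: span %.2f, %d robustness passes, surface range %.4g - %.4g\n",
              object@span, object@iterations, min(f), max(f)))
})

## Result containers ----------------------------------------------------------

#' RankProductResult: rank-product hit statistics for one comparison
#'
#' Hit calling of one culture model against the 2D reference with each drug
#' concentration treated as an independent origin.  `resultTable()` returns
#' one row per drug with its per-origin ranks, the rank product RP
#' (geometric mean of ranks), the expected RP of the matching position under
#' the permutation null, a permutation p-value and the pfp (proportion of
#' false positives / expected false discovery rate) at the drug's position
#' in the RP-sorted list.
#'
#' @slot table `data.frame` of per-drug statistics, sorted by RP.
#' @slot comparison Character, e.g. `"MG7d vs 2D7d"`.
#' @slot direction `"down"` (sensitization) or `"up"` (resistance).
#' @slot origins Numeric vector of the concentrations used as origins.
#' @slot permutations Number of permutations used (or enumerated).
#' @slot exhaustive Logical, whether the null was enumerated exactly.
#' @slot seed Integer seed.
#'
#' @seealso [rankProduct()]
#' @export
setClass("RankProductResult",
  slots = c(table = "data.frame", comparison = "character",
            direction = "character", origins = "numeric",
            permutations = "numeric", exhaustive = "logical",
            seed = "integer"))

setValidity("RankProductResult", function(object) {
  t <- object@table
  msg <- character()
  if (nrow(t)) {
    n <- nrow(t)
    if (any(t$RP < 1 - 1e-9 | t$RP > n + 1e-9))
      msg <- c(msg, "RP outside [1, n_drugs]")
    if (any(t$pfp < 0)) msg <- c(msg, "pfp must be >= 0")
    if (is.unsorted(t$pfp, strictly = FALSE))
      msg <- c(msg, "pfp must be non-decreasing along the RP-sorted list")
    if (any(t$p < 0 | t$p > 1)) msg <- c(msg, "p outside [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname RankProductResult
#' @param x A result object.
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' @rdname RankProductResult
#' @export
setMethod("resultTable", "RankProductResult", function(x) x@table)

setMethod("show", "RankProductResult", function(object) {
  cat("RankProductResult:", object@comparison, sprintf("(direction %s)\n", object@direction))
  cat(sprintf("  %d drugs, %d origins, %s null (%g permutations), seed %d\n",
              nrow(object@table), length(object@origins),
              if (object@exhaustive) "enumerated" else "sampled",
              object@permutations, object@seed))
  print(head(object@table[, c("drug", "RP", "expectedRP", "p", "pfp")], 5))
})

#' MLRResult: multiple linear regression comparison of culture models
#'
#' Least-squares fit of loess-log normalized drug response on culture model
#' (2D as the reference level) with drug x concentration combinations as
#' blocking covariates, so each model coefficient is the matched mean
#' response shift versus 2D in log2 units.  Negative significant estimates
#' identify drug-sensitized culture models.
#'
#' @slot table `data.frame` with columns `term, estimate, se, t, p, n`.
#' @slot reference Reference culture model.
#' @slot mode `"blocked"` (one fit, concentration-blocked strata) or
#'   `"per-concentration"` (separate fits per dose).
#' @slot library Library label(s) the fit used.
#'
#' @seealso [fitMLR()], [classifySensitized()]
#' @export
setClass("MLRResult",
  slots = c(table = "data.frame", reference = "character",
            mode = "character", library = "character"))

setValidity("MLRResult", function(object) {
  t <- object@table
  if (nrow(t)) {
    if (any(t$p < 0 | t$p > 1)) return("p outside [0, 1]")
    ok <- abs(t$t - t$estimate / t$se) < 1e-9 * pmax(1, abs(t$t))
    if (!all(ok)) return("t must equal estimate / se")
  }
  TRUE
})

#' @rdname MLRResult
#' @export
setMethod("resultTable", "MLRResult", function(x) x@table)

setMethod("show", "MLRResult", function(object) {
  cat("MLRResult vs", object@reference,
      sprintf("(%s, library %s)\n", object@mode, paste(object@library, collapse = "+")))
  print(object@table)
})
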