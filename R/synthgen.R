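## Synthetic 384-well screen generator: Hill dose-response truth, spatial
## plate artifacts, multiplicative lognormal noise, model-specific growth.

#' Four-parameter Hill viability model
#'
#' Viability fraction at concentration `conc`:
#' `emax + (e0 - emax) / (1 + (conc / ec50)^h)`.  Monotone non-increasing in
#' `conc`; `conc = 0` returns `e0` exactly and `conc = ec50` the midpoint
#' `(e0 + emax) / 2` for any Hill coefficient.
#'
#' @param conc Concentration(s), uM, `>= 0`.
#' @param e0 Top asymptote (viability fraction at zero dose).
#' @param emax Bottom asymptote, `0 <= emax <= e0`.
#' @param ec50 Half-effect concentration, uM, `> 0`.
#' @param h Hill coefficient, `> 0`.
#' @return Viability fraction(s), same length as `conc`.
#' @examples
#' hillViability(10, e0 = 1, emax = 0.2, ec50 = 1, h = 1)  # 0.27273
#' @export
hillViability <- function(conc, e0, emax, ec50, h) {
  stopifnot(all(conc >= 0), all(ec50 > 0), all(h > 0),
            all(emax >= 0), all(emax <= e0))
  out <- emax + (e0 - emax) / (1 + (conc / ec50)^h)
  out[conc == 0] <- (e0 + numeric(length(out)))[conc == 0]  # exact limit
  out
}

#' Default per-model growth scales and plated cell numbers
#'
#' Growth scale is the endpoint signal per plated cell relative to 2D:
#' Matrigel cultures grow 1.86x faster and polyHEMA cultures 7.2x slower
#' than the monolayer, so the Matrigel/polyHEMA rate ratio is
#' 1.86 * 7.2 = 13.392.  Cell numbers at plating follow the screen design
#' (850 for 2D, 500 for Matrigel, 5000 for polyHEMA).
#'
#' @return `data.frame` with columns `model, growth_scale, cells_plated`.
#' @export
defaultGrowthScales <- function() {
  data.frame(
    model = screenModels(),
    growth_scale = c(1, 1.86, 1.86, 1 / 7.2, 1 / 7.2),
    cells_plated = c(850, 500, 500, 5000, 5000))
}

#' Default concentration series of the two libraries
#'
#' `lib80`: four ten-fold dilutions, 0.02-20 uM.  `lib22`: seven ten-fold
#' dilutions from the same 20 uM top, reaching a lower starting point
#' (2e-5 uM).
#'
#' @param library `"lib80"` or `"lib22"`.
#' @return Numeric vector of concentrations in uM, ascending.
#' @export
defaultConcentrations <- function(library = c("lib80", "lib22")) {
  library <- match.arg(library)
  if (library == "lib80") c(0.02, 0.2, 2, 20) else 20 / 10^(6:0)
}

## substream seeds derived deterministically from a master seed
deriveSeeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Draw a synthetic dose-response truth
#'
#' Per drug, draws `e0 = 1`, `emax ~ U(0, 0.9)`, Hill coefficient
#' `h ~ U(0.5, 3)` and a base EC50 log-uniform over the tested dose range
#' (`ec50Range`, default 0.02-20 uM).  Per culture model, the drug's
#' log2(EC50) is offset by `sensitivityShift[model]` plus an independent
#' `N(0, modelSd)` jitter, so `sensitivityShift` moves the model's mean
#' log2(EC50) relative to 2D (negative shift = sensitized model).
#' Regeneration with the same arguments is byte-identical.
#'
#' @param nDrugs Number of drugs (`>= 0`). Drug ids are `drug001`, ...
#' @param models Culture-model labels (subset of [screenModels()] or
#'   custom labels declared here).
#' @param sensitivityShift Named numeric, per-model log2(EC50) offset
#'   (missing models get 0).
#' @param responseShift Named numeric, per-model uniform log2 shift applied
#'   to sample-well viability at simulation time (calibration hook;
#'   default 0).
#' @param seed Integer master seed.
#' @param ec50Range Length-2 numeric, EC50 support in uM.
#' @param modelSd SD of the per-drug-per-model log2(EC50) jitter.
#' @param gradientRow,gradientCol Linear gradient amplitudes, fraction of
#'   the plate mean across the plate.
#' @param radial Radial bowl amplitude (fraction of plate mean).
#' @param edgeEffect Multiplicative factor on the outermost wells.
#' @param noiseCv Coefficient of variation of the multiplicative lognormal
#'   well noise.
#' @param plateScale RLU per plated 2D-equivalent cell.
#' @param posKill Positive-control kill fraction (viability `1 - posKill`).
#' @param growthScales `data.frame` as [defaultGrowthScales()]; custom
#'   model labels must appear here.
#' @return A [SyntheticTruth-class] object.
#' @examples
#' tr <- makeTruth(5, seed = 7)
#' truthDrugs(tr)[1:3, ]
#' @export
makeTruth <- function(nDrugs,
                      models = screenModels(),
                      sensitivityShift = numeric(),
                      responseShift = numeric(),
                      seed = 1L,
                      ec50Range = c(0.02, 20),
                      modelSd = 0.25,
                      gradientRow = 0.1,
                      gradientCol = 0.05,
                      radial = 0,
                      edgeEffect = 0.95,
                      noiseCv = 0.05,
                      plateScale = 600,
                      posKill = 0.95,
                      growthScales = defaultGrowthScales()) {
  if (length(nDrugs) != 1L || is.na(nDrugs) || nDrugs < 0)
    stop("nDrugs must be a single non-negative count")
  nDrugs <- as.integer(nDrugs)
  unknown <- setdiff(models, growthScales$model)
  if (length(unknown))
    stop("unknown model label(s): ", paste(unknown, collapse = ", "))
  stopifnot(all(is.finite(sensitivityShift)), all(is.finite(responseShift)))
  bad <- setdiff(names(sensitivityShift), models)
  if (length(bad))
    stop("sensitivityShift names not in models: ", paste(bad, collapse = ", "))

  shift <- setNames(numeric(length(models)), models)
  shift[names(sensitivityShift)] <- sensitivityShift
  rshift <- setNames(numeric(length(models)), models)
  rshift[intersect(names(responseShift), models)] <-
    responseShift[intersect(names(responseShift), models)]

  set.seed(as.integer(seed))
  ids <- sprintf("drug%03d", seq_len(nDrugs))
  if (nDrugs > 0) {
    emax <- runif(nDrugs, 0, 0.9)
    h <- runif(nDrugs, 0.5, 3)
    lec50 <- runif(nDrugs, log2(ec50Range[1]), log2(ec50Range[2]))
    jitter <- matrix(rnorm(nDrugs * length(models), 0, modelSd),
                     nDrugs, length(models))
    drugs <- do.call(rbind, lapply(seq_along(models), function(j) {
      data.frame(drug = ids, model = models[j], e0 = 1, emax = emax,
                 ec50 = 2^(lec50 + shift[j] + jitter[, j]), h = h)
    }))
  } else {
    drugs <- data.frame(drug = character(), model = character(),
                        e0 = numeric(), emax = numeric(),
                        ec50 = numeric(), h = numeric())
  }
  mtab <- growthScales[match(models, growthScales$model), ]
  mtab$response_shift <- unname(rshift)
  rownames(mtab) <- NULL
  new("SyntheticTruth",
      drugs = drugs, models = mtab,
      plate = list(gradient_row = gradientRow, gradient_col = gradientCol,
                   radial = radial, edge_effect = edgeEffect,
                   noise_cv = noiseCv, plate_scale = plateScale,
                   pos_kill = posKill),
      seed = as.integer(seed))
}

#' Multiplicative spatial field of a plate
#'
#' `1 + gRow * u + gCol * v + radial * (rho^2 - mean(rho^2))` with `u`, `v`
#' the row/column coordinates scaled to `[-1, 1]` and `rho` the normalized
#' distance to the plate centre; the outermost wells are multiplied by
#' `edgeEffect`; finally the field is rescaled to plate mean 1, so the
#' artifact redistributes but does not create signal.
#'
#' @param gradientRow,gradientCol,radial,edgeEffect Field parameters, see
#'   [makeTruth()].
#' @return 16 x 24 matrix with mean exactly 1.
#' @export
spatialField <- function(gradientRow = 0, gradientCol = 0, radial = 0,
                         edgeEffect = 1) {
  r <- seq_len(PLATE_NROW)
  c <- seq_len(PLATE_NCOL)
  u <- (r - (PLATE_NROW + 1) / 2) / ((PLATE_NROW - 1) / 2)
  v <- (c - (PLATE_NCOL + 1) / 2) / ((PLATE_NCOL - 1) / 2)
  f <- 1 + outer(u, rep(0, PLATE_NCOL), "*") + gradientRow * outer(u, rep(1, PLATE_NCOL)) +
    gradientCol * outer(rep(1, PLATE_NROW), v)
  if (radial != 0) {
    rho2 <- outer(u^2, rep(1, PLATE_NCOL)) + outer(rep(1, PLATE_NROW), v^2)
    f <- f + radial * (rho2 - mean(rho2))
  }
  edge <- matrix(1, PLATE_NROW, PLATE_NCOL)
  edge[c(1, PLATE_NROW), ] <- edgeEffect
  edge[, c(1, PLATE_NCOL)] <- edgeEffect
  f <- f * edge
  f / mean(f)
}

#' Build the plate layouts / annotation table of a screen
#'
#' Lays out the two-library, five-model, three-biological-replicate screen
#' design: for each (model, biological replicate, library) the library's
#' drugs are placed at all concentrations (in `techReps` technical
#' replicates for `lib22`) in the 320 sample wells of columns 3-22, chunking
#' onto additional plates when a library exceeds one plate.  Columns 1-2
#' are negative controls and columns 23-24 positive controls (>= 8 negative
#' controls per plate, as the normalization requires).
#'
#' @param truth A [SyntheticTruth-class]; its drugs are assigned to
#'   libraries with `lib22Drugs` drawn from the end of the drug table.
#' @param models Models to lay out (default: all models in `truth`).
#' @param bioReps Number of biological replicates (default 3).
#' @param lib22Drugs How many of the last drugs form the 7-concentration
#'   library (default 22 when there are more than 22 drugs, else 0).
#' @param conc80,conc22 Concentration series of the two libraries.
#' @param techReps22 Technical replicates of `lib22` (default 2).
#' @return `data.frame` in the annotation-table format: `barcode, well,
#'   row, column, role, drug, concentration_uM, model, bio_rep, tech_rep,
#'   library`.
#' @examples
#' tr <- makeTruth(10, seed = 1)
#' head(screenLayouts(tr, bioReps = 1))
#' @export
screenLayouts <- function(truth,
                          models = unique(truthModels(truth)$model),
                          bioReps = 3,
                          lib22Drugs = NULL,
                          conc80 = defaultConcentrations("lib80"),
                          conc22 = defaultConcentrations("lib22"),
                          techReps22 = 2) {
  ids <- unique(truthDrugs(truth)$drug)
  if (is.null(lib22Drugs)) lib22Drugs <- if (length(ids) > 22) 22L else 0L
  stopifnot(lib22Drugs <= length(ids))
  lib22 <- if (lib22Drugs > 0) utils::tail(ids, lib22Drugs) else character()
  lib80 <- setdiff(ids, lib22)

  sampleCols <- 3:(PLATE_NCOL - 2)
  nSample <- PLATE_NROW * length(sampleCols)

  ## per-library list of per-plate sample assignments (drug, conc, tech_rep)
  libPlates <- function(drugs, conc, techReps, label) {
    if (!length(drugs)) return(list())
    perDrug <- length(conc) * techReps
    drugsPerPlate <- nSample %/% perDrug
    if (drugsPerPlate < 1)
      stop("dose series of ", label, " does not fit a plate")
    chunks <- split(drugs, ceiling(seq_along(drugs) / drugsPerPlate))
    lapply(chunks, function(ch) {
      data.frame(drug = rep(ch, each = perDrug),
                 concentration_uM = rep(rep(conc, times = techReps), length(ch)),
                 tech_rep = rep(rep(seq_len(techReps), each = length(conc)), length(ch)),
                 library = label)
    })
  }
  plates <- c(libPlates(lib80, conc80, 1L, "lib80"),
              libPlates(lib22, conc22, as.integer(techReps22), "lib22"))
  if (!length(plates)) stop("no drugs to lay out")

  rowcol <- expand.grid(row = seq_len(PLATE_NROW), column = sampleCols)
  rowcol <- rowcol[order(rowcol$column, rowcol$row), ]
  ctrl <- expand.grid(row = seq_len(PLATE_NROW), column = c(1:2, 23:24))
  ctrlRole <- ifelse(ctrl$column <= 2, "negative_control", "positive_control")

  out <- list()
  k <- 0L
  for (m in models) for (b in seq_len(bioReps)) for (pi in seq_along(plates)) {
    k <- k + 1L
    smp <- plates[[pi]]
    bc <- sprintf("%s_r%d_p%02d", gsub("[^A-Za-z0-9]", "", m), b, pi)
    n <- nrow(smp)
    samp <- data.frame(barcode = bc,
                       row = rowcol$row[seq_len(n)],
                       column = rowcol$column[seq_len(n)],
                       role = "sample", drug = smp$drug,
                       concentration_uM = smp$concentration_uM,
                       model = m, bio_rep = b, tech_rep = smp$tech_rep,
                       library = smp$library)
    ctl <- data.frame(barcode = bc, row = ctrl$row, column = ctrl$column,
                      role = ctrlRole, drug = NA_character_,
                      concentration_uM = NA_real_, model = m, bio_rep = b,
                      tech_rep = 1L, library = smp$library[1])
    ## unused sample positions stay empty
    if (n < nSample) {
      emp <- data.frame(barcode = bc,
                        row = rowcol$row[(n + 1):nSample],
                        column = rowcol$column[(n + 1):nSample],
                        role = "empty", drug = NA_character_,
                        concentration_uM = NA_real_, model = m, bio_rep = b,
                        tech_rep = 1L, library = smp$library[1])
      out[[k]] <- rbind(samp, ctl, emp)
    } else out[[k]] <- rbind(samp, ctl)
  }
  ann <- do.call(rbind, out)
  ann$well <- sprintf("%s%02d", plateRowNames()[ann$row], ann$column)
  ann <- ann[order(ann$barcode, ann$row, ann$column),
             c("barcode", "well", "row", "column", "role", "drug",
               "concentration_uM", "model", "bio_rep", "tech_rep", "library")]
  rownames(ann) <- NULL
  ann
}

#' Simulate the raw plates of a screen
#'
#' Well signal = `plate_scale * cells_plated * growth_scale(model) *
#' viability * field(row, col) * noise`, where viability is the Hill value
#' at the well's dose (1 for negative controls, `1 - pos_kill` for positive
#' controls, times `2^response_shift[model]` on sample wells), `field` is
#' the mean-1 multiplicative spatial artifact of [spatialField()] and
#' `noise` is lognormal with mean 1 and the configured CV.  Empty wells
#' read 0.  A single master seed deterministically derives one substream
#' per plate, so identical inputs give identical plates.
#'
#' @param truth A [SyntheticTruth-class].
#' @param layouts Annotation-format `data.frame` from [screenLayouts()].
#' @param seed Integer master seed for the noise (independent of the truth
#'   seed).
#' @return Named list of [RawPlate-class] objects, one per barcode.
#' @examples
#' tr <- makeTruth(4, models = c("2D7d", "MG7d"), seed = 1, noiseCv = 0)
#' pl <- simulateScreen(tr, screenLayouts(tr, bioReps = 1), seed = 2)
#' length(pl)
#' @export
simulateScreen <- function(truth, layouts, seed = 1L) {
  stopifnot(is(truth, "SyntheticTruth"))
  if (!nrow(layouts)) stop("empty layout list")
  td <- truthDrugs(truth)
  lay.drugs <- unique(layouts$drug[layouts$role == "sample"])
  unknown <- setdiff(lay.drugs, unique(td$drug))
  if (length(unknown))
    stop("layout references unknown drug(s): ", paste(unknown, collapse = ", "))
  mt <- truthModels(truth)
  p <- plateParams(truth)
  field <- spatialField(p$gradient_row, p$gradient_col, p$radial, p$edge_effect)
  sdlog <- sqrt(log(1 + p$noise_cv^2))

  barcodes <- unique(layouts$barcode)
  seeds <- deriveSeeds(seed, length(barcodes))
  key <- paste(td$drug, td$model)

  plates <- lapply(seq_along(barcodes), function(i) {
    ann <- layouts[layouts$barcode == barcodes[i], ]
    mrow <- mt[match(ann$model[1], mt$model), ]
    if (is.na(mrow$model)) stop("unknown model label: ", ann$model[1])
    viab <- numeric(nrow(ann))
    smp <- ann$role == "sample"
    if (any(smp)) {
      idx <- match(paste(ann$drug[smp], ann$model[smp]), key)
      viab[smp] <- hillViability(ann$concentration_uM[smp], td$e0[idx],
                                 td$emax[idx], td$ec50[idx], td$h[idx]) *
        2^mrow$response_shift
    }
    viab[ann$role == "negative_control"] <- 1
    viab[ann$role == "positive_control"] <- 1 - p$pos_kill
    base <- p$plate_scale * mrow$cells_plated * mrow$growth_scale
    set.seed(seeds[i])
    noise <- if (p$noise_cv > 0)
      rlnorm(nrow(ann), meanlog = -sdlog^2 / 2, sdlog = sdlog) else rep(1, nrow(ann))
    g <- matrix(0, PLATE_NROW, PLATE_NCOL)
    g[cbind(ann$row, ann$column)] <-
      base * viab * field[cbind(ann$row, ann$column)] * noise
    RawPlate(barcodes[i], g,
             metadata = list(model = ann$model[1], bio_rep = ann$bio_rep[1],
                             simulated = TRUE))
  })
  names(plates) <- barcodes
  plates
}

#' Serialize / restore a SyntheticTruth as JSON
#'
#' @param truth A [SyntheticTruth-class].
#' @param path File path; `writeTruth` writes, `readTruth` restores an
#'   identical object.
#' @return `readTruth` returns a [SyntheticTruth-class].
#' @export
writeTruth <- function(truth, path) {
  stopifnot(is(truth, "SyntheticTruth"))
  jsonlite::write_json(
    list(drugs = truthDrugs(truth), models = truthModels(truth),
         plate = plateParams(truth), seed = truth@seed),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SyntheticTruth",
      drugs = as.data.frame(x$drugs), models = as.data.frame(x$models),
      plate = as.list(x$plate), seed = as.integer(x$seed))
}
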