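## Loess-log normalization: robust (outlier-down-weighted) local regression
## of well signal on plate coordinates, multiplicative correction preserving
## the plate median, division by the negative-control centre, log2
## transform, least-squares replicate aggregation and plate-median
## centering.

#' Robust loess spatial-bias correction of one plate
#'
#' Fits a degree-1 locally weighted regression of well value on
#' `(row, column)` with tricube distance weights, followed by `iterations`
#' robustness passes that re-weight each well by the Tukey bisquare
#' function of its residual scaled by six times the median absolute
#' residual, so outlying wells are down-weighted before the final surface
#' is computed (`stats::loess` with `family = "symmetric"`).  The
#' correction is multiplicative and preserves the plate median:
#' `corrected = raw * median(fitted) / fitted`.
#'
#' @param plate A [RawPlate-class], or a 16 x 24 numeric matrix with `NA`
#'   at wells to ignore.
#' @param span Loess span, fraction of wells in each local neighbourhood,
#'   in (0, 1].
#' @param iterations Number of robustness passes (0 = plain loess).
#' @param fitMask Optional logical 16 x 24 matrix; `FALSE` wells are
#'   excluded from the fit (but still corrected by the predicted surface).
#'   By default all non-`NA` wells, controls included, enter the fit.
#' @return List with `corrected` (matrix), `fit` (a [LoessFit-class]).
#' @examples
#' g <- matrix(1000, 16, 24) * spatialField(gradientRow = 0.2)
#' cor <- correctSpatialBias(g)
#' range(cor$corrected)  # gradient removed
#' @export
correctSpatialBias <- function(plate, span = 0.7, iterations = 2,
                               fitMask = NULL) {
  g <- if (is(plate, "RawPlate")) plateGrid(plate) else as.matrix(plate)
  stopifnot(identical(dim(g), c(PLATE_NROW, PLATE_NCOL)))
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  iterations <- as.integer(iterations)
  use <- is.finite(g)
  if (!is.null(fitMask)) use <- use & fitMask
  if (sum(use) < 20) stop("fewer than 20 usable wells")
  if (all(g[use] == 0)) stop("degenerate plate: all usable wells are zero")

  df <- data.frame(y = g[use],
                   r = row(g)[use], c = col(g)[use])
  ## span must cover enough neighbours for a degree-1 local fit
  if (span * nrow(df) < 4) stop("span too small to cover any neighbourhood")
  fam <- if (iterations > 0) "symmetric" else "gaussian"
  fit <- loess(y ~ r + c, data = df, span = span, degree = 1, family = fam,
               normalize = FALSE,
               control = loess.control(surface = "direct",
                                       iterations = iterations + 1L))
  fitted <- matrix(NA_real_, PLATE_NROW, PLATE_NCOL)
  obs <- is.finite(g)
  fitted[obs] <- predict(fit, newdata = data.frame(r = row(g)[obs],
                                                   c = col(g)[obs]))
  if (any(!is.finite(fitted[obs])))
    stop("loess surface is undefined on this plate")
  ## wells outside the fitted set (e.g. kill controls excluded from the
  ## fit) take the surface only within its observed range: degree-1
  ## extrapolation far from the fitted region is unreliable
  outside <- obs & !use
  if (any(outside)) {
    rng <- range(fitted[use])
    fitted[outside] <- pmin(pmax(fitted[outside], rng[1]), rng[2])
  }
  pos <- fitted[use] > 0
  if (!any(pos)) stop("loess surface is not positive on this plate")
  if (!all(pos)) {
    nBad <- sum(!pos)
    if (nBad > 0.1 * sum(use))
      stop("loess surface non-positive on ", nBad, " wells")
    warning("loess surface floored on ", nBad, " well(s)")
    floorVal <- 0.05 * median(fitted[use][pos])
    fitted[use][fitted[use] <= 0] <- floorVal
    fitted[outside] <- pmax(fitted[outside], floorVal)
  }

  target <- median(fitted[use])
  corrected <- g * target / fitted

  ## final robustness weights (bisquare of residual / (6 * median |residual|))
  w <- matrix(NA_real_, PLATE_NROW, PLATE_NCOL)
  res <- df$y - fit$fitted
  s <- 6 * median(abs(res))
  bw <- if (s > 0) pmax(0, 1 - (res / s)^2)^2 else rep(1, length(res))
  w[use] <- if (iterations > 0) bw else 1
  dimnames(fitted) <- dimnames(w) <- list(plateRowNames(), seq_len(PLATE_NCOL))
  list(corrected = corrected,
       fit = new("LoessFit", fitted = fitted, weights = w,
                 span = span, iterations = iterations))
}

#' Normalize corrected values to the negative controls and log2-transform
#'
#' Per plate: centre = `center` (default median) of the corrected negative
#' controls; `ctrl_ratio = corrected / centre`; `loess_log =
#' log2(ctrl_ratio)`.  Non-positive corrected values are floored at
#' `epsFraction` of the control centre and flagged in the `floored`
#' column.  At least `minControls` negative controls are required per
#' plate (hard error naming the plate).
#'
#' @param screen A [ScreenData-class] with the `corrected` column filled
#'   (or raw values, see [normalizeScreen()]).
#' @param center `"median"` (robust, default) or `"mean"`.
#' @param epsFraction Floor for non-positive values, as a fraction of the
#'   control centre.
#' @param minControls Minimum negative-control wells per plate.
#' @param value Column to normalize (default `"corrected"`).
#' @return The screen with `ctrl_ratio`, `loess_log` and `floored` filled.
#' @export
normalizeToControls <- function(screen, center = c("median", "mean"),
                                epsFraction = 1e-3, minControls = 3L,
                                value = "corrected") {
  stopifnot(is(screen, "ScreenData"))
  center <- match.arg(center)
  cfun <- if (center == "median") median else mean
  w <- wells(screen)
  if (all(is.na(w[[value]]))) stop("column '", value, "' is empty; run correction first")
  for (bc in unique(w$barcode)) {
    i <- w$barcode == bc
    neg <- i & w$role == "negative_control"
    if (sum(neg) < minControls)
      stop("plate ", bc, " has ", sum(neg), " negative controls (need >= ",
           minControls, ")")
    m <- cfun(w[[value]][neg])
    if (!is.finite(m) || m <= 0)
      stop("plate ", bc, ": non-positive negative-control centre")
    v <- w[[value]][i]
    floor <- v <= 0
    v[floor] <- epsFraction * m
    w$ctrl_ratio[i] <- v / m
    w$loess_log[i] <- log2(v / m)
    w$floored[i] <- floor
  }
  lg <- screen@log
  lg$control_center <- center
  ScreenData(w, log = lg)
}

#' Centre loess-log values to the plate median
#'
#' Subtracts, per plate, the median loess-log value of the wells selected
#' by `over` (default: sample wells, so the drug-effect distribution is
#' centred without being pulled to the controls' zero).  The centred
#' values feed rank-product hit calling.
#'
#' @param screen A [ScreenData-class] with `loess_log` filled.
#' @param over `"sample"` or `"all"` wells for the median.
#' @return The screen with the `centered` column filled.
#' @export
centerToPlateMedian <- function(screen, over = c("sample", "all")) {
  stopifnot(is(screen, "ScreenData"))
  over <- match.arg(over)
  w <- wells(screen)
  for (bc in unique(w$barcode)) {
    i <- w$barcode == bc
    sel <- if (over == "sample") i & w$role == "sample" else i
    w$centered[i] <- w$loess_log[i] - median(w$loess_log[sel], na.rm = TRUE)
  }
  ScreenData(w, log = screen@log)
}

#' Full loess-log normalization pipeline
#'
#' Per plate: robust loess spatial correction (optional), normalization to
#' the negative controls, log2 transform; then plate-median centering.
#' The processing log records the per-plate negative-control CV before and
#' after correction.
#'
#' @param screen A [ScreenData-class] with raw values.
#' @param correct Apply the loess spatial correction (default `TRUE`;
#'   `FALSE` passes raw values through, for artifact-free data).
#' @param span,iterations See [correctSpatialBias()].
#' @param fitSamplesOnly Exclude all control wells from the surface fit
#'   (default `FALSE`: sample and negative-control wells enter).
#' @param fitPositiveControls Include the positive-control (killed) wells
#'   in the surface fit.  Default `FALSE`: their near-zero signal is
#'   biology, not spatial artifact, and a steep kill-control boundary
#'   would drag the local-linear surface non-positive at the plate edge.
#' @param center,epsFraction See [normalizeToControls()].
#' @return A normalized [ScreenData-class] (all value columns filled).
#' @examples
#' tr <- makeTruth(4, models = "2D7d", seed = 1)
#' lay <- screenLayouts(tr, bioReps = 1)
#' scr <- assembleScreen(simulateScreen(tr, lay, seed = 2), lay)
#' nrm <- normalizeScreen(scr)
#' summary(wells(nrm)$loess_log)
#' @export
normalizeScreen <- function(screen, correct = TRUE, span = 0.7,
                            iterations = 2, fitSamplesOnly = FALSE,
                            fitPositiveControls = FALSE,
                            center = "median", epsFraction = 1e-3) {
  stopifnot(is(screen, "ScreenData"))
  w <- wells(screen)
  ctrlCV <- list()
  for (bc in unique(w$barcode)) {
    i <- which(w$barcode == bc)
    g <- matrix(NA_real_, PLATE_NROW, PLATE_NCOL)
    g[cbind(w$row[i], w$column[i])] <- w$raw[i]
    if (correct) {
      fitRoles <- if (fitSamplesOnly) "sample"
        else if (fitPositiveControls) c("sample", "negative_control", "positive_control")
        else c("sample", "negative_control")
      mask <- matrix(FALSE, PLATE_NROW, PLATE_NCOL)
      use <- i[w$role[i] %in% fitRoles]
      mask[cbind(w$row[use], w$column[use])] <- TRUE
      cs <- correctSpatialBias(g, span = span, iterations = iterations,
                               fitMask = mask)
      w$corrected[i] <- cs$corrected[cbind(w$row[i], w$column[i])]
    } else {
      w$corrected[i] <- w$raw[i]
    }
    neg <- i[w$role[i] == "negative_control"]
    cv <- function(x) stats::sd(x) / mean(x)
    ctrlCV[[bc]] <- c(before = cv(w$raw[neg]), after = cv(w$corrected[neg]))
  }
  lg <- screen@log
  lg$control_cv <- ctrlCV
  lg$normalization <- list(correct = correct, span = span,
                           iterations = iterations,
                           fit_samples_only = fitSamplesOnly,
                           fit_positive_controls = fitPositiveControls,
                           control_center = center,
                           eps_fraction = epsFraction)
  out <- ScreenData(w, log = lg)
  out <- normalizeToControls(out, center = center, epsFraction = epsFraction)
  centerToPlateMedian(out)
}

#' Aggregate replicates by least squares
#'
#' Per culture model and library, fits the linear model
#' `loess_log ~ 0 + cell + replicate` where `cell` is the drug x
#' concentration combination and `replicate` a sum-to-zero biological
#' replicate (plate) offset, and returns the least-squares cell
#' coefficients.  On a balanced design this equals the replicate mean per
#' cell; with systematic replicate offsets the offsets are absorbed rather
#' than averaged into the estimates.  A replicate with no overlap with the
#' rest of the design is a rank-deficiency error naming the block.
#'
#' @param screen A normalized [ScreenData-class].
#' @param value Which value column to aggregate (`"loess_log"` default or
#'   `"centered"`).
#' @return `data.frame` with columns `drug, concentration_uM, model,
#'   library, estimate, n`.
#' @export
aggregateReplicates <- function(screen, value = "loess_log") {
  stopifnot(is(screen, "ScreenData"))
  w <- wells(screen)
  w <- w[w$role == "sample", ]
  if (all(is.na(w[[value]]))) stop("screen is not normalized yet")
  out <- list()
  for (m in unique(w$model)) for (lib in unique(w$library[w$model == m])) {
    s <- w[w$model == m & w$library == lib, ]
    cell <- factor(paste(s$drug, s$concentration_uM, sep = "@"))
    rep <- factor(s$bio_rep)
    y <- s[[value]]
    if (nlevels(rep) > 1) {
      fit <- lm(y ~ 0 + cell + stats::C(rep, stats::contr.sum))
    } else {
      fit <- lm(y ~ 0 + cell)
    }
    cf <- coef(fit)
    if (anyNA(cf))
      stop("rank-deficient design in block (model ", m, ", library ", lib, ")")
    cellIdx <- grep("^cell", names(cf))
    est <- cf[cellIdx]
    names(est) <- sub("^cell", "", names(est))
    parts <- strsplit(names(est), "@", fixed = TRUE)
    nrep <- table(cell)
    out[[paste(m, lib)]] <- data.frame(
      drug = vapply(parts, `[`, "", 1L),
      concentration_uM = as.numeric(vapply(parts, `[`, "", 2L)),
      model = m, library = lib, estimate = unname(est),
      n = as.integer(nrep[names(est)]))
  }
  agg <- do.call(rbind, out)
  agg <- agg[order(agg$model, agg$library, agg$drug, agg$concentration_uM), ]
  rownames(agg) <- NULL
  agg
}
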