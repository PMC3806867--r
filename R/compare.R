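## 3D-vs-2D hit calling: rank product across concentration origins with a
## permutation (or exactly enumerated) null, and the multiple linear
## regression that classifies culture models as drug-sensitized.

rpFromRanks <- function(ranks) exp(rowMeans(log(ranks)))

## all permutations of 1..n (n <= 7 kept small by the exhaustive guard)
allPerms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Rank-product hit calling against the 2D reference
#'
#' For one culture model versus the reference, computes the per-drug
#' response difference (model minus reference) of plate-median-centred
#' loess-log values at each concentration, treats each concentration as an
#' independent origin, ranks the drugs within each origin (direction
#' `"down"`: most sensitizing difference gets rank 1; ties share
#' mid-ranks) and combines the ranks into the rank product
#' `RP = (prod ranks)^(1/k)`.
#'
#' Significance comes from the permutation null: ranks are permuted
#' independently within each origin, RPs recomputed, and
#' `p = fraction of permutation RPs <= observed`,
#' `pfp = (mean per-permutation count of RPs <= observed) / (position in
#' the RP-sorted list)`, made monotone non-decreasing down the sorted
#' list.  When the number of distinct rank assignments `(n!)^k` does not
#' exceed `permutations` the null is enumerated exactly instead of
#' sampled (`exhaustive = "auto"`).
#'
#' @param values `data.frame` with columns `drug, concentration_uM, model`
#'   and a value column (default `"estimate"`), typically
#'   [aggregateReplicates()] on centred values.
#' @param model Culture model to compare.
#' @param reference Reference model (default `"2D7d"`).
#' @param direction `"down"`: hits are drugs consistently more suppressed
#'   in `model` than in the reference; `"up"`: the reverse.
#' @param permutations Number of null permutations (>= 100 for pfp use).
#' @param seed Integer seed for the sampled null.
#' @param exhaustive `"auto"` (enumerate when feasible), `"never"`,
#'   `"always"`.
#' @param value Name of the value column.
#' @return A [RankProductResult-class], rows sorted by RP.
#' @examples
#' v <- data.frame(drug = rep(c("a", "b", "c"), 2),
#'                 concentration_uM = rep(c(1, 10), each = 3),
#'                 model = "MG7d", estimate = c(-2, 0, 1, -1.5, 0.2, 0.9))
#' r <- data.frame(drug = rep(c("a", "b", "c"), 2),
#'                 concentration_uM = rep(c(1, 10), each = 3),
#'                 model = "2D7d", estimate = 0)
#' rankProduct(rbind(v, r), "MG7d", permutations = 50)
#' @export
rankProduct <- function(values, model, reference = "2D7d",
                        direction = c("down", "up"), permutations = 10000,
                        seed = 1L, exhaustive = c("auto", "never", "always"),
                        value = "estimate") {
  direction <- match.arg(direction)
  exhaustive <- match.arg(exhaustive)
  stopifnot(all(c("drug", "concentration_uM", "model", value) %in% names(values)))
  vm <- values[values$model == model, ]
  vr <- values[values$model == reference, ]
  if (!nrow(vm)) stop("model arm absent: ", model)
  if (!nrow(vr)) stop("reference arm absent: ", reference)

  origins <- sort(unique(vm$concentration_uM))
  if (!length(origins)) stop("no concentration origins")
  drugs <- sort(unique(vm$drug))
  diffs <- matrix(NA_real_, length(drugs), length(origins),
                  dimnames = list(drugs, origins))
  for (j in seq_along(origins)) {
    sm <- vm[vm$concentration_uM == origins[j], ]
    sr <- vr[vr$concentration_uM == origins[j], ]
    d <- sm[[value]][match(drugs, sm$drug)] - sr[[value]][match(drugs, sr$drug)]
    diffs[, j] <- d
  }
  keep <- rowSums(!is.finite(diffs)) == 0
  if (!all(keep)) {
    warning("drug(s) absent from an origin, dropped: ",
            paste(drugs[!keep], collapse = ", "))
    diffs <- diffs[keep, , drop = FALSE]
    drugs <- drugs[keep]
  }
  n <- length(drugs)
  k <- length(origins)
  if (n < 2) stop("need at least 2 drugs")

  sgn <- if (direction == "down") 1 else -1
  ranks <- apply(sgn * diffs, 2, rank)  # ties.method = "average" (mid-ranks)
  if (is.null(dim(ranks))) ranks <- matrix(ranks, n, k)
  RP <- rpFromRanks(ranks)

  useExact <- switch(exhaustive,
    always = TRUE, never = FALSE,
    auto = {
      lognp <- k * lgamma(n + 1)
      lognp <= log(permutations)
    })

  if (useExact) {
    P <- allPerms(n)                # n! x n
    B <- nrow(P)^k
    ## enumerate all k-tuples of within-origin permutations
    idx <- rep(1L, k)
    permRP <- matrix(NA_real_, n, B)
    b <- 0L
    repeat {
      b <- b + 1L
      permRP[, b] <- rpFromRanks(t(P[idx, , drop = FALSE]))
      j <- k
      while (j >= 1) {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= nrow(P)) break
        idx[j] <- 1L
        j <- j - 1L
      }
      if (j < 1) break
    }
    nPerm <- B
  } else {
    set.seed(as.integer(seed))
    nPerm <- as.integer(permutations)
    permRP <- matrix(NA_real_, n, nPerm)
    for (b in seq_len(nPerm)) {
      pr <- vapply(seq_len(k), function(j) sample.int(n), integer(n))
      permRP[, b] <- rpFromRanks(matrix(pr, n, k))
    }
  }

  allPerm <- sort(as.vector(permRP))
  ord <- order(RP)
  ## counts of permutation RPs <= each observed RP (with fp slack for exact ties)
  cnt <- findInterval(RP[ord] * (1 + 1e-12), allPerm)
  position <- seq_len(n)
  p <- cnt / (nPerm * n)
  expFP <- cnt / nPerm
  pfp <- cummax(expFP / position)
  ## expected RP at each sorted position under the null
  sortedPerm <- apply(permRP, 2, sort)
  expectedRP <- rowMeans(matrix(sortedPerm, n, nPerm))

  tab <- data.frame(drug = drugs[ord], RP = RP[ord], position = position,
                    expectedRP = expectedRP, p = p, pfp = pfp)
  rk <- as.data.frame(ranks[ord, , drop = FALSE])
  names(rk) <- paste0("rank_", origins)
  tab <- cbind(tab, rk)
  rownames(tab) <- NULL
  new("RankProductResult", table = tab,
      comparison = paste(model, "vs", reference), direction = direction,
      origins = origins, permutations = as.numeric(nPerm),
      exhaustive = useExact, seed = as.integer(seed))
}

#' Multiple linear regression of normalized response on culture model
#'
#' Least-squares fit of loess-log normalized drug response on culture
#' model (categorical, `reference` as the reference level) with the drug x
#' concentration combinations as blocking covariates, so each model
#' coefficient is the pairwise-matched mean response shift versus the
#' reference in log2 units; each concentration's observations enter as
#' separately blocked strata (the concentration-wise fit).  With
#' `mode = "per-concentration"`, separate fits per concentration (drug
#' blocking only) are returned instead, one set of model terms per dose.
#'
#' @param data A normalized [ScreenData-class], or a long `data.frame`
#'   with columns `drug, concentration_uM, model` and the value column.
#' @param reference Reference model (default `"2D7d"`).
#' @param library Restrict to one library (e.g. `"lib80"`); `NULL` = all
#'   rows (fits are normally run per library).
#' @param mode `"blocked"` (single fit, default) or `"per-concentration"`.
#' @param value Value column (default `"loess_log"`).
#' @return An [MLRResult-class]; the table has one row per non-reference
#'   model (and per concentration for `"per-concentration"`).
#' @seealso [classifySensitized()]
#' @export
fitMLR <- function(data, reference = "2D7d", library = NULL,
                   mode = c("blocked", "per-concentration"),
                   value = "loess_log") {
  mode <- match.arg(mode)
  d <- if (is(data, "ScreenData")) {
    w <- wells(data)
    w[w$role == "sample", ]
  } else data
  stopifnot(all(c("drug", "concentration_uM", "model", value) %in% names(d)))
  if (!is.null(library)) d <- d[d$library == library, ]
  d <- d[is.finite(d[[value]]), ]
  if (!reference %in% d$model) stop("reference arm absent: ", reference)
  if (length(unique(d$model)) < 2) stop("need at least 2 culture models")

  oneFit <- function(s, strata, label = NA_real_) {
    mod <- stats::relevel(factor(s$model), ref = reference)
    fit <- lm(s[[value]] ~ mod + strata)
    sm <- summary(fit)$coefficients
    rows <- grep("^mod", rownames(sm))
    terms <- sub("^mod", "", rownames(sm)[rows])
    data.frame(term = terms,
               concentration_uM = label,
               estimate = sm[rows, 1], se = sm[rows, 2],
               t = sm[rows, 1] / sm[rows, 2],
               p = sm[rows, 4],
               n = as.integer(table(s$model)[terms]))
  }
  tab <- if (mode == "blocked") {
    oneFit(d, factor(paste(d$drug, d$concentration_uM, sep = "@")))
  } else {
    do.call(rbind, lapply(sort(unique(d$concentration_uM)), function(cc) {
      s <- d[d$concentration_uM == cc, ]
      oneFit(s, factor(s$drug), label = cc)
    }))
  }
  rownames(tab) <- NULL
  new("MLRResult", table = tab, reference = reference, mode = mode,
      library = if (is.null(library)) "all" else library)
}

#' Classify culture models from MLR estimates
#'
#' A model is `sensitized` when its estimate is negative with p below
#' `alpha` (lower viability under drug than the reference), `resistant`
#' when positive and significant, otherwise `indistinguishable`.
#'
#' @param results An [MLRResult-class] or its table.
#' @param alpha Significance level (default 0.05).
#' @return `data.frame` with `term, estimate, p, label`.
#' @examples
#' classifySensitized(data.frame(term = "MG7d", estimate = -0.1, p = 0.03))
#' @export
classifySensitized <- function(results, alpha = 0.05) {
  t <- if (is(results, "MLRResult")) resultTable(results) else results
  if (!nrow(t)) stop("empty result table")
  label <- ifelse(t$p < alpha & t$estimate < 0, "sensitized",
           ifelse(t$p < alpha & t$estimate > 0, "resistant",
                  "indistinguishable"))
  data.frame(term = t$term, estimate = t$estimate, p = t$p, label = label)
}
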