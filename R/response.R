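## Dose-response summaries: percent-of-control and percent-of-lowest
## profiles, the >30% activity filter, concentration-binned cross-model
## averages with t-tests, and growth rates.

#' Express aggregated responses as dose-response profiles
#'
#' Converts aggregated loess-log estimates to the linear scale
#' (`pctControl = 100 * 2^estimate`, percent of the negative controls) and
#' expresses each drug's responses as the percentage of its
#' lowest-concentration response: the baseline is the response at the
#' lowest concentration (`lib80`) or the mean of the two lowest (`lib22`,
#' whose dose series starts lower).  By construction the lowest
#' concentration (or the mean of the two lowest) reads 100%.
#'
#' @param aggregated `data.frame` from [aggregateReplicates()] (columns
#'   `drug, concentration_uM, model, library, estimate`), or any table
#'   with those columns; `estimate` on the log2 scale unless
#'   `logScale = FALSE`, in which case it must already be a linear
#'   (anti-logged) response.
#' @param logScale Whether `estimate` is log2 (default) or linear.
#' @return `data.frame` with columns `drug, model, library,
#'   concentration_uM, pctControl, percent` (percent of lowest), sorted by
#'   drug, model and ascending concentration.
#' @examples
#' agg <- data.frame(drug = "d1", model = "2D7d", library = "lib80",
#'                   concentration_uM = c(0.02, 0.2, 2, 20),
#'                   estimate = log2(c(1, 1, 0.8, 0.5)))
#' percentOfLowest(agg)$percent  # 100 100 80 50
#' @export
percentOfLowest <- function(aggregated, logScale = TRUE) {
  need <- c("drug", "concentration_uM", "model", "library", "estimate")
  stopifnot(all(need %in% names(aggregated)))
  a <- aggregated
  a$linear <- if (logScale) 2^a$estimate else a$estimate
  a <- a[order(a$drug, a$model, a$library, a$concentration_uM), ]
  key <- paste(a$drug, a$model, a$library)
  out <- lapply(split(a, key), function(s) {
    if (nrow(s) < 2) stop("drug ", s$drug[1], " has fewer than 2 concentrations")
    nBase <- if (s$library[1] == "lib22") 2L else 1L
    baseline <- mean(s$linear[seq_len(nBase)])
    if (!is.finite(baseline) || baseline <= 0)
      stop("non-positive baseline for drug ", s$drug[1], " (", s$model[1], ")")
    data.frame(drug = s$drug, model = s$model, library = s$library,
               concentration_uM = s$concentration_uM,
               pctControl = 100 * s$linear,
               percent = 100 * s$linear / baseline)
  })
  prof <- do.call(rbind, out)
  prof <- prof[order(prof$drug, prof$model, prof$concentration_uM), ]
  rownames(prof) <- NULL
  prof
}

#' Select active drugs (>30% viability response filter)
#'
#' A drug is active if, in any culture model at any concentration, it
#' reduced viability by strictly more than `threshold` percent relative to
#' the negative controls, i.e. its minimum percent-of-control response is
#' strictly below `100 - threshold`.  A response of exactly
#' `100 - threshold` percent is not active.
#'
#' @param profiles Profile `data.frame` from [percentOfLowest()].
#' @param threshold Response threshold in percent (default 30).
#' @param basis `"control"` (default: percent of negative controls, the
#'   scale the filter is defined on) or `"lowest"` (percent of lowest
#'   concentration).
#' @param models Models every drug must span; drugs missing an arm are
#'   excluded with a warning (`strict = TRUE` turns this into an error).
#' @param strict Error on drugs missing a model arm.
#' @return Character vector of active drug ids (sorted).  The full
#'   per-drug minima are attached as attribute `"details"`.
#' @export
selectActiveDrugs <- function(profiles, threshold = 30,
                              basis = c("control", "lowest"),
                              models = unique(profiles$model),
                              strict = FALSE) {
  basis <- match.arg(basis)
  v <- if (basis == "control") profiles$pctControl else profiles$percent
  byDrug <- split(data.frame(v = v, model = profiles$model), profiles$drug)
  incomplete <- names(byDrug)[vapply(byDrug, function(s)
    !all(models %in% s$model), TRUE)]
  if (length(incomplete)) {
    msg <- paste("drug(s) missing a model arm, excluded:",
                 paste(incomplete, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
    byDrug <- byDrug[setdiff(names(byDrug), incomplete)]
  }
  mins <- vapply(byDrug, function(s) min(s$v), 0)
  active <- sort(names(mins)[mins < (100 - threshold)])
  details <- data.frame(drug = names(mins), min_response = unname(mins),
                        active = names(mins) %in% active)
  details <- details[order(details$drug), ]
  rownames(details) <- NULL
  attr(active, "details") <- details
  active
}

starCode <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", ""))))
}

#' Concentration-binned cross-model averages with t-tests versus 2D
#'
#' Assigns each drug's three highest tested concentrations to the
#' high/medium/low bins by rank (highest dose = `high`), averages the
#' percent-of-lowest responses across drugs per model per bin and across
#' the three bins, and tests each non-reference model against the
#' reference with a two-sided t-test over the per-drug values (Welch by
#' default).  Significance stars: `*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001.  A bin with fewer than 2 drugs has an undefined
#' p-value, reported as `NA`.
#'
#' @param profiles Profile `data.frame` from [percentOfLowest()].
#' @param drugs Drugs to include (e.g. the active set); default all.
#' @param reference Reference model (default `"2D7d"`).
#' @param varEqual Pooled-variance t-test instead of Welch.
#' @param value Response scale to average: `"percent"` (of lowest
#'   concentration, default) or `"pctControl"` (of negative controls).
#' @return `data.frame` with columns `model, bin, mean, n, p, stars`; bins
#'   are `high`, `medium`, `low` and `across`.
#' @export
averageByConcentrationBin <- function(profiles, drugs = unique(profiles$drug),
                                      reference = "2D7d", varEqual = FALSE,
                                      value = c("percent", "pctControl")) {
  value <- match.arg(value)
  profiles$percent <- profiles[[value]]
  p <- profiles[profiles$drug %in% drugs, ]
  if (!nrow(p)) stop("no drugs selected")
  if (!reference %in% p$model) stop("reference model absent: ", reference)
  ## three highest concentrations per drug (shared dose series across models)
  top3 <- lapply(split(p, paste(p$drug, p$model)), function(s) {
    s <- s[order(-s$concentration_uM), ]
    k <- min(3L, nrow(s))
    data.frame(drug = s$drug[seq_len(k)], model = s$model[seq_len(k)],
               bin = c("high", "medium", "low")[seq_len(k)],
               percent = s$percent[seq_len(k)])
  })
  top3 <- do.call(rbind, top3)
  across <- stats::aggregate(percent ~ drug + model, top3, mean)
  across$bin <- "across"
  top3 <- rbind(top3[, c("drug", "model", "bin", "percent")], across)

  bins <- c("high", "medium", "low", "across")
  out <- list()
  for (m in unique(top3$model)) for (b in bins) {
    v <- top3$percent[top3$model == m & top3$bin == b]
    ref <- top3$percent[top3$model == reference & top3$bin == b]
    pval <- if (m == reference || length(v) < 2 || length(ref) < 2) NA_real_
      else tryCatch(t.test(v, ref, var.equal = varEqual)$p.value,
                    error = function(e) {
                      # degenerate spread: identical groups are the null
                      if (isTRUE(all.equal(mean(v), mean(ref)))) 1 else NA_real_
                    })
    out[[paste(m, b)]] <- data.frame(model = m, bin = b, mean = mean(v),
                                     n = length(v), p = pval,
                                     stars = starCode(pval))
  }
  res <- do.call(rbind, out)
  res$bin <- factor(res$bin, levels = bins)
  res <- res[order(res$model, res$bin), ]
  rownames(res) <- NULL
  res
}

#' Growth rate from endpoint viability reads
#'
#' Rate = endpoint luminescence divided by the number of cells plated;
#' optionally expressed as percent of a reference (2D) rate.
#'
#' @param endpoint Endpoint signal(s), RLU.
#' @param cellsPlated Cells plated per well (> 0).
#' @param reference Optional reference rate (RLU per cell); when given,
#'   `percentOf2D` is returned.
#' @return `data.frame` with `rate` and (if `reference` given)
#'   `percentOf2D`.
#' @examples
#' growthRate(1860, 1000, reference = 1)  # 186% of 2D
#' @export
growthRate <- function(endpoint, cellsPlated, reference = NULL) {
  if (any(endpoint <= 0) || any(cellsPlated <= 0))
    stop("endpoint and cellsPlated must be positive")
  rate <- endpoint / cellsPlated
  out <- data.frame(rate = rate)
  if (!is.null(reference)) {
    if (any(reference <= 0)) stop("reference rate must be positive")
    out$percentOf2D <- 100 * rate / reference
  }
  out
}
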