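#' Relative expression by the 2^-ddCt method
#'
#' Per sample: \eqn{\Delta Ct = \overline{Ct}_{target} -
#' \overline{Ct}_{reference}} (replicate Ct values averaged before
#' differencing), \eqn{\Delta\Delta Ct = \Delta Ct - \Delta Ct_{calibrator}}
#' and \eqn{RQ = 2^{-\Delta\Delta Ct}}; the calibrator sample has RQ 1 by
#' construction.
#'
#' @param ct data.frame with columns \code{sample}, \code{gene},
#'   \code{ct} (one row per replicate well).
#' @param calibrator sample id whose expression defines RQ = 1 (e.g. the
#'   untreated control).
#' @param target,reference gene names in \code{ct$gene}; with exactly two
#'   genes and \code{reference} given, \code{target} defaults to the other.
#' @param perReplicate also return per-replicate RQ values (pairing
#'   replicate i of target with replicate i of reference) for SD
#'   propagation.
#' @return data.frame per sample: \code{sample}, \code{d_ct},
#'   \code{dd_ct}, \code{rq}; with \code{perReplicate = TRUE} a list with
#'   elements \code{summary} and \code{replicates}.
#' @examples
#' tab <- simCtTable(trueRq = c(Control = 1, Heat = 8), seed = 3)
#' ddct(tab, calibrator = "Control",
#'      target = "target", reference = "reference")
#' @export
ddct <- function(ct, calibrator, target = "target",
                 reference = "reference", perReplicate = FALSE) {
  need <- c("sample", "gene", "ct")
  if (!all(need %in% colnames(ct)))
    stop("ct table needs columns: ", paste(need, collapse = ", "))
  if (!reference %in% ct$gene) stop("reference gene not found in table")
  if (!target %in% ct$gene) stop("target gene not found in table")
  if (!calibrator %in% ct$sample) stop("calibrator sample not found")
  samples <- unique(ct$sample)
  mct <- function(s, g) {
    v <- ct$ct[ct$sample == s & ct$gene == g]
    if (!length(v)) stop("no Ct for sample ", s, ", gene ", g)
    mean(v)
  }
  dct <- vapply(samples, function(s) mct(s, target) - mct(s, reference),
                numeric(1))
  ddc <- dct - dct[samples == calibrator]
  out <- data.frame(sample = samples, d_ct = dct, dd_ct = ddc,
                    rq = 2^(-ddc), row.names = NULL)
  if (!perReplicate) return(out)
  reps <- do.call(rbind, lapply(samples, function(s) {
    tv <- ct$ct[ct$sample == s & ct$gene == target]
    rv <- ct$ct[ct$sample == s & ct$gene == reference]
    k <- min(length(tv), length(rv))
    data.frame(sample = s, replicate = seq_len(k),
               rq = 2^(-((tv[seq_len(k)] - rv[seq_len(k)]) -
                           out$dd_ct[out$sample == calibrator] -
                           out$d_ct[out$sample == calibrator])))
  }))
  list(summary = out, replicates = reps)
}

#' Heat injury index
#'
#' \deqn{HII(\%) = \frac{\sum_l (\mbox{plants at level } l) \times l
#'   \times 100}{(\mbox{highest level}) \times (\mbox{total plants})}}
#' over ordinal injury levels 0..\code{maxLevel} (default grading: 0 no
#' leaf curling, 1 up to half the leaves curled, 2 more than half, 3 the
#' whole plant wilted). 0 when every plant is at level 0, 100 when every
#' plant is at the highest level.
#'
#' @param counts nonnegative integer vector of plants per level, ordered
#'   level 0 first (length \code{maxLevel + 1}).
#' @param maxLevel highest level rank (default inferred,
#'   \code{length(counts) - 1}).
#' @return percentage in \[0, 100\].
#' @examples
#' heatInjuryIndex(c(0, 0, 0, 30))       # 100
#' heatInjuryIndex(c(0, 5, 0, 5))        # 66.67
#' @export
heatInjuryIndex <- function(counts, maxLevel = length(counts) - 1) {
  if (maxLevel < 1) stop("maxLevel must be >= 1")
  if (length(counts) != maxLevel + 1)
    stop("counts must cover levels 0..maxLevel")
  if (any(counts < 0)) stop("negative plant counts")
  total <- sum(counts)
  if (total == 0) stop("no plants tallied")
  sum(counts * (0:maxLevel)) * 100 / (maxLevel * total)
}

#' Replicate summary with t-test significance stars
#'
#' Mean +/- sample SD per group with a two-sided two-sample Student's
#' t-test (equal variance by default; \code{welch = TRUE} for Welch) and
#' the usual star coding: \code{**} if p < 0.01, \code{*} if p < 0.05.
#' Two groups that are both constant get p = 1 when their means are equal
#' and p = 0 otherwise.
#'
#' @param valuesA,valuesB numeric replicate measurements (>= 2 each).
#' @param alphaLevels thresholds for one and two stars
#'   (default \code{c(0.05, 0.01)}).
#' @param welch use Welch's unequal-variance t-test.
#' @return one-row data.frame: \code{mean_a}, \code{sd_a}, \code{mean_b},
#'   \code{sd_b}, \code{p}, \code{stars}.
#' @examples
#' replicateSummary(c(1, 1.1, 0.9), c(2, 2.1, 1.9))
#' @export
replicateSummary <- function(valuesA, valuesB,
                             alphaLevels = c(0.05, 0.01), welch = FALSE) {
  if (length(valuesA) < 2 || length(valuesB) < 2)
    stop("at least 2 replicates per group")
  if (sd(valuesA) == 0 && sd(valuesB) == 0) {
    p <- if (mean(valuesA) == mean(valuesB)) 1 else 0
  } else {
    p <- t.test(valuesA, valuesB, var.equal = !welch)$p.value
  }
  stars <- if (p < alphaLevels[2]) "**" else
    if (p < alphaLevels[1]) "*" else ""
  data.frame(mean_a = mean(valuesA), sd_a = sd(valuesA),
             mean_b = mean(valuesB), sd_b = sd(valuesB),
             p = p, stars = stars)
}
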