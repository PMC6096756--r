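# Group contrasts and effect sizes.

#' Cohen's d with pooled standard deviation
#'
#' `(mean_a - mean_b) / s_pooled`, with the pooled SD weighted by n - 1.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return d (scalar).
#' @examples
#' cohensD(c(1, 2, 3), c(3, 4, 5))  # -2
#' @export
cohensD <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 values")
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  if (sp == 0) stop("zero pooled SD")
  (mean(a) - mean(b)) / sp
}

#' Partial eta squared
#'
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param ssEffect,ssError sums of squares (>= 0, not both 0).
#' @return effect size in [0, 1].
#' @export
partialEtaSquared <- function(ssEffect, ssError) {
  if (ssEffect < 0 || ssError < 0) stop("sums of squares must be >= 0")
  if (ssEffect + ssError == 0) stop("both sums of squares are zero")
  ssEffect / (ssEffect + ssError)
}

#' Per-cell Welch contrasts with Holm correction
#'
#' For each stimulus-by-level cell of a tidy measurement table, a Welch
#' two-sample contrast of the noise condition against sham (group-specific
#' variances, Welch-Satterthwaite df), with Holm correction across the
#' requested family of cells. This is a deliberately simplified contract
#' standing in for full mixed-model machinery.
#'
#' @param table data.frame with columns `subject`, `condition`
#'   (`"sham"`/`"noise"`), `cell` (a stimulus-by-level label), `value`.
#' @param conf.level confidence level for the interval (default 0.95).
#' @return data.frame, one row per cell: `cell`, `diff` (noise - sham),
#'   `ciLow`, `ciHigh`, `t`, `df`, `p`, `pHolm`, `cohensD`.
#' @export
welchContrast <- function(table, conf.level = 0.95) {
  stopifnot(all(c("subject", "condition", "cell", "value") %in%
                names(table)))
  cells <- unique(table$cell)
  rows <- lapply(cells, function(cl) {
    d <- table[table$cell == cl, ]
    a <- d$value[d$condition == "noise"]
    b <- d$value[d$condition == "sham"]
    if (length(a) < 2 || length(b) < 2)
      stop("singleton group in cell ", cl)
    tt <- t.test(a, b, var.equal = FALSE, conf.level = conf.level)
    data.frame(cell = cl, diff = mean(a) - mean(b),
               ciLow = tt$conf.int[1], ciHigh = tt$conf.int[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, cohensD = cohensD(a, b))
  })
  out <- do.call(rbind, rows)
  out$pHolm <- p.adjust(out$p, method = "holm")
  out[, c("cell", "diff", "ciLow", "ciHigh", "t", "df", "p", "pHolm",
          "cohensD")]
}
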