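#' @include utils.R
NULL

#' Simulate marker count fields
#'
#' Emulates counting immunoreactive cells in randomly selected visual
#' fields: per field, the number of neurons (MAP2+) is Poisson around
#' `cellsPerField` and the number of marker-positive neurons is binomial at
#' the true fraction. The default of 15 fields corresponds to five fields
#' per coverslip from three independent differentiations.
#'
#' @param trueFractions Named numeric vector, marker -> true positive
#'   fraction in \[0, 1\].
#' @param cellsPerField Mean MAP2+ cells per field.
#' @param nFields Fields per marker and time point.
#' @param timepoints Time-point labels (days in vitro).
#' @param seed Seed.
#' @return `data.frame(marker, timepoint, field, n_marker, n_map2)`.
#' @export
simulateCountFields <- function(trueFractions, cellsPerField = 52,
                                nFields = 15, timepoints = c(35, 49),
                                seed = NULL) {
  stopifnot(length(trueFractions) >= 1, !is.null(names(trueFractions)),
            all(trueFractions >= 0 & trueFractions <= 1))
  withSeed(seed, {
    rows <- expand.grid(field = seq_len(nFields), timepoint = timepoints,
                        marker = names(trueFractions),
                        stringsAsFactors = FALSE)
    nMap2 <- pmax(1L, stats::rpois(nrow(rows), cellsPerField))
    nMark <- stats::rbinom(nrow(rows), nMap2,
                           trueFractions[rows$marker])
    data.frame(marker = rows$marker, timepoint = rows$timepoint,
               field = rows$field, n_marker = nMark, n_map2 = nMap2,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a qPCR Ct table with technical triplicates
#'
#' `Ct_gene = hkCt - log2(level) + noise`, so a gene expressed at the level
#' of the housekeeping genes has the same Ct and a gene at relative level
#' `2^-5` sits 5 cycles later. Undetected genes (`NA` or 0 level) are
#' emitted as `NA` triplicates.
#'
#' @param trueExpr Named numeric vector, gene -> relative expression level
#'   (relative to housekeeping); `NA` or 0 marks an undetected gene.
#' @param hkCt Housekeeping-gene Ct value.
#' @param triplicateSd Technical-replicate noise sd, cycles.
#' @param hkGenes Housekeeping gene names added to the table.
#' @param timepoint Time-point label stored in the table.
#' @param nRep Technical replicates per gene.
#' @param seed Seed.
#' @return `data.frame(timepoint, gene, replicate, ct)`.
#' @export
simulateCtTable <- function(trueExpr, hkCt = 20, triplicateSd = 0.1,
                            hkGenes = c("ACTB", "GAPDH"), timepoint = 35,
                            nRep = 3, seed = NULL) {
  stopifnot(length(trueExpr) >= 1, !is.null(names(trueExpr)))
  withSeed(seed, {
    genes <- c(hkGenes, names(trueExpr))
    levels <- c(rep(1, length(hkGenes)), unname(trueExpr))
    out <- do.call(rbind, lapply(seq_along(genes), function(i) {
      ct <- if (is.na(levels[i]) || levels[i] <= 0) rep(NA_real_, nRep)
            else hkCt - log2(levels[i]) +
              stats::rnorm(nRep, 0, triplicateSd)
      data.frame(timepoint = timepoint, gene = genes[i],
                 replicate = seq_len(nRep), ct = ct,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}
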