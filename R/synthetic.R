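# Synthetic UMI-count generator: negative-binomial counts with cell-type
# marker structure, i.i.d. dropout zeros, and optional multiplicative
# per-gene batch factors. Used as the desk-scale benchmark for training,
# transfer, rejection and metric code.

#' Simulation configuration
#'
#' Defaults define the benchmark used throughout the package: 5 cell types
#' of 300 cells each over 1,024 genes (a 32x32 gene image with no padding),
#' 20 disjoint marker genes per type with a 5-fold mean increase, moderate
#' negative-binomial overdispersion, and 30\% dropout zeros.
#'
#' @param nGenes total genes.
#' @param cellTypeSizes named integer vector, cells per type.
#' @param markersPerType disjoint marker genes per type.
#' @param baselineMean negative-binomial mean of non-marker genes.
#' @param markerFold mean multiplier of a type's markers in its own cells
#'   (1 = no signal).
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed; variance is \code{mu + mu^2/dispersion}).
#' @param dropoutRate probability of zeroing each count independently.
#' @param batchShift sd of the per-gene log-normal batch factor used by
#'   [generateBatchPair()] (0 = identical batches).
#' @param seed integer seed.
#' @return a \code{SimConfig} list.
#' @export
simConfig <- function(nGenes = 1024L,
                      cellTypeSizes = c(alpha = 300L, beta = 300L,
                                        delta = 300L, gamma = 300L,
                                        ductal = 300L),
                      markersPerType = 20L,
                      baselineMean = 2,
                      markerFold = 5,
                      dispersion = 2,
                      dropoutRate = 0.3,
                      batchShift = 0,
                      seed = 1L) {
  if (is.null(names(cellTypeSizes)) || anyDuplicated(names(cellTypeSizes)))
    stop("cellTypeSizes must be a named vector with unique type names")
  nTypes <- length(cellTypeSizes)
  if (markersPerType * nTypes > nGenes)
    stop("infeasible marker allocation: ", nTypes, " types x ",
         markersPerType, " markers exceed ", nGenes, " genes")
  assertScalarNumber(baselineMean, "baselineMean", 1e-12)
  assertScalarNumber(markerFold, "markerFold", 1)
  assertScalarNumber(dispersion, "dispersion", 1e-12)
  assertScalarNumber(dropoutRate, "dropoutRate", 0, 1 - 1e-12)
  assertScalarNumber(batchShift, "batchShift", 0)
  structure(list(nGenes = as.integer(nGenes),
                 cellTypeSizes = cellTypeSizes,
                 markersPerType = as.integer(markersPerType),
                 baselineMean = baselineMean, markerFold = markerFold,
                 dispersion = dispersion, dropoutRate = dropoutRate,
                 batchShift = batchShift, seed = as.integer(seed)),
            class = "SimConfig")
}

# Per-type mean vectors; markers are disjoint leading blocks of the gene
# list so every gene's role is reproducible from the config alone.
.simMeans <- function(cfg) {
  types <- names(cfg$cellTypeSizes)
  markers <- lapply(seq_along(types), function(t)
    (t - 1L) * cfg$markersPerType + seq_len(cfg$markersPerType))
  names(markers) <- types
  mus <- lapply(types, function(t) {
    mu <- rep(cfg$baselineMean, cfg$nGenes)
    mu[markers[[t]]] <- cfg$baselineMean * cfg$markerFold
    mu
  })
  names(mus) <- types
  list(markers = markers, mus = mus)
}

.simDraw <- function(cfg, geneFactors = NULL, sizes = NULL, idPrefix = "cell") {
  sizes <- sizes %||% cfg$cellTypeSizes
  mm <- .simMeans(cfg)
  types <- names(sizes)
  blocks <- lapply(types, function(t) {
    nc <- sizes[[t]]
    mu <- mm$mus[[t]]
    if (!is.null(geneFactors)) mu <- mu * geneFactors
    matrix(stats::rnbinom(nc * cfg$nGenes, size = cfg$dispersion,
                          mu = rep(mu, each = nc)),
           nrow = nc)
  })
  counts <- do.call(rbind, blocks)
  if (cfg$dropoutRate > 0)
    counts[stats::runif(length(counts)) < cfg$dropoutRate] <- 0
  labels <- rep(types, times = as.integer(sizes))
  n <- nrow(counts)
  dimnames(counts) <- list(sprintf("%s_%05d", idPrefix, seq_len(n)),
                           sprintf("gene_%05d", seq_len(cfg$nGenes)))
  list(counts = counts, labels = labels, markers = mm$markers)
}

#' Generate a labeled synthetic count matrix
#'
#' Counts are negative-binomial with mean \code{baselineMean}
#' (\code{baselineMean * markerFold} for a cell's own-type markers) and the
#' configured dispersion; zeros are then injected i.i.d. at
#' \code{dropoutRate}. Fully reproducible from the config seed.
#'
#' @param cfg a [simConfig()].
#' @return list with \code{matrix} (raw-count [ExpressionMatrix-class]),
#'   \code{labels} (character vector, one per cell), and \code{markers}
#'   (per-type marker gene indices).
#' @export
generateDataset <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  withSeed(deriveSeed(cfg$seed, "simulate"), {
    d <- .simDraw(cfg)
    list(matrix = ExpressionMatrix(d$counts, normalized = FALSE),
         labels = d$labels, markers = d$markers)
  })
}

#' Generate two batches with a technical shift
#'
#' Both batches share the biological structure of \code{cfg}; the second
#' batch multiplies every gene's mean by a log-normal factor with log-sd
#' \code{batchShift}, emulating platform biases uncorrelated with cell
#' type. Optionally one type can be withheld from batch 1 (the training
#' batch) while kept in batch 2, the protocol for open-set rejection
#' experiments.
#'
#' @param cfg a [simConfig()].
#' @param batchShift overrides \code{cfg$batchShift} when given.
#' @param holdOutType type name to omit from batch 1 (default none).
#' @return list with \code{batch1} and \code{batch2}, each as returned by
#'   [generateDataset()].
#' @export
generateBatchPair <- function(cfg, batchShift = NULL, holdOutType = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  shift <- batchShift %||% cfg$batchShift
  assertScalarNumber(shift, "batchShift", 0)
  sizes1 <- cfg$cellTypeSizes
  if (!is.null(holdOutType)) {
    if (!holdOutType %in% names(sizes1))
      stop("holdOutType '", holdOutType, "' is not a simulated type")
    sizes1 <- sizes1[setdiff(names(sizes1), holdOutType)]
  }
  withSeed(deriveSeed(cfg$seed, "batch"), {
    d1 <- .simDraw(cfg, sizes = sizes1, idPrefix = "b1")
    factors <- if (shift > 0) exp(stats::rnorm(cfg$nGenes, 0, shift))
               else rep(1, cfg$nGenes)
    d2 <- .simDraw(cfg, geneFactors = factors, idPrefix = "b2")
    list(batch1 = list(matrix = ExpressionMatrix(d1$counts),
                       labels = d1$labels, markers = d1$markers),
         batch2 = list(matrix = ExpressionMatrix(d2$counts),
                       labels = d2$labels, markers = d2$markers),
         geneFactors = factors)
  })
}
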