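# Shared fixtures. Expensive objects (a small trained model) are built once
# per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

# A small but non-trivial simulated benchmark: 3 types, 64 genes (8x8
# image, no padding), strong markers.
tinySimConfig <- function(seed = 11L, ...) {
  defaults <- list(nGenes = 64L,
                   cellTypeSizes = c(acinar = 60L, beta = 60L,
                                     ductal = 60L),
                   markersPerType = 6L, baselineMean = 2, markerFold = 6,
                   dispersion = 2, dropoutRate = 0.2, seed = seed)
  do.call(simConfig, utils::modifyList(defaults, list(...)))
}

# Down-scaled network that still exercises both conv branches and PCA.
tinyModelConfig <- function(seed = 5L, ...) {
  defaults <- list(convBranches = list(
                     list(filters = 8L, kernel = c(2L, 2L),
                          pools = list(c(2L, 2L), c(2L, 2L)),
                          dropout = 0.25),
                     list(filters = 6L, kernel = c(3L, 3L),
                          pools = list(c(2L, 2L)), dropout = 0.25)),
                   pcaComponents = 10L, hiddenSizes = c(32L, 16L),
                   learningRate = 0.01, epochs = 40L, batchSize = 16L,
                   seed = seed)
  do.call(modelConfig, utils::modifyList(defaults, list(...)))
}

# Normalized train/test split of the tiny benchmark plus a trained model;
# cached because several test files reuse it.
tinyTrainedFixture <- function() {
  if (!is.null(.fixtureCache$tiny)) return(.fixtureCache$tiny)
  d <- generateDataset(tinySimConfig())
  split <- splitDataset(nrow(exprValues(d$matrix)), d$labels,
                        splitSpec(seed = 3L))
  sub <- function(idx) ExpressionMatrix(exprValues(d$matrix)[idx, ])
  filter <- fitGeneFilter(sub(split$train), minNonzeroCells = 5)
  norm <- function(idx) normalizeCpmLog(applyGeneFilter(filter, sub(idx)))
  model <- buildModel(tinyModelConfig(), filter$keptGeneIds,
                      sort(unique(d$labels[split$train])))
  model <- trainModel(model, norm(split$train), d$labels[split$train],
                      norm(split$val), d$labels[split$val])
  .fixtureCache$tiny <- list(data = d, split = split, filter = filter,
                             model = model,
                             trainX = norm(split$train),
                             testX = norm(split$test),
                             testY = d$labels[split$test])
  .fixtureCache$tiny
}

# Write a small dense matrix + labels pair to temp files.
writeTempDataset <- function(counts, labels,
                             dir = tempfile("fixture")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  x <- ExpressionMatrix(counts)
  mPath <- file.path(dir, "matrix.tsv")
  lPath <- file.path(dir, "labels.tsv")
  writeExpressionMatrix(x, mPath)
  utils::write.table(data.frame(cell_id = cellIds(x), label = labels),
                     lPath, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mPath, labels = lPath)
}

randomCounts <- function(n, g, seed = 1) {
  set.seed(seed)
  matrix(rpois(n * g, 3), n, g,
         dimnames = list(sprintf("c%03d", seq_len(n)),
                         sprintf("g%03d", seq_len(g))))
}
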