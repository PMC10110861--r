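# End-to-end pipeline commands. Each cmd* function is a thin, scriptable
# wrapper over the package API: resolved configuration and seeds are
# serialized next to the outputs so every run is reproducible.

#' Assemble a run configuration
#'
#' Merges data paths (or a simulation config), preprocessing thresholds,
#' split fractions and model hyperparameters into one list consumed by
#' [cmdTrain()]. One global seed fans out to fixed per-stage streams
#' (simulate, split, init, shuffle) so stages can be re-run independently.
#'
#' @param matrix,labels input paths (omit when \code{sim} is given).
#' @param format matrix layout for [readExpressionMatrix()].
#' @param sim optional [simConfig()]; when set, data are simulated.
#' @param outDir output directory.
#' @param minNonzeroCells gene filter threshold (see [fitGeneFilter()]).
#' @param cpmScale per-cell normalization scale (see [normalizeCpmLog()]).
#' @param fractions train/val/test fractions.
#' @param stratified stratify the split by cell type.
#' @param seed global seed.
#' @param model a [modelConfig()]; its seed is overridden by \code{seed}.
#' @param epochs optional override of the model's epoch count.
#' @param threshold rejection threshold used at prediction time.
#' @return a \code{RunConfig} list.
#' @export
runConfig <- function(matrix = NULL, labels = NULL,
                      format = "dense_delim", sim = NULL,
                      outDir = tempfile("run"),
                      minNonzeroCells = 200, cpmScale = 10000,
                      fractions = c(0.70, 0.15, 0.15), stratified = TRUE,
                      seed = 1L, model = modelConfig(), epochs = NULL,
                      threshold = 0.97) {
  if (is.null(sim) && (is.null(matrix) || is.null(labels)))
    stop("provide either matrix+labels paths or a simulation config")
  model$seed <- as.integer(seed)
  structure(list(matrix = matrix, labels = labels, format = format,
                 sim = sim, outDir = outDir,
                 minNonzeroCells = minNonzeroCells, cpmScale = cpmScale,
                 fractions = fractions, stratified = stratified,
                 seed = as.integer(seed), model = model, epochs = epochs,
                 threshold = threshold),
            class = "RunConfig")
}

.loadTrainingData <- function(cfg) {
  if (!is.null(cfg$sim)) {
    sim <- cfg$sim
    sim$seed <- cfg$seed
    d <- generateDataset(sim)
    list(x = d$matrix, labels = d$labels)
  } else {
    x <- readExpressionMatrix(cfg$matrix, cfg$format)
    lab <- readLabels(cfg$labels)
    list(x = x, labels = matchLabels(x, lab))
  }
}

#' Train end-to-end and evaluate on the held-out test split
#'
#' Runs the full pipeline: load (or simulate) counts and labels, split
#' cells, fit the gene filter on training cells only, CPM/log normalize,
#' train, and evaluate on the test split. Writes \code{model.rds},
#' \code{history.csv}, \code{metrics.json} and \code{config.yaml} into the
#' output directory.
#'
#' @param cfg a [runConfig()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the trained model, split indices, test
#'   metrics and output paths.
#' @export
cmdTrain <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "RunConfig"))
  say <- function(...) if (!quiet) message("[train] ", ...)
  dat <- .loadTrainingData(cfg)
  n <- nrow(exprValues(dat$x))
  say(n, " cells, ", ncol(exprValues(dat$x)), " genes, ",
      length(unique(dat$labels)), " types")

  split <- splitDataset(n, dat$labels,
                        splitSpec(cfg$fractions, seed = cfg$seed,
                                  stratified = cfg$stratified))
  sub <- function(idx) ExpressionMatrix(
    exprValues(dat$x)[idx, , drop = FALSE], normalized = isNormalized(dat$x))

  filter <- fitGeneFilter(sub(split$train), cfg$minNonzeroCells)
  say(length(filter$keptGeneIds), " genes pass the filter")
  norm <- function(idx)
    normalizeCpmLog(applyGeneFilter(filter, sub(idx)), cfg$cpmScale)
  trainX <- norm(split$train); valX <- norm(split$val)
  testX <- norm(split$test)
  trainY <- dat$labels[split$train]

  model <- buildModel(cfg$model, filter$keptGeneIds, sort(unique(trainY)))
  say("training for ", cfg$epochs %||% cfg$model$epochs, " epochs")
  model <- trainModel(model, trainX, trainY, valX, dat$labels[split$val],
                      epochs = cfg$epochs)

  probs <- predictProba(model, testX)
  testPred <- colnames(probs)[max.col(probs, ties.method = "first")]
  metrics <- evaluatePredictions(dat$labels[split$test], testPred, probs)
  say(sprintf("test accuracy %.4f, macro F1 %.4f, ARI %.4f",
              metrics$accuracy, metrics$macro_f1, metrics$ari))

  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(model = file.path(cfg$outDir, "model.rds"),
                history = file.path(cfg$outDir, "history.csv"),
                metrics = file.path(cfg$outDir, "metrics.json"),
                config = file.path(cfg$outDir, "config.yaml"))
  saveModel(model, paths$model)
  utils::write.csv(trainingHistory(model), paths$history, row.names = FALSE)
  jsonlite::write_json(metrics[setdiff(names(metrics), "per_class")],
                       paths$metrics, auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(.serializableConfig(cfg), paths$config)
  invisible(list(model = model, filter = filter, split = split,
                 metrics = metrics, paths = paths,
                 data = dat, test = testX))
}

.serializableConfig <- function(cfg) {
  out <- unclass(cfg)
  out$model <- unclass(out$model)
  if (!is.null(out$sim)) out$sim <- lapply(unclass(out$sim), function(v)
    if (is.null(names(v))) v else as.list(v))
  rapply(out, function(v) v, how = "replace")
}

#' Predict query cells with rejection
#'
#' Restricts the query to the model's gene list, normalizes, predicts, and
#' writes a predictions TSV (cell id, label, max probability, per-class
#' probabilities).
#'
#' @param model a [CellTypeModel-class] or checkpoint path.
#' @param query an [ExpressionMatrix-class] of raw counts or a matrix path.
#' @param out output TSV path (optional).
#' @param threshold rejection threshold.
#' @param format matrix layout when \code{query} is a path.
#' @param cpmScale normalization scale.
#' @return the [PredictionResult-class], invisibly when \code{out} is set.
#' @export
cmdPredict <- function(model, query, out = NULL, threshold = 0.97,
                       format = "dense_delim", cpmScale = 10000) {
  if (is.character(model)) model <- loadModel(model)
  if (is.character(query)) query <- readExpressionMatrix(query, format)
  filter <- structure(list(minNonzeroCells = NA,
                           keptGeneIds = modelGeneIds(model)),
                      class = "GeneFilter")
  q <- applyGeneFilter(filter, query)
  if (!isNormalized(q)) q <- normalizeCpmLog(q, cpmScale)
  pred <- predictWithRejection(model, threshold = threshold, x = q)
  if (!is.null(out)) {
    writePredictions(pred, out)
    return(invisible(pred))
  }
  pred
}

#' Score predictions against true labels
#'
#' @param truth labels path (or data.frame from [readLabels()]).
#' @param pred predictions TSV path (from [cmdPredict()]) or a
#'   [PredictionResult-class].
#' @param out optional metrics JSON path.
#' @return named list of metrics.
#' @export
cmdEvaluate <- function(truth, pred, out = NULL) {
  if (is.character(truth)) truth <- readLabels(truth)
  if (is.character(pred)) {
    df <- utils::read.table(pred, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    predLabels <- df$predicted_label
    predIds <- df$cell_id
  } else {
    predLabels <- predictedLabels(pred)
    predIds <- pred@cellIds
  }
  idx <- match(predIds, truth$cell_id)
  if (anyNA(idx))
    stop("cells missing from the truth labels: ",
         paste(utils::head(predIds[is.na(idx)], 5), collapse = ", "))
  metrics <- evaluatePredictions(truth$label[idx], predLabels)
  if (!is.null(out))
    jsonlite::write_json(metrics[setdiff(names(metrics), "per_class")],
                         out, auto_unbox = TRUE, digits = NA)
  metrics
}

#' Simulate a dataset and write it in the package's I/O formats
#'
#' @param sim a [simConfig()].
#' @param outPrefix directory (created if needed) receiving
#'   \code{matrix.tsv}, \code{labels.tsv} and \code{markers.json}.
#' @return invisibly, the generated dataset.
#' @export
cmdSimulate <- function(sim, outPrefix) {
  d <- generateDataset(sim)
  dir.create(outPrefix, showWarnings = FALSE, recursive = TRUE)
  writeExpressionMatrix(d$matrix, file.path(outPrefix, "matrix.tsv"))
  utils::write.table(
    data.frame(cell_id = cellIds(d$matrix), label = d$labels),
    file.path(outPrefix, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(d$markers, file.path(outPrefix, "markers.json"))
  invisible(d)
}

#' Sweep the rejection threshold on a labeled evaluation set
#'
#' @param model a [CellTypeModel-class] or checkpoint path.
#' @param x normalized evaluation [ExpressionMatrix-class].
#' @param labels true labels (may include unseen types).
#' @param from,to,by threshold grid (default 0.89 to 0.998 step 0.002).
#' @param out optional TSV path.
#' @return data.frame of threshold, accuracy and unknown counts.
#' @export
cmdSweep <- function(model, x, labels, from = 0.89, to = 0.998, by = 0.002,
                     out = NULL) {
  if (is.character(model)) model <- loadModel(model)
  res <- sweepThreshold(model, x, labels, thresholdGrid(from, to, by))
  if (!is.null(out))
    utils::write.table(res, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  res
}
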