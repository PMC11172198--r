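#' Build an experiment configuration
#'
#' Collects every setting of one end-to-end run: the data source, the
#' preprocessing chain, the PCA component count, the feature extractor
#' (classical LDA, DLDA or FDLDA with its fuzzy exponent), the classifier
#' with its hyperparameters, and the stratified-split fraction and seed.
#' Validation happens here, before any computation.
#'
#' @param data a \linkS4class{SpectralSet}, or NULL to generate from
#'   \code{spec}.
#' @param spec a \linkS4class{SyntheticSpec} (used when \code{data} is
#'   NULL).
#' @param steps preprocessing chain (default SG then SNV).
#' @param sgWindow,sgPolyorder Savitzky-Golay settings.
#' @param npc PCA components (default 5).
#' @param method "lda", "dlda" or "fdlda".
#' @param m fuzzy weight exponent for FDLDA (default 3.5).
#' @param classifier "knn", "elm" or "nb".
#' @param k KNN neighbour count (default 7).
#' @param hidden ELM hidden neurons (default 10).
#' @param elmRuns ELM repetitions averaged, seeds 1..runs (default 50).
#' @param testFraction held-out proportion per class (default 0.25).
#' @param splitSeed seed of the stratified split.
#' @return an \linkS4class{ExperimentConfig}.
#' @export
experimentConfig <- function(data = NULL, spec = NULL,
                             steps = c("SG", "SNV"), sgWindow = 11L,
                             sgPolyorder = 2L, npc = 5L,
                             method = "fdlda", m = 3.5,
                             classifier = "knn", k = 7L, hidden = 10L,
                             elmRuns = 50L, testFraction = 0.25,
                             splitSeed = 1L) {
    new("ExperimentConfig", data = data, spec = spec,
        steps = toupper(steps), sgWindow = as.integer(sgWindow),
        sgPolyorder = as.integer(sgPolyorder), npc = as.integer(npc),
        method = tolower(method), m = m,
        classifier = tolower(classifier), k = as.integer(k),
        hidden = as.integer(hidden), elmRuns = as.integer(elmRuns),
        testFraction = testFraction, splitSeed = as.integer(splitSeed))
}

.fitExtractor <- function(cfg, scores, labels) {
    switch(cfg@method,
        lda = fitLDA(scores, labels),
        dlda = fitDLDA(scores, labels),
        fdlda = fitFDLDA(scores, labels, m = cfg@m))
}

#' Run one end-to-end experiment
#'
#' Executes the full pipeline: replicate averaging (when replicate ids
#' are present), stratified train/test split, preprocessing fitted on the
#' training set and applied to both sets, PCA fitted on the training set,
#' feature extraction fitted on the training scores, classifier fitted on
#' the training discriminant scores, and accuracy measured on the test
#' set. No test-set value influences any fitted parameter. The run is
#' deterministic given the config seeds; for the ELM classifier the
#' reported accuracy is the mean over \code{elmRuns} seeds.
#'
#' @param cfg an \linkS4class{ExperimentConfig}.
#' @return an \linkS4class{ExperimentReport} with one result row.
#' @examples
#' cfg <- experimentConfig(spec = syntheticMilkSpec(overlap = 0, seed = 1),
#'                         method = "fdlda", classifier = "knn")
#' report <- runExperiment(cfg)
#' resultsTable(report)
#' @export
runExperiment <- function(cfg) {
    stopifnot(is(cfg, "ExperimentConfig"))
    validObject(cfg)
    stage <- "data"
    tryCatch({
        ds <- if (!is.null(cfg@data)) cfg@data else simulateSpectra(cfg@spec)
        if (!is.null(replicateIds(ds))) ds <- averageReplicates(ds)
        stage <- "split"
        parts <- stratifiedSplit(ds, cfg@testFraction, cfg@splitSeed)
        stage <- "preprocess"
        prep <- fitPreprocess(parts$train, cfg@steps, cfg@sgWindow,
                              cfg@sgPolyorder)
        trainP <- applyPreprocess(prep, parts$train)
        testP <- applyPreprocess(prep, parts$test)
        stage <- "pca"
        pca <- fitPCA(trainP, cfg@npc)
        trS <- pcaTransform(pca, trainP)
        teS <- pcaTransform(pca, testP)
        stage <- "feature extraction"
        disc <- .fitExtractor(cfg, trS$scores, trS$labels)
        trD <- discriminantTransform(disc, trS$scores)
        teD <- discriminantTransform(disc, teS$scores)
        stage <- "classification"
        if (cfg@classifier == "elm") {
            acc <- elmRepeatEval(trD, trS$labels, teD, teS$labels,
                                 hidden = cfg@hidden, runs = cfg@elmRuns)
            mdl <- elmTrain(trD, trS$labels, hidden = cfg@hidden,
                            seed = 1L)
            pred <- elmPredict(mdl, teD)
        } else if (cfg@classifier == "knn") {
            mdl <- knnFit(trD, trS$labels, cfg@k)
            pred <- knnPredict(mdl, teD)
            acc <- accuracy(pred, teS$labels)
        } else {
            mdl <- nbFit(trD, trS$labels)
            pred <- nbPredict(mdl, teD)
            acc <- accuracy(pred, teS$labels)
        }
        conf <- table(predicted = pred,
                      truth = factor(teS$labels,
                                     levels = levels(factor(trS$labels))))
        res <- data.frame(
            steps = paste(cfg@steps, collapse = "+"), npc = cfg@npc,
            method = toupper(cfg@method),
            m = if (cfg@method == "fdlda") cfg@m else NA_real_,
            classifier = cfg@classifier, k = cfg@k, hidden = cfg@hidden,
            nTrain = length(trS$labels), nTest = length(teS$labels),
            accuracy = round(100 * acc, 2), stringsAsFactors = FALSE)
        new("ExperimentReport", results = res, confusion = list(conf),
            models = list(preprocess = prep, pca = pca,
                          discriminant = disc, classifier = mdl),
            provenance = list(splitSeed = cfg@splitSeed,
                              timestamp = format(Sys.time()),
                              version = as.character(
                                  utils::packageVersion("fdlda"))))
    }, error = function(e) {
        stop("pipeline failed at stage '", stage, "': ",
             conditionMessage(e), call. = FALSE)
    })
}

#' Run a Cartesian sweep of experiments
#'
#' Expands the supplied grids (any of \code{steps} — a list of chains —
#' \code{npc}, \code{method}, \code{m}, \code{k}, \code{hidden},
#' \code{classifier}, \code{splitSeed}) against the base configuration
#' and runs one experiment per cell. The fuzzy exponent grid applies only
#' to FDLDA: for LDA/DLDA cells the \code{m} values collapse to a single
#' run.
#'
#' @param cfg base \linkS4class{ExperimentConfig}.
#' @param grid named list of values to sweep.
#' @return an \linkS4class{ExperimentReport} whose results table has one
#'   row per grid cell.
#' @export
runGrid <- function(cfg, grid = list()) {
    stopifnot(is(cfg, "ExperimentConfig"))
    if (!length(grid)) return(runExperiment(cfg))
    allowed <- c("steps", "npc", "method", "m", "k", "hidden",
                 "classifier", "splitSeed")
    if (!all(names(grid) %in% allowed))
        stop("validation error: unknown grid name(s): ",
             paste(setdiff(names(grid), allowed), collapse = ", "))
    if (any(!lengths(grid)))
        stop("validation error: empty grid component")
    cells <- expand.grid(lapply(grid, seq_along))
    seen <- character(0)
    rows <- list(); confs <- list()
    for (i in seq_len(nrow(cells))) {
        ci <- cfg
        for (nm in names(grid)) {
            val <- grid[[nm]][[cells[i, nm]]]
            slot(ci, nm) <- switch(nm,
                steps = toupper(val),
                method = tolower(val),
                classifier = tolower(val),
                m = as.numeric(val),
                as.integer(val))
        }
        # m only matters for fdlda; collapse duplicate lda/dlda cells
        if (ci@method != "fdlda" && "m" %in% names(grid)) {
            key <- paste(ci@method, paste(ci@steps, collapse = "+"),
                         ci@npc, ci@classifier, ci@k, ci@hidden,
                         ci@splitSeed)
            if (key %in% seen) next
            seen <- c(seen, key)
        }
        rep <- runExperiment(ci)
        rows[[length(rows) + 1L]] <- rep@results
        confs[[length(confs) + 1L]] <- rep@confusion[[1]]
    }
    new("ExperimentReport", results = do.call(rbind, rows),
        confusion = confs, models = list(),
        provenance = list(splitSeed = cfg@splitSeed,
                          timestamp = format(Sys.time()),
                          version = as.character(
                              utils::packageVersion("fdlda"))))
}

#' @describeIn ExperimentReport-class the per-configuration results
#'   data.frame (accuracy in percent, 2 decimals).
#' @param report an \code{ExperimentReport}.
#' @export
resultsTable <- function(report) {
    stopifnot(is(report, "ExperimentReport"))
    report@results
}

#' @describeIn ExperimentReport-class list of confusion tables
#'   (predicted x truth), one per run.
#' @export
confusionTables <- function(report) {
    stopifnot(is(report, "ExperimentReport"))
    report@confusion
}

#' Write an experiment report to disk
#'
#' Writes \code{<prefix>.csv} (the results table) and \code{<prefix>.json}
#' (results plus provenance).
#'
#' @param report an \linkS4class{ExperimentReport}.
#' @param prefix output path prefix.
#' @return the two paths, invisibly.
#' @export
writeReport <- function(report, prefix) {
    stopifnot(is(report, "ExperimentReport"))
    csv <- paste0(prefix, ".csv"); js <- paste0(prefix, ".json")
    write.csv(report@results, csv, row.names = FALSE)
    jsonlite::write_json(list(results = report@results,
                              provenance = report@provenance),
                         js, auto_unbox = TRUE, digits = NA)
    invisible(c(csv, js))
}

setMethod("show", "ExperimentReport", function(object) {
    cat(sprintf("ExperimentReport: %d run(s)\n", nrow(object@results)))
    print(object@results)
    invisible(NULL)
})

setMethod("show", "ExperimentConfig", function(object) {
    cat(sprintf(
        "ExperimentConfig: %s -> PCA(%d) -> %s%s -> %s (split seed %d)\n",
        paste(object@steps, collapse = "+"), object@npc,
        toupper(object@method),
        if (object@method == "fdlda") sprintf("(m=%g)", object@m) else "",
        object@classifier, object@splitSeed))
    invisible(NULL)
})
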