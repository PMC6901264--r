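# Orchestration: build per-patient networks, find minimum driver sets,
# evaluate against gold standards, profile cohort frequency. One entry
# point, declarative config, deterministic outputs.

#' Validate a pipeline configuration
#'
#' A config is a plain named list (or a path to a JSON file holding one).
#' Required: \code{networkFile}, \code{normalFile}, \code{tumorFile},
#' \code{outputDir}. Optional: \code{referenceFile} (reference expression
#' panel; defaults to the normal matrix, i.e. all normal samples),
#' \code{goldFiles} (named list of gene-list paths), \code{geneSetsFile}
#' (GMT), \code{mutationFile}, \code{alpha} (0.05), \code{method}
#' (\code{"paired_ssn"}, \code{"ssn"} or \code{"lioness"}),
#' \code{timeLimit} (600 s), \code{seed} (1).
#'
#' @param config named list or JSON path.
#' @return the completed config list (defaults filled in).
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  need <- c("networkFile", "normalFile", "tumorFile", "outputDir")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config lacks: ", paste(miss, collapse = ", "))
  defaults <- list(referenceFile = NULL, goldFiles = list(),
                   geneSetsFile = NULL, mutationFile = NULL,
                   alpha = 0.05, method = "paired_ssn",
                   timeLimit = 600, seed = 1)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[nm] <- defaults[nm]
  if (config$alpha <= 0 || config$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!config$method %in% c("paired_ssn", "ssn", "lioness"))
    stop("unknown method: ", config$method)
  paths <- c(config$networkFile, config$normalFile, config$tumorFile,
             config$referenceFile, config$geneSetsFile, config$mutationFile,
             unlist(config$goldFiles))
  for (p in paths) if (!file.exists(p)) stop("input file missing: ", p)
  config
}

#' Run the full personalized-driver pipeline
#'
#' For every patient (a column shared by the normal and tumor expression
#' matrices): build the state transition network, solve for the minimum
#' driver set, compute controllability. Cohort level: driver-frequency
#' profile with cohort drivers (frequency > 0.8), and — when gold-standard
#' lists are configured — precision/recall/F and hypergeometric enrichment
#' of the cohort drivers against each list, with the reference network's
#' genes as background. All outputs are tab-delimited (plus one JSON
#' summary) under \code{outputDir}; reruns with an identical config are
#' byte-identical.
#'
#' @param config named list or JSON path; see \code{\link{validateConfig}}.
#' @return invisibly, a list with \code{drivers} (list of
#'   \linkS4class{DriverResult}), \code{networks} (list of
#'   \linkS4class{StateTransitionNetwork}), \code{frequency} (data.frame),
#'   \code{evaluation} (data.frame or NULL) and \code{summary} (list).
#' @export
runPipeline <- function(config) {
  config <- validateConfig(config)
  stage <- function(what, patient, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed for %s: %s", what, patient,
                   conditionMessage(e)), call. = FALSE))
  }
  net <- stage("read_network", "-", readNetwork(config$networkFile))
  normal <- stage("read_expression", "-", readExpression(config$normalFile))
  tumor <- stage("read_expression", "-", readExpression(config$tumorFile))
  refs <- if (is.null(config$referenceFile)) normal else
    stage("read_expression", "-", readExpression(config$referenceFile))
  patients <- intersect(colnames(normal), colnames(tumor))
  if (length(patients) == 0) stop("no patients shared by normal and tumor matrices")
  exprGenes <- intersect(rownames(normal), rownames(tumor))
  exprGenes <- intersect(exprGenes, rownames(refs))
  net <- restrictNetwork(net, exprGenes)
  message(sprintf("pipeline: %d patients, %d usable genes, %d network edges",
                  length(patients), length(net@nodes), nrow(net@edges)))
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)

  networks <- list(); driverResults <- list()
  for (pid in patients) {
    stn <- stage("build_network", pid, switch(config$method,
      paired_ssn = pairedSSN(refs,
        patientPair(pid, normal[exprGenes, pid], tumor[exprGenes, pid]),
        net, config$alpha),
      ssn = ssnNetwork(refs, stats::setNames(tumor[exprGenes, pid], exprGenes),
        net, config$alpha, patientId = pid),
      lioness = lionessNetwork(tumor[exprGenes, , drop = FALSE], pid, net)))
    dr <- stage("drivers", pid,
      ncuaDrivers(stn, timeLimit = config$timeLimit))
    message(sprintf("  %s: %d edges kept, %d drivers, controllability %.3f",
                    pid, nrow(stn@edges), length(dr@drivers),
                    dr@controllability))
    writeStateNetwork(stn, file.path(config$outputDir,
                                     paste0(pid, ".network.tsv")))
    networks[[pid]] <- stn
    driverResults[[pid]] <- dr
  }

  # driver table with per-gene component ids inside each patient network
  drvRows <- lapply(patients, function(pid) {
    dr <- driverResults[[pid]]
    if (length(dr@drivers) == 0) return(NULL)
    memb <- igraph::components(asIgraph(networks[[pid]]))$membership
    data.frame(patient = pid, gene = dr@drivers,
               component = as.integer(memb[dr@drivers]),
               stringsAsFactors = FALSE)
  })
  drvTab <- do.call(rbind, drvRows)
  write.table(drvTab, file.path(config$outputDir, "drivers.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  freq <- driverFrequency(driverResults)
  write.table(freq, file.path(config$outputDir, "driver_frequency.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cohortDrivers <- freq$gene[freq$cohortDriver]

  evaluation <- NULL
  if (length(config$goldFiles)) {
    background <- net@nodes
    evalRows <- lapply(names(config$goldFiles), function(listName) {
      gold <- readGeneSets(config$goldFiles[[listName]], "list")[[1]]
      perPat <- vapply(patients, function(pid)
        fMeasure(driverResults[[pid]]@drivers, gold, background)[["F"]], 1)
      goldIn <- intersect(gold, background)
      k <- length(intersect(cohortDrivers, goldIn))
      enr <- hypergeomEnrichment(length(background), length(goldIn),
                                 length(cohortDrivers), k)
      fm <- fMeasure(cohortDrivers, gold, background)
      data.frame(gold_list = listName,
                 cohort_precision = fm[["precision"]],
                 cohort_recall = fm[["recall"]],
                 cohort_F = fm[["F"]],
                 mean_patient_F = mean(perPat),
                 enrichment_p = enr$p,
                 stringsAsFactors = FALSE)
    })
    evaluation <- do.call(rbind, evalRows)
    write.table(evaluation, file.path(config$outputDir, "evaluation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    method = config$method, alpha = config$alpha, seed = config$seed,
    nPatients = length(patients),
    nNetworkGenes = length(net@nodes),
    nNetworkEdges = nrow(net@edges),
    controllability = lapply(stats::setNames(patients, patients), function(pid)
      driverResults[[pid]]@controllability),
    nDrivers = lapply(stats::setNames(patients, patients), function(pid)
      length(driverResults[[pid]]@drivers)),
    cohortDrivers = cohortDrivers)
  jsonlite::write_json(summary, file.path(config$outputDir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(drivers = driverResults, networks = networks,
                 frequency = freq, evaluation = evaluation,
                 summary = summary))
}

#' Write a synthetic cohort as pipeline input files
#'
#' Exports the network edge list, the reference panel, and the per-patient
#' normal/tumor matrices in the formats \code{\link{runPipeline}} reads,
#' plus the ground-truth manifest.
#'
#' @param cohort a \linkS4class{PlantedCohort}.
#' @param dir output directory (created if needed).
#' @return the file paths as a named list, invisibly.
#' @export
writeCohortInputs <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    networkFile = file.path(dir, "network.tsv"),
    referenceFile = file.path(dir, "reference.tsv"),
    normalFile = file.path(dir, "normal.tsv"),
    tumorFile = file.path(dir, "tumor.tsv"),
    manifest = file.path(dir, "manifest.json"))
  writeNetwork(cohort@network, paths$networkFile)
  writeExpression(cohort@refExpr, paths$referenceFile)
  nm <- vapply(cohort@pairs, function(p) p@patientId, "")
  genes <- rownames(cohort@refExpr)
  normal <- vapply(cohort@pairs, function(p) p@normal[genes], numeric(length(genes)))
  tumor <- vapply(cohort@pairs, function(p) p@tumor[genes], numeric(length(genes)))
  dimnames(normal) <- dimnames(tumor) <- list(genes, nm)
  writeExpression(normal, paths$normalFile)
  writeExpression(tumor, paths$tumorFile)
  writeCohortManifest(cohort, paths$manifest)
  invisible(paths)
}
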