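# Pipeline orchestration: simulate -> tags -> novel -> de -> targets ->
# enrich -> screen, with a run manifest recording parameters, row counts
# and output checksums so identical configurations reproduce identical
# outputs.

#' Pipeline configuration
#'
#' A plain list of every tunable parameter, serializable to and from a
#' single YAML file (\code{\link{writePipelineConfig}} /
#' \code{\link{readPipelineConfig}}; the round trip is stable).  With
#' \code{simulate = TRUE} the synthetic-data stage generates all inputs;
#' otherwise the \code{inputs} paths must all exist.
#'
#' @param outDir output directory for all stage outputs and the manifest.
#' @param seed global random seed; every stochastic stage derives its seed
#'   from it.
#' @param simulate generate inputs with the synthetic-data module.
#' @param readsPerLib reads per simulated library.
#' @param chromLen,nChrom,nKnown,nNovel,nNcrna synthetic genome shape.
#' @param dispersion,errorRate read-simulation noise parameters.
#' @param adapter 3' adapter sequence (used by simulation and trimming).
#' @param minLen,maxLen tag length window (nt).
#' @param flank genomic flank folded around mapped tags (nt).
#' @param mireap named list of \linkS4class{MireapParams} overrides.
#' @param floor,alpha normalization floor and significance level.
#' @param maxTargetScore maximal complementarity penalty for a target site.
#' @param minLabel minimal DE label entering the screen.
#' @param pathways pathway terms of interest for the screen.
#' @param inputs named list of input paths (genome, mature, hairpin, ncrna,
#'   readsHH, readsLL, utrs, annotation, targetExpr) used when
#'   \code{simulate = FALSE}.
#' @return A list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(outDir, seed = 7, simulate = TRUE,
                           readsPerLib = 50000, chromLen = 100000,
                           nChrom = 1, nKnown = 20, nNovel = 5, nNcrna = 10,
                           dispersion = 100, errorRate = 0.001,
                           adapter = "TGGAATTCTCGGGTGCCAAGG",
                           minLen = 18, maxLen = 30, flank = 100,
                           mireap = list(), floor = 0.01, alpha = 0.05,
                           maxTargetScore = 4.0, minLabel = "*",
                           pathways = lipidPathways(), inputs = list()) {
  structure(list(outDir = outDir, seed = seed, simulate = simulate,
                 readsPerLib = readsPerLib, chromLen = chromLen,
                 nChrom = nChrom, nKnown = nKnown, nNovel = nNovel,
                 nNcrna = nNcrna, dispersion = dispersion,
                 errorRate = errorRate, adapter = adapter, minLen = minLen,
                 maxLen = maxLen, flank = flank, mireap = mireap,
                 floor = floor, alpha = alpha,
                 maxTargetScore = maxTargetScore, minLabel = minLabel,
                 pathways = pathways, inputs = inputs),
            class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param cfg a \code{PipelineConfig}.
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipelineConfig, cfg)
}

#' Validate a pipeline configuration
#'
#' Fails before any stage runs if the configuration is inconsistent, in
#' particular when simulation is disabled but input files are missing.
#'
#' @param cfg a \code{PipelineConfig}.
#' @return TRUE, invisibly.
#' @export
validatePipelineConfig <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  if (is.null(cfg$outDir) || !nzchar(cfg$outDir))
    stop("validation error: outDir is required")
  if (!isTRUE(cfg$simulate)) {
    need <- c("genome", "mature", "hairpin", "readsHH", "readsLL",
              "utrs", "annotation", "targetExpr")
    missing <- need[!vapply(need, function(k) {
      p <- cfg$inputs[[k]]
      !is.null(p) && file.exists(p)
    }, logical(1))]
    if (length(missing))
      stop("validation error: simulate is disabled and input(s) missing: ",
           paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

.stage_files <- function(dir) {
  f <- list.files(dir, recursive = TRUE, full.names = TRUE)
  data.frame(file = sub(paste0("^", dir, "/?"), "", f),
             md5 = unname(tools::md5sum(f)), stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Executes the stages in order (simulate, tags, novel, de, targets,
#' enrich, screen), writing per-stage outputs under \code{cfg$outDir} and a
#' \code{manifest.yaml} recording parameter values, per-stage row counts
#' and output checksums.  Rerunning with an identical configuration and
#' seed reproduces identical outputs.  On a stage failure the manifest
#' written so far is saved with the failing stage and error recorded, and
#' partial outputs are retained.
#'
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return Invisibly, a list with \code{manifest} and the in-memory
#'   \code{results} of every stage.
#' @export
runPipeline <- function(cfg) {
  validatePipelineConfig(cfg)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, params = unclass(cfg), stages = list())
  res <- list()
  record <- function(name, rows) {
    manifest$stages[[name]] <<- list(status = "complete", rows = rows)
  }
  finish <- function() {
    manifest$files <- .stage_files(cfg$outDir)$md5
    names(manifest$files) <- .stage_files(cfg$outDir)$file
    yaml::write_yaml(manifest, file.path(cfg$outDir, "manifest.yaml"))
  }
  on.exit({
    # record the failure point; partial outputs stay on disk
    if (!length(manifest$stages) ||
        manifest$stages[[length(manifest$stages)]]$status == "failed")
      yaml::write_yaml(manifest, file.path(cfg$outDir, "manifest.yaml"))
  })

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      yaml::write_yaml(manifest, file.path(cfg$outDir, "manifest.yaml"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # stage 1: simulate (or load inputs)
  run_stage("simulate", function() {
    if (isTRUE(cfg$simulate)) {
      sg <- makeGenome(chromLen = cfg$chromLen, nChrom = cfg$nChrom,
                       nKnown = cfg$nKnown, nNovel = cfg$nNovel,
                       nNcrna = cfg$nNcrna, seed = cfg$seed)
      libs <- simulateLibraries(sg, readSimConfig(
        readsPerLib = cfg$readsPerLib, dispersion = cfg$dispersion,
        errorRate = cfg$errorRate, adapter = cfg$adapter,
        seed = cfg$seed + 1))
      bundle <- simulateTargetBundle(sg$truth, seed = cfg$seed + 2)
      simDir <- file.path(cfg$outDir, "sim")
      writeGenomeBundle(sg, simDir)
      writeLibraryFastq(libs, simDir)
      writeTargetBundle(bundle, simDir)
      res$sim <<- list(sg = sg, libs = libs, bundle = bundle,
                       readsHH = libs$reads$HH, readsLL = libs$reads$LL,
                       genome = sg$genome, mature = sg$refs$mature,
                       hairpin = sg$refs$hairpin, ncrna = sg$refs$ncrna,
                       knownLoci = sg$loci[sg$loci$class == "known_mirna", ],
                       utrs = bundle$utrs, annotation = bundle$annotation,
                       targetExpr = bundle$targetExpr)
      record("simulate", c(readsHH = length(libs$reads$HH),
                           readsLL = length(libs$reads$LL),
                           loci = nrow(sg$loci)))
    } else {
      inp <- cfg$inputs
      res$sim <<- list(
        readsHH = .read_seqs(inp$readsHH), readsLL = .read_seqs(inp$readsLL),
        genome = .read_seqs(inp$genome), mature = .read_seqs(inp$mature),
        hairpin = .read_seqs(inp$hairpin),
        ncrna = if (!is.null(inp$ncrna)) .read_seqs(inp$ncrna) else character(0),
        knownLoci = NULL,
        utrs = .read_seqs(inp$utrs), annotation = .read_tsv(inp$annotation),
        targetExpr = .read_tsv(inp$targetExpr))
      record("simulate", c(readsHH = length(res$sim$readsHH),
                           readsLL = length(res$sim$readsLL)))
    }
  })

  # stage 2: tags
  run_stage("tags", function() {
    sim <- res$sim
    tags <- collapseReads(sim$readsHH, sim$readsLL, adapter = cfg$adapter)
    tags <- filterLength(tags, cfg$minLen, cfg$maxLen)
    ncr <- sim$ncrna
    refs <- list(miRNA = c(sim$mature, sim$hairpin))
    for (cat in c("rRNA", "tRNA", "snRNA", "snoRNA")) {
      sel <- ncr[grepl(paste0("^", tolower(cat)), names(ncr))]
      if (length(sel)) refs[[cat]] <- sel
    }
    annot <- annotateTags(tags, refs)
    known <- matchKnown(tags, sim$mature, sim$hairpin)
    writeTagFasta(tags, file.path(cfg$outDir, "tags.fa"))
    .write_tsv(annot$summary, file.path(cfg$outDir, "annotation_summary.tsv"))
    .write_tsv(known$expression, file.path(cfg$outDir, "known_expression.tsv"))
    res$tags <<- list(tags = tags, annot = annot, known = known)
    record("tags", c(tags = length(tags),
                     readsIn = length(sim$readsHH) + length(sim$readsLL),
                     knownMiRNAs = nrow(known$expression)))
  })

  # stage 3: novel miRNA prediction
  run_stage("novel", function() {
    novel <- predictNovel(res$tags$tags, res$sim$genome, flank = cfg$flank,
                          knownLoci = res$sim$knownLoci,
                          params = do.call(mireapParams, cfg$mireap))
    if (!is.null(novel$candidates))
      .write_tsv(novel$candidates, file.path(cfg$outDir, "novel_candidates.tsv"))
    if (!is.null(novel$accepted) && nrow(novel$accepted))
      .write_tsv(novel$accepted, file.path(cfg$outDir, "novel_accepted.tsv"))
    res$novel <<- novel
    record("novel", c(candidates = if (is.null(novel$candidates)) 0L
                                   else nrow(novel$candidates),
                      accepted = if (is.null(novel$accepted)) 0L
                                 else nrow(novel$accepted)))
  })

  # stage 4: differential expression
  run_stage("de", function() {
    tags <- res$tags$tags
    counts <- res$tags$known$expression
    counts <- data.frame(name = counts$mirna, countHH = counts$countHH,
                         countLL = counts$countLL, stringsAsFactors = FALSE)
    acc <- res$novel$accepted
    if (!is.null(acc) && nrow(acc)) {
      idx <- match(acc$matureSeq, tagSequences(tags))
      nov <- data.frame(name = acc$id, countHH = tags@countHH[idx],
                        countLL = tags@countLL[idx], stringsAsFactors = FALSE)
      counts <- rbind(counts, nov[!is.na(idx), , drop = FALSE])
    }
    # normalization denominator: candidate-miRNA reads per library
    summ <- res$tags$annot$summary
    nHH <- summ$readsHH[summ$category == "miRNA"]
    nLL <- summ$readsLL[summ$category == "miRNA"]
    de <- diffExpression(counts, max(nHH, 1), max(nLL, 1), floor = cfg$floor)
    .write_tsv(de, file.path(cfg$outDir, "de.tsv"))
    res$de <<- de
    record("de", c(miRNAs = nrow(de), significant = sum(de$label != "")))
  })

  # stage 5: target prediction
  run_stage("targets", function() {
    de <- res$de
    sel <- de$name[de$label != ""]
    mirseq <- c(res$sim$mature,
                if (!is.null(res$novel$accepted) && nrow(res$novel$accepted))
                  stats::setNames(res$novel$accepted$matureSeq,
                                  res$novel$accepted$id))
    mirseq <- mirseq[names(mirseq) %in% sel]
    sites <- if (length(mirseq))
      scanUTRs(mirseq, res$sim$utrs, maxScore = cfg$maxTargetScore)
    else scanUTRs("ACGTACGTACGTACGTACGTAC", res$sim$utrs,
                  maxScore = -1)               # empty result, same shape
    .write_tsv(sites, file.path(cfg$outDir, "target_sites.tsv"))
    res$sites <<- sites
    record("targets", c(miRNAs = length(mirseq), sites = nrow(sites)))
  })

  # stage 6: enrichment
  run_stage("enrich", function() {
    sites <- res$sites
    genes <- unique(sites$transcript[sites$schwab])
    enr <- if (length(genes))
      enrichTerms(genes, res$sim$annotation) else NULL
    if (!is.null(enr)) .write_tsv(enr, file.path(cfg$outDir, "enrichment.tsv"))
    res$enrich <<- enr
    record("enrich", c(targetGenes = length(genes),
                       terms = if (is.null(enr)) 0L else nrow(enr)))
  })

  # stage 7: screen
  run_stage("screen", function() {
    scfg <- screenConfig(pathways = cfg$pathways, minLabel = cfg$minLabel,
                         alpha = cfg$alpha)
    short <- filterByPathway(res$de, res$sites[res$sites$schwab, ],
                             res$sim$annotation, scfg)
    screen <- inverseCorrelationScreen(short, res$de, res$sim$targetExpr, scfg)
    .write_tsv(short$edges, file.path(cfg$outDir, "screen_edges.tsv"))
    .write_tsv(screen$verdicts, file.path(cfg$outDir, "screen_verdicts.tsv"))
    .write_tsv(screen$detail, file.path(cfg$outDir, "screen_detail.tsv"))
    res$screen <<- screen
    res$shortlist <<- short
    record("screen", c(shortlist = length(short$shortlist),
                       retained = sum(screen$verdicts$retained)))
  })

  finish()
  invisible(list(manifest = manifest, results = res))
}

#' Run the full synthetic demo pipeline
#'
#' One call that generates a synthetic genome (1 chromosome of 100 kb, 20
#' known and 5 novel miRNA loci, 10 ncRNA loci), simulates two 50k-read
#' libraries, and runs every downstream stage.
#'
#' @param outDir output directory.
#' @param seed global seed.
#' @param readsPerLib reads per library.
#' @param ... further \code{\link{pipelineConfig}} overrides.
#' @return As \code{\link{runPipeline}}.
#' @export
demoPipeline <- function(outDir = file.path(tempdir(), "milkmir-demo"),
                         seed = 7, readsPerLib = 50000, ...) {
  runPipeline(pipelineConfig(outDir = outDir, seed = seed,
                             readsPerLib = readsPerLib, ...))
}
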