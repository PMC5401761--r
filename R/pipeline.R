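#' Configuration for the end-to-end synthetic pipeline
#'
#' Bundles the generator parameters with every stage's tuning knobs. The
#' config is serialized verbatim into the run directory, and together with
#' the seed it reproduces a run bit-identically.
#'
#' @param params a \code{\link{simulationParams}} list.
#' @param filter a \code{\link{filterParams}} list.
#' @param flank annotation flank distance (bases).
#' @param blockWindow block-mode similarity window (bases).
#' @param slidingWindow,slidingStep sliding-mode window and step (bases).
#' @param threshold tract-calling similarity threshold (strict >).
#' @param minCallable minimum callable sites per similarity window.
#' @param locusLength concordance locus length (bases).
#' @param bootstrap bootstrap replicates per locus.
#' @param minSupport minimum winning bootstrap frequency.
#' @param knownRateSnp,knownRateIndel fractions of simulated SNPs/indels
#'   seeded into the synthetic known-variant catalog (emulating how most
#'   calls match strain-panel/dbSNP catalogs).
#' @param diseaseTable optional data.frame (gene, phenotype, omim_id) for
#'   the disease join.
#' @param outDir output directory for the run.
#' @return a list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(params = simulationParams(),
                           filter = filterParams(),
                           flank = 5000,
                           blockWindow = 1e5,
                           slidingWindow = 5e5, slidingStep = 1e5,
                           threshold = 0.997, minCallable = 1000,
                           locusLength = 2e5, bootstrap = 200,
                           minSupport = 0.5,
                           knownRateSnp = 0.936, knownRateIndel = 0.837,
                           diseaseTable = NULL,
                           outDir = tempfile("mosaicrun")) {
  cfg <- as.list(environment())
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Run the full synthetic analysis pipeline
#'
#' simulate -> filter -> annotate -> paint -> concord, writing each stage's
#' outputs as plain standard-format files under \code{outDir} plus a
#' manifest (input hashes, package version, seed) and an aggregated JSON
#' report. Because the inputs are simulated, the report also contains
#' recovery metrics against the ground-truth tracts.
#'
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param quiet suppress progress messages.
#' @return the report, invisibly (list; also written as report.json).
#' @export
runPipeline <- function(cfg = pipelineConfig(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  p <- cfg$params
  report <- list(seed = p$seed, chromLength = p$chromosomeLength)

  say("stage simulate")
  sim <- stage("simulate", {
    haps <- simulateHaplotypes(p)
    models <- emitGeneModels(p)
    haps <- harmonizeCodingSequence(haps, models)
    mask <- emitMask(p)
    mos <- simulateMosaic(p, haps, mask = mask)
    ref <- maskedSequence(haps@sequences[["REF"]], mask = mask,
                          label = "REF")
    v <- emitVariants(mos$focal, ref, p)
    writeFasta(c(list(KM = dnaSeq(mos$focal)),
                 as.list(haps@sequences)),
               file.path(cfg$outDir, "panel.fa"))
    writeVariantVcf(v, file.path(cfg$outDir, "focal.vcf"),
                    p$chromosomeLength)
    writeBed(mask, file.path(cfg$outDir, "mask.bed"), p$chromName)
    writeGeneModelsGff3(models, file.path(cfg$outDir, "genes.gff3"))
    writeTruthJson(mos$truth, p, file.path(cfg$outDir, "truth.json"))
    list(haps = haps, models = models, mask = mask, mos = mos, ref = ref)
  })

  say("stage filter")
  flt <- stage("filter", {
    v <- readVariantVcf(file.path(cfg$outDir, "focal.vcf"))
    v <- filterVariants(v, cfg$filter)
    v <- proximityFilter(v, cfg$filter)
    ## synthetic known-variant catalog: a seeded fraction of the calls
    catalog <- withSeed(p$seed + 5L, {
      sel <- c(sample(which(v$vclass == "snp"),
                      round(cfg$knownRateSnp * sum(v$vclass == "snp"))),
               sample(which(v$vclass != "snp"),
                      round(cfg$knownRateIndel * sum(v$vclass != "snp"))))
      v[sort(sel), , drop = FALSE]
    })
    v$known <- classifyKnown(v, list(catalog), dnaSeq(sim$ref))
    writeVariantVcf(v, file.path(cfg$outDir, "filtered.vcf"),
                    p$chromosomeLength)
    summ <- summarizeVariants(v)
    utils::write.table(data.frame(metric = names(summ),
                                  value = unlist(summ)),
                       file.path(cfg$outDir, "variant_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dens <- densityProfile(v$pos[v$vclass == "snp"], p$chromosomeLength)
    writeBed(dens$windows, file.path(cfg$outDir, "snp_density.bed"),
             p$chromName)
    list(variants = v, summary = summ, density = dens)
  })
  report$variantSummary <- flt$summary
  report$meanSnpDensity <- flt$density$meanDensity
  report$densityClassFractions <- as.list(flt$density$classFractions)

  say("stage annotate")
  ann <- stage("annotate", {
    calls <- classifyConsequences(flt$variants, sim$models, sim$ref,
                                  flank = cfg$flank)
    tally <- tallyConsequences(calls)
    utils::write.table(calls, file.path(cfg$outDir, "consequences.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tally, file.path(cfg$outDir, "consequence_tally.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res <- list(calls = calls, tally = tally)
    if (!is.null(cfg$diseaseTable)) {
      genes <- unique(calls$gene_id[!is.na(calls$gene_id)])
      res$disease <- diseaseJoin(genes, cfg$diseaseTable)
      utils::write.table(res$disease$table,
                         file.path(cfg$outDir, "disease_join.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    res
  })
  report$consequenceTally <- ann$tally
  if (!is.null(ann$disease))
    report$disease <- ann$disease[c("nGenes", "nPhenotypes")]

  say("stage paint")
  paint <- stage("paint", {
    cons <- buildConsensus(sim$ref, flt$variants, label = "KM")
    writeFasta(cons, file.path(cfg$outDir, "consensus_KM.fa"))
    comps <- c("DOM", "MUS", "CAS")
    res <- list()
    for (cmp in comps) {
      other <- maskedSequence(sim$haps@sequences[[cmp]], mask = sim$mask,
                              label = cmp)
      block <- windowSimilarity(cons, other, cfg$blockWindow,
                                cfg$blockWindow, cfg$minCallable)
      slide <- windowSimilarity(cons, other, cfg$slidingWindow,
                                cfg$slidingStep, cfg$minCallable)
      hist <- similarityHistogram(block)
      tracts <- callTracts(slide, cfg$threshold)
      w <- profileWindows(slide)
      utils::write.table(cbind(chrom = p$chromName, w),
                         file.path(cfg$outDir,
                                   sprintf("similarity_%s.tsv", cmp)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      bg <- w[!is.na(w$similarity), c("start", "end", "similarity")]
      utils::write.table(cbind(p$chromName, bg),
                         file.path(cfg$outDir,
                                   sprintf("similarity_%s.bedgraph", cmp)),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      if (nrow(tracts$tracts))
        writeBed(tracts$tracts, file.path(cfg$outDir,
                                          sprintf("tracts_%s.bed", cmp)),
                 p$chromName)
      res[[cmp]] <- list(block = block, slide = slide, hist = hist,
                         tracts = tracts)
    }
    res$consensus <- cons
    res
  })
  report$tractFractions <- lapply(paint[c("DOM", "MUS", "CAS")],
                                  function(x) x$tracts$fraction)
  report$similarityPeaks <- lapply(paint[c("DOM", "MUS", "CAS")],
                                   function(x) x$hist$peaks)

  say("stage concord")
  conc <- stage("concord", {
    ms <- function(lab) maskedSequence(sim$haps@sequences[[lab]],
                                       mask = sim$mask, label = lab)
    aln <- chromAlignment(paint$consensus, ms("DOM"), ms("MUS"), ms("CAS"),
                          ms("OUT"))
    calls <- topologyCalls(aln, B = cfg$bootstrap, seed = p$seed,
                           minSupport = cfg$minSupport,
                           locusLength = cfg$locusLength)
    summ <- concordanceSummary(calls, paint$MUS$tracts$tracts)
    utils::write.table(cbind(chrom = p$chromName, calls),
                       file.path(cfg$outDir, "topology_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(fractions = as.list(summ$fractions),
                              nLoci = summ$nLoci,
                              musTractAgreement = summ$musTractAgreement),
                         file.path(cfg$outDir, "concordance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(calls = calls, summary = summ)
  })
  report$concordance <- as.list(conc$summary$fractions)
  report$musTractAgreement <- conc$summary$musTractAgreement

  ## recovery metrics against ground truth
  report$recovery <- stage("recovery", {
    truth <- sim$mos$truth
    truthFr <- donorFractions(truth)
    tt <- truthTracts(truth)
    majorityDonor <- function(s, e) {
      ovl <- pmax(0, pmin(tt$end, e) - pmax(tt$start, s))
      names(which.max(vapply(split(ovl, tt$donor), sum, 0)))[1]
    }
    calls <- conc$calls[!is.na(conc$calls$label), , drop = FALSE]
    truthLab <- vapply(seq_len(nrow(calls)), function(i)
      majorityDonor(calls$start[i], calls$end[i]), "")
    confusion <- table(truth = truthLab,
                       called = sub("FOCAL_WITH_", "", calls$label))
    list(truthFractions = as.list(truthFr),
         confusion = as.data.frame(confusion),
         locusAccuracy = mean(sub("FOCAL_WITH_", "", calls$label) ==
                                truthLab))
  })

  manifest <- list(package = "mosaicAncestry",
                   version = as.character(utils::packageVersion(
                     "mosaicAncestry")),
                   seed = p$seed,
                   config = cfg[setdiff(names(cfg), "diseaseTable")],
                   files = as.list(tools::md5sum(
                     sort(list.files(cfg$outDir, full.names = TRUE)))))
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  jsonlite::write_json(report, file.path(cfg$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
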