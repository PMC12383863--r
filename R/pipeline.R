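#' Build a validated end-to-end pipeline configuration
#'
#' Collects every tunable of the simulate -> call -> clean/impute ->
#' cluster -> characterize pipeline, with the reference study conditions
#' as defaults. Per-stage seeds are derived deterministically from the
#' global seed and recorded in the run manifest.
#'
#' @param seed global integer seed.
#' @param n cohort size (default 200).
#' @param missingRate per-cell missingness injected before cleaning
#'   (default 0.02).
#' @param maxMissing subject-removal threshold on missing fraction
#'   (default 0.5).
#' @param nSequenced number of subjects for which read-level simulation
#'   and methylation calling are run (default 2; the cohort-level
#'   statistics use the generator's methylation table).
#' @param nPairs read pairs simulated per subject x amplicon (default 120).
#' @param conversionEff simulated bisulfite conversion efficiency
#'   (default 0.998).
#' @param errorRate simulated per-base sequencing error rate
#'   (default 0.001).
#' @param minCoverage,minConversion QC thresholds (defaults 100x and 99%).
#' @param families,KRange mixture-model grid (defaults EII/VII/EEI, 1:5).
#' @param nRestarts EM restarts per fit (default 10).
#' @param tol EM convergence tolerance (default 1e-8).
#' @param variant t-test variant for the report (default `"welch"`).
#' @param alpha significance level (default 0.05).
#' @param cohort a `"CohortSpec"` overriding `defaultCohortSpec(n)`.
#' @return validated list of class `"PipelineConfig"`.
#' @seealso [runPipeline()]
#' @export
pipelineConfig <- function(seed = 1L, n = 200L, missingRate = 0.02,
                           maxMissing = 0.5, nSequenced = 2L,
                           nPairs = 120L, conversionEff = 0.998,
                           errorRate = 0.001, minCoverage = 100,
                           minConversion = 99,
                           families = c("EII", "VII", "EEI"),
                           KRange = 1:5, nRestarts = 10L, tol = 1e-8,
                           variant = "welch", alpha = 0.05,
                           cohort = NULL) {
  stopifnot(minCoverage > 0, minConversion > 0, nPairs > 0,
            nSequenced >= 0, missingRate >= 0, missingRate < 1,
            conversionEff >= 0, conversionEff <= 1,
            errorRate >= 0, errorRate <= 1)
  if (is.null(cohort)) cohort <- defaultCohortSpec(n)
  stopifnot(inherits(cohort, "CohortSpec"))
  seed <- as.integer(seed)
  structure(list(
    seed = seed,
    stageSeeds = c(cohort = seed, missing = seed + 1L, impute = seed + 2L,
                   reads = seed + 3L, refs = seed + 4L, cluster = seed + 5L),
    cohort = cohort, missingRate = missingRate, maxMissing = maxMissing,
    nSequenced = as.integer(nSequenced), nPairs = as.integer(nPairs),
    conversionEff = conversionEff, errorRate = errorRate,
    minCoverage = minCoverage, minConversion = minConversion,
    families = families, KRange = KRange,
    nRestarts = as.integer(nRestarts), tol = tol,
    variant = variant, alpha = alpha
  ), class = "PipelineConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline into an output directory
#'
#' Executes the stages in order: simulate references and cohort; simulate
#' reads and call methylation (with QC and an exclusion log) for the first
#' `nSequenced` subjects; inject missingness, clean and impute; fit the
#' mixture grid and assign clusters; characterize the clusters. Every
#' output file is declared in `manifest.json` with an MD5 content digest;
#' rerunning with the same configuration reproduces identical digests.
#'
#' @param config a [pipelineConfig()] object.
#' @param outDir output directory (created if absent).
#' @return invisibly, a list with the principal in-memory results
#'   (`cohort`, `profiles`, `model`, `assignment`, `report`, `manifest`)
#'   and `dir`.
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(outDir, ...)
  files <- character(0)
  emit <- function(p) { files <<- c(files, p); p }

  regions <- ampliconRegions()
  refs <- .stage("simulate", {
    refs <- lapply(seq_len(nrow(regions)), function(i)
      makeAmpliconReference(regions$length[i], regions$n_cpg[i],
                            gcFrac = 0.5,
                            seed = config$stageSeeds[["refs"]] + i,
                            name = regions$name[i],
                            chrom = regions$chrom[i],
                            start = regions$start[i],
                            end = regions$end[i]))
    names(refs) <- regions$name
    for (r in refs)
      writeAmpliconReference(r, emit(pth(paste0(r@name, ".fasta"))),
                             emit(pth(paste0(r@name, ".json"))))
    refs
  })

  cohort <- .stage("simulate", {
    ch <- generateCohort(config$cohort, seed = config$stageSeeds[["cohort"]])
    truth <- cbind(ch$table, true_component = ch$labels)
    write.csv(truth, emit(pth("cohort_truth.csv")), row.names = FALSE)
    ch
  })

  callRes <- .stage("call", {
    mp <- config$cohort$methylation
    profiles <- list(); excl <- list()
    nSeq <- min(config$nSequenced, nrow(cohort$table))
    for (si in seq_len(nSeq)) {
      subj <- cohort$table$subject[si]
      for (ref in refs) {
        vars <- mp$variable[mp$amplicon == ref@name]
        meth <- as.numeric(cohort$table[si, vars]) / 100
        rps <- simulateBisulfitePairs(
          ref, meth, conversionEff = config$conversionEff,
          errorRate = config$errorRate, nPairs = config$nPairs,
          seed = config$stageSeeds[["reads"]] + si * 101L +
            match(ref@name, names(refs)))
        pr <- callSampleMethylation(rps, refs, sample = subj,
                                    minCoverage = config$minCoverage,
                                    minConversion = config$minConversion)
        profiles <- c(profiles, pr)
        for (p in pr) if (!isTRUE(p@qc$pass))
          excl[[length(excl) + 1L]] <- data.frame(
            sample = subj, amplicon = p@amplicon,
            reasons = paste(p@qc$reasons, collapse = "; "))
      }
    }
    exclusions <- if (length(excl)) do.call(rbind, excl)
      else data.frame(sample = character(0), amplicon = character(0),
                      reasons = character(0))
    if (length(profiles))
      write.csv(methylationTable(profiles, refs),
                emit(pth("methylation_calls.csv")), row.names = FALSE)
    write.csv(exclusions, emit(pth("exclusions.csv")), row.names = FALSE)
    list(profiles = profiles, exclusions = exclusions)
  })

  cleaned <- .stage("clean_impute", {
    obs <- injectMissingness(cohort$table, config$missingRate,
                             seed = config$stageSeeds[["missing"]])
    write.csv(obs, emit(pth("cohort_observed.csv")), row.names = FALSE)
    ci <- cleanAndImpute(obs, maxMissing = config$maxMissing,
                         seed = config$stageSeeds[["impute"]])
    write.csv(ci$table, emit(pth("cohort_clean.csv")), row.names = FALSE)
    write.csv(ci$removed, emit(pth("removed_subjects.csv")),
              row.names = FALSE)
    ci
  })

  clustered <- .stage("cluster", {
    X <- as.matrix(cleaned$table[, c("internalizing", "externalizing")])
    sel <- selectModel(X, KRange = config$KRange,
                       families = config$families,
                       seed = config$stageSeeds[["cluster"]],
                       tol = config$tol, nRestarts = config$nRestarts)
    asg <- mapAssign(sel$best, X)
    mdl <- sel$best
    jsonlite::write_json(list(
      family = mdl@family, K = mdl@K, weights = mdl@weights,
      means = mdl@means, variances = mdl@variances,
      loglik = mdl@loglik, m = mdl@m, n = mdl@n, bic = mdl@bic),
      emit(pth("model.json")), auto_unbox = TRUE, digits = NA)
    write.csv(cbind(data.frame(subject = cleaned$table$subject,
                               label = asg$labels),
                    round(asg$responsibilities, 6)),
              emit(pth("assignment.csv")), row.names = FALSE)
    write.csv(sel$ranking, emit(pth("ranking.csv")), row.names = FALSE)
    list(sel = sel, assignment = asg)
  })

  report <- .stage("characterize", {
    rep <- characterize(cleaned$table, clustered$assignment,
                        variant = config$variant, alpha = config$alpha)
    write.csv(rep, emit(pth("report.csv")), row.names = FALSE)
    jsonlite::write_json(rep, emit(pth("report.json")), digits = NA)
    rep
  })

  manifest <- .stage("manifest", {
    digests <- tools::md5sum(files)
    man <- list(
      package = "cpgmix",
      version = as.character(utils::packageVersion("cpgmix")),
      seed = config$seed,
      stage_seeds = as.list(config$stageSeeds),
      config = list(n = config$cohort$n, missingRate = config$missingRate,
                    nSequenced = config$nSequenced, nPairs = config$nPairs,
                    conversionEff = config$conversionEff,
                    errorRate = config$errorRate,
                    minCoverage = config$minCoverage,
                    minConversion = config$minConversion,
                    families = config$families, KRange = config$KRange,
                    variant = config$variant, alpha = config$alpha),
      files = as.list(setNames(unname(digests), basename(names(digests)))))
    jsonlite::write_json(man, pth("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
    man
  })

  invisible(list(dir = outDir, cohort = cohort,
                 profiles = callRes$profiles,
                 exclusions = callRes$exclusions,
                 model = clustered$sel$best,
                 ranking = clustered$sel$ranking,
                 assignment = clustered$assignment,
                 report = report, manifest = manifest))
}
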