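#' Run the full delta-radiomics pipeline
#'
#' Orchestrates the stages into one reproducible run: load (or generate)
#' the cohort, kidney-median normalize, extract features, build the
#' F5/F1 delta table, optionally run the drift-correlation and
#' spatial-stability analyses, screen every feature ratio against PFS by
#' univariate Cox with family-wise Holm correction, attempt a maximally
#' selected log-rank risk split on each significant feature, and fit
#' Kaplan-Meier curves per risk group. All outputs are written as CSV
#' under \code{outputDir} together with a run log (software version,
#' configuration echo, seed, per-patient exclusions) and a manifest with
#' a content hash per file. Patients are processed in sorted id order;
#' reruns with the same inputs, configuration and seed are byte
#' identical.
#'
#' @param input either a cohort directory (read via [loadCohort()]) or a
#'   [syntheticConfig()] (generated via [generateCohort()]).
#' @param outputDir output directory (created if needed).
#' @param normalization \code{"kidney_median"} (default) or
#'   \code{"none"}.
#' @param nBins intensity bins (default 64).
#' @param pair delta scan pair, default \code{c("F5", "F1")}.
#' @param stability run the spatial-stability analysis (default
#'   \code{TRUE}).
#' @param driftReport run the drift-correlation analysis (default
#'   \code{TRUE}).
#' @param radialDeltaMm stability perturbation radius (default 1.5 mm).
#' @param alpha significance level for screening and the split.
#' @param nPerm permutations for the split p-value (default 9999).
#' @param seed integer seed for the permutation stage (and recorded in
#'   the log).
#' @param format cohort directory format (\code{"nifti"} or
#'   \code{"dicom"}), used when \code{input} is a path.
#' @return List with \code{deltaTable}, \code{screen}, \code{splits},
#'   \code{stability}, \code{drift}, \code{riskGroups}, \code{files}
#'   (the manifest), invisibly.
#' @export
runPipeline <- function(input, outputDir,
                        normalization = c("kidney_median", "none"),
                        nBins = 64, pair = c("F5", "F1"),
                        stability = TRUE, driftReport = TRUE,
                        radialDeltaMm = 1.5, alpha = 0.05, nPerm = 9999,
                        seed = 1, format = "nifti") {
  normalization <- match.arg(normalization)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outputDir, "run_log.txt")
  logLines <- c(
    sprintf("DeltaRadiomics %s",
            as.character(utils::packageVersion("DeltaRadiomics"))),
    sprintf("run started %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed %d | normalization %s | nBins %d | pair %s/%s | alpha %g | nPerm %d",
            seed, normalization, nBins, pair[1], pair[2], alpha, nPerm))

  if (inherits(input, "SyntheticConfig")) {
    logLines <- c(logLines, sprintf("input: synthetic cohort (n = %d, seed %d)",
                                    input$nPatients, input$seed))
    cohort <- generateCohort(input)
    studies <- cohort$studies
  } else {
    logLines <- c(logLines, sprintf("input: cohort directory %s (%s)",
                                    input, format))
    studies <- loadCohort(input, format)
  }

  dt <- withCallingHandlers(
    buildDeltaTable(studies, normalization, nBins, pair),
    warning = function(w) {
      logLines <<- c(logLines, paste("warning:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  saveFeatureTable(dt, file.path(outputDir, "delta_table.csv"))

  sv <- do.call(rbind, lapply(studies, function(s) s@survival))
  screen <- coxScreen(dt, sv)
  write.csv(screen, file.path(outputDir, "screen.csv"), row.names = FALSE)

  stab <- NULL
  if (stability) {
    stab <- withCallingHandlers(
      stabilityReport(studies, radialDeltaMm, nBins, normalization),
      warning = function(w) {
        logLines <<- c(logLines, paste("warning:", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    write.csv(stab$perFeature, file.path(outputDir, "stability.csv"),
              row.names = FALSE)
  }

  drift <- NULL
  if (driftReport) {
    drift <- tryCatch(driftAnalysis(studies, normalized = FALSE),
                      error = function(e) {
                        logLines <<- c(logLines, paste("drift analysis skipped:",
                                                       conditionMessage(e)))
                        NULL
                      })
    if (!is.null(drift)) {
      write.csv(drift$perPatient, file.path(outputDir, "drift.csv"),
                row.names = FALSE)
      logLines <- c(logLines,
                    sprintf("drift correlation (raw): r = %.3f, p = %.3g",
                            drift$pearsonR, drift$pValue))
    }
  }

  sig <- screen[!is.na(screen$p_adjusted) & screen$p_adjusted < alpha, ]
  splits <- list(); riskRows <- list()
  svMatched <- sv[match(rownames(dt@values), sv$patient_id), ]
  for (j in seq_len(nrow(sig))) {
    feat <- sig$feature[j]
    rs <- bestSplit(dt@values[, feat], svMatched$pfs_days,
                    svMatched$event, alpha = alpha, nPerm = nPerm,
                    seed = seed)
    splits[[feat]] <- rs
    logLines <- c(logLines,
                  sprintf("split on %s: %s (threshold %.4g, permutation p %.4g)",
                          feat, if (rs$splitFound) "found" else "not significant",
                          rs$threshold, rs$permutationP))
    if (rs$splitFound) {
      riskRows[[feat]] <- data.frame(
        patient_id = rownames(dt@values), feature = feat,
        value = unname(dt@values[, feat]), group = rs$group,
        threshold = rs$threshold, stringsAsFactors = FALSE)
      kmPlotFile <- file.path(outputDir, sprintf("km_%s.pdf", feat))
      plotRiskGroups(svMatched$pfs_days, svMatched$event, rs$group,
                     feat, kmPlotFile)
    }
  }
  riskGroups <- if (length(riskRows)) do.call(rbind, riskRows) else
    data.frame(patient_id = character(0), feature = character(0),
               value = numeric(0), group = character(0),
               threshold = numeric(0))
  rownames(riskGroups) <- NULL
  write.csv(riskGroups, file.path(outputDir, "risk_groups.csv"),
            row.names = FALSE)

  if (nrow(dt@exclusions))
    logLines <- c(logLines, sprintf("excluded %s: %s",
                                    dt@exclusions$patient_id,
                                    dt@exclusions$reason))
  writeLines(logLines, logFile)

  outFiles <- setdiff(list.files(outputDir), "manifest.csv")
  manifest <- data.frame(
    file = outFiles,
    md5 = unname(tools::md5sum(file.path(outputDir, outFiles))),
    stringsAsFactors = FALSE)
  write.csv(manifest, file.path(outputDir, "manifest.csv"),
            row.names = FALSE)

  invisible(list(deltaTable = dt, screen = screen, splits = splits,
                 stability = stab, drift = drift,
                 riskGroups = riskGroups, files = manifest))
}

# Kaplan-Meier curves of the two risk groups written as a PDF figure.
plotRiskGroups <- function(times, events, group, feature, path) {
  grDevices::pdf(path, width = 6, height = 5)
  on.exit(grDevices::dev.off())
  fit <- survival::survfit(survival::Surv(times, events) ~ group)
  graphics::plot(fit, col = c("firebrick", "steelblue"), lwd = 2,
                 xlab = "Days from treatment",
                 ylab = "Progression-free survival",
                 main = sprintf("Risk groups by %s", feature))
  graphics::legend("topright", legend = sub("group=", "", names(fit$strata)),
                   col = c("firebrick", "steelblue"), lwd = 2, bty = "n")
}
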