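## Study orchestration: group/treatment comparisons and the full pipeline.

#' Compare two arms with Student's t-test
#'
#' Unpaired comparisons use the pooled-variance (classical Student) test;
#' paired comparisons test the difference scores.  Degenerate inputs are
#' handled explicitly: two constant arms with equal means give p = 1, and
#' a paired design with a constant non-zero difference is flagged
#' significant through an exact-difference branch (p = 0) rather than a
#' division by zero.
#'
#' @param valuesA,valuesB numeric vectors (matched ordering for paired).
#' @param paired paired test (default FALSE).
#' @param alpha significance level (default 0.05).
#' @param labels length-2 character vector naming the arms.
#' @return One-row data.frame: labels, per-arm n/mean/sd/se, t, df, p,
#'   paired, significant.
#' @examples
#' compareGroups(c(1, 2, 3), c(2, 3, 4))
#' @export
compareGroups <- function(valuesA, valuesB, paired = FALSE, alpha = 0.05,
                          labels = c("A", "B")) {
  a <- as.numeric(valuesA); b <- as.numeric(valuesB)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (paired && length(valuesA) != length(valuesB))
    iwireStop("iwirePairingError",
              "paired comparison requires matched arms of equal length")
  if (paired) {
    keep <- !is.na(valuesA) & !is.na(valuesB)
    a <- as.numeric(valuesA)[keep]; b <- as.numeric(valuesB)[keep]
  }
  if (length(a) < 2L || length(b) < 2L)
    iwireParamStop("need n >= 2 per arm")
  tt <- tryCatch(
    if (paired) stats::t.test(b, a, paired = TRUE)
    else stats::t.test(a, b, var.equal = TRUE),
    error = function(e) NULL)
  if (is.null(tt)) {  # essentially-constant data
    if (paired) {
      d <- b - a
      if (stats::sd(d) == 0 && mean(d) != 0) {
        tstat <- Inf; p <- 0; df <- length(d) - 1L
      } else { tstat <- 0; p <- 1; df <- length(d) - 1L }
    } else {
      if (mean(a) == mean(b)) { tstat <- 0; p <- 1 }
      else { tstat <- Inf; p <- 0 }
      df <- length(a) + length(b) - 2L
    }
  } else {
    tstat <- unname(tt$statistic); p <- tt$p.value
    df <- unname(tt$parameter)
  }
  data.frame(labelA = labels[1], labelB = labels[2],
             nA = length(a), nB = length(b),
             meanA = mean(a), meanB = mean(b),
             sdA = stats::sd(a), sdB = stats::sd(b),
             seA = stats::sd(a) / sqrt(length(a)),
             seB = stats::sd(b) / sqrt(length(b)),
             t = tstat, df = df, p = p, paired = paired,
             significant = p < alpha, alpha = alpha,
             stringsAsFactors = FALSE)
}

#' Summarize every recording of a generated study
#'
#' @param study a \code{SyntheticStudy}.
#' @param cal a \code{ProbeCalibration} (default: the design's known
#'   stiffness).
#' @param ... passed to \code{\link{summarizeRecording}}.
#' @return data.frame: the study manifest joined with the per-recording
#'   summary fields.
#' @export
summarizeStudy <- function(study, cal = probeCalibration(study@design@kProbe),
                           ...) {
  geom <- study@design@geometry
  rows <- lapply(seq_along(study@recordings), function(i) {
    m <- study@manifest[i, ]
    s <- summarizeRecording(study@recordings[[i]]@trace, cal, geom,
                            deltaStage = m$deltaStage,
                            recordingId = m$recordingId, ...)
    cbind(m[setdiff(names(m), "recordingId")], s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Internal: align pre/post arms of a summary table by construct x level.
.pairArms <- function(summaries, pre, post, value) {
  a <- summaries[summaries$treatment == pre, ]
  b <- summaries[summaries$treatment == post, ]
  key <- function(d) paste(d$constructId, d$targetForce, sep = "@")
  ka <- key(a); kb <- key(b)
  common <- intersect(ka, kb)
  missing <- union(setdiff(ka, kb), setdiff(kb, ka))
  a <- a[match(common, ka), ]
  b <- b[match(common, kb), ]
  list(pre = a, post = b, missing = missing)
}

#' Chronotropy analysis of a pre/post study
#'
#' Per-recording spontaneous frequencies with (i) a paired pre/post
#' comparison pooling all recordings (pairing unit = recording, i.e.
#' construct x tension level) and (ii) optionally a per-construct-mean
#' paired comparison, which avoids pseudo-replicating constructs.
#'
#' @param summaries output of \code{\link{summarizeStudy}} (or a compatible
#'   table with \code{constructId}, \code{treatment}, \code{targetForce},
#'   \code{beatRate}).
#' @param pre,post treatment labels of the two arms.
#' @param alpha significance level.
#' @param perConstruct also report the per-construct-mean comparison.
#' @return list: \code{table} (paired per-recording frequencies),
#'   \code{comparison} (recording-level paired test),
#'   \code{comparisonPerConstruct} (optional), \code{excluded}
#'   (unmatched recording keys).
#' @export
runChronotropyAnalysis <- function(summaries, pre = "control",
                                   post = "treated", alpha = 0.05,
                                   perConstruct = TRUE) {
  pp <- .pairArms(summaries, pre, post)
  if (length(pp$missing))
    warning("excluded unmatched pre/post recordings: ",
            paste(pp$missing, collapse = ", "))
  ok <- !is.na(pp$pre$beatRate) & !is.na(pp$post$beatRate)
  tab <- data.frame(constructId = pp$pre$constructId[ok],
                    targetForce = pp$pre$targetForce[ok],
                    ratePre = pp$pre$beatRate[ok],
                    ratePost = pp$post$beatRate[ok],
                    stringsAsFactors = FALSE)
  cmp <- compareGroups(tab$ratePre, tab$ratePost, paired = TRUE,
                       alpha = alpha, labels = c(pre, post))
  out <- list(table = tab, comparison = cmp, excluded = pp$missing)
  if (perConstruct) {
    agg <- stats::aggregate(cbind(ratePre, ratePost) ~ constructId, tab, mean)
    out$comparisonPerConstruct <- compareGroups(
      agg$ratePre, agg$ratePost, paired = TRUE, alpha = alpha,
      labels = paste0(c(pre, post), " (construct means)"))
  }
  out
}

#' Inotropy analysis of a pre/post study
#'
#' Per tension level, a paired comparison of developed force before and
#' after treatment across constructs, with the percent change and its
#' 95% confidence interval (t-based, on per-construct percent changes).
#'
#' @param summaries output of \code{\link{summarizeStudy}}.
#' @param pre,post treatment labels.
#' @param alpha significance level.
#' @return list: \code{perLevel} (data.frame: targetForce, meanPre,
#'   meanPost, pctChange, pctLo, pctHi, t, p, significant),
#'   \code{comparisons} (the underlying rows), \code{curvePre},
#'   \code{curvePost} (force-tension tables), \code{excluded}.
#' @export
runInotropyAnalysis <- function(summaries, pre = "control", post = "treated",
                                alpha = 0.05) {
  pp <- .pairArms(summaries, pre, post)
  levels <- sort(unique(pp$pre$targetForce))
  rows <- list(); cmps <- list()
  for (i in seq_along(levels)) {
    sel <- pp$pre$targetForce == levels[i]
    a <- pp$pre$devForceMean[sel]; b <- pp$post$devForceMean[sel]
    ok <- !is.na(a) & !is.na(b)
    cmp <- compareGroups(a[ok], b[ok], paired = TRUE, alpha = alpha,
                         labels = paste(c(pre, post), "level",
                                        format(levels[i])))
    pct <- 100 * (b[ok] - a[ok]) / a[ok]
    n <- length(pct)
    half <- if (n > 1) stats::qt(0.975, n - 1) * stats::sd(pct) / sqrt(n)
            else NA_real_
    rows[[i]] <- data.frame(
      targetForce = levels[i], n = n,
      meanPre = mean(a[ok]), meanPost = mean(b[ok]),
      pctChange = mean(pct), pctLo = mean(pct) - half,
      pctHi = mean(pct) + half,
      t = cmp$t, p = cmp$p, significant = cmp$significant)
    cmps[[i]] <- cmp
  }
  list(perLevel = do.call(rbind, rows),
       comparisons = do.call(rbind, cmps),
       curvePre = buildForceTensionCurve(pp$pre),
       curvePost = buildForceTensionCurve(pp$post),
       excluded = pp$missing)
}

#' Elasticity analysis per construct
#'
#' Builds each construct's diastolic stretch-stress curve across the stage
#' protocol (within one treatment arm) and fits Young's modulus.
#'
#' @param summaries output of \code{\link{summarizeStudy}}.
#' @param geom a \code{ConstructGeometry}.
#' @param treatment arm to use (default "control").
#' @param ... passed to \code{\link{fitYoungModulus}}.
#' @return data.frame, one row per construct, with the fit fields plus
#'   \code{constructId}; group mean, SD and SE are in the attributes
#'   \code{groupMean}, \code{groupSd}, \code{groupSe}.
#' @export
runElasticityAnalysis <- function(summaries, geom, treatment = "control",
                                  ...) {
  s <- summaries[summaries$treatment == treatment, ]
  out <- lapply(split(s, s$constructId), function(sc) {
    r <- tryCatch({
      curve <- buildStretchStress(sc, geom)
      fitYoungModulus(curve, ...)
    }, iwireError = function(e) NULL)
    if (is.null(r)) return(NULL)
    cbind(constructId = sc$constructId[1], r)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  e <- out$youngsModulus
  attr(out, "groupMean") <- mean(e)
  attr(out, "groupSd") <- stats::sd(e)
  attr(out, "groupSe") <- stats::sd(e) / sqrt(length(e))
  out
}

#' Paper-like demo configuration
#'
#' Two experimental lines under a rapamycin-style pre/post design (9 vs 8
#' constructs, stage protocol 0.424/0.530/0.636/0.742 mN) plus an
#' isoproterenol-style arm, with group means centered on the reference
#' phenotypes (control modulus 5.4 vs 6.8 kPa; control rates 0.76 vs 0.93
#' Hz; chronotropy multipliers 0.89/0.76 and 1.5/1.09; inotropy 1.25 for
#' the responsive line, 1.0 for the non-responsive line).
#'
#' @param seed master seed.
#' @param fps,duration acquisition overrides (defaults 180 fps, 14 s).
#' @return A config list accepted by \code{\link{runStudy}}.
#' @export
paperLikeConfig <- function(seed = 1L, fps = 180, duration = 14) {
  acq <- list(fps = fps, duration = duration, centroidNoiseSd = 2)
  list(
    seed = seed,
    geometry = list(halfLength = 5, diameter = 0.4, pixelScale = 10),
    calibration = list(kProbe = 0.5),
    acquisition = acq,
    arms = list(
      list(label = "CC3", nConstructs = 9L, cv = 0.2,
           params = list(youngsModulus = 5.4, beatRate = 0.76,
                         activeTension = 0.15),
           treatments = list(
             list(label = "control", inotropy = 1, chronotropy = 1),
             list(label = "rapamycin", inotropy = 1.25,
                  chronotropy = 0.89 / 0.76))),
      list(label = "TSP8-15", nConstructs = 8L, cv = 0.2,
           params = list(youngsModulus = 6.8, beatRate = 0.93,
                         activeTension = 0.15),
           treatments = list(
             list(label = "control", inotropy = 1, chronotropy = 1),
             list(label = "rapamycin", inotropy = 1, chronotropy = 1))),
      list(label = "CC3-iso", nConstructs = 8L, cv = 0.2,
           params = list(youngsModulus = 5.4, beatRate = 1.09,
                         activeTension = 0.15),
           treatments = list(
             list(label = "control", inotropy = 1, chronotropy = 1),
             list(label = "isoproterenol", inotropy = 1.3,
                  chronotropy = 1.5 / 1.09)))),
    analysis = list(alpha = 0.05,
                    targetForces = c(0.424, 0.530, 0.636, 0.742)))
}

# Internal: build a StudyDesign from one config arm.
.designFromArm <- function(arm, config, armIndex) {
  g <- config$geometry
  geom <- ConstructGeometry(halfLength = g$halfLength %||% 5,
                            diameter = g$diameter %||% 0.4,
                            pixelScale = g$pixelScale %||% 10)
  a <- config$acquisition %||% list()
  acq <- AcquisitionParams(fps = a$fps %||% 180,
                           duration = a$duration %||% 14,
                           centroidNoiseSd = a$centroidNoiseSd %||% 2)
  p <- arm$params %||% list()
  params <- do.call(TissueParams, p)
  tr <- do.call(rbind, lapply(arm$treatments, function(x)
    data.frame(label = x$label, inotropy = x$inotropy,
               chronotropy = x$chronotropy, stringsAsFactors = FALSE)))
  StudyDesign(label = arm$label, params = params,
              cv = arm$cv %||% 0.2, nConstructs = arm$nConstructs,
              targetForces = config$analysis$targetForces %||%
                c(0.424, 0.530, 0.636, 0.742),
              treatments = tr,
              kProbe = config$calibration$kProbe %||% 0.5,
              geometry = geom, acquisition = acq,
              seed = seedStream(config$seed %||% 1L, 1000L * armIndex))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full simulated study from a configuration
#'
#' Validates the configuration, generates every arm's recordings, analyzes
#' them (per-recording summaries, chronotropy, per-level inotropy,
#' force-tension curves, per-construct elasticity), performs the paired
#' pre/post and unpaired between-line comparisons, and assembles a
#' \code{StudyReport}.  Fully seeded: the same configuration and seed give
#' byte-identical tables.  If \code{outDir} is given, tables are written as
#' CSV and the comparisons as JSON.
#'
#' @param config a config list (see \code{\link{paperLikeConfig}}) or the
#'   path to a YAML file with the same structure.
#' @param outDir optional output directory.
#' @return A \code{\link{StudyReport-class}}.
#' @export
runStudy <- function(config, outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$arms) || !length(config$arms))
    iwireStop("iwireConfigError", "config must define at least one arm")
  for (arm in config$arms)
    if (is.null(arm$nConstructs) || arm$nConstructs < 1)
      iwireStop("iwireConfigError",
                sprintf("arm '%s' has no constructs", arm$label %||% "?"))
  alpha <- config$analysis$alpha %||% 0.05
  summaries <- list(); chron <- list(); ino <- list(); ftc <- list()
  elas <- list(); cmps <- list(); qc <- list()
  for (i in seq_along(config$arms)) {
    arm <- config$arms[[i]]
    design <- .designFromArm(arm, config, i)
    study <- generateStudy(design)
    s <- summarizeStudy(study)
    summaries[[arm$label]] <- s
    noBeat <- s[s$noBeat, c("recordingId", "group", "treatment")]
    if (nrow(noBeat)) {
      noBeat$reason <- "no beats detected"
      qc[[arm$label]] <- noBeat
    }
    trLabels <- design@treatments$label
    ftc[[arm$label]] <- lapply(stats::setNames(trLabels, trLabels),
      function(tl) buildForceTensionCurve(s[s$treatment == tl, ]))
    elas[[arm$label]] <- runElasticityAnalysis(s, design@geometry,
                                               treatment = trLabels[1])
    if (length(trLabels) >= 2L) {
      ch <- runChronotropyAnalysis(s, pre = trLabels[1], post = trLabels[2],
                                   alpha = alpha)
      ch$comparison$labelA <- paste(arm$label, ch$comparison$labelA)
      ch$comparison$labelB <- paste(arm$label, ch$comparison$labelB)
      chron[[arm$label]] <- ch
      io <- runInotropyAnalysis(s, pre = trLabels[1], post = trLabels[2],
                                alpha = alpha)
      ino[[arm$label]] <- io
      cmps[[paste0(arm$label, "_chronotropy")]] <- ch$comparison
      cmps[[paste0(arm$label, "_inotropy")]] <- io$comparisons
    }
  }
  # between-line unpaired comparison of control-arm beating rates
  if (length(summaries) >= 2L) {
    l1 <- names(summaries)[1]; l2 <- names(summaries)[2]
    ctrl <- function(l) {
      s <- summaries[[l]]
      s$beatRate[s$treatment == "control" & !is.na(s$beatRate)]
    }
    cmps[["between_lines_control_rate"]] <-
      compareGroups(ctrl(l1), ctrl(l2), paired = FALSE, alpha = alpha,
                    labels = paste(c(l1, l2), "control rate"))
  }
  allSum <- do.call(rbind, summaries)
  rownames(allSum) <- NULL
  report <- new("StudyReport",
    summaries = allSum, forceTension = ftc, chronotropy = chron,
    inotropy = ino,
    elasticity = {
      e <- do.call(rbind, lapply(names(elas), function(l)
        cbind(group = l, elas[[l]])))
      rownames(e) <- NULL; e
    },
    comparisons = { d <- do.call(rbind, cmps); rownames(d) <- NULL; d },
    qcExclusions = if (length(qc)) do.call(rbind, qc) else
      data.frame(recordingId = character(), group = character(),
                 treatment = character(), reason = character()),
    config = config, seed = as.integer(config$seed %||% 1L),
    version = as.character(utils::packageVersion("iwire")))
  if (!is.null(outDir)) writeStudyReport(report, outDir)
  report
}

#' Write a study report bundle
#'
#' Emits \code{summaries.csv}, \code{elasticity.csv},
#' \code{comparisons.csv}, \code{qc_exclusions.csv}, per-arm force-tension
#' CSVs and a \code{report.json} with configuration echo, seed and
#' version.
#'
#' @param report a \code{StudyReport}.
#' @param outDir output directory (created if needed).
#' @return Invisibly, \code{outDir}.
#' @export
writeStudyReport <- function(report, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.csv(df, file.path(outDir, name), row.names = FALSE,
                     quote = FALSE)
  w(report@summaries, "summaries.csv")
  w(report@elasticity, "elasticity.csv")
  w(report@comparisons, "comparisons.csv")
  w(report@qcExclusions, "qc_exclusions.csv")
  for (arm in names(report@forceTension))
    for (tl in names(report@forceTension[[arm]]))
      w(report@forceTension[[arm]][[tl]],
        sprintf("force_tension_%s_%s.csv", arm, tl))
  jsonlite::write_json(
    list(seed = report@seed, version = report@version,
         config = report@config),
    file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}
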