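## End-to-end batch pipeline: segment pre/post slice pairs, compute damage
## records and group summaries, fit the deformation-rate models, and render
## a report.  Failures are isolated per sample (batch CT processing must
## tolerate bad slices), never silently dropped.

.paramsToList <- function(p) {
  list(thresholdMethod = p@thresholdMethod, thresholdValue = p@thresholdValue,
       erosionCoreRadius = as.list(p@erosionCoreRadius),
       refineDilateRadius = p@refineDilateRadius,
       refineErodeRadius = p@refineErodeRadius,
       connectivity = p@connectivity,
       blockageFractionThreshold = p@blockageFractionThreshold,
       seedRule = p@seedRule)
}

#' Run the damage-quantification pipeline
#'
#' Segments every pre/post image pair with [extractCavity()], computes the
#' per-sample damage rate, summarizes per deformation group, and fits the
#' deformation-damage regression (plus the deformation-decay regression
#' when decay data are supplied).  A failing sample is recorded in the
#' failure table with its failing stage and excluded from the statistics;
#' all other samples proceed.
#'
#' @param samples either a data.frame with columns \code{sample_id},
#'   \code{deformation_mm}, \code{pre_path}, \code{post_path} (TIFF paths,
#'   loaded with [loadSlice()]) or a list of [PhantomPair-class] objects.
#' @param params a [SegmentationParams-class] used for all samples.
#' @param decayTable optional data.frame with \code{deformation_mm} and
#'   either \code{decay_rate} or \code{decayed_count} (+ optional
#'   \code{group_size}, default 20) for the decay regression.
#' @param includeControl include deformation 0 groups in the regressions
#'   (default FALSE: the study's fits use the 4-16 mm treatment groups).
#' @param sectionKind section kind for images loaded from paths.
#' @param seed seed recorded in the provenance (the segmentation itself is
#'   deterministic).
#' @return A [RunReport-class].
#' @examples
#' pairs <- lapply(1:2, function(i)
#'   generatePair(PhantomSpec(imageSize = 128, fruitRadius = 52,
#'                            peelThickness = 6, cavityRadius = 16,
#'                            noiseSd = 0, seed = i), deformationMm = 8))
#' rep <- runPipeline(pairs, SegmentationParams(erosionCoreRadius = 5))
#' @export
runPipeline <- function(samples, params = SegmentationParams(),
                        decayTable = NULL, includeControl = FALSE,
                        sectionKind = "cross", seed = 1) {
  if (is.data.frame(samples)) {
    stopifnot(all(c("sample_id", "deformation_mm", "pre_path", "post_path")
                  %in% names(samples)))
    n <- nrow(samples)
    getPair <- function(i) list(
      id = samples$sample_id[i], deformation = samples$deformation_mm[i],
      pre = loadSlice(samples$pre_path[i], sectionKind),
      post = loadSlice(samples$post_path[i], sectionKind))
  } else if (is.list(samples) && length(samples) &&
             all(vapply(samples, is, logical(1), "PhantomPair"))) {
    n <- length(samples)
    ids <- if (!is.null(names(samples)) && all(nzchar(names(samples))))
      names(samples) else sprintf("sample_%03d", seq_len(n))
    getPair <- function(i) list(
      id = ids[i], deformation = samples[[i]]@deformationMm,
      pre = samples[[i]]@preImage, post = samples[[i]]@postImage)
  } else stop("'samples' must be a sample table or a list of PhantomPair")
  if (n == 0L) stop("empty sample list")

  records <- failures <- NULL
  for (i in seq_len(n)) {
    rec <- tryCatch({
      s <- getPair(i)
      pre <- extractCavity(s$pre, params)
      post <- extractCavity(s$post, params)
      data.frame(sample_id = s$id, deformation_mm = s$deformation,
                 S1 = pre@areaPx, S2 = post@areaPx,
                 A = damageRate(pre@areaPx, post@areaPx),
                 blocked_pre = pre@blocked, blocked_post = post@blocked)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      failures <- rbind(failures, data.frame(
        sample_id = tryCatch(getPair(i)$id, error = function(e)
          sprintf("sample_%03d", i)),
        stage = sub(":.*$", "", conditionMessage(rec)),
        message = conditionMessage(rec)))
    } else records <- rbind(records, rec)
  }
  if (is.null(records))
    stop("all ", n, " samples failed; first failure: ", failures$message[1])
  if (is.null(failures))
    failures <- data.frame(sample_id = character(), stage = character(),
                           message = character())

  summaries <- summarizeDamage(records)
  models <- list()
  fitGroups <- if (includeControl) summaries
               else summaries[summaries$deformation_mm > 0, , drop = FALSE]
  if (nrow(fitGroups) >= 2L)
    models$Y1 <- fitRateModel(fitGroups$deformation_mm, fitGroups$mean_A,
                              response = "Y1")
  if (!is.null(decayTable)) {
    dt <- decayTable
    if (!"decay_rate" %in% names(dt)) {
      gs <- if ("group_size" %in% names(dt)) dt$group_size else 20
      dt$decay_rate <- decayRate(dt$decayed_count, gs)
    }
    if (!includeControl) dt <- dt[dt$deformation_mm > 0, , drop = FALSE]
    if (nrow(dt) >= 2L)
      models$Y2 <- fitRateModel(dt$deformation_mm, dt$decay_rate,
                                response = "Y2")
  }

  new("RunReport", records = records, summaries = summaries,
      models = models, failures = failures,
      provenance = list(seed = seed, params = .paramsToList(params),
                        n_samples = n, n_failed = nrow(failures),
                        version = as.character(utils::packageVersion("pulpscan")),
                        timestamp = format(Sys.time(), tz = "UTC")))
}

#' Render a run report as text
#'
#' A damage/decay summary table (mean +/- sd per deformation, two decimals)
#' followed by the fitted regression equations; omits the equation block
#' when no models were fitted.  The rendered body is deterministic for a
#' given report (timestamps are excluded).
#'
#' @param report a [RunReport-class].
#' @return Character vector of lines.
#' @export
renderReport <- function(report) {
  stopifnot(is(report, "RunReport"))
  s <- report@summaries
  lines <- c("Damage rate by compression deformation",
             "Deformation(mm)  n   Damage Rate(%)")
  lines <- c(lines, sprintf("%14g  %2d   %.2f ± %.2f",
                            s$deformation_mm, s$n, s$mean_A, s$sd_A))
  if (any(s$any_negative))
    lines <- c(lines, "note: some samples had negative damage rates (cavity shrinkage)")
  if (nrow(report@failures))
    lines <- c(lines, sprintf("failed samples: %d", nrow(report@failures)))
  if (length(report@models)) {
    lines <- c(lines, "", "Fitted deformation-rate models")
    for (m in report@models)
      lines <- c(lines, sprintf("  %s  (R^2 = %.2f, slope p = %.3g, n = %d)",
                                formatModelEquation(m), m@rSquared,
                                m@slopePValue, as.integer(m@n)))
  }
  lines
}

#' Write a run report to disk
#'
#' Writes \code{records.csv}, \code{summaries.csv}, \code{failures.csv},
#' \code{models.json} (coefficients, statistics and provenance) and the
#' rendered \code{report.txt} into a directory.
#'
#' @param report a [RunReport-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report@records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(report@summaries, file.path(dir, "summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(report@failures, file.path(dir, "failures.csv"),
                   row.names = FALSE)
  models <- lapply(report@models, function(m) list(
    response = m@response, equation = formatModelEquation(m),
    slope = m@slope, intercept = m@intercept, r_squared = m@rSquared,
    slope_p_value = m@slopePValue, n = m@n))
  jsonlite::write_json(list(models = models,
                            provenance = report@provenance),
                       file.path(dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(renderReport(report), file.path(dir, "report.txt"))
  invisible(dir)
}
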