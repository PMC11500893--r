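#' Assemble the robustness report of a feature table
#'
#' From a complete lesions x settings x discretizations feature design
#' (native resampling rows of a [featureTable()]), computes per index:
#' relative differences of every non-reference setting against the
#' reference; the inter-setting CV per lesion and discretization with its
#' category; the absolute-agreement ICC across settings with lesions as
#' targets; and Wilcoxon rank-sum p-values between each lesion pair (the
#' eight per-setting values of one index per group), Benjamini-Hochberg
#' adjusted jointly over all index x lesion-pair tests within each
#' discretization.
#'
#' @param ft feature table (data.frame from [featureTable()]).
#' @param reference reference setting code (default `"D"`; the choice is
#'   arbitrary and configurable).
#' @param resampling which resampling level of the table to analyse.
#' @return a [RobustnessReport-class].
#' @examples
#' \donttest{
#' rep <- buildReport(featureTable(acquireAll(seed = 1)))
#' nrow(cvTable(rep))  # 276
#' }
#' @export
buildReport <- function(ft, reference = "D", resampling = "native") {
  stopifnot(is.data.frame(ft))
  ft <- ft[ft$resampling == resampling, , drop = FALSE]
  if (!nrow(ft)) stopf("no rows at resampling level '%s'", resampling)
  feats <- featureCatalogue()$name
  feats <- feats[feats %in% names(ft)]
  lesions <- sort(unique(ft$lesion))
  settings <- sort(unique(ft$setting))
  discs <- sort(unique(ft$discretization))
  if (!reference %in% settings)
    stopf("reference setting '%s' not present", reference)

  cell <- function(lesion, disc) {
    sub <- ft[ft$lesion == lesion & ft$discretization == disc, , drop = FALSE]
    sub[match(settings, sub$setting), , drop = FALSE]
  }

  rd <- NULL; cv <- NULL; icc <- NULL; pv <- NULL
  for (disc in discs) {
    for (les in lesions) {
      sub <- cell(les, disc)
      if (anyNA(sub$setting))
        warnf("missing settings for lesion %s (%s); statistics use available cells",
              les, disc)
      for (f in feats) {
        vals <- sub[[f]]
        ref <- vals[settings == reference]
        oth <- settings != reference
        rdv <- suppressWarnings(
          if (is.na(ref) || ref == 0) rep(NA_real_, sum(oth))
          else relativeDifference(vals[oth], ref))
        rd <- rbind(rd, data.frame(
          feature = f, lesion = les, discretization = disc,
          setting = settings[oth], rd_percent = rdv,
          stringsAsFactors = FALSE))
        cvv <- suppressWarnings(interSettingCV(vals[!is.na(vals)]))
        cv <- rbind(cv, data.frame(
          feature = f, lesion = les, discretization = disc,
          cv_percent = cvv$cv, category = cvv$category,
          stringsAsFactors = FALSE))
      }
    }
    # ICC: lesions are rows (targets), settings are raters
    for (f in feats) {
      m <- do.call(rbind, lapply(lesions, function(les) cell(les, disc)[[f]]))
      res <- suppressWarnings(iccAbsoluteAgreement(m))
      icc <- rbind(icc, data.frame(
        feature = f, discretization = disc, icc = res$icc,
        category = res$category, stringsAsFactors = FALSE))
    }
    # lesion-pair tests, BH-adjusted within this discretization
    pairRows <- NULL
    for (f in feats) {
      for (i in seq_len(length(lesions) - 1)) {
        for (j in seq(i + 1, length(lesions))) {
          va <- cell(lesions[i], disc)[[f]]
          vb <- cell(lesions[j], disc)[[f]]
          p <- wilcoxonRankSum(va[!is.na(va)], vb[!is.na(vb)])
          pairRows <- rbind(pairRows, data.frame(
            feature = f, discretization = disc,
            lesion_a = lesions[i], lesion_b = lesions[j], p_raw = p,
            stringsAsFactors = FALSE))
        }
      }
    }
    pairRows$p_adjusted <- bhFdr(pairRows$p_raw)
    pv <- rbind(pv, pairRows)
  }

  new("RobustnessReport", rd = rd, cv = cv, icc = icc, pvalues = pv,
      reference = reference)
}

#' Write a robustness report as CSV files
#'
#' Emits `rd.csv`, `cv.csv`, `icc.csv` and `pvalues.csv` into `dir`.
#'
#' @param report a [RobustnessReport-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeReport <- function(report, dir) {
  stopifnot(is(report, "RobustnessReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(rd = file.path(dir, "rd.csv"), cv = file.path(dir, "cv.csv"),
             icc = file.path(dir, "icc.csv"),
             pvalues = file.path(dir, "pvalues.csv"))
  utils::write.csv(report@rd, paths["rd"], row.names = FALSE)
  utils::write.csv(report@cv, paths["cv"], row.names = FALSE)
  utils::write.csv(report@icc, paths["icc"], row.names = FALSE)
  utils::write.csv(report@pvalues, paths["pvalues"], row.names = FALSE)
  invisible(paths)
}

#' Heat-map view of a report table
#'
#' Convenience heat map (features x design cells) of the CV, RD magnitude
#' or adjusted p-values, in the style of the study figures. Requires the
#' `pheatmap` package.
#'
#' @param report a [RobustnessReport-class].
#' @param table `"cv"`, `"rd"` or `"pvalues"`.
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
reportHeatmap <- function(report, table = c("cv", "rd", "pvalues"), ...) {
  table <- match.arg(table)
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stopf("'pheatmap' is required for heat maps")
  df <- switch(table, cv = report@cv, rd = report@rd, pvalues = report@pvalues)
  valueCol <- switch(table, cv = "cv_percent", rd = "rd_percent",
                     pvalues = "p_adjusted")
  colKey <- switch(table,
                   cv = paste(df$lesion, df$discretization, sep = "_"),
                   rd = paste(df$lesion, df$discretization, df$setting,
                              sep = "_"),
                   pvalues = paste(df$lesion_a, df$lesion_b,
                                   df$discretization, sep = "_"))
  m <- tapply(df[[valueCol]], list(df$feature, colKey), function(x) x[1])
  m <- m[match(featureCatalogue()$name, rownames(m)), , drop = FALSE]
  ph <- pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                           ...)
  invisible(ph)
}
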