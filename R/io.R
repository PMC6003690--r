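#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list: `data` (numeric array), `voxelSize` (mm), `affine`.
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)),
       voxelSize = RNifti::pixdim(img),
       affine = RNifti::xform(img))
}

#' Write a volume to NIfTI-1
#'
#' @param data numeric array (3D or 4D) or a [ParameterMap-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxelSize voxel size in mm (taken from a ParameterMap input).
#' @return the path, invisibly.
#' @export
writeVolume <- function(data, path, voxelSize = 2) {
  if (is(data, "ParameterMap")) {
    voxelSize <- data@voxelSize
    data <- data@data
  }
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check that two volumes of one subject share a grid
#'
#' @param a,b lists from [readVolume()] (or arrays).
#' @param nameA,nameB labels used in the error message.
#' @return TRUE invisibly; hard error naming both inputs on mismatch.
#' @export
checkSameGrid <- function(a, b, nameA = "volume A", nameB = "volume B") {
  da <- if (is.list(a)) dim(a$data) else dim(a)
  db <- if (is.list(b)) dim(b$data) else dim(b)
  if (!identical(da, db))
    stop("grid mismatch between ", nameA, " (", paste(da, collapse = "x"),
         ") and ", nameB, " (", paste(db, collapse = "x"), ")")
  invisible(TRUE)
}

#' Write a table as TSV / read a covariate table
#'
#' Tables are written tab-separated with header, missing cells encoded as
#' "NA". Covariate files must contain a unique `subject` column, numeric
#' `age` and `gender` in {M, F}.
#'
#' @param table data.frame.
#' @param path file path.
#' @return `writeTable`: the path invisibly; `readCovariates`: data.frame.
#' @export
writeTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeTable
#' @export
readCovariates <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA")
  if (!all(c("subject", "age", "gender") %in% colnames(tab)))
    stop("covariates need columns subject, age, gender")
  if (anyDuplicated(tab$subject))
    stop("duplicate subject id: ",
         tab$subject[duplicated(tab$subject)][1])
  bad <- which(!is.na(tab$age) & !is.finite(suppressWarnings(as.numeric(tab$age))))
  if (length(bad)) stop("non-numeric age in row ", bad[1])
  tab$age <- as.numeric(tab$age)
  badg <- which(!is.na(tab$gender) & !tab$gender %in% c("M", "F"))
  if (length(badg)) stop("gender must be M or F (row ", badg[1], ")")
  tab
}

#' Run the full phantom-to-statistics pipeline
#'
#' Generates (or accepts) a cohort, smooths and normalizes the maps, builds
#' the group matrix, runs spatial ICA at the requested model orders,
#' selects WM components, matches them across orders, averages them into a
#' subtype atlas with Fleiss kappa, extracts fingerprints from the
#' unsmoothed maps, and runs the statistics. All thresholds, the seed and
#' the model orders are serialized into `provenance.json` in the output
#' directory together with the result tables; the run is deterministic for
#' a fixed seed.
#'
#' @param outDir output directory (created if needed).
#' @param cohort a [PhantomCohort-class]; generated from `spec` when NULL.
#' @param spec a [phantomSpec()] used when `cohort` is NULL.
#' @param orders ICA model orders.
#' @param seed decomposition seed.
#' @param fwhm_mm smoothing kernel FWHM (mm).
#' @param zDisplay,zExtract,clusterK,ratioMin,overlapMin,wmPMin thresholds.
#' @param writeVolumes also write subtype z-maps as NIfTI.
#' @return list with the atlas, selection tables, fingerprint table and
#'   statistics (invisibly also written to `outDir`).
#' @export
runPipeline <- function(outDir, cohort = NULL, spec = phantomSpec(),
                        orders = c(6L, 8L, 10L, 12L), seed = 17L,
                        fwhm_mm = 5, zDisplay = 2, zExtract = 3.2,
                        clusterK = 200L, ratioMin = 1.5, overlapMin = 0.5,
                        wmPMin = 0.8, writeVolumes = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cohort)) cohort <- generatePhantomCohort(spec)
  gt <- cohort@groundTruth
  mask <- gt$brainMask
  prep <- prepareMapsForDecomposition(cohort, mask, fwhm_mm = fwhm_mm)
  gm <- buildGroupMatrix(prep$records, mask)
  runs <- list(); selTables <- list()
  for (N in orders) {
    cs <- runSpatialIca(gm, N, seed = seed + N)
    sel <- selectWmComponents(cs, gt$pWM, zThresh = zDisplay,
                              overlapMin = overlapMin, ratioMin = ratioMin)
    runs[[as.character(N)]] <- sel
    st <- attr(sel, "allStats")
    st$modelOrder <- N
    selTables[[as.character(N)]] <- st
  }
  matched <- matchComponentsAcrossRuns(unname(runs))
  atlas <- averageMatchedComponents(matched, zDisplay = zDisplay,
                                    zExtract = zExtract, clusterK = clusterK)
  fp <- extractFingerprintTable(atlas, cohort, z_min = zExtract,
                                wm_p_min = wmPMin)
  paired <- pairedSubtypeTests(fp)
  dcon <- cohensDContributions(fp)
  xcor <- crossCorrelationMatrix(fp)
  glm <- tryCatch(glmSubtypeAgeGender(fp),
                  error = function(e) list(error = conditionMessage(e)))
  tover <- if (!is.null(gt$tracts))
    tractOverlapProportions(atlas, gt$tracts, zThresh = zDisplay) else NULL
  ## serialize
  writeTable(do.call(rbind, selTables), file.path(outDir, "selection.tsv"))
  writeTable(kappaTable(atlas), file.path(outDir, "kappa.tsv"))
  writeTable(fp, file.path(outDir, "fingerprints.tsv"))
  writeTable(paired, file.path(outDir, "paired_tests.tsv"))
  writeTable(dcon$d, file.path(outDir, "cohens_d.tsv"))
  if (!is.null(tover))
    writeTable(data.frame(tract = rownames(tover), tover),
               file.path(outDir, "tract_overlap.tsv"))
  prov <- list(seed = seed, orders = orders,
               thresholds = list(zDisplay = zDisplay, zExtract = zExtract,
                                 clusterK = clusterK, ratioMin = ratioMin,
                                 overlapMin = overlapMin, wmPMin = wmPMin,
                                 fwhm_mm = fwhm_mm),
               nSubjects = length(cohort@records),
               nRows = nrow(matrixData(gm)),
               nSelected = as.list(vapply(runs, function(r) nrow(r@stats),
                                          integer(1))),
               package = tryCatch(
                 as.character(utils::packageVersion("wmsubtypes")),
                 error = function(e) "devel"),
               rversion = R.version.string)
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (writeVolumes) {
    for (nm in names(atlas@zMaps)) {
      v <- atlas@zMaps[[nm]]
      v[is.na(v)] <- 0
      writeVolume(v, file.path(outDir, paste0(nm, "_z.nii.gz")),
                  cohort@spec$voxel_size_mm)
    }
  }
  invisible(list(atlas = atlas, groupMatrix = gm, runs = runs,
                 selection = do.call(rbind, selTables), matched = matched,
                 fingerprints = fp, paired = paired, cohensD = dcon,
                 crossCorrelation = xcor, glm = glm,
                 tractOverlap = tover, provenance = prov))
}
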