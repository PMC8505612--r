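#' Configuration of a full synthetic-cohort experiment
#'
#' Describes the whole study design: cohort size, phantom and motion
#' parameters, the perturbation recipe, the extraction-parameter grid for
#' the test--retest arm, the fixed combination for the perturbed arm,
#' metrics, classification thresholds, and habitat settings. Every
#' stochastic stage derives its seed from `seed`.
#'
#' @param nLesions Number of synthetic patients (test--retest pairs).
#' @param phantom A [phantomSpec()] template (per-lesion seeds and small
#'   size jitters are derived automatically).
#' @param motion A [rigidMotionSpec()].
#' @param perturbation A [perturbationSpec()].
#' @param binWidths,kernelRadii Extraction grid for the reproducibility arm.
#' @param fixedCombo Named vector `c(B = , R = )` for the repeatability and
#'   perturbed arms.
#' @param features Feature names to extract.
#' @param cccThreshold,gammaThreshold Repeatability thresholds.
#' @param habitatKs Cluster counts for the habitat arm.
#' @param nComponents Principal components for habitats.
#' @param metrics Agreement metrics to compute in the repeatability arms.
#' @param registrationResidualMm,registrationResidualDeg Residual
#'   misalignment left by the emulated rigid registration of the retest
#'   (see [alignRetest()]).
#' @param perturbedArm If `TRUE` (default), include the perturbed-surrogate
#'   arm at the fixed combination.
#' @param runGrid If `TRUE`, run the full (B, R) reproducibility grid.
#' @param padMm Crop padding in mm.
#' @param seed Master seed.
#' @return An `experimentConfig` list.
#' @export
experimentConfig <- function(nLesions = 10L, phantom = phantomSpec(),
                             motion = rigidMotionSpec(),
                             perturbation = perturbationSpec(),
                             binWidths = c(12, 25),
                             kernelRadii = c(1, 3, 5),
                             fixedCombo = c(B = 12, R = 1),
                             features = glcmFeatureNames(),
                             cccThreshold = 0.9, gammaThreshold = 95,
                             habitatKs = c(3L, 5L), nComponents = 5L,
                             metrics = c("ccc", "pcorr", "ssim",
                                         "gamma_pass"),
                             registrationResidualMm = c(0.3, -0.2, 0.25),
                             registrationResidualDeg = 0.5,
                             perturbedArm = TRUE, runGrid = FALSE,
                             padMm = 10, seed = 1L) {
  structure(list(nLesions = as.integer(nLesions), phantom = phantom,
                 motion = motion, perturbation = perturbation,
                 binWidths = binWidths, kernelRadii = kernelRadii,
                 fixedCombo = fixedCombo, features = features,
                 cccThreshold = cccThreshold,
                 gammaThreshold = gammaThreshold,
                 habitatKs = as.integer(habitatKs),
                 nComponents = as.integer(nComponents),
                 metrics = metrics,
                 registrationResidualMm = registrationResidualMm,
                 registrationResidualDeg = registrationResidualDeg,
                 perturbedArm = isTRUE(perturbedArm),
                 runGrid = isTRUE(runGrid), padMm = padMm,
                 seed = as.integer(seed)),
            class = "experimentConfig")
}

#' Enumerate every feature-map extraction task of a design
#'
#' Deterministically lists one task per (lesion, feature, arm, B, R):
#' the test and retest scans at every grid combination, plus the perturbed
#' scan at the fixed combination. The total is returned before any
#' computation, for design bookkeeping.
#'
#' @param cfg An [experimentConfig()]. `cfg$features` may also be a plain
#'   character vector of feature labels for counting purposes.
#' @return A tibble (lesion, feature, arm, B, R) with attribute `"total"`;
#'   errors on duplicate task keys.
#' @examples
#' cfg <- experimentConfig(nLesions = 1, features = "JointEnergy",
#'                         binWidths = 12, kernelRadii = 1)
#' nrow(enumerateTasks(cfg))   # 2 grid tasks + 1 perturbed task
#' @export
enumerateTasks <- function(cfg) {
  combos <- expand.grid(B = cfg$binWidths, R = cfg$kernelRadii,
                        KEEP.OUT.ATTRS = FALSE)
  lesions <- seq_len(cfg$nLesions)
  feats <- cfg$features
  grid <- expand.grid(lesion = lesions, feature = feats,
                      arm = c("test", "retest"),
                      combo = seq_len(nrow(combos)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gridTasks <- tibble::tibble(
    lesion = grid$lesion, feature = grid$feature, arm = grid$arm,
    B = combos$B[grid$combo], R = combos$R[grid$combo])
  tasks <- gridTasks
  if (cfg$perturbedArm) {
    pert <- expand.grid(lesion = lesions, feature = feats,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tasks <- rbind(tasks, tibble::tibble(
      lesion = pert$lesion, feature = pert$feature, arm = "perturbed",
      B = unname(cfg$fixedCombo["B"]), R = unname(cfg$fixedCombo["R"])))
  }
  key <- paste(tasks$lesion, tasks$feature, tasks$arm, tasks$B, tasks$R)
  if (anyDuplicated(key)) stop("duplicate task keys in the design")
  ord <- order(tasks$lesion, tasks$feature, tasks$arm, tasks$B, tasks$R)
  tasks <- tasks[ord, ]
  attr(tasks, "total") <- nrow(tasks)
  tasks
}

#' Simulate a cohort of synthetic test--retest--perturbed lesion triplets
#'
#' For each lesion: a phantom is generated from the template (with a small
#' seeded jitter of the semi-axes, so lesions differ in size and shape),
#' the retest is acquired through the rigid motion plus independent noise
#' and aligned back through the known transform (emulating rigid
#' registration residuals), all volumes are cropped to the padded lesion
#' bounding box, and the perturbed surrogate is generated from the cropped
#' test image.
#'
#' @param cfg An [experimentConfig()].
#' @return List of lesions, each with `id`, `test`, `retest`, `perturbed`,
#'   `mask`, `truth`.
#' @export
simulateCohort <- function(cfg) {
  seeds <- deriveSeeds(cfg$seed, 3L * cfg$nLesions)
  lapply(seq_len(cfg$nLesions), function(i) {
    sPh <- seeds[3 * i - 2]
    sJit <- seeds[3 * i - 1]
    sRe <- seeds[3 * i]
    jitter <- withSeed(sJit, stats::runif(3, 0.85, 1.1))
    spec <- cfg$phantom
    spec$lesionSemiaxesMm <- spec$lesionSemiaxesMm * jitter
    spec$seed <- sPh
    spec <- do.call(phantomSpec, unclass(spec))
    ph <- generatePhantom(spec)
    retestFull <- alignRetest(
      generateRetest(ph$image, cfg$motion, seed = sRe, mask = ph$mask),
      residualShiftMm = cfg$registrationResidualMm,
      residualAngleDeg = cfg$registrationResidualDeg)
    cropT <- cropToLesion(ph$image, ph$mask, cfg$padMm)
    cropR <- cropToLesion(retestFull, ph$mask, cfg$padMm)
    truthCrop <- cropToLesion(
      ImageVolume(array(as.numeric(habitatLabels(ph$truth)),
                        dim(habitatLabels(ph$truth))),
                  spacing = spacingMm(ph$image)), ph$mask, cfg$padMm)$image
    pspec <- cfg$perturbation
    pspec$seed <- sRe
    perturbed <- makeSyntheticRetest(cropT$image, cropT$mask,
                                     do.call(perturbationSpec,
                                             unclass(pspec)))
    list(id = sprintf("phantom%02d", i), test = cropT$image,
         retest = cropR$image, perturbed = perturbed, mask = cropT$mask,
         truth = HabitatMap(array(as.integer(round(voxelData(truthCrop))),
                                  dim(voxelData(truthCrop))),
                            spec$kTrue))
  })
}

#' Spearman agreement between two per-feature repeatability rankings
#'
#' Computes per-feature median CCCs from two agreement tables (e.g.
#' test-vs-retest and test-vs-perturbed) and returns the Spearman rank
#' correlation between them across the shared features.
#'
#' @param tableA,tableB Tidy agreement tables with a `"ccc"` metric.
#' @return List with `rho`, and the two named median vectors.
#' @export
surrogateValidity <- function(tableA, tableB) {
  medOf <- function(tab) {
    tab <- tab[tab$metric == "ccc", , drop = FALSE]
    tapply(tab$value, tab$feature, stats::median)
  }
  ma <- medOf(tableA)
  mb <- medOf(tableB)
  common <- intersect(names(ma), names(mb))
  rho <- stats::cor(ma[common], mb[common], method = "spearman")
  list(rho = unname(rho), medianA = ma[common], medianB = mb[common])
}

#' Run the full synthetic-cohort experiment
#'
#' Executes simulate, perturb, extract, compare, rank and habitat stages,
#' and (optionally) writes tidy CSV reports plus a JSON manifest whose hash
#' changes iff the configuration changes. Re-running with the same
#' configuration reproduces every numeric output exactly.
#'
#' @param cfg An [experimentConfig()].
#' @param outDir Output directory for reports, or `NULL` to skip writing.
#' @return Invisibly, a list with `cohort`, `agreement` (tidy table over
#'   retest and perturbed arms), `ranking`, `surrogate` (Spearman rho),
#'   `habitats` (per-lesion DSC table), `gridTable` (when `runGrid`), and
#'   `manifest`.
#' @export
runExperiment <- function(cfg, outDir = NULL) {
  stopifnot(inherits(cfg, "experimentConfig"))
  if (!length(cfg$binWidths) || !length(cfg$kernelRadii))
    stop("extraction grids must be nonempty to run the experiment")
  cohort <- simulateCohort(cfg)
  params <- extractionParams(binWidth = cfg$fixedCombo[["B"]],
                             kernelRadius = cfg$fixedCombo[["R"]],
                             featureList = cfg$features)

  agr <- list()
  habRows <- list()
  mapCache <- list()
  for (les in cohort) {
    st <- computeFeatureMaps(les$test, les$mask, params,
                             paste0(les$id, "_test"))
    sr <- computeFeatureMaps(les$retest, les$mask, params,
                             paste0(les$id, "_retest"))
    mapCache[[les$id]] <- list(test = st, retest = sr)
    tabR <- agreementTable(st, sr, les$mask, les$id, metrics = cfg$metrics)
    tabR$arm <- "retest"
    agr[[les$id]] <- tabR
    if (cfg$perturbedArm) {
      sp <- computeFeatureMaps(les$perturbed, les$mask, params,
                               paste0(les$id, "_perturbed"))
      mapCache[[les$id]]$perturbed <- sp
      tabP <- agreementTable(st, sp, les$mask, les$id,
                             metrics = cfg$metrics)
      tabP$arm <- "perturbed"
      agr[[les$id]] <- rbind(tabR, tabP)
    }

    for (k in cfg$habitatKs) for (selName in c("robust", "all")) {
      mats <- buildFeatureMatrix(st, sr, les$mask, selName)
      hab <- computeHabitats(mats$test, mats$retest, les$mask,
                             habitatConfig(k = k,
                                           nComponents = cfg$nComponents,
                                           featureSelection = selName,
                                           kmeansSeed = cfg$seed))
      habRows[[length(habRows) + 1L]] <- tibble::tibble(
        lesion = les$id, selection = selName, k = k,
        dsc = meanDsc(hab$test, hab$retest, les$mask, k = k))
    }
  }
  agreement <- do.call(rbind, agr)
  habitats <- do.call(rbind, habRows)

  retestTab <- agreement[agreement$arm == "retest", , drop = FALSE]
  perturbedTab <- agreement[agreement$arm == "perturbed", , drop = FALSE]
  ranking <- rankFeatures(retestTab, cfg$cccThreshold, cfg$gammaThreshold)
  surrogate <- if (cfg$perturbedArm)
    surrogateValidity(retestTab, perturbedTab) else NULL

  gridTable <- NULL
  if (cfg$runGrid)
    gridTable <- reproducibilityGrid(cohort, cfg$binWidths,
                                     cfg$kernelRadii, cfg$features)

  manifest <- list(
    configHash = rlang::hash(unclass(cfg)),
    seed = cfg$seed,
    nLesions = cfg$nLesions,
    nTasks = attr(enumerateTasks(cfg), "total"),
    package = as.character(utils::packageVersion("habitatlab")))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(agreement, file.path(outDir, "agreement.csv"),
                     row.names = FALSE)
    utils::write.csv(ranking$ranking, file.path(outDir, "ranking.csv"),
                     row.names = FALSE)
    utils::write.csv(habitats, file.path(outDir, "habitats.csv"),
                     row.names = FALSE)
    if (!is.null(gridTable))
      utils::write.csv(gridTable, file.path(outDir, "reproducibility.csv"),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(cohort = cohort, maps = mapCache, agreement = agreement,
                 ranking = ranking, surrogate = surrogate,
                 habitats = habitats, gridTable = gridTable,
                 manifest = manifest))
}

#' Read an experiment configuration from YAML
#'
#' Scalar fields map directly onto [experimentConfig()] arguments; the
#' `phantom`, `motion` and `perturbation` blocks map onto their
#' constructors.
#'
#' @param path YAML file path.
#' @return An `experimentConfig`.
#' @export
readExperimentConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("nLesions", "binWidths", "kernelRadii", "cccThreshold",
               "gammaThreshold", "habitatKs", "nComponents", "runGrid",
               "padMm", "seed", "features"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$fixedCombo)) args$fixedCombo <- unlist(y$fixedCombo)
  if (!is.null(y$phantom)) args$phantom <- do.call(phantomSpec, y$phantom)
  if (!is.null(y$motion)) args$motion <- do.call(rigidMotionSpec, y$motion)
  if (!is.null(y$perturbation))
    args$perturbation <- do.call(perturbationSpec, y$perturbation)
  do.call(experimentConfig, args)
}
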