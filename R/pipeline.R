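#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates, on a synthetic cohort with planted ground truth, the
#' stage sequence of the study workflow: cohort simulation; reference
#' template estimation and regional scoring; mortality-model fitting with
#' biological-age prediction and its physical-health validation CCA; the
#' physiology-psychopathology CCA (analysis 1); the brain PLS with axis
#' alignment (analysis 2); the serial mediation with a null-risk control
#' arm (analysis 3); the projection CCA onto a second cohort (analysis 4);
#' and the parcel-level CCA over the measure-specific differentiation
#' maps with spin significance (analysis 5, 13 maps). All intermediate
#' tables are persisted as TSV and stage results as JSON; a run manifest
#' is written atomically at the end.
#'
#' @param config a \code{\link{simConfig}} (or path to a YAML file whose
#'   entries are \code{simConfig} arguments plus optional \code{pipeline}
#'   overrides).
#' @param outDir output directory (created if missing).
#' @param stages character vector of stages to run, in order; unknown
#'   names are rejected.
#' @param k cross-validation folds.
#' @param nPerm permutations for CCA/PLS significance.
#' @param nBoot bootstrap samples for loadings/correlation CIs.
#' @param nSpins spin permutations.
#' @param medBoot bootstrap samples for mediation CIs.
#' @return the run manifest (invisibly a list), also written to
#'   \code{manifest.json}.
#' @export
runPipeline <- function(config = simConfig(), outDir = tempfile("nsd"),
                        stages = c("simulate", "template", "phenoage",
                                   "analysis1", "analysis2", "analysis3",
                                   "analysis4", "analysis5"),
                        k = 10, nPerm = 1000, nBoot = 1000,
                        nSpins = 1000, medBoot = 1000) {
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    pipe <- cfg$pipeline %||% list()
    cfg$pipeline <- NULL
    config <- do.call(simConfig, cfg)
    for (nm in intersect(names(pipe), c("k", "nPerm", "nBoot", "nSpins",
                                        "medBoot")))
      assign(nm, pipe[[nm]])
  }
  known <- c("simulate", "template", "phenoage", "analysis1", "analysis2",
             "analysis3", "analysis4", "analysis5")
  if (!all(stages %in% known))
    stop("unknown stage name(s): ",
         paste(setdiff(stages, known), collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "neuroSexDiff",
                   version = as.character(utils::packageVersion("neuroSexDiff")),
                   seed = config$seed, configHash = configHash(config),
                   stages = list(), outputs = character())
  env <- new.env()
  for (st in known) {
    if (!(st %in% stages)) next
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({
      outs <- switch(st,
        simulate = stageSimulate(config, outDir, env),
        template = stageTemplate(config, outDir, env),
        phenoage = stagePhenoage(config, outDir, env, k, nPerm),
        analysis1 = stageAnalysis1(config, outDir, env, k, nPerm, nBoot),
        analysis2 = stageAnalysis2(config, outDir, env, k, nPerm, nBoot,
                                   nSpins),
        analysis3 = stageAnalysis3(config, outDir, env, medBoot),
        analysis4 = stageAnalysis4(config, outDir, env, k, nPerm),
        analysis5 = stageAnalysis5(config, outDir, env, k, nSpins))
      manifest$outputs <- c(manifest$outputs, outs)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      manifest$failedStage <- st
      writeManifest(manifest, outDir)
      stop(sprintf("stage '%s' failed: %s", st, conditionMessage(ok)))
    }
    manifest$stages[[st]] <- list(seconds =
      round(proc.time()[["elapsed"]] - t0, 3))
  }
  writeManifest(manifest, outDir)
  invisible(manifest)
}

configHash <- function(config) {
  s <- paste(names(unlist(config)), format(unlist(config), digits = 12),
             collapse = ";")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

writeManifest <- function(manifest, outDir) {
  tmp <- file.path(outDir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, file.path(outDir, "manifest.json"))
}

writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  path
}

stageSimulate <- function(config, outDir, env) {
  env$geometry <- generateParcelGeometry(config$nRois, config$seed)
  env$ref <- generateReferenceCohort(config, env$geometry)
  env$adol <- generateAdolescentCohort(config, env$geometry)
  env$mortality <- generateMortalityCohort(config)
  cfg2 <- config
  cfg2$nAdolescents <- max(150L, round(config$nAdolescents * 0.6))
  cfg2$seed <- config$seed + 1000L
  env$adol2 <- generateAdolescentCohort(cfg2, env$geometry)
  p1 <- file.path(outDir, "geometry.tsv")
  write.table(env$geometry, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(outDir, "adolescent_phenotypes.tsv")
  write.table(env$adol$pheno, p2, sep = "\t", quote = FALSE,
              row.names = FALSE)
  p3 <- file.path(outDir, "mortality.tsv")
  write.table(env$mortality, p3, sep = "\t", quote = FALSE,
              row.names = FALSE)
  p4 <- writeJson(list(paths = env$adol$truth$paths,
                       sexEffectScale = env$adol$truth$sexEffectScale,
                       brainLoadScale = env$adol$truth$brainLoadScale,
                       axis = env$adol$truth$axis),
                  file.path(outDir, "ground_truth.json"))
  c(p1, p2, p3, p4)
}

stageTemplate <- function(config, outDir, env) {
  env$template <- fitSexDiffTemplate(env$ref$fc, env$ref$pheno)
  env$profT1 <- scoreCohortSexDiff(env$adol$fcT1, env$template)
  env$profT2 <- scoreCohortSexDiff(env$adol$fcT2, env$template)
  env$prof2T1 <- scoreCohortSexDiff(env$adol2$fcT1, env$template)
  tm <- tstatMatrix(env$template)
  rownames(tm) <- seq_len(nrow(tm))
  p1 <- file.path(outDir, "template.tsv")
  writeTsvMatrix(tm, p1)
  p2 <- file.path(outDir, "profiles_t1.tsv")
  writeTsvMatrix(env$profT1, p2, idColumn = "subject_index")
  p3 <- file.path(outDir, "profiles_t2.tsv")
  writeTsvMatrix(env$profT2, p3, idColumn = "subject_index")
  c(p1, p2, p3)
}

# PDS items of one wave with the suffix stripped (as selfReportIndices
# expects).
pdsWaveItems <- function(ph, timepoint) {
  cols <- grep(paste0("^pds_.*_", timepoint, "$"), names(ph), value = TRUE)
  out <- ph[cols]
  names(out) <- sub(paste0("_", timepoint, "$"), "", cols)
  out
}

adolConfounds <- function(ph, timepoint = "t2") {
  data.frame(age = ph[[paste0("age_months_", timepoint)]],
             handedness = ph$handedness, site = ph$site, race = ph$race,
             adopted = ph$adopted, ambiguous_sex = ph$ambiguous_sex,
             mean_fd = ph[[paste0("mean_fd_", timepoint)]])
}

# Pubertal indices + phenoage + change scores for the main cohort.
buildIndices <- function(env) {
  ph <- env$adol$pheno
  horm <- hormonalIndices(
    data.frame(dhea = ph$dhea_t2, testosterone = ph$testosterone_t2,
               estradiol = ph$estradiol_t2),
    ph$sex,
    data.frame(delay = ph$saliva_delay_h, caffeine = ph$caffeine_mg,
               activity = ph$activity_flag, quality = ph$saliva_quality),
    data.frame(menarche_age = ph$menarche_age,
               days_since_cycle = ph$days_since_cycle,
               cycle_regular = ph$cycle_regular))
  sr <- selfReportIndices(pdsWaveItems(ph, "t2"), ph$sex)
  cbind(horm, sr)
}

stagePhenoage <- function(config, outDir, env, k, nPerm) {
  env$mortModel <- fitMortalityModel(env$mortality,
                                     horizon = config$gompertz$horizonYears)
  ph <- env$adol$pheno
  bm <- ph[biomarkerReference()$name]
  env$phenoage <- phenoAge(env$mortModel, ph$age_months_t2 / 12, bm)
  env$accel <- ageAcceleration(env$phenoage, ph$age_months_t2 / 12, ph$sex)
  # physical-health validation: CCA linking biological age to concurrent
  # health correlates, adjusted for sex and chronological age
  val <- crossValidateCca(cbind(phenoage = env$phenoage),
                          cbind(bmi = ph$bmi, deprivation = ph$deprivation,
                                medical_visits = ph$medical_visits),
                          confounds = data.frame(sex = ph$sex,
                                                 age = ph$age_months_t2),
                          k = k, seed = config$seed + 11L)
  val <- ccaPermutationPvalue(val, cbind(phenoage = env$phenoage),
                              cbind(bmi = ph$bmi,
                                    deprivation = ph$deprivation,
                                    medical_visits = ph$medical_visits),
                              confounds = data.frame(sex = ph$sex,
                                                     age = ph$age_months_t2),
                              k = k, nPerm = nPerm,
                              seed = config$seed + 12L)
  env$phenoageValidation <- val
  p1 <- file.path(outDir, "phenoage.tsv")
  write.table(data.frame(subject = ph$subject, phenoage = env$phenoage,
                         acceleration = env$accel),
              p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- writeJson(list(
    model = list(intercept = env$mortModel@intercept,
                 ageCoef = env$mortModel@ageCoef,
                 biomarkerCoef = as.list(env$mortModel@biomarkerCoef),
                 gamma = env$mortModel@gamma,
                 horizon = env$mortModel@horizon,
                 logLik = env$mortModel@logLik),
    validation = list(rCV = rCV(val), permP = permutationP(val))),
    file.path(outDir, "phenoage_model.json"))
  c(p1, p2)
}

stageAnalysis1 <- function(config, outDir, env, k, nPerm, nBoot) {
  ph <- env$adol$pheno
  idx <- buildIndices(env)
  t2 <- ph[grep("_t2$", names(ph))][paste0("cbcl_",
    c("anxiety", "depression", "somatic", "adhd", "odd", "conduct", "ocd",
      "ptsd", "sct"), "_t2")]
  t3 <- ph[paste0("cbcl_", c("anxiety", "depression", "somatic", "adhd",
                             "odd", "conduct", "ocd", "ptsd", "sct"),
                  "_t3")]
  ch <- changeScores(t2, t3)
  names(ch) <- paste0(names(ch), "_change")
  X <- cbind(zscoreColumns(t2), as.matrix(ch))
  Y <- cbind(sex = ph$sex, phenoage = env$phenoage, as.matrix(idx))
  conf <- adolConfounds(ph)
  res <- crossValidateCca(X, Y, conf, k = k, seed = config$seed + 21L)
  # reporting orientation: the psychopathology variate is oriented toward
  # rising internalizing symptoms; its partner follows so r_CV is unchanged
  intern <- rowMeans(as.matrix(ch[, c("cbcl_anxiety_change",
                                      "cbcl_depression_change",
                                      "cbcl_somatic_change")]))
  flip <- sign(cor(res@scoresX, intern))
  if (is.finite(flip) && flip < 0)
    res <- initialize(res, scoresX = -res@scoresX, scoresY = -res@scoresY)
  res <- ccaPermutationPvalue(res, X, Y, conf, k = k, nPerm = nPerm,
                              seed = config$seed + 22L)
  res <- bootstrapLoadings(res, nBoot = nBoot, seed = config$seed + 23L)
  env$cca1 <- res
  contrib <- standardizedContributions(res@scoresY,
                                       as.data.frame(Y), conf)
  p1 <- writeJson(list(rCV = rCV(res), permP = permutationP(res),
                       loadings = loadingTable(res),
                       contributions = contrib),
                  file.path(outDir, "analysis1_cca.json"))
  p2 <- file.path(outDir, "analysis1_variates.tsv")
  write.table(data.frame(subject = ph$subject,
                         psychopathology = res@scoresX,
                         physiology = res@scoresY),
              p2, sep = "\t", quote = FALSE, row.names = FALSE)
  c(p1, p2)
}

stageAnalysis2 <- function(config, outDir, env, k, nPerm, nBoot, nSpins) {
  ph <- env$adol$pheno
  brain <- cbind(env$profT1, env$profT2)
  behavior <- cbind(psychopathology = env$cca1@scoresX,
                    physiology = env$cca1@scoresY)
  disc <- fitPls(brain, behavior, conditions = 2L)
  discP <- plsPermutationPvalues(brain, behavior, conditions = 2L,
                                 nPerm = nPerm, seed = config$seed + 31L)
  bsr <- plsBootstrapRatios(disc, brain, behavior, nBoot = max(200, nBoot),
                            seed = config$seed + 32L)
  conf <- cbind(adolConfounds(ph, "t2"),
                mean_fd_t1 = ph$mean_fd_t1)
  cvres <- crossValidatePls(brain, behavior, conditions = 2L,
                            confounds = conf, k = k, nPerm = nPerm,
                            nBoot = nBoot, seed = config$seed + 33L)
  env$pls <- cvres
  env$plsDiscovery <- disc
  spins <- generateSpins(env$geometry, nSpins, seed = config$seed + 34L)
  env$spins <- spins
  axis <- env$adol$truth$axis
  align <- alignToAxis(loadingMap(cvres)[, 1], axis, spins)
  env$axisAlign <- align
  p1 <- writeJson(list(
    discovery = list(covExplained = covarianceExplained(disc)[1],
                     permP = discP[1],
                     reliableParcels = sum(bsr$reliable)),
    crossValidated = list(permP = permutationP(cvres),
                          cor = as.data.frame(cvres@cis)),
    axisAlignment = list(rho = align$rho, pSpin = align$pSpin)),
    file.path(outDir, "analysis2_pls.json"))
  lm2 <- loadingMap(cvres)
  rownames(lm2) <- seq_len(nrow(lm2))
  p2 <- file.path(outDir, "analysis2_brain_loadings.tsv")
  writeTsvMatrix(cbind(lm2, bsr = bsr$bsr[seq_len(nrow(lm2))]), p2)
  c(p1, p2)
}

stageAnalysis3 <- function(config, outDir, env, medBoot) {
  ph <- env$adol$pheno
  idxT1 <- {
    horm <- hormonalIndices(
      data.frame(dhea = ph$dhea_t1, testosterone = ph$testosterone_t1,
                 estradiol = ph$estradiol_t1),
      ph$sex,
      data.frame(delay = ph$saliva_delay_h, caffeine = ph$caffeine_mg,
                 activity = ph$activity_flag, quality = ph$saliva_quality),
      data.frame(menarche_age = ph$menarche_age,
                 days_since_cycle = ph$days_since_cycle,
                 cycle_regular = ph$cycle_regular))
    sr <- selfReportIndices(pdsWaveItems(ph, "t1"), ph$sex)
    cbind(horm, sr)
  }
  conf <- cbind(adolConfounds(ph, "t2"), mean_fd_t1 = ph$mean_fd_t1,
                idxT1)
  runArm <- function(prs) {
    dat <- data.frame(X = zvec(prs),
                      M1 = env$pls@brainScores[, 1],
                      M2 = env$cca1@scoresY,
                      M3 = env$pls@brainScores[, 2],
                      Y = env$cca1@scoresX)
    bootstrapIndirectEffects(dat, covariates = conf, nBoot = medBoot,
                             seed = config$seed + 41L)
  }
  env$mediationAnx <- runArm(ph$prs_anx)
  env$mediationAdhd <- runArm(ph$prs_adhd)
  p1 <- writeJson(list(anx = effectTable(env$mediationAnx),
                       adhd = effectTable(env$mediationAdhd)),
                  file.path(outDir, "analysis3_mediation.json"))
  p1
}

stageAnalysis4 <- function(config, outDir, env, k, nPerm) {
  ph2 <- env$adol2$pheno
  # project the discovery PLS brain weights onto the second cohort's
  # T1 profiles to obtain its brain LV scores
  R <- config$nRois
  v <- env$plsDiscovery@brainSaliences[seq_len(R), 1]
  blv <- drop(scale(env$prof2T1) %*% v)
  sr2 <- selfReportIndices(pdsWaveItems(ph2, "t1"), ph2$sex)
  t2 <- ph2[paste0("cbcl_", c("anxiety", "depression", "somatic", "adhd",
                              "odd", "conduct", "ocd", "ptsd", "sct"),
                   "_t2")]
  Y <- cbind(zscoreColumns(t2), sex = ph2$sex, as.matrix(sr2),
             bmi = ph2$bmi, deprivation = ph2$deprivation)
  conf <- data.frame(age = ph2$age_months_t1, handedness = ph2$handedness,
                     site = ph2$site, adopted = ph2$adopted,
                     mean_fd = ph2$mean_fd_t1)
  res <- crossValidateCca(cbind(brainLV = blv), Y, conf, k = k,
                          seed = config$seed + 51L)
  res <- ccaPermutationPvalue(res, cbind(brainLV = blv), Y, conf, k = k,
                              nPerm = nPerm, seed = config$seed + 52L)
  env$cca4 <- res
  writeJson(list(rCV = rCV(res), permP = permutationP(res)),
            file.path(outDir, "analysis4_projection_cca.json"))
}

stageAnalysis5 <- function(config, outDir, env, k, nSpins) {
  ph2 <- env$adol2$pheno
  sr2 <- selfReportIndices(pdsWaveItems(ph2, "t1"), ph2$sex)
  cb <- ph2[paste0("cbcl_", c("anxiety", "depression", "somatic", "adhd",
                              "odd", "conduct", "ocd", "ptsd", "sct"),
                   "_t2")]
  names(cb) <- sub("_t2$", "", names(cb))
  measures <- cbind(cb, bmi = ph2$bmi, deprivation = ph2$deprivation,
                    adrenarche = sr2$selfreport_adrenarche,
                    gonadarche = sr2$selfreport_gonadarche)
  confounds <- data.frame(age = ph2$age_months_t1, sex = ph2$sex,
                          handedness = ph2$handedness, race = ph2$race,
                          site = ph2$site, mean_fd = ph2$mean_fd_t1)
  maps <- mapPartialCorrelations(env$prof2T1, measures, confounds)
  env$maps13 <- maps
  # parcel-level CCA: reference brain LV map against the 13 maps, spin
  # significance (rows are parcels)
  X <- cbind(brainMap = loadingMap(env$pls)[, 1])
  res <- crossValidateCca(X, maps, k = min(k, nrow(maps) %/% 3),
                          seed = config$seed + 61L)
  res <- ccaPermutationPvalue(res, X, maps, k = min(k, nrow(maps) %/% 3),
                              nPerm = min(nSpins, nrow(env$spins@perms)),
                              spins = env$spins,
                              seed = config$seed + 62L)
  env$cca5 <- res
  p1 <- file.path(outDir, "analysis5_maps.tsv")
  m <- maps
  rownames(m) <- seq_len(nrow(m))
  writeTsvMatrix(m, p1)
  p2 <- writeJson(list(nMaps = ncol(maps), rCV = rCV(res),
                       pSpin = permutationP(res)),
                  file.path(outDir, "analysis5_roicca.json"))
  c(p1, p2)
}
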