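# Run configuration and the command-layer functions the shell entry point
# (inst/exec/beadstress) is a thin wrapper around.

#' Create a run configuration
#'
#' Defaults are the production/validation bead parameters: E = 1800 Pa,
#' nu = 0.443, reference diameter 17.0 um, 0.1 um xy pixels, 1.0 um
#' z-sections.
#'
#' @param E,nu material parameters (Pa, -).
#' @param diameter reference sphere diameter, um.
#' @param refinement icosphere subdivision level.
#' @param layers radial tet layers (0 = choose automatically).
#' @param nLoadSteps,tol FE solver controls.
#' @param spacingXY,spacingZ voxel spacing, um.
#' @param blurSigma,noiseLevel rendering parameters.
#' @param seed RNG seed.
#' @param outputDir output directory.
#' @return a [RunConfig].
#' @export
runConfig <- function(E = 1800, nu = 0.443, diameter = 17, refinement = 3,
                      layers = 0, nLoadSteps = 5, tol = 1e-8,
                      spacingXY = 0.1, spacingZ = 1, blurSigma = 0.2,
                      noiseLevel = 0.05, seed = 1, outputDir = ".") {
  new("RunConfig", material = material(E, nu),
      diameter = as.numeric(diameter), refinement = as.integer(refinement),
      layers = as.integer(layers), nLoadSteps = as.integer(nLoadSteps),
      tol = as.numeric(tol), spacingXY = as.numeric(spacingXY),
      spacingZ = as.numeric(spacingZ), blurSigma = as.numeric(blurSigma),
      noiseLevel = as.numeric(noiseLevel), seed = as.integer(seed),
      outputDir = outputDir)
}

setValidity("RunConfig", function(object) {
  if (object@diameter <= 0 || object@spacingXY <= 0 || object@spacingZ <= 0)
    return("physical sizes must be positive")
  if (object@tol <= 0) return("tol must be positive")
  TRUE
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf(
    "RunConfig: E = %g Pa, nu = %g, D = %g um, refinement %d, seed %d\n",
    youngModulus(object@material), poissonRatio(object@material),
    object@diameter, object@refinement, object@seed))
})

configLayers <- function(config) if (config@layers > 0) config@layers else NULL

#' Write / read a run configuration as YAML
#' @param config a [RunConfig].
#' @param path YAML path.
#' @return the path (write) or a [RunConfig] (read).
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(list(
    E = youngModulus(config@material), nu = poissonRatio(config@material),
    diameter = config@diameter, refinement = config@refinement,
    layers = config@layers, nLoadSteps = config@nLoadSteps,
    tol = config@tol, spacingXY = config@spacingXY,
    spacingZ = config@spacingZ, blurSigma = config@blurSigma,
    noiseLevel = config@noiseLevel, seed = config@seed,
    outputDir = config@outputDir), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  do.call(runConfig, yaml::read_yaml(path))
}

#' Reconstruct stresses for one or more observed stacks
#'
#' For each TIFF stack: segment, mesh, run the inverse reconstruction, and
#' write a VTK stress field plus a JSON summary; across a sequence, a CSV
#' time series of normal-stress profiles (amplified by a factor of 5 and
#' max-abs normalized over the series) is written.
#'
#' @param stackPaths character vector of TIFF paths.
#' @param config a [RunConfig].
#' @return named list of per-frame summaries, invisibly.
#' @export
cmdRun <- function(stackPaths, config = runConfig()) {
  if (!all(file.exists(stackPaths)))
    stop("missing input: ",
         paste(stackPaths[!file.exists(stackPaths)], collapse = ", "))
  dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
  summaries <- list()
  profiles <- list()
  for (i in seq_along(stackPaths)) {
    stack <- readImageStack(stackPaths[i], config@spacingXY,
                            config@spacingZ)
    rec <- reconstructFromStack(stack, config@material,
                                diameter = config@diameter,
                                refinement = config@refinement,
                                layers = configLayers(config))
    base <- file.path(config@outputDir,
                      sprintf("frame%03d", i))
    writeStressVTK(rec, paste0(base, ".vtk"))
    writeStressSummaryJSON(rec$summary, paste0(base, ".json"))
    summaries[[i]] <- rec$summary
    profiles[[i]] <- normalStressProfile(meanTensor(rec$summary))
    message(sprintf("frame %d: mean pressure %.1f Pa, V_c %.1f um^3", i,
                    meanPressure(rec$summary),
                    summaryVolumes(rec$summary)[1]))
  }
  series <- do.call(profileSeries, profiles)
  amp <- tryCatch(amplifyNormalize(series, 5), error = function(e) NULL)
  writeProfileCSV(series, amp,
                  file.path(config@outputDir, "profiles.csv"))
  invisible(summaries)
}

scenarioByName <- function(name) {
  switch(name,
         homogeneous = scenarioHomogeneous(),
         periodic = scenarioPeriodic(),
         quadratic = scenarioQuadratic(),
         pressure_shear = scenarioPressureShear(),
         stop("unknown scenario '", name, "'; valid: homogeneous, ",
              "periodic, quadratic, pressure_shear"))
}

#' Run validation round trips for named scenarios
#'
#' @param names scenario names (`"all"` = the four standard scenarios).
#' @param config a [RunConfig].
#' @param pressureTol,angleTol pass/fail tolerances: relative mean-pressure
#'   difference and principal-direction angle (degrees).
#' @return list of per-scenario reports (also written as JSON to the
#'   output directory), invisibly.
#' @export
cmdValidate <- function(names = "all", config = runConfig(),
                        pressureTol = 0.05, angleTol = 5) {
  if (identical(names, "all"))
    names <- c("homogeneous", "periodic", "quadratic", "pressure_shear")
  dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
  reports <- list()
  for (nm in names) {
    vr <- runValidation(scenarioByName(nm), mat = config@material,
                        diameter = config@diameter,
                        refinement = config@refinement,
                        layers = configLayers(config),
                        nLoadSteps = config@nLoadSteps, tol = config@tol)
    cmp <- vr@comparison
    rep <- list(scenario = nm,
                reference_mean_pressure_Pa = meanPressure(vr@reference),
                recovered_mean_pressure_Pa = meanPressure(vr@recovered),
                pressure_rel_diff = cmp$pressureRelDiff,
                principal_diffs_Pa = cmp$principalDiffs,
                direction_angles_deg = cmp$directionAngles,
                local_pressure_rms_diff_Pa = cmp$localPressureRMSDiff,
                pass = isTRUE(abs(cmp$pressureRelDiff) <= pressureTol &&
                              max(cmp$directionAngles) <= angleTol))
    reports[[nm]] <- rep
    message(sprintf("%s: p_rec/p_ref = %.4f, max angle %.2f deg [%s]", nm,
                    1 + cmp$pressureRelDiff, max(cmp$directionAngles),
                    if (rep$pass) "ok" else "DEVIATES"))
  }
  writeLines(jsonlite::toJSON(reports, digits = NA, auto_unbox = TRUE,
                              na = "null"),
             file.path(config@outputDir, "validation.json"))
  invisible(reports)
}

#' Simulate a scenario and emit fixtures
#'
#' Forward-solves the scenario on the configured bead, then writes the
#' deformed surface (STL), a rendered synthetic stack (TIFF + sidecar)
#' and the reference stress summary (JSON).
#'
#' @param name scenario name.
#' @param config a [RunConfig].
#' @return paths of written artifacts, invisibly.
#' @export
cmdSimulate <- function(name, config = runConfig()) {
  dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
  sc <- scenarioByName(name)
  mesh <- tetrahedralize(makeSphereSurface(config@diameter / 2,
                                           config@refinement),
                         layers = configLayers(config))
  fwd <- forwardScenario(sc, mesh, config@material, config@nLoadSteps,
                         config@tol)
  surf <- boundarySurface(fwd$mesh)
  stack <- renderBeadStack(surf, config@spacingXY, config@spacingZ,
                           config@blurSigma, config@noiseLevel,
                           config@seed)
  base <- file.path(config@outputDir, name)
  writeSTL(surf, paste0(base, "_deformed.stl"))
  writeImageStack(stack, paste0(base, "_stack.tif"))
  writeStressSummaryJSON(fwd$summary, paste0(base, "_reference.json"))
  invisible(c(paste0(base, "_deformed.stl"), paste0(base, "_stack.tif"),
              paste0(base, "_reference.json")))
}

#' Fit moduli from an osmotic compression CSV
#'
#' @param csvPath CSV with `pressure_Pa` and `volumetric_strain` columns.
#' @param nu Poisson ratio for the E conversion.
#' @param strainCutoff small-strain fit cutoff.
#' @return list with `kappa_Pa`, `kappa_se_Pa`, `E_Pa`.
#' @export
cmdMaterial <- function(csvPath, nu = 0.443, strainCutoff = 0.15) {
  df <- readCompressionSeries(csvPath)
  fit <- fitBulkModulus(df$pressure_Pa, df$volumetric_strain, strainCutoff)
  list(kappa_Pa = unname(fit["kappa"]), kappa_se_Pa = unname(fit["se"]),
       E_Pa = youngFromBulk(fit[["kappa"]], nu))
}
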