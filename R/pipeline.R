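## End-to-end orchestration: synthetic system -> minimum distances ->
## histograms/reference -> MDDF -> KB integrals / Gamma / coordination /
## hydration -> residue maps, with replica-level SEMs and deterministic
## TSV + JSON outputs.

.configDefaults <- list(
  seed = 1, replicas = 1, frames = 10, system = "ideal",
  binning = list(width = 0.1, rmax = 30),
  bulk_shell = c(20, 30), protein_domain = 20,
  coordination_cutoff = 5, reference_factor = 10,
  pairing = FALSE, pair_radius = 3)

.validateConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML file or a list",
                             call. = FALSE)
  for (nm in names(.configDefaults))
    if (is.null(config[[nm]])) config[[nm]] <- .configDefaults[[nm]]
  if (is.null(config$box) || length(config$box) != 3L)
    stop("config error: 'box' must give three side lengths", call. = FALSE)
  if (!config$system %in% c("ideal", "excluded", "profile"))
    stop("config error: system must be ideal, excluded or profile",
         call. = FALSE)
  if (is.null(config$species) || !length(config$species))
    stop("config error: at least one species required", call. = FALSE)
  if (config$frames >= 10000)
    stop("config error: frames per replica must stay below 10000",
         call. = FALSE)
  config
}

.recipeFromConfig <- function(config, seed) {
  solute <- if (is.null(config$solute)) NULL else
    buildToySolute(config$solute$n_residues,
                   classes = unlist(config$solute$classes))
  species <- lapply(config$species, function(s)
    profileSpec(tag = s$tag, count = s$count,
                template = if (is.null(s$template)) "point" else s$template,
                exclusion = if (is.null(s$exclusion)) 0 else s$exclusion,
                breaks = as.numeric(unlist(s$breaks)),
                lambda = as.numeric(unlist(s$lambda)),
                role = if (is.null(s$role)) "neutral" else s$role))
  systemRecipe(box = as.numeric(config$box), species = species,
               solute = solute, nFrames = config$frames, seed = seed,
               pairing = isTRUE(config$pairing),
               pairRadius = config$pair_radius)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full solvation-analysis pipeline on a synthetic system
#'
#' Generates the configured synthetic system for each replica, computes
#' minimum distances, MDDFs, bulk densities, KB integrals, the
#' preferential-solvation parameter of the merged cosolvent pseudo-component
#' against water, coordination numbers, optional hydration numbers, and
#' residue maps; aggregates headline quantities across replicas (mean and
#' SEM) and writes TSV tables plus a JSON summary. Rerunning with the same
#' config and seed reproduces every output byte for byte.
#'
#' @param config path to a YAML config, or an equivalent list.
#' @param outDir output directory (overrides \code{config$out_dir}); NULL
#'   writes nothing.
#' @return (invisibly) a list with per-replica results and the aggregated
#'   summary.
#' @export
runPipeline <- function(config, outDir = NULL) {
  config <- .validateConfig(config)
  if (is.null(outDir)) outDir <- config$out_dir
  bw <- config$binning$width
  rmax <- config$binning$rmax
  shell <- as.numeric(config$bulk_shell)
  Rdom <- config$protein_domain
  tags <- vapply(config$species, `[[`, "", "tag")
  waterTag <- if (is.null(config$water)) intersect("water", tags) else
    config$water
  cosolventTags <- if (is.null(config$cosolvent))
    setdiff(tags, waterTag) else unlist(config$cosolvent)

  build <- switch(config$system, ideal = buildIdealGasSystem,
                  excluded = buildExcludedShellSystem,
                  profile = buildProfileSystem)
  replicas <- vector("list", config$replicas)
  for (rep in seq_len(config$replicas)) {
    seedR <- config$seed + (rep - 1L) * 10000L
    sys <- .stage("synth", build(.recipeFromConfig(config, seedR)))
    topo <- sys$topology
    frames <- sys$frames
    perSpecies <- list()
    for (tag in tags) {
      rec <- .stage("mindist",
                    minimumDistances(frames, topo, tag, rMax = rmax))
      hist <- .stage("mddf", accumulateHistogram(rec, topo, bw, rmax))
      ref <- .stage("mddf", referenceCounts(frames, topo, tag,
                                            nRandomFactor =
                                              config$reference_factor,
                                            seed = seedR + 5000L,
                                            binWidth = bw, rMax = rmax))
      rho <- .stage("mddf", bulkDensity(hist, ref, shell))
      mddfRes <- .stage("mddf", computeMddf(hist, ref, rho$rho))
      mddfRes <- decomposeMddf(mddfRes, "solvent_atom")
      kbiRes <- .stage("kbi", kbIntegral(hist, ref, rho$rho, Rdom, shell))
      perSpecies[[tag]] <- list(records = rec, hist = hist, ref = ref,
                                rho = rho, mddf = mddfRes, kbi = kbiRes,
                                map = residueDistanceMap(hist, ref,
                                                         rho$rho))
    }
    gamma <- NULL
    if (length(waterTag) && length(cosolventTags)) {
      merged <- .stage("gamma", do.call(mergePseudoComponents,
        c(lapply(cosolventTags, function(t) perSpecies[[t]]$records),
          list(tag = "cosolvent"))))
      mhist <- accumulateHistogram(merged, topo, bw, rmax)
      mref <- .stage("gamma", referenceCounts(frames, topo, cosolventTags,
                                              nRandomFactor =
                                                config$reference_factor,
                                              seed = seedR + 6000L,
                                              binWidth = bw, rMax = rmax))
      mrho <- bulkDensity(mhist, mref, shell)
      mkbi <- kbIntegral(mhist, mref, mrho$rho, Rdom, shell)
      gamma <- .stage("gamma",
                      preferentialSolvation(mkbi,
                                            perSpecies[[waterTag]]$kbi))
      perSpecies[["cosolvent"]] <- list(hist = mhist, ref = mref,
                                        rho = mrho, kbi = mkbi)
    }
    allRec <- do.call(rbind, lapply(tags, function(t)
      perSpecies[[t]]$records))
    attr(allRec, "nFrames") <- length(frames)
    coord <- .stage("coord",
                    coordinationNumber(allRec,
                                       config$coordination_cutoff))
    hyd <- NULL
    if (!is.null(config$hydration))
      hyd <- .stage("hydration", bulkCoordination(
        frames, topo, config$hydration$ion,
        waterSpecies = config$hydration$water,
        radii = as.numeric(unlist(config$hydration$radii)),
        rMax = rmax))
    replicas[[rep]] <- list(species = perSpecies, gamma = gamma,
                            coordination = coord, hydration = hyd,
                            seed = seedR)
  }

  agg <- function(v) {
    c(mean = mean(v),
      sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_)
  }
  summary <- list(seed = config$seed, replicas = config$replicas,
                  frames = config$frames, system = config$system,
                  protein_domain = Rdom)
  for (tag in c(tags, if (length(waterTag) && length(cosolventTags))
    "cosolvent")) {
    Gs <- vapply(replicas, function(r)
      kbiAt(r$species[[tag]]$kbi, Rdom), 0)
    rhos <- vapply(replicas, function(r) r$species[[tag]]$rho$molar, 0)
    summary[[paste0("G_", tag)]] <- as.list(agg(Gs))
    summary[[paste0("molar_", tag)]] <- as.list(agg(rhos))
    summary[[paste0("converged_", tag)]] <-
      all(vapply(replicas, function(r) r$species[[tag]]$kbi@converged,
                 TRUE))
  }
  if (!is.null(replicas[[1]]$gamma)) {
    gs <- vapply(replicas, function(r) gammaAt(r$gamma, Rdom), 0)
    summary$gamma <- as.list(agg(gs))
  }

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    r1 <- replicas[[1]]
    for (tag in tags) {
      writeMddf(r1$species[[tag]]$mddf,
                file.path(outDir, paste0("mddf_", tag, ".tsv")))
      k <- kbi(r1$species[[tag]]$kbi)
      write.table(format(k, digits = 10, trim = TRUE),
                  file.path(outDir, paste0("kbi_", tag, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      writeMap(r1$species[[tag]]$map,
               file.path(outDir, paste0("map_", tag, ".tsv")))
    }
    if (!is.null(r1$gamma))
      write.table(format(gammaCurve(r1$gamma), digits = 10, trim = TRUE),
                  file.path(outDir, "gamma.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    write.table(format(r1$coordination, digits = 10, trim = TRUE),
                file.path(outDir, "coordination.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(r1$hydration))
      write.table(format(r1$hydration, digits = 10, trim = TRUE),
                  file.path(outDir, "hydration.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(replicas = replicas, summary = summary))
}
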