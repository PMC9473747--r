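#' Run the full oligomer-analysis pipeline
#'
#' End-to-end analysis of a multi-model PDB trajectory into the standard
#' report set: secondary-structure statistics and timeline, hydrogen-bond
#' and contact time series, radius-of-gyration series, per-frame sheet
#' topology classification, gromos clustering with representative
#' structures, the 2D free-energy landscape over (beta-sheet contacts, Rg),
#' contact probability maps, and a split-window convergence check.  All
#' tables are CSV with units in the header row; the run is deterministic
#' for a given input and configuration.
#'
#' The analysis window defaults to the final `lastFraction` of frames
#' (4/15, the analog of analysing the last 400 ns of 1.5 us runs);
#' timelines and time series always cover all frames.
#'
#' @param input path to a multi-model PDB file, or a
#'   [PeptideTrajectory-class].
#' @param outputDir output directory (created if missing).
#' @param params an [AnalysisParameters-class].
#' @param window explicit frame indices for ensemble statistics
#'   (overrides `lastFraction`).
#' @param lastFraction fraction of trailing frames analysed by default.
#' @param nClusterStructures representative cluster centers written as PDB.
#' @return invisibly, a list with the output paths and the in-memory
#'   results (`ssStats`, `topology`, `clusters`, `landscape`, ...).
#' @export
runPipeline <- function(input, outputDir, params = analysisParameters(),
                        window = NULL, lastFraction = 4 / 15,
                        nClusterStructures = 4L) {
  t0 <- Sys.time()
  traj <- if (is(input, "PeptideTrajectory")) input
          else readMultimodelPDB(input)
  nf <- nFrames(traj)
  if (is.null(window)) {
    start <- max(1L, nf - ceiling(nf * lastFraction) + 1L)
    window <- start:nf
  }
  window <- as.integer(window)
  if (!length(window) || any(window < 1L) || any(window > nf))
    stop("analysis window is empty or out of range")
  if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
  paths <- list()
  logline <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(fmt, ...))
    logline <<- c(logline, msg)
  }
  wfile <- function(df, name) {
    p <- file.path(outputDir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
    p
  }
  say("input: %d frames, %d chains of %s; analysis window %d..%d",
      nf, nChains(traj), peptideSequence(traj), min(window), max(window))

  sys <- trajectorySystem(traj)
  nwarn <- 0L
  withCallingHandlers({
    ss <- assignSS(traj)

    # secondary structure
    stats <- ssStatistics(traj, window = window, ss = ss)
    wfile(data.frame(category = names(stats$overall),
                     probability = as.numeric(stats$overall)),
          "ss_overall.csv")
    per <- data.frame(residue = as.integer(rownames(stats$perResidue)),
                      stats$perResidue, check.names = FALSE)
    wfile(per, "ss_per_residue.csv")
    tl <- ssTimeline(traj, ss = ss)
    wfile(data.frame(residue = rownames(tl), tl, check.names = FALSE),
          "ss_timeline.csv")
    say("secondary structure done")

    # interactions
    ts <- interactionTimeseries(traj, params)
    names(ts)[names(ts) == "time"] <- "time_ns"
    wfile(ts, "hbond_timeseries.csv")

    rg <- vapply(seq_len(nf), function(k)
      radiusOfGyration(getFrame(traj, k), sys), numeric(1))
    wfile(data.frame(frame = seq_len(nf),
                     time_ns = if (length(frameTimes(traj)))
                       frameTimes(traj) else NA_real_,
                     rg_nm = rg / 10),
          "rg_series.csv")
    say("interaction and Rg series done")

    # contact maps over the window
    cmaps <- contactProbabilityMap(traj, window = window, params = params)
    wfile(data.frame(residue = rownames(cmaps$interchain),
                     cmaps$interchain, check.names = FALSE),
          "contact_map_inter.csv")
    wfile(data.frame(residue = rownames(cmaps$intrachain),
                     cmaps$intrachain, check.names = FALSE),
          "contact_map_intra.csv")

    # sheet topology per frame (flagging the analysis window)
    topo <- classifyFrames(traj, params, ss = ss)
    topo$in_window <- topo$frame %in% window
    wfile(topo, "sheet_topology.csv")
    say("topology classification done")

    # gromos clustering on the window
    sub <- peptideTrajectory(sys, traj@coords[, , window, drop = FALSE])
    rmat <- rmsdMatrix(sub)
    cl <- dauraCluster(rmat, cutoff = params@clusterCutoff)
    cldf <- data.frame(
      cluster = seq_along(clusterCenters(cl)),
      center_frame = window[clusterCenters(cl)],
      size = lengths(clusterMembers(cl)),
      population = clusterPopulations(cl))
    wfile(cldf, "clusters.csv")
    for (i in seq_len(min(nClusterStructures, nrow(cldf)))) {
      p <- file.path(outputDir, sprintf("cluster_center_%02d.pdb", i))
      writeMultimodelPDB(
        peptideTrajectory(sys, getFrame(traj, cldf$center_frame[i])), p)
      paths[[basename(p)]] <- p
    }
    say("clustering done: %d clusters", nrow(cldf))

    # 2D free-energy landscape over the window
    land <- pmf2d(topo$betaContacts[window], rg[window] / 10,
                  temperature = params@temperature)
    grid <- expand.grid(
      beta_contacts = (land@xedges[-1] + land@xedges[-length(land@xedges)]) / 2,
      rg_nm = (land@yedges[-1] + land@yedges[-length(land@yedges)]) / 2)
    grid$pmf_kJ_per_mol <- as.vector(land@pmf)
    wfile(grid, "pmf.csv")

    # convergence: split the window into halves, compare distributions
    half <- length(window) %/% 2
    conv <- if (half >= 1) {
      wa <- window[seq_len(half)]
      wb <- window[(half + 1L):length(window)]
      data.frame(
        observable = c("hbonds", "rg"),
        overlap = c(
          convergenceOverlap(traj, wa, wb, "hbonds", params = params),
          convergenceOverlap(traj, wa, wb, "rg", params = params)))
    } else data.frame(observable = character(0), overlap = numeric(0))
    wfile(conv, "convergence.csv")
    say("landscape and convergence done")
  }, warning = function(w) {
    nwarn <<- nwarn + 1L
    invokeRestart("muffleWarning")
  })

  say("warnings (aggregated): %d", nwarn)
  say("parameters: hbond %.2f A/%g deg, contact %.2f A, cutoff %.2f A, T %g K",
      params@hbondMaxDist, params@hbondMinAngle, params@contactMaxDist,
      params@clusterCutoff, params@temperature)
  say("elapsed: %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  writeLines(c(sprintf("OligoTraj %s",
                       as.character(utils::packageVersion("OligoTraj"))),
               logline),
             file.path(outputDir, "run_log.txt"))
  invisible(list(paths = paths, window = window, ssStats = stats,
                 topology = topo, clusters = cl, landscape = land,
                 contactMaps = cmaps))
}

#' Summarize a pipeline run
#'
#' Condenses a report bundle written by [runPipeline()] into a single JSON
#' summary: overall secondary-structure fractions, the dominant oligomer
#' class over the analysis window, the top clusters, and the range of the
#' beta-sheet contact coordinate.  Every number is read back from the CSVs.
#'
#' @param outputDir directory written by [runPipeline()].
#' @param jsonPath output JSON path (default `summary.json` inside
#'   `outputDir`).
#' @return the summary list, invisibly; the JSON file is written as a side
#'   effect.
#' @export
summarizeRun <- function(outputDir, jsonPath = file.path(outputDir,
                                                         "summary.json")) {
  need <- c("ss_overall.csv", "sheet_topology.csv", "clusters.csv",
            "pmf.csv")
  missing_files <- need[!file.exists(file.path(outputDir, need))]
  if (length(missing_files))
    stop("missing report(s): ", paste(missing_files, collapse = ", "))
  ssov <- utils::read.csv(file.path(outputDir, "ss_overall.csv"))
  topo <- utils::read.csv(file.path(outputDir, "sheet_topology.csv"))
  cl <- utils::read.csv(file.path(outputDir, "clusters.csv"))

  if ("in_window" %in% names(topo) && any(topo$in_window))
    topo <- topo[topo$in_window, , drop = FALSE]
  labtab <- sort(table(topo$label), decreasing = TRUE)
  summary <- list(
    ssFractions = stats::setNames(as.list(ssov$probability), ssov$category),
    dominantClass = names(labtab)[1],
    classCounts = as.list(labtab),
    topClusters = lapply(seq_len(min(4L, nrow(cl))), function(i)
      list(cluster = cl$cluster[i], centerFrame = cl$center_frame[i],
           population = cl$population[i])),
    betaContactRange = range(topo$betaContacts)
  )
  jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
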