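## Run configuration, provenance manifests, and the subcommand dispatcher
## that binds the pipeline together.

.CONFIG_DEFAULTS <- function() list(
  params = NULL,          # path to a parameter YAML, or NULL for defaults
  profile = list(diaHigh = 1, diaLow = 0.4, rockHigh = 2, rockLow = 1,
                 xSwitch = 0.9, cellLength = 50),
  diffusion = list(dRhoActive = 0.2, dRhoInactive = 20,
                   dRacActive = 0.2, dRacInactive = 20),
  inhibitors = list(ipa3Dose = 0, kIPAK = 2.5, y27632Dose = 0, kIROCK = 0.1,
                    atp = 1000, kdATP = 300),
  domain = list(mask = NULL, spacing = 1,
                synthetic = list(lengthPx = 120, widthPx = 50,
                                 shape = "teardrop")),
  solver = list(tMax = 600, dt = 1, outputDt = 5, nNodes = 200,
                rtol = 1e-7, atol = 1e-9),
  analysis = list(burstWindow = 600, minSeparation = 10),
  seed = 1,
  outdir = "."
)

#' Load and validate a run configuration
#'
#' Reads a YAML/JSON configuration, checks every key against the schema
#' (unknown keys are errors, listed exhaustively), fills defaults for
#' omitted keys, and validates types and signs.
#'
#' @param path configuration file path.
#' @return a list of class "RunConfig" with all defaults filled.
#' @export
loadValidateConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  def <- .CONFIG_DEFAULTS()
  errs <- character(0)
  bad <- setdiff(names(raw), names(def))
  if (length(bad)) errs <- c(errs, paste("unknown top-level key(s):",
                                         paste(bad, collapse = ", ")))
  for (sec in intersect(names(raw), names(def))) {
    if (is.list(def[[sec]]) && !is.null(raw[[sec]])) {
      if (!is.list(raw[[sec]])) {
        errs <- c(errs, paste0("section '", sec, "' must be a mapping"))
        next
      }
      extra <- setdiff(names(raw[[sec]]), names(def[[sec]]))
      if (length(extra)) {
        errs <- c(errs, paste0("unknown key(s) in '", sec, "': ",
                               paste(extra, collapse = ", ")))
      }
    }
  }
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  cfg <- modifyList(def, raw, keep.null = TRUE)
  ## type/sign checks
  num <- function(sec, key, positive = FALSE) {
    x <- cfg[[sec]][[key]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      errs <<- c(errs, sprintf("%s.%s must be a finite number", sec, key))
    } else if (positive && x <= 0) {
      errs <<- c(errs, sprintf("%s.%s must be positive", sec, key))
    }
  }
  for (k in c("diaHigh", "diaLow", "rockHigh", "rockLow", "xSwitch",
              "cellLength")) num("profile", k, positive = TRUE)
  for (k in names(cfg$diffusion)) num("diffusion", k)
  for (k in c("kIPAK", "kIROCK", "kdATP")) num("inhibitors", k, positive = TRUE)
  for (k in c("ipa3Dose", "y27632Dose", "atp")) num("inhibitors", k)
  for (k in c("tMax", "dt", "outputDt", "rtol", "atol")) num("solver", k, positive = TRUE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    errs <- c(errs, "seed must be a single integer")
  }
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  if (!is.null(cfg$params)) {
    cfg$kineticParams <- readKineticParams(cfg$params)
  } else {
    cfg$kineticParams <- defaultKineticParams()
  }
  class(cfg) <- "RunConfig"
  cfg
}

#' Write a run manifest
#'
#' Records the configuration, seed, package and R versions, runtime and
#' output files of a run as JSON next to the outputs.
#'
#' @param outdir output directory.
#' @param config the RunConfig (or any serializable list).
#' @param files character vector of written files.
#' @param elapsed elapsed seconds.
#' @return invisibly, the manifest path.
#' @export
writeManifest <- function(outdir, config, files, elapsed) {
  cfg <- config
  cfg$kineticParams <- if (!is.null(cfg$kineticParams)) {
    as.list(kineticValues(cfg$kineticParams))
  }
  man <- list(
    package = "RhoRacWaves",
    version = as.character(utils::packageVersion("RhoRacWaves")),
    rVersion = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    elapsedSeconds = elapsed,
    config = unclass(cfg),
    outputs = files
  )
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

## parse "0.1:3:41" into a seq specification
.parseRangeSpec <- function(s) {
  parts <- as.numeric(strsplit(s, ":", fixed = TRUE)[[1L]])
  if (length(parts) != 3L || any(!is.finite(parts))) {
    stop("range spec must be min:max:n, got '", s, "'")
  }
  list(range = parts[1:2], n = as.integer(parts[3L]))
}

.cliUsage <- function() {
  paste(
    "usage: rhoracwaves <subcommand> [options]",
    "subcommands:",
    "  simulate-ode --t <s> [--config cfg.yaml] [--out dir]",
    "  atlas --axis1 DIA <min:max:n> --axis2 ROCK <min:max:n> [--config cfg.yaml] [--out dir]",
    "  trace --axis PAK <min:max:n> [--config cfg.yaml] [--out dir]",
    "  qss [--config cfg.yaml] [--out dir]",
    "  simulate-pde [--mask cell.png] --t <s> [--config cfg.yaml] [--out dir]",
    "  hysteresis [--wellmixed] [--config cfg.yaml] [--out dir]",
    "  analyze --run <solution.rds> [--out dir]",
    "  synth [--config cfg.yaml] [--out dir]",
    sep = "\n")
}

## pull "--flag value" pairs and bare "--flag" switches out of argv
.parseArgv <- function(argv, switches = character(0)) {
  out <- list(positional = character(0))
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3L)
      if (key %in% switches) {
        out[[key]] <- TRUE
        i <- i + 1L
      } else {
        vals <- character(0)
        j <- i + 1L
        while (j <= length(argv) && !startsWith(argv[j], "--")) {
          vals <- c(vals, argv[j]); j <- j + 1L
        }
        out[[key]] <- vals
        i <- j
      }
    } else {
      out$positional <- c(out$positional, a)
      i <- i + 1L
    }
  }
  out
}

#' Command-line dispatcher
#'
#' Parses a subcommand argument vector, runs the corresponding pipeline
#' step, writes outputs and a provenance manifest into the output
#' directory, and returns an exit status (0 on success).  All randomness
#' derives from the single configured seed.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return integer exit status.
#' @export
cliDispatch <- function(argv) {
  t0 <- proc.time()[["elapsed"]]
  if (!length(argv)) { message(.cliUsage()); return(2L) }
  sub <- argv[1L]
  known <- c("simulate-ode", "atlas", "trace", "qss", "simulate-pde",
             "hysteresis", "analyze", "synth")
  if (!sub %in% known) {
    message("unknown subcommand '", sub, "'\n", .cliUsage())
    return(2L)
  }
  opt <- .parseArgv(argv[-1L], switches = "wellmixed")
  status <- tryCatch({
    cfg <- if (!is.null(opt$config)) loadValidateConfig(opt$config[1L]) else {
      cfg0 <- .CONFIG_DEFAULTS(); cfg0$kineticParams <- defaultKineticParams()
      class(cfg0) <- "RunConfig"; cfg0
    }
    outdir <- if (!is.null(opt$out)) opt$out[1L] else cfg$outdir
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    set.seed(as.integer(cfg$seed))
    files <- .cliRun(sub, opt, cfg, outdir)
    writeManifest(outdir, cfg, files, proc.time()[["elapsed"]] - t0)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}

.cliRun <- function(sub, opt, cfg, outdir) {
  kp <- cfg$kineticParams
  inh <- do.call(inhibitorParams, cfg$inhibitors)
  prof <- do.call(spatialProfile, cfg$profile)
  diff <- do.call(diffusionParams, cfg$diffusion)
  files <- character(0)
  put <- function(name) { files <<- c(files, file.path(outdir, name)); files[length(files)] }
  if (sub == "simulate-ode") {
    tMax <- if (!is.null(opt$t)) as.numeric(opt$t[1L]) else cfg$solver$tMax
    tr <- simulateOde(kp, inh, times = seq(0, tMax, cfg$solver$outputDt))
    write.table(tr, put("trajectory.tsv"), sep = "\t", row.names = FALSE,
                quote = FALSE)
  } else if (sub == "atlas") {
    ax1 <- if (!is.null(opt$axis1)) opt$axis1 else c("DIA", "0.1:3:41")
    ax2 <- if (!is.null(opt$axis2)) opt$axis2 else c("ROCK", "0.1:3:41")
    nm <- function(s) switch(toupper(s), DIA = "DIAtot", ROCK = "ROCKtot",
                             PAK = "PAKtot", stop("unknown axis '", s, "'"))
    r1 <- .parseRangeSpec(ax1[2L]); r2 <- .parseRangeSpec(ax2[2L])
    map <- scanBifurcationPlane(kp, inh, nm(ax1[1L]), nm(ax2[1L]),
                                r1$range, r2$range, c(r1$n, r2$n))
    write.table(regimeMapTable(map), put("regime_map.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    grDevices::png(put("regime_map.png"), 800, 700)
    plotRegimeMap(map)
    grDevices::dev.off()
  } else if (sub == "trace") {
    ax <- if (!is.null(opt$axis)) opt$axis else c("PAK", "0.1:1:19")
    nm <- switch(toupper(ax[1L]), DIA = "DIAtot", ROCK = "ROCKtot",
                 PAK = "PAKtot", stop("unknown axis '", ax[1L], "'"))
    r <- .parseRangeSpec(ax[2L])
    br <- traceBranch(kp, inh, axis = nm, range = r$range, resolution = r$n)
    write.table(br, put("branch.tsv"), sep = "\t", row.names = FALSE,
                quote = FALSE)
  } else if (sub == "qss") {
    pp <- computePhasePortrait(kp, inh)
    for (i in seq_along(pp$rhoNullcline)) {
      write.table(pp$rhoNullcline[[i]], put(sprintf("rho_nullcline_%d.tsv", i)),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
    for (i in seq_along(pp$racNullcline)) {
      write.table(pp$racNullcline[[i]], put(sprintf("rac_nullcline_%d.tsv", i)),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (!is.null(pp$intersections)) {
      write.table(pp$intersections, put("fixed_points.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
    }
    grDevices::png(put("phase_portrait.png"), 800, 700)
    plotPhasePortrait(pp)
    grDevices::dev.off()
  } else if (sub == "simulate-pde") {
    tMax <- if (!is.null(opt$t)) as.numeric(opt$t[1L]) else cfg$solver$tMax
    domain <- if (!is.null(opt$mask)) {
      rasterizeDomain(opt$mask[1L], cfg$domain$spacing)
    } else if (!is.null(cfg$domain$mask)) {
      rasterizeDomain(cfg$domain$mask, cfg$domain$spacing)
    } else {
      syn <- cfg$domain$synthetic
      mk <- generateCellMask(syn$lengthPx, syn$widthPx, syn$shape,
                             seed = cfg$seed)
      rasterizeDomain(mk, cfg$domain$spacing)
    }
    sol <- simulatePde(domain, prof, kp, diff, inh, tMax = tMax,
                       outputDt = cfg$solver$outputDt, dt = cfg$solver$dt)
    saveRDS(sol, put("solution.rds"))
    K <- buildKymograph(sol)
    write.table(K, put("kymograph.tsv"), sep = "\t", row.names = FALSE,
                col.names = FALSE, quote = FALSE)
  } else if (sub == "hysteresis") {
    hc <- runHysteresisProtocol(kp, "PAKtot", spatial = is.null(opt$wellmixed),
                                profile = prof, diffusion = diff,
                                inhibitors = inh)
    write.table(hc, put("hysteresis.tsv"), sep = "\t", row.names = FALSE,
                quote = FALSE)
  } else if (sub == "analyze") {
    if (is.null(opt$run)) stop("analyze needs --run <solution.rds>")
    sol <- readRDS(opt$run[1L])
    window <- min(cfg$analysis$burstWindow, diff(range(sol@times)))
    bt <- countBurstsByRegion(sol, window = window)
    write.table(as.data.frame(unclass(bt)), put("bursts.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    K <- buildKymograph(sol)
    write.table(K, put("kymograph.tsv"), sep = "\t", row.names = FALSE,
                col.names = FALSE, quote = FALSE)
    grDevices::png(put("kymograph.png"), 800, 500)
    plotKymograph(K)
    grDevices::dev.off()
  } else if (sub == "synth") {
    syn <- cfg$domain$synthetic
    mk <- generateCellMask(syn$lengthPx, syn$widthPx, syn$shape, seed = cfg$seed)
    writeMaskPng(mk, put("mask.png"))
    for (ch in c("RhoA-DIA", "RhoA-ROCK")) {
      pat <- generatePlaPattern(mk, ch, seed = cfg$seed)
      write.table(pat, put(paste0("pla_", gsub("RhoA-", "", ch), ".tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  files
}

#' Flatten a RegimeMap into a table
#'
#' @param map a \linkS4class{RegimeMap}.
#' @return data.frame with columns axis1, axis2, label, nStates, nStable,
#'   cycle.
#' @export
regimeMapTable <- function(map) {
  stopifnot(is(map, "RegimeMap"))
  g <- expand.grid(a1 = map@grid1, a2 = map@grid2)
  out <- data.frame(g$a1, g$a2, as.vector(map@labels), as.vector(map@nStates),
                    as.vector(map@nStable), as.vector(map@limitCycle))
  names(out) <- c(map@axis1, map@axis2, "label", "nStates", "nStable", "cycle")
  out
}
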