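# File I/O and pipeline plumbing. CSV dialect: comma-separated, '.' decimal,
# UTF-8, mandatory header row, header-keyed columns (order free).
# Units: concentrations nM, time s, distances Angstrom, angles degrees,
# 0-based bp indices.

#' Read and validate a typed data table
#'
#' @param path CSV file path.
#' @param schema `"titration"` (`conc_nM`, `proximity_ratio`, optional
#'   `sigma`), `"chase"` (`time_s`, `proximity_ratio`, strictly increasing
#'   time) or `"bursts"` (`burst_id`, `donor_counts`, `acceptor_counts`,
#'   non-negative integers).
#' @return Validated `data.frame` (a `"BurstSet"` for the bursts schema).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(conc_nM = c(1, 10, 100),
#'                      proximity_ratio = c(0.3, 0.4, 0.5)), f,
#'           row.names = FALSE)
#' readTable(f, "titration")
#' @export
readTable <- function(path, schema = c("titration", "chase", "bursts")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- switch(schema,
    titration = c("conc_nM", "proximity_ratio"),
    chase = c("time_s", "proximity_ratio"),
    bursts = c("burst_id", "donor_counts", "acceptor_counts"))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("missing column(s) for ", schema, " schema: ",
         paste(missing, collapse = ", "))
  checkNumeric <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0L)
      stop("non-numeric value in column '", col, "' at row ", bad[1L])
    if (anyNA(v)) stop("missing value in column '", col, "' at row ",
                       which(is.na(v))[1L])
    v
  }
  for (col in intersect(c(required, "sigma"), names(df)))
    df[[col]] <- checkNumeric(col)
  if (schema == "titration") {
    bad <- which(df$conc_nM < 0)
    if (length(bad) > 0L)
      stop("negative concentration at row ", bad[1L])
  } else if (schema == "chase") {
    if (is.unsorted(df$time_s, strictly = TRUE)) {
      bad <- which(diff(df$time_s) <= 0)[1L] + 1L
      stop("time_s not strictly increasing at row ", bad)
    }
  } else {
    for (col in c("donor_counts", "acceptor_counts")) {
      bad <- which(df[[col]] < 0 | df[[col]] != round(df[[col]]))
      if (length(bad) > 0L)
        stop("column '", col, "' must hold non-negative integers (row ",
             bad[1L], ")")
    }
    class(df) <- c("BurstSet", "data.frame")
  }
  df
}

knownConfigKeys <- list(
  top = c("construct", "energetics", "fret", "bend", "kinetics",
          "nucleosome", "fixture", "input", "conc_grid_nM", "phases",
          "out_dir", "seed", "log_level"),
  construct = c("name", "length_bp", "sequence", "fasta",
                "specific_register", "footprint_bp", "contact_span_bp",
                "inactive_registers", "donor_bp", "acceptor_bp"),
  energetics = c("kd_specific_nM", "kd_nonspecific_nM", "omega", "salt_mM",
                 "salt_ref_mM", "salt_exp_specific", "salt_exp_nonspecific",
                 "tfiia", "tfiia_specificity_boost", "tfiia_ns_suppression"),
  fret = c("r0_A", "gamma", "crosstalk", "direct_excitation",
           "background_donor", "background_acceptor"),
  bend = c("angle_specific_deg", "angle_nonspecific_deg", "rise_per_bp_A",
           "linker_offset_A"),
  kinetics = c("k_on_per_M_s", "k_off_specific_per_s",
               "k_off_nonspecific_per_s", "k_slide_per_s", "tbp_nM",
               "competitor_nM", "incubation_s", "observation_s"),
  nucleosome = c("construct_length_bp", "wrapped_bp", "tata_depth_bp",
                 "histone_state", "salt_mM", "tfiia"),
  fixture = c("name", "action"))

checkKeys <- function(block, what) {
  unknown <- setdiff(names(block), knownConfigKeys[[what]])
  if (length(unknown) > 0L)
    stop("unknown key(s) in ", what, " config: ",
         paste(unknown, collapse = ", "))
  block
}

#' Read a run configuration file
#'
#' Parses a YAML configuration with blocks `construct`, `energetics`,
#' `fret`, `bend`, `kinetics`, `nucleosome`, `fixture` plus `input`,
#' `conc_grid_nM`, `out_dir` and `seed`. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  checkKeys(cfg, "top")
  for (blk in intersect(names(cfg), c("construct", "energetics", "fret",
                                      "bend", "kinetics", "nucleosome",
                                      "fixture")))
    checkKeys(cfg[[blk]], blk)
  cfg
}

constructFromConfig <- function(cc) {
  cc <- checkKeys(cc, "construct")
  seqStr <- cc$sequence %||% NA_character_
  if (!is.null(cc$fasta)) {
    fa <- Biostrings::readDNAStringSet(cc$fasta)
    seqStr <- as.character(fa[[1L]])
    if (is.null(cc$length_bp)) cc$length_bp <- nchar(seqStr)
  }
  latticeSpec(cc$length_bp,
              sequence = seqStr,
              specificRegister = cc$specific_register %||% NA,
              footprintBp = cc$footprint_bp %||% 8L,
              contactSpanBp = cc$contact_span_bp %||% cc$footprint_bp %||% 8L,
              inactiveRegisters = unlist(cc$inactive_registers) %||%
                integer(0),
              dyeDonor = dyeSite(cc$donor_bp %||% 0L),
              dyeAcceptor = dyeSite(cc$acceptor_bp %||% (cc$length_bp - 1L)),
              name = cc$name %||% "construct")
}

energeticsFromConfig <- function(ec) {
  ec <- checkKeys(ec, "energetics")
  bindingEnergetics(
    kdSpecific = ec$kd_specific_nM %||% 5,
    kdNonspecific = ec$kd_nonspecific_nM %||% 40,
    cooperativityOmega = ec$omega %||% 5,
    saltMM = ec$salt_mM %||% 50,
    saltRefMM = ec$salt_ref_mM %||% 50,
    saltExpSpecific = ec$salt_exp_specific %||% 0.4,
    saltExpNonspecific = ec$salt_exp_nonspecific %||% 4,
    tfiiaMode = isTRUE(ec$tfiia),
    tfiiaSpecificityBoost = ec$tfiia_specificity_boost %||% 4,
    tfiiaNsSuppression = ec$tfiia_ns_suppression %||% 25)
}

fretFromConfig <- function(fc) {
  fc <- checkKeys(fc %||% list(), "fret")
  fretParameters(r0 = fc$r0_A %||% 51, gamma = fc$gamma %||% 1,
                 donorCrosstalkFraction = fc$crosstalk %||% 0,
                 directExcitationFraction = fc$direct_excitation %||% 0,
                 backgroundDonor = fc$background_donor %||% 0,
                 backgroundAcceptor = fc$background_acceptor %||% 0)
}

bendFromConfig <- function(bc) {
  bc <- checkKeys(bc %||% list(), "bend")
  bendModel(bendAngleSpecific = bc$angle_specific_deg %||% 105,
            bendAngleNonspecific = bc$angle_nonspecific_deg %||% 105,
            risePerBp = bc$rise_per_bp_A %||% 3.4,
            dyeLinkerOffset = bc$linker_offset_A %||% 0)
}

writeManifest <- function(outDir, subcommand, cfg, seed, artifacts) {
  manifest <- list(subcommand = subcommand,
                   package = "TBPbind",
                   version = as.character(utils::packageVersion("TBPbind")),
                   seed = seed,
                   config = cfg,
                   artifacts = artifacts)
  path <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  path
}

#' Run a pipeline subcommand
#'
#' Executes one stage of the simulation/analysis pipeline and writes its
#' CSV/JSON artifacts plus a run manifest (resolved configuration, package
#' version, seed) into `out_dir`. All randomness derives from the single
#' `seed`. Deterministic: repeated runs with identical config and seed give
#' byte-identical CSV artifacts.
#'
#' Subcommands: `simulate-isotherm`, `simulate-chase`, `simulate-bursts`,
#' `fit-isotherm`, `fit-chase`, `analyze-bursts`, `nucleosome-predict`,
#' `fixtures`.
#'
#' @param name subcommand name.
#' @param config configuration list (see [readRunConfig()]) or a YAML path.
#' @param outDir output directory (created if needed; overrides
#'   `config$out_dir`).
#' @param seed integer seed (overrides `config$seed`; default 1).
#' @return Invisibly, a list with `artifacts` (paths) and `results`.
#' @examples
#' out <- runSubcommand("fixtures",
#'                      config = list(fixture = list(action = "list")),
#'                      outDir = tempfile())
#' @export
runSubcommand <- function(name, config = list(), outDir = NULL,
                          seed = NULL) {
  subcommands <- c("simulate-isotherm", "simulate-chase", "simulate-bursts",
                   "fit-isotherm", "fit-chase", "analyze-bursts",
                   "nucleosome-predict", "fixtures")
  if (!name %in% subcommands)
    stop("unknown subcommand '", name, "'; usage: one of ",
         paste(subcommands, collapse = ", "))
  if (is.character(config)) config <- readRunConfig(config)
  checkKeys(config, "top")
  outDir <- outDir %||% config$out_dir %||% file.path(tempdir(), "tbpbind")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  artifacts <- character(0)
  results <- list()
  writeCsv <- function(df, file) {
    path <- file.path(outDir, file)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    artifacts <<- c(artifacts, path)
    path
  }
  writeJson <- function(x, file) {
    path <- file.path(outDir, file)
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    artifacts <<- c(artifacts, path)
    path
  }

  if (name == "simulate-isotherm") {
    lat <- constructFromConfig(config$construct %||% list(length_bp = 14,
                                                          specific_register = 6))
    en <- energeticsFromConfig(config$energetics %||% list())
    grid <- unlist(config$conc_grid_nM) %||% defaultTitrationGrid()
    iso <- predictedIsotherm(lat, en, grid, fret = fretFromConfig(config$fret),
                             bend = bendFromConfig(config$bend))
    writeCsv(iso[, c("conc_nM", "proximity_ratio")], "isotherm.csv")
    writeJson(list(kd_specific_nM = en@kdSpecific, salt_mM = en@saltMM,
                   omega = en@cooperativityOmega), "isotherm_params.json")
    results$isotherm <- iso
  } else if (name == "simulate-chase") {
    kc <- checkKeys(config$kinetics %||% list(), "kinetics")
    scheme <- kineticScheme(
      lattice = if (is.null(config$construct)) latticeSpec(
        14, specificRegister = 6, name = "TATA-14E") else
        constructFromConfig(config$construct),
      kOnPerRegister = kc$k_on_per_M_s %||% 2e6,
      kOffSpecific = kc$k_off_specific_per_s %||% 0.0014,
      kOffNonspecific = kc$k_off_nonspecific_per_s %||% 0.02,
      kSlide = kc$k_slide_per_s %||% 0,
      tbpNM = kc$tbp_nM %||% 30,
      competitorNM = kc$competitor_nM %||% 2000,
      incubationS = kc$incubation_s %||% 60,
      observationS = kc$observation_s %||% 1800)
    tr <- simulateChase(scheme, fret = fretFromConfig(config$fret),
                        bend = bendFromConfig(config$bend))
    writeCsv(tr, "chase.csv")
    results$trace <- tr
  } else if (name == "simulate-bursts") {
    fxName <- config$fixture$name %||% "fig2_tata14E_10nM"
    b <- generateBurstStream(fxName, seed = seed)
    writeCsv(as.data.frame(b), "bursts.csv")
    results$bursts <- b
  } else if (name == "fit-isotherm") {
    series <- readTable(config$input, "titration")
    fit <- fitSingleSite(series)
    report <- list(kd_nM = fit$kd, p_min = fit$pMin, p_max = fit$pMax,
                   se_kd_nM = unname(fit$se["kd"]), rss = fit$rss,
                   aic = fit$aic)
    pos <- series$conc_nM[series$conc_nM > 0]
    if (nrow(series) >= 8L && length(pos) >= 2L &&
        max(pos) / min(pos) >= 100) {
      bi <- detectBiphasic(series)
      report$biphasic <- list(is_biphasic = bi$isBiphasic,
                              delta_aic = bi$deltaAIC,
                              decline_amplitude = bi$decline$amplitude,
                              decline_midpoint_nM = bi$decline$midpoint_nM)
      results$biphasic <- bi
    }
    writeJson(report, "isotherm_fit.json")
    results$fit <- fit
  } else if (name == "fit-chase") {
    trace <- readTable(config$input, "chase")
    fit1 <- fitExponential(trace, phases = 1)
    fit2 <- fitExponential(trace, phases = 2)
    writeJson(list(
      one_phase = list(k_per_s = fit1$kFast, rss = fit1$rss,
                       aic = fit1$aic),
      two_phase = list(k_fast_per_s = fit2$kFast, k_slow_per_s = fit2$kSlow,
                       a_fast = fit2$aFast, a_slow = fit2$aSlow,
                       fast_fraction = fastFraction(fit2),
                       se = as.list(fit2$se), rss = fit2$rss,
                       aic = fit2$aic)), "chase_fit.json")
    results$fit1 <- fit1
    results$fit2 <- fit2
  } else if (name == "analyze-bursts") {
    bursts <- readTable(config$input, "bursts")
    sel <- selectBursts(bursts, 30)
    h <- proximityHistogram(sel)
    writeCsv(as.data.frame(h), "histogram.csv")
    gf <- fitWidth(h)
    writeJson(list(n_selected = nrow(sel),
                   mean_p = mean(burstProximityRatios(sel)),
                   gaussian_mean = gf$mean, gaussian_sigma = gf$sigma),
              "burst_analysis.json")
    results$histogram <- h
    results$width <- gf
  } else if (name == "nucleosome-predict") {
    nc <- checkKeys(config$nucleosome %||% list(), "nucleosome")
    scen <- nucleosomeScenario(
      constructLengthBp = nc$construct_length_bp %||% 159,
      wrappedBp = nc$wrapped_bp %||% 147,
      tataDepthBp = nc$tata_depth_bp %||% 5,
      histoneState = nc$histone_state %||% "recombinant",
      saltMM = nc$salt_mM %||% 150,
      tfiia = isTRUE(nc$tfiia))
    res <- nucleosomeIsotherm(scen)
    writeCsv(res$isotherm, "nucleosome_isotherm.csv")
    writeJson(list(exposure_probability = res$exposureProbability,
                   apparent_kd_nM = res$apparentKd,
                   naked_kd_nM = res$nakedKd,
                   amplitude_fraction = res$maxAmplitudeFraction,
                   mode = res$mode), "nucleosome_predict.json")
    results$competition <- res
  } else if (name == "fixtures") {
    action <- config$fixture$action %||% "list"
    if (action == "list") {
      writeJson(listFixtures(), "fixtures.json")
    } else if (action == "make") {
      fxName <- config$fixture$name
      fx <- getFixture(fxName)
      df <- switch(fx$kind,
                   titration = generateTitration(fxName, seed = seed),
                   chase = generateChase(fxName, seed = seed),
                   bursts = as.data.frame(generateBurstStream(fxName,
                                                              seed = seed)))
      writeCsv(df, paste0(fxName, ".csv"))
      results$fixture <- df
    } else stop("fixture action must be 'list' or 'make'")
  }
  writeManifest(outDir, name, config, seed, artifacts)
  invisible(list(artifacts = artifacts, results = results))
}
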