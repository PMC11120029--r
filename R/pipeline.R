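## allowed configuration keys (nested); NULL marks a leaf
.configSchema <- function() {
  list(
    seed = NULL,
    traces = list(conditions = NULL, n_points = NULL, t_max = NULL,
                  noise_sd = NULL, enzyme = NULL, duplex = NULL),
    fit = list(n_starts = NULL),
    selection = list(enabled = NULL, windows = NULL, alpha = NULL,
                     n_starts = NULL),
    melting = list(duplexes = NULL, noise_sd = NULL, window = NULL,
                   poly_order = NULL),
    titration = list(clamp_conc = NULL, points = NULL, noise_sd = NULL),
    cleavage = list(conditions = NULL, t_max = NULL, n_points = NULL,
                    noise_sd = NULL)
  )
}

.checkKeys <- function(value, schema, path = "") {
  if (!is.list(schema)) return(invisible(TRUE))
  for (nm in names(value)) {
    here <- if (nzchar(path)) paste0(path, "$", nm) else nm
    if (!nm %in% names(schema)) {
      stop("unknown config key: ", here, call. = FALSE)
    }
    if (is.list(schema[[nm]]) && !is.null(value[[nm]])) {
      if (!is.list(value[[nm]])) stop("config key ", here, " must be a mapping",
                                      call. = FALSE)
      .checkKeys(value[[nm]], schema[[nm]], here)
    }
  }
  invisible(TRUE)
}

#' Pipeline configuration
#'
#' `defaultRunConfig()` returns the full-size default configuration;
#' `readRunConfig()` loads a YAML file, merges it over the defaults and
#' rejects unknown keys naming their location; `validateRunConfig()` checks
#' a configuration list directly.
#'
#' @param path YAML file path.
#' @param config configuration list.
#' @return a validated configuration list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    traces = list(
      conditions = c("oxoG/C", "G/C", "oxoG/oxoG-clamp"),
      n_points = 400L, t_max = 1.0, noise_sd = 0.01,
      enzyme = 1e-6, duplex = c(0.4, 0.8, 1.2, 1.6) * 1e-6
    ),
    fit = list(n_starts = 5L),
    selection = list(enabled = TRUE, windows = c(0.05, 1.0), alpha = 0.01,
                     n_starts = 3L),
    melting = list(
      duplexes = c("oxoG/C", "oxoG/oxoG-clamp", "G/C", "G/oxoG-clamp"),
      noise_sd = 0.002, window = 11L, poly_order = 2L
    ),
    titration = list(
      clamp_conc = 1e-5,
      points = c(0, 0.1, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 2) * 1e-5,
      noise_sd = 0.01
    ),
    cleavage = list(
      conditions = c("oxoG/C", "oxoG/oxoG-clamp"),
      t_max = 7200, n_points = 12L, noise_sd = 0.02
    )
  )
}

#' @rdname defaultRunConfig
#' @export
validateRunConfig <- function(config) {
  .checkKeys(config, .configSchema())
  config
}

#' @rdname defaultRunConfig
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validateRunConfig(user)
  merge2 <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge2(base[[nm]], over[[nm]])
      } else over[[nm]]
    }
    base
  }
  merge2(defaultRunConfig(), user)
}

.reportLines <- function(report) {
  fmt <- function(x, d = 4) formatC(x, digits = d, format = "g")
  ln <- c("clamp-kinetics pipeline report",
          paste0("seed: ", report$seed), "")
  if (!is.null(report$binding)) {
    ln <- c(ln, "== Binding constants (global stopped-flow fits) ==")
    tab <- report$binding$constants
    for (i in seq_len(nrow(tab))) {
      ln <- c(ln, sprintf("  %-16s K1 = %s /M  K2 = %s  Ka = %s /M (SE %s)",
                          tab$condition[i], fmt(tab$K1[i]), fmt(tab$K2[i], 3),
                          fmt(tab$Ka[i]), fmt(tab$KaSE[i], 2)))
    }
    if (!is.null(report$binding$kaRatios)) {
      r <- report$binding$kaRatios
      for (i in seq_len(nrow(r))) for (j in seq_len(ncol(r))) {
        if (i < j) ln <- c(ln, sprintf("  Ka ratio %s / %s = %s",
                                       rownames(r)[i], colnames(r)[j],
                                       fmt(r[i, j], 3)))
      }
    }
    ln <- c(ln, "")
  }
  if (!is.null(report$melting)) {
    ln <- c(ln, "== Melting temperatures (derivative maxima) ==")
    tab <- report$melting$tm
    for (i in seq_len(nrow(tab))) {
      ln <- c(ln, sprintf("  %-16s Tm = %.2f degC", tab$duplex[i], tab$tm[i]))
    }
    for (i in seq_len(nrow(report$melting$delta))) {
      d <- report$melting$delta[i, ]
      ln <- c(ln, sprintf("  deltaT %s - %s = %.2f degC", d$a, d$b, d$deltaT))
    }
    ln <- c(ln, "")
  }
  if (!is.null(report$quench)) {
    q <- report$quench
    ln <- c(ln, "== Hybridization quenching ==",
            sprintf("  fitted Kd = %s M, quench efficiency = %.3f",
                    fmt(q$Kd), q$quenchEff),
            sprintf("  equimolar quench = %.1f%%; G-partner control flat at 1",
                    q$equimolarQuenchPct), "")
  }
  if (!is.null(report$cleavage)) {
    ln <- c(ln, "== Cleavage (single-turnover, joint fits) ==")
    for (nm in names(report$cleavage)) {
      f <- report$cleavage[[nm]]
      ln <- c(ln, sprintf(
        "  %-16s kg = %s /s  kl = %s /s  active fraction = %.3f%s",
        nm, fmt(f$kg), fmt(f$kl), f$activeFraction,
        if (length(f$flags)) paste0("  [", paste(f$flags, collapse = ", "), "]") else ""))
    }
  }
  ln
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes generate -> fit (-> select) -> melt -> titrate -> cleave as
#' configured, using the reference fixtures as generator ground truth,
#' writes all intermediate CSVs plus a structured `report.txt` into
#' `outDir`, and returns the report as a list. Output is deterministic for
#' a fixed configuration (every stage seed derives from `config$seed`).
#'
#' @param config configuration list (see [defaultRunConfig()]).
#' @param outDir output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return the report list, invisibly.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = tempfile("run"),
                        quiet = FALSE) {
  validateRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  say <- function(...) if (!quiet) message(...)
  report <- list(seed = seed)
  safeName <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

  ## -- stopped-flow global fits per condition ------------------------------
  tc <- config$traces
  fx <- conditionFixtures()
  fits <- list()
  selections <- list()
  for (i in seq_along(tc$conditions)) {
    cond <- tc$conditions[i]
    if (!cond %in% names(fx)) stop("no binding fixture for condition ", cond)
    k <- fx[[cond]]
    scheme <- twoStepBindingScheme(k$k1, k$k_1, k$k2, k$k_2)
    inst <- instrumentModel(tMax = tc$t_max, nPoints = tc$n_points,
                            noiseSd = tc$noise_sd)
    design <- data.frame(enzyme = tc$enzyme, duplex = tc$duplex)
    say("simulating and fitting traces: ", cond)
    ts <- simulateTraceSet(scheme, clampResponseModel(), inst, design,
                           seed = seed + 10L + i, condition = cond)
    writeTraceSetCSV(ts, file.path(outDir, sprintf("traces_%s.csv", safeName(cond))))
    if (isTRUE(config$selection$enabled)) {
      sel <- selectMechanism(ts, windows = config$selection$windows,
                             alpha = config$selection$alpha,
                             nStarts = config$selection$n_starts,
                             seed = seed + 10L + i)
      selections[[cond]] <- sel
      fits[[cond]] <- sel@fits[[sel@chosen]]
    } else {
      fits[[cond]] <- globalFit(ts, twoStepBindingScheme(1e6, 10, 10, 10),
                                nStarts = config$fit$n_starts,
                                seed = seed + 10L + i)
    }
  }
  if (length(fits)) {
    report$binding <- compareConditions(fits)
    report$selection <- lapply(selections, function(s)
      list(chosen = s@chosen, flags = s@flags))
    utils::write.csv(report$binding$constants,
                     file.path(outDir, "binding_constants.csv"),
                     row.names = FALSE)
  }

  ## -- melting -------------------------------------------------------------
  mc <- config$melting
  if (length(mc$duplexes)) {
    say("simulating and processing melting curves")
    mfx <- meltingFixtures()
    ests <- list()
    for (i in seq_along(mc$duplexes)) {
      dp <- mc$duplexes[i]
      tmTrue <- mfx$anchor[match(dp, mfx$duplex)]
      if (is.na(tmTrue)) stop("no melting fixture for duplex ", dp)
      curve <- simulateMeltingCurve(tmTrue, noiseSd = mc$noise_sd,
                                    seed = seed + 30L + i, label = dp)
      writeMeltingCurveCSV(curve, file.path(outDir, sprintf("melting_%s.csv",
                                                            safeName(dp))))
      ests[[dp]] <- differentialMelting(baselineCorrect(curve),
                                        window = mc$window,
                                        polyOrder = mc$poly_order)
    }
    tmTab <- data.frame(duplex = names(ests),
                        tm = vapply(ests, function(e) e@consensus, numeric(1)))
    pairs <- list(c("oxoG/C", "oxoG/oxoG-clamp"), c("G/C", "G/oxoG-clamp"),
                  c("AP/C", "AP/oxoG-clamp"))
    delta <- do.call(rbind, Filter(Negate(is.null), lapply(pairs, function(p) {
      if (!all(p %in% names(ests))) return(NULL)
      data.frame(a = p[1L], b = p[2L],
                 deltaT = deltaTm(ests[[p[1L]]], ests[[p[2L]]]))
    })))
    report$melting <- list(tm = tmTab,
                           delta = if (is.null(delta))
                             data.frame(a = character(), b = character(),
                                        deltaT = numeric()) else delta)
    utils::write.csv(tmTab, file.path(outDir, "melting_tm.csv"),
                     row.names = FALSE)
  }

  ## -- titration -----------------------------------------------------------
  ti <- config$titration
  if (length(ti$points)) {
    say("simulating and fitting quench titration")
    qm <- quenchFixture()
    ser <- simulateTitration(ti$clamp_conc, ti$points, qm@Kd, qm@quenchEff,
                             noiseSd = ti$noise_sd, seed = seed + 50L)
    utils::write.csv(ser, file.path(outDir, "titration.csv"), row.names = FALSE)
    fit <- fitQuenchTitration(ser, ti$clamp_conc)
    eqQuench <- 100 * (1 - predictRelativeFluorescence(fit, ti$clamp_conc,
                                                       ti$clamp_conc))
    report$quench <- list(Kd = fit@Kd, quenchEff = fit@quenchEff,
                          equimolarQuenchPct = eqQuench, flags = fit@flags)
  }

  ## -- cleavage ------------------------------------------------------------
  cl <- config$cleavage
  if (length(cl$conditions)) {
    say("simulating and fitting cleavage time courses")
    cfx <- cleavageFixtures()
    tgrid <- seq(0, cl$t_max, length.out = cl$n_points + 1L)[-1L]
    courses <- list()
    report$cleavage <- list()
    for (i in seq_along(cl$conditions)) {
      cond <- cl$conditions[i]
      p <- cfx[[cond]]
      if (is.null(p)) stop("no cleavage fixture for condition ", cond)
      alk <- simulateCleavageTimecourse(p@kg, p@kl, p@activeFraction, tgrid,
                                        alkali = TRUE, noiseSd = cl$noise_sd,
                                        seed = seed + 60L + 2L * i,
                                        condition = cond)
      unt <- simulateCleavageTimecourse(p@kg, p@kl, p@activeFraction, tgrid,
                                        alkali = FALSE, noiseSd = cl$noise_sd,
                                        seed = seed + 61L + 2L * i,
                                        condition = cond)
      courses <- c(courses, list(alk, unt))
      f <- fitCleavage(alk, unt)
      report$cleavage[[cond]] <- list(kg = f@params@kg, kl = f@params@kl,
                                      activeFraction = f@params@activeFraction,
                                      flags = f@flags)
    }
    writeCleavageCSV(courses, file.path(outDir, "cleavage.csv"))
  }

  writeLines(.reportLines(report), file.path(outDir, "report.txt"))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("report written to ", file.path(outDir, "report.txt"))
  invisible(report)
}
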