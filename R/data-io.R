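#' Read and write instrument-style CSV tables
#'
#' All tabular I/O uses plain CSV with header rows, mirroring vendor
#' exports. Trace sets are written tidy (`trace`, `enzyme`, `duplex`,
#' `time`, `signal`); melting curves spectrometer-style (`temperature` plus
#' one column per wavelength, e.g. `A260`); titrations as
#' (`partner_total`, `rel_fluorescence`); cleavage densitometry as
#' (`time_s`, `fraction_cleaved`, `alkali`, `condition`).
#'
#' @param x object to write.
#' @param file CSV path.
#' @return writers return `file` invisibly; readers return the package
#'   object.
#' @name table-io
NULL

#' @rdname table-io
#' @export
writeTraceSetCSV <- function(x, file) {
  stopifnot(is(x, "TraceSet"))
  rows <- do.call(rbind, lapply(seq_along(x@traces), function(i) {
    data.frame(trace = i,
               enzyme = x@design$enzyme[i], duplex = x@design$duplex[i],
               time = x@traces[[i]]$time, signal = x@traces[[i]]$signal)
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' @rdname table-io
#' @param condition condition label attached on read.
#' @export
readTraceSetCSV <- function(file, condition = "imported") {
  d <- utils::read.csv(file)
  stopifnot(all(c("trace", "enzyme", "duplex", "time", "signal") %in% names(d)))
  ids <- sort(unique(d$trace))
  traces <- lapply(ids, function(i) {
    di <- d[d$trace == i, ]
    data.frame(time = di$time, signal = di$signal)
  })
  design <- do.call(rbind, lapply(ids, function(i) {
    di <- d[d$trace == i, ][1L, ]
    data.frame(enzyme = di$enzyme, duplex = di$duplex)
  }))
  new("TraceSet", traces = traces, design = design,
      condition = condition, groundTruth = list())
}

#' @rdname table-io
#' @export
writeMeltingCurveCSV <- function(x, file) {
  stopifnot(is(x, "MeltingCurve"))
  d <- data.frame(temperature = x@temperatures)
  for (wl in names(x@absorbance)) d[[paste0("A", wl)]] <- x@absorbance[[wl]]
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}

#' @rdname table-io
#' @param label duplex label attached on read.
#' @param strandConc molar strand concentration attached on read.
#' @export
readMeltingCurveCSV <- function(file, label = "imported", strandConc = 2e-6) {
  d <- utils::read.csv(file)
  stopifnot("temperature" %in% names(d))
  wls <- grep("^A\\d+$", names(d), value = TRUE)
  if (!length(wls)) stop("no wavelength columns (A260, A270, ...) found")
  absorbance <- stats::setNames(lapply(wls, function(w) d[[w]]), sub("^A", "", wls))
  new("MeltingCurve", temperatures = d$temperature, absorbance = absorbance,
      label = label, strandConc = strandConc, processing = list(),
      groundTruth = list())
}

#' @rdname table-io
#' @export
writeCleavageCSV <- function(x, file) {
  stopifnot(is.list(x))
  rows <- do.call(rbind, lapply(x, function(tc) {
    data.frame(time_s = tc@times, fraction_cleaved = tc@readout,
               alkali = tc@alkaliTreated, condition = tc@condition)
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' @rdname table-io
#' @export
readCleavageCSV <- function(file) {
  d <- utils::read.csv(file)
  stopifnot(all(c("time_s", "fraction_cleaved", "alkali", "condition") %in% names(d)))
  groups <- split(d, interaction(d$condition, d$alkali, drop = TRUE))
  lapply(groups, function(g) {
    new("CleavageTimeCourse", times = g$time_s, readout = g$fraction_cleaved,
        alkaliTreated = g$alkali[1L], condition = as.character(g$condition[1L]),
        groundTruth = list())
  })
}
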