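#' Read and write kinetic schemes as plain text
#'
#' Schemes are serialized one step per line in the form
#' `E + S <-> ES ; k1, k_1` (irreversible steps use `->` and a single rate
#' name), followed by a `[rates]` section of `name = value` pairs. A
#' `# species:` header preserves species order so that
#' `readScheme(writeScheme(x))` round-trips exactly.
#'
#' @param scheme a [KineticScheme-class].
#' @param file path (or connection) to write to / read from.
#' @return `writeScheme()` returns `file` invisibly; `readScheme()` returns a
#'   validated [KineticScheme-class].
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeScheme(twoStepBindingScheme(5e6, 50, 15, 10), f)
#' readScheme(f)
#' @export
writeScheme <- function(scheme, file) {
  validObject(scheme)
  lines <- c(sprintf("# species: %s", paste(scheme@species, collapse = " ")))
  for (st in scheme@steps) {
    arrow <- if (is.na(st$kr)) "->" else "<->"
    klab <- if (is.na(st$kr)) st$kf else paste(st$kf, st$kr, sep = ", ")
    lines <- c(lines, sprintf("%s %s %s ; %s",
                              paste(st$reactants, collapse = " + "), arrow,
                              paste(st$products, collapse = " + "), klab))
  }
  lines <- c(lines, "", "[rates]",
             sprintf("%s = %s", names(scheme@rateConstants),
                     formatC(scheme@rateConstants, digits = 17, format = "g")))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname writeScheme
#' @export
readScheme <- function(file) {
  lines <- readLines(file)
  lines <- trimws(lines)
  speciesOrder <- character(0)
  hdr <- grep("^# species:", lines, value = TRUE)
  if (length(hdr)) {
    speciesOrder <- strsplit(trimws(sub("^# species:", "", hdr[1L])), "\\s+")[[1L]]
  }
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ratesAt <- match("[rates]", lines)
  if (is.na(ratesAt)) stop("scheme file has no [rates] section")
  stepLines <- lines[seq_len(ratesAt - 1L)]
  rateLines <- lines[-seq_len(ratesAt)]

  steps <- list()
  seen <- character(0)
  for (ln in stepLines) {
    parts <- strsplit(ln, ";", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("malformed step line: ", ln)
    eqn <- trimws(parts[1L])
    knames <- trimws(strsplit(parts[2L], ",", fixed = TRUE)[[1L]])
    reversible <- grepl("<->", eqn, fixed = TRUE)
    sides <- strsplit(eqn, if (reversible) "<->" else "->", fixed = TRUE)[[1L]]
    if (length(sides) != 2L) stop("malformed step equation: ", eqn)
    splitSide <- function(s) trimws(strsplit(s, "+", fixed = TRUE)[[1L]])
    reactants <- splitSide(sides[1L])
    products <- splitSide(sides[2L])
    if (reversible && length(knames) != 2L) {
      stop("reversible step needs two rate names: ", ln)
    }
    if (!reversible && length(knames) != 1L) {
      stop("irreversible step needs one rate name: ", ln)
    }
    steps[[length(steps) + 1L]] <- kineticStep(
      reactants, products, knames[1L],
      if (reversible) knames[2L] else NA_character_
    )
    seen <- c(seen, reactants, products)
  }
  rates <- numeric(0)
  for (ln in rateLines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed rate line: ", ln)
    rates[trimws(kv[1L])] <- as.numeric(trimws(kv[2L]))
  }
  species <- if (length(speciesOrder)) speciesOrder else unique(seen)
  kineticScheme(species = species, steps = steps, rateConstants = rates)
}
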