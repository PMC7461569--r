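#' Read an enthalpogram from a delimited file
#'
#' Expects header columns `concentration_mol_dm3`, `dH_kJ_mol` and optional
#' `sigma`; the temperature comes from a `temperature_K` column, the
#' argument, or a `T<kelvin>` token in the filename (e.g.
#' `curve_T298.15.csv`).
#'
#' @param file Path to a CSV/TSV file.
#' @param temperature Optional temperature override, K.
#' @param sep Field separator (`","` default, `"\t"` for TSV).
#' @return An [enthalpogram()].
#' @export
read_enthalpogram <- function(file, temperature = NULL, sep = ",") {
  d <- read.csv(file, sep = sep, check.names = FALSE)
  need <- c("concentration_mol_dm3", "dH_kJ_mol")
  if (!all(need %in% names(d)))
    stop("expected columns concentration_mol_dm3 and dH_kJ_mol", call. = FALSE)
  if (is.null(temperature)) {
    if ("temperature_K" %in% names(d)) temperature <- d$temperature_K[1]
    else {
      m <- regmatches(basename(file), regexpr("T[0-9]+(\\.[0-9]+)?", basename(file)))
      temperature <- if (length(m)) as.numeric(sub("^T", "", m)) else NA_real_
    }
  }
  enthalpogram(d$concentration_mol_dm3, d$dH_kJ_mol, temperature,
               sigma = if ("sigma" %in% names(d)) d$sigma else NULL)
}

#' Write an enthalpogram to CSV
#'
#' @param curve An [enthalpogram()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_enthalpogram <- function(curve, file) {
  d <- data.frame(concentration_mol_dm3 = curve$conc, dH_kJ_mol = curve$dh)
  if (!is.null(curve[["sigma"]])) d$sigma <- curve[["sigma"]]
  tmp <- attr(curve, "temperature")
  if (!is.null(tmp) && !is.na(tmp)) d$temperature_K <- tmp
  write.csv(d, file, row.names = FALSE)
  invisible(file)
}

#' Read a three-column scattering file
#'
#' Whitespace- or comma-separated columns `Q`, `I`, `sigma` (third column
#' optional); lines starting with `#` are comments, and a comment of the
#' form `# unit: nm-1` (or `A-1`) declares the Q unit.
#'
#' @param file Path.
#' @param unit Q unit; overrides any declaration in the file.
#' @return A [scattering_curve()].
#' @export
read_scattering <- function(file, unit = NULL) {
  lines <- readLines(file)
  if (is.null(unit)) {
    decl <- grep("^#\\s*unit:", lines, value = TRUE)
    unit <- if (length(decl)) trimws(sub("^#\\s*unit:", "", decl[1])) else "nm-1"
  }
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  d <- read.table(text = gsub(",", " ", body), header = FALSE)
  scattering_curve(d[[1]], d[[2]],
                   sigma = if (ncol(d) >= 3) d[[3]] else NULL,
                   unit = match.arg(unit, c("nm-1", "A-1")))
}

#' Write a scattering curve as a three-column text file
#'
#' @param curve A [scattering_curve()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_scattering <- function(curve, file) {
  s <- if (!is.null(curve[["sigma"]])) curve[["sigma"]] else rep(NA_real_, nrow(curve))
  lines <- c(sprintf("# unit: %s", attr(curve, "unit")),
             sprintf("%.8g %.8g %.8g", curve$q, curve$intensity, s))
  writeLines(lines, file)
  invisible(file)
}
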