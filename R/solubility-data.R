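# Data model and CSV I/O for (T, P, y) solubility tables.

.R_GAS <- 8.314      # J mol-1 K-1
.M_CO2 <- 44.01      # g mol-1

#' Construct a solubility table
#'
#' A solubility table is a data frame of equilibrium mole-fraction
#' solubilities on a (temperature, pressure) grid, together with the solute
#' identity and molar mass. Missing grid cells are simply absent rows.
#'
#' @param records data frame with columns `T_K` (kelvin), `P_bar` (bar),
#'   `y2` (mole-fraction solubility in (0,1)) and optionally `u_y`
#'   (standard uncertainty of `y2`).
#' @param solute_name name of the solute.
#' @param M_solute solute molar mass in g mol^-1.
#' @return an object of class `solubility_table` (a data frame with
#'   attributes `solute_name` and `M_solute`).
#' @examples
#' tab <- solubility_table(
#'   data.frame(T_K = c(308.15, 318.15), P_bar = 200, y2 = c(1.4e-4, 1.7e-4)),
#'   solute_name = "demo", M_solute = 293.72
#' )
#' @export
solubility_table <- function(records, solute_name = "unknown", M_solute = NA_real_) {
  records <- as.data.frame(records)
  req <- c("T_K", "P_bar", "y2")
  if (!all(req %in% names(records)))
    stop("records must have columns T_K, P_bar, y2", call. = FALSE)
  if (!"u_y" %in% names(records)) records$u_y <- NA_real_
  records <- records[c("T_K", "P_bar", "y2", "u_y")]
  for (col in names(records)) {
    if (!is.numeric(records[[col]]))
      stop(sprintf("column %s is not numeric", col), call. = FALSE)
  }
  .validate_records(records)
  if (!is.na(M_solute) && M_solute <= 0) stop("M_solute must be positive", call. = FALSE)
  structure(records,
            solute_name = solute_name, M_solute = M_solute,
            class = c("solubility_table", "data.frame"))
}

.validate_records <- function(records) {
  bad <- which(!is.finite(records$T_K) | !is.finite(records$P_bar) | !is.finite(records$y2))
  if (length(bad))
    stop(sprintf("row %d: non-numeric or missing T_K/P_bar/y2", bad[1]), call. = FALSE)
  bad <- which(records$y2 <= 0 | records$y2 >= 1)
  if (length(bad))
    stop(sprintf("row %d: y2 = %g outside (0, 1)", bad[1], records$y2[bad[1]]), call. = FALSE)
  bad <- which(!is.na(records$u_y) & records$u_y < 0)
  if (length(bad))
    stop(sprintf("row %d: negative uncertainty", bad[1]), call. = FALSE)
  key <- paste(records$T_K, records$P_bar)
  if (anyDuplicated(key))
    stop(sprintf("row %d: duplicate (T, P) grid point", which(duplicated(key))[1]),
         call. = FALSE)
  invisible(records)
}

#' @export
print.solubility_table <- function(x, ...) {
  cat(sprintf("Solubility table: %s (M = %s g/mol), %d records\n",
              attr(x, "solute_name"),
              format(attr(x, "M_solute")), nrow(x)))
  iso <- sort(unique(x$T_K))
  cat(sprintf("Isotherms (K): %s\n", paste(iso, collapse = ", ")))
  cat(sprintf("Pressure range (bar): %g-%g;  y2 range: %.3g-%.3g\n",
              min(x$P_bar), max(x$P_bar), min(x$y2), max(x$y2)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read or write a solubility table as CSV
#'
#' The CSV dialect is a header `T_K,P_bar,y2,u_y` (the uncertainty column is
#' optional), full decimal precision, `.` as decimal separator. Solute
#' identity travels in `# solute:` / `# M_solute:` comment lines so that a
#' write/read round trip is the identity.
#'
#' @param path file path.
#' @param solute_name,M_solute overrides for the solute metadata; defaults
#'   are taken from the file's comment header when present.
#' @return `read_solubility()` returns a [solubility_table()];
#'   `write_solubility()` invisibly returns `path`.
#' @export
read_solubility <- function(path, solute_name = NULL, M_solute = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines))))
    stop(sprintf("%s: empty solubility file", path), call. = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(sprintf("^#\\s*%s:", key), meta, value = TRUE)
    if (length(m)) trimws(sub(sprintf("^#\\s*%s:", key), "", m[1])) else NULL
  }
  if (is.null(solute_name)) solute_name <- get_meta("solute") %||% "unknown"
  if (is.null(M_solute)) {
    m <- get_meta("M_solute")
    M_solute <- if (is.null(m)) NA_real_ else as.numeric(m)
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2) stop(sprintf("%s: no data rows", path), call. = FALSE)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        colClasses = "character", strip.white = TRUE)
  if (!all(c("T_K", "P_bar", "y2") %in% names(df)))
    stop(sprintf("%s: header must contain T_K,P_bar,y2", path), call. = FALSE)
  if (!"u_y" %in% names(df)) df$u_y <- NA
  num <- df
  for (col in c("T_K", "P_bar", "y2", "u_y")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(df[[col]]) & !is.na(df[[col]]))
    if (length(bad) && col != "u_y")
      stop(sprintf("%s: row %d: non-numeric value '%s' in column %s",
                   path, bad[1], df[[col]][bad[1]], col), call. = FALSE)
    num[[col]] <- v
  }
  solubility_table(num, solute_name = solute_name, M_solute = M_solute)
}

#' @param table a [solubility_table()].
#' @rdname read_solubility
#' @export
write_solubility <- function(table, path) {
  stopifnot(inherits(table, "solubility_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# solute: %s", attr(table, "solute_name")), con)
  writeLines(sprintf("# M_solute: %s", format(attr(table, "M_solute"), digits = 17)), con)
  utils::write.csv(format(as.data.frame(table), digits = 17, trim = TRUE,
                          scientific = NA),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mole-fraction solubility from measured amounts
#'
#' The gravimetric route reports the dissolved amount of drug and the amount
#' of CO2 in the cell; the equilibrium solubility is their mole ratio.
#'
#' @param n_drug moles of dissolved drug (>= 0).
#' @param n_co2 moles of CO2 (> 0).
#' @return mole fraction `n_drug / (n_drug + n_co2)`.
#' @examples
#' mole_fraction_from_amounts(2.9988e-5, 0.3333)
#' @export
mole_fraction_from_amounts <- function(n_drug, n_co2) {
  if (any(n_co2 <= 0)) stop("n_co2 must be positive", call. = FALSE)
  if (any(n_drug < 0)) stop("n_drug must be non-negative", call. = FALSE)
  n_drug / (n_drug + n_co2)
}

#' Convert between mole-fraction solubility and mass concentration
#'
#' The Chrastil correlation works with the solute mass concentration
#' s (kg m^-3) in the fluid phase; measurements are mole fractions. For a
#' binary solute(2) + CO2(1) phase of density `rho_co2`,
#' `s = rho_co2 * y2 * M_solute / ((1 - y2) * M_CO2)` with M_CO2 = 44.01 g/mol.
#'
#' @param y2 mole-fraction solubility in (0, 1).
#' @param rho_co2 CO2 mass density in kg m^-3.
#' @param M_solute solute molar mass in g mol^-1.
#' @return `mass_concentration()`: s in kg m^-3;
#'   `mole_fraction_from_concentration()`: y2.
#' @examples
#' s <- mass_concentration(1e-4, 700, 293.72)
#' mole_fraction_from_concentration(s, 700, 293.72)
#' @export
mass_concentration <- function(y2, rho_co2, M_solute) {
  if (any(y2 >= 1) || any(y2 <= 0)) stop("y2 must lie in (0, 1)", call. = FALSE)
  rho_co2 * y2 * M_solute / ((1 - y2) * .M_CO2)
}

#' @param s solute mass concentration in kg m^-3.
#' @rdname mass_concentration
#' @export
mole_fraction_from_concentration <- function(s, rho_co2, M_solute) {
  q <- s * .M_CO2 / (rho_co2 * M_solute)
  q / (1 + q)
}

#' Packaged solubility data sets
#'
#' `lumiracoxib_data()` returns the 31-point lumiracoxib solubility table
#' (four isotherms 308.15-338.15 K, 120-400 bar; the 338.15 K / 120 bar cell
#' was below the gravimetric detection limit and is absent).
#' `nimesulide_data()` returns the 6-point nimesulide validation table and,
#' with `source = "macnaughton"`, the literature values measured at the same
#' states that the validation is judged against.
#'
#' @return a [solubility_table()].
#' @examples
#' nrow(lumiracoxib_data())
#' @export
lumiracoxib_data <- function() {
  read_solubility(system.file("extdata", "lumiracoxib_table3.csv",
                              package = "scsolub", mustWork = TRUE))
}

#' @param source `"this_work"` for the package's measured table or
#'   `"macnaughton"` for the literature comparison values.
#' @rdname lumiracoxib_data
#' @export
nimesulide_data <- function(source = c("this_work", "macnaughton")) {
  source <- match.arg(source)
  f <- switch(source,
              this_work = "nimesulide_table2.csv",
              macnaughton = "nimesulide_macnaughton.csv")
  read_solubility(system.file("extdata", f, package = "scsolub", mustWork = TRUE))
}
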