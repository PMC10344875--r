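#' Parse a concentration with an SI molar suffix
#'
#' All concentrations inside the package are plain numerics in molar units.
#' Config files and user input may carry unit suffixes (`"10 pM"`, `"100aM"`,
#' `"1.5 nM"`); this parser converts them. Bare numerics pass through
#' unchanged and are taken to be molar already.
#'
#' @param x Numeric (molar, returned as-is) or character vector like
#'   `"10 pM"`. Recognised suffixes: aM, fM, pM, nM, uM (or µM), mM, M.
#' @return Numeric vector of molar concentrations.
#' @examples
#' parse_conc("10 pM")     # 1e-11
#' parse_conc(c("2 fM", "70 nM"))
#' @export
parse_conc <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x)) stop("concentration must be numeric (molar) or character with unit suffix")
  mult <- c(aM = 1e-18, fM = 1e-15, pM = 1e-12, nM = 1e-9,
            uM = 1e-6, mM = 1e-3, M = 1)
  vapply(x, function(s) {
    s <- gsub("µ", "u", trimws(s))
    m <- regmatches(s, regexec("^([0-9.eE+-]+)\\s*([afpnum]?M)$", s))[[1]]
    if (length(m) != 3L) stop("cannot parse concentration: '", s, "'")
    as.numeric(m[2]) * mult[[m[3]]]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Render a molar concentration with a human-readable suffix
#'
#' @param x Numeric molar concentrations.
#' @param digits Significant digits.
#' @return Character vector like `"50 pM"`.
#' @examples
#' format_conc(5e-11)  # "50 pM"
#' @export
format_conc <- function(x, digits = 3) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(as.character(v))
    if (v == 0) return("0 M")
    av <- abs(v)
    units <- c(1e-18, 1e-15, 1e-12, 1e-9, 1e-6, 1e-3, 1)
    names(units) <- c("aM", "fM", "pM", "nM", "uM", "mM", "M")
    i <- findInterval(av, units * 0.9995)
    i <- max(1L, min(i, length(units)))
    paste0(signif(v / units[i], digits), " ", names(units)[i])
  }, character(1), USE.NAMES = FALSE)
}

# round half away from zero (thermocyclers take integer cycles)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)
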