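# Reaction-equation strings: "1 A + 2 B <=> C", "lac_c + nad_c --> pyr_c ..."
# "<=>" marks a reversible reaction, "-->" an irreversible one. A side may
# be empty (exchange / demand reactions).

parse_equation <- function(text) {
  arrow <- if (grepl("<=>", text, fixed = TRUE)) "<=>"
    else if (grepl("-->", text, fixed = TRUE)) "-->"
    else stop("malformed equation (no '<=>' or '-->' arrow): '", text, "'")
  sides <- strsplit(text, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  if (length(sides) != 2L) stop("malformed equation: '", text, "'")
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric())
    terms <- strsplit(side, "\\s+\\+\\s+")[[1]]
    out <- numeric()
    for (tm in terms) {
      m <- regmatches(tm, regexec(
        "^\\s*(?:([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)\\s+)?([^\\s]+)\\s*$",
        tm, perl = TRUE))[[1]]
      if (length(m) == 0 || !nzchar(m[3])) {
        stop("malformed term '", tm, "' in equation '", text, "'")
      }
      coef <- if (nzchar(m[2])) as.numeric(m[2]) else 1
      out[m[3]] <- (out[m[3]] %||% 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  stoich <- c(lhs, numeric())
  for (id in names(rhs)) stoich[id] <- (stoich[id] %||% 0) + rhs[id]
  stoich <- stoich[stoich != 0]
  if (length(stoich) == 0) stop("equation cancels to nothing: '", text, "'")
  list(stoichiometry = stoich, reversible = arrow == "<=>")
}

format_equation <- function(stoich, reversible) {
  fmt_side <- function(s) {
    if (length(s) == 0) return("")
    paste(ifelse(s == 1, names(s), paste(num2chr(s), names(s))),
          collapse = " + ")
  }
  lhs <- -stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  paste(fmt_side(lhs), if (reversible) "<=>" else "-->", fmt_side(rhs))
}

# shortest decimal text that round-trips through as.numeric for our data
num2chr <- function(x) {
  vapply(x, function(v) {
    s <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, character(1))
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0) b
  else if (length(a) == 1 && is.na(a)) b
  else a
}
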