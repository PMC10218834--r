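#' Select atoms with a small expression language
#'
#' The grammar supports field tests (`residue_name HOH`, `residue_id 372`,
#' `residue_id 300:310`, `name O CA`, `element H`, `chain A`), the
#' keywords `protein`, `water`, `ligand`, `hydrogen` and `all`, and the
#' boolean connectives `and`, `or`, `not` with parentheses.  `protein`
#' matches the 20 standard amino-acid residue names; `water` matches
#' common water residue names (HOH, WAT, SOL, ...); `ligand` matches
#' anything that is neither protein, water, nor a monatomic ion.
#'
#' @param top topology to select from.
#' @param expression selection string.
#' @return integer vector of atom indices (class `"selection"`, ascending,
#'   unique) with the expression kept in the `"expression"` attribute.
#'   An empty result is returned as an empty selection, not an error.
#' @examples
#' ## top <- make_hbond_fixture(2.0, 150)$topology
#' ## select_atoms(top, "element O and not water")
#' @export
select_atoms <- function(top, expression) {
  toks <- .sel_tokenize(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$top <- top; st$expr <- expression
  mask <- .sel_parse_or(st)
  if (st$pos <= length(st$toks))
    .sel_err(st, "unexpected trailing token")
  idx <- which(mask)
  structure(idx, class = "selection", expression = expression)
}

#' @export
print.selection <- function(x, ...) {
  cat("selection of", length(x), "atom(s):",
      sQuote(attr(x, "expression")), "\n")
  invisible(x)
}

.sel_tokenize <- function(expr) {
  expr <- gsub("([()])", " \\1 ", expr)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  toks[nzchar(toks)]
}

.sel_err <- function(st, msg) {
  stop("selection syntax error at token ", st$pos, " (",
       if (st$pos <= length(st$toks)) sQuote(st$toks[st$pos]) else "end",
       ") in ", sQuote(st$expr), ": ", msg, call. = FALSE)
}

.sel_peek <- function(st)
  if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

.sel_parse_or <- function(st) {
  m <- .sel_parse_and(st)
  while (identical(.sel_peek(st), "or")) {
    st$pos <- st$pos + 1L
    m <- m | .sel_parse_and(st)
  }
  m
}

.sel_parse_and <- function(st) {
  m <- .sel_parse_not(st)
  while (identical(.sel_peek(st), "and")) {
    st$pos <- st$pos + 1L
    m <- m & .sel_parse_not(st)
  }
  m
}

.sel_parse_not <- function(st) {
  tok <- .sel_peek(st)
  if (is.na(tok)) .sel_err(st, "expression ended unexpectedly")
  if (tok == "not") {
    st$pos <- st$pos + 1L
    return(!.sel_parse_not(st))
  }
  if (tok == "(") {
    st$pos <- st$pos + 1L
    m <- .sel_parse_or(st)
    if (!identical(.sel_peek(st), ")")) .sel_err(st, "expected ')'")
    st$pos <- st$pos + 1L
    return(m)
  }
  .sel_parse_primary(st)
}

.sel_reserved <- c("and", "or", "not", "(", ")")

.sel_parse_primary <- function(st) {
  a <- st$top$atoms
  tok <- .sel_peek(st)
  st$pos <- st$pos + 1L
  switch(tok,
    all      = rep(TRUE, nrow(a)),
    protein  = a$resname %in% .AA3,
    water    = a$resname %in% .WATER_RES,
    hydrogen = a$element == "H",
    ligand   = !(a$resname %in% c(.AA3, .WATER_RES, .ION_RES)),
    residue_name = ,
    resname  = a$resname %in% .sel_values(st),
    name     = a$name %in% .sel_values(st),
    element  = a$element %in% .sel_values(st),
    chain    = a$chain %in% .sel_values(st),
    residue_id = ,
    resid    = a$resid %in% .sel_id_values(st),
    { st$pos <- st$pos - 1L; .sel_err(st, "unknown keyword or field") })
}

.sel_values <- function(st) {
  vals <- character(0)
  repeat {
    tok <- .sel_peek(st)
    if (is.na(tok) || tok %in% .sel_reserved) break
    vals <- c(vals, tok)
    st$pos <- st$pos + 1L
  }
  if (!length(vals)) .sel_err(st, "field needs at least one value")
  vals
}

.sel_id_values <- function(st) {
  vals <- integer(0)
  got <- FALSE
  repeat {
    tok <- .sel_peek(st)
    if (is.na(tok) || tok %in% .sel_reserved) break
    if (grepl("^-?[0-9]+:-?[0-9]+$", tok)) {
      ab <- as.integer(strsplit(tok, ":")[[1]])
      vals <- c(vals, ab[1]:ab[2])
    } else if (grepl("^-?[0-9]+$", tok)) {
      vals <- c(vals, as.integer(tok))
    } else .sel_err(st, "residue_id values must be integers or a:b ranges")
    got <- TRUE
    st$pos <- st$pos + 1L
  }
  if (!got) .sel_err(st, "residue_id needs at least one value")
  vals
}

#' Coerce indices to a selection
#' @param idx integer atom indices.
#' @param expression provenance string.
#' @return a `"selection"`.
#' @export
as_selection <- function(idx, expression = "<indices>") {
  idx <- sort(unique(as.integer(idx)))
  structure(idx, class = "selection", expression = expression)
}
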